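---
title: "Volumetric pocket detection with equivariant non-expansive operators"
author: "geneopocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric pocket detection with equivariant non-expansive operators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneopocket)
```

## The model

Ligand-binding pockets are cavities in the empty space around a protein
whose local physicochemical environment favors small-molecule binding.
`geneopocket` detects them volumetrically. The space around the protein is
discretized into a grid of cubic voxels (default spacing 1 Å, padding 5 Å
beyond the van der Waals bounding box), and eight scalar potentials
("channels") are evaluated at every voxel center $x$:

| channel | type | definition |
|---|---|---|
| distance | geometric | $d(x, x_{a^*}) - r_{a^*}$, nearest atom $a^*$ |
| gravitational | geometric | $\sum_a m(a) / d(x, x_a)$ |
| electrostatic | physical | $\sum_a q(a) / d(x, x_a)$ |
| lipophilic | chemical | $\sum_a l(a) / d(x, x_a)$, negative lipophilicity part |
| hydrophilic | chemical | $\sum_a h(a) / d(x, x_a)$, positive part |
| polar | chemical | $\sum_a p(a) / d(x, x_a)$, indicator $p$ |
| HB acceptor | chemical | $\sum_a -\varepsilon_a (R^6 - 2R^4)$, $R = R_{min}/d + 0.96$ |
| HB donor | chemical | acceptor term $\times \cos^2\phi_1 \cos^2\phi_2$ over bonded H |

The sums run over atoms within a spherical neighborhood of the voxel
(default 10 Å); distances are clamped below at half the voxel spacing so
that the $1/d$ potentials stay bounded inside atoms. Each channel is then
min-max normalized to $[0, 1]$ per protein, so only the spatial *shape* of
each potential matters — the absolute parameter scales (charges,
lipophilicity magnitudes, well depths) wash out, which is why the bundled
atom-parameter table only needs defensible sign and ordering conventions.

Each normalized channel $\varphi_i$ is filtered by a convolutional operator
$F_i(\varphi_i) = \varphi_i * K_i$ whose kernel is sampled from a radial
profile, truncated and normalized to unit $L^1$ norm. Radial symmetry makes
every $F_i$ *equivariant*: rotating or translating the protein rotates the
output fields without changing them otherwise. $\|K\|_1 = 1$ together with
convexity makes the pipeline *non-expansive*: a sup-norm perturbation of
the inputs can never be amplified, which gives stability to noise and to
small conformational changes. The filtered fields are combined convexly
with weights $\alpha_1, \dots, \alpha_8$ (interpretable as channel
importances), min-max normalized over the empty-space voxels into a pocket
likelihood $\psi \in [0,1]$, and thresholded strictly at $\theta$. Connected
components of $\{\psi > \theta\}$ within the empty-space mask (26-neighbor
connectivity by default) are the pockets.

The model therefore has exactly 17 learnable parameters: 8 kernel widths
$\sigma_i$, 8 convex weights $\alpha_i$, and the threshold $\theta$.

## Scoring and ranking

A pocket's druggability score is its mean likelihood adjusted for volume,
$\mathrm{score}(P) = \overline{\psi}(P)\,\bigl(1 - e^{-V_P / V_{ref}}\bigr)$
with $V_{ref} = 30$ voxels. The exact form of the volume adjustment is a
design choice of this package: it is bounded, strictly increasing in
volume (removing the bias toward tiny high-mean components), and preserves
mean-likelihood ordering at equal volume. Ties are broken by larger
volume, then lower component label. Pocket summaries add the centroid,
equivalent-sphere radius, hydrogen-bond acceptor/donor contacts within
4 Å, mean lipophilicity/polarity descriptors, and a "small" flag below
100 Å³.

## Training

The loss to maximize compares the thresholded output $\widehat\psi$ with a
ground-truth mask $\tau$ (voxels overlapping the co-crystallized ligand's
heavy-atom spheres, by an exact sphere–box test):

$$L(\widehat\psi, \tau) =
  \frac{|\widehat\psi \wedge \tau| + k\,|(1-\widehat\psi) \wedge (1-\tau)|}
       {|\tau| + k\,|1 - \tau|} \in [0, 1].$$

$k = 0$ gives plain recall of the true pocket, $k = 1$ plain voxel
accuracy; the default $k = 0.02$ sits in the range where the loss balances
the heavy class imbalance between pocket and background voxels while still
penalizing over-prediction.

The hard threshold is not differentiable, so optimization goes through a
logistic surrogate $\sigma\!\left((\psi - \theta)/T\right)$ whose
temperature anneals linearly from 0.1 to 0.01 over the epochs; all
reported losses use the hard threshold. Gradients are computed in closed
form (the adjoint of the convolution gives the kernel gradients; the
min/max of the output normalization are treated as constants, the usual
stop-gradient convention), and parameters are updated with Adam
(learning rate 0.01, 50 epochs by default) one example at a time with
seeded shuffling — grids differ in shape across proteins, so there is no
natural batching, and per-example updates keep runs exactly reproducible.
Constraints are enforced by re-parameterization: $\alpha$ by softmax,
$\theta$ by a logistic, $\sigma$ by a softplus above the floor
$0.25 \times$ spacing. During optimization the kernel tap support is
frozen at the radius implied by the initial $\sigma$ (3$\sigma$ for the
Gaussian family), so the parameter space has a fixed dimension and
$\sigma$ reshapes the profile inside that stencil.

Two ablation variants drop the structural guarantees for comparison:
`NE-NE` replaces the radial kernels with fully free taps re-normalized to
unit $L^1$ norm in the forward pass (non-expansive but not equivariant),
and `NE-E` uses raw free taps (neither property). Both are trained with
the same surrogate; their kernel gradients flow through the
$L^1$-normalization where applicable.

Multi-restart selection trains one model per training set and keeps the
one with the highest top-$n$ identification coefficient on a validation
set, ties going to the lower restart index.

## Evaluation

A predicted pocket *matches* the truth if it has the largest overlap
$|P \cap \tau| / |\tau|$; if no pocket intersects the truth the method
*failed* on that protein. With $n$ the protein's number of true pockets,
$H_{n}$ is the fraction of proteins matched within the first $n$ ranked
pockets, $H_{n+j}$ ($j \ge 1$) the fraction matched exactly at rank
$n + j$, and $T_{n+j}$ the cumulative sum. Failures enter no $H$ bucket
and are reported separately, so buckets plus failures partition the data
set. Distance metrics follow the conventions of the pocket-prediction
literature: DCA is the minimal distance from the prediction centroid to
any ligand heavy atom, DCC the distance between truth and prediction
centroids, and success curves report the fraction of proteins strictly
below thresholds from 4 to 20 Å, with per-protein values taken as the best
among the top $n + 2$ ranked pockets.

## Numerical choices and degenerate inputs

* **Strict threshold.** $\psi > \theta$, so voxels exactly at the
  threshold are background; $\theta = 1$ yields zero pockets.
* **Constant fields.** A channel (or combined output) constant over its
  normalization domain maps to 0.5 rather than an arbitrary extreme.
* **Inside-atom singularities.** $1/d$ sums clamp $d$ at spacing/2. The
  hydrogen-bond terms additionally cap the reduced distance $R$ at 2: the
  repulsive branch grows like $R^6$ and a voxel near an atom center would
  otherwise dominate the min-max normalization and flatten the channel
  everywhere else. The cap preserves the attractive well exactly — the
  per-atom term still peaks at $32/27\,\varepsilon$ at $R = \sqrt{4/3}$
  and vanishes at $R = \sqrt 2$ — and retains a bounded repulsion of
  $-32\varepsilon$.
* **Donor geometry.** $\phi_1$ is the angle between the D→H bond and the
  H→x direction (contribution zeroed beyond 90°), $\phi_2$ the angle
  between antecedent→D and D→x ($\cos^2\phi_2 := 1$ when the donor has no
  heavy-atom antecedent); the angular factor is maximized over the donor's
  hydrogens. This gives 1 on an ideal linear hydrogen bond and decays
  smoothly.
* **Truth mask edge cases.** Tangency (zero-volume contact) does not mark
  a voxel; a zero-radius point on a voxel corner marks only the half-open
  cube that owns it.
* **Empty-space masking** is applied at thresholding, not to $\psi$
  itself, so scores are computed on a smooth field.
* **Kernel stencils** are capped to the grid so small test grids remain
  usable; `applyGeneo` still rejects kernels larger than the field.

## Synthetic data: what it emulates and what it does not

Two generators make the package fully testable without external data.
`makeShellComplex` builds a quasi-uniform spherical shell of C/N/O atoms
(Fibonacci lattice, 70/15/15 element mix, radius 8 Å by default) with an
opening cap as the pocket mouth and a 5-atom ligand cluster at the center,
written as valid PDB; half of the N/O atoms carry an inward-pointing
hydrogen so the donor channel is non-degenerate. `makePhantomChannels`
builds channel stacks directly: per-channel ball indicators plus i.i.d.
Gaussian noise (σ = 0.1 by default), min-max normalized, with a concentric
truth ball. For parameter-recovery experiments, `generateFromModel` gives
every channel its *own* random ball so the convex weights are identifiable,
runs a known model, and takes its top pocket as the truth.

These fixtures exercise the geometry, the operator algebra, training and
the metrics end to end, but they are not proteins: shells have no
secondary structure, no realistic packing, charges are a simple
per-element table, and phantom noise is spatially white. Passing tests
demonstrate that the machinery is implemented correctly and that the
training recovers generating parameters under controlled conditions — not
that the default parameters are competitive on real structures, which
requires training on curated complexes.

## Problem sizes used by the checks

The test suite and the acceptance script train on desk-scale versions of
the study design: phantom recovery uses 24 training and 12 held-out
12³-voxel phantoms from a generating model with a near-vertex weight
vector (50 epochs); the shell experiment trains on 8 shell complexes at
1.25 Å spacing (30 epochs) and evaluates top-1 cavity retrieval on 20
fresh shells; equivariance is checked over all 24 proper 90° grid
rotations of a cubic shell grid. These sizes were chosen as the smallest
at which the properties of interest are informative; the package itself
has no intrinsic size limits beyond the configurable voxel-count cap.

## Known limitations

* Channel normalization is per protein, so absolute $\psi$ values are not
  comparable across proteins; rankings and within-protein scores are.
* The distance channel enters the convex combination as computed (large in
  open space); per-channel orientation flips are available in
  `normalizeChannels` when a model family needs inverted polarity, and the
  default kernels compensate with a signed difference-of-Gaussians on the
  distance channel.
* Subcavity splitting is out of scope: a pocket is exactly a connected
  component above threshold.
* Bond inference is geometric (covalent radii + 0.4 Å); exotic
  coordination chemistry may mis-assign donors.
* `NE-E` deliberately voids the non-expansivity guarantee; it exists only
  for ablation comparisons.

## A minimal session

```{r, eval = FALSE}
pdb <- makeShellComplex(shellComplexSpec(seed = 1))
res <- predictPockets(paste(pdb, collapse = "\n"), geneoModel(),
                      ligand = "LIG")
pocketTable(res$prediction)

truth <- ligandTruthMask(res$structure, stackGrid(res$stack))
matchRank(res$prediction, truth)
```
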