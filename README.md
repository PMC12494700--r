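# geneopocket

Volumetric detection and ranking of protein ligand-binding pockets with
group-equivariant non-expansive operators.

## What it does, and for whom

Structure-based virtual screening needs the binding pocket before it can
dock anything. `geneopocket` is for computational chemists and structural
bioinformaticians who want an interpretable, light-weight pocket detector:
it voxelizes the empty space around a protein, evaluates eight
physicochemical potentials per voxel — signed distance to the molecular
surface, mass ("gravitational"), partial-charge (electrostatic),
lipophilic, hydrophilic and polar inverse-distance sums, and
hydrogen-bond acceptor/donor wells — and processes them with a single
layer of convolutional operators whose kernels are radially symmetric and
L1-normalized. Radial symmetry makes the operators equivariant to rigid
motions of the protein; unit L1 norm plus a convex combination makes the
whole pipeline 1-Lipschitz in sup norm (non-expansive), i.e. provably
stable to input perturbations.

The combined, normalized output field ψ ∈ [0, 1] is read as a pocket
likelihood; connected components of {ψ > θ} in the empty space are the
pockets, ranked by the volume-adjusted mean score
`mean(ψ) · (1 − exp(−V/V_ref))`. The model has exactly **17 learnable
parameters** — eight kernel widths σᵢ, eight convex weights αᵢ (channel
importances), and the threshold θ — trained against co-crystallized ligand
masks by maximizing the volumetric loss

    L(ψ̂, τ) = (|ψ̂ ∧ τ| + k·|(1−ψ̂) ∧ (1−τ)|) / (|τ| + k·|1−τ|)  ∈ [0, 1]

with Adam through a temperature-annealed soft threshold. Evaluation
implements the field's ranking metrics (H/T top-n coefficients, volumetric
overlap, DCA/DCC distance-success curves).

Everything is exercisable offline: deterministic generators build shell
"proteins" with a central cavity as valid PDB, and phantom channel stacks
with known ground truth.

## Worked example

```r
library(geneopocket)

# a synthetic complex: a spherical shell protein with a ligand in the cavity
pdb <- makeShellComplex(shellComplexSpec(seed = 1))
res <- predictPockets(paste(pdb, collapse = "\n"), geneoModel(theta = 0.6),
                      ligand = "LIG")
pocketTable(res$prediction)[, c("rank", "score", "meanPsi", "volume",
                                "cx", "cy", "cz", "radius", "hba", "hbd",
                                "small")]
#>   rank score meanPsi volume      cx    cy    cz radius hba hbd small
#> 1    1 0.695   0.695  11373 -0.0406 0.366 -1.09     14  63  30 FALSE

truth <- ligandTruthMask(res$structure, stackGrid(res$stack))
matchRank(res$prediction, truth)
#> [1] 1
```

The single detected pocket covers the cavity (the ligand sits at the
origin; the pocket centroid is within ~1 Å of it), its score is the
volume-adjusted mean likelihood, and `hba`/`hbd` count the acceptor/donor
protein atoms within 4 Å of the pocket. `matchRank` returns 1: the
top-ranked pocket has the largest overlap with the ligand mask.

Training on model-generated phantoms (each channel carries its own signal
ball, so the weights are identifiable):

```r
gen <- geneoModel(alpha = c(0.01, 0.93, rep(0.01, 6)), theta = 0.6)
exs <- generateFromModel(gen, 8, seed = 7)
fit <- fitGeneo(exs, trainingConfig(epochs = 10, seed = 1))
fit
#> FitResult [E-NE]: 10 epochs, final train loss 0.9715
fittedModel(fit)
#> GENEOModel [E-NE]
#>   sigma: 2.302 1.620 1.783 1.734 1.816 1.794 1.748 1.773
#>   alpha: 0.083 0.199 0.110 0.143 0.105 0.112 0.141 0.108
#>   theta: 0.423   connectivity: 26
```

After 10 epochs the weight on the generating channel (α₂) is already the
largest; the acceptance run below trains for 50 epochs and recovers it to
within 0.15.

A thin command-line wrapper ships in `inst/exec/geneopocket`
(`predict` / `train` / `evaluate` / `simulate` subcommands).

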