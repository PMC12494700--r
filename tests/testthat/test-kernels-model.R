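# Kernels, convolution, convex combination, thresholding, labeling,
# scoring and the operator pipeline.

test_that("kernels are L1-normalized and centrally symmetric", {
  for (fam in c("gaussian", "difference_of_gaussians", "spherical_shell")) {
    k <- buildKernel(fam, sigma = 1.3, spacing = 1)
    expect_equal(sum(abs(k$taps)), 1, tolerance = 1e-12, label = fam)
    expect_equal(k$taps, k$taps[rev(seq_len(dim(k$taps)[1])),
                                rev(seq_len(dim(k$taps)[2])),
                                rev(seq_len(dim(k$taps)[3]))],
                 label = paste(fam, "symmetry"))
  }
})

test_that("a kernel at the sigma floor is close to the identity tap", {
  k <- buildKernel("gaussian", sigma = 0.25, spacing = 1)
  ctr <- (dim(k$taps) + 1) %/% 2
  expect_gte(k$taps[ctr[1], ctr[2], ctr[3]], 0.9)
  expect_error(buildKernel("gaussian", sigma = 0.2, spacing = 1),
               class = "geneo_parameter_floor")
})

test_that("analytic kernel gradients match finite differences", {
  for (fam in c("gaussian", "difference_of_gaussians", "spherical_shell")) {
    s <- 1.5; h <- 1e-6
    k <- buildKernel(fam, s, spacing = 1, radius = 5, grad = TRUE)
    kp <- buildKernel(fam, s + h, spacing = 1, radius = 5)
    km <- buildKernel(fam, s - h, spacing = 1, radius = 5)
    expect_equal(k$dtaps, (kp$taps - km$taps) / (2 * h), tolerance = 1e-5,
                 label = fam)
  }
})

test_that("convolution matches the direct-summation oracle", {
  set.seed(42)
  for (rep in 1:3) {
    f <- array(rnorm(6 * 5 * 7), dim = c(6, 5, 7))
    taps <- array(rnorm(27), dim = c(3, 3, 3))
    expect_equal(applyGeneo(f, taps), convOracle(f, taps),
                 tolerance = 1e-12)
  }
})

test_that("identity, averaging and impulse convolution behave as expected", {
  f <- array(runif(5^3), dim = c(5, 5, 5))
  idK <- array(0, dim = c(3, 3, 3)); idK[2, 2, 2] <- 1
  expect_equal(applyGeneo(f, idK), f)
  # constant input far from the boundary stays 1 under a unit-sum kernel
  k <- buildKernel("gaussian", 0.5, 1)
  ones <- array(1, dim = c(9, 9, 9))
  out <- applyGeneo(ones, k)
  ctr <- out[4:6, 4:6, 4:6]
  expect_equal(as.numeric(ctr), rep(1, 27), tolerance = 1e-12)
  # impulse reproduces the taps
  imp <- array(0, dim = c(7, 7, 7)); imp[4, 4, 4] <- 1
  kt <- buildKernel("gaussian", 0.6, 1, radius = 2)$taps
  expect_equal(applyGeneo(imp, kt)[2:6, 2:6, 2:6], kt, tolerance = 1e-15)
  expect_error(applyGeneo(array(0, dim = c(3, 3, 3)),
                          array(1, dim = c(5, 5, 5))),
               class = "geneo_kernel_too_large")
})

test_that("convex combination respects the simplex and its bounds", {
  fields <- lapply(1:8, function(i) array(i / 8, dim = c(3, 3, 3)))
  a <- c(1, rep(0, 7))
  expect_equal(convexCombine(fields, a), fields[[1]])
  same <- lapply(1:8, function(i) fields[[3]])
  expect_equal(convexCombine(same, rep(1 / 8, 8)), fields[[3]])
  two <- convexCombine(list(array(0, dim = c(2, 2, 2)),
                            array(1, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2)),
                            array(0.5, dim = c(2, 2, 2))),
                       c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(two), rep(0.5, 8))
  expect_error(convexCombine(fields, rep(0.2, 8)),
               class = "geneo_invalid_weights")
  # pointwise convexity bound on random fields
  set.seed(1)
  fl <- lapply(1:8, function(i) array(rnorm(27), dim = c(3, 3, 3)))
  al <- runif(8); al <- al / sum(al)
  cmb <- convexCombine(fl, al)
  mn <- Reduce(pmin, fl); mx <- Reduce(pmax, fl)
  expect_true(all(cmb >= mn - 1e-12 & cmb <= mx + 1e-12))
})

test_that("output normalization uses the empty-space voxels only", {
  f <- array(0, dim = c(2, 2, 2)); f[1:4] <- c(-1, 3, 1, 2)
  f[5:8] <- 100   # masked out: must not influence the rescale
  mask <- array(c(rep(TRUE, 4), rep(FALSE, 4)), dim = c(2, 2, 2))
  psi <- normalizeOutput(f, mask)
  expect_equal(psi[1, 1, 1], 0)
  expect_equal(psi[2, 1, 1], 1)
  expect_equal(psi[1, 2, 1], 0.5)
  expect_true(all(psi <= 1))   # off-mask values clamped
  cst <- normalizeOutput(array(7, dim = c(2, 2, 2)),
                         array(TRUE, dim = c(2, 2, 2)))
  expect_true(all(cst == 0.5))
  expect_error(normalizeOutput(f, array(FALSE, dim = c(2, 2, 2))),
               class = "geneo_empty_space")
})

test_that("thresholding is strict and masked", {
  psi <- array(c(0.2, 0.5, 0.7, 0.9), dim = c(4, 1, 1))
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), dim = c(4, 1, 1))
  out <- hardThreshold(psi, 0.5, mask)
  expect_equal(as.logical(out), c(FALSE, FALSE, TRUE, FALSE))  # 0.5 is not > 0.5
  expect_true(all(hardThreshold(psi, 0, array(TRUE, dim = dim(psi)))))
  expect_false(any(hardThreshold(psi, 1, mask)))
})

test_that("labeling honors the connectivity and scan order", {
  b <- array(FALSE, dim = c(4, 4, 4))
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE   # touch only at a corner
  l26 <- labelPockets(b, 26)
  expect_equal(max(l26), 1L)
  l6 <- labelPockets(b, 6)
  expect_equal(max(l6), 2L)
  expect_equal(l6[1, 1, 1], 1L)   # scan order: first-encountered is label 1
  expect_equal(max(labelPockets(array(FALSE, dim = c(3, 3, 3)), 26)), 0L)
  # determinism
  expect_identical(labelPockets(b, 18), labelPockets(b, 18))
})

test_that("scoring follows the volume-adjusted mean and its tie rules", {
  psi <- array(0, dim = c(10, 10, 10))
  labels <- array(0L, dim = c(10, 10, 10))
  # pocket 1: single voxel with mean 0.9; pocket 2: 200 voxels with 0.7
  labels[1, 1, 1] <- 1L; psi[1, 1, 1] <- 0.9
  vox2 <- which(labels == 0)[1:200]
  labels[vox2] <- 2L; psi[vox2] <- 0.7
  pk <- scoreAndRank(psi, labels, volumeRef = 30)
  expect_equal(pk$label[pk$rank == 1], 2L)   # the large pocket outranks
  expect_equal(pk$score[pk$rank == 1], 0.7 * (1 - exp(-200 / 30)),
               tolerance = 1e-12)
  expect_equal(pk$score[pk$rank == 2], 0.9 * (1 - exp(-1 / 30)),
               tolerance = 1e-12)
  # equal volume: higher mean psi wins
  l2 <- array(0L, dim = c(6, 6, 6)); p2 <- array(0, dim = c(6, 6, 6))
  l2[1:5, 1, 1] <- 1L; p2[1:5, 1, 1] <- 0.6
  l2[1:5, 3, 1] <- 2L; p2[1:5, 3, 1] <- 0.9
  pk2 <- scoreAndRank(p2, l2)
  expect_equal(pk2$label[pk2$rank == 1], 2L)
  # single pocket is rank 1 regardless of score
  l3 <- array(0L, dim = c(3, 3, 3)); l3[1, 1, 1] <- 1L
  expect_equal(scoreAndRank(array(0.01, dim = c(3, 3, 3)), l3)$rank, 1L)
})

test_that("pocket summaries report centroid, radius and the small flag", {
  grid <- VoxelGrid(c(0, 0, 0), 1, c(6L, 6L, 6L))
  st <- stackFromArrays(lapply(1:8, function(i) array(0.5, dim = c(6, 6, 6))),
                        grid = grid, normalized = TRUE)
  labels <- array(0L, dim = c(6, 6, 6))
  labels[3, 4, 5] <- 1L
  psi <- array(0.8, dim = c(6, 6, 6))
  pk <- summarizePockets(scoreAndRank(psi, labels), psi, labels, st)
  expect_equal(c(pk$cx, pk$cy, pk$cz), c(2.5, 3.5, 4.5))
  expect_true(pk$small)   # 1 A^3 < 100 A^3
  expect_equal(pk$radius, (3 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  # 2x2x2 block: centroid at the block center
  labels2 <- array(0L, dim = c(6, 6, 6)); labels2[3:4, 3:4, 3:4] <- 1L
  pk2 <- summarizePockets(scoreAndRank(psi, labels2), psi, labels2, st)
  expect_equal(c(pk2$cx, pk2$cy, pk2$cz), c(3, 3, 3))
})

test_that("the pipeline recovers a constructed ball as a single pocket", {
  grid <- VoxelGrid(c(0, 0, 0), 1, c(14L, 14L, 14L))
  cc <- voxelCenters(grid)
  ball <- array(sqrt(colSums((t(cc) - 7)^2)) <= 3, dim = c(14, 14, 14))
  arrays <- c(list(array(as.numeric(ball), dim = dim(ball))),
              lapply(2:8, function(i) array(0.5, dim = dim(ball))))
  stack <- stackFromArrays(arrays, grid = grid, normalized = TRUE)
  m <- geneoModel(sigma = rep(0.5, 8), alpha = c(1, rep(0, 7)), theta = 0.6,
                  families = rep("gaussian", 8))
  pred <- detectPockets(stack, m)
  expect_equal(nrow(pocketTable(pred)), 1L)
  vox <- pocketVoxels(pred, 1)
  expect_true(all(ball[vox]))
  expect_gt(length(vox), 0.5 * sum(ball))
  # theta = 1 gives zero pockets
  m1 <- geneoModel(sigma = rep(0.5, 8), alpha = c(1, rep(0, 7)), theta = 1,
                   families = rep("gaussian", 8))
  expect_equal(nrow(pocketTable(detectPockets(stack, m1))), 0L)
})

test_that("identical inputs give identical label fields across runs", {
  ph <- makePhantomChannels(phantomSpec(seed = 9))
  m <- geneoModel()
  p1 <- detectPockets(ph$stack, m)
  p2 <- detectPockets(ph$stack, m)
  expect_identical(pocketLabels(p1), pocketLabels(p2))
  expect_identical(pocketTable(p1), pocketTable(p2))
})

test_that("non-expansivity holds through convolution and convex combination", {
  m <- geneoModel()
  kerns <- lapply(1:8, function(i)
    buildKernel(m@families[i], m@sigma[i], 1, radius = 3)$taps)
  set.seed(11)
  worst <- 0
  for (rep in 1:20) {
    s1 <- randomStack(rep)
    s2 <- randomStack(rep + 1000)
    dIn <- max(abs(unlist(stackChannels(s1)) - unlist(stackChannels(s2))))
    o1 <- convexCombine(lapply(1:8, function(i)
      applyGeneo(stackChannels(s1)[[i]], kerns[[i]])), m@alpha)
    o2 <- convexCombine(lapply(1:8, function(i)
      applyGeneo(stackChannels(s2)[[i]], kerns[[i]])), m@alpha)
    worst <- max(worst, max(abs(o1 - o2)) - dIn)
  }
  expect_lte(worst, 1e-12)
})

test_that("an L1 norm above 1 can violate non-expansivity", {
  expK <- array(0, dim = c(3, 3, 3)); expK[2, 2, 2] <- 2   # L1 norm 2
  f1 <- array(0, dim = c(5, 5, 5))
  f2 <- array(1, dim = c(5, 5, 5))
  dOut <- max(abs(applyGeneo(f1, expK) - applyGeneo(f2, expK)))
  expect_gt(dOut, max(abs(f1 - f2)))
})

test_that("NE variants run the pipeline on free taps", {
  ph <- makePhantomChannels(phantomSpec(seed = 33))
  m <- geneoModel(theta = 0.6)
  base <- detectPockets(ph$stack, m)
  # free taps equal to the parametric kernels reproduce the E-NE output
  taps <- lapply(1:8, function(i)
    buildKernel(m@families[i], m@sigma[i], 1,
                radius = min(kernelRadius(m@families[i], m@sigma[i], 1, 3),
                             5L))$taps)
  mNN <- geneoModel(theta = 0.6, variant = "NE-NE", taps = taps)
  predNN <- detectPockets(ph$stack, mNN)
  expect_equal(pocketField(predNN), pocketField(base), tolerance = 1e-12)
  expect_identical(pocketLabels(predNN), pocketLabels(base))
  # NE-NE re-normalizes scaled taps, NE-E uses them raw
  mScaled <- geneoModel(theta = 0.6, variant = "NE-NE",
                        taps = lapply(taps, function(t) 3 * t))
  expect_equal(pocketField(detectPockets(ph$stack, mScaled)),
               pocketField(base), tolerance = 1e-12)
  mE <- geneoModel(theta = 0.6, variant = "NE-E",
                   taps = lapply(taps, function(t) 3 * t))
  predE <- detectPockets(ph$stack, mE)
  expect_s4_class(predE, "PocketPrediction")
})

test_that("the full pipeline commutes with grid rotations", {
  ph <- makePhantomChannels(phantomSpec(seed = 21, dims = c(12L, 12L, 12L),
                                        center = c(4, 5, 7), radius = 2.5))
  m <- geneoModel(theta = 0.6)
  base <- detectPockets(ph$stack, m)
  for (R in gridRotations()[c(2, 7, 13, 20)]) {
    rotStack <- stackFromArrays(lapply(stackChannels(ph$stack),
                                       function(a) rotateField(a, R)),
                                grid = stackGrid(ph$stack),
                                normalized = TRUE)
    rotPred <- detectPockets(rotStack, m)
    expect_equal(pocketField(rotPred), rotateField(pocketField(base), R),
                 tolerance = 1e-10)
    expect_equal(nrow(pocketTable(rotPred)), nrow(pocketTable(base)))
    expect_equal(sort(pocketTable(rotPred)$score),
                 sort(pocketTable(base)$score), tolerance = 1e-10)
  }
})
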