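# Grid construction, the eight potentials, normalization and the truth mask.

test_that("grid covers the padded bounding box with ceil(extent/spacing) voxels", {
  g <- buildGrid(data.frame(x = 0, y = 0, z = 0, vdw = 1.5),
                 spacing = 1, padding = 2.5)
  expect_equal(gridDims(g), c(8L, 8L, 8L))
  expect_equal(gridOrigin(g), c(-4, -4, -4))
  g2 <- buildGrid(data.frame(x = 0, y = 0, z = 0, vdw = 1),
                  spacing = 1, padding = 0)
  expect_equal(gridDims(g2), c(2L, 2L, 2L))
  expect_error(buildGrid(data.frame(x = 0, y = 0, z = 0, vdw = 1),
                         spacing = 0), class = "geneo_bad_argument")
  expect_error(buildGrid(data.frame(x = 0, y = 0, z = 0, vdw = 1),
                         spacing = 0.01, padding = 50),
               class = "geneo_grid_too_large")
})

# a voxel grid whose single voxel center sits at a chosen point
pointGrid <- function(p, spacing = 1) {
  VoxelGrid(p - spacing / 2, spacing, c(1L, 1L, 1L))
}

test_that("distance channel is signed distance to the nearest atom sphere", {
  at <- toyAtoms(c(0, 10), c(0, 0), c(0, 0), element = c("C", "C"))
  at$vdw <- c(1.5, 1)
  st <- computeChannels(at, grid = pointGrid(c(3, 0, 0)), normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st)$distance), 3 - 1.5)
  st2 <- computeChannels(at, grid = pointGrid(c(0, 0, 0)), normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st2)$distance), -1.5)
  # nearest-atom selection at (1,0,0): first atom wins
  st3 <- computeChannels(at, grid = pointGrid(c(1, 0, 0)), normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st3)$distance), 1 - 1.5)
  expect_false(as.logical(emptySpaceMask(st3)))
})

test_that("inverse-distance channels sum coefficient over distance", {
  at <- toyAtoms(0, 0, 0, element = "C")
  at$mass <- 12; at$charge <- -0.4; at$lipo <- -1; at$polar <- 1L
  st <- computeChannels(at, grid = pointGrid(c(2, 0, 0)), normalize = FALSE)
  ch <- stackChannels(st)
  expect_equal(as.numeric(ch$gravitational), 6)     # 12 / 2
  expect_equal(as.numeric(ch$electrostatic), -0.2)  # -0.4 / 2
  expect_equal(as.numeric(ch$lipophilic), -0.5)     # negative part
  expect_equal(as.numeric(ch$hydrophilic), 0)       # positive part empty
  expect_equal(as.numeric(ch$polar), 0.5)
  # a hydrophilic atom feeds phi5 and contributes 0 to phi4
  at$lipo <- 1
  st2 <- computeChannels(at, grid = pointGrid(c(2, 0, 0)), normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st2)$lipophilic), 0)
  expect_equal(as.numeric(stackChannels(st2)$hydrophilic), 0.5)
})

test_that("sum channels respect the cutoff and the distance clamp", {
  at <- toyAtoms(c(0, 50), c(0, 0), c(0, 0), element = c("C", "C"))
  at$mass <- c(12, 1e6)
  st <- computeChannels(at, grid = pointGrid(c(2, 0, 0)), cutoff = 10,
                        normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st)$gravitational), 6)  # far atom ignored
  # voxel on the atom center: d clamped at spacing/2
  st2 <- computeChannels(at[1, ], grid = pointGrid(c(0, 0, 0)),
                         normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st2)$gravitational), 12 / 0.5)
})

test_that("acceptor potential matches the analytic well", {
  # R = sqrt(4/3) maximizes -(R^6 - 2 R^4) at 32/27
  dstar <- 1.9 / (sqrt(4 / 3) - 0.96)
  at <- toyAtoms(0, 0, 0, element = "O")
  st <- computeChannels(at, grid = pointGrid(c(dstar, 0, 0)), cutoff = 15,
                        normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st)$hb_acceptor), 32 / 27,
               tolerance = 1e-12)
  # R = sqrt(2) is a root
  dzero <- 1.9 / (sqrt(2) - 0.96)
  st2 <- computeChannels(at, grid = pointGrid(c(dzero, 0, 0)),
                         normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st2)$hb_acceptor), 0,
               tolerance = 1e-12)
  # no acceptors in range -> identically zero
  atc <- toyAtoms(0, 0, 0, element = "C")
  st3 <- computeChannels(atc, grid = pointGrid(c(3, 0, 0)),
                         normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st3)$hb_acceptor), 0)
})

test_that("donor potential applies the angular factors", {
  # antecedent C - donor O - H - x all collinear: factor 1
  at <- toyAtoms(c(-1.4, 0, 0.96), c(0, 0, 0), c(0, 0, 0),
                 element = c("C", "O", "H"), resno = c(1, 1, 1))
  dstar <- 1.9 / (sqrt(4 / 3) - 0.96)
  st <- computeChannels(at, grid = pointGrid(c(dstar, 0, 0)), cutoff = 15,
                        normalize = FALSE)
  expect_equal(as.numeric(stackChannels(st)$hb_donor), 32 / 27,
               tolerance = 1e-10)
  # x placed perpendicular to the D->H bond at H: contribution 0
  xperp <- c(0.96, 3, 0)
  stp <- computeChannels(at, grid = pointGrid(xperp), normalize = FALSE)
  dOx <- sqrt(sum(xperp^2))
  expect_equal(as.numeric(stackChannels(stp)$hb_donor), 0, tolerance = 1e-12)
  # no donors -> zero everywhere
  atc <- toyAtoms(c(0, 3), c(0, 0), c(0, 0), element = c("C", "C"))
  stn <- computeChannels(atc, grid = pointGrid(c(1.5, 0, 0)),
                         normalize = FALSE)
  expect_equal(as.numeric(stackChannels(stn)$hb_donor), 0)
})

test_that("normalization rescales to [0,1], constants to 0.5, flips invert", {
  a <- array(c(-2, 6, 2, rep(0, 24 - 3)), dim = c(2, 3, 4))
  st <- stackFromArrays(list(a))
  ns <- normalizeChannels(st)
  v <- stackChannels(ns)$distance
  expect_equal(v[1, 1, 1], 0)
  expect_equal(v[2, 1, 1], 1)
  expect_equal(v[1, 2, 1], 0.5)
  cst <- stackFromArrays(list(array(3, dim = c(2, 2, 2))))
  expect_true(all(stackChannels(normalizeChannels(cst))$distance == 0.5))
  idf <- stackFromArrays(list(array(seq(0, 1, length.out = 8),
                                    dim = c(2, 2, 2))))
  expect_equal(stackChannels(normalizeChannels(idf))$distance,
               array(seq(0, 1, length.out = 8), dim = c(2, 2, 2)))
  flipped <- normalizeChannels(st, flip = "distance")
  expect_equal(stackChannels(flipped)$distance[1, 1, 1], 1)
  bad <- stackFromArrays(list(array(NaN, dim = c(2, 2, 2))))
  expect_error(normalizeChannels(bad), class = "geneo_invalid_field")
})

test_that("channel signs hold before normalization", {
  st <- computeChannels(shellStructure(seed = 5), spacing = 1.5,
                        padding = 3, normalize = FALSE)
  ch <- stackChannels(st)
  expect_true(all(ch$gravitational >= 0))
  expect_true(all(ch$lipophilic <= 0))
  expect_true(all(ch$hydrophilic >= 0))
  expect_true(all(ch$polar >= 0))
})

test_that("sum channels are additive over disjoint atom sets", {
  at <- toyAtoms(c(0, 2, -1), c(0, 1, 2), c(1, 0, -1),
                 element = c("C", "N", "O"))
  g <- VoxelGrid(c(-3, -3, -3), 1.5, c(4L, 4L, 4L))
  stAll <- computeChannels(at, grid = g, normalize = FALSE)
  stA <- computeChannels(at[1, ], grid = g, normalize = FALSE)
  stB <- computeChannels(at[2:3, ], grid = g, normalize = FALSE)
  for (nm in c("gravitational", "electrostatic", "polar", "hb_acceptor")) {
    expect_equal(stackChannels(stAll)[[nm]],
                 stackChannels(stA)[[nm]] + stackChannels(stB)[[nm]],
                 tolerance = 1e-12, label = nm)
  }
})

test_that("channels are exactly equivariant to integer-spacing translations", {
  at <- toyAtoms(c(0, 2, -1), c(0, 1, 2), c(1, 0, -1),
                 element = c("C", "N", "O"))
  g <- VoxelGrid(c(-4, -4, -4), 1, c(8L, 8L, 8L))
  st <- computeChannels(at, grid = g, normalize = FALSE)
  shift <- c(3, -2, 1)   # integer multiples of spacing
  at2 <- at; at2$x <- at$x + shift[1]; at2$y <- at$y + shift[2]
  at2$z <- at$z + shift[3]
  g2 <- VoxelGrid(gridOrigin(g) + shift, 1, gridDims(g))
  st2 <- computeChannels(at2, grid = g2, normalize = FALSE)
  for (nm in channelNames())
    expect_identical(stackChannels(st)[[nm]], stackChannels(st2)[[nm]],
                     label = nm)
})

test_that("channels commute with the 24 proper grid rotations", {
  at <- toyAtoms(c(0.3, 2, -1), c(0.2, 1.1, 2), c(1, 0, -1.2),
                 element = c("C", "N", "O"))
  g <- VoxelGrid(c(-4, -4, -4), 1, c(8L, 8L, 8L))
  st <- computeChannels(at, grid = g, normalize = FALSE)
  rots <- gridRotations()
  expect_length(rots, 24L)
  for (R in rots[c(1, 5, 9, 14, 19, 24)]) {
    co <- rotateCoords(as.matrix(at[, c("x", "y", "z")]), R, g)
    at2 <- at; at2$x <- co[, 1]; at2$y <- co[, 2]; at2$z <- co[, 3]
    st2 <- computeChannels(at2, grid = g, normalize = FALSE)
    for (nm in c("distance", "gravitational", "electrostatic",
                 "hb_acceptor")) {
      expect_equal(stackChannels(st2)[[nm]],
                   rotateField(stackChannels(st)[[nm]], R),
                   tolerance = 1e-10, label = nm)
    }
  }
})

test_that("enlarging the cutoff converges with a 1/cutoff bound", {
  st <- computeChannels(shellStructure(seed = 6), spacing = 1.5, padding = 3,
                        cutoff = 20, normalize = FALSE)
  at <- shellStructure(seed = 6)
  st40 <- computeChannels(at, grid = stackGrid(st), cutoff = 40,
                          normalize = FALSE)
  totalMass <- sum(proteinAtoms(at)$mass)
  dev <- max(abs(stackChannels(st40)$gravitational -
                   stackChannels(st)$gravitational))
  expect_lt(dev, totalMass / 20)
  expect_true(all(stackChannels(st40)$gravitational >= 0))
})

test_that("truth mask implements the exact sphere-box test", {
  at <- toyAtoms(0, 0, 0, element = "C")
  at$vdw <- 1.5
  g <- VoxelGrid(c(-3.5, -3.5, -3.5), 1, c(7L, 7L, 7L))   # atom centered in a voxel
  tm <- ligandTruthMask(at, g)
  v <- maskValues(tm)
  # point-sampling oracle: a voxel is occupied iff some point of its cube
  # lies strictly inside the sphere
  for (i in 1:7) for (j in 1:7) for (k in 1:7) {
    lo <- gridOrigin(g) + (c(i, j, k) - 1) * 1
    nearest <- pmin(pmax(c(0, 0, 0), lo), lo + 1)
    expect_equal(v[i, j, k], sum(nearest^2) < 1.5^2,
                 label = paste(i, j, k))
  }
  # the center voxel and all 6 face neighbors are occupied
  expect_true(v[4, 4, 4])
  expect_true(all(v[c(3, 5), 4, 4], v[4, c(3, 5), 4], v[4, 4, c(3, 5)]))
})

test_that("zero-radius atom on a corner marks only the owning half-open voxel", {
  at <- toyAtoms(1, 1, 1, element = "C")
  at$vdw <- 0
  g <- VoxelGrid(c(0, 0, 0), 1, c(3L, 3L, 3L))
  v <- maskValues(ligandTruthMask(at, g))
  expect_equal(sum(v), 1L)
  expect_true(v[2, 2, 2])   # the half-open cube [1,2)^3 owns the corner
})

test_that("a ligand outside the grid is an empty-truth error", {
  at <- toyAtoms(100, 100, 100, element = "C")
  g <- VoxelGrid(c(0, 0, 0), 1, c(4L, 4L, 4L))
  expect_error(ligandTruthMask(at, g), class = "geneo_empty_truth")
  ath <- toyAtoms(1, 1, 1, element = "H")
  expect_error(ligandTruthMask(ath, g), class = "geneo_empty_truth")
})
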