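# Shared builders for the test suite; everything is generated in code.

# a minimal fixed-column PDB line
pdbLine <- function(record = "ATOM", serial = 1, name = "C", resid = "GLY",
                    chain = "A", resno = 1, x = 0, y = 0, z = 0, occ = 1,
                    altloc = " ", element = "C") {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resid, chain, resno, x, y, z, occ,
          0, toupper(element))
}

pdbText <- function(...) paste(c(..., "END"), collapse = "\n")

# parameterized atom table without going through a PDB file
toyAtoms <- function(x, y, z, element = "C", record = "ATOM",
                     chain = "A", resno = seq_along(x)) {
  df <- data.frame(record = record, serial = seq_along(x),
                   name = element, resid = "GLY", chain = chain,
                   resno = resno, insert = "", x = x, y = y, z = z,
                   occ = 1, element = element, stringsAsFactors = FALSE)
  assignParameters(df)
}

# channel stack built directly from arrays (bypassing the potentials)
stackFromArrays <- function(arrays, grid = NULL, mask = NULL,
                            normalized = FALSE) {
  dims <- dim(arrays[[1]])
  if (is.null(grid)) grid <- VoxelGrid(c(0, 0, 0), 1, dims)
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  arrays <- rep_len(arrays, 8)
  names(arrays) <- channelNames()
  new("ChannelStack", grid = grid, channels = arrays, emptyMask = mask,
      normalization = data.frame(channel = character(0), min = numeric(0),
                                 max = numeric(0)),
      normalized = normalized)
}

randomStack <- function(seed, dims = c(8L, 8L, 8L), normalized = TRUE) {
  set.seed(seed)
  arrays <- lapply(1:8, function(i) array(runif(prod(dims)), dim = dims))
  stackFromArrays(arrays, normalized = normalized)
}

randomMaskArray <- function(seed, dims = c(5L, 5L, 5L), p = 0.3) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}

# direct triple-loop convolution oracle (zero padding), independent of the
# C++ path
convOracle <- function(field, taps) {
  fd <- dim(field); kd <- dim(taps); r <- (kd - 1) %/% 2
  out <- array(0, dim = fd)
  for (z in seq_len(fd[3])) for (y in seq_len(fd[2])) for (x in seq_len(fd[1])) {
    acc <- 0
    for (tz in -r[3]:r[3]) for (ty in -r[2]:r[2]) for (tx in -r[1]:r[1]) {
      sx <- x - tx; sy <- y - ty; sz <- z - tz
      if (sx >= 1 && sx <= fd[1] && sy >= 1 && sy <= fd[2] &&
          sz >= 1 && sz <= fd[3])
        acc <- acc + taps[tx + r[1] + 1, ty + r[2] + 1, tz + r[3] + 1] *
          field[sx, sy, sz]
    }
    out[x, y, z] <- acc
  }
  out
}

# brute-force volumetric loss by explicit voxel counting
lossOracle <- function(pred, truth, k) {
  hit <- 0L; tneg <- 0L; tv <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) hit <- hit + 1L
    if (!pred[i] && !truth[i]) tneg <- tneg + 1L
    if (truth[i]) tv <- tv + 1L
  }
  (hit + k * tneg) / (tv + k * (length(truth) - tv))
}

shellStructure <- function(seed = 1, ...) {
  txt <- makeShellComplex(shellComplexSpec(seed = seed, ...))
  prepareStructure(paste(txt, collapse = "\n"), ligand = "LIG")
}
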