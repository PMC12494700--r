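# Serialization: model parameters as JSON, channel stacks as gzipped JSON
# with a self-describing header, label fields as run-length-encoded text,
# pocket voxel clouds as pseudo-atom PDB and OpenDX grid export.

.FORMAT_VERSION <- "geneopocket-1"

#' Write / read model parameters as JSON
#'
#' @param model A \linkS4class{GENEOModel}.
#' @param path Output path.
#' @return \code{readGENEOModel} returns the model; \code{writeGENEOModel}
#'   the path, invisibly.
#' @export
writeGENEOModel <- function(model, path) {
  obj <- list(version = .FORMAT_VERSION, variant = model@variant,
              sigma = model@sigma, alpha = model@alpha, theta = model@theta,
              families = model@families,
              connectivity = model@connectivity,
              volumeRef = model@volumeRef, smallVolume = model@smallVolume)
  if (model@variant != "E-NE")
    obj$taps <- lapply(model@taps, function(t)
      list(dim = dim(t), values = as.numeric(t)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeGENEOModel
#' @export
readGENEOModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  taps <- if (!is.null(obj$taps))
    lapply(obj$taps, function(t) array(t$values, dim = t$dim)) else list()
  geneoModel(sigma = obj$sigma, alpha = obj$alpha, theta = obj$theta,
             families = obj$families, variant = obj$variant, taps = taps,
             connectivity = obj$connectivity, volumeRef = obj$volumeRef,
             smallVolume = obj$smallVolume)
}

#' Persist a channel stack
#'
#' Gzipped JSON container: grid origin/spacing/dims, channel order,
#' normalization records and the flattened fields.
#'
#' @param stack A \linkS4class{ChannelStack}.
#' @param path Output path (conventionally .json.gz).
#' @return \code{readChannelStack} returns the stack.
#' @export
writeChannelStack <- function(stack, path) {
  obj <- list(version = .FORMAT_VERSION,
              grid = list(origin = stack@grid@origin,
                          spacing = stack@grid@spacing,
                          dims = stack@grid@dims),
              channels = channelNames(),
              normalized = stack@normalized,
              normalization = stack@normalization,
              emptyMask = as.integer(stack@emptyMask),
              values = lapply(stack@channels, as.numeric))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname writeChannelStack
#' @export
readChannelStack <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  grid <- VoxelGrid(obj$grid$origin, obj$grid$spacing, obj$grid$dims)
  dims <- grid@dims
  chans <- lapply(obj$values, function(v) array(v, dim = dims))
  names(chans) <- channelNames()
  norm <- as.data.frame(obj$normalization)
  if (nrow(norm) == 0)
    norm <- data.frame(channel = character(0), min = numeric(0),
                       max = numeric(0))
  new("ChannelStack", grid = grid, channels = chans,
      emptyMask = array(as.logical(obj$emptyMask), dim = dims),
      normalization = norm, normalized = isTRUE(obj$normalized))
}

#' Write the pocket label field as run-length-encoded text
#'
#' @param prediction A \linkS4class{PocketPrediction}.
#' @param path Output path.
#' @export
writeLabelField <- function(prediction, path) {
  r <- rle(as.integer(prediction@labels))
  obj <- list(version = .FORMAT_VERSION,
              grid = list(origin = prediction@grid@origin,
                          spacing = prediction@grid@spacing,
                          dims = prediction@grid@dims),
              lengths = r$lengths, values = r$values)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeLabelField
#' @export
readLabelField <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lab <- inverse.rle(structure(list(lengths = obj$lengths,
                                    values = obj$values), class = "rle"))
  array(lab, dim = obj$grid$dims)
}

#' Write pocket voxels as a pseudo-atom PDB
#'
#' One HETATM per pocket voxel center, residue number = pocket rank, for
#' inspection in molecular viewers.
#'
#' @param prediction A \linkS4class{PocketPrediction}.
#' @param path Output path.
#' @param maxRank Write pockets up to this rank (default all).
#' @export
writeVoxelCloudPDB <- function(prediction, path, maxRank = Inf) {
  centers <- voxelCenters(prediction@grid)
  rows <- list()
  serial <- 0L
  pk <- prediction@pockets
  for (q in seq_len(nrow(pk))) {
    if (pk$rank[q] > maxRank) next
    vox <- which(prediction@labels == pk$label[q])
    cc <- centers[vox, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      record = "HETATM", serial = serial + seq_len(nrow(cc)), name = "C",
      resid = "PKT", chain = "P", resno = pk$rank[q],
      x = cc[, 1], y = cc[, 2], z = cc[, 3], occ = 1, element = "C",
      stringsAsFactors = FALSE)
    serial <- serial + nrow(cc)
  }
  if (length(rows) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  writePDB(do.call(rbind, rows), path)
  invisible(path)
}

#' Export a scalar field as OpenDX grid
#'
#' @param field 3D array on the grid.
#' @param grid The \linkS4class{VoxelGrid}.
#' @param path Output path.
#' @export
writeOpenDX <- function(field, grid, path) {
  d <- grid@dims; s <- grid@spacing
  org <- grid@origin + s / 2   # DX positions are voxel centers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", org[1], org[2], org[3]),
    sprintf("delta %.6f 0 0", s), sprintf("delta 0 %.6f 0", s),
    sprintf("delta 0 0 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX expects the last index fastest; our arrays have the first fastest
  v <- as.numeric(aperm(field, c(3, 2, 1)))
  writeLines(vapply(split(v, ceiling(seq_along(v) / 3)),
                    function(row) paste(sprintf("%.6g", row), collapse = " "),
                    character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
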