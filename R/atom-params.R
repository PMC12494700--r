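# Per-atom physicochemical parameters and their assignment, including
# covalent-bond inference for donor hydrogens and antecedents.

.REQUIRED_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I")
.PARAM_COLUMNS <- c("element", "vdw", "mass", "charge", "lipo", "covalent",
                    "acceptor", "hbEps", "hbRmin")

#' Default per-element parameter table
#'
#' Van der Waals radii follow Bondi, masses are standard atomic weights and
#' covalent radii the usual single-bond values. The remaining scalars encode
#' only the conventions the potentials need, since channel-wise min-max
#' normalization removes their absolute scale: partial charges are a small
#' formal-charge-free set, lipophilicity is a sign convention (carbon,
#' sulfur and halogens lipophilic = -1; nitrogen and oxygen hydrophilic =
#' +1; phosphorus +0.5; hydrogen inherits its bonded heavy atom), and the
#' hydrogen-bond well is eps = 1 with Rmin 1.9 A for oxygen and 2.0 A for
#' nitrogen acceptors.
#'
#' @return data.frame with one row per element.
#' @export
defaultAtomParameters <- function() {
  data.frame(
    element  = c("H",   "C",   "N",    "O",    "S",    "P",    "F",    "CL",   "BR",   "I"),
    vdw      = c(1.20,  1.70,  1.55,   1.52,   1.80,   1.80,   1.47,   1.75,   1.85,   1.98),
    mass     = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45,  79.904, 126.904),
    charge   = c(0.15,  0.00,  -0.30,  -0.40,  -0.10,  0.40,   -0.15,  -0.15,  -0.15,  -0.15),
    lipo     = c(NA,    -1,    1,      1,      -1,     0.5,    -1,     -1,     -1,     -1),
    covalent = c(0.31,  0.76,  0.71,   0.66,   1.05,   1.07,   0.57,   1.02,   1.20,   1.39),
    acceptor = c(FALSE, FALSE, TRUE,   TRUE,   FALSE,  FALSE,  FALSE,  FALSE,  FALSE,  FALSE),
    hbEps    = c(0,     0,     1,      1,      0,      0,      0,      0,      0,      0),
    hbRmin   = c(0,     0,     2.0,    1.9,    0,      0,      0,      0,      0,      0),
    stringsAsFactors = FALSE)
}

#' Load a parameter table from TSV or YAML
#'
#' The table must provide the columns of
#' \code{\link{defaultAtomParameters}} and cover at least H, C, N, O, S, P
#' and the halogens; anything less fails loudly.
#'
#' @param path Path to a tab-separated table or a .yml/.yaml file holding a
#'   list of per-element records.
#' @return data.frame.
#' @export
readAtomParameters <- function(path) {
  if (!file.exists(path)) geneoStop("geneo_io_error", "file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      geneoStop("geneo_io_error", "the 'yaml' package is required for YAML tables")
    rows <- yaml::read_yaml(path)
    tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
  }
  miss <- setdiff(.PARAM_COLUMNS, names(tab))
  if (length(miss))
    geneoStop("geneo_bad_parameter_table",
              "parameter table lacks columns: ", paste(miss, collapse = ", "))
  missEl <- setdiff(.REQUIRED_ELEMENTS, toupper(tab$element))
  if (length(missEl))
    geneoStop("geneo_bad_parameter_table",
              "parameter table lacks required elements: ",
              paste(missEl, collapse = ", "))
  tab
}

#' Assign physicochemical parameters to atoms
#'
#' Looks every atom up in the per-element table and infers covalent bonds
#' (distance below the sum of covalent radii plus 0.4 A) to find donor
#' hydrogens and donor antecedents. Nitrogen and oxygen are hydrogen-bond
#' acceptors; with at least one bonded hydrogen they are donors as well.
#' The polarity indicator is 1 for N, O and for S carrying a bonded
#' hydrogen. A hydrogen atom inherits the lipophilicity sign of its bonded
#' heavy atom.
#'
#' @param atoms Atom table from \code{\link{readPDB}}.
#' @param table Parameter table (default \code{\link{defaultAtomParameters}}).
#' @return The atom table with columns vdw, mass, charge, lipo, polar,
#'   hbRole ("none", "acceptor", "donor", "both"), hbEps, hbRmin and list
#'   columns donorH (matrix of bonded-hydrogen coordinates) and antecedent
#'   (heavy-neighbor coordinates or NULL).
#' @export
assignParameters <- function(atoms, table = defaultAtomParameters()) {
  el <- toupper(atoms$element)
  idx <- match(el, toupper(table$element))
  if (anyNA(idx))
    geneoStop("geneo_unknown_element",
              "unknown element(s) ",
              paste(unique(el[is.na(idx)]), collapse = ", "),
              " for atom serial(s) ",
              paste(atoms$serial[is.na(idx)], collapse = ", "))
  out <- atoms
  out$vdw <- table$vdw[idx]
  out$mass <- table$mass[idx]
  out$charge <- table$charge[idx]
  out$lipo <- table$lipo[idx]
  out$hbEps <- table$hbEps[idx]
  out$hbRmin <- table$hbRmin[idx]
  acceptor <- table$acceptor[idx]

  coords <- as.matrix(atoms[, c("x", "y", "z")])
  bonds <- cpp_bond_pairs(coords, table$covalent[idx], 0.4)
  nbr <- vector("list", nrow(atoms))
  if (nrow(bonds) > 0) {
    for (q in seq_len(nrow(bonds))) {
      i <- bonds[q, 1]; j <- bonds[q, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  isH <- el == "H"
  donorH <- vector("list", nrow(atoms))
  antecedent <- vector("list", nrow(atoms))
  hasH <- logical(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    nb <- nbr[[i]]
    if (isH[i]) {
      # inherit lipophilicity from the bonded heavy atom
      heavy <- nb[!isH[nb]]
      out$lipo[i] <- if (length(heavy)) out$lipo[heavy[1]] else 0
      next
    }
    hnb <- nb[isH[nb]]
    hasH[i] <- length(hnb) > 0
    if (hasH[i]) donorH[[i]] <- coords[hnb, , drop = FALSE]
    heavy <- nb[!isH[nb]]
    if (length(heavy)) {
      d <- sqrt(colSums((t(coords[heavy, , drop = FALSE]) - coords[i, ])^2))
      antecedent[[i]] <- coords[heavy[which.min(d)], ]
    }
  }
  out$lipo[is.na(out$lipo)] <- 0
  out$polar <- as.integer(el %in% c("N", "O") | (el == "S" & hasH))
  out$hbRole <- ifelse(acceptor & hasH, "both",
                       ifelse(acceptor, "acceptor", "none"))
  out$donorH <- donorH
  out$antecedent <- antecedent
  out
}

# ------------------------------------------------- ParameterizedStructure

#' ParameterizedStructure: a prepared protein-ligand complex
#'
#' @slot proteinAtoms Parameterized protein atom table.
#' @slot ligandAtoms Parameterized ligand atom table (may be empty for
#'   apo predictions).
#' @slot provenance list(source, ligand) bookkeeping.
#' @export
setClass("ParameterizedStructure",
         representation(proteinAtoms = "data.frame",
                        ligandAtoms = "data.frame", provenance = "list"))

setValidity("ParameterizedStructure", function(object) {
  if (nrow(object@proteinAtoms) == 0L)
    return("protein atom set is empty")
  both <- intersect(object@proteinAtoms$serial, object@ligandAtoms$serial)
  if (length(both)) return("protein and ligand atom sets overlap")
  TRUE
})

#' @describeIn ParameterizedStructure-class protein atom table
#' @param x,object A ParameterizedStructure.
#' @export
proteinAtoms <- function(x) x@proteinAtoms

#' @describeIn ParameterizedStructure-class ligand atom table
#' @export
ligandAtoms <- function(x) x@ligandAtoms

#' Ligand heavy-atom coordinates
#'
#' @param x A \linkS4class{ParameterizedStructure}.
#' @return Matrix of coordinates (hydrogens excluded).
#' @export
ligandHeavyCoords <- function(x) {
  lig <- x@ligandAtoms
  lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  as.matrix(lig[, c("x", "y", "z")])
}

setMethod("show", "ParameterizedStructure", function(object) {
  cat("ParameterizedStructure:", nrow(object@proteinAtoms),
      "protein atoms,", nrow(object@ligandAtoms), "ligand atoms",
      sprintf("(ligand %s)\n", object@provenance$ligand %||% "none"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepare a structure end to end
#'
#' Reads a PDB complex, splits off the ligand, optionally keeps only chains
#' near the ligand, and assigns per-atom parameters to both sides.
#'
#' @param input PDB path or text (see \code{\link{readPDB}}).
#' @param ligand Ligand residue name or "AUTO".
#' @param table Parameter table.
#' @param chainCutoff Chain-filter distance in Angstrom (default 10).
#' @param filterChains Apply the chain filter (default TRUE; ignored when
#'   there is no ligand).
#' @return A \linkS4class{ParameterizedStructure}.
#' @export
prepareStructure <- function(input, ligand = "AUTO",
                             table = defaultAtomParameters(),
                             chainCutoff = 10, filterChains = TRUE) {
  atoms <- readPDB(input)
  parts <- splitComplex(atoms, ligand)
  prot <- parts$protein
  if (filterChains && nrow(parts$ligand) > 0)
    prot <- filterChainsNearLigand(prot, parts$ligand, chainCutoff)
  new("ParameterizedStructure",
      proteinAtoms = assignParameters(prot, table),
      ligandAtoms = assignParameters(parts$ligand, table),
      provenance = list(source = if (length(input) == 1L &&
                                     !grepl("\n", input[1], fixed = TRUE))
                          input else "<text>",
                        ligand = unique(parts$ligand$resid)[1]))
}
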