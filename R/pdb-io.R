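# PDB input/output and the protein/ligand split.
#
# Parsing is delegated to bio3d::read.pdb; on top of it we apply the
# conventions assumed throughout the package: first MODEL only, waters
# removed, alternate locations collapsed to the highest-occupancy variant,
# element symbols inferred from atom names when the element column is blank.

.WATERS <- c("HOH", "WAT", "DOD", "H2O")

.TWO_LETTER_ELEMENTS <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN",
                          "CU", "NI", "CO", "CD", "HG", "SI", "LI", "AL")

inferElement <- function(name, record = "ATOM") {
  letters <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(letters) == 0L) return("")
  two <- substr(letters, 1, 2)
  # two-letter symbols are only trusted for heteroatoms; in polymer records
  # "CA"/"CD" etc. are carbons
  if (record == "HETATM" && two %in% .TWO_LETTER_ELEMENTS && letters == two)
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  substr(letters, 1, 1)
}

#' Read a PDB file or text
#'
#' Parses ATOM/HETATM records of the first MODEL, drops waters, collapses
#' alternate locations to the highest-occupancy variant (ties: first seen)
#' and infers missing element symbols from atom names.
#'
#' @param input Path to a PDB file, or PDB-format text (a string containing
#'   newlines, or a character vector of lines).
#' @param dropWaters Remove HOH/WAT residues (default TRUE).
#' @return data.frame with columns record, serial, name, resid, chain,
#'   resno, insert, x, y, z, occ, element.
#' @export
readPDB <- function(input, dropWaters = TRUE) {
  if (length(input) > 1L || grepl("\n", input[1], fixed = TRUE)) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
  } else {
    if (!file.exists(input))
      geneoStop("geneo_io_error", "file not found: ", input)
    lines <- readLines(input, warn = FALSE)
  }
  # first MODEL only
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  isAtom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  # validate coordinate fields up front so errors can name the line
  for (ln in which(isAtom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[ln], fld[1], fld[2])))
      if (is.na(v))
        geneoStop("geneo_parse_error",
                  "malformed coordinate field at line ", ln, ": '",
                  lines[ln], "'")
    }
  }
  if (!any(isAtom))
    geneoStop("geneo_empty_structure", "no ATOM/HETATM records found")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      geneoStop("geneo_parse_error", "PDB parse failed: ", conditionMessage(e)))
  at <- pdb$atom
  df <- data.frame(record = at$type, serial = at$eleno,
                   name = trimws(at$elety),
                   resid = trimws(at$resid),
                   chain = ifelse(is.na(at$chain), "", at$chain),
                   resno = at$resno,
                   insert = ifelse(is.na(at$insert), "", at$insert),
                   x = at$x, y = at$y, z = at$z,
                   occ = ifelse(is.na(at$o), 1, at$o),
                   element = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
                   altloc = ifelse(is.na(at$alt), "", at$alt),
                   stringsAsFactors = FALSE)
  if (dropWaters) df <- df[!df$resid %in% .WATERS, , drop = FALSE]
  if (nrow(df) == 0L)
    geneoStop("geneo_empty_structure",
              "no atoms left after removing solvent")
  blank <- df$element == ""
  if (any(blank))
    df$element[blank] <- mapply(inferElement, df$name[blank],
                                df$record[blank])
  # collapse altlocs: highest occupancy wins, ties broken by file order
  key <- paste(df$record, df$chain, df$resno, df$insert, df$resid, df$name,
               sep = "|")
  ord <- order(key, -df$occ, seq_len(nrow(df)), method = "radix")
  df <- df[ord[!duplicated(key[ord])], , drop = FALSE]
  df <- df[order(df$serial), , drop = FALSE]
  df$altloc <- NULL
  rownames(df) <- NULL
  df
}

#' Write atoms as PDB text
#'
#' Fixed-column, byte-deterministic writer used for fixtures and for pocket
#' voxel clouds.
#'
#' @param atoms data.frame with the columns produced by \code{\link{readPDB}}
#'   (occ and insert optional).
#' @param file Optional path; when NULL the lines are returned.
#' @return Character vector of PDB lines, invisibly when written to file.
#' @export
writePDB <- function(atoms, file = NULL) {
  n <- nrow(atoms)
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, n)
  ins <- if ("insert" %in% names(atoms)) atoms$insert else rep("", n)
  name4 <- ifelse(nchar(atoms$name) >= 4L, substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  lines <- sprintf("%-6s%5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$record, atoms$serial %% 100000L, name4,
                   atoms$resid, substr(paste0(atoms$chain, " "), 1, 1),
                   atoms$resno %% 10000L, substr(paste0(ins, " "), 1, 1),
                   atoms$x, atoms$y, atoms$z, occ, 0,
                   toupper(atoms$element))
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

.ION_BUFFER <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
                 "CO", "CD", "HG", "IOD", "BR", "SO4", "PO4", "PO3", "GOL",
                 "EDO", "PEG", "PGE", "ACT", "DMS", "BME", "MPD", "FMT",
                 "NO3", "ACY", "TRS", "MES", "EPE", "IMD", "CIT", "TLA")

#' Split a complex into protein and ligand atoms
#'
#' @param atoms Atom table from \code{\link{readPDB}}.
#' @param ligand Residue name of the ligand, or "AUTO" to pick the HETATM
#'   residue instance with the most heavy atoms after excluding common ions
#'   and buffer molecules.
#' @param exclude Residue names never considered ligands in AUTO mode.
#' @return list(protein = data.frame, ligand = data.frame).
#' @export
splitComplex <- function(atoms, ligand = "AUTO", exclude = .ION_BUFFER) {
  if (identical(ligand, "AUTO")) {
    het <- atoms[atoms$record == "HETATM" & !atoms$resid %in% exclude, ,
                 drop = FALSE]
    if (nrow(het) == 0L)
      geneoStop("geneo_unknown_ligand",
                "no ligand candidate among HETATM residues")
    inst <- paste(het$chain, het$resno, het$insert, het$resid, sep = "|")
    heavy <- tapply(het$element != "H", inst, sum)
    # ties: first instance in file order
    first <- tapply(seq_len(nrow(het)), inst, min)
    best <- names(heavy)[order(-heavy, first[names(heavy)])][1]
    lig <- het[inst == best, , drop = FALSE]
  } else {
    lig <- atoms[atoms$resid == ligand, , drop = FALSE]
    if (nrow(lig) == 0L)
      geneoStop("geneo_unknown_ligand",
                "no residue named '", ligand, "' in the structure")
  }
  prot <- atoms[atoms$record == "ATOM" &
                  !atoms$serial %in% lig$serial, , drop = FALSE]
  list(protein = prot, ligand = lig)
}

#' Keep only protein chains near the ligand
#'
#' A chain is kept when at least one of its atoms lies within \code{cutoff}
#' of any ligand atom; used to avoid symmetry copies of the true pocket.
#'
#' @param protein,ligand Atom tables.
#' @param cutoff Distance cutoff in Angstrom (default 10).
#' @return The filtered protein atom table.
#' @export
filterChainsNearLigand <- function(protein, ligand, cutoff = 10) {
  if (cutoff <= 0) geneoStop("geneo_bad_argument", "cutoff must be > 0")
  lc <- as.matrix(ligand[, c("x", "y", "z")])
  keep <- vapply(split(seq_len(nrow(protein)), protein$chain), function(idx) {
    pc <- as.matrix(protein[idx, c("x", "y", "z")])
    min(cpp_min_dist_each(pc, lc)) <= cutoff
  }, logical(1))
  chains <- names(keep)[keep]
  if (length(chains) == 0L)
    geneoStop("geneo_no_chain_near_ligand",
              "no protein chain within ", cutoff, " A of the ligand")
  protein[protein$chain %in% chains, , drop = FALSE]
}
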