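three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Coarse-grain a PDB structure to one or two beads per residue
#'
#' Reads standard PDB text (ATOM records; first model of multi-model
#' files) via \pkg{bio3d} and reduces each residue to its CA bead
#' (`scheme = "backbone"`) or CA plus CB (`scheme = "backbone+sidechain"`;
#' glycine contributes only its backbone bead).  Alternate locations are
#' resolved by first occurrence; insertion codes are rejected rather than
#' silently renumbered.
#'
#' @param pdb_text Character scalar (or vector of lines) with PDB content.
#' @param scheme Coarse-graining scheme.
#' @return A [coarse_structure()] preserving chain ids and residue numbers.
#' @export
read_pdb_coarse <- function(pdb_text,
                            scheme = c("backbone", "backbone+sidechain")) {
  scheme <- match.arg(scheme)
  lines <- if (length(pdb_text) == 1 && grepl("\n", pdb_text)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  atom_lines <- grep("^ATOM", lines)
  if (length(atom_lines) == 0) stop("no ATOM records in PDB input", call. = FALSE)
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(
          substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)
        ))))) {
      stop(sprintf("malformed ATOM record at line %d", ln), call. = FALSE)
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (any(nzchar(at$insert) & !is.na(at$insert))) {
    stop("insertion codes are not supported; renumber the structure first",
         call. = FALSE)
  }
  # altLoc: first occurrence of each (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]

  res_key <- paste(at$chain, at$resno)
  for (rk in unique(res_key)) {
    sub <- at[res_key == rk, , drop = FALSE]
    if (!"CA" %in% sub$elety) {
      stop(sprintf("residue %s of chain %s has no CA atom",
                   sub$resno[1], sub$chain[1]), call. = FALSE)
    }
  }
  wanted <- if (scheme == "backbone") "CA" else c("CA", "CB")
  at <- at[at$elety %in% wanted, , drop = FALSE]
  at <- at[order(at$chain, at$resno, match(at$elety, c("CA", "CB"))), ,
           drop = FALSE]
  one <- unname(three_to_one[at$resid])
  one[is.na(one)] <- "G"
  beads <- tibble::tibble(
    chain_id = at$chain,
    residue_index = as.integer(at$resno),
    residue_name = one,
    bead_kind = ifelse(at$elety == "CA", "backbone", "sidechain"),
    x = at$x, y = at$y, z = at$z
  )
  coarse_structure(beads, list())
}
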