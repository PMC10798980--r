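#' Average residue masses, charges and hydropathy classes
#'
#' Residue-level property tables used to assign bead masses, charges and
#' hydrophobicity classes.  Masses are average (isotope-weighted) residue
#' masses in Da; a free peptide adds one water (18.0153 Da).  Charges follow
#' the neutral-pH convention: D/E carry -1, K/R carry +1, histidine is
#' treated as neutral.  The hydropathy partition follows the Kyte-Doolittle
#' split into hydrophobic (A, V, L, I, M, F, W, C), charged and polar.
#'
#' @return A tibble with one row per standard amino acid: `code` (one-letter),
#'   `mass` (Da), `charge` (elementary charges), `hydro_class` (one of
#'   `"hydrophobic"`, `"polar"`, `"charged+"`, `"charged-"`).
#' @export
residue_properties <- function() {
  mass <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
  )
  charge <- stats::setNames(rep(0, 20), names(mass))
  charge[c("D", "E")] <- -1
  charge[c("K", "R")] <- 1
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C")
  hydro <- ifelse(names(mass) %in% hydrophobic, "hydrophobic",
    ifelse(charge > 0, "charged+", ifelse(charge < 0, "charged-", "polar"))
  )
  tibble::tibble(
    code = names(mass), mass = unname(mass),
    charge = unname(charge), hydro_class = unname(hydro)
  )
}

#' Benchmark amyloid sequences
#'
#' One-letter sequences of amyloid-beta 1-42 and full-length (140-residue)
#' alpha-synuclein, used as reference inputs for mass bookkeeping and as
#' sequence templates for ligand beads.
#'
#' @param id One of `"abeta42"` or `"asyn"`.
#' @return A one-row tibble with columns `id` and `sequence`
#'   (a `sequence_record` in the package's vocabulary).
#' @export
amyloid_sequence <- function(id = c("abeta42", "asyn")) {
  id <- match.arg(id)
  seqs <- c(
    abeta42 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA",
    asyn = paste0(
      "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTKEQ",
      "VTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDPDNEA",
      "YEMPSEEGYQDYEPEA"
    )
  )
  tibble::tibble(id = id, sequence = unname(seqs[id]))
}

split_sequence <- function(sequence) {
  letters1 <- strsplit(sequence, "", fixed = TRUE)[[1]]
  props <- residue_properties()
  bad <- which(!letters1 %in% props$code)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid amino-acid letter '%s' at position %d",
      letters1[bad[1]], bad[1]
    ), call. = FALSE)
  }
  letters1
}

#' Average mass of a linear peptide
#'
#' Sums average residue masses and adds one water (18.0153 Da).  An
#' unmodified linear peptide is assumed: no amidation and no disulfide
#' mass correction.  The amyloid-beta 1-42 sequence evaluates to 4514.1 Da
#' and 140-residue alpha-synuclein to 14460.2 Da, matching their nominal
#' molecular weights.
#'
#' @param sequence One-letter amino-acid string, or a one-row tibble with a
#'   `sequence` column (as returned by [amyloid_sequence()]).
#' @return Mass in Da (numeric scalar).
#' @examples
#' peptide_average_mass("G") # free glycine, 75.07 Da
#' peptide_average_mass(amyloid_sequence("abeta42"))
#' @export
peptide_average_mass <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  letters1 <- split_sequence(sequence)
  props <- residue_properties()
  sum(props$mass[match(letters1, props$code)]) + dmd_constants$water_mass
}
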