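#' Coarse-grained structures as bead tables
#'
#' A `coarse_structure` is a tibble with one row per bead and columns
#' `chain_id` (character), `residue_index` (integer, 1-based, strictly
#' increasing within a chain), `residue_name` (one-letter code),
#' `bead_kind` (`"backbone"` or `"sidechain"`) and Cartesian coordinates
#' `x`, `y`, `z` in Å.  Named bead-index sets (interface pairs, the
#' domain-swapped subset, calcium sites, immobilized/flexible domains,
#' per-component membership) live in the `annotations` attribute so the
#' table itself stays tidy.
#'
#' @param beads A data frame with the columns above.
#' @param annotations Named list.  Entries are integer bead indices, except
#'   `interface_pairs` / `domain_swap_pairs` / `inter_peptide_pairs`, which
#'   are two-column matrices of bead-index pairs.
#' @return A `coarse_structure` tibble.
#' @export
coarse_structure <- function(beads, annotations = list()) {
  beads <- tibble::as_tibble(beads)
  required <- c("chain_id", "residue_index", "residue_name", "bead_kind",
                "x", "y", "z")
  missing <- setdiff(required, names(beads))
  if (length(missing) > 0) {
    stop("missing bead columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  beads$residue_index <- as.integer(beads$residue_index)
  structure(beads,
    annotations = annotations,
    class = c("coarse_structure", class(beads))
  )
}

#' @export
print.coarse_structure <- function(x, ...) {
  ann <- names(structure_annotations(x))
  cat(sprintf(
    "<coarse_structure> %d beads, %d chain(s)%s\n",
    nrow(x), length(unique(x$chain_id)),
    if (length(ann)) paste0("; annotations: ", paste(ann, collapse = ", "))
    else ""
  ))
  NextMethod()
}

#' Retrieve or set structure annotations
#'
#' @param structure A `coarse_structure`.
#' @return Named list of annotations.
#' @export
structure_annotations <- function(structure) {
  attr(structure, "annotations") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_annotation <- function(structure, name, value) {
  ann <- structure_annotations(structure)
  ann[[name]] <- value
  attr(structure, "annotations") <- ann
  structure
}

bead_positions <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

#' Validate the invariants of a coarse structure
#'
#' Checks, exhaustively over beads: residue indices strictly increasing
#' within each chain; consecutive backbone beads of a chain 2.0-6.0 Å
#' apart; no two beads closer than 1.0 Å; every annotation referencing
#' existing bead indices.
#'
#' @param structure A `coarse_structure`.
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
validate_structure <- function(structure) {
  stopifnot(inherits(structure, "coarse_structure"))
  pos <- bead_positions(structure)
  for (ch in unique(structure$chain_id)) {
    idx <- which(structure$chain_id == ch & structure$bead_kind == "backbone")
    ri <- structure$residue_index[idx]
    if (any(diff(ri) <= 0)) {
      stop(sprintf("chain %s: residue_index not strictly increasing", ch),
           call. = FALSE)
    }
    if (length(idx) > 1) {
      d <- sqrt(rowSums((pos[idx[-1], , drop = FALSE] -
                         pos[idx[-length(idx)], , drop = FALSE])^2))
      if (any(d < 2.0 | d > 6.0)) {
        k <- which(d < 2.0 | d > 6.0)[1]
        stop(sprintf(
          "chain %s: consecutive backbone beads %d-%d separated by %.2f Å (allowed 2-6 Å)",
          ch, ri[k], ri[k + 1], d[k]
        ), call. = FALSE)
      }
    }
  }
  if (nrow(structure) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < 1.0) {
      stop(sprintf("bead pair closer than 1.0 Å (min %.3f Å)", dmin),
           call. = FALSE)
    }
  }
  ann <- structure_annotations(structure)
  for (nm in names(ann)) {
    idx <- if (is.matrix(ann[[nm]])) as.vector(ann[[nm]]) else ann[[nm]]
    if (length(idx) > 0 &&
        (any(idx < 1) || any(idx > nrow(structure)) ||
         any(idx != as.integer(idx)))) {
      stop(sprintf("annotation '%s' references non-existent beads", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Merge two structures into one, tracking component membership
#'
#' Bead indices of the second component are shifted; pair annotations are
#' re-based.  Components are recorded in annotations `component_1` and
#' `component_2`.
#' @noRd
combine_structures <- function(a, b) {
  offset <- nrow(a)
  ann_a <- structure_annotations(a)
  ann_b <- structure_annotations(b)
  shift <- function(v) if (is.matrix(v)) v + offset else v + offset
  ann_b <- lapply(ann_b, shift)
  if (length(ann_b) > 0) names(ann_b) <- paste0(names(ann_b), "_ligand")
  ann <- c(ann_a, ann_b)
  ann$component_1 <- seq_len(nrow(a))
  ann$component_2 <- offset + seq_len(nrow(b))
  beads <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  coarse_structure(beads, ann)
}
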