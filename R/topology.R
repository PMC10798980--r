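#' Per-bead masses, charges and hydropathy classes
#'
#' Maps each bead to its residue properties.  With the backbone-only
#' scheme each bead carries the whole residue's average mass.  Charges
#' follow the neutral-pH rule (D/E -1, K/R +1, histidine neutral — see
#' [residue_properties()]).
#'
#' @param structure A [coarse_structure()].
#' @param sequences Optional named character vector of one-letter
#'   sequences, one per chain; when given, it overrides the structure's
#'   `residue_name` column and must match each chain's residue count.
#' @return Tibble with one row per bead: `bead`, `chain_id`,
#'   `residue_index`, `code`, `mass`, `charge`, `hydro_class`.
#' @export
assign_bead_properties <- function(structure, sequences = NULL) {
  props <- residue_properties()
  codes <- structure$residue_name
  if (!is.null(sequences)) {
    for (ch in unique(structure$chain_id)) {
      if (!ch %in% names(sequences)) {
        stop(sprintf("no sequence supplied for chain %s", ch), call. = FALSE)
      }
      idx <- which(structure$chain_id == ch)
      n_res <- length(unique(structure$residue_index[idx]))
      letters1 <- split_sequence(sequences[[ch]])
      if (length(letters1) != n_res) {
        stop(sprintf(
          "sequence length %d does not match %d residues of chain %s",
          length(letters1), n_res, ch
        ), call. = FALSE)
      }
      codes[idx] <- letters1[match(structure$residue_index[idx],
                                   sort(unique(structure$residue_index[idx])))]
    }
  }
  m <- match(codes, props$code)
  if (anyNA(m)) {
    stop(sprintf("unknown residue code '%s'", codes[which(is.na(m))[1]]),
         call. = FALSE)
  }
  tibble::tibble(
    bead = seq_len(nrow(structure)),
    chain_id = structure$chain_id,
    residue_index = structure$residue_index,
    code = codes,
    mass = props$mass[m],
    charge = props$charge[m],
    hydro_class = props$hydro_class[m]
  )
}

#' Geometric native contacts of a structure
#'
#' All bead pairs whose reference distance is at most `cutoff`, keeping
#' within-chain pairs only when their residue separation is at least
#' `min_seq_separation` (no separation rule across chains).  This is the
#' standard Gō-model construction; each contact defaults to the weak
#' 0.4 kcal/mol well (about 0.67 kT at 300 K).
#'
#' @param structure A [coarse_structure()].
#' @param cutoff Contact cutoff, Å.
#' @param min_seq_separation Minimum within-chain residue separation.
#' @param epsilon Well depth, kcal/mol.
#' @return Tibble of contacts: `i`, `j` (bead indices, i < j), `r_ref`
#'   (Å), `epsilon`.
#' @export
find_native_contacts <- function(structure, cutoff = 6.5,
                                 min_seq_separation = 3, epsilon = 0.4) {
  stopifnot(cutoff > 0)
  pos <- bead_positions(structure)
  n <- nrow(pos)
  if (n < 2) {
    return(tibble::tibble(i = integer(), j = integer(),
                          r_ref = numeric(), epsilon = numeric()))
  }
  d <- as.matrix(stats::dist(pos))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          r_ref = numeric(), epsilon = numeric()))
  }
  i <- hit[, 1]; j <- hit[, 2]
  same <- structure$chain_id[i] == structure$chain_id[j]
  sep <- abs(structure$residue_index[i] - structure$residue_index[j])
  keep <- !same | sep >= min_seq_separation
  ik <- unname(i[keep]); jk <- unname(j[keep])
  tibble::tibble(
    i = as.integer(ik), j = as.integer(jk),
    r_ref = d[cbind(ik, jk)],
    epsilon = epsilon
  ) |> dplyr::arrange(.data$i, .data$j)
}

default_topology_options <- function() {
  list(
    contact_cutoff = 6.5,
    min_seq_separation = 3,
    contact_epsilon = 0.4,
    contact_well_width = 0.15,
    intra_epsilon = NULL,
    interface_well_width = NULL,
    bond_tolerance = 0.02,
    pseudo_bond_tolerance = 0.05,
    calcium_tolerance = 0.01,
    hard_core = 4.0,
    hydrophobic_depth = 0.3,
    hydrophobic_width = 2.0,
    electrostatics = TRUE,
    dielectric = 80,
    screening_length = 10,
    coulomb_steps = 4,
    coulomb_range = 12
  )
}

class_pair_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = "|")
}

build_nonbonded_rules <- function(opts) {
  classes <- c("hydrophobic", "polar", "charged+", "charged-")
  core <- step_potential(opts$hard_core, Inf)
  rules <- list()
  for (a in seq_along(classes)) {
    for (b in a:length(classes)) {
      ca <- classes[a]; cb <- classes[b]
      key <- class_pair_key(ca, cb)
      if (ca == "hydrophobic" && cb == "hydrophobic") {
        rules[[key]] <- discretize_pair_potential("hydrophobic-well",
          list(core = opts$hard_core, depth = opts$hydrophobic_depth,
               width = opts$hydrophobic_width))
      } else if (opts$electrostatics &&
                 grepl("charged", ca) && grepl("charged", cb)) {
        q <- (if (ca == "charged+") 1 else -1) * (if (cb == "charged+") 1 else -1)
        rules[[key]] <- discretize_pair_potential("screened-coulomb",
          list(core = opts$hard_core, q1q2 = q,
               lambda = opts$screening_length,
               dielectric = opts$dielectric),
          n_steps = opts$coulomb_steps, r_max = opts$coulomb_range)
      } else {
        rules[[key]] <- core
      }
    }
  }
  rules
}

#' Build a runnable topology from a coarse structure
#'
#' Assembles the full simulation Hamiltonian: covalent chain bonds as
#' narrow infinite square wells (±2% of the reference distance),
#' next-nearest pseudo-bonds as ±5% wells (an angle surrogate), native
#' contacts as single square wells of depth `epsilon` spanning ±15% of
#' their reference distance, calcium-site annotations as rigid ±1%
#' cross-links between calcium residues of the same chain, and
#' class-resolved non-bonded step potentials (hard core, a
#' hydrophobic-hydrophobic well, and screened Coulomb shells between
#' charged beads).
#'
#' Native contacts are intra-component only.  Between the two dimer
#' chains, contacts come from the `interface_pairs` annotation (the
#' Gō constraint applied to the strand-swapped interface); a ligand's
#' annotated inter-peptide pairs are merged with its geometric contacts.
#' The dimer and the ligand interact through non-bonded terms alone.
#'
#' @param structure A [coarse_structure()] (optionally combined via
#'   [place_components()]).
#' @param sequences Optional per-chain sequences for
#'   [assign_bead_properties()].
#' @param options Named list overriding [default_topology_options()].
#' @return A `dmd_topology` list: `beads` (property tibble incl.
#'   `hard_radius` and `class`), `bonds` (`i`, `j`, `d_min`, `d_max`),
#'   `contacts` (`i`, `j`, `r_ref`, `epsilon`, `well_width`), `nonbonded`
#'   (class-pair rules), `immobilized`, `pulled`, `interface_contacts`,
#'   `box_edge`.
#' @export
build_topology <- function(structure, sequences = NULL, options = list()) {
  opts <- utils::modifyList(default_topology_options(), options)
  ann <- structure_annotations(structure)
  props <- assign_bead_properties(structure, sequences)
  props$hard_radius <- opts$hard_core / 2
  pos <- bead_positions(structure)
  n <- nrow(pos)
  pdist <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))

  check_ann <- function(nm) {
    v <- ann[[nm]]
    idx <- if (is.matrix(v)) as.vector(v) else v
    if (length(idx) > 0 && (any(idx < 1) || any(idx > n))) {
      stop(sprintf("annotation '%s' references missing beads", nm),
           call. = FALSE)
    }
  }
  for (nm in names(ann)) check_ann(nm)

  # chain connectivity: bonds between consecutive backbone beads and
  # next-nearest pseudo-bonds as an angle surrogate
  bonds <- list()
  add_bond <- function(i, j, tol) {
    r <- pdist(i, j)
    bonds[[length(bonds) + 1]] <<- c(i, j, r * (1 - tol), r * (1 + tol))
  }
  for (ch in unique(structure$chain_id)) {
    idx <- which(structure$chain_id == ch & structure$bead_kind == "backbone")
    if (length(idx) >= 2) {
      for (k in seq_len(length(idx) - 1)) {
        add_bond(idx[k], idx[k + 1], opts$bond_tolerance)
      }
    }
    if (length(idx) >= 3) {
      for (k in seq_len(length(idx) - 2)) {
        add_bond(idx[k], idx[k + 2], opts$pseudo_bond_tolerance)
      }
    }
  }
  # rigid calcium-site cross-links within each chain
  ca_sites <- ann$calcium_sites %||% integer()
  if (length(ca_sites) >= 2) {
    for (ch in unique(structure$chain_id[ca_sites])) {
      sub <- ca_sites[structure$chain_id[ca_sites] == ch]
      if (length(sub) >= 2) {
        cmb <- utils::combn(sort(sub), 2)
        for (k in seq_len(ncol(cmb))) {
          add_bond(cmb[1, k], cmb[2, k], opts$calcium_tolerance)
        }
      }
    }
  }
  bonds <- if (length(bonds)) {
    b <- do.call(rbind, bonds)
    tibble::tibble(i = as.integer(b[, 1]), j = as.integer(b[, 2]),
                   d_min = b[, 3], d_max = b[, 4])
  } else {
    tibble::tibble(i = integer(), j = integer(),
                   d_min = numeric(), d_max = numeric())
  }

  # native contacts, intra-component; dimer cross-chain pairs from the
  # interface annotation only
  comp1 <- ann$component_1 %||% seq_len(n)
  comp2 <- ann$component_2 %||% integer()
  component <- integer(n)
  component[comp1] <- 1L
  component[comp2] <- 2L
  geo <- find_native_contacts(structure, opts$contact_cutoff,
                              opts$min_seq_separation, opts$contact_epsilon)
  same_comp <- component[geo$i] == component[geo$j]
  # cross-chain contacts inside the dimer come from the interface
  # annotation alone (where one exists), not from raw geometry
  cross_dimer <- if (!is.null(ann$interface_pairs)) {
    component[geo$i] == 1L & component[geo$j] == 1L &
      structure$chain_id[geo$i] != structure$chain_id[geo$j]
  } else {
    rep(FALSE, nrow(geo))
  }
  geo <- geo[same_comp & !cross_dimer, , drop = FALSE]

  pair_rows <- function(mat, eps) {
    if (is.null(mat) || nrow(mat) == 0) {
      return(tibble::tibble(i = integer(), j = integer(),
                            r_ref = numeric(), epsilon = numeric()))
    }
    i <- pmin(mat[, 1], mat[, 2]); j <- pmax(mat[, 1], mat[, 2])
    tibble::tibble(
      i = as.integer(i), j = as.integer(j),
      r_ref = vapply(seq_along(i), function(k) pdist(i[k], j[k]), numeric(1)),
      epsilon = eps
    )
  }
  iface <- pair_rows(ann$interface_pairs, opts$contact_epsilon)
  inter_pep <- dplyr::bind_rows(
    pair_rows(ann$inter_peptide_pairs, opts$contact_epsilon),
    pair_rows(ann$inter_peptide_pairs_ligand, opts$contact_epsilon)
  )
  # folding wells may be deeper than the adhesive interface wells: the
  # weak 0.4 kcal/mol Go energy is specific to the strand-swapped
  # interface, while the fold itself emulates a full force field
  if (!is.null(opts$intra_epsilon) && nrow(geo) > 0) {
    same_chain <- structure$chain_id[geo$i] == structure$chain_id[geo$j]
    geo$epsilon[same_chain] <- opts$intra_epsilon
  }
  contacts <- dplyr::bind_rows(geo, iface, inter_pep) |>
    dplyr::distinct(.data$i, .data$j, .keep_all = TRUE) |>
    dplyr::arrange(.data$i, .data$j)
  contacts$well_width <- opts$contact_well_width
  iface_key <- if (nrow(iface)) paste(iface$i, iface$j) else character()
  if (!is.null(opts$interface_well_width)) {
    contacts$well_width[paste(contacts$i, contacts$j) %in% iface_key] <-
      opts$interface_well_width
  }
  interface_contacts <- contacts[paste(contacts$i, contacts$j) %in% iface_key, ,
                                 drop = FALSE]

  immobilized <- sort(unique(ann$immobilized_domain %||% integer()))
  pulled <- sort(unique(ann$flexible_domain %||% integer()))
  if (length(intersect(immobilized, pulled)) > 0) {
    stop("immobilized and pulled selections overlap", call. = FALSE)
  }

  topo <- structure(
    list(
      beads = dplyr::mutate(props, class = .data$hydro_class),
      bonds = bonds,
      contacts = contacts,
      nonbonded = build_nonbonded_rules(opts),
      immobilized = immobilized,
      pulled = pulled,
      interface_contacts = interface_contacts,
      annotations = ann,
      positions = pos,
      box_edge = attr(structure, "box_edge") %||% NULL,
      options = opts
    ),
    class = "dmd_topology"
  )
  topo
}

#' @export
print.dmd_topology <- function(x, ...) {
  cat(sprintf(
    "<dmd_topology> %d beads, %d bonds, %d contacts (%d interface), %d immobilized, %d pulled\n",
    nrow(x$beads), nrow(x$bonds), nrow(x$contacts),
    nrow(x$interface_contacts), length(x$immobilized), length(x$pulled)
  ))
  invisible(x)
}

#' Constant-force steering protocol
#'
#' A constant pulling force is realized as a linear potential
#' \eqn{-F x} along the pulling direction, discretized into parallel
#' planes `delta` Å apart: crossing one plane along the force gains
#' \eqn{\Delta U = F \delta \times 0.0143933} kcal/mol (per pN·Å).  At run
#' time the total force is split equally over the pulled bead set (or
#' applied to a single bead with `share = "single"`).
#'
#' @param magnitude Force in pN (>= 0; 0 gives a no-op protocol).
#' @param direction 3-vector; normalized to unit length.
#' @param delta Plane spacing, Å.  The default 0.5 Å keeps the per-plane
#'   energy below kT even at 60 pN.
#' @param share `"equal"` or `"single"`.
#' @return A `force_protocol` list with `energy_per_plane` (total-force
#'   energy gain per plane, kcal/mol).
#' @examples
#' build_force_protocol(10, c(0, 0, 1), delta = 1)$energy_per_plane # 0.1439
#' @export
build_force_protocol <- function(magnitude, direction = c(0, 0, 1),
                                 delta = 0.5, share = c("equal", "single")) {
  share <- match.arg(share)
  stopifnot(magnitude >= 0)
  if (delta <= 0) stop("plane spacing delta must be positive", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector", call. = FALSE)
  direction <- direction / nrm
  structure(
    list(
      magnitude = magnitude,
      direction = direction,
      delta = delta,
      share = share,
      energy_per_plane = magnitude * delta * dmd_constants$pN_A_to_kcal_mol
    ),
    class = "force_protocol"
  )
}
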