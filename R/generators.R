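#' Generate a toy strand-swapped dimer
#'
#' Builds a two-chain coarse-grained model that emulates the EC1 cadherin
#' trans dimer: each chain is a compact beta-hairpin, the two hairpins are
#' stacked face to face, and a small set of inter-chain bead pairs is
#' annotated as the adhesive interface.  Pairs whose sequence positions lie
#' in both chains' N-terminal strands are flagged `domain_swap`, mimicking
#' the exchanged N-terminal strand of the real dimer.  Residues listed as
#' calcium sites are annotated on both chains and later become rigid
#' cross-links in the topology.
#'
#' Geometry: backbone bond 3.8 Å, hairpin strands 4.4 Å apart, chains
#' 5.2 Å apart, plus a small seed-controlled jitter so replicate systems
#' differ while all structural invariants hold.
#'
#' @param n_per_chain Residues per chain (>= 10).
#' @param n_interface_contacts Number of annotated interface pairs (>= 1).
#' @param swap_fraction Fraction of interface pairs drawn from the
#'   N-terminal strands (rounded).
#' @param calcium_site_indices Residue indices to mark as calcium sites;
#'   indices beyond `n_per_chain` are dropped.
#' @param seed RNG seed; output is bitwise-reproducible for a fixed seed.
#' @return A [coarse_structure()] with annotations `interface_pairs`
#'   (matrix of bead-index pairs), `domain_swap_pairs`, `calcium_sites`,
#'   `immobilized_domain` (chain A) and `flexible_domain` (chain B).
#' @examples
#' dim <- generate_toy_dimer(30, 6, 0.5, c(11, 25), seed = 1)
#' validate_structure(dim)
#' @export
generate_toy_dimer <- function(n_per_chain,
                               n_interface_contacts,
                               swap_fraction = 0.5,
                               calcium_site_indices = integer(),
                               seed = 1) {
  stopifnot(n_per_chain >= 10, n_interface_contacts >= 1,
            swap_fraction >= 0, swap_fraction <= 1)
  calcium_site_indices <- as.integer(
    calcium_site_indices[calcium_site_indices >= 1 &
                         calcium_site_indices <= n_per_chain]
  )
  h <- n_per_chain %/% 2
  chain_coords <- function(reversed, z) {
    xs <- numeric(n_per_chain); ys <- numeric(n_per_chain)
    for (i in seq_len(n_per_chain)) {
      if (i <= h) {
        xs[i] <- (i - 1) * 3.8; ys[i] <- 0
      } else {
        xs[i] <- (h - 1) * 3.8 - (i - h - 1) * 3.8; ys[i] <- 4.4
      }
    }
    if (reversed) xs <- (h - 1) * 3.8 - xs
    cbind(xs, ys, rep(z, n_per_chain))
  }
  pos <- rbind(chain_coords(FALSE, 0), chain_coords(TRUE, 5.2))

  # interface pairings available by construction:
  # N-strand: A bead i <-> B bead (h - i + 1); C-strand: A bead i <-> B bead
  # at the matching x, both at inter-chain distance 5.2 A
  swap_avail <- lapply(seq_len(h), function(i) {
    c(i, n_per_chain + (h - i + 1))
  })
  cterm_i <- seq(h + 1, n_per_chain)
  cterm_avail <- list()
  for (i in cterm_i) {
    j <- 3 * h + 1 - i
    if (j >= h + 1 && j <= n_per_chain) {
      cterm_avail[[length(cterm_avail) + 1]] <- c(i, n_per_chain + j)
    }
  }
  n_swap <- round(swap_fraction * n_interface_contacts)
  n_other <- n_interface_contacts - n_swap
  if (n_swap > length(swap_avail)) {
    stop(sprintf(
      "cannot place %d domain-swap contacts: only %d N-terminal strand pairings exist for %d residues/chain",
      n_swap, length(swap_avail), n_per_chain
    ), call. = FALSE)
  }
  if (n_other > length(cterm_avail)) {
    stop(sprintf(
      "cannot place %d non-swap interface contacts: only %d C-terminal strand pairings exist for %d residues/chain",
      n_other, length(cterm_avail), n_per_chain
    ), call. = FALSE)
  }
  pick_spread <- function(avail, k) {
    if (k == 0) return(NULL)
    idx <- unique(round(seq(1, length(avail), length.out = k)))
    while (length(idx) < k) idx <- unique(c(idx, setdiff(seq_along(avail), idx)[1]))
    do.call(rbind, avail[sort(idx[seq_len(k)])])
  }
  swap_pairs <- pick_spread(swap_avail, n_swap)
  other_pairs <- pick_spread(cterm_avail, n_other)
  interface <- rbind(swap_pairs, other_pairs)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  jitter <- withr_seed(matrix(stats::rnorm(length(pos), sd = 0.25), ncol = 3))
  pos <- pos + jitter

  seqs <- toy_dimer_sequence(n_per_chain)
  res <- split_sequence(seqs)
  beads <- tibble::tibble(
    chain_id = rep(c("A", "B"), each = n_per_chain),
    residue_index = rep(seq_len(n_per_chain), 2),
    residue_name = rep(res, 2),
    bead_kind = "backbone",
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  ann <- list(
    interface_pairs = interface,
    domain_swap_pairs = if (is.null(swap_pairs)) {
      matrix(integer(), ncol = 2)
    } else swap_pairs,
    calcium_sites = c(calcium_site_indices,
                      n_per_chain + calcium_site_indices),
    immobilized_domain = seq_len(n_per_chain),
    flexible_domain = n_per_chain + seq_len(n_per_chain)
  )
  out <- coarse_structure(beads, ann)
  validate_structure(out)
  out
}

#' Default sequence for one toy dimer chain
#'
#' Cationic lysines at the hairpin turn (the region an anionic ligand is
#' expected to target), hydrophobic leucines along the strands, glutamates
#' near the C-terminus, serines elsewhere.
#'
#' @param n_per_chain Chain length.
#' @return One-letter sequence string.
#' @export
toy_dimer_sequence <- function(n_per_chain) {
  h <- n_per_chain %/% 2
  res <- rep("S", n_per_chain)
  res[seq_len(n_per_chain) %% 2 == 1] <- "L"
  turn <- intersect(seq(h - 1, h + 2), seq_len(n_per_chain))
  res[turn] <- "K"
  cterm <- seq(max(1, n_per_chain - 3), n_per_chain)
  res[cterm] <- rep(c("E", "S"), length.out = length(cterm))
  paste(res, collapse = "")
}

ligand_sequence <- function(n, net_charge_sign) {
  res <- rep("S", n)
  res[seq_len(n) %% 2 == 1] <- "L"
  idx <- seq_len(n)
  switch(net_charge_sign,
    negative = {
      res[idx %% 5 == 0] <- "E"
      res[idx %% 10 == 7] <- "K"
    },
    positive = {
      res[idx %% 5 == 0] <- "K"
      res[idx %% 10 == 7] <- "E"
    },
    neutral = {
      res[idx %% 10 == 0] <- "E"
      res[idx %% 10 == 5] <- "K"
      # balance the counts exactly so the net charge is zero
      nE <- sum(res == "E"); nK <- sum(res == "K")
      if (nE != nK) {
        surplus <- if (nE > nK) "E" else "K"
        drop <- utils::tail(which(res == surplus), abs(nE - nK))
        res[drop] <- "S"
      }
    }
  )
  paste(res, collapse = "")
}

#' Specify a synthetic amyloid-like ligand
#'
#' Three ligand classes emulate the amyloid species used in the binding
#' study: a flexible `monomer` (single chain, no intra-chain native
#' contacts), a compact rigid `oligomer` (single collapsed chain with a
#' target density of intra-chain contacts), and a `seed` (several stacked
#' extended chains cross-linked by inter-peptide contacts, emulating a
#' cross-beta fibril fragment).
#'
#' @param kind `"monomer"`, `"oligomer"` or `"seed"`.
#' @param n_residues_per_chain Residues per chain.  Class defaults (15 /
#'   25 / 4 x 10) give the oligomer and seed comparable masses while the
#'   monomer stays the smallest species, as for the amyloid assemblies
#'   they emulate.
#' @param n_chains Chains (must be 1 unless `kind = "seed"`).
#' @param intra_contact_density Target intra-chain native contacts per
#'   residue, in \[0, 1\]; forced to 0 for monomers.
#' @param inter_peptide_contact_energy Gō well depth for seed inter-peptide
#'   pairs, kcal/mol.
#' @param net_charge_sign `"negative"` (amyloid-beta-like), `"positive"` or
#'   `"neutral"`.
#' @param seed RNG seed.
#' @return A `ligand_spec` list.
#' @export
ligand_spec <- function(kind = c("monomer", "oligomer", "seed"),
                        n_residues_per_chain = switch(kind,
                          monomer = 15, oligomer = 25, seed = 10),
                        n_chains = if (kind == "seed") 4L else 1L,
                        intra_contact_density = switch(kind,
                          monomer = 0, oligomer = 0.8, seed = 0.4),
                        inter_peptide_contact_energy = 0.4,
                        net_charge_sign = "negative",
                        seed = 1) {
  kind <- match.arg(kind)
  if (kind != "seed" && n_chains != 1) {
    stop("n_chains must be 1 unless kind = 'seed'", call. = FALSE)
  }
  if (kind == "monomer") intra_contact_density <- 0
  structure(
    list(
      kind = kind, n_residues_per_chain = as.integer(n_residues_per_chain),
      n_chains = as.integer(n_chains),
      intra_contact_density = intra_contact_density,
      inter_peptide_contact_energy = inter_peptide_contact_energy,
      net_charge_sign = match.arg(net_charge_sign,
                                  c("negative", "positive", "neutral")),
      seed = seed
    ),
    class = "ligand_spec"
  )
}

#' Build a ligand structure from its specification
#'
#' Monomers are near-straight chains with a small seed-dependent kink, so
#' no non-neighbour pair falls inside the native-contact cutoff.  Oligomers
#' are layered serpentines: the first `k` residues are collapsed into a
#' compact slab and the remainder left as a tail, with `k` chosen so the
#' realized intra-chain contact count (6.5 Å cutoff, sequence separation
#' >= 3) lies within 20% of `intra_contact_density * n_residues`.  Seeds
#' are `n_chains` parallel extended strands 4.8 Å apart with annotated
#' inter-peptide pairs between every adjacent chain.
#'
#' @param spec A [ligand_spec()].
#' @return A [coarse_structure()]; seeds carry an `inter_peptide_pairs`
#'   annotation.
#' @export
generate_ligand <- function(spec) {
  stopifnot(inherits(spec, "ligand_spec"))
  n <- spec$n_residues_per_chain
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  make_beads <- function(pos, chain_ids, res) {
    tibble::tibble(
      chain_id = chain_ids,
      residue_index = unlist(lapply(table(factor(chain_ids, unique(chain_ids))),
                                    seq_len), use.names = FALSE),
      residue_name = res,
      bead_kind = "backbone",
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
  }
  res1 <- split_sequence(ligand_sequence(n, spec$net_charge_sign))

  if (spec$kind == "monomer") {
    pos <- cbind((seq_len(n) - 1) * 3.8, 0, 0) +
      matrix(stats::rnorm(3 * n, sd = 0.15), ncol = 3)
    out <- coarse_structure(make_beads(pos, rep("L1", n), res1), list())
  } else if (spec$kind == "oligomer") {
    target <- spec$intra_contact_density * n
    build <- function(k) {
      # first k residues in a 4-residue-wide serpentine slab, rest extended
      pos <- matrix(0, n, 3)
      row_len <- 4
      for (i in seq_len(n)) {
        if (i <= k) {
          r <- (i - 1) %/% row_len
          c0 <- (i - 1) %% row_len
          if (r %% 2 == 1) c0 <- row_len - 1 - c0
          layer <- r %/% 4
          rr <- r %% 4
          if (layer %% 2 == 1) rr <- 3 - rr
          pos[i, ] <- c(c0 * 3.8, rr * 4.5, layer * 4.5)
        } else {
          pos[i, ] <- pos[max(k, 1), ] + c(0, 0, 4.5 + (i - k - 1) * 3.8)
        }
      }
      pos
    }
    realized <- function(pos) {
      d <- as.matrix(stats::dist(pos))
      idx <- which(upper.tri(d) & d <= 6.5, arr.ind = TRUE)
      sum(abs(idx[, 1] - idx[, 2]) >= 3)
    }
    ks <- seq(0, n)
    counts <- vapply(ks, function(k) realized(build(k)), numeric(1))
    ok <- which(abs(counts - target) <= 0.2 * target |
                (target == 0 & counts == 0))
    if (length(ok) == 0) {
      stop(sprintf(
        "intra-contact density %.2f unreachable for %d residues (achievable counts %d..%d, target %.1f +/- 20%%)",
        spec$intra_contact_density, n, min(counts), max(counts), target
      ), call. = FALSE)
    }
    k <- ks[ok[which.min(abs(counts[ok] - target))]]
    pos <- build(k) + matrix(stats::rnorm(3 * n, sd = 0.15), ncol = 3)
    out <- coarse_structure(make_beads(pos, rep("L1", n), res1), list())
  } else {
    nc <- spec$n_chains
    pos <- NULL
    for (c in seq_len(nc)) {
      strand <- cbind((seq_len(n) - 1) * 3.8, (c - 1) * 4.8,
                      0.6 * ((c - 1) %% 2))
      pos <- rbind(pos, strand)
    }
    pos <- pos + matrix(stats::rnorm(3 * n * nc, sd = 0.15), ncol = 3)
    chain_ids <- rep(paste0("L", seq_len(nc)), each = n)
    beads <- make_beads(pos, chain_ids, rep(res1, nc))
    pairs <- NULL
    for (c in seq_len(nc - 1)) {
      pairs <- rbind(pairs, cbind((c - 1) * n + seq_len(n),
                                  c * n + seq_len(n)))
    }
    out <- coarse_structure(beads, list(inter_peptide_pairs = pairs))
  }
  validate_structure(out)
  out
}

#' Place a ligand near a dimer with a minimum separation
#'
#' Centres the dimer in a cubic box with reflecting walls, applies a
#' uniformly random rotation to the ligand and draws its position uniformly
#' in the box, rejecting draws that put any ligand bead within
#' `min_separation` of any dimer bead or outside the box.  Counter ions
#' are not represented as beads; charge screening is carried by the
#' screened-Coulomb step potential.
#'
#' @param dimer,ligand [coarse_structure()] objects.
#' @param min_separation Minimum inter-component bead distance, Å
#'   (12 Å emulates random initial placement near the dimer).
#' @param max_separation Optional upper bound on the initial separation,
#'   Å; bounding it keeps the diffusive encounter time short in
#'   desk-scale runs while still satisfying the minimum-distance rule.
#' @param box_edge Cubic box edge, Å; `NULL` sizes it to 4x the combined
#'   system diameter.
#' @param seed RNG seed.
#' @param max_attempts Rejection-sampling budget before failing.
#' @return Combined [coarse_structure()] with `component_1` (dimer) and
#'   `component_2` (ligand) annotations and a `box_edge` attribute.
#' @export
place_components <- function(dimer, ligand, min_separation = 12,
                             box_edge = NULL, seed = 1,
                             max_separation = Inf,
                             max_attempts = 1000) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pd <- bead_positions(dimer)
  pl <- bead_positions(ligand)
  diam <- function(p) if (nrow(p) > 1) max(stats::dist(p)) else 0
  if (is.null(box_edge)) box_edge <- 4 * (diam(rbind(pd, pl)) / 2 + 5)
  need <- diam(pd) / 2 + diam(pl) / 2 + min_separation
  if (box_edge < need) {
    stop(sprintf(
      "box edge %.1f Å too small to hold both components %.1f Å apart (need >= %.1f Å)",
      box_edge, min_separation, need
    ), call. = FALSE)
  }
  centre <- rep(box_edge / 2, 3)
  pd <- sweep(pd, 2, colMeans(pd)) + rep(centre, each = nrow(pd))

  random_rotation <- function() {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  pl0 <- sweep(pl, 2, colMeans(pl))
  margin <- 1.0
  placed <- NULL
  for (attempt in seq_len(max_attempts)) {
    rot <- random_rotation()
    cand <- pl0 %*% t(rot)
    shift <- stats::runif(3, margin, box_edge - margin)
    cand <- sweep(cand, 2, shift, `+`)
    if (any(cand < margin) || any(cand > box_edge - margin)) next
    dmin <- min(proxy_cross_dist(pd, cand))
    if (dmin >= min_separation && dmin <= max_separation && dmin >= 1.0) {
      placed <- cand
      break
    }
  }
  if (is.null(placed)) {
    stop(sprintf(
      "no valid ligand placement in %d attempts; increase box_edge (currently %.1f Å)",
      max_attempts, box_edge
    ), call. = FALSE)
  }
  d2 <- dimer
  d2$x <- pd[, 1]; d2$y <- pd[, 2]; d2$z <- pd[, 3]
  l2 <- ligand
  l2$x <- placed[, 1]; l2$y <- placed[, 2]; l2$z <- placed[, 3]
  out <- combine_structures(d2, l2)
  attr(out, "box_edge") <- box_edge
  validate_structure(out)
  out
}

# minimum-distance helper: full cross-distance matrix (small systems)
proxy_cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
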