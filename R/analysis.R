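window_frames <- function(n_frames, window_fraction) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  k <- max(1L, ceiling(window_fraction * n_frames))
  seq.int(n_frames - k + 1L, n_frames)
}

frame_matrix <- function(traj, f) {
  cbind(traj$frames[f, , 1], traj$frames[f, , 2], traj$frames[f, , 3])
}

#' Surviving interface contacts per frame
#'
#' Counts, in every sampled frame, how many of the given native contacts
#' are still formed — i.e. the pair distance is at most the contact's own
#' well outer radius `r_ref * (1 + well_width)`, so survival is defined by
#' the Hamiltonian rather than a generic map cutoff.
#'
#' @param traj A `dmd_trajectory`.
#' @param contacts Contact tibble (`i`, `j`, `r_ref`, `well_width`);
#'   default: the topology's interface contacts.
#' @return Tibble: `time` (ns), `count`.
#' @export
contact_count_series <- function(traj, contacts = NULL) {
  contacts <- contacts %||% traj$topology$interface_contacts
  nf <- length(traj$times)
  if (nrow(contacts) == 0) {
    return(tibble::tibble(time = traj$times, count = 0L))
  }
  outer_r <- contacts$r_ref * (1 + contacts$well_width)
  dx <- traj$frames[, contacts$i, 1] - traj$frames[, contacts$j, 1]
  dy <- traj$frames[, contacts$i, 2] - traj$frames[, contacts$j, 2]
  dz <- traj$frames[, contacts$i, 3] - traj$frames[, contacts$j, 3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d <- matrix(d, nrow = nf)
  counts <- rowSums(sweep(d, 2, outer_r, `<=`))
  tibble::tibble(time = traj$times, count = as.integer(counts))
}

#' First dissociation time with censoring
#'
#' The dissociation time is the time of the first frame in which the
#' interface contact count is zero.  Runs that never reach zero are
#' censored at the run duration — the convention under which a reported
#' time equal to the full run length means the dimer stayed associated.
#'
#' @param series Tibble from [contact_count_series()].
#' @param duration Run duration, ns (default: last time in the series).
#' @return One-row tibble: `dissociation_time` (ns), `censored`.
#' @export
first_dissociation_time <- function(series, duration = max(series$time)) {
  stopifnot(nrow(series) > 0)
  hit <- which(series$count == 0)
  if (length(hit) == 0) {
    tibble::tibble(dissociation_time = duration, censored = TRUE)
  } else {
    tibble::tibble(dissociation_time = series$time[hit[1]], censored = FALSE)
  }
}

#' Keep only the first frames of a trajectory
#'
#' Used to restrict analyses (e.g. bound-state RMSF) to the segment of a
#' run before a dissociation event.
#'
#' @param traj A `dmd_trajectory`.
#' @param n_frames Number of leading frames to keep (>= 2).
#' @return A `dmd_trajectory` with truncated frames and energy series.
#' @export
truncate_trajectory <- function(traj, n_frames) {
  stopifnot(n_frames >= 2, n_frames <= length(traj$times))
  traj$times <- traj$times[seq_len(n_frames)]
  traj$frames <- traj$frames[seq_len(n_frames), , , drop = FALSE]
  traj$energy <- traj$energy[seq_len(n_frames), ]
  traj
}

resolve_group <- function(traj, group) {
  if (is.character(group) && length(group) == 1) {
    ann <- traj$topology$annotations
    g <- ann[[group]]
    if (is.null(g)) stop(sprintf("no annotation '%s' in topology", group),
                         call. = FALSE)
    as.integer(g)
  } else {
    as.integer(group)
  }
}

#' Per-residue binding frequency
#'
#' For each residue of `group_a`, the fraction of analysis-window frames
#' in which any of its beads lies within `cutoff` of any bead of
#' `group_b`.  The 6.5 Å default reproduces the 0.65 nm contact criterion
#' used for the binding maps; the window defaults to the last 40% of
#' frames (the last 20 ns of a 50 ns run).
#'
#' @param traj A `dmd_trajectory`.
#' @param group_a,group_b Bead index vectors, or the name of a topology
#'   annotation (e.g. `"component_1"`, `"component_2"`); must be disjoint.
#' @param cutoff Contact cutoff, Å.
#' @param window_fraction Fraction of trailing frames analyzed.
#' @return A `binding_frequency_map` tibble: `chain_id`, `residue_index`,
#'   `frequency` in \[0, 1\], with the window description as attributes.
#' @export
binding_frequency <- function(traj, group_a, group_b, cutoff = 6.5,
                              window_fraction = 0.4) {
  ga <- resolve_group(traj, group_a)
  gb <- resolve_group(traj, group_b)
  if (length(intersect(ga, gb)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(ga) == 0 || length(gb) == 0) {
    stop("empty bead group", call. = FALSE)
  }
  frames <- window_frames(length(traj$times), window_fraction)
  beads <- traj$topology$beads
  hit_any <- matrix(FALSE, length(frames), length(ga))
  for (k in seq_along(frames)) {
    pa <- frame_matrix(traj, frames[k])[ga, , drop = FALSE]
    pb <- frame_matrix(traj, frames[k])[gb, , drop = FALSE]
    d <- proxy_cross_dist(pa, pb)
    hit_any[k, ] <- apply(d <= cutoff, 1, any)
  }
  per_bead <- tibble::tibble(
    bead = ga,
    chain_id = beads$chain_id[ga],
    residue_index = beads$residue_index[ga],
    hit = colMeans(hit_any)
  )
  out <- per_bead |>
    dplyr::group_by(.data$chain_id, .data$residue_index) |>
    dplyr::summarise(frequency = max(.data$hit), .groups = "drop")
  structure(
    tibble::new_tibble(out, class = "binding_frequency_map"),
    cutoff = cutoff, window_fraction = window_fraction,
    window_ns = range(traj$times[frames])
  )
}

kabsch_rotation <- function(p, q) {
  # optimal rotation R minimizing ||p R - q|| (both centred)
  h <- t(p) %*% q
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square fluctuation profile
#'
#' Per-bead RMSF about the window-mean position over the analysis window.
#' With `align = "none"` frames are used as sampled (valid when one
#' domain is immobilized, which pins the reference frame); with
#' `align = "kabsch"` every window frame is first rigidly superposed onto
#' the first window frame using `align_selection`.
#'
#' @param traj A `dmd_trajectory`.
#' @param selection Bead indices or annotation name; default all beads.
#' @param window_fraction Fraction of trailing frames analyzed.
#' @param align `"none"` or `"kabsch"`.
#' @param align_selection Beads used for the superposition (default: the
#'   selection itself).
#' @return An `rmsf_profile` tibble: `bead`, `chain_id`, `residue_index`,
#'   `rmsf` (Å).
#' @export
rmsf_profile <- function(traj, selection = NULL, window_fraction = 0.4,
                         align = c("none", "kabsch"),
                         align_selection = NULL) {
  align <- match.arg(align)
  sel <- if (is.null(selection)) seq_len(dim(traj$frames)[2]) else
    resolve_group(traj, selection)
  if (length(sel) == 0) stop("empty selection", call. = FALSE)
  frames <- window_frames(length(traj$times), window_fraction)
  if (length(frames) < 2) {
    stop("RMSF needs at least two frames in the window", call. = FALSE)
  }
  asel <- if (is.null(align_selection)) sel else
    resolve_group(traj, align_selection)
  coords <- array(NA_real_, c(length(frames), length(sel), 3))
  ref <- frame_matrix(traj, frames[1])
  ref_a <- ref[asel, , drop = FALSE]
  ref_cen <- colMeans(ref_a)
  for (k in seq_along(frames)) {
    p <- frame_matrix(traj, frames[k])
    if (align == "kabsch") {
      pa <- p[asel, , drop = FALSE]
      cen <- colMeans(pa)
      rot <- kabsch_rotation(sweep(pa, 2, cen), sweep(ref_a, 2, ref_cen))
      p <- sweep(sweep(p, 2, cen) %*% rot, 2, ref_cen, `+`)
    }
    coords[k, , ] <- p[sel, , drop = FALSE]
  }
  mean_pos <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_pos)^2
  # mean squared deviation per bead: average over frames, sum over xyz
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)
  beads <- traj$topology$beads
  tibble::new_tibble(
    tibble::tibble(
      bead = sel,
      chain_id = beads$chain_id[sel],
      residue_index = beads$residue_index[sel],
      rmsf = rmsf
    ),
    class = "rmsf_profile"
  )
}

#' Residue-class breakdown of intermolecular contacts
#'
#' Among all dimer-ligand bead pairs within `cutoff` over the analysis
#' window, the fraction attributable to each unordered hydropathy-class
#' pair (hydrophobic / polar / charged+ / charged-).  Fractions sum to 1
#' whenever any contact exists; the map is all-zero otherwise.
#'
#' @param traj A `dmd_trajectory` of a combined dimer+ligand system.
#' @param cutoff Contact cutoff, Å.
#' @param window_fraction Fraction of trailing frames analyzed.
#' @return Tibble: `class_a`, `class_b`, `n_contacts`, `fraction`.
#' @export
interaction_class_breakdown <- function(traj, cutoff = 6.5,
                                        window_fraction = 0.4) {
  ann <- traj$topology$annotations
  ga <- ann$component_1
  gb <- ann$component_2
  if (is.null(ga) || is.null(gb)) {
    stop("trajectory topology has no component annotations", call. = FALSE)
  }
  frames <- window_frames(length(traj$times), window_fraction)
  cls <- traj$topology$beads$hydro_class
  counts <- list()
  for (k in seq_along(frames)) {
    p <- frame_matrix(traj, frames[k])
    d <- proxy_cross_dist(p[ga, , drop = FALSE], p[gb, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      a <- cls[ga[hit[, 1]]]; b <- cls[gb[hit[, 2]]]
      key <- paste(pmin(a, b), pmax(a, b), sep = "|")
      counts[[length(counts) + 1]] <- key
    }
  }
  all_classes <- sort(unique(cls))
  grid <- expand.grid(a = all_classes, b = all_classes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$a <= grid$b, ]
  key_all <- paste(grid$a, grid$b, sep = "|")
  tab <- table(factor(unlist(counts), levels = key_all))
  total <- sum(tab)
  tibble::tibble(
    class_a = grid$a, class_b = grid$b,
    n_contacts = as.integer(tab),
    fraction = if (total > 0) as.numeric(tab) / total else 0
  )
}

#' Aggregate a steered campaign into per-force summaries
#'
#' Censored dissociation times enter the mean at the run duration (the
#' convention under which fully associated runs are plotted at the
#' maximum time).  `association_fraction` is the fraction of censored
#' (never-dissociated) replicas.  A Kaplan-Meier style restricted mean is
#' also reported for reference.
#'
#' @param records Tibble of dissociation records: `force`,
#'   `dissociation_time`, `censored`, and optionally `condition`.
#' @return Tibble with one row per (condition,) force: `n`,
#'   `mean_dissociation`, `median_dissociation`, `association_fraction`,
#'   `km_mean`, plus a `values` list-column with the full time list for
#'   violin rendering.
#' @export
aggregate_campaign <- function(records) {
  grp <- intersect(c("condition", "force"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dissociation = mean(.data$dissociation_time),
      median_dissociation = stats::median(.data$dissociation_time),
      association_fraction = mean(.data$censored),
      km_mean = km_restricted_mean(.data$dissociation_time, .data$censored),
      values = list(.data$dissociation_time),
      .groups = "drop"
    )
}

km_restricted_mean <- function(times, censored) {
  # restricted mean survival time by the Kaplan-Meier product limit
  ord <- order(times)
  times <- times[ord]; event <- !censored[ord]
  uniq <- unique(times[event])
  s <- 1
  surv <- numeric(0); tt <- numeric(0)
  n <- length(times)
  for (u in uniq) {
    at_risk <- sum(times >= u)
    d <- sum(times == u & event)
    s <- s * (1 - d / at_risk)
    tt <- c(tt, u); surv <- c(surv, s)
  }
  horizon <- max(times)
  steps <- c(tt, horizon)
  sv <- c(1, surv)
  sum(diff(c(0, steps)) * sv[seq_along(steps)])
}
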