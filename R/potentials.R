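#' Discretized pairwise step potential
#'
#' Event-driven dynamics requires piecewise-constant potentials.  A
#' `step_potential` stores strictly increasing shell radii (the first is
#' the hard core) and the energy level inside each shell band:
#' `energies[i]` is the level for distances between `radii[i-1]` and
#' `radii[i]` (with `radii[0] = 0`), so `energies[1]` is the hard-core
#' sentinel (`Inf`).  Beyond the last radius the level is exactly 0,
#' which keeps every interaction finite-range.
#'
#' @param radii Strictly increasing shell radii, Å.
#' @param energies Energy levels, kcal/mol; same length as `radii`; only
#'   the first may be infinite.
#' @param bounded If `TRUE` the outermost radius is an uncrossable wall
#'   (used for bond constraints).
#' @return A `step_potential` object.
#' @export
step_potential <- function(radii, energies, bounded = FALSE) {
  stopifnot(length(radii) == length(energies), length(radii) >= 1)
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing",
                                  call. = FALSE)
  if (any(!is.finite(energies[-1]))) {
    stop("only the innermost (hard-core) level may be infinite", call. = FALSE)
  }
  structure(list(radii = as.numeric(radii), energies = as.numeric(energies),
                 bounded = isTRUE(bounded)),
            class = "step_potential")
}

#' @export
print.step_potential <- function(x, ...) {
  cat("<step_potential>", length(x$radii), "shell(s)",
      if (x$bounded) "(bounded)" else "", "\n")
  print(tidy.step_potential(x))
  invisible(x)
}

#' Tabulate a step potential
#'
#' @param x A [step_potential()].
#' @param ... Unused.
#' @return Tibble with `r_inner`, `r_outer`, `energy` per band, including
#'   the implicit zero level beyond the last radius.
#' @export
tidy.step_potential <- function(x, ...) {
  m <- length(x$radii)
  tibble::tibble(
    r_inner = c(0, x$radii),
    r_outer = c(x$radii, Inf),
    energy = c(x$energies, if (x$bounded) Inf else 0)
  )
}

#' Energy level of a step potential at a distance
#'
#' @param pot A [step_potential()].
#' @param r Distance(s), Å.
#' @return Energy level(s) in kcal/mol.
#' @export
step_energy_at <- function(pot, r) {
  m <- length(pot$radii)
  band <- findInterval(r, pot$radii, left.open = TRUE) + 1L
  lv <- c(pot$energies, if (pot$bounded) Inf else 0)
  lv[band]
}

#' Discretize a continuous pair interaction into shells
#'
#' Supported forms: `"screened-coulomb"` (Debye-Hückel,
#' \eqn{U(r) = 332.0637\, q_1 q_2\, e^{-r/\lambda} / r} kcal/mol with
#' charges in elementary units), `"hydrophobic-well"` (a single attractive
#' square well) and `"hard-sphere"`.  Shell energies are the mean of the
#' continuous form over each shell; beyond `r_max` the level is exactly 0.
#'
#' @param form Interaction form.
#' @param params Named list: `core` (hard-core radius, Å) for all forms;
#'   `q1q2`, `lambda` (screening length, Å) and `dielectric` (relative
#'   solvent permittivity, default 80 for water) for screened-coulomb;
#'   `depth` (kcal/mol) and `width` (Å) for the hydrophobic well.
#' @param n_steps Number of shells between the core and `r_max`.
#' @param r_max Interaction range, Å.
#' @return A [step_potential()].
#' @examples
#' discretize_pair_potential("screened-coulomb",
#'   list(core = 4, q1q2 = 1, lambda = 10), n_steps = 4, r_max = 12)
#' @export
discretize_pair_potential <- function(form = c("screened-coulomb",
                                               "hydrophobic-well",
                                               "hard-sphere"),
                                      params, n_steps = 4, r_max = 12) {
  form <- match.arg(form)
  core <- params$core %||% 4.0
  if (form == "hard-sphere") {
    return(step_potential(core, Inf))
  }
  if (form == "hydrophobic-well") {
    return(step_potential(c(core, core + params$width),
                          c(Inf, -abs(params$depth))))
  }
  lambda <- params$lambda
  if (is.null(lambda) || lambda <= 0) {
    stop("screening length must be positive", call. = FALSE)
  }
  stopifnot(n_steps >= 1, r_max > core)
  dielectric <- params$dielectric %||% 80
  coulomb_k <- 332.0637 / dielectric
  u <- function(r) coulomb_k * params$q1q2 * exp(-r / lambda) / r
  edges <- seq(core, r_max, length.out = n_steps + 1)
  levels <- vapply(seq_len(n_steps), function(k) {
    stats::integrate(u, edges[k], edges[k + 1])$value /
      (edges[k + 1] - edges[k])
  }, numeric(1))
  step_potential(edges, c(Inf, levels))
}
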