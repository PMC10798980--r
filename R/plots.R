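#' Plot a per-residue binding-frequency map
#'
#' @param object A `binding_frequency_map` from [binding_frequency()].
#' @param ... Unused.
#' @return A ggplot: frequency vs residue, one panel per chain.
#' @export
autoplot.binding_frequency_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$residue_index, .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain_id)) +
    ggplot2::labs(x = "residue", y = "binding frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an RMSF profile
#'
#' @param object An `rmsf_profile` from [rmsf_profile()].
#' @param ... Unused.
#' @return A ggplot of per-residue RMSF.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$residue_index, .data$rmsf)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain_id)) +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Violin plot of a steered campaign
#'
#' First dissociation times per force level (censored runs sit at the run
#' duration), one violin per force, coloured by ligand condition.
#'
#' @param object A `steered_campaign`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.steered_campaign <- function(object, ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(factor(.data$force),
                                    .data$dissociation_time,
                                    fill = .data$condition)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7,
                         position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = "applied force (pN)",
                  y = "first dissociation time (ns)",
                  fill = "ligand") +
    ggplot2::theme_minimal()
}

#' Plot the energy ledger of a trajectory
#'
#' @param object A `dmd_trajectory`.
#' @param ... Unused.
#' @return A ggplot of kinetic, potential and total energy vs time.
#' @export
autoplot.dmd_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$energy, -"time",
                              names_to = "component", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$energy,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Tidy / glance methods for campaign objects
#'
#' `tidy()` returns the long per-replica record table; `glance()` a
#' one-row summary.
#'
#' @param x A `steered_campaign` or `binding_campaign`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.steered_campaign <- function(x, ...) x$records

#' @rdname tidy.steered_campaign
#' @export
glance.steered_campaign <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$report$conditions),
    n_forces = length(x$report$force_grid),
    n_records = nrow(x$records),
    n_failures = length(x$report$failures),
    simulated_us = x$report$aggregate_time_us,
    association_fraction = mean(x$records$censored)
  )
}

#' @rdname tidy.steered_campaign
#' @export
tidy.binding_campaign <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$dimer_frequency, group = "dimer"),
    dplyr::mutate(x$ligand_frequency, group = "ligand")
  )
}

#' @rdname tidy.steered_campaign
#' @export
glance.binding_campaign <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    n_replicas = x$report$n_replicas,
    n_failures = length(x$report$failures),
    simulated_us = x$report$aggregate_time_us,
    mean_dimer_frequency = mean(x$dimer_frequency$frequency),
    mean_ligand_frequency = mean(x$ligand_frequency$frequency)
  )
}
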