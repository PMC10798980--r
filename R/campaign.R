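#' Campaign configuration
#'
#' Describes the two in-silico campaigns end to end: the zero-force
#' binding campaign (replica simulations of a dimer-ligand system,
#' analyzed into binding-frequency maps and a residue-class breakdown)
#' and the steered campaign (a constant-force grid, replica dissociation
#' times with censoring, and flexible-domain RMSF).
#'
#' Two presets are provided.  `"desk"` (the default) runs the toy system
#' at desk scale: a 2 x 30-residue dimer, 10 replicas, 1 ns runs and a
#' {0, 10, 20, 40} pN force grid — sized so the full pipeline runs in
#' minutes on one CPU.  `"paper"` encodes the published campaign sizes
#' (binding: 40 x 50 ns; steered: 0-60 pN in 10 pN steps, 70 x 100 ns
#' each) and is meant for configuration checks and time bookkeeping, not
#' for desk execution.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ligand A [ligand_spec()], a list of them (named by condition),
#'   or `NULL` for the ligand-free control.
#' @param n_per_chain,n_interface_contacts,swap_fraction,calcium_sites
#'   Dimer generator parameters.
#' @param binding List: `n_replicas`, `duration_ns`, `sampling_ns`.
#' @param steered List: `force_grid` (pN, strictly increasing),
#'   `n_replicas`, `duration_ns`, `sampling_ns`.
#' @param temperature,thermostat_rate Engine parameters.
#' @param min_separation,max_separation,box_edge Placement parameters,
#'   Å; the initial dimer-ligand distance is drawn between the two bounds
#'   so encounters happen within desk-scale run lengths.
#' @param topology_options Options forwarded to [build_topology()].  The
#'   default deepens intra-chain folding wells to 1.5 kcal/mol, widens
#'   interface wells to ±30% (so the toy dimer is marginally stable on
#'   the ns scale at zero force while the strand-swap interface contact
#'   energy stays at the canonical 0.4 kcal/mol) and uses a 0.8 kcal/mol
#'   (~1.3 kT) hydrophobic contact well, the scale typical of one-bead
#'   implicit-solvent contact potentials, so amyloid-dimer binding
#'   persists on the ns scale.
#' @param cutoff,window_fraction Analysis parameters.
#' @param pull_delta Force-plane spacing, Å.
#' @param master_seed Master RNG seed; all per-replica seeds derive from
#'   it by a documented counter scheme, so conditions can run in any
#'   order.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(preset = c("desk", "paper"),
                            ligand = ligand_spec("oligomer"),
                            n_per_chain = 30,
                            n_interface_contacts = 16,
                            swap_fraction = 0.5,
                            calcium_sites = c(5, 11, 20, 26),
                            binding = NULL,
                            steered = NULL,
                            temperature = 300,
                            thermostat_rate = 0.1,
                            min_separation = 12,
                            max_separation = 20,
                            box_edge = 70,
                            topology_options = list(
                              intra_epsilon = 1.5,
                              interface_well_width = 0.3,
                              hydrophobic_depth = 0.8),
                            cutoff = 6.5,
                            window_fraction = 0.4,
                            pull_delta = 0.5,
                            master_seed = 1) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper") {
    list(
      binding = list(n_replicas = 40, duration_ns = 50, sampling_ns = 0.25),
      steered = list(force_grid = seq(0, 60, by = 10), n_replicas = 70,
                     duration_ns = 100, sampling_ns = 0.5)
    )
  } else {
    list(
      binding = list(n_replicas = 10, duration_ns = 1, sampling_ns = 0.005),
      steered = list(force_grid = c(0, 10, 20, 40), n_replicas = 10,
                     duration_ns = 1, sampling_ns = 0.005)
    )
  }
  binding <- utils::modifyList(defaults$binding, binding %||% list())
  steered <- utils::modifyList(defaults$steered, steered %||% list())
  stopifnot(binding$n_replicas >= 1, steered$n_replicas >= 1)
  fg <- steered$force_grid
  if (any(fg < 0) || any(diff(fg) <= 0)) {
    stop("force grid must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (inherits(ligand, "ligand_spec")) ligand <- list(ligand)
  if (!is.null(ligand) && is.null(names(ligand))) {
    names(ligand) <- vapply(ligand, function(l) l$kind, character(1))
  }
  structure(
    list(
      preset = preset, ligand = ligand, n_per_chain = n_per_chain,
      n_interface_contacts = n_interface_contacts,
      swap_fraction = swap_fraction, calcium_sites = calcium_sites,
      binding = binding, steered = steered,
      temperature = temperature, thermostat_rate = thermostat_rate,
      min_separation = min_separation, max_separation = max_separation,
      box_edge = box_edge,
      topology_options = topology_options,
      cutoff = cutoff, window_fraction = window_fraction,
      pull_delta = pull_delta, master_seed = master_seed
    ),
    class = "campaign_config"
  )
}

#' Aggregate simulated time of a campaign
#'
#' `n_replicas x duration` summed over the campaign's conditions, in
#' microseconds.  The paper-scale binding preset (40 x 50 ns) totals
#' 2.0 μs; its steered preset (7 forces x 70 x 100 ns) totals 49 μs.
#'
#' @param config A [campaign_config()].
#' @param campaign `"binding"` or `"steered"`.
#' @return Simulated time in μs.
#' @export
campaign_total_time <- function(config, campaign = c("binding", "steered")) {
  campaign <- match.arg(campaign)
  if (campaign == "binding") {
    config$binding$n_replicas * config$binding$duration_ns / 1000
  } else {
    length(config$steered$force_grid) * config$steered$n_replicas *
      config$steered$duration_ns / 1000
  }
}

# per-replica seeds: a documented counter scheme over (condition, force,
# replica), keeping every derived seed positive and below 2^31
derive_seed <- function(master_seed, condition_index = 0, force_index = 0,
                        replica_index = 0) {
  m <- 2147483629
  s <- (master_seed %% m)
  s <- (s * 48271 + condition_index * 1000003) %% m
  s <- (s * 48271 + force_index * 10007) %% m
  s <- (s * 48271 + replica_index) %% m
  as.integer(s + 1)
}

build_campaign_system <- function(config, condition, replica_seed) {
  dimer <- generate_toy_dimer(
    config$n_per_chain, config$n_interface_contacts, config$swap_fraction,
    config$calcium_sites, seed = derive_seed(config$master_seed)
  )
  if (is.null(condition)) {
    attr(dimer, "box_edge") <- config$box_edge
    sys <- dimer
    pos <- bead_positions(sys)
    shift <- config$box_edge / 2 - colMeans(pos)
    sys$x <- sys$x + shift[1]; sys$y <- sys$y + shift[2]
    sys$z <- sys$z + shift[3]
  } else {
    lig <- generate_ligand(condition)
    sys <- place_components(dimer, lig, config$min_separation,
                            config$box_edge, seed = replica_seed,
                            max_separation = config$max_separation)
  }
  build_topology(sys, options = config$topology_options)
}

condition_list <- function(config, include_control = TRUE) {
  c(if (include_control) list(none = NULL), config$ligand %||% list())
}

#' Run the zero-force binding campaign
#'
#' Builds the dimer-ligand system (a fresh random placement per replica),
#' runs `n_replicas` thermostatted trajectories at zero force, and
#' computes both directions of per-residue binding frequency plus the
#' residue-class interaction breakdown on the configured analysis window,
#' averaged over replicas.  Engine failures in single replicas are
#' recorded in the report and do not abort the campaign.
#'
#' @param config A [campaign_config()].
#' @param keep_trajectories Keep the trajectory objects in the result.
#' @return A `binding_campaign` list: `dimer_frequency` and
#'   `ligand_frequency` tibbles (mean, per-replica spread), `breakdown`,
#'   `contact_series`, `report`.
#' @export
run_binding_campaign <- function(config, keep_trajectories = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  lig <- config$ligand
  condition <- if (is.null(lig)) NULL else lig[[1]]
  cond_name <- if (is.null(condition)) "none" else names(lig)[1]
  b <- config$binding
  freq_d <- list(); freq_l <- list(); brk <- list(); cs <- list()
  trajs <- list(); failures <- character(); seeds <- integer()
  for (k in seq_len(b$n_replicas)) {
    seed_k <- derive_seed(config$master_seed, 1, 0, k)
    seeds[k] <- seed_k
    res <- tryCatch({
      topo <- build_campaign_system(config, condition, seed_k)
      cfg <- sim_config(b$duration_ns, b$sampling_ns, config$temperature,
                        config$thermostat_rate, seed = seed_k,
                        box_edge = config$box_edge)
      tr <- run_dmd(topo, cfg)
      cs[[k]] <- dplyr::mutate(contact_count_series(tr), replicate = k)
      if (!is.null(condition)) {
        freq_d[[k]] <- dplyr::mutate(
          binding_frequency(tr, "component_1", "component_2",
                            config$cutoff, config$window_fraction),
          replicate = k)
        freq_l[[k]] <- dplyr::mutate(
          binding_frequency(tr, "component_2", "component_1",
                            config$cutoff, config$window_fraction),
          replicate = k)
        brk[[k]] <- dplyr::mutate(
          interaction_class_breakdown(tr, config$cutoff,
                                      config$window_fraction),
          replicate = k)
      }
      if (keep_trajectories) trajs[[k]] <- tr
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures <- c(failures, sprintf("replica %d: %s", k, res))
  }
  summarise_freq <- function(lst) {
    if (length(lst) == 0) {
      return(tibble::tibble(chain_id = character(), residue_index = integer(),
                            frequency = numeric(), sd = numeric()))
    }
    dplyr::bind_rows(lst) |>
      dplyr::group_by(.data$chain_id, .data$residue_index) |>
      dplyr::summarise(sd = stats::sd(.data$frequency),
                       frequency = mean(.data$frequency), .groups = "drop")
  }
  breakdown <- if (length(brk) > 0) {
    dplyr::bind_rows(brk) |>
      dplyr::group_by(.data$class_a, .data$class_b) |>
      dplyr::summarise(n_contacts = sum(.data$n_contacts),
                       fraction = mean(.data$fraction), .groups = "drop")
  } else {
    tibble::tibble(class_a = character(), class_b = character(),
                   n_contacts = integer(), fraction = numeric())
  }
  structure(
    list(
      condition = cond_name,
      dimer_frequency = summarise_freq(freq_d),
      ligand_frequency = summarise_freq(freq_l),
      breakdown = breakdown,
      contact_series = dplyr::bind_rows(cs),
      trajectories = if (keep_trajectories) trajs else NULL,
      report = list(
        campaign = "binding", condition = cond_name,
        control_only = is.null(condition),
        n_replicas = b$n_replicas, duration_ns = b$duration_ns,
        aggregate_time_us = campaign_total_time(config, "binding"),
        seeds = seeds, failures = failures,
        tables = c("dimer_frequency", "ligand_frequency", "breakdown",
                   "contact_series"),
        config = config
      )
    ),
    class = "binding_campaign"
  )
}

#' Run the steered (constant-force) campaign
#'
#' For every configured ligand condition (always including the
#' ligand-free control) and every force on the grid, runs `n_replicas`
#' steered trajectories pulling the flexible domain along +z, extracts
#' censored first dissociation times, aggregates them per force, and
#' computes the flexible-domain RMSF from the zero-force replicas.
#'
#' @param config A [campaign_config()].
#' @param include_control Also run the ligand-free dimer.
#' @return A `steered_campaign` list: `records` (long tibble: condition,
#'   force, replicate, dissociation_time, censored), `summary` (via
#'   [aggregate_campaign()]), `rmsf` (per condition), `report`.
#' @export
run_steered_campaign <- function(config, include_control = TRUE) {
  stopifnot(inherits(config, "campaign_config"))
  s <- config$steered
  conds <- condition_list(config, include_control)
  records <- list(); rmsf_tabs <- list(); failures <- character()
  seeds <- list()
  for (ci in seq_along(conds)) {
    cond_name <- names(conds)[ci]
    condition <- conds[[ci]]
    for (fi in seq_along(s$force_grid)) {
      force <- s$force_grid[fi]
      protocol <- if (force > 0) {
        build_force_protocol(force, c(0, 0, 1), config$pull_delta)
      } else {
        NULL
      }
      for (k in seq_len(s$n_replicas)) {
        seed_k <- derive_seed(config$master_seed, ci, fi, k)
        seeds[[length(seeds) + 1]] <- tibble::tibble(
          condition = cond_name, force = force, replicate = k, seed = seed_k)
        res <- tryCatch({
          topo <- build_campaign_system(config, condition, seed_k)
          cfg <- sim_config(s$duration_ns, s$sampling_ns, config$temperature,
                            config$thermostat_rate, seed = seed_k,
                            box_edge = config$box_edge)
          tr <- run_dmd(topo, cfg, protocol)
          series <- contact_count_series(tr)
          rec <- first_dissociation_time(series, s$duration_ns)
          records[[length(records) + 1]] <- dplyr::mutate(
            rec, condition = cond_name, force = force, replicate = k,
            .before = 1)
          if (force == 0) {
            # bound-state flexibility: use the associated segment only,
            # so a dissociation event does not masquerade as flexibility
            zero <- which(series$count == 0)
            lastf <- if (length(zero)) zero[1] - 1L else length(series$time)
            if (lastf >= 25) {
              sub <- truncate_trajectory(tr, lastf)
              rmsf_tabs[[length(rmsf_tabs) + 1]] <- dplyr::mutate(
                rmsf_profile(sub, "flexible_domain", config$window_fraction),
                condition = cond_name, replicate = k)
            }
          }
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res)) {
          failures <- c(failures, sprintf("%s F=%g replica %d: %s",
                                          cond_name, force, k, res))
        }
      }
    }
  }
  records <- dplyr::bind_rows(records)
  rmsf <- if (length(rmsf_tabs) > 0) {
    dplyr::bind_rows(rmsf_tabs) |>
      dplyr::group_by(.data$condition, .data$chain_id,
                      .data$residue_index) |>
      dplyr::summarise(rmsf = mean(.data$rmsf), .groups = "drop")
  } else {
    tibble::tibble()
  }
  structure(
    list(
      records = records,
      summary = aggregate_campaign(records),
      rmsf = rmsf,
      report = list(
        campaign = "steered",
        conditions = names(conds),
        force_grid = s$force_grid,
        n_replicas = s$n_replicas, duration_ns = s$duration_ns,
        aggregate_time_us = campaign_total_time(config, "steered"),
        seeds = dplyr::bind_rows(seeds), failures = failures,
        tables = c("records", "summary", "rmsf"),
        config = config
      )
    ),
    class = "steered_campaign"
  )
}

#' @export
print.binding_campaign <- function(x, ...) {
  cat(sprintf(
    "<binding_campaign> condition %s, %d replicas (%d failed), %.3g us simulated\n",
    x$condition, x$report$n_replicas, length(x$report$failures),
    x$report$aggregate_time_us
  ))
  invisible(x)
}

#' @export
print.steered_campaign <- function(x, ...) {
  cat(sprintf(
    "<steered_campaign> %s; forces {%s} pN, %d replicas each\n",
    paste(x$report$conditions, collapse = ", "),
    paste(x$report$force_grid, collapse = ", "), x$report$n_replicas
  ))
  invisible(x)
}

#' Validate a campaign configuration without running it
#'
#' Checks the structural invariants of a config (force grid, replica
#' counts, preset arithmetic) and, for the paper preset, that it matches
#' the published campaign sizes exactly.
#'
#' @param config A [campaign_config()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_campaign_config <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  if (config$preset == "paper") {
    stopifnot(
      config$binding$n_replicas == 40,
      config$binding$duration_ns == 50,
      identical(as.numeric(config$steered$force_grid),
                as.numeric(seq(0, 60, 10))),
      config$steered$n_replicas == 70,
      config$steered$duration_ns == 100,
      campaign_total_time(config, "binding") == 2.0
    )
  }
  invisible(TRUE)
}
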