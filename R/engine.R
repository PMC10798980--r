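#' Simulation configuration
#'
#' Durations are given in ns and converted to reduced time units
#' (1 unit ≈ 48.89 fs) internally.
#'
#' @param duration_ns Run length, ns.
#' @param sampling_ns Frame spacing, ns.
#' @param temperature Target temperature, K.
#' @param thermostat_rate Anderson-thermostat velocity reassignments per
#'   mobile bead per reduced time unit; 0 disables the thermostat (NVE).
#'   The default 0.1 couples the heat bath weakly enough not to distort
#'   escape kinetics.
#' @param seed Integer seed governing the thermostat stream (velocities
#'   are seeded separately via [initialize_velocities()]).
#' @param box_edge Reflecting cubic box edge, Å; `NULL` defers to the
#'   topology (or 4x the system diameter).
#' @return A `sim_config` list; durations also stored in reduced units.
#' @export
sim_config <- function(duration_ns = 1, sampling_ns = duration_ns / 200,
                       temperature = 300, thermostat_rate = 0.1,
                       seed = 1, box_edge = NULL) {
  stopifnot(temperature > 0, duration_ns > 0, sampling_ns <= duration_ns,
            sampling_ns > 0, thermostat_rate >= 0)
  structure(
    list(
      duration_ns = duration_ns, sampling_ns = sampling_ns,
      duration = ns_to_reduced(duration_ns),
      sampling_interval = ns_to_reduced(sampling_ns),
      temperature = temperature, thermostat_rate = thermostat_rate,
      seed = seed, box_edge = box_edge
    ),
    class = "sim_config"
  )
}

#' Maxwell-Boltzmann initial velocities
#'
#' Each mobile bead's velocity components are drawn from a zero-mean
#' Gaussian with variance kB T / m; the centre-of-mass momentum of the
#' mobile set is then removed.  Immobilized beads get zero velocity.
#'
#' @param topology A `dmd_topology`.
#' @param temperature Temperature, K.
#' @param seed RNG seed.
#' @return n x 3 matrix of velocities, Å per reduced time unit.
#' @export
initialize_velocities <- function(topology, temperature = 300, seed = 1) {
  n <- nrow(topology$beads)
  m <- topology$beads$mass
  mobile <- setdiff(seq_len(n), topology$immobilized)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vel <- matrix(0, n, 3)
  kT <- thermal_energy(temperature)
  vel[mobile, ] <- stats::rnorm(length(mobile) * 3) *
    sqrt(kT / m[mobile])
  if (length(mobile) > 0) {
    p <- colSums(vel[mobile, , drop = FALSE] * m[mobile])
    vel[mobile, ] <- sweep(vel[mobile, , drop = FALSE], 2,
                           p / sum(m[mobile]))
  }
  vel
}

#' Predict the next shell crossing of a pair
#'
#' Solves \eqn{|r + v t| = R} for the nearest reachable shell of a pair
#' moving ballistically.  Bands are numbered so that band `k` is the
#' region between `shell_radii[k]` and `shell_radii[k+1]` (band 0 lies
#' inside the first radius, band `m` beyond the last).
#'
#' @param rel_position,rel_velocity Relative position / velocity 3-vectors
#'   (bead j minus bead i).
#' @param shell_radii Increasing shell radii, Å.
#' @param current_band Band index the pair currently occupies (0-based, as
#'   above); pairs exactly on a shell are treated as just-crossed.
#' @return `NULL` if no shell is reachable, else a list with `time` (>= 0)
#'   and `target_band`.
#' @export
predict_pair_event <- function(rel_position, rel_velocity, shell_radii,
                               current_band) {
  r2 <- sum(rel_position^2)
  v2 <- sum(rel_velocity^2)
  if (v2 == 0) return(NULL)
  b <- sum(rel_position * rel_velocity)
  m <- length(shell_radii)
  best <- Inf; target <- NA_integer_
  if (current_band > 0) {
    R <- shell_radii[current_band]
    c0 <- r2 - R^2
    if (b < 0) {
      if (c0 <= 0) {
        best <- 0; target <- current_band - 1L
      } else {
        disc <- b^2 - v2 * c0
        if (disc >= 0) {
          tt <- (-b - sqrt(disc)) / v2
          if (tt >= 0 && tt < best) { best <- tt; target <- current_band - 1L }
        }
      }
    }
  }
  if (current_band < m) {
    R <- shell_radii[current_band + 1]
    disc <- b^2 - v2 * (r2 - R^2)
    if (disc > 0) {
      tt <- (-b + sqrt(disc)) / v2
      if (tt >= 0 && tt < best) { best <- tt; target <- current_band + 1L }
    }
  }
  if (!is.finite(best)) return(NULL)
  list(time = best, target_band = target)
}

#' Resolve a shell crossing energetically
#'
#' At a potential step of height `dU`, a pair with reduced mass `mu` and
#' radial speed `v_r` crosses when its radial kinetic energy exceeds the
#' step (the radial speed is rescaled, conserving total energy exactly)
#' and reflects otherwise; tangential components never change.  An
#' infinite step (hard core, bond wall) always reflects.
#'
#' @param masses Length-2 vector of bead masses, Da (use `Inf` for an
#'   immobilized partner).
#' @param v_r Relative radial velocity at the shell.
#' @param dU Energy step to be climbed, kcal/mol.
#' @return List: `v_r_new`, `crossed`, `ledger_delta` (potential-energy
#'   change, 0 on reflection).
#' @export
resolve_crossing <- function(masses, v_r, dU) {
  mu <- 1 / sum(1 / masses)
  if (is.infinite(dU) && dU > 0) {
    return(list(v_r_new = -v_r, crossed = FALSE, ledger_delta = 0))
  }
  if (0.5 * mu * v_r^2 > dU) {
    s <- if (v_r >= 0) 1 else -1
    list(v_r_new = s * sqrt(v_r^2 - 2 * dU / mu), crossed = TRUE,
         ledger_delta = dU)
  } else {
    list(v_r_new = -v_r, crossed = FALSE, ledger_delta = 0)
  }
}

# assemble per-pair step potentials for the compiled engine:
# a pooled potential list + an n x n index matrix (0 = hard core only via
# class rules is also in the pool; the matrix is fully populated)
compile_interactions <- function(topology) {
  n <- nrow(topology$beads)
  opts <- topology$options
  pots <- list()
  add_pot <- function(radii, levels) {
    pots[[length(pots) + 1]] <<- list(radii = radii, levels = levels)
    length(pots)
  }
  as_levels <- function(sp) c(sp$energies, if (sp$bounded) Inf else 0)

  classes <- c("hydrophobic", "polar", "charged+", "charged-")
  class_id <- match(topology$beads$class, classes)
  class_pot_id <- matrix(0L, 4, 4)
  for (a in 1:4) {
    for (b in a:4) {
      sp <- topology$nonbonded[[class_pair_key(classes[a], classes[b])]]
      id <- add_pot(sp$radii, as_levels(sp))
      class_pot_id[a, b] <- id
      class_pot_id[b, a] <- id
    }
  }
  pot_index <- matrix(class_pot_id[class_id, class_id], n, n)
  diag(pot_index) <- 0L

  # bonds: merge duplicates on a pair into the tightest well
  bonds <- topology$bonds
  if (nrow(bonds) > 0) {
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    merged <- dplyr::summarise(
      dplyr::group_by(bonds, key = key),
      i = pmin(.data$i[1], .data$j[1]), j = pmax(.data$i[1], .data$j[1]),
      d_min = max(.data$d_min), d_max = min(.data$d_max), .groups = "drop"
    )
    for (k in seq_len(nrow(merged))) {
      id <- add_pot(c(merged$d_min[k], merged$d_max[k]), c(Inf, 0, Inf))
      pot_index[merged$i[k], merged$j[k]] <- id
      pot_index[merged$j[k], merged$i[k]] <- id
    }
    bond_keys <- merged$key
  } else {
    bond_keys <- character()
  }

  # native contacts: hard core + square well of depth epsilon
  contacts <- topology$contacts
  if (nrow(contacts) > 0) {
    ckey <- paste(contacts$i, contacts$j)
    keep <- !ckey %in% bond_keys
    contacts <- contacts[keep, , drop = FALSE]
    for (k in seq_len(nrow(contacts))) {
      r_in <- contacts$r_ref[k] * (1 - contacts$well_width[k])
      r_out <- contacts$r_ref[k] * (1 + contacts$well_width[k])
      core <- opts$hard_core
      if (r_in > core) {
        id <- add_pot(c(core, r_in, r_out), c(Inf, 0, -contacts$epsilon[k], 0))
      } else {
        id <- add_pot(c(r_in, r_out), c(Inf, -contacts$epsilon[k], 0))
      }
      pot_index[contacts$i[k], contacts$j[k]] <- id
      pot_index[contacts$j[k], contacts$i[k]] <- id
    }
  }
  list(pots = pots, pot_index = pot_index)
}

resolve_box_edge <- function(topology, config) {
  config$box_edge %||% topology$box_edge %||% {
    pos <- topology$positions
    4 * (max(stats::dist(pos)) / 2 + 5)
  }
}

#' Run one event-driven DMD trajectory
#'
#' Event loop with a priority queue and per-bead validity counters; exact
#' ballistic propagation between events; energy-conserving shell
#' crossings; reflecting box walls; optional Anderson thermostat and
#' constant-force steering (force planes).  Immobilized beads are
#' infinite-mass collision partners and never move.  Fully reproducible
#' for a fixed config seed.
#'
#' @param topology A `dmd_topology` from [build_topology()].
#' @param config A [sim_config()].
#' @param protocol Optional [build_force_protocol()] result; the total
#'   force is divided over the topology's `pulled` set (or applied to its
#'   first bead with `share = "single"`).
#' @param initial_velocities Optional n x 3 matrix; default
#'   [initialize_velocities()] at the config temperature and seed.
#' @return A `dmd_trajectory`: `times` (ns), `frames`
#'   (frame x bead x 3 array, Å), `energy` tibble (per-frame kinetic,
#'   potential and total, kcal/mol), event counts, and the inputs.
#' @export
run_dmd <- function(topology, config, protocol = NULL,
                    initial_velocities = NULL) {
  stopifnot(inherits(topology, "dmd_topology"), inherits(config, "sim_config"))
  n <- nrow(topology$beads)
  if (is.null(initial_velocities)) {
    initial_velocities <- initialize_velocities(topology, config$temperature,
                                                config$seed)
  }
  comp <- compile_interactions(topology)
  mobile <- as.integer(!seq_len(n) %in% topology$immobilized)
  box <- resolve_box_edge(topology, config)
  pos <- topology$positions
  if (any(pos < 0) || any(pos > box)) {
    shift <- box / 2 - colMeans(pos)
    pos <- sweep(pos, 2, shift, `+`)
    if (any(pos < 0) || any(pos > box)) {
      stop("system does not fit in the simulation box", call. = FALSE)
    }
  }
  steer <- list()
  if (!is.null(protocol) && protocol$magnitude > 0) {
    pulled <- topology$pulled
    if (length(pulled) == 0) stop("no pulled beads annotated", call. = FALSE)
    if (protocol$share == "single") pulled <- pulled[1]
    steer <- list(
      direction = protocol$direction,
      delta = protocol$delta,
      energy_per_plane_per_bead = protocol$energy_per_plane / length(pulled),
      pulled = as.integer(pulled)
    )
  }
  res <- .dmd_run_cpp(
    pos, initial_velocities, topology$beads$mass, mobile,
    comp$pots, comp$pot_index, box,
    config$duration, config$sampling_interval,
    config$temperature, config$thermostat_rate, config$seed, steer
  )
  nf <- res$n_frames
  frames <- res$frames[seq_len(nf), , , drop = FALSE]
  structure(
    list(
      times = reduced_to_ns(res$times),
      frames = frames,
      energy = tibble::tibble(
        time = reduced_to_ns(res$times),
        kinetic = res$kinetic,
        potential = res$potential,
        total = res$kinetic + res$potential
      ),
      n_events = res$n_events,
      event_counts = c(
        pair = res$n_pair_events, thermostat = res$n_thermostat_events,
        wall = res$n_wall_events, plane = res$n_plane_events
      ),
      final_velocities = res$final_velocities,
      topology = topology, config = config, protocol = protocol,
      box_edge = box
    ),
    class = "dmd_trajectory"
  )
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dmd_trajectory> %d frames x %d beads, %.3g ns, %d events (%s)\n",
    length(x$times), dim(x$frames)[2], max(x$times), x$n_events,
    paste(names(x$event_counts), x$event_counts, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a trajectory into a long bead table
#'
#' @param x A `dmd_trajectory`.
#' @param ... Unused.
#' @return Tibble: `frame`, `time` (ns), `bead`, `x`, `y`, `z`.
#' @export
tidy.dmd_trajectory <- function(x, ...) {
  nf <- length(x$times); n <- dim(x$frames)[2]
  xs <- as.vector(x$frames[, , 1])
  ys <- as.vector(x$frames[, , 2])
  zs <- as.vector(x$frames[, , 3])
  tibble::tibble(
    frame = rep(seq_len(nf), n),
    time = rep(x$times, n),
    bead = rep(seq_len(n), each = nf),
    x = xs, y = ys, z = zs
  )
}

#' Run independent replicas
#'
#' Replica `k` uses seed `base_seed + k` for both its initial velocities
#' and its thermostat stream, so replicas are independent and can be run
#' in any order.
#'
#' @param topology,config,protocol As in [run_dmd()].
#' @param n_replicas Number of replicas.
#' @param base_seed Base seed.
#' @return List of `dmd_trajectory` objects.
#' @export
run_replicas <- function(topology, config, protocol = NULL,
                         n_replicas = 10, base_seed = 1) {
  stopifnot(n_replicas >= 1)
  purrr::map(seq_len(n_replicas), function(k) {
    cfg <- config
    cfg$seed <- base_seed + k
    run_dmd(topology, cfg, protocol)
  })
}
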