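free_topology <- function(positions, codes = NULL, options = list()) {
  build_topology(toy_beads(positions, codes), options = options)
}

test_that("Maxwell-Boltzmann initialization satisfies its contracts", {
  dim <- generate_toy_dimer(30, 6, 0.5, seed = 1)
  topo <- build_topology(dim)

  # all-immobilized limit
  topo_all <- topo
  topo_all$immobilized <- seq_len(60)
  expect_true(all(initialize_velocities(topo_all, 300, 1) == 0))

  # single mobile bead: COM removal zeroes it
  topo_one <- topo
  topo_one$immobilized <- seq_len(59)
  v1 <- initialize_velocities(topo_one, 300, 1)
  expect_equal(max(abs(v1)), 0)

  # many beads: mean kinetic energy per DOF within 5% of kT/2
  big <- toy_beads(matrix(seq_len(1000 * 3) * 10, 1000, 3), rep("L", 1000))
  topo_big <- build_topology(big)
  v <- initialize_velocities(topo_big, 300, 2)
  ke_dof <- sum(0.5 * topo_big$beads$mass * rowSums(v^2)) / (3 * 1000)
  expect_equal(ke_dof, 0.5 * 0.0019872041 * 300, tolerance = 0.05)

  # immobilized beads stay at zero
  v2 <- initialize_velocities(topo, 300, 3)
  expect_true(all(v2[topo$immobilized, ] == 0))
})

test_that("pair event prediction solves the crossing kinematics", {
  # head-on closing: separation 4, speed 2, shell at 2 -> t = 1
  ev <- predict_pair_event(c(4, 0, 0), c(-2, 0, 0), shell_radii = 2,
                           current_band = 1)
  expect_equal(ev$time, 1.0)
  expect_equal(ev$target_band, 0)

  # receding: separation 3, speed 2, outermost shell 5 -> exit at t = 1
  ev2 <- predict_pair_event(c(3, 0, 0), c(2, 0, 0), shell_radii = 5,
                            current_band = 0)
  expect_equal(ev2$time, 1.0)
  expect_equal(ev2$target_band, 1)

  # never reaches the shell
  expect_null(predict_pair_event(c(4, 0, 0), c(2, 0, 0), 2, 1))

  # oblique case vs brute-force propagation at dt = 1e-4
  r0 <- c(sqrt(4^2 - 1.5^2), 1.5, 0)
  v0 <- c(-1, 0, 0)
  ev3 <- predict_pair_event(r0, v0, shell_radii = 2, current_band = 1)
  t <- 0
  repeat {
    t <- t + 1e-4
    if (sqrt(sum((r0 + v0 * t)^2)) <= 2) break
    if (t > 10) break
  }
  expect_equal(ev3$time, t, tolerance = 2e-4)
})

test_that("crossing resolution conserves energy and reflects hard walls", {
  # radial KE 1.0 against step 0.5: crossing with radial KE 0.5
  mu <- 50
  vr <- sqrt(2 * 1.0 / mu)
  res <- resolve_crossing(c(100, 100), vr, 0.5)
  expect_true(res$crossed)
  expect_equal(0.5 * mu * res$v_r_new^2, 0.5, tolerance = 1e-12)

  # radial KE 0.3 against step 0.5: reflection, magnitude unchanged
  vr2 <- sqrt(2 * 0.3 / mu)
  res2 <- resolve_crossing(c(100, 100), vr2, 0.5)
  expect_false(res2$crossed)
  expect_equal(abs(res2$v_r_new), vr2)
  expect_equal(res2$ledger_delta, 0)

  # falling into the canonical 0.4 kcal/mol contact well
  res3 <- resolve_crossing(c(100, 100), -vr2, -0.4)
  expect_true(res3$crossed)
  expect_equal(0.5 * mu * res3$v_r_new^2, 0.3 + 0.4, tolerance = 1e-12)

  # infinite step always reflects
  res4 <- resolve_crossing(c(100, Inf), 1, Inf)
  expect_false(res4$crossed)
})

test_that("NVE runs conserve total energy to arithmetic precision", {
  dim <- generate_toy_dimer(30, 8, 0.5, c(5, 11), seed = 1)
  topo <- build_topology(dim)
  topo$immobilized <- integer() # fully mobile, no thermostat
  cfg <- sim_config(0.15, 0.001, thermostat_rate = 0, seed = 4, box_edge = 80)
  tr <- run_dmd(topo, cfg)
  expect_gt(tr$n_events, 1e5)
  drift <- max(abs(tr$energy$total - tr$energy$total[1]))
  expect_lt(drift, 1e-6 * tr$n_events / 1e5)
})

test_that("a bound pair below the well depth never escapes", {
  pos <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  topo <- free_topology(pos, c("L", "L"))
  # single deep square well around 5 A; tiny initial speed
  topo$contacts <- tibble::tibble(i = 1L, j = 2L, r_ref = 5, epsilon = 5,
                                  well_width = 0.15)
  vel <- matrix(c(0.005, 0, 0, -0.005, 0, 0), 2, 3, byrow = TRUE)
  cfg <- sim_config(0.05, 0.001, thermostat_rate = 0, seed = 1,
                    box_edge = 60)
  tr <- run_dmd(topo, cfg, initial_velocities = vel)
  d <- sqrt((tr$frames[, 1, 1] - tr$frames[, 2, 1])^2 +
            (tr$frames[, 1, 2] - tr$frames[, 2, 2])^2 +
            (tr$frames[, 1, 3] - tr$frames[, 2, 3])^2)
  expect_true(all(d <= 5 * 1.15 + 1e-9))
})

test_that("thermostatted speeds follow Maxwell-Boltzmann and equipartition", {
  # 50-bead chain of leucines at 300 K
  n <- 50
  pos <- cbind((seq_len(n) - 1) * 3.8, 0, 0) + 40
  beads <- tibble::tibble(
    chain_id = "A", residue_index = seq_len(n), residue_name = "L",
    bead_kind = "backbone", x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  topo <- build_topology(coarse_structure(beads))
  speeds <- c(); ke <- c(); nev <- 0
  for (k in 1:8) {
    cfg <- sim_config(0.04, 0.002, thermostat_rate = 0.2, seed = 50 + k,
                      box_edge = 300)
    tr <- run_dmd(topo, cfg)
    speeds <- c(speeds, sqrt(rowSums(tr$final_velocities^2)))
    ke <- c(ke, tr$energy$kinetic[-(1:5)])
    nev <- nev + tr$n_events
  }
  expect_gt(nev, 1e5)
  kT <- 0.0019872041 * 300
  expect_equal(mean(ke) / (3 * n), kT / 2, tolerance = 0.05)
  ks <- stats::ks.test(speeds, function(s) maxwell_speed_cdf(s, 113.1594, kT))
  expect_gt(ks$p.value, 0.01)
})

test_that("no sampled frame ever violates a hard core", {
  dim <- generate_toy_dimer(24, 6, 0.5, c(5, 9), seed = 3)
  topo <- build_topology(dim)
  cfg <- sim_config(0.05, 0.001, thermostat_rate = 0.1, seed = 9,
                    box_edge = 70)
  tr <- run_dmd(topo, cfg)
  comp <- cgdmd:::compile_interactions(topo)
  n <- nrow(topo$beads)
  viol <- 0
  for (f in seq_along(tr$times)) {
    p <- cbind(tr$frames[f, , 1], tr$frames[f, , 2], tr$frames[f, , 3])
    d <- as.matrix(stats::dist(p))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pid <- comp$pot_index[i, j]
        if (pid > 0) {
          lv <- comp$pots[[pid]]$levels
          core <- comp$pots[[pid]]$radii[1]
          if (is.infinite(lv[1]) && d[i, j] < core - 1e-9) viol <- viol + 1
        }
      }
    }
  }
  expect_equal(viol, 0)
})

test_that("event-driven trajectories match brute-force integration", {
  # three beads, mixed square wells and hard cores, NVE, no walls nearby
  pos <- matrix(c(500, 500, 500,
                  505, 500, 500,
                  500, 506, 500), 3, 3, byrow = TRUE)
  topo <- free_topology(pos, c("L", "L", "S"))
  topo$contacts <- tibble::tibble(
    i = c(1L, 2L), j = c(2L, 3L),
    r_ref = c(5, 6.1), epsilon = c(0.8, 0.5), well_width = 0.2
  )
  vel <- matrix(c(0.02, 0.01, 0, -0.015, 0.005, 0.01, 0, -0.02, -0.01),
                3, 3, byrow = TRUE)
  cfg <- sim_config(
    duration_ns = reduced_to_ns(400), sampling_ns = reduced_to_ns(400),
    thermostat_rate = 0, seed = 1, box_edge = 1000
  )
  tr <- run_dmd(topo, cfg, initial_velocities = vel)
  expect_gt(tr$n_events, 20)

  comp <- cgdmd:::compile_interactions(topo)
  oracle <- brute_force_dmd(pos, vel, topo$beads$mass, comp$pots,
                            comp$pot_index, t_end = 400, dt = 5e-3)
  final <- cbind(tr$frames[dim(tr$frames)[1], , 1],
                 tr$frames[dim(tr$frames)[1], , 2],
                 tr$frames[dim(tr$frames)[1], , 3])
  expect_lt(max(abs(final - oracle$pos)), 1e-4)
})

test_that("immobilized beads are static, infinite-mass collision partners", {
  dim <- generate_toy_dimer(20, 6, 0.5, seed = 5)
  topo <- build_topology(dim)
  cfg <- sim_config(0.03, 0.001, thermostat_rate = 0.1, seed = 2,
                    box_edge = 70)
  tr <- run_dmd(topo, cfg)
  for (a in 1:3) {
    rng <- apply(tr$frames[, topo$immobilized, a, drop = FALSE], 2,
                 function(z) diff(range(z)))
    expect_true(all(rng == 0))
  }
})

test_that("replicas are deterministic, independent and order-insensitive", {
  dim <- generate_toy_dimer(16, 4, 0.5, seed = 1)
  topo <- build_topology(dim)
  cfg <- sim_config(0.01, 0.001, thermostat_rate = 0.1, seed = 1,
                    box_edge = 70)
  r1 <- run_replicas(topo, cfg, n_replicas = 2, base_seed = 10)
  r2 <- run_replicas(topo, cfg, n_replicas = 2, base_seed = 10)
  expect_identical(r1[[1]]$frames, r2[[1]]$frames)
  expect_identical(r1[[2]]$frames, r2[[2]]$frames)
  expect_false(identical(r1[[1]]$frames, r1[[2]]$frames))
  # replica k depends only on base_seed + k, not on position in the list
  r3 <- run_replicas(topo, cfg, n_replicas = 3, base_seed = 9)
  expect_identical(r3[[2]]$frames, r1[[1]]$frames)
})

test_that("bond escape accelerates with force in the Bell-model sense", {
  # single square-well bond between an immobilized and a pulled bead
  beads <- tibble::tibble(
    chain_id = c("A", "B"), residue_index = 1L, residue_name = "L",
    bead_kind = "backbone", x = 30, y = 30, z = c(30, 35)
  )
  s <- coarse_structure(beads, list(
    interface_pairs = matrix(c(1L, 2L), 1),
    immobilized_domain = 1L, flexible_domain = 2L
  ))
  attr(s, "box_edge") <- 60
  topo <- build_topology(s, options = list(contact_epsilon = 2.5,
                                           contact_well_width = 0.3))
  mean_life <- sapply(c(0, 40), function(F) {
    pro <- if (F > 0) build_force_protocol(F, c(0, 0, 1), 0.5) else NULL
    mean(sapply(1:10, function(k) {
      cfg <- sim_config(2, 0.01, thermostat_rate = 0.02, seed = 7000 + k,
                        box_edge = 60)
      tr <- run_dmd(topo, cfg, pro)
      first_dissociation_time(contact_count_series(tr), 2)$dissociation_time
    }))
  })
  expect_lt(mean_life[2], mean_life[1])
})
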