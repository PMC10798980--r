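# hand-built trajectory: known frames for a tiny topology
fake_traj <- function(frames_list, topo, times = NULL) {
  nf <- length(frames_list)
  n <- nrow(frames_list[[1]])
  arr <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames_list[[f]]
  times <- times %||% seq(0, by = 0.01, length.out = nf)
  structure(
    list(
      times = times, frames = arr,
      energy = tibble::tibble(time = times, kinetic = 0, potential = 0,
                              total = 0),
      topology = topo
    ),
    class = "dmd_trajectory"
  )
}

two_bead_topo <- function() {
  pos <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  topo <- build_topology(toy_beads(pos, c("L", "K")))
  topo$interface_contacts <- tibble::tibble(
    i = 1L, j = 2L, r_ref = 5, epsilon = 0.4, well_width = 0.15
  )
  topo
}

test_that("contact counting matches a per-frame brute-force scan", {
  dim <- generate_toy_dimer(20, 6, 0.5, seed = 2)
  topo <- build_topology(dim)
  cfg <- sim_config(0.02, 0.001, thermostat_rate = 0.1, seed = 3,
                    box_edge = 70)
  tr <- run_dmd(topo, cfg)
  cs <- contact_count_series(tr)
  ic <- topo$interface_contacts
  for (f in seq_along(tr$times)) {
    cnt <- 0
    for (k in seq_len(nrow(ic))) {
      d <- sqrt(sum((tr$frames[f, ic$i[k], ] - tr$frames[f, ic$j[k], ])^2))
      if (d <= ic$r_ref[k] * (1 + ic$well_width[k])) cnt <- cnt + 1
    }
    expect_equal(cs$count[f], cnt)
  }
  expect_true(all(cs$count >= 0))

  # all pairs at reference distance -> full count; far apart -> zero
  topo2 <- two_bead_topo()
  t_at <- fake_traj(list(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)),
                    topo2)
  expect_equal(contact_count_series(t_at)$count, 1L)
  t_far <- fake_traj(list(matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE)),
                     topo2)
  expect_equal(contact_count_series(t_far)$count, 0L)
})

test_that("first dissociation time follows the censoring convention", {
  s <- tibble::tibble(time = 0:4, count = c(3L, 2L, 1L, 0L, 0L))
  r <- first_dissociation_time(s, duration = 4)
  expect_equal(r$dissociation_time, 3)
  expect_false(r$censored)

  s2 <- tibble::tibble(time = seq(0, 100, by = 25), count = rep(2L, 5))
  r2 <- first_dissociation_time(s2, duration = 100)
  expect_equal(r2$dissociation_time, 100)
  expect_true(r2$censored)

  s3 <- tibble::tibble(time = 0:2, count = c(0L, 1L, 1L))
  expect_equal(first_dissociation_time(s3, 2)$dissociation_time, 0)

  # monotone under prefixing: a prefix never dissociates later
  set.seed(5)
  for (rep in 1:20) {
    counts <- sample(0:3, 30, TRUE)
    s4 <- tibble::tibble(time = seq(0, 29), count = counts)
    full <- first_dissociation_time(s4, 29)
    pre <- first_dissociation_time(s4[1:15, ], 14)
    if (!full$censored && full$dissociation_time <= 14) {
      expect_equal(pre$dissociation_time, full$dissociation_time)
    } else {
      expect_true(pre$censored)
    }
  }
})

test_that("binding frequency matches brute force and the stated examples", {
  topo <- two_bead_topo()
  # single frame at 5.0 A with the 6.5 A criterion -> frequency 1
  tr1 <- fake_traj(list(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)),
                   topo)
  bf <- binding_frequency(tr1, 1L, 2L, cutoff = 6.5, window_fraction = 1)
  expect_equal(bf$frequency, 1)

  # 7.0 A throughout -> 0
  tr2 <- fake_traj(list(matrix(c(0, 0, 0, 7, 0, 0), 2, 3, byrow = TRUE)),
                   topo)
  expect_equal(binding_frequency(tr2, 1L, 2L, 6.5, 1)$frequency, 0)

  # 10 frames, 4 within cutoff -> 0.4
  frames <- lapply(1:10, function(f) {
    d <- if (f %in% c(2, 5, 7, 9)) 6.0 else 8.0
    matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE)
  })
  tr3 <- fake_traj(frames, topo)
  expect_equal(binding_frequency(tr3, 1L, 2L, 6.5, 1)$frequency, 0.4)

  # random frames vs an explicit loop over a larger system
  dim <- generate_toy_dimer(16, 4, 0.5, seed = 3)
  lig <- generate_ligand(ligand_spec("monomer", 8, seed = 4))
  sys <- place_components(dim, lig, 5, 70, seed = 2)
  topo2 <- build_topology(sys)
  cfg <- sim_config(0.02, 0.001, thermostat_rate = 0.1, seed = 5,
                    box_edge = 70)
  tr4 <- run_dmd(topo2, cfg)
  ga <- topo2$annotations$component_1
  gb <- topo2$annotations$component_2
  got <- binding_frequency(tr4, "component_1", "component_2", 6.5, 0.5)
  nf <- length(tr4$times)
  win <- seq(nf - ceiling(0.5 * nf) + 1, nf)
  for (row in sample(nrow(got), 5)) {
    ch <- got$chain_id[row]; ri <- got$residue_index[row]
    bead <- which(topo2$beads$chain_id == ch &
                  topo2$beads$residue_index == ri)
    bead <- intersect(bead, ga)
    hits <- 0
    for (f in win) {
      dmin <- Inf
      for (b in bead) {
        for (g in gb) {
          dmin <- min(dmin, sqrt(sum((tr4$frames[f, b, ] -
                                      tr4$frames[f, g, ])^2)))
        }
      }
      if (dmin <= 6.5) hits <- hits + 1
    }
    expect_equal(got$frequency[row], hits / length(win))
  }
})

test_that("binding frequency is bounded and monotone in the cutoff", {
  dim <- generate_toy_dimer(16, 4, 0.5, seed = 1)
  lig <- generate_ligand(ligand_spec("monomer", 8, seed = 1))
  sys <- place_components(dim, lig, 5, 70, seed = 3)
  topo <- build_topology(sys)
  cfg <- sim_config(0.02, 0.001, thermostat_rate = 0.1, seed = 2,
                    box_edge = 70)
  tr <- run_dmd(topo, cfg)
  f1 <- binding_frequency(tr, "component_1", "component_2", 5, 0.5)
  f2 <- binding_frequency(tr, "component_1", "component_2", 8, 0.5)
  expect_true(all(f1$frequency >= 0 & f1$frequency <= 1))
  expect_true(all(f2$frequency - f1$frequency >= 0))
  expect_error(binding_frequency(tr, "component_1", "component_1", 6.5, 0.5),
               "disjoint")
})

test_that("RMSF handles static, closed-form and rigid-motion cases", {
  topo <- two_bead_topo()
  static <- fake_traj(rep(list(matrix(c(0, 0, 0, 5, 0, 0), 2, 3,
                                      byrow = TRUE)), 5), topo)
  expect_true(all(rmsf_profile(static, 1:2, 1)$rmsf == 0))

  # one bead alternating x = +/- a -> RMSF = a
  a <- 1.7
  frames <- lapply(1:6, function(f) {
    matrix(c((-1)^f * a, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  })
  tr <- fake_traj(frames, topo)
  expect_equal(rmsf_profile(tr, 1L, 1)$rmsf, a, tolerance = 1e-12)

  # single-frame window fails
  expect_error(rmsf_profile(fake_traj(frames[1], topo), 1:2, 1), "two frames")

  # translation invariance without alignment
  shift_frames <- lapply(seq_along(frames), function(f) {
    sweep(frames[[f]], 2, c(f * 10, -f, 2 * f), `+`)
  })
  # (translating every frame equally leaves deviations unchanged only in
  # kabsch mode; for no-alignment use a fixed shift)
  fixed <- lapply(frames, function(m) sweep(m, 2, c(10, -3, 2), `+`))
  expect_equal(rmsf_profile(fake_traj(fixed, topo), 1L, 1)$rmsf, a)

  # kabsch mode: rigid rotation + translation of every frame is removed
  dimr <- generate_toy_dimer(12, 2, 0.5, seed = 6)
  topo2 <- build_topology(dimr)
  base <- cbind(dimr$x, dimr$y, dimr$z)
  set.seed(8)
  wob <- lapply(1:8, function(f) base + matrix(rnorm(nrow(base) * 3, 0, 0.2),
                                               ncol = 3))
  th <- seq(0.1, 0.8, length.out = 8)
  moved <- lapply(1:8, function(f) {
    R <- matrix(c(cos(th[f]), -sin(th[f]), 0,
                  sin(th[f]), cos(th[f]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    sweep(wob[[f]] %*% R, 2, c(f, 2 * f, -f), `+`)
  })
  r_plain <- rmsf_profile(fake_traj(wob, topo2), NULL, 1)
  r_moved <- rmsf_profile(fake_traj(moved, topo2), NULL, 1,
                          align = "kabsch")
  expect_equal(r_moved$rmsf, r_plain$rmsf, tolerance = 0.05)
})

test_that("class breakdown fractions are exact on constructed frames", {
  # dimer bead classes: L (hydrophobic) and K (charged+); ligand bead E
  pos <- matrix(c(0, 0, 0, 8, 0, 0, 4, 0, 0), 3, 3, byrow = TRUE)
  beads <- tibble::tibble(
    chain_id = c("A", "A", "L1"), residue_index = c(1L, 3L, 1L),
    residue_name = c("L", "K", "E"), bead_kind = "backbone",
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  s <- coarse_structure(beads, list(component_1 = 1:2, component_2 = 3L))
  topo <- build_topology(s)
  tr <- fake_traj(list(pos), topo)
  br <- interaction_class_breakdown(tr, cutoff = 5, window_fraction = 1)
  # ligand E within 5 A of both dimer beads -> two contacts, classes
  # hydrophobic|charged- and charged+|charged-
  expect_equal(sum(br$n_contacts), 2)
  expect_equal(sum(br$fraction), 1)
  hit <- br[br$n_contacts > 0, ]
  expect_setequal(
    paste(hit$class_a, hit$class_b),
    c("charged- hydrophobic", "charged+ charged-")
  )

  # no contacts -> all-zero map
  far <- pos; far[3, 1] <- 100
  tr2 <- fake_traj(list(far), topo)
  br2 <- interaction_class_breakdown(tr2, 5, 1)
  expect_true(all(br2$fraction == 0))
})

test_that("campaign aggregation reproduces spreadsheet arithmetic", {
  rec <- tibble::tibble(
    force = c(10, 10, 10, 20, 20),
    replicate = c(1:3, 1:2),
    dissociation_time = c(20, 40, 100, 100, 100),
    censored = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  agg <- aggregate_campaign(rec)
  r10 <- agg[agg$force == 10, ]
  expect_equal(r10$n, 3)
  expect_equal(r10$mean_dissociation, (20 + 40 + 100) / 3, tolerance = 1e-12)
  expect_equal(r10$association_fraction, 1 / 3)
  expect_equal(r10$values[[1]], c(20, 40, 100))
  r20 <- agg[agg$force == 20, ]
  expect_equal(r20$mean_dissociation, 100)
  expect_equal(r20$association_fraction, 1)
})

test_that("charge selectivity: anionic ligand prefers cationic residues", {
  # beads of both charges on the dimer at equal geometric footing
  dim <- generate_toy_dimer(30, 16, 0.5, c(5, 11, 20, 26), seed = 1)
  lig <- generate_ligand(ligand_spec("oligomer", seed = 2))
  freqs <- list()
  for (k in 1:6) {
    sys <- place_components(dim, lig, 12, 70, seed = 40 + k)
    topo <- build_topology(sys, options = list(intra_epsilon = 1.5,
                                               interface_well_width = 0.3,
                                               dielectric = 40))
    cfg <- sim_config(0.6, 0.006, thermostat_rate = 0.1, seed = 40 + k,
                      box_edge = 70)
    tr <- run_dmd(topo, cfg)
    bf <- binding_frequency(tr, "component_1", "component_2", 6.5, 0.4)
    props <- topo$beads[topo$annotations$component_1, ]
    bf$charge <- props$charge[match(
      paste(bf$chain_id, bf$residue_index),
      paste(props$chain_id, props$residue_index)
    )]
    freqs[[k]] <- bf
  }
  all <- dplyr::bind_rows(freqs)
  f_cat <- mean(all$frequency[all$charge > 0])
  f_ani <- mean(all$frequency[all$charge < 0])
  expect_gt(f_cat, f_ani)
})
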