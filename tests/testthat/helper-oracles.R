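# Independent oracles used across the test files.

# Brute-force propagation of the same step-potential Hamiltonian the
# engine runs: small-timestep ballistic motion with bisected crossing
# detection.  Independent of the event-driven code path.
brute_force_dmd <- function(pos, vel, masses, pots, pot_index,
                            t_end, dt = 1e-4) {
  n <- nrow(pos)
  band_of <- function(p, r) sum(r < p - 1e-12)
  # current band per pair
  band <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- pot_index[i, j]
      if (pid > 0) {
        r <- sqrt(sum((pos[j, ] - pos[i, ])^2))
        band[i, j] <- sum(pots[[pid]]$radii < r - 1e-12)
      }
    }
  }
  t <- 0
  n_events <- 0
  while (t < t_end - 1e-12) {
    step <- min(dt, t_end - t)
    # find earliest crossing within step by bisection on each pair
    repeat {
      earliest <- step
      hit <- NULL
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          pid <- pot_index[i, j]
          if (pid == 0) next
          radii <- pots[[pid]]$radii
          b <- band[i, j]
          dvec <- (pos[j, ] + vel[j, ] * earliest) -
                  (pos[i, ] + vel[i, ] * earliest)
          nb <- sum(radii < sqrt(sum(dvec^2)) - 1e-12)
          if (nb != b) {
            # bisect the first crossing time
            lo <- 0; hi <- earliest
            for (it in 1:80) {
              mid <- (lo + hi) / 2
              dvec <- (pos[j, ] + vel[j, ] * mid) - (pos[i, ] + vel[i, ] * mid)
              nbm <- sum(radii < sqrt(sum(dvec^2)) - 1e-12)
              if (nbm != b) hi <- mid else lo <- mid
            }
            earliest <- hi
            hit <- c(i, j)
          }
        }
      }
      if (is.null(hit)) {
        pos <- pos + vel * earliest
        t <- t + earliest
        break
      }
      # advance to the crossing and resolve it
      pos <- pos + vel * earliest
      t <- t + earliest
      step <- step - earliest
      i <- hit[1]; j <- hit[2]
      pid <- pot_index[i, j]
      radii <- pots[[pid]]$radii
      levels <- pots[[pid]]$levels
      b <- band[i, j]
      r <- pos[j, ] - pos[i, ]
      rr <- sqrt(sum(r^2))
      nb <- sum(radii < rr - 1e-12)
      target <- if (nb > b) b + 1L else b - 1L
      nh <- r / rr
      vr <- sum((vel[j, ] - vel[i, ]) * nh)
      res <- resolve_crossing(masses[c(i, j)], vr, levels[target + 1] - levels[b + 1])
      mu <- 1 / sum(1 / masses[c(i, j)])
      dv <- res$v_r_new - vr
      vel[j, ] <- vel[j, ] + mu / masses[j] * dv * nh
      vel[i, ] <- vel[i, ] - mu / masses[i] * dv * nh
      if (res$crossed) {
        band[i, j] <- target
      } else {
        # reflected: the bisected position sits a hair beyond the shell;
        # nudge it back to the occupied side (error ~1e-12 A)
        side <- if (target > b) 1 - 1e-12 else 1 + 1e-12
        pos[j, ] <- pos[i, ] + nh * radii[min(b, target) + 1] * side
      }
      n_events <- n_events + 1
      if (step <= 1e-15) break
    }
  }
  list(pos = pos, vel = vel, n_events = n_events)
}

# closed-form Maxwell-Boltzmann speed CDF (3D), mass in Da, kT in kcal/mol
maxwell_speed_cdf <- function(s, mass, kT) {
  x <- s * sqrt(mass / (2 * kT))
  pmin(pmax(2 * stats::pnorm(x * sqrt(2)) - 1 -
            2 * x * exp(-x^2) / sqrt(pi), 0), 1)
}

# a tiny free-floating test system: k single-residue chains (no bonds),
# polar residues (hard core only) unless codes given
toy_beads <- function(positions, codes = NULL) {
  n <- nrow(positions)
  codes <- codes %||% rep("S", n)
  beads <- tibble::tibble(
    chain_id = LETTERS[seq_len(n)],
    residue_index = 1L,
    residue_name = codes,
    bead_kind = "backbone",
    x = positions[, 1], y = positions[, 2], z = positions[, 3]
  )
  coarse_structure(beads, list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small canned PDB text: three residues (ALA, GLY, SER) on one chain,
# CA + CB records where chemically present
toy_pdb_text <- function() {
  c(
    "HEADER    SYNTHETIC TEST STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       5.100   0.200   0.100  1.00  0.00           C",
    "ATOM      5  N   SER A   3       7.000   1.000   0.500  1.00  0.00           N",
    "ATOM      6  CA  SER A   3       8.700   0.900   0.400  1.00  0.00           C",
    "ATOM      7  CB  SER A   3       9.300   2.280   0.600  1.00  0.00           C",
    "END"
  )
}
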