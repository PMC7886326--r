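# Physics-level checks of the Langevin engine use small closed-form
# systems; phenomenology at realistic sizes lives in the acceptance tests.

kBT310 <- 0.0019872041 * 310

test_that("bead mapping groups three residues with averaged partial beads", {
  b <- map_to_beads(strrep("L", 9))
  expect_equal(nrow(b), 3)
  expect_equal(b$hydrophobicity, rep(-0.55 * 3, 3))
  # KRD: one bead, +1 + 1 - 1 = +1
  krd <- map_to_beads("KRD")
  expect_equal(krd$charge, 1)
  # partial final bead averages its residues, then scales by 3
  b7 <- map_to_beads(strrep("L", 7))
  expect_equal(nrow(b7), 3)
  expect_equal(b7$n_res, c(3L, 3L, 1L))
  expect_equal(b7$hydrophobicity[3], -0.55 * 3)
  # favorable partitioning is negative on the transfer scale
  expect_lt(
    map_to_beads("LLL")$hydrophobicity,
    map_to_beads("NNN")$hydrophobicity
  )
  expect_error(map_to_beads("LLX"), "non-canonical")
  # charge bound |q| <= 3
  expect_equal(map_to_beads("RRR")$charge, 3)
})

test_that("free-bead mean-squared displacement follows 6 D t", {
  p <- cg_params()
  n_steps <- 12000L
  t_total <- n_steps * p$dt
  d <- fpatools:::cpp_free_diffusion(3000L, n_steps, p$dt, p$D, 1234)
  msd <- rowSums(d^2)
  se <- sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - 6 * p$D * t_total), 3 * se)
})

test_that("drift and stationary variance match the overdamped closed forms", {
  p <- cg_params()
  # constant force: mean displacement = (D / kBT) * F * t
  n <- 10000L
  xs <- vapply(1:300, function(w) {
    fpatools:::cpp_sim_1d(
      n, p$dt, p$D, kBT310,
      1, 0, 0, 0, n - 1L, 1L, 5000 + w
    )[1]
  }, numeric(1))
  t_tot <- n * p$dt
  drift_expected <- p$D / kBT310 * (-1) * t_tot
  se <- sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - drift_expected), 3 * se)

  # harmonic well U = c2 x^2 (k = 2 c2): Var(x) = kBT / k by equipartition
  c2 <- 5
  samp <- fpatools:::cpp_sim_1d(
    4e6, p$dt, p$D, kBT310, 0, c2, 0, 0, 5e4, 50L, 99
  )
  expect_equal(var(samp), kBT310 / (2 * c2), tolerance = 0.05)
  # tilted harmonic: mean position -c1 / (2 c2), i.e. force balance
  # (averaged over independent streams to beat the OU correlation time)
  m_tilt <- mean(vapply(100:102, function(s) {
    mean(fpatools:::cpp_sim_1d(
      4e6, p$dt, p$D, kBT310, 1.5, c2, 0, 0, 5e4, 50L, s
    ))
  }, numeric(1)))
  expect_equal(m_tilt, -1.5 / (2 * c2), tolerance = 0.04)
})

test_that("double-well occupancy matches the Boltzmann quadrature oracle", {
  p <- cg_params()
  c1 <- 0.5
  c4 <- 1
  un <- function(x) c1 * x + c4 * (x^2 - 1)^2
  z_left <- integrate(function(x) exp(-un(x) / kBT310), -3, 0)$value
  z_right <- integrate(function(x) exp(-un(x) / kBT310), 0, 3)$value
  p_left_expected <- z_left / (z_left + z_right)
  samp <- fpatools:::cpp_sim_1d(
    3e8, p$dt, p$D, kBT310, c1, 0, c4, -1, 1e5, 100L, 4242
  )
  p_left <- mean(samp < 0)
  expect_equal(p_left, p_left_expected, tolerance = 0.02)
})

test_that("gate switching satisfies the two-state Boltzmann law and detailed balance", {
  g <- cg_geometry()
  p <- cg_params()
  # empty gate region, dG0 = 2 kcal/mol favoring closed
  pos <- matrix(c(0, 0, 3.8), 1)
  frac <- fpatools:::cpp_gate_equilibrium(
    pos, 0, fpatools:::cpp_geom(g), fpatools:::cpp_par(p), 2e6, 77
  )
  expected <- 1 / (1 + exp(p$gate_dG0 / p$kBT))
  expect_equal(frac, expected, tolerance = 0.02 * expected + 0.005)
  # a hydrophobic bead parked in the gate region biases the gate open:
  # dG_eff = dG0 + coupling * h
  h <- -3.3
  pos2 <- matrix(c(0, 0, 1.0), 1) # inside pore, below the gate-region top
  frac2 <- fpatools:::cpp_gate_equilibrium(
    pos2, h, fpatools:::cpp_geom(g), fpatools:::cpp_par(p), 2e6, 78
  )
  dg_eff <- p$gate_dG0 + p$gate_coupling * h
  expected2 <- 1 / (1 + exp(dg_eff / p$kBT))
  expect_equal(frac2, expected2, tolerance = 0.02)
})

test_that("potential energy terms behave as constructed", {
  g <- cg_geometry()
  p <- cg_params(transfer_scale = 1)
  neutral <- tibble::tibble(hydrophobicity = 0, charge = 0)
  # far in the cytoplasm: no field terms at all
  expect_equal(potential_energy(matrix(c(5, 5, 2), 1), neutral, g, p), 0)
  # electrostatic cost of exporting +1 across -100 mV: 0.1 eV = 2.306 kcal/mol
  plus <- tibble::tibble(hydrophobicity = 0, charge = 1)
  cost <- potential_energy(matrix(c(0, 0, -3), 1), plus, g, p) -
    potential_energy(matrix(c(0, 0, 3), 1), plus, g, p)
  expect_equal(cost, 0.1 * 23.0605, tolerance = 1e-9)
  # hydrophobic bead at the slab center (in open-gate lipid) vs in water:
  # difference equals its hydrophobicity (fully inside both switches)
  hb <- tibble::tibble(hydrophobicity = -1.65, charge = 0)
  at_center <- potential_energy(matrix(c(1.2, 0, 0), 1), hb, g, p, gate_open = TRUE)
  in_water <- potential_energy(matrix(c(1.2, 0, 2.0), 1), hb, g, p, gate_open = TRUE)
  expect_equal(at_center - in_water, -1.65, tolerance = 1e-9)
  # closed gate walls the lipid: a bead there pays repulsion instead
  closed <- potential_energy(matrix(c(1.2, 0, 0), 1), hb, g, p, gate_open = FALSE)
  expect_gt(closed, at_center)
})

test_that("arrest sampling is deterministic per seed and obeys its contracts", {
  g <- cg_geometry()
  p <- cg_params(
    replicates = 2, force_sample_duration = 0.03,
    equilibration = 0.006, seed = 7
  )
  seqs <- strrep("NQSG", 10)
  a <- run_arrested_sampling(seqs, 24, g, p, baseline = "none")
  b <- run_arrested_sampling(seqs, 24, g, p, baseline = "none")
  expect_identical(a, b)
  p2 <- p
  p2$seed <- 8L
  c <- run_arrested_sampling(seqs, 24, g, p2, baseline = "none")
  expect_false(identical(a$mean_force_pN, c$mean_force_pN))
  # contracts
  expect_error(run_arrested_sampling(seqs, 12, g, p), "first_measured_length")
  expect_error(run_arrested_sampling(seqs, 99, g, p), "exceeds")
  pbad <- p
  pbad$force_sample_duration <- 0.004
  expect_error(run_arrested_sampling(seqs, 24, g, pbad), "2 samples")
})

test_that("translation timing and sample counts follow the stated schedule", {
  p_full <- cg_params(scale = "full")
  # one bead (3 aa) per 0.6 s at 5 aa/s; exact step multiples
  expect_equal(3 / p_full$translation_rate, 0.6)
  expect_equal(round(3 / (p_full$translation_rate * p_full$dt)), 2e6)
  # 6 s / 3 ms -> 2000 force samples per replicate
  expect_equal(
    floor(p_full$force_sample_duration / p_full$force_sample_interval),
    2000
  )
  expect_equal(p_full$replicates, 100L)
  expect_equal(p_full$length_increment, 4L)
  expect_equal(p_full$initial_translated, 12L)
})

test_that("profile reporting applies the tunnel shift and stays reproducible", {
  g <- cg_geometry()
  expect_equal(estimate_tunnel_shift(g), 24L)
  # taller model tunnels need smaller shifts
  g_tall <- cg_geometry(tunnel_length = 4.0)
  expect_lt(estimate_tunnel_shift(g_tall), estimate_tunnel_shift(g))
  p <- cg_params(
    replicates = 2, force_sample_duration = 0.03,
    equilibration = 0.006, seed = 3
  )
  seqs <- strrep("NQSG", 12)
  prof <- compute_cgmd_profile(seqs, g, p, lengths = c(18, 26))
  expect_equal(prof$reported_N, prof$length_aa + 24L)
  expect_equal(attr(prof, "shift"), 24L)
  prof_b <- compute_cgmd_profile(seqs, g, p, lengths = c(18, 26))
  expect_identical(tidy(prof), tidy(prof_b))
  expect_s3_class(autoplot(prof), "ggplot")
  gl <- glance(prof)
  expect_equal(gl$n_lengths, 2)
  # explicit shift override
  prof0 <- compute_cgmd_profile(seqs, g, p, shift = 0, lengths = c(18, 26))
  expect_equal(prof0$reported_N, prof0$length_aa)
})

test_that("a membrane-engaged hydrophobic block outpulls a polar control", {
  g <- cg_geometry()
  p <- cg_params(
    replicates = 6, force_sample_duration = 0.15,
    equilibration = 0.03, seed = 31
  )
  tmh <- paste0(strrep("N", 9), strrep("L", 21), strrep("Q", 30))
  polar <- strrep("NQSG", 15)
  f_tmh <- run_arrested_sampling(tmh, 38, g, p)
  f_polar <- run_arrested_sampling(polar, 38, g, p)
  expect_gt(
    f_tmh$mean_force_pN - f_polar$mean_force_pN,
    2 * sqrt(f_tmh$sem_pN^2 + f_polar$sem_pN^2)
  )
  # the polar chain itself reads ~0 against the entropic reference
  expect_lt(abs(f_polar$mean_force_pN), 3.5)
})
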