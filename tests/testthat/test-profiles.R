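triangle <- tibble::tibble(N = c(70, 80, 90), mean_ffl = c(0.1, 0.9, 0.1))

test_that("profile assembly keys points by N, sorts, and rejects conflicts", {
  ap <- arrest_peptide("SecM-Ec")
  ser <- build_truncation_series(
    strrep("A", 80), strrep("G", 20), strrep("S", 9), ap, "",
    n_values = c(50, 55, 60), id_prefix = "c"
  )
  stats <- tibble::tibble(
    construct_id = c("c_N60", "c_N50", "c_N55"),
    mean_ffl = c(0.7, 0.2, 0.5), sem = c(0.05, 0.02, 0.04), n = 3L
  )
  fp <- assemble_profile(stats, ser, protein_id = "toy", ap_name = "SecM-Ec")
  expect_s3_class(fp, "force_profile")
  expect_equal(fp$points$N, c(50, 55, 60))
  expect_equal(fp$points$mean_ffl, c(0.2, 0.5, 0.7))
  # unknown construct errors
  bad <- stats
  bad$construct_id[1] <- "c_N99"
  expect_error(assemble_profile(bad, ser), "missing from series")
  # conflicting duplicate N errors, identical duplicates collapse
  dup <- rbind(stats, stats[1, ])
  expect_silent(assemble_profile(dup, ser))
  dup$mean_ffl[4] <- 0.9
  expect_error(assemble_profile(dup, ser), "conflicting")
  # tidy/glance carry metadata
  expect_equal(unique(tidy(fp)$protein_id), "toy")
  expect_equal(glance(fp)$n_points, 3)
})

test_that("peak calling recovers planted metrics on noiseless piecewise-linear profiles", {
  pk <- call_peaks(triangle)
  expect_equal(pk$N_start, 75)
  expect_equal(pk$N_max, 80)
  expect_equal(pk$N_end, 85)
  expect_equal(pk$amplitude, 0.8)
  # flat profile -> no peaks
  expect_equal(nrow(call_peaks(tibble::tibble(N = 1:10, mean_ffl = 0.2))), 0)
  # two planted triangles, segment baselines
  two <- tibble::tibble(
    N = c(10, 20, 30, 40, 50),
    mean_ffl = c(0.1, 0.7, 0.1, 0.5, 0.1)
  )
  pk2 <- call_peaks(two)
  expect_equal(pk2$N_max, c(20, 40))
  expect_equal(pk2$N_start, c(15, 35))
  expect_equal(pk2$N_end, c(25, 45))
  # prominence filter suppresses the smaller peak
  pk3 <- call_peaks(two, min_prominence = 0.5)
  expect_equal(pk3$N_max, 20)
  # ties in the maximum resolve to the smallest N
  plateau <- tibble::tibble(N = c(1, 2, 3, 4), mean_ffl = c(0, 0.8, 0.8, 0))
  expect_equal(call_peaks(plateau)$N_max, 2)
})

test_that("peak calls are invariant to adding a constant to the profile", {
  base <- call_peaks(triangle)
  shifted <- triangle
  shifted$mean_ffl <- shifted$mean_ffl + 0.07
  up <- call_peaks(shifted)
  expect_equal(up$N_start, base$N_start)
  expect_equal(up$N_max, base$N_max)
  expect_equal(up$N_end, base$N_end)
  expect_equal(up$amplitude, base$amplitude)
})

test_that("peaks recovered from synthetic Gaussian truth match the analytic half-max points", {
  spec <- profile_spec(
    n_range = c(40, 120), sampling_step = 1,
    peaks = tibble::tibble(center = 80, fwhm = 20, amplitude = 0.8),
    baseline = 0.1, replicate_noise_sd = 0, n_replicates = 1
  )
  out <- synth_profile(spec, seed = 1)
  pk <- call_peaks(out$profile)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$N_max, out$true_peaks$N_max)
  expect_equal(pk$N_start, out$true_peaks$N_start, tolerance = 0.01)
  expect_equal(pk$N_end, out$true_peaks$N_end, tolerance = 0.01)
})

test_that("hydropathy profiles are sliding-window means over the chosen scale", {
  # homopolymer is constant at the per-residue value
  hp <- hydropathy_profile(strrep("L", 25), "biological", 19)
  expect_equal(nrow(hp), 7)
  expect_true(all(abs(hp$value - hydrophobicity_scales()$biological["L"]) < 1e-12))
  # window 1 returns the raw scale values
  raw <- hydropathy_profile("LNDK", "biological", 1)
  expect_equal(raw$value, unname(hydrophobicity_scales()$biological[c("L", "N", "D", "K")]))
  # alternating 19-mer: mean of 10 L and 9 N
  s19 <- paste(rep(c("L", "N"), length.out = 19), collapse = "")
  v <- hydropathy_profile(s19, "biological", 19)$value
  expect_equal(v, (10 * (-0.55) + 9 * 2.05) / 19)
  expect_error(hydropathy_profile("LLLL", "nope", 1), "Available scales")
  expect_error(hydropathy_profile("LLLL", window = 2), "odd")
  expect_error(hydropathy_profile("LLL", window = 19), "exceeds")
})

test_that("profile alignment recovers planted shifts and is antisymmetric", {
  spec <- profile_spec(
    n_range = c(30, 130), sampling_step = 1,
    peaks = tibble::tibble(
      center = c(60, 100), fwhm = c(14, 18), amplitude = c(0.5, 0.7)
    ),
    baseline = 0.1, replicate_noise_sd = 0, n_replicates = 1
  )
  a <- synth_profile(spec, seed = 3)$profile
  # self-alignment
  self <- align_profiles(a, a)
  expect_equal(self$shift, 0)
  expect_equal(self$score, 1)
  # displaced copy: shifting b by -7 brings it back onto a
  b_pts <- a$points
  b_pts$N <- b_pts$N + 7
  b <- force_profile(b_pts)
  expect_equal(align_profiles(a, b)$shift, -7)
  # antisymmetry
  expect_equal(align_profiles(a, b)$shift, -align_profiles(b, a)$shift)
  # noisy shifted copy still recovers the planted shift
  noisy <- synth_profile(
    profile_spec(
      n_range = c(30, 130), sampling_step = 1,
      peaks = spec$peaks, baseline = 0.1,
      replicate_noise_sd = 0.05, n_replicates = 3
    ),
    seed = 11
  )$profile
  n_pts <- noisy$points
  n_pts$N <- n_pts$N + 12
  expect_equal(align_profiles(a, force_profile(n_pts))$shift, -12)
  # disjoint supports error
  far <- force_profile(tibble::tibble(N = 500:510, mean_ffl = runif(11)))
  expect_error(align_profiles(a, far), "overlap")
})

test_that("mutant comparison reports the mean drop and a Welch two-sided p", {
  wt <- tibble::tibble(N = 80, f_fl = c(0.8, 0.82, 0.78))
  mut <- tibble::tibble(N = 80, f_fl = c(0.2, 0.22, 0.18))
  out <- compare_mutant(wt, mut, 80)
  expect_equal(out$delta, 0.6)
  # closed-form Welch t on these values
  t_stat <- 0.6 / sqrt(var(wt$f_fl) / 3 + var(mut$f_fl) / 3)
  df <- (var(wt$f_fl) / 3 + var(mut$f_fl) / 3)^2 /
    ((var(wt$f_fl) / 3)^2 / 2 + (var(mut$f_fl) / 3)^2 / 2)
  expect_equal(out$p, 2 * pt(-abs(t_stat), df))
  expect_lt(out$p, 0.01)
  # identical replicate sets -> delta 0, p 1
  same <- compare_mutant(wt, wt, 80)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # single replicate -> p missing, delta defined
  one <- compare_mutant(tibble::tibble(N = 80, f_fl = 0.9), mut, 80)
  expect_equal(one$delta, 0.9 - 0.2)
  expect_true(is.na(one$p))
})

test_that("profile TSV round-trips with its header metadata", {
  fp <- force_profile(triangle, protein_id = "toy", ap_name = "SecM-Ec")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(fp, tmp)
  back <- read_profile_tsv(tmp)
  expect_equal(back$protein_id, "toy")
  expect_equal(back$ap_name, "SecM-Ec")
  expect_equal(back$points$N, fp$points$N)
  expect_equal(back$points$mean_ffl, fp$points$mean_ffl)
})

test_that("profile plots build without error", {
  fp <- force_profile(triangle, protein_id = "toy", ap_name = "SecM-Ec")
  p <- autoplot(fp, peaks = call_peaks(fp))
  expect_s3_class(p, "ggplot")
  hp <- hydropathy_profile(strrep("LLLLNNNN", 10), window = 19)
  expect_s3_class(plot_hydropathy(hp), "ggplot")
})
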