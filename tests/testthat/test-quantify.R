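test_that("compute_ffl reproduces the intensity ratio with its edge cases", {
  expect_equal(compute_ffl(1000, 1000), 0.5)
  expect_equal(compute_ffl(0, 500), 0)
  expect_equal(compute_ffl(750, 250), 0.75)
  # role symmetry
  expect_equal(compute_ffl(321, 123) + compute_ffl(123, 321), 1)
  # both zero -> missing, with a warning
  expect_warning(out <- compute_ffl(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(compute_ffl(-1, 5), "non-negative")
  # monotone non-decreasing in I_FL at fixed I_A
  v <- compute_ffl(seq(0, 1000, by = 50), 400)
  expect_true(all(diff(v) >= 0))
})

test_that("replicate aggregation uses sample-SD SEM; n = 2 SEM is the half-range", {
  expect_equal(
    aggregate_replicates(c(0.4, 0.6)),
    tibble::tibble(n = 2L, mean_ffl = 0.5, sem = 0.1)
  )
  # n = 1 -> SEM missing
  one <- aggregate_replicates(0.5)
  expect_true(is.na(one$sem))
  # closed form sd/sqrt(3)
  three <- aggregate_replicates(c(0.2, 0.4, 0.6))
  expect_equal(three$mean_ffl, 0.4)
  expect_equal(three$sem, 0.2 / sqrt(3))
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
  # permutation invariance and boundedness
  set.seed(4)
  v <- runif(5)
  expect_equal(
    aggregate_replicates(v)$mean_ffl,
    aggregate_replicates(rev(v))$mean_ffl
  )
  expect_true(aggregate_replicates(v)$mean_ffl >= min(v))
  expect_true(aggregate_replicates(v)$mean_ffl <= max(v))
})

test_that("quantify_intensities summarises a lane table per construct", {
  tbl <- tibble::tibble(
    construct_id = rep(c("c1", "c2"), each = 2),
    N = rep(c(50, 55), each = 2),
    replicate = c(1, 2, 1, 2),
    i_fl = c(400, 600, 100, 150),
    i_a = c(600, 400, 900, 850)
  )
  out <- quantify_intensities(tbl)
  expect_equal(out$n, c(2L, 2L))
  expect_equal(out$mean_ffl, c(0.5, 0.125))
  expect_equal(out$sem[1], 0.1)
  expect_true(all(c("construct_id", "N") %in% names(out)))
  expect_error(quantify_intensities(tbl[, 1:3]), "lacks column")
})

test_that("lane quantification calls FL and A bands and integrates them", {
  # two equal, well-separated bands -> f_FL = 0.5 by symmetry
  ln <- synth_lane(lane_spec())
  q <- quantify_lane(ln$trace)
  expect_equal(sort(q$bands$label), c("A", "FL"))
  expect_equal(q$quantification$f_fl, 0.5, tolerance = 1e-6)
  expect_equal(q$quantification$flag, "ok")
  # flat trace -> no bands
  flat <- tibble::tibble(position = 1:100, intensity = rep(5, 100))
  expect_error(quantify_lane(flat), "no bands")
})

test_that("stacked-ribosome bands below A are excluded from f_FL", {
  spec <- lane_spec(bands = tibble::tibble(
    label = c("FL", "A", "stacked"),
    center = c(25, 55, 62), area = c(300, 100, 200), sd = c(1.5, 1.5, 1.5)
  ))
  q <- quantify_lane(synth_lane(spec)$trace)
  expect_equal(q$bands$label, c("FL", "A", "stacked"))
  expect_equal(q$quantification$f_fl, 0.75, tolerance = 0.02)
  # exclusion invariance: the stacked band's area does not move f_FL
  for (a in c(0, 50, 500)) {
    spec_a <- lane_spec(bands = tibble::tibble(
      label = c("FL", "A", "stacked"),
      center = c(25, 55, 62), area = c(300, 100, a), sd = c(1.5, 1.5, 1.5)
    ))
    tr <- synth_lane(spec_a)$trace
    if (a == 0) {
      expect_equal(quantify_lane(tr)$quantification$f_fl, 0.75, tolerance = 0.02)
    } else {
      expect_equal(quantify_lane(tr)$quantification$f_fl,
        quantify_lane(synth_lane(spec)$trace)$quantification$f_fl,
        tolerance = 0.02
      )
    }
  }
})

test_that("slowly migrating extra bands are excluded by default, pooled on request", {
  spec <- lane_spec(bands = tibble::tibble(
    label = c("other", "FL", "A"),
    center = c(12, 25, 55), area = c(100, 300, 100), sd = c(1.5, 1.5, 1.5)
  ))
  tr <- synth_lane(spec)$trace
  template <- tibble::tibble(label = c("FL", "A"), center = c(25, 55))
  q_excl <- quantify_lane(tr, expected_bands = template)
  expect_equal(q_excl$bands$label, c("other", "FL", "A"))
  expect_equal(q_excl$quantification$f_fl, 0.75, tolerance = 0.02)
  q_incl <- quantify_lane(tr,
    expected_bands = template,
    include_other_in_fl = TRUE
  )
  expect_equal(q_incl$quantification$f_fl, 0.8, tolerance = 0.02)
})

test_that("missing bands are flagged rather than silently zeroed", {
  one <- lane_spec(bands = tibble::tibble(
    label = "FL", center = 40, area = 400, sd = 2
  ))
  q <- quantify_lane(synth_lane(one)$trace)
  expect_equal(q$quantification$flag, "missing_band")
  expect_true(is.na(q$quantification$f_fl))
})
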