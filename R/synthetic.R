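# Synthetic-data generators. These define the study conditions every other
# module is tested under: replicate f_FL profiles with Gaussian-shaped peaks
# and truncated-normal replicate noise, 1-D lane traces with FL / A /
# stacked-ribosome bands over a smooth background, and multi-TMH topologies
# for the simulator. Truth parameters are always returned alongside the
# data so recovery is testable.

#' Specification of a synthetic force profile
#'
#' @param n_range Integer interval `c(lo, hi)` of N values.
#' @param sampling_step Spacing of N values (residues).
#' @param peaks A data frame with columns `center`, `fwhm` (full width at
#'   half maximum, residues) and `amplitude` (f_FL units); zero rows for a
#'   flat profile.
#' @param baseline Baseline f_FL.
#' @param replicate_noise_sd SD of the additive replicate noise (f_FL
#'   units); replicates are clipped to \[0, 1\] (truncated-normal model).
#' @param n_replicates Replicates per construct.
#' @param noise_model `"truncnorm"` (default) or `"beta"` (mean-preserving
#'   beta noise with matching SD at the truth value).
#' @return A `profile_spec` list, validated.
#' @export
profile_spec <- function(n_range = c(30L, 150L), sampling_step = 5L,
                         peaks = tibble(
                           center = 80, fwhm = 20, amplitude = 0.6
                         ),
                         baseline = 0.1, replicate_noise_sd = 0.05,
                         n_replicates = 3L,
                         noise_model = c("truncnorm", "beta")) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    length(n_range) == 2L, n_range[1] <= n_range[2], sampling_step >= 1L,
    is.data.frame(peaks), baseline >= 0, baseline <= 1,
    replicate_noise_sd >= 0, n_replicates >= 1L
  )
  if (nrow(peaks) > 0L) {
    stopifnot(
      all(c("center", "fwhm", "amplitude") %in% names(peaks)),
      all(peaks$amplitude >= 0), all(peaks$fwhm > 0)
    )
  }
  spec <- list(
    n_range = as.integer(n_range), sampling_step = as.integer(sampling_step),
    peaks = as_tibble(peaks), baseline = baseline,
    replicate_noise_sd = replicate_noise_sd,
    n_replicates = as.integer(n_replicates), noise_model = noise_model
  )
  truth <- synth_truth_curve(spec, seq(n_range[1], n_range[2]))
  if (all(truth >= 1 - 1e-9)) {
    abort("impossible spec: truth curve saturates at 1 everywhere")
  }
  class(spec) <- "profile_spec"
  spec
}

# Noise-free truth curve: baseline + sum of Gaussian peaks, clipped to [0,1].
synth_truth_curve <- function(spec, n_values) {
  v <- rep(spec$baseline, length(n_values))
  if (nrow(spec$peaks) > 0L) {
    for (k in seq_len(nrow(spec$peaks))) {
      sigma <- spec$peaks$fwhm[k] / (2 * sqrt(2 * log(2)))
      v <- v + spec$peaks$amplitude[k] *
        exp(-(n_values - spec$peaks$center[k])^2 / (2 * sigma^2))
    }
  }
  pmin(1, pmax(0, v))
}

# Analytic peak metrics of the (unclipped) truth: half-max crossings of a
# Gaussian of FWHM w centered at c are c +/- w/2.
synth_true_peaks <- function(spec) {
  if (nrow(spec$peaks) == 0L) {
    return(empty_peaks())
  }
  spec$peaks %>%
    mutate(
      peak_id = as.character(utils::as.roman(dplyr::row_number())),
      N_start = .data$center - .data$fwhm / 2,
      N_max = .data$center,
      N_end = .data$center + .data$fwhm / 2,
      baseline = spec$baseline,
      f_max = pmin(1, spec$baseline + .data$amplitude)
    ) %>%
    dplyr::select(
      "peak_id", "N_start", "N_max", "N_end", "amplitude",
      "baseline", "f_max"
    )
}

#' Generate a synthetic force profile with known truth
#'
#' Simulates replicate f_FL measurements from a smooth truth curve
#' (baseline plus Gaussian peaks, clipped to \[0, 1\]) with independent
#' replicate noise, and returns the analytic peak metrics of the truth for
#' recovery testing.
#'
#' @param spec A [profile_spec()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   `spec` and `seed`.
#' @return A list: `replicates` (long tibble: `N`, `replicate`, `f_fl`),
#'   `profile` (a [force_profile()] of replicate means/SEMs), `truth`
#'   (tibble: `N`, `f_fl_true`) and `true_peaks` (analytic peak table).
#' @export
#' @examples
#' out <- synth_profile(profile_spec(), seed = 1)
#' out$true_peaks
synth_profile <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "profile_spec"))
  n_values <- seq(spec$n_range[1], spec$n_range[2], by = spec$sampling_step)
  truth <- synth_truth_curve(spec, n_values)
  reps <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(spec$n_replicates), function(r) {
      noisy <- if (spec$replicate_noise_sd == 0) {
        truth
      } else if (spec$noise_model == "truncnorm") {
        pmin(1, pmax(0, truth + stats::rnorm(length(truth), 0, spec$replicate_noise_sd)))
      } else {
        # beta noise: match mean and (approximately) sd at each truth value
        m <- pmin(1 - 1e-6, pmax(1e-6, truth))
        s2 <- pmin(spec$replicate_noise_sd^2, m * (1 - m) * 0.95)
        nu <- m * (1 - m) / s2 - 1
        stats::rbeta(length(m), m * nu, (1 - m) * nu)
      }
      tibble(N = n_values, replicate = r, f_fl = noisy)
    }) %>% dplyr::bind_rows()
  })
  stats <- reps %>%
    group_by(.data$N) %>%
    summarise(aggregate_replicates(.data$f_fl), .groups = "drop")
  list(
    replicates = reps,
    profile = force_profile(stats,
      protein_id = "synthetic", ap_name = "synthetic",
      replicates = reps[, c("N", "f_fl")]
    ),
    truth = tibble(N = n_values, f_fl_true = truth),
    true_peaks = synth_true_peaks(spec)
  )
}

#' Specification of a synthetic gel-lane trace
#'
#' @param bands A data frame with columns `label` (`FL`, `A`, `stacked`,
#'   `other`), `center`, `area`, `sd` (Gaussian band shape parameters in
#'   migration/densitometry units).
#' @param background Polynomial coefficients (intercept first) of the smooth
#'   background evaluated on `positions`.
#' @param noise_sd SD of additive detector noise.
#' @param positions Migration-coordinate grid.
#' @return A `lane_spec` list.
#' @export
lane_spec <- function(bands = tibble(
                        label = c("FL", "A"),
                        center = c(30, 60), area = c(500, 500), sd = c(2, 2)
                      ),
                      background = c(5, 0), noise_sd = 0,
                      positions = seq(0, 100, by = 0.25)) {
  stopifnot(
    is.data.frame(bands),
    all(c("label", "center", "area", "sd") %in% names(bands)),
    all(bands$area >= 0), all(bands$sd > 0),
    noise_sd >= 0, all(diff(positions) > 0)
  )
  structure(
    list(
      bands = as_tibble(bands), background = background,
      noise_sd = noise_sd, positions = positions
    ),
    class = "lane_spec"
  )
}

#' Generate a synthetic 1-D gel-lane trace
#'
#' Gaussian bands over a polynomial background plus optional detector
#' noise. True band areas are returned for checking quantification.
#'
#' @param spec A [lane_spec()].
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return A list: `trace` (tibble `position`, `intensity`) and
#'   `true_bands` (the planted band table).
#' @export
#' @examples
#' ln <- synth_lane(lane_spec())
#' quantify_lane(ln$trace)$quantification
synth_lane <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lane_spec"))
  x <- spec$positions
  y <- rep(0, length(x))
  for (p in seq_along(spec$background)) {
    y <- y + spec$background[p] * x^(p - 1)
  }
  if (nrow(spec$bands) > 0L) {
    for (k in seq_len(nrow(spec$bands))) {
      b <- spec$bands[k, ]
      y <- y + b$area * stats::dnorm(x, b$center, b$sd)
    }
  }
  if (spec$noise_sd > 0) {
    y <- withr::with_seed(
      as.integer(seed),
      y + stats::rnorm(length(y), 0, spec$noise_sd)
    )
  }
  y <- pmax(0, y)
  list(
    trace = tibble(position = x, intensity = y),
    true_bands = spec$bands
  )
}

#' Generate a synthetic multi-spanning membrane-protein topology
#'
#' Builds a sequence of alternating polar loops (N/Q/S/G-rich, with
#' optional K/R placement per loop) and hydrophobic TMHs (L/A/I/V-rich,
#' 19-21 residues), together with a consistent topology annotation
#' (alternating N_in / N_out orientations, first loop cytoplasmic).
#' Emulates the architecture of small multi-spanning inner-membrane
#' proteins for simulator tests.
#'
#' @param n_tmh Number of transmembrane helices (>= 1).
#' @param loop_lengths Integer vector of loop lengths, length `n_tmh + 1`
#'   (N-terminal tail, inter-TMH loops, C-terminal tail); recycled if
#'   shorter.
#' @param tmh_lengths TMH lengths (19-21), recycled.
#' @param loop_charges Integer vector (length `n_tmh + 1`) of positive
#'   charges (R residues) to place in each loop; default 1 for cytoplasmic
#'   loops, 0 for periplasmic (positive-inside rule).
#' @param seed Integer seed.
#' @return A list: `seq` (amino-acid string), `topology` (tibble: `label`,
#'   `first`, `last`, `kind`, `orientation`), `loop_charge` (tibble per
#'   loop: `label`, `side`, `net_charge`).
#' @export
#' @examples
#' top <- synth_topology(n_tmh = 4, loop_lengths = c(6, 12, 8, 12, 20), seed = 1)
#' top$topology
synth_topology <- function(n_tmh, loop_lengths = 12L, tmh_lengths = 21L,
                           loop_charges = NULL, seed = 1L) {
  stopifnot(n_tmh >= 1L)
  n_loops <- n_tmh + 1L
  loop_lengths <- rep_len(as.integer(loop_lengths), n_loops)
  tmh_lengths <- rep_len(as.integer(tmh_lengths), n_tmh)
  if (any(tmh_lengths < 15L | tmh_lengths > 25L)) {
    abort("tmh_lengths should be helix-like (15-25 residues)")
  }
  # side of each loop: loop i sits before TMH i; first loop cytoplasmic (in)
  sides <- rep(c("in", "out"), length.out = n_loops)
  if (is.null(loop_charges)) {
    loop_charges <- ifelse(sides == "in", 1L, 0L) * (loop_lengths >= 3L)
  }
  loop_charges <- rep_len(as.integer(loop_charges), n_loops)

  withr::local_seed(as.integer(seed))
  polar_pool <- c("N", "Q", "S", "G", "T")
  hydro_pool <- c("L", "A", "I", "V")
  make_loop <- function(len, ncharge) {
    if (len == 0L) {
      return(character(0))
    }
    res <- sample(polar_pool, len, replace = TRUE)
    ncharge <- min(ncharge, len)
    if (ncharge > 0L) {
      pos <- sample(seq_len(len), ncharge)
      res[pos] <- "R"
    }
    res
  }
  make_tmh <- function(len) {
    sample(hydro_pool, len, replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15))
  }

  pieces <- list()
  topo <- list()
  loop_tbl <- list()
  pos <- 1L
  for (i in seq_len(n_tmh)) {
    lp <- make_loop(loop_lengths[i], loop_charges[i])
    if (length(lp) > 0L) {
      topo[[length(topo) + 1L]] <- tibble(
        label = paste0("loop", i), first = pos, last = pos + length(lp) - 1L,
        kind = "loop", orientation = "none"
      )
      loop_tbl[[length(loop_tbl) + 1L]] <- tibble(
        label = paste0("loop", i), side = sides[i],
        net_charge = sum(lp == "R") - sum(lp %in% c("D", "E"))
      )
      pieces[[length(pieces) + 1L]] <- lp
      pos <- pos + length(lp)
    }
    th <- make_tmh(tmh_lengths[i])
    topo[[length(topo) + 1L]] <- tibble(
      label = paste0("TMH", i), first = pos, last = pos + length(th) - 1L,
      kind = "TMH",
      orientation = if (sides[i] == "in") "N_in" else "N_out"
    )
    pieces[[length(pieces) + 1L]] <- th
    pos <- pos + length(th)
  }
  lp <- make_loop(loop_lengths[n_loops], loop_charges[n_loops])
  if (length(lp) > 0L) {
    topo[[length(topo) + 1L]] <- tibble(
      label = paste0("loop", n_loops), first = pos,
      last = pos + length(lp) - 1L, kind = "loop", orientation = "none"
    )
    loop_tbl[[length(loop_tbl) + 1L]] <- tibble(
      label = paste0("loop", n_loops), side = sides[n_loops],
      net_charge = sum(lp == "R") - sum(lp %in% c("D", "E"))
    )
    pieces[[length(pieces) + 1L]] <- lp
  }
  list(
    seq = paste(unlist(pieces), collapse = ""),
    topology = dplyr::bind_rows(topo),
    loop_charge = dplyr::bind_rows(loop_tbl)
  )
}
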