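# From band intensities (or 1-D gel-lane traces) to f_FL, the fraction
# full-length protein: f_FL = I_FL / (I_FL + I_A). Ribosome-stacking bands
# that run just below the arrested (A) band are excluded from the ratio.

#' Fraction full-length protein from band intensities
#'
#' `compute_ffl(i_fl, i_a)` returns `i_fl / (i_fl + i_a)`. Both intensities
#' zero is undefined and yields `NA` (flagged missing, not 0).
#'
#' @param i_fl,i_a Non-negative intensities of the full-length (FL) and
#'   arrested (A) bands (vectorized).
#' @return Numeric vector of f_FL values in \[0, 1\].
#' @export
#' @examples
#' compute_ffl(750, 250) # 0.75
compute_ffl <- function(i_fl, i_a) {
  if (any(i_fl < 0, na.rm = TRUE) || any(i_a < 0, na.rm = TRUE)) {
    abort("band intensities must be non-negative")
  }
  tot <- i_fl + i_a
  out <- ifelse(tot > 0, i_fl / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE)) {
    warn("I_FL + I_A = 0 for some lane(s); f_FL is undefined there (NA)")
  }
  out
}

#' Replicate statistics for f_FL values
#'
#' Mean and standard error of the mean (sample standard deviation divided by
#' sqrt(n)). For two replicates this SEM equals half the range, so plotting
#' mean +/- SEM is the same as plotting the two measurements themselves. For
#' a single replicate the SEM is reported missing.
#'
#' @param values Numeric vector of f_FL replicate values.
#' @return A one-row tibble: `n`, `mean_ffl`, `sem`.
#' @export
#' @examples
#' aggregate_replicates(c(0.4, 0.6)) # mean 0.5, sem 0.1
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    abort("no replicate values to aggregate")
  }
  n <- length(values)
  tibble(
    n = n,
    mean_ffl = mean(values),
    sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_
  )
}

#' Quantify a table of band intensities
#'
#' Data-frame-first wrapper for intensity tables: computes per-lane f_FL and
#' per-construct replicate statistics.
#'
#' @param data A data frame with columns `construct_id`, `replicate`,
#'   `i_fl`, `i_a` (a `N` column, if present, is carried through).
#' @return A tibble with one row per construct: `construct_id` (and `N` if
#'   supplied), `n`, `mean_ffl`, `sem`.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   construct_id = c("c1", "c1", "c2", "c2"),
#'   replicate = c(1, 2, 1, 2),
#'   i_fl = c(400, 600, 100, 150), i_a = c(600, 400, 900, 850)
#' )
#' quantify_intensities(tbl)
quantify_intensities <- function(data) {
  needed <- c("construct_id", "i_fl", "i_a")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "`data` lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  keys <- intersect(c("construct_id", "N"), names(data))
  data %>%
    mutate(f_fl = compute_ffl(.data$i_fl, .data$i_a)) %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(aggregate_replicates(.data$f_fl), .groups = "drop")
}

# Centered rolling minimum followed by a rolling mean of the same window:
# a deterministic, smooth lower envelope for gel backgrounds.
rolling_baseline <- function(y, window) {
  n <- length(y)
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  rmin <- vapply(seq_len(n), function(i) {
    min(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    mean(rmin[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

local_extrema <- function(y) {
  n <- length(y)
  dy <- diff(y)
  sign_dy <- sign(dy)
  # collapse flats to the left edge
  maxima <- integer(0)
  minima <- integer(0)
  last_sign <- 0
  last_change <- 1L
  for (i in seq_along(sign_dy)) {
    s <- sign_dy[i]
    if (s == 0) next
    if (last_sign > 0 && s < 0) maxima <- c(maxima, last_change)
    if (last_sign < 0 && s > 0) minima <- c(minima, last_change)
    last_sign <- s
    last_change <- i + 1L
  }
  list(maxima = maxima, minima = minima)
}

#' Quantify a 1-D gel-lane trace
#'
#' Calls bands on a densitometry trace and computes f_FL. The trace is
#' baseline-subtracted (rolling-minimum envelope), bands are local maxima
#' above a prominence threshold, and each band is integrated between its
#' flanking local minima (trapezoidal rule). Bands are labelled in migration
#' order: the first (slowest-migrating) band is FL, the second is A; any
#' later band whose center falls inside the stacked-ribosome window just
#' below the A band is labelled `stacked` and excluded from f_FL, and other
#' extra bands are labelled `other` (also excluded).
#'
#' @param trace A data frame with columns `position` (strictly increasing;
#'   larger = further migrated) and `intensity` (non-negative).
#' @param expected_bands Optional template: a data frame with columns
#'   `label` (`FL` / `A`) and `center` (approximate migration coordinate).
#'   Each called band is assigned to the nearest template entry; leftover
#'   bands fall back to the stacked-window / `other` rules. Without a
#'   template, the first band in migration order is FL and the second is A
#'   (FL runs above A).
#' @param baseline_window Rolling-minimum window (points); default one fifth
#'   of the trace length.
#' @param min_height Minimum band height as a fraction of the tallest band
#'   (default 0.05).
#' @param min_snr Minimum ratio of the tallest baseline-subtracted,
#'   smoothed signal to the trace's median absolute deviation for any band
#'   to be considered resolvable (default 10); traces of pure noise fail
#'   this gate.
#' @param stacked_window Either `NULL` (default: centers within 1.5 A-band
#'   widths below the A band) or an explicit `c(lo, hi)` interval of
#'   migration coordinates.
#' @param include_other_in_fl If `TRUE`, bands labelled `other` that run
#'   above the FL..A interval (e.g. slowly migrating species) are added to
#'   I_FL; default `FALSE` (exclude).
#' @return A list with `bands` (tibble: `label`, `center`, `area`, `left`,
#'   `right`) and `quantification` (one-row tibble: `i_fl`, `i_a`, `f_fl`,
#'   `flag`).
#' @export
quantify_lane <- function(trace, expected_bands = NULL,
                          baseline_window = NULL, min_height = 0.05,
                          min_snr = 10,
                          stacked_window = NULL,
                          include_other_in_fl = FALSE) {
  stopifnot(is.data.frame(trace), all(c("position", "intensity") %in% names(trace)))
  x <- trace$position
  y <- trace$intensity
  if (length(x) != length(y) || length(x) < 5L) {
    abort("trace must have matching position/intensity columns (>= 5 points)")
  }
  if (any(diff(x) <= 0)) abort("trace positions must be strictly increasing")
  if (any(y < 0)) abort("trace intensities must be non-negative")

  if (is.null(baseline_window)) baseline_window <- max(5L, length(y) %/% 5L)
  base <- rolling_baseline(y, baseline_window)
  ys <- y - base
  if (any(ys < 0)) {
    ys[ys < 0] <- 0
  }

  # resolvability gate: pure-noise traces have no band-like structure
  half5 <- 2L
  smoothed <- vapply(seq_along(ys), function(i) {
    mean(ys[max(1L, i - half5):min(length(ys), i + half5)])
  }, numeric(1))
  if (max(smoothed) < min_snr * max(stats::mad(smoothed), 1e-12)) {
    abort("no bands found in trace (signal indistinguishable from noise)")
  }

  ext <- local_extrema(ys)
  peaks <- ext$maxima
  peaks <- peaks[ys[peaks] >= min_height * max(ys)]
  if (max(ys) <= 0 || length(peaks) == 0L) {
    abort("no bands found in trace (flat after baseline subtraction)")
  }

  bounds <- purrr::map(peaks, function(p) {
    left_candidates <- c(1L, ext$minima[ext$minima < p])
    right_candidates <- c(ext$minima[ext$minima > p], length(x))
    c(max(left_candidates), min(right_candidates))
  })
  areas <- purrr::map_dbl(seq_along(peaks), function(i) {
    idx <- bounds[[i]][1]:bounds[[i]][2]
    sum(diff(x[idx]) * (ys[idx][-1] + ys[idx][-length(idx)]) / 2)
  })
  bands <- tibble(
    center = x[peaks],
    area = pmax(areas, 0),
    left = x[purrr::map_int(bounds, 1L)],
    right = x[purrr::map_int(bounds, 2L)]
  ) %>% arrange(.data$center)

  labels <- rep("other", nrow(bands))
  flag <- "ok"
  if (!is.null(expected_bands)) {
    stopifnot(all(c("label", "center") %in% names(expected_bands)))
    for (k in seq_len(nrow(expected_bands))) {
      free <- which(labels == "other")
      if (length(free) == 0L) break
      nearest <- free[which.min(abs(bands$center[free] - expected_bands$center[k]))]
      labels[nearest] <- expected_bands$label[k]
    }
  } else {
    if (nrow(bands) >= 1L) labels[1] <- "FL"
    if (nrow(bands) >= 2L) labels[2] <- "A"
  }
  a_idx <- which(labels == "A")
  if (length(a_idx) == 1L) {
    a_center <- bands$center[a_idx]
    a_width <- bands$right[a_idx] - bands$left[a_idx]
    win <- if (is.null(stacked_window)) {
      c(a_center, a_center + 1.5 * a_width)
    } else {
      stacked_window
    }
    in_win <- bands$center > win[1] & bands$center <= win[2]
    labels[in_win & labels == "other"] <- "stacked"
  }
  bands$label <- labels
  bands <- bands[, c("label", "center", "area", "left", "right")]

  i_fl <- sum(bands$area[bands$label == "FL"])
  if (include_other_in_fl) {
    i_fl <- i_fl + sum(bands$area[bands$label == "other"])
  }
  i_a <- sum(bands$area[bands$label == "A"])
  if (!any(bands$label == "FL") || !any(bands$label == "A")) {
    flag <- "missing_band"
    f_fl <- NA_real_
  } else {
    f_fl <- compute_ffl(i_fl, i_a)
  }
  list(
    bands = bands,
    quantification = tibble(i_fl = i_fl, i_a = i_a, f_fl = f_fl, flag = flag)
  )
}
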