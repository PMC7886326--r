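# Force profiles: f_FL versus N. Assembly from per-construct replicate
# statistics, peak calling (N_start / N_max / N_end at half-maximal
# amplitude), hydropathy tracks, profile alignment and mutant comparison.

#' Create a force profile
#'
#' A force profile (FP) is the series of mean f_FL values (with SEM and
#' replicate count) against construct length N. Points are sorted by N and N
#' values must be unique.
#'
#' @param points A data frame with columns `N`, `mean_ffl` and optionally
#'   `sem`, `n`.
#' @param protein_id,ap_name Identifiers carried as metadata.
#' @param replicates Optional long-format tibble of per-lane values
#'   (columns `N`, `f_fl`), kept for significance tests at single N values.
#' @return An object of class `force_profile`.
#' @export
force_profile <- function(points, protein_id = NA_character_,
                          ap_name = NA_character_, replicates = NULL) {
  stopifnot(is.data.frame(points), all(c("N", "mean_ffl") %in% names(points)))
  points <- as_tibble(points)
  if (!"sem" %in% names(points)) points$sem <- NA_real_
  if (!"n" %in% names(points)) points$n <- NA_integer_
  points <- points[, c("N", "mean_ffl", "sem", "n")] %>% arrange(.data$N)
  if (anyDuplicated(points$N)) {
    dup <- unique(points$N[duplicated(points$N)])
    abort(paste0(
      "duplicate N values in profile: ", paste(dup, collapse = ", ")
    ))
  }
  if (any(points$mean_ffl < -1e-9 | points$mean_ffl > 1 + 1e-9, na.rm = TRUE)) {
    abort("mean_ffl values must lie in [0, 1]")
  }
  structure(
    list(
      points = points, protein_id = protein_id, ap_name = ap_name,
      replicates = replicates
    ),
    class = "force_profile"
  )
}

#' @export
print.force_profile <- function(x, ...) {
  cat("<force_profile> ", x$protein_id, " / ", x$ap_name, ": ",
    nrow(x$points), " points, N = ", min(x$points$N), "..",
    max(x$points$N), "\n",
    sep = ""
  )
  print(x$points, n = 6)
  invisible(x)
}

#' @method tidy force_profile
#' @export
tidy.force_profile <- function(x, ...) {
  x$points %>% mutate(protein_id = x$protein_id, ap_name = x$ap_name)
}

#' @method glance force_profile
#' @export
glance.force_profile <- function(x, ...) {
  tibble(
    protein_id = x$protein_id, ap_name = x$ap_name,
    n_points = nrow(x$points),
    n_min = min(x$points$N), n_max = max(x$points$N),
    max_ffl = max(x$points$mean_ffl), min_ffl = min(x$points$mean_ffl)
  )
}

#' Assemble a force profile from quantifications and a construct series
#'
#' Joins per-construct replicate statistics (as from
#' [quantify_intensities()]) to the construct series to key each point by N.
#' Gaps (constructs without data) are simply absent; nothing is
#' interpolated at assembly time.
#'
#' @param stats A data frame with `construct_id`, `mean_ffl` and optionally
#'   `sem`, `n` (an `N` column is used directly if the series is `NULL`).
#' @param series A construct series (as from [build_truncation_series()])
#'   with `construct_id` and `N`; may be `NULL` when `stats` already has `N`.
#' @param protein_id,ap_name Metadata for the profile.
#' @param replicates Optional long replicate table (columns `construct_id`
#'   or `N`, plus `f_fl`).
#' @return A [force_profile()].
#' @export
assemble_profile <- function(stats, series = NULL,
                             protein_id = NA_character_,
                             ap_name = NA_character_,
                             replicates = NULL) {
  stopifnot(is.data.frame(stats))
  if (!"N" %in% names(stats)) {
    if (is.null(series)) {
      abort("`stats` has no N column and no `series` was given")
    }
    unmatched <- setdiff(stats$construct_id, series$construct_id)
    if (length(unmatched) > 0L) {
      abort(paste0(
        "constructs missing from series: ", paste(unmatched, collapse = ", ")
      ))
    }
    stats <- stats %>%
      left_join(series[, c("construct_id", "N")], by = "construct_id")
  }
  if (!is.null(replicates) && !"N" %in% names(replicates) && !is.null(series)) {
    replicates <- replicates %>%
      left_join(series[, c("construct_id", "N")], by = "construct_id")
  }
  # identical duplicate rows collapse; conflicting ones are an error
  key <- stats[, intersect(c("N", "mean_ffl", "sem", "n"), names(stats))]
  key <- dplyr::distinct(key)
  if (anyDuplicated(key$N)) {
    dup <- sort(unique(key$N[duplicated(key$N)]))
    abort(paste0(
      "conflicting values at duplicate N: ", paste(dup, collapse = ", ")
    ))
  }
  force_profile(key,
    protein_id = protein_id, ap_name = ap_name,
    replicates = replicates
  )
}

profile_points <- function(profile) {
  if (inherits(profile, "force_profile")) {
    return(profile$points)
  }
  if (is.data.frame(profile) && all(c("N", "mean_ffl") %in% names(profile))) {
    return(as_tibble(profile) %>% arrange(.data$N))
  }
  abort("expected a force_profile or a data frame with columns N, mean_ffl")
}

# Interior local minima (strict, flats collapsed) of a numeric vector.
interior_minima <- function(v) {
  local_extrema(v)$minima
}

#' Call peaks in a force profile
#'
#' Segments the profile at interior local minima and reports, per segment
#' with amplitude at or above `min_prominence`: the position of the maximum
#' (`N_max`; ties resolved to the smallest N), the half-maximal crossings on
#' the rise (`N_start`) and fall (`N_end`), the baseline and the amplitude
#' (max minus baseline). Crossings are linearly interpolated between sampled
#' N values; a crossing that never happens inside the segment (peak riding
#' on a high shoulder or clipped at the profile edge) is reported missing.
#' Segments whose amplitude is below `min_prominence` are merged into their
#' neighbours across the shallower boundary before calling.
#'
#' @param profile A [force_profile()] or data frame with `N`, `mean_ffl`.
#' @param baseline `"segment"` (default): per-peak baseline is the minimum
#'   of the profile within the peak's segment; `"global"`: the profile-wide
#'   minimum.
#' @param min_prominence Minimum amplitude (f_FL units) for a peak to be
#'   reported; default 0.1.
#' @return A tibble with one row per peak: `peak_id` (roman), `N_start`,
#'   `N_max`, `N_end`, `amplitude`, `baseline`, `f_max`. Zero rows if the
#'   profile is flat or nothing passes the prominence filter.
#' @export
#' @examples
#' tri <- tibble::tibble(N = c(70, 80, 90), mean_ffl = c(0.1, 0.9, 0.1))
#' call_peaks(tri) # N_start 75, N_max 80, N_end 85
call_peaks <- function(profile, baseline = c("segment", "global"),
                       min_prominence = 0.1) {
  baseline <- match.arg(baseline)
  pts <- profile_points(profile)
  if (nrow(pts) < 3L) abort("peak calling needs at least 3 profile points")
  Nv <- pts$N
  v <- pts$mean_ffl
  npts <- length(v)
  if (diff(range(v)) == 0) {
    return(empty_peaks())
  }
  global_min <- min(v)

  # prune segment boundaries by topographic prominence: a dividing local
  # minimum only separates two peaks if both adjacent segment maxima rise
  # at least min_prominence above it
  boundaries <- interior_minima(v)
  repeat {
    if (length(boundaries) == 0L) break
    edges <- c(1L, boundaries, npts)
    seg_max <- purrr::map_dbl(seq_len(length(edges) - 1L), function(k) {
      max(v[edges[k]:edges[k + 1L]])
    })
    depths <- purrr::map_dbl(seq_along(boundaries), function(b) {
      min(seg_max[b], seg_max[b + 1L]) - v[boundaries[b]]
    })
    if (min(depths) >= min_prominence) break
    boundaries <- boundaries[-which.min(depths)]
  }

  edges <- c(1L, boundaries, npts)
  rows <- purrr::map(seq_len(length(edges) - 1L), function(k) {
    idx <- edges[k]:edges[k + 1L]
    base <- if (baseline == "segment") min(v[idx]) else global_min
    vmax <- max(v[idx])
    amplitude <- vmax - base
    if (amplitude < min_prominence) {
      return(NULL)
    }
    imax <- idx[which(v[idx] == vmax)[1]] # ties -> smallest N
    half <- base + amplitude / 2

    cross_left <- NA_real_
    i <- imax
    while (i > idx[1]) {
      if (v[i - 1L] <= half && v[i] >= half) {
        cross_left <- if (v[i] == v[i - 1L]) {
          Nv[i]
        } else {
          Nv[i - 1L] + (half - v[i - 1L]) / (v[i] - v[i - 1L]) * (Nv[i] - Nv[i - 1L])
        }
        break
      }
      i <- i - 1L
    }
    cross_right <- NA_real_
    i <- imax
    while (i < idx[length(idx)]) {
      if (v[i + 1L] <= half && v[i] >= half) {
        cross_right <- if (v[i] == v[i + 1L]) {
          Nv[i]
        } else {
          Nv[i] + (v[i] - half) / (v[i] - v[i + 1L]) * (Nv[i + 1L] - Nv[i])
        }
        break
      }
      i <- i + 1L
    }
    tibble(
      N_start = cross_left, N_max = as.numeric(Nv[imax]), N_end = cross_right,
      amplitude = amplitude, baseline = base, f_max = vmax
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(empty_peaks())
  }
  out %>%
    mutate(peak_id = as.character(utils::as.roman(dplyr::row_number())), .before = 1)
}

empty_peaks <- function() {
  tibble(
    peak_id = character(0), N_start = numeric(0), N_max = numeric(0),
    N_end = numeric(0), amplitude = numeric(0), baseline = numeric(0),
    f_max = numeric(0)
  )
}

#' Sliding-window hydropathy profile
#'
#' Mean per-residue hydrophobicity over an odd-width sliding window,
#' reported at the window-center position. With the default biological
#' (translocon) scale, dips below zero mark segments that favour the
#' bilayer.
#'
#' @param seq Amino-acid sequence.
#' @param scale_name One of [hydrophobicity_scales()]; default
#'   `"biological"`.
#' @param window Odd window width, at most the sequence length; default 19.
#' @return A tibble: `center` (1-based residue index), `value`
#'   (scale units), with attributes `scale_name` and `window`.
#' @export
#' @examples
#' hydropathy_profile(strrep("L", 25), window = 19)
hydropathy_profile <- function(seq, scale_name = "biological", window = 19L) {
  scale <- get_scale(scale_name)
  ch <- aa_chars(seq)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("`window` must be a positive odd integer")
  }
  if (window > length(ch)) {
    abort("`window` exceeds the sequence length")
  }
  vals <- unname(scale[ch])
  cs <- cumsum(c(0, vals))
  L <- length(ch)
  starts <- seq_len(L - window + 1L)
  means <- (cs[starts + window] - cs[starts]) / window
  out <- tibble(center = starts + (window - 1L) %/% 2L, value = means)
  attr(out, "scale_name") <- scale_name
  attr(out, "window") <- window
  out
}

#' Align two force profiles by an integer N shift
#'
#' Finds the integer shift applied to `fp_b`'s N values that maximizes the
#' Pearson correlation with `fp_a` over their overlapping N support (used,
#' e.g., to register simulated profiles to experimental ones). Ties are
#' broken toward the smallest absolute shift.
#'
#' @param fp_a,fp_b [force_profile()]s or data frames with `N`, `mean_ffl`.
#' @param shift_range Integer interval `c(lo, hi)` of candidate shifts;
#'   default -30..30.
#' @param min_overlap Minimum number of overlapping points (default 3).
#' @return A one-row tibble: `shift`, `score`, `n_overlap`.
#' @export
align_profiles <- function(fp_a, fp_b, shift_range = c(-30L, 30L),
                           min_overlap = 3L) {
  a <- profile_points(fp_a)
  b <- profile_points(fp_b)
  shifts <- seq(as.integer(shift_range[1]), as.integer(shift_range[2]))
  scored <- purrr::map(shifts, function(s) {
    common <- intersect(a$N, b$N + s)
    if (length(common) < min_overlap) {
      return(NULL)
    }
    va <- a$mean_ffl[match(common, a$N)]
    vb <- b$mean_ffl[match(common, b$N + s)]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      return(NULL)
    }
    tibble(shift = s, score = stats::cor(va, vb), n_overlap = length(common))
  })
  scored <- dplyr::bind_rows(scored)
  if (nrow(scored) == 0L) {
    abort("profiles do not overlap (with >= min_overlap points) for any candidate shift")
  }
  best <- max(scored$score)
  cand <- scored %>% filter(.data$score >= best - 1e-12)
  cand <- cand[order(abs(cand$shift), cand$shift), ]
  cand[1L, ]
}

#' Compare wild-type and mutant f_FL at one construct length
#'
#' Difference of replicate means (wild type minus mutant, so a positive
#' `delta` is a drop in the mutant) and the two-sided Welch t-test p-value
#' at a single N. With fewer than two replicates on either side the p-value
#' is reported missing.
#'
#' @param fp_wt,fp_mut [force_profile()]s carrying replicate tables, or
#'   long-format data frames with columns `N` and `f_fl`.
#' @param n The construct length N at which to compare.
#' @return A one-row tibble: `N`, `delta`, `p`, `n_wt`, `n_mut`.
#' @export
compare_mutant <- function(fp_wt, fp_mut, n) {
  vals <- function(fp, label) {
    df <- if (inherits(fp, "force_profile")) fp$replicates else fp
    if (is.null(df) || !all(c("N", "f_fl") %in% names(df))) {
      abort(paste0(label, " carries no replicate table with columns N, f_fl"))
    }
    v <- df$f_fl[df$N == n & !is.na(df$f_fl)]
    if (length(v) == 0L) {
      abort(paste0(label, " has no replicate values at N = ", n))
    }
    v
  }
  wt <- vals(fp_wt, "`fp_wt`")
  mut <- vals(fp_mut, "`fp_mut`")
  delta <- mean(wt) - mean(mut)
  p <- if (length(wt) < 2L || length(mut) < 2L) {
    NA_real_
  } else {
    tryCatch(
      stats::t.test(wt, mut, var.equal = FALSE)$p.value,
      error = function(e) if (isTRUE(all.equal(delta, 0))) 1 else 0
    )
  }
  tibble(N = n, delta = delta, p = p, n_wt = length(wt), n_mut = length(mut))
}

#' Plot a force profile
#'
#' Publication-style f_FL-versus-N plot with SEM error bars; called peaks
#' (from [call_peaks()]) can be overlaid as shaded half-max spans.
#'
#' @param object A [force_profile()].
#' @param peaks Optional peak table from [call_peaks()].
#' @param colour Line/point colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot force_profile
#' @export
autoplot.force_profile <- function(object, peaks = NULL,
                                   colour = "#E69F00", ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$N, y = .data$mean_ffl)) +
    ggplot2::geom_line(colour = colour) +
    ggplot2::geom_point(colour = colour, size = 1.6)
  if (any(!is.na(pts$sem))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$mean_ffl - .data$sem),
        ymax = pmin(1, .data$mean_ffl + .data$sem)
      ),
      width = 0, colour = colour, alpha = 0.7
    )
  }
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    shade <- peaks %>% filter(!is.na(.data$N_start) & !is.na(.data$N_end))
    if (nrow(shade) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(
          xmin = .data$N_start, xmax = .data$N_end,
          ymin = -Inf, ymax = Inf
        ),
        inherit.aes = FALSE, fill = "grey70", alpha = 0.25
      )
    }
    p <- p + ggplot2::geom_vline(
      data = peaks, ggplot2::aes(xintercept = .data$N_max),
      linetype = "dashed", colour = "grey40"
    )
  }
  p +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "N (residues to end of AP)", y = expression(f[FL]),
      title = paste(object$protein_id, object$ap_name, sep = " / ")
    ) +
    ggplot2::theme_classic()
}

#' Plot a hydropathy profile
#'
#' @param hp Output of [hydropathy_profile()].
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(hp) {
  ggplot2::ggplot(hp, ggplot2::aes(x = .data$center, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::labs(
      x = "residue (window center)",
      y = paste0("hydropathy (", attr(hp, "scale_name"), ", window ", attr(hp, "window"), ")")
    ) +
    ggplot2::theme_classic()
}

#' Read / write the profile TSV interchange format
#'
#' Tab-separated `(N, mean_ffl, sem, n)` with `# key=value` header lines for
#' `protein_id` and `ap_name`.
#'
#' @param profile A [force_profile()].
#' @param path File path.
#' @return `read_profile_tsv()`: a [force_profile()]. `write_profile_tsv()`:
#'   the path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "force_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# protein_id=", profile$protein_id),
    paste0("# ap_name=", profile$ap_name)
  ), con)
  utils::write.table(profile$points, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(hit) == 0L) {
      return(NA_character_)
    }
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  body <- utils::read.table(
    text = lines[!grepl("^#", lines)],
    header = TRUE, sep = "\t"
  )
  force_profile(body,
    protein_id = get_field("protein_id"),
    ap_name = get_field("ap_name")
  )
}
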