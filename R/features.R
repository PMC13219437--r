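#' The 20 time-domain feature names
#'
#' Canonical names, in canonical order, of the time-domain descriptors this
#' package computes per electrode and window: central moments (`mean`, `std`,
#' `kurt`, `skew`), extremum amplitudes and latencies (`pp`, `ppt`, `pps`,
#' `lmin`, `amp_max`, `amp_min`, `alar`, `lmax`, `lar`), successive-difference
#' magnitudes (`mdif1`, `mdif2`, `mdif1norm`, `mdif2norm`), signal energy
#' (`energy`, `energy_norm`) and amplitude-histogram entropy (`entropy`).
#' Feature-table columns are named `"<electrode>_<feature>"`.
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c(
    "mean", "std", "kurt", "skew", "pp", "ppt", "pps", "lmin",
    "amp_max", "amp_min", "alar", "mdif1", "mdif2", "lmax",
    "mdif1norm", "mdif2norm", "energy", "energy_norm", "lar", "entropy"
  )
}

#' Central moments of a signal window
#'
#' Mean, sample standard deviation (n-1 divisor) and the standardized third
#' and fourth central moments (Pearson coefficients). Kurtosis is not excess
#' kurtosis: a Gaussian signal has `kurt` near 3. For a zero-variance window
#' skewness and kurtosis are undefined; both are returned as 0 and the
#' `degenerate` flag is set.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named list: `mean`, `std`, `skew`, `kurt`, `degenerate` (logical).
#' @export
compute_moments <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop_input("compute_moments() needs a numeric vector of length >= 2")
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    return(list(mean = m, std = 0, skew = 0, kurt = 0, degenerate = TRUE))
  }
  z <- (x - m) / s
  list(
    mean = m,
    std = s,
    skew = mean(z^3),
    kurt = mean(z^4),
    degenerate = FALSE
  )
}

#' Extremum amplitude and latency features
#'
#' Amplitude extrema, their latencies, and the ratios built from them.
#' Latencies use the 1-based index of the first occurrence of each extremum
#' divided by the sampling rate, so they lie in (0, T/fs] and the
#' latency-ratio denominators are strictly positive. `pps` (peak-to-peak
#' slope) is guarded to 0 when the two extrema coincide in time, and `lar`
#' to 0 when the maximum amplitude is 0.
#'
#' @param x Numeric vector, length >= 1.
#' @param fs Sampling rate in Hz.
#' @return Named list: `amp_max`, `amp_min`, `lmax`, `lmin` (seconds),
#'   `pp`, `ppt` (seconds), `pps`, `alar`, `lar`, `degenerate`.
#' @export
compute_extrema_features <- function(x, fs) {
  if (!is.numeric(x) || length(x) < 1) {
    stop_input("compute_extrema_features() needs a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_input("fs must be a single positive number")
  }
  amp_max <- max(x)
  amp_min <- min(x)
  lmax <- which.max(x) / fs
  lmin <- which.min(x) / fs
  pp <- amp_max - amp_min
  ppt <- abs(lmax - lmin)
  degenerate <- FALSE
  if (ppt == 0) {
    pps <- 0
    degenerate <- TRUE
  } else {
    pps <- pp / ppt
  }
  alar <- abs(amp_max) / lmax
  if (amp_max == 0) {
    lar <- 0
    degenerate <- TRUE
  } else {
    lar <- lmax / amp_max
  }
  list(
    amp_max = amp_max, amp_min = amp_min, lmax = lmax, lmin = lmin,
    pp = pp, ppt = ppt, pps = pps, alar = alar, lar = lar,
    degenerate = degenerate
  )
}

#' Mean absolute successive-difference features
#'
#' Sums of absolute first differences (S1, over the N-1 adjacent pairs) and
#' absolute second differences (S2, over the N-2 interior points), reported
#' under two normalizations each: divided by the sample count N (`mdif1`,
#' `mdif2`) and divided by the number of terms actually summed
#' (`mdif1norm` = S1/(N-1), `mdif2norm` = S2/(N-2)).
#'
#' @param x Numeric vector, length >= 3.
#' @return Named list: `mdif1`, `mdif2`, `mdif1norm`, `mdif2norm`.
#' @export
compute_difference_features <- function(x) {
  if (!is.numeric(x) || length(x) < 3) {
    stop_input("compute_difference_features() needs a numeric vector of length >= 3")
  }
  n <- length(x)
  s1 <- sum(abs(diff(x)))
  s2 <- sum(abs(diff(x, differences = 2L)))
  list(
    mdif1 = s1 / n,
    mdif2 = s2 / n,
    mdif1norm = s1 / (n - 1),
    mdif2norm = s2 / (n - 2)
  )
}

#' Signal energy
#'
#' Total energy (sum of squared samples) and its per-sample normalization.
#' `energy == T * energy_norm` holds exactly, T being the sample count.
#'
#' @param x Numeric vector, length >= 1.
#' @return Named list: `energy`, `energy_norm`.
#' @export
compute_energy <- function(x) {
  if (!is.numeric(x) || length(x) < 1) {
    stop_input("compute_energy() needs a non-empty numeric vector")
  }
  e <- sum(x^2)
  list(energy = e, energy_norm = e / length(x))
}

#' Amplitude-histogram entropy
#'
#' Samples are binned into `n_bins` equal-width bins spanning
#' `[min(x), max(x)]` (a single bin when the window is constant); bin
#' probabilities are bin counts over the sample count, and the Shannon
#' entropy `-sum(p * log2(p))` is returned in bits, with `0 * log(0) := 0`.
#' `as_printed = TRUE` drops the leading minus, returning the (non-positive)
#' raw summation instead.
#'
#' @param x Numeric vector, length >= 1.
#' @param n_bins Number of histogram bins, >= 2. Default 64.
#' @param as_printed Return `sum(p * log2(p))` without the minus sign.
#' @return Entropy in bits (non-negative unless `as_printed`).
#' @export
compute_entropy <- function(x, n_bins = 64L, as_printed = FALSE) {
  if (!is.numeric(x) || length(x) < 1) {
    stop_input("compute_entropy() needs a non-empty numeric vector")
  }
  if (n_bins < 2) stop_input("n_bins must be >= 2")
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    return(0)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(x)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (as_printed) -h else h
}

#' Extract the 20 time-domain features from one segment
#'
#' Applies every single-purpose feature kernel to a segment's samples and
#' assembles the named 20-element feature vector. The result carries a
#' `degenerate` attribute flagging zero-variance or zero-amplitude windows.
#'
#' @param seg A segment as returned by [segment_recording()] (a list with
#'   `samples` and `fs`), or a bare numeric vector if `fs` is supplied.
#' @param fs Sampling rate in Hz; only needed when `seg` is a bare vector.
#' @param entropy_bins Histogram bins for the entropy feature. Default 64.
#' @param entropy_as_printed Use the sign-free entropy summation.
#' @return Named numeric vector of length 20 (order of [feature_names()]),
#'   with attribute `degenerate`.
#' @export
extract_features <- function(seg, fs = NULL, entropy_bins = 64L,
                             entropy_as_printed = FALSE) {
  if (is.list(seg)) {
    x <- seg$samples
    fs <- fs %||% seg$fs
  } else {
    x <- seg
  }
  if (is.null(fs)) stop_input("sampling rate fs is required")
  if (!is.numeric(x) || length(x) < 3) {
    stop_input("a segment must hold at least 3 samples")
  }
  mo <- compute_moments(x)
  ex <- compute_extrema_features(x, fs)
  di <- compute_difference_features(x)
  en <- compute_energy(x)
  ent <- compute_entropy(x, n_bins = entropy_bins, as_printed = entropy_as_printed)
  out <- c(
    mean = mo$mean, std = mo$std, kurt = mo$kurt, skew = mo$skew,
    pp = ex$pp, ppt = ex$ppt, pps = ex$pps, lmin = ex$lmin,
    amp_max = ex$amp_max, amp_min = ex$amp_min, alar = ex$alar,
    mdif1 = di$mdif1, mdif2 = di$mdif2, lmax = ex$lmax,
    mdif1norm = di$mdif1norm, mdif2norm = di$mdif2norm,
    energy = en$energy, energy_norm = en$energy_norm, lar = ex$lar,
    entropy = ent
  )
  out <- out[feature_names()]
  attr(out, "degenerate") <- mo$degenerate || ex$degenerate
  out
}

#' Assemble the instance feature table
#'
#' Computes the 20 features for every segment and lays them out as instances
#' by `"<electrode>_<feature>"` columns. With `aggregation = "per_subject_mean"`
#' (the default) each subject contributes one row whose cells are the
#' arithmetic mean of that (electrode, feature) over the subject's windows;
#' with `"per_segment"` each (subject, window offset) is one instance with
#' the channels side by side.
#'
#' @param segments Segment table from [segment_recording()] (rows
#'   `subject_id`, `channel`, `start_s`, `fs`, `samples` list-column), for one
#'   or many subjects (rbind them).
#' @param aggregation `"per_subject_mean"` or `"per_segment"`.
#' @param channels Electrode order for the columns. Default: order of first
#'   appearance in `segments`.
#' @param entropy_bins,entropy_as_printed Passed to [extract_features()].
#' @return A tibble with `subject_id` (and `start_s` in per-segment mode),
#'   80 numeric feature columns for the default 4-electrode montage, and a
#'   `degenerate_windows` count per row.
#' @export
build_feature_table <- function(segments,
                                aggregation = c("per_subject_mean", "per_segment"),
                                channels = NULL,
                                entropy_bins = 64L,
                                entropy_as_printed = FALSE) {
  aggregation <- match.arg(aggregation)
  if (!is.data.frame(segments) || nrow(segments) == 0) {
    stop_input("segments must be a non-empty segment table")
  }
  channels <- channels %||% unique(segments$channel)
  missing_ch <- segments |>
    dplyr::distinct(.data$subject_id, .data$channel) |>
    dplyr::count(.data$subject_id, name = "n_ch") |>
    dplyr::filter(.data$n_ch < length(channels))
  if (nrow(missing_ch) > 0) {
    stop_input(
      "subject(s) missing an electrode: ",
      paste(missing_ch$subject_id, collapse = ", ")
    )
  }

  feats <- matrix(
    NA_real_, nrow = nrow(segments), ncol = 20L,
    dimnames = list(NULL, feature_names())
  )
  degen <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    fv <- extract_features(
      segments$samples[[i]], fs = segments$fs[i],
      entropy_bins = entropy_bins, entropy_as_printed = entropy_as_printed
    )
    feats[i, ] <- fv
    degen[i] <- attr(fv, "degenerate")
  }
  long <- tibble::tibble(
    subject_id = segments$subject_id,
    channel = segments$channel,
    start_s = segments$start_s,
    degenerate = degen
  )
  long <- dplyr::bind_cols(long, tibble::as_tibble(feats))

  col_order <- as.vector(outer(feature_names(), channels,
    function(f, ch) paste(ch, f, sep = "_")
  ))

  if (aggregation == "per_subject_mean") {
    wide <- long |>
      tidyr::pivot_longer(dplyr::all_of(feature_names()),
        names_to = "feature", values_to = "value"
      ) |>
      dplyr::group_by(.data$subject_id, .data$channel, .data$feature) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      tidyr::pivot_wider(
        names_from = c("channel", "feature"),
        values_from = "value", names_sep = "_"
      )
    dcount <- long |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(degenerate_windows = sum(.data$degenerate))
    out <- dplyr::left_join(wide, dcount, by = "subject_id")
    out <- out[, c("subject_id", col_order, "degenerate_windows")]
  } else {
    wide <- long |>
      tidyr::pivot_longer(dplyr::all_of(feature_names()),
        names_to = "feature", values_to = "value"
      ) |>
      tidyr::pivot_wider(
        id_cols = c("subject_id", "start_s"),
        names_from = c("channel", "feature"),
        values_from = "value", names_sep = "_"
      )
    dcount <- long |>
      dplyr::group_by(.data$subject_id, .data$start_s) |>
      dplyr::summarise(degenerate_windows = sum(.data$degenerate), .groups = "drop")
    out <- dplyr::left_join(wide, dcount, by = c("subject_id", "start_s"))
    out <- out[, c("subject_id", "start_s", col_order, "degenerate_windows")]
  }
  if (anyNA(out)) {
    stop_input("feature table has missing cells; check segment coverage per electrode")
  }
  out
}
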