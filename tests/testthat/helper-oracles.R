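# Independent straight-loop reference implementations used as oracles.
# Deliberately written with explicit loops and no shared code with the
# package's feature kernels.

naive_features <- function(x, fs, n_bins = 64) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n

  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (n - 1))

  if (s == 0) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- 0
    kurt <- 0
    for (v in x) {
      skew <- skew + ((v - m) / s)^3
      kurt <- kurt + ((v - m) / s)^4
    }
    skew <- skew / n
    kurt <- kurt / n
  }

  amp_max <- x[1]
  amp_min <- x[1]
  imax <- 1
  imin <- 1
  for (i in seq_len(n)) {
    if (x[i] > amp_max) {
      amp_max <- x[i]
      imax <- i
    }
    if (x[i] < amp_min) {
      amp_min <- x[i]
      imin <- i
    }
  }
  lmax <- imax / fs
  lmin <- imin / fs
  pp <- amp_max - amp_min
  ppt <- abs(lmax - lmin)
  pps <- if (ppt == 0) 0 else pp / ppt
  alar <- abs(amp_max) / lmax
  lar <- if (amp_max == 0) 0 else lmax / amp_max

  s1 <- 0
  for (i in 2:n) s1 <- s1 + abs(x[i] - x[i - 1])
  s2 <- 0
  for (i in 2:(n - 1)) s2 <- s2 + abs(x[i + 1] - 2 * x[i] + x[i - 1])

  e <- 0
  for (v in x) e <- e + v^2

  # entropy: equal-width bins over [min, max]
  if (amp_max == amp_min) {
    ent <- 0
  } else {
    counts <- rep(0, n_bins)
    width <- (amp_max - amp_min) / n_bins
    for (v in x) {
      b <- floor((v - amp_min) / width) + 1
      if (b > n_bins) b <- n_bins
      counts[b] <- counts[b] + 1
    }
    ent <- 0
    for (cnt in counts) {
      if (cnt > 0) {
        p <- cnt / n
        ent <- ent - p * log2(p)
      }
    }
  }

  c(
    mean = m, std = s, kurt = kurt, skew = skew, pp = pp, ppt = ppt,
    pps = pps, lmin = lmin, amp_max = amp_max, amp_min = amp_min,
    alar = alar, mdif1 = s1 / n, mdif2 = s2 / n, lmax = lmax,
    mdif1norm = s1 / (n - 1), mdif2norm = s2 / (n - 2),
    energy = e, energy_norm = e / n, lar = lar, entropy = ent
  )
}

# Direct enumeration of label entropy, conditional entropy and information
# gain for an already-discrete feature.
naive_info_gain <- function(feature, labels) {
  n <- length(labels)
  ent <- function(lv) {
    h <- 0
    for (cl in unique(lv)) {
      p <- sum(lv == cl) / length(lv)
      h <- h - p * log2(p)
    }
    h
  }
  hy <- ent(labels)
  hc <- 0
  for (v in unique(feature)) {
    sel <- feature == v
    hc <- hc + sum(sel) / n * ent(labels[sel])
  }
  list(h = hy, h_cond = hc, gain = hy - hc)
}

# Small labeled feature table built directly (no EEG simulation): two
# Gaussian classes in a handful of numeric columns.
make_blob_table <- function(n = 100, p = 4, sep = 5, seed = 1) {
  set.seed(seed)
  n1 <- n %/% 2
  n2 <- n - n1
  x <- rbind(
    matrix(rnorm(n1 * p, mean = 0), ncol = p),
    matrix(rnorm(n2 * p, mean = sep), ncol = p)
  )
  colnames(x) <- paste0("f", seq_len(p))
  tab <- tibble::as_tibble(x)
  tab$subject_id <- sprintf("s%03d", seq_len(n))
  tab$label <- factor(
    rep(c("stressed", "non_stressed"), c(n1, n2)),
    levels = c("stressed", "non_stressed")
  )
  tab
}

# Compact synthetic cohort -> labeled per-subject feature table using the
# true class as label (bypasses PSQ labeling where a test targets feature /
# selection behaviour only).
cohort_feature_table <- function(params,
                                 scheme = segmentation_scheme("non_overlapping", window_s = 10)) {
  co <- simulate_cohort(params)
  segs <- dplyr::bind_rows(lapply(co$recordings, segment_recording, scheme = scheme))
  tab <- build_feature_table(segs)
  labs <- tibble::tibble(
    subject_id = co$participants$subject_id,
    label = factor(co$participants$true_class,
      levels = c("stressed", "non_stressed", "excluded")
    )
  )
  suppressMessages(attach_labels(tab, labs))
}
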