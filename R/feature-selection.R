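#' Discretization specification for information-gain ranking
#'
#' The information-gain equations operate on categorical attributes, so
#' continuous feature columns are binned first. `equal_width` cuts the
#' observed range into `n_bins` equal intervals; `equal_frequency` bins by
#' rank so each bin holds (up to ties) the same number of instances — and is
#' therefore invariant under strictly monotone feature transforms;
#' `supervised_mdl` is entropy-minimization discretization with the
#' minimum-description-length stopping rule (recursive binary splits accepted
#' only while the information gain exceeds the MDL coding cost).
#'
#' @param method One of `"equal_frequency"`, `"equal_width"`,
#'   `"supervised_mdl"`.
#' @param n_bins Bin count for the unsupervised methods, >= 2. Default 10.
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(method = c("equal_frequency", "equal_width", "supervised_mdl"),
                                n_bins = 10L) {
  method <- match.arg(method)
  if (method != "supervised_mdl" && n_bins < 2) {
    stop_input("n_bins must be >= 2 for unsupervised discretization")
  }
  structure(list(method = method, n_bins = as.integer(n_bins)),
    class = "discretization_spec"
  )
}

# Bin a numeric vector according to a discretization_spec; labels are needed
# only for the supervised method. Returns an integer bin id per value.
discretize <- function(values, disc, labels = NULL) {
  stopifnot(inherits(disc, "discretization_spec"))
  n <- length(values)
  switch(disc$method,
    equal_width = {
      lo <- min(values)
      hi <- max(values)
      if (lo == hi) {
        return(rep(1L, n))
      }
      breaks <- seq(lo, hi, length.out = disc$n_bins + 1L)
      findInterval(values, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    },
    equal_frequency = {
      # rank-based binning: a tie group lands in the bin holding its average
      # rank, and monotone transforms leave the assignment unchanged
      r <- rank(values, ties.method = "average")
      b <- floor((r - 1) * disc$n_bins / n) + 1L
      as.integer(pmin(b, disc$n_bins))
    },
    supervised_mdl = {
      if (is.null(labels)) {
        stop_input("supervised_mdl discretization requires labels")
      }
      mdlp_bins(values, labels)
    }
  )
}

# Fayyad-Irani entropy-minimization discretization with MDL stopping.
# Returns integer bin ids (1 bin when no split is accepted).
mdlp_bins <- function(values, labels) {
  labels <- as.integer(factor(labels))
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  cuts <- mdlp_splits(v, y)
  if (length(cuts) == 0) {
    return(rep(1L, length(values)))
  }
  findInterval(values, sort(cuts)) + 1L
}

mdlp_splits <- function(v, y) {
  n <- length(v)
  if (n < 2) {
    return(numeric(0))
  }
  ent <- function(yy) {
    p <- tabulate(yy) / length(yy)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  # candidate boundaries: between adjacent distinct values
  distinct <- which(diff(v) > 0)
  if (length(distinct) == 0) {
    return(numeric(0))
  }
  h_full <- ent(y)
  best_gain <- -Inf
  best_i <- NA_integer_
  best_h1 <- best_h2 <- NA_real_
  for (i in distinct) {
    y1 <- y[seq_len(i)]
    y2 <- y[(i + 1):n]
    h1 <- ent(y1)
    h2 <- ent(y2)
    g <- h_full - (i / n) * h1 - ((n - i) / n) * h2
    if (g > best_gain) {
      best_gain <- g
      best_i <- i
      best_h1 <- h1
      best_h2 <- h2
    }
  }
  k <- length(unique(y))
  k1 <- length(unique(y[seq_len(best_i)]))
  k2 <- length(unique(y[(best_i + 1):n]))
  delta <- log2(3^k - 2) - (k * h_full - k1 * best_h1 - k2 * best_h2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) {
    return(numeric(0))
  }
  cut <- (v[best_i] + v[best_i + 1]) / 2
  c(
    mdlp_splits(v[seq_len(best_i)], y[seq_len(best_i)]),
    cut,
    mdlp_splits(v[(best_i + 1):n], y[(best_i + 1):n])
  )
}

#' Entropy of a label vector
#'
#' Shannon entropy of the empirical class frequencies, in bits, with
#' `0 * log(0) := 0`.
#'
#' @param labels Vector (factor or otherwise) of >= 1 class labels.
#' @return Entropy in bits.
#' @export
entropy_of_labels <- function(labels) {
  if (length(labels) < 1) stop_input("at least one label is required")
  p <- table(labels)
  p <- as.numeric(p[p > 0]) / length(labels)
  -sum(p * log2(p))
}

#' Conditional entropy of labels given a discrete feature
#'
#' Weighted average, over the feature's values v, of the label entropy within
#' the instances taking value v, weighted by |D_v| / |D|.
#'
#' @param feature_bins Discrete feature values (same length as `labels`).
#' @param labels Class labels.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels)) {
    stop_input("feature_bins and labels must have equal length")
  }
  n <- length(labels)
  h <- 0
  for (v in unique(feature_bins)) {
    sel <- feature_bins == v
    h <- h + sum(sel) / n * entropy_of_labels(labels[sel])
  }
  h
}

#' Information gain of a continuous feature
#'
#' Discretizes the feature and returns `H(D) - H(D | A)` in bits, clipped at
#' zero against negative floating-point residue.
#'
#' @param feature_values Numeric feature column.
#' @param labels Class labels.
#' @param disc A [discretization_spec()].
#' @return Information gain in bits, in `[0, H(labels)]`.
#' @export
information_gain <- function(feature_values, labels,
                             disc = discretization_spec()) {
  bins <- discretize(feature_values, disc, labels = labels)
  g <- entropy_of_labels(labels) - conditional_entropy(bins, labels)
  max(g, 0)
}

#' Rank feature columns by information gain and select the top k
#'
#' Computes the gain of every feature column against the binary stress label,
#' sorts non-increasing with deterministic lexicographic tie-breaking on the
#' column name, and flags the first `k` as selected. Performed once on the
#' full labeled table by default (see the methods vignette for the leakage
#' implications of selecting outside versus inside cross-validation).
#'
#' @param table Labeled feature table (a `label` column plus numeric feature
#'   columns; `subject_id`, `start_s` and `degenerate_windows` are ignored).
#' @param k Number of features to select (default 10).
#' @param disc A [discretization_spec()].
#' @return A tibble `rank`, `feature`, `gain_bits`, `selected`, ordered by
#'   rank; attribute `selected` holds the selected column names.
#' @export
rank_and_select <- function(table, k = 10L, disc = discretization_spec()) {
  if (!"label" %in% names(table)) stop_input("table must carry a label column")
  if (k <= 0) stop_input("k must be positive")
  drop_cols <- c("subject_id", "start_s", "degenerate_windows", "label")
  feat_cols <- setdiff(names(table), drop_cols)
  feat_cols <- feat_cols[vapply(table[feat_cols], is.numeric, logical(1))]
  if (k > length(feat_cols)) {
    stop_input("k exceeds the number of feature columns")
  }
  gains <- vapply(
    feat_cols,
    function(cn) information_gain(table[[cn]], table$label, disc),
    numeric(1)
  )
  ord <- order(-gains, feat_cols)
  out <- tibble::tibble(
    rank = seq_along(feat_cols),
    feature = feat_cols[ord],
    gain_bits = gains[ord],
    selected = seq_along(feat_cols) <= k
  )
  attr(out, "selected") <- out$feature[out$selected]
  out
}
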