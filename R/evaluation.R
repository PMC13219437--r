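#' Random fold assignment for k-fold cross-validation
#'
#' Partitions instances into `n_folds` disjoint folds whose sizes differ by
#' at most one, deterministically given the seed. With `stratified = TRUE`
#' the class proportions are balanced per fold (requires `labels`).
#'
#' @param instance_ids Vector of instance identifiers (or indices).
#' @param n_folds Number of folds, >= 2.
#' @param seed RNG seed for the shuffle. Default 1.
#' @param stratified Balance class proportions across folds.
#' @param labels Class labels (needed when `stratified`).
#' @return Integer vector of fold numbers (1..n_folds), named by instance id.
#' @export
make_folds <- function(instance_ids, n_folds = 10L, seed = 1L,
                       stratified = FALSE, labels = NULL) {
  n <- length(instance_ids)
  if (n_folds < 2) stop_input("n_folds must be >= 2")
  if (n < n_folds) stop_input("need at least as many instances as folds")
  fold <- integer(n)
  if (stratified) {
    if (is.null(labels) || length(labels) != n) {
      stop_input("stratified folds need one label per instance")
    }
    with_seed(seed, {
      # deal each class round-robin, continuing the rotation across classes
      # so global fold sizes still differ by at most one
      start <- sample.int(n_folds, 1) - 1L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((seq_along(idx) - 1L + start) %% n_folds) + 1L
        start <- (start + length(idx)) %% n_folds
      }
    })
  } else {
    sizes <- rep(n %/% n_folds, n_folds)
    if (n %% n_folds > 0) sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
    fold[with_seed(seed, sample.int(n))] <- rep(seq_len(n_folds), times = sizes)
  }
  names(fold) <- as.character(instance_ids)
  fold
}

#' Classification metrics from a pooled confusion matrix
#'
#' Accuracy (percent), class-frequency-weighted precision, recall and
#' F-measure, and Cohen's kappa, from a 2x2 (or k x k) confusion matrix with
#' actual classes in rows and predicted classes in columns. A per-class
#' metric with a zero denominator is defined as 0 and flagged.
#'
#' @param cm Square integer matrix, rows = actual, columns = predicted, with
#'   matching dimnames.
#' @return List: `accuracy` (percent), `precision`, `recall`, `f_measure`,
#'   `kappa`, `flagged` (character vector of zero-denominator classes).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_input("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop_input("confusion matrix is empty")
  diagv <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  wts <- rows / total
  flagged <- character(0)
  prec <- ifelse(cols > 0, diagv / cols, 0)
  if (any(cols == 0)) flagged <- c(flagged, paste0("precision:", rownames(cm)[cols == 0]))
  rec <- ifelse(rows > 0, diagv / rows, 0)
  if (any(rows == 0)) flagged <- c(flagged, paste0("recall:", rownames(cm)[rows == 0]))
  fden <- prec + rec
  f1 <- ifelse(fden > 0, 2 * prec * rec / fden, 0)
  p_o <- sum(diagv) / total
  p_e <- sum(rows * cols) / total^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  list(
    accuracy = 100 * p_o,
    precision = sum(wts * prec),
    recall = sum(wts * rec),
    f_measure = sum(wts * f1),
    kappa = kappa,
    flagged = flagged
  )
}

#' Cross-validated evaluation of one classifier
#'
#' Runs k-fold cross-validation on a labeled feature table: for each fold the
#' classifier is trained on the remaining folds and predicts the held-out
#' instances; all held-out predictions are pooled into a single confusion
#' matrix from which the metric suite is computed, with ROC AUC from the
#' pooled class scores.
#'
#' @param table Labeled feature table ([attach_labels()] output), optionally
#'   restricted to selected feature columns via `features`.
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds. Default 10.
#' @param seed Fold-assignment seed. Default 1.
#' @param stratified Use stratified folds. Default `FALSE` (random
#'   assignment).
#' @param features Character vector of feature columns to use; default all
#'   numeric feature columns.
#' @return An object of class `metrics_report`: classifier name and scheme,
#'   hyperparameters, fold seed, pooled `confusion` matrix (rows actual ST/NS,
#'   columns predicted), `accuracy`, `precision`, `recall`, `f_measure`,
#'   `kappa`, `roc_auc`, `n_instances`.
#' @export
cross_validate <- function(table, spec, n_folds = 10L, seed = 1L,
                           stratified = FALSE, features = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!"label" %in% names(table)) stop_input("table must carry a label column")
  y <- droplevels(factor(table$label, levels = c("stressed", "non_stressed")))
  if (nlevels(y) < 2) stop_input("both classes must be present")
  y <- factor(table$label, levels = c("stressed", "non_stressed"))
  drop_cols <- c("subject_id", "start_s", "degenerate_windows", "label")
  features <- features %||% setdiff(names(table), drop_cols)
  x <- as.matrix(table[, features, drop = FALSE])
  if (!is.numeric(x)) stop_input("feature columns must be numeric")

  fold <- make_folds(seq_len(nrow(x)), n_folds, seed,
    stratified = stratified, labels = y
  )
  for (f in seq_len(n_folds)) {
    if (nlevels(droplevels(y[fold != f])) < 2) {
      stop_input(
        "fold ", f, " leaves a single-class training set; ",
        "consider stratified = TRUE"
      )
    }
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  score <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- tryCatch(
      train_classifier(spec, x[!test, , drop = FALSE], y[!test], fold_seed = f),
      error = function(e) {
        stop_input(
          "classifier ", spec$name, " failed on fold ", f, ": ",
          conditionMessage(e)
        )
      }
    )
    pr <- predict_classifier(model, x[test, , drop = FALSE])
    pred[test] <- pr$class
    score[test] <- pr$score
  }
  cm <- table(actual = y, predicted = pred)
  m <- metrics_from_confusion(cm)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = score,
    levels = c("non_stressed", "stressed"), direction = "<", quiet = TRUE
  )))
  structure(
    list(
      classifier = spec$name, scheme = spec$scheme,
      hyperparameters = spec$hyperparameters,
      n_folds = n_folds, seed = seed, stratified = stratified,
      features = features,
      confusion = unclass(cm),
      accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f_measure = m$f_measure, kappa = m$kappa, roc_auc = auc,
      flagged = m$flagged, n_instances = length(y)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s / %s: accuracy %.2f%%, F %.2f, kappa %.2f, ROC %.2f (n = %d)\n",
    x$classifier, x$scheme, x$accuracy, x$f_measure, x$kappa, x$roc_auc,
    x$n_instances
  ))
  cm <- x$confusion
  dimnames(cm) <- list(
    actual = c("ST", "NS")[seq_len(nrow(cm))],
    predicted = c("ST", "NS")[seq_len(ncol(cm))]
  )
  print(cm)
  invisible(x)
}

#' Golden Distance
#'
#' Unified classifier-quality score: the Euclidean distance of the
#' `(Av-NAV, Av-DCO)` pair from the ideal point `(1, 0)`,
#' `gd = sqrt((1 - av_nav)^2 + av_dco^2)`. Lower is better; 0 only at the
#' ideal point, and at most `sqrt(2)` on the unit square. Av-NAV and Av-DCO
#' are taken as reported inputs.
#'
#' @param av_nav,av_dco Numeric vectors (recycled) of the two component
#'   scores in `[0, 1]`.
#' @return Numeric vector of Golden Distances.
#' @export
golden_distance <- function(av_nav, av_dco) {
  if (any(!is.finite(av_nav)) || any(!is.finite(av_dco))) {
    stop_input("av_nav and av_dco must be finite")
  }
  sqrt((1 - av_nav)^2 + av_dco^2)
}

#' Ranked comparison of classifier results
#'
#' Collects evaluation reports for (classifier, scheme) pairs into one table,
#' joins optional `(av_nav, av_dco)` components and their Golden Distance,
#' and sorts by Golden Distance ascending (results without components sort
#' last), breaking ties by accuracy descending and then classifier name.
#'
#' @param reports List of `metrics_report` objects from [cross_validate()].
#' @param av Optional data frame `classifier`, `scheme`, `av_nav`, `av_dco`.
#' @return A tibble with one row per report, carrying all metrics,
#'   hyperparameter provenance (deparsed), and `golden_distance` where the
#'   components are available.
#' @export
compare_report <- function(reports, av = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (length(reports) == 0) stop_input("at least one report is required")
  tab <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(
      classifier = r$classifier, scheme = r$scheme,
      accuracy = r$accuracy, f_measure = r$f_measure, kappa = r$kappa,
      recall = r$recall, precision = r$precision, roc_auc = r$roc_auc,
      n_instances = r$n_instances, n_folds = r$n_folds, seed = r$seed,
      hyperparameters = paste(
        names(r$hyperparameters), unlist(r$hyperparameters),
        sep = "=", collapse = ", "
      )
    )
  }))
  if (!is.null(av)) {
    tab <- dplyr::left_join(tab, av, by = c("classifier", "scheme"))
    tab$golden_distance <- ifelse(
      is.finite(tab$av_nav) & is.finite(tab$av_dco),
      golden_distance(tab$av_nav, tab$av_dco), NA_real_
    )
  } else {
    tab$golden_distance <- NA_real_
  }
  tab[order(
    xtfrm(tab$golden_distance), -tab$accuracy, tab$classifier, tab$scheme
  ), ]
}
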