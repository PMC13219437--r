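#' Perceived-stress labeling thresholds
#'
#' Computes the two-sided labeling rule TP = mu +/- sigma/2 from a cohort's
#' PSQ scores: `mu` is the arithmetic mean, `sigma` the sample standard
#' deviation (n-1 divisor), and the thresholds `t_low = mu - sigma/2`,
#' `t_high = mu + sigma/2` delimit the excluded intermediate band.
#'
#' @param psq_scores Numeric vector of >= 2 finite scores, or an externally
#'   supplied pair via `mu` and `sigma` (then `psq_scores` may be `NULL`).
#' @param mu,sigma Optional externally supplied moments overriding the
#'   empirical ones.
#' @return An object of class `labeling_rule`: `mu`, `sigma`, `t_low`,
#'   `t_high`.
#' @export
compute_thresholds <- function(psq_scores = NULL, mu = NULL, sigma = NULL) {
  if (is.null(mu) || is.null(sigma)) {
    if (is.null(psq_scores) || length(psq_scores) < 2) {
      stop_input("at least 2 PSQ scores are required")
    }
    if (any(!is.finite(psq_scores))) {
      stop_input("PSQ scores must all be finite")
    }
    mu <- mean(psq_scores)
    sigma <- stats::sd(psq_scores)
  }
  if (sigma < 0) stop_input("sigma must be >= 0")
  structure(
    list(mu = mu, sigma = sigma, t_low = mu - sigma / 2, t_high = mu + sigma / 2),
    class = "labeling_rule"
  )
}

#' @export
print.labeling_rule <- function(x, ...) {
  cat(sprintf(
    "<labeling_rule> mu = %.2f, sigma = %.2f -> non-stressed < %.2f, stressed > %.2f\n",
    x$mu, x$sigma, x$t_low, x$t_high
  ))
  invisible(x)
}

#' Assign stress labels from PSQ scores
#'
#' Scores strictly below `t_low` are `non_stressed`, strictly above `t_high`
#' are `stressed`, and scores in the closed intermediate band (boundary
#' equality included) are `excluded`, yielding an exhaustive three-way
#' partition.
#'
#' @param scores Data frame with columns `subject_id` and `psq_score`.
#' @param rule A [compute_thresholds()] rule.
#' @return Tibble `subject_id`, `label` (factor stressed / non_stressed /
#'   excluded).
#' @export
assign_labels <- function(scores, rule) {
  stopifnot(inherits(rule, "labeling_rule"))
  if (!all(c("subject_id", "psq_score") %in% names(scores))) {
    stop_input("scores needs columns subject_id and psq_score")
  }
  bad <- scores$subject_id[!is.finite(scores$psq_score)]
  if (length(bad) > 0) {
    stop_input(
      "non-finite PSQ score for subject(s): ",
      paste(bad, collapse = ", ")
    )
  }
  lab <- ifelse(
    scores$psq_score < rule$t_low, "non_stressed",
    ifelse(scores$psq_score > rule$t_high, "stressed", "excluded")
  )
  tibble::tibble(
    subject_id = as.character(scores$subject_id),
    label = factor(lab, levels = c("stressed", "non_stressed", "excluded"))
  )
}

#' Attach binary labels to a feature table
#'
#' Joins labels onto the instance table, drops rows of excluded subjects and
#' returns the table with a binary `label` column (levels stressed /
#' non_stressed). The retained-subject count is reported via a message.
#'
#' @param table A feature table from [build_feature_table()].
#' @param labels Output of [assign_labels()].
#' @return The labeled feature table (excluded rows removed).
#' @export
attach_labels <- function(table, labels) {
  unlabeled <- setdiff(unique(table$subject_id), labels$subject_id)
  if (length(unlabeled) > 0) {
    stop_input(
      "no label for subject(s): ", paste(unlabeled, collapse = ", ")
    )
  }
  out <- dplyr::inner_join(table, labels, by = "subject_id") |>
    dplyr::filter(.data$label != "excluded")
  out$label <- factor(as.character(out$label), levels = c("stressed", "non_stressed"))
  n_kept <- length(unique(out$subject_id))
  if (nrow(out) == 0) {
    stop_input("all subjects fall in the excluded PSQ band; nothing to classify")
  }
  message(
    n_kept, " of ", length(unique(table$subject_id)),
    " subjects retained after PSQ-band exclusion"
  )
  out
}
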