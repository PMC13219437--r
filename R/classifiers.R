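#' Classifier specification
#'
#' One of the five benchmark classifiers with its per-scheme default
#' hyperparameters: Random Forest (`RF`: 100 trees, max depth 10, seed 1),
#' a pruned decision tree (`J48`: confidence 0.15, min leaf 5), K-nearest
#' neighbors (`KNN`: k = 5, inverse-distance weighting, linear search),
#' a multilayer perceptron (`MLP`: 500 epochs; hidden-layer size defaults to
#' `(n_features + n_classes) / 2`), and AdaBoostM1 over decision stumps
#' (`ABM`: 100 iterations non-overlapping, 200 overlapping). Defaults differ
#' between the two segmentation schemes only where the reference settings
#' differ. Every hyperparameter is recorded in the evaluation report for
#' provenance; unknown names are rejected. The mapping from the reference
#' workbench vocabulary onto the R back-ends (ranger, rpart, nnet, and the
#' in-package weighted-KNN and AdaBoost routines) is documented in the
#' methods vignette.
#'
#' @param name One of `"RF"`, `"J48"`, `"KNN"`, `"MLP"`, `"ABM"`.
#' @param scheme Segmentation scheme the defaults are keyed to.
#' @param ... Hyperparameter overrides (must match known names).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("RF", "J48", "KNN", "MLP", "ABM"),
                            scheme = c("non_overlapping", "overlapping"),
                            ...) {
  name <- match.arg(name)
  scheme <- match.arg(scheme)
  defaults <- switch(name,
    RF = list(iterations = 100L, max_depth = 10L, seed = 1L),
    J48 = list(
      confidence = 0.15, min_leaf = 5L,
      folds = if (scheme == "non_overlapping") 3L else 5L
    ),
    KNN = list(k = 5L, weight = "inverse_distance", search = "linear"),
    MLP = list(
      learning_rate = 0.3, momentum = 0.2, epochs = 500L,
      hidden = NA_integer_, seed = 1L,
      batch_size = if (scheme == "overlapping") 100L else NA_integer_
    ),
    ABM = list(
      iterations = if (scheme == "non_overlapping") 100L else 200L,
      weight_threshold = if (scheme == "non_overlapping") 100L else 200L,
      base_learner = "decision_stump"
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop_input(
      "unknown hyperparameter(s) for ", name, ": ", paste(bad, collapse = ", ")
    )
  }
  structure(
    list(
      name = name, scheme = scheme,
      hyperparameters = utils::modifyList(defaults, over)
    ),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
    sep = "=", collapse = ", "
  )
  cat("<classifier_spec>", x$name, "(", x$scheme, "):", hp, "\n")
  invisible(x)
}

# --- internal train/predict dispatch -----------------------------------------
# All back-ends take x (numeric matrix), y (factor, first level = positive
# class "stressed") and return a model; predictions return list(class, score)
# with score = P(first level).

train_classifier <- function(spec, x, y, fold_seed = 0L) {
  hp <- spec$hyperparameters
  switch(spec$name,
    RF = {
      fit <- ranger::ranger(
        x = x, y = y,
        num.trees = hp$iterations, max.depth = hp$max_depth,
        seed = hp$seed, probability = TRUE
      )
      list(kind = "RF", fit = fit, levels = levels(y))
    },
    J48 = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
        control = rpart::rpart.control(
          minbucket = hp$min_leaf, xval = 0, cp = 0.01
        )
      )
      list(kind = "J48", fit = fit, levels = levels(y))
    },
    KNN = {
      rng <- apply(x, 2, range)
      span <- rng[2, ] - rng[1, ]
      span[span == 0] <- 1
      list(
        kind = "KNN", k = hp$k,
        lo = rng[1, ], span = span,
        x = sweep(sweep(x, 2, rng[1, ]), 2, span, "/"),
        y = y, levels = levels(y)
      )
    },
    MLP = {
      p <- ncol(x)
      size <- hp$hidden
      if (is.na(size)) size <- max(1L, round((p + nlevels(y)) / 2))
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      fit <- with_seed(hp$seed + fold_seed, nnet::nnet(
        .y ~ ., data = df, size = size, maxit = hp$epochs,
        decay = 0, trace = FALSE
      ))
      list(kind = "MLP", fit = fit, levels = levels(y))
    },
    ABM = {
      fit <- adaboost_stumps(x, y, iterations = hp$iterations)
      list(kind = "ABM", fit = fit, levels = levels(y))
    }
  )
}

predict_classifier <- function(model, x) {
  lev <- model$levels
  switch(model$kind,
    RF = {
      pr <- stats::predict(model$fit, data = x)$predictions
      score <- pr[, lev[1]]
      list(class = factor(lev[(score < 0.5) + 1], levels = lev), score = score)
    },
    J48 = {
      pr <- stats::predict(model$fit, newdata = data.frame(x, check.names = FALSE),
        type = "prob"
      )
      score <- pr[, lev[1]]
      list(class = factor(lev[(score < 0.5) + 1], levels = lev), score = score)
    },
    KNN = predict_wknn(model, x),
    MLP = {
      raw <- stats::predict(model$fit,
        newdata = data.frame(x, check.names = FALSE), type = "raw"
      )
      # nnet's single output unit models P(second factor level)
      score <- 1 - as.numeric(raw)
      list(class = factor(lev[(score < 0.5) + 1], levels = lev), score = score)
    },
    ABM = predict_adaboost(model$fit, x, lev)
  )
}

# Inverse-distance-weighted K-nearest-neighbor vote over min-max-normalized
# features, exhaustive (linear) neighbor search.
predict_wknn <- function(model, x) {
  xn <- sweep(sweep(x, 2, model$lo), 2, model$span, "/")
  lev <- model$levels
  n_test <- nrow(xn)
  score <- numeric(n_test)
  train_sq <- rowSums(model$x^2)
  for (i in seq_len(n_test)) {
    d2 <- train_sq - 2 * (model$x %*% xn[i, ]) + sum(xn[i, ]^2)
    d <- sqrt(pmax(as.numeric(d2), 0))
    nb <- order(d)[seq_len(min(model$k, length(d)))]
    w <- 1 / pmax(d[nb], 1e-12)
    score[i] <- sum(w[model$y[nb] == lev[1]]) / sum(w)
  }
  list(class = factor(lev[(score < 0.5) + 1], levels = lev), score = score)
}

# AdaBoost.M1 with depth-1 decision stumps as the weak learner.
adaboost_stumps <- function(x, y, iterations) {
  n <- nrow(x)
  yy <- ifelse(y == levels(y)[1], 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(iterations)) {
    st <- best_stump(x, yy, w)
    pred <- stump_predict(st, x)
    err <- sum(w[pred != yy])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

best_stump <- function(x, yy, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]
    ys <- yy[ord]
    ws <- w[ord]
    # cumulative weighted class mass left of each candidate cut
    pos_cum <- cumsum(ws * (ys == 1))
    neg_cum <- cumsum(ws * (ys == -1))
    pos_tot <- pos_cum[length(pos_cum)]
    neg_tot <- neg_cum[length(neg_cum)]
    cuts <- which(diff(vs) > 0)
    if (length(cuts) == 0) next
    # rule A: predict +1 below cut -> error = neg mass below + pos mass above
    err_a <- neg_cum[cuts] + (pos_tot - pos_cum[cuts])
    # rule B: predict -1 below cut
    err_b <- pos_cum[cuts] + (neg_tot - neg_cum[cuts])
    ia <- which.min(err_a)
    ib <- which.min(err_b)
    if (err_a[ia] < best$err) {
      best <- list(
        err = err_a[ia], feature = j,
        threshold = (vs[cuts[ia]] + vs[cuts[ia] + 1]) / 2, below = 1
      )
    }
    if (err_b[ib] < best$err) {
      best <- list(
        err = err_b[ib], feature = j,
        threshold = (vs[cuts[ib]] + vs[cuts[ib] + 1]) / 2, below = -1
      )
    }
  }
  if (!is.finite(best$err)) {
    # all features constant: majority stump
    best <- list(
      err = min(sum(w[yy == 1]), sum(w[yy == -1])),
      feature = 1L, threshold = Inf,
      below = if (sum(w[yy == 1]) >= sum(w[yy == -1])) 1 else -1
    )
  }
  best
}

stump_predict <- function(st, x) {
  ifelse(x[, st$feature] <= st$threshold, st$below, -st$below)
}

predict_adaboost <- function(fit, x, lev) {
  if (length(fit$alphas) == 0) {
    score <- rep(0.5, nrow(x))
  } else {
    margin <- numeric(nrow(x))
    for (t in seq_along(fit$stumps)) {
      margin <- margin + fit$alphas[t] * stump_predict(fit$stumps[[t]], x)
    }
    score <- (margin / sum(fit$alphas) + 1) / 2
  }
  list(class = factor(lev[(score < 0.5) + 1], levels = lev), score = score)
}
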