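#' Lagged history design matrix for song-prediction GLMs
#'
#' For each frame t beyond the history window, the design row concatenates
#' the previous `n_lags` values of each selected behavior track,
#' `[b(t-1), ..., b(t-n_lags)]` — roughly one second of behavioral history
#' at 60 fps with the default 64 lags. The response is the target song track
#' at frame t. The first `n_lags` frames are dropped.
#'
#' @param fs a `behavior_tracks` object (or its `frames` data.frame).
#' @param behaviors character vector of predictor track names.
#' @param target response track name (e.g. `"female_song"`).
#' @param n_lags history length in frames.
#' @return list of class `history_design`: `X` (rows x (behaviors*n_lags)),
#'   `y` (0/1), `behaviors`, `n_lags`, `fps`.
#' @export
build_history_design <- function(fs, behaviors, target = "female_song",
                                 n_lags = 64) {
  frames <- if (inherits(fs, "behavior_tracks")) fs$frames else fs
  fps <- if (inherits(fs, "behavior_tracks")) fs$fps else 60
  missing <- setdiff(c(behaviors, target), names(frames))
  if (length(missing))
    stop("unknown track name(s): ", paste(missing, collapse = ", "))
  n <- nrow(frames)
  if (n <= n_lags) stop("series shorter than the history window")
  blocks <- lapply(behaviors, function(b) {
    x <- frames[[b]]
    # embed row t = [x(t), x(t-1), ...]; we need lags 1..n_lags for frame t
    E <- stats::embed(x, n_lags + 1)[, -1, drop = FALSE]
    colnames(E) <- paste0(b, "_lag", seq_len(n_lags))
    E
  })
  X <- do.call(cbind, blocks)
  y <- frames[[target]][(n_lags + 1):n]
  structure(list(X = X, y = y, behaviors = behaviors, n_lags = n_lags,
                 fps = fps, target = target),
            class = "history_design")
}

#' Sparse logistic history-filter GLM
#'
#' Logistic GLM predicting framewise song presence from lagged behavior
#' histories, with an L1 penalty on the filter weights (bias unpenalized).
#' Annotated behaviors are strongly auto- and cross-correlated; the sparsity
#' penalty shrinks weights that would be large merely through those
#' correlations. When `penalty_weight` is `NULL` the penalty is chosen by
#' cross-validated deviance over glmnet's lambda path (folds seeded for
#' determinism).
#'
#' @param design a `history_design` (or a plain matrix, with `response`).
#' @param response 0/1 response when `design` is a matrix.
#' @param penalty_weight penalty strength lambda; `NULL` to select by CV.
#' @param seed integer seed (CV fold assignment).
#' @param n_folds CV folds for penalty selection.
#' @param alpha elastic-net mixing: 1 = pure L1 (lasso); the default keeps a
#'   small ridge component, whose grouping effect stabilizes weight placement
#'   across the strongly collinear neighboring lags. 0 = pure ridge.
#' @param nlambda length of the penalty grid searched by CV.
#' @return An object of class `history_glm`: `filters` (named list of
#'   per-behavior weight vectors, lag 1..n_lags), `bias`, `lambda`,
#'   `behaviors`, `n_lags`, `fps`, plus the glmnet `fit`.
#' @export
fit_sparse_logistic <- function(design, response = NULL,
                                penalty_weight = NULL, seed = 1,
                                n_folds = 5, alpha = 0.95, nlambda = 30) {
  if (inherits(design, "history_design")) {
    X <- design$X; y <- design$y
    behaviors <- design$behaviors; n_lags <- design$n_lags
    fps <- design$fps
  } else {
    X <- as.matrix(design); y <- response
    behaviors <- "x"; n_lags <- ncol(X); fps <- 60
  }
  if (length(unique(y)) < 2) stop("response is constant")
  if (all(X == 0)) {
    warning("all-zero design; returning bias-only model")
    p <- mean(y)
    filters <- lapply(setNames(behaviors, behaviors),
                      function(b) numeric(n_lags))
    return(structure(list(filters = filters, bias = qlogis(p),
                          lambda = penalty_weight %||% Inf,
                          behaviors = behaviors, n_lags = n_lags, fps = fps,
                          fit = NULL), class = "history_glm"))
  }
  if (!is.null(penalty_weight) && is.infinite(penalty_weight)) {
    filters <- lapply(setNames(behaviors, behaviors),
                      function(b) numeric(n_lags))
    return(structure(list(filters = filters, bias = qlogis(mean(y)),
                          lambda = Inf, behaviors = behaviors,
                          n_lags = n_lags, fps = fps, fit = NULL),
                     class = "history_glm"))
  }
  if (is.null(penalty_weight)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(y))))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            foldid = foldid, standardize = FALSE,
                            nlambda = nlambda, type.measure = "deviance")
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    lambda <- penalty_weight
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE,
                          thresh = 1e-10)
  }
  beta <- as.numeric(coef(fit, s = lambda))
  bias <- beta[1]
  w <- beta[-1]
  filters <- lapply(seq_along(behaviors), function(i)
    w[(i - 1) * n_lags + seq_len(n_lags)])
  names(filters) <- behaviors
  structure(list(filters = filters, bias = bias, lambda = lambda,
                 behaviors = behaviors, n_lags = n_lags, fps = fps,
                 fit = fit), class = "history_glm")
}

#' @method print history_glm
#' @export
print.history_glm <- function(x, ...) {
  cat(sprintf("Sparse logistic history GLM: %d lag(s) x %d behavior(s), lambda = %.3g\n",
              x$n_lags, length(x$behaviors), x$lambda))
  for (b in x$behaviors) {
    pk <- filter_peak_lag(x, b)
    cat(sprintf("  %-18s peak lag %s ms, %d non-zero weights\n", b,
                if (is.na(pk)) "NA" else sprintf("%.0f", pk),
                sum(x$filters[[b]] != 0)))
  }
  invisible(x)
}

#' @export
coef.history_glm <- function(object, ...) {
  c(bias = object$bias, unlist(object$filters))
}

#' @export
plot.history_glm <- function(x, behavior = x$behaviors[1], ...) {
  w <- x$filters[[behavior]]
  lag_ms <- seq_along(w) * 1000 / x$fps
  plot(lag_ms, w, type = "h", xlab = "lag before frame (ms)",
       ylab = "filter weight", main = behavior, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Predict song probability from a history GLM
#'
#' @param object a `history_glm`.
#' @param design a `history_design` or matrix.
#' @param ... unused.
#' @return Vector of predicted song probabilities.
#' @export
predict.history_glm <- function(object, design, ...) {
  X <- if (inherits(design, "history_design")) design$X else as.matrix(design)
  w <- unlist(object$filters)
  plogis(object$bias + as.numeric(X %*% w))
}

#' Cross-validated relative deviance reduction
#'
#' The performance metric for history GLMs: on each random 80/20 split the
#' model is refit on the training frames (at the supplied or CV-chosen
#' penalty) and its binomial deviance on the held-out frames is compared to
#' a bias-only model trained on the same split:
#' `1 - deviance(model) / deviance(bias-only)`. The mean over splits is
#' returned. Held-out folds with constant response are skipped and counted.
#'
#' @param design a `history_design`.
#' @param penalty_weight L1 penalty; `NULL` selects once by CV on the full
#'   data and reuses it across splits.
#' @param train_frac training fraction per split.
#' @param n_splits number of random subsampling splits.
#' @param seed integer seed.
#' @return list of class `model_performance`: `relative_deviance_reduction`
#'   (mean), `per_split`, `sd`, `n_skipped`, `lambda`.
#' @export
relative_deviance_reduction <- function(design, penalty_weight = NULL,
                                        train_frac = 0.8, n_splits = 20,
                                        seed = 1, alpha = 0.95) {
  stopifnot(inherits(design, "history_design"))
  n <- length(design$y)
  if (n < 10) stop("too few frames for a train/test split")
  if (is.null(penalty_weight)) {
    full <- fit_sparse_logistic(design, seed = seed, alpha = alpha)
    penalty_weight <- full$lambda
  }
  with_seed(seed, {
    vals <- numeric(0); skipped <- 0L
    for (s in seq_len(n_splits)) {
      tr <- sort(sample.int(n, round(train_frac * n)))
      te <- setdiff(seq_len(n), tr)
      ytr <- design$y[tr]; yte <- design$y[te]
      if (length(unique(ytr)) < 2 || length(unique(yte)) < 2) {
        skipped <- skipped + 1L; next
      }
      sub <- design; sub$X <- design$X[tr, , drop = FALSE]; sub$y <- ytr
      fit <- fit_sparse_logistic(sub, penalty_weight = penalty_weight,
                                 alpha = alpha)
      p <- plogis(fit$bias +
                    as.numeric(design$X[te, , drop = FALSE] %*%
                                 unlist(fit$filters)))
      p0 <- mean(ytr)
      vals <- c(vals, 1 - binomial_deviance(yte, p) /
                  binomial_deviance(yte, rep(p0, length(yte))))
    }
    structure(list(relative_deviance_reduction = mean(vals),
                   per_split = vals, sd = sd(vals), n_skipped = skipped,
                   lambda = penalty_weight, cv_scheme = "80/20 random subsampling"),
              class = "model_performance")
  })
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @method print model_performance
#' @export
print.model_performance <- function(x, ...) {
  cat(sprintf("Relative deviance reduction: %.3f (sd %.3f over %d splits%s)\n",
              x$relative_deviance_reduction, x$sd, length(x$per_split),
              if (x$n_skipped) sprintf(", %d skipped", x$n_skipped) else ""))
  invisible(x)
}

#' Bootstrap s.e.m. of history filters and performance
#'
#' Refits the model `n_boot` times on random 75% subsets of the data. The
#' subsampling unit is a contiguous one-second block of frames rather than
#' single frames, respecting the strong temporal autocorrelation of the
#' annotated behaviors.
#'
#' @param design a `history_design`.
#' @param n_boot bootstrap replicates.
#' @param subsample_frac fraction of blocks used per replicate.
#' @param block_s block length, s.
#' @param penalty_weight L1 penalty; `NULL` selects once on the full data.
#' @param seed integer seed.
#' @return list: `filter_sem` (named list per behavior, per-lag s.e.m.),
#'   `performance_sem`, `n_boot`, `low_n` flag (`n_boot < 10`).
#' @export
bootstrap_filters <- function(design, n_boot = 1000, subsample_frac = 0.75,
                              block_s = 1, penalty_weight = NULL, seed = 1,
                              alpha = 0.95) {
  stopifnot(inherits(design, "history_design"))
  n <- length(design$y)
  block <- max(1L, round(block_s * design$fps))
  starts <- seq(1L, n, by = block)
  if (is.null(penalty_weight))
    penalty_weight <- fit_sparse_logistic(design, seed = seed,
                                          alpha = alpha)$lambda
  with_seed(seed, {
    wmat <- NULL; perf <- numeric(0)
    for (b in seq_len(n_boot)) {
      keep_blocks <- sort(sample(length(starts),
                                 round(subsample_frac * length(starts))))
      idx <- unlist(lapply(starts[keep_blocks], function(s0)
        s0:min(s0 + block - 1L, n)))
      sub <- design
      sub$X <- design$X[idx, , drop = FALSE]; sub$y <- design$y[idx]
      if (length(unique(sub$y)) < 2) next
      fit <- tryCatch(
        fit_sparse_logistic(sub, penalty_weight = penalty_weight,
                            alpha = alpha),
        error = function(e) NULL)
      if (is.null(fit)) next
      w <- unlist(fit$filters)
      wmat <- rbind(wmat, w)
      p <- plogis(fit$bias + as.numeric(sub$X %*% w))
      perf <- c(perf, 1 - binomial_deviance(sub$y, p) /
                  binomial_deviance(sub$y, rep(mean(sub$y), length(sub$y))))
    }
    nl <- design$n_lags
    sems <- apply(wmat, 2, sd)
    filter_sem <- lapply(seq_along(design$behaviors), function(i)
      sems[(i - 1) * nl + seq_len(nl)])
    names(filter_sem) <- design$behaviors
    list(filter_sem = filter_sem, performance_sem = sd(perf),
         n_boot = nrow(wmat), low_n = nrow(wmat) < 10)
  })
}

#' Peak lag of a history filter
#'
#' Lag index of the maximum filter weight, converted to milliseconds
#' (`lag * 1000 / fps`). Ties are broken toward the smaller lag and flagged.
#'
#' @param fit a `history_glm` (or numeric weight vector).
#' @param behavior which filter, when `fit` is a model.
#' @param fps frame rate (taken from the model when available).
#' @return Peak lag in ms (`NA` with flag `"all_zero"` for a zero filter;
#'   attribute `tie = TRUE` when the maximum is not unique).
#' @export
filter_peak_lag <- function(fit, behavior = NULL, fps = NULL) {
  if (inherits(fit, "history_glm")) {
    behavior <- behavior %||% fit$behaviors[1]
    w <- fit$filters[[behavior]]
    fps <- fps %||% fit$fps
  } else {
    w <- fit
    fps <- fps %||% 60
  }
  if (all(w == 0)) return(structure(NA_real_, flag = "all_zero"))
  pk <- which.max(w)
  tie <- sum(w == w[pk]) > 1
  structure(pk * 1000 / fps, tie = tie)
}

#' Single-variable ranking and best-plus-one models
#'
#' Fits each behavior as a single-variable history GLM, ranks them by
#' cross-validated relative deviance reduction, then extends the best
#' predictor with each remaining behavior and reports the absolute and
#' relative performance gains of the two-variable models.
#'
#' @param fs a `behavior_tracks` object.
#' @param behaviors candidate predictor tracks (>= 2).
#' @param target response track.
#' @param n_lags history length, frames.
#' @param n_splits CV splits for the performance estimates.
#' @param seed integer seed.
#' @return list of class `stepwise_models`: `single` (data.frame `behavior`,
#'   `rdd`, ranked), `best`, `pairs` (data.frame `added`, `rdd`,
#'   `abs_gain`, `rel_gain`).
#' @export
stepwise_two_variable <- function(fs, behaviors, target = "female_song",
                                  n_lags = 64, n_splits = 10, seed = 1) {
  if (length(behaviors) < 2) stop("need at least two candidate behaviors")
  single <- vapply(behaviors, function(b) {
    d <- build_history_design(fs, b, target = target, n_lags = n_lags)
    relative_deviance_reduction(d, n_splits = n_splits,
                                seed = seed)$relative_deviance_reduction
  }, 0)
  ord <- order(single, decreasing = TRUE)
  best <- behaviors[ord[1]]
  rest <- behaviors[ord[-1]]
  pairs <- do.call(rbind, lapply(rest, function(b) {
    d <- build_history_design(fs, c(best, b), target = target,
                              n_lags = n_lags)
    rdd <- relative_deviance_reduction(d, n_splits = n_splits,
                                       seed = seed)$relative_deviance_reduction
    data.frame(added = b, rdd = rdd, abs_gain = rdd - single[ord[1]],
               rel_gain = (rdd - single[ord[1]]) / abs(single[ord[1]]))
  }))
  structure(list(
    single = data.frame(behavior = behaviors[ord], rdd = single[ord],
                        row.names = NULL),
    best = best, pairs = pairs), class = "stepwise_models")
}

#' @method print stepwise_models
#' @export
print.stepwise_models <- function(x, ...) {
  cat("Single-variable models (ranked by relative deviance reduction):\n")
  print(x$single, digits = 3)
  cat("\nBest (", x$best, ") plus one:\n", sep = "")
  print(x$pairs, digits = 3)
  invisible(x)
}
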