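#' Build a rate-GLM design
#'
#' Design for linking song production rates to the presence/absence of
#' sensory channels (or mating state and courtship success), coded
#' -1/+1 per predictor, one row per courtship pair.
#'
#' @param design matrix or data.frame of predictors with entries in
#'   \{-1, +1\}.
#' @param counts per-pair song counts (bouts or pulses); used with
#'   `durations` as a Poisson count response with a log-duration offset.
#' @param durations per-pair courtship durations, s.
#' @param rates per-pair rates, Hz; used (quasi-Poisson) when counts are
#'   unavailable.
#' @return A list of class `rate_design`.
#' @export
rate_design <- function(design, counts = NULL, durations = NULL,
                        rates = NULL) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (!all(design %in% c(-1, 1)))
    stop("design entries must be coded -1/+1")
  if (is.null(counts) && is.null(rates))
    stop("supply either counts (+ durations) or rates")
  if (!is.null(counts)) {
    stopifnot(!is.null(durations), length(counts) == nrow(design),
              all(counts >= 0), all(durations > 0))
  } else {
    stopifnot(length(rates) == nrow(design), all(rates >= 0))
  }
  structure(list(design = design, counts = counts, durations = durations,
                 rates = rates), class = "rate_design")
}

#' Poisson GLM for song rates under sensory manipulation
#'
#' Rates are non-negative and Poisson-like, so the model uses a log link
#' (mean = exp(eta)). Predictor columns are z-scored before fitting so that
#' coefficients reflect the relative impact of each channel; the response is
#' left on its natural scale (z-scoring a count response would break the
#' Poisson support). With counts available the fit is a Poisson GLM with a
#' log-duration offset; otherwise a quasi-Poisson fit on the rates.
#'
#' @param d a [rate_design()].
#' @return An object of class `rate_glm`: `coefficients` (data.frame `term`,
#'   `beta`, `se`, `p`), the underlying `fit`, `converged`, and notes on any
#'   dropped constant columns.
#' @export
fit_rate_glm <- function(d) {
  stopifnot(inherits(d, "rate_design"))
  X <- d$design
  const <- apply(X, 2, function(col) length(unique(col)) < 2)
  dropped <- colnames(X)[const]
  if (any(const)) {
    warning("dropping constant predictor column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (!ncol(X)) stop("no non-constant predictors left")
  if (nrow(unique(X)) < 2) stop("need at least two distinct design rows")
  Xz <- scale(X)
  df <- as.data.frame(Xz)
  if (!is.null(d$counts)) {
    df$.y <- d$counts
    fit <- glm(.y ~ ., data = df, family = poisson(),
               offset = log(d$durations))
  } else {
    df$.y <- d$rates
    fit <- suppressWarnings(
      glm(.y ~ ., data = df, family = quasipoisson()))
  }
  if (!fit$converged)
    warning("IRLS did not converge; coefficients may be unstable")
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), beta = s[, 1], se = s[, 2],
                    p = s[, 4], row.names = NULL)
  structure(list(coefficients = out, fit = fit, converged = fit$converged,
                 dropped = dropped, scale_center = attr(Xz, "scaled:center"),
                 scale_sd = attr(Xz, "scaled:scale")),
            class = "rate_glm")
}

#' @method print rate_glm
#' @export
print.rate_glm <- function(x, ...) {
  cat("Poisson rate GLM (log link, z-scored +/-1 predictors)\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @export
coef.rate_glm <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$term)
}

#' @method summary rate_glm
#' @export
summary.rate_glm <- function(object, ...) {
  cat("Poisson rate GLM\n\n")
  print(object$coefficients, digits = 4)
  if (length(object$dropped))
    cat("\nDropped constant columns:",
        paste(object$dropped, collapse = ", "), "\n")
  invisible(object)
}

#' Bootstrap standard errors for rate-GLM coefficients
#'
#' Pairs (rows) are resampled with replacement `n_boot` times and the model
#' refit; the per-coefficient standard deviation of the bootstrap estimates
#' is the bootstrap s.e.m. Refit failures (e.g. resamples with a constant
#' predictor) are skipped and counted; more than 10% failures flags the
#' result.
#'
#' @param d a [rate_design()].
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame `term`, `boot_sem`, with attributes `n_failed` and
#'   `flag` (`"unstable"` if >10% of refits failed, `"degenerate"` if
#'   `n_boot < 2`).
#' @export
bootstrap_coefficients <- function(d, n_boot = 1000, seed = 1) {
  stopifnot(inherits(d, "rate_design"))
  base <- fit_rate_glm(d)
  terms <- base$coefficients$term
  n <- nrow(d$design)
  with_seed(seed, {
    mat <- matrix(NA_real_, n_boot, length(terms),
                  dimnames = list(NULL, terms))
    failed <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- tryCatch(rate_design(
        d$design[idx, , drop = FALSE],
        counts = d$counts[idx], durations = d$durations[idx],
        rates = d$rates[idx]), error = function(e) NULL)
      fb <- if (is.null(db)) NULL else
        tryCatch(suppressWarnings(fit_rate_glm(db)), error = function(e) NULL)
      if (is.null(fb)) { failed <- failed + 1L; next }
      est <- setNames(fb$coefficients$beta, fb$coefficients$term)
      mat[b, intersect(terms, names(est))] <-
        est[intersect(terms, names(est))]
    }
    sem <- apply(mat, 2, sd, na.rm = TRUE)
    if (n_boot < 2) sem[] <- 0
    flag <- if (n_boot < 2) "degenerate" else
      if (failed > 0.1 * n_boot) "unstable" else NA_character_
    structure(data.frame(term = terms, boot_sem = unname(sem)),
              n_failed = failed, flag = flag)
  })
}
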