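frames_from <- function(tracks, fps = 60) {
  n <- length(tracks[[1]])
  d <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 0.5) / fps)
  for (nm in names(tracks)) d[[nm]] <- tracks[[nm]]
  d
}

test_that("the history design has the right shape and lag alignment", {
  fr <- frames_from(list(b = rep(0L, 100), target_song = rep(0L, 100)))
  d <- build_history_design(fr, "b", target = "target_song")
  expect_equal(dim(d$X), c(36, 64))
  expect_true(all(d$X == 0))

  # impulse at frame k appears on the anti-diagonal of lags
  x <- rep(0L, 100); x[30] <- 1L
  fr <- frames_from(list(b = x, target_song = rep(0L, 100)))
  d <- build_history_design(fr, "b", target = "target_song")
  # design row for frame t has lag column l = t - 30
  for (t in c(65, 80, 94)) {
    row <- d$X[t - 64, ]
    expect_equal(unname(which(row == 1)), t - 30L)
  }
  expect_error(build_history_design(fr, "nope"), "unknown")
  expect_error(build_history_design(fr[1:50, ], "b", target = "target_song",
                                    n_lags = 64), "shorter")
})

test_that("sparse logistic fits recover a planted single-lag effect", {
  set.seed(15)
  n <- 20000
  b <- rbinom(n, 1, 0.2)
  eta <- -2 + 2.5 * c(rep(0, 12), b[1:(n - 12)])
  y <- rbinom(n, 1, plogis(eta))
  fr <- frames_from(list(b = b, target_song = y))
  d <- build_history_design(fr, "b", target = "target_song")
  fit <- fit_sparse_logistic(d, seed = 1)
  w <- fit$filters$b
  expect_equal(which.max(w), 12L)
  expect_lt(median(abs(w[-12])), 0.1 * w[12])
  expect_equal(as.numeric(filter_peak_lag(fit, "b")), 200)
})

test_that("penalty limits behave as expected", {
  set.seed(16)
  n <- 3000
  b <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * b))
  fr <- frames_from(list(b = b, target_song = y))
  d <- build_history_design(fr, "b", target = "target_song", n_lags = 8)
  inf_fit <- fit_sparse_logistic(d, penalty_weight = Inf)
  expect_true(all(unlist(inf_fit$filters) == 0))
  expect_equal(inf_fit$bias, qlogis(mean(d$y)), tolerance = 1e-9)

  # penalty 0 on an orthogonal design equals the unpenalized logistic fit
  set.seed(17)
  X <- matrix(0L, 600, 3)
  slot <- sample(1:4, 600, replace = TRUE)
  for (j in 1:3) X[slot == j, j] <- 1L  # mutually exclusive -> orthogonal
  eta <- -0.5 + X %*% c(1, -1, 0.5)
  y <- rbinom(600, 1, plogis(eta))
  f0 <- fit_sparse_logistic(X, y, penalty_weight = 0)
  ref <- glm(y ~ X, family = binomial())
  expect_lt(max(abs(coef(f0)[-1] - coef(ref)[-1])), 1e-4)

  expect_error(fit_sparse_logistic(X, rep(1, 600)), "constant")
  expect_warning(fz <- fit_sparse_logistic(matrix(0L, 100, 4), rbinom(100, 1, 0.5)),
                 "all-zero")
  expect_true(all(unlist(fz$filters) == 0))
})

test_that("relative deviance reduction separates signal from no-signal", {
  set.seed(18)
  n <- 12000
  b <- rbinom(n, 1, 0.3)
  y <- c(rep(0L, 3), b[1:(n - 3)])  # deterministic lagged copy
  fr <- frames_from(list(b = b, target_song = y))
  d <- build_history_design(fr, "b", target = "target_song", n_lags = 16)
  perf <- relative_deviance_reduction(d, n_splits = 5, seed = 1)
  expect_gt(perf$relative_deviance_reduction, 0.9)

  y2 <- rbinom(n, 1, 0.3)  # independent of b
  fr2 <- frames_from(list(b = b, target_song = y2))
  d2 <- build_history_design(fr2, "b", target = "target_song", n_lags = 16)
  perf2 <- relative_deviance_reduction(d2, n_splits = 5, seed = 1)
  expect_lt(abs(perf2$relative_deviance_reduction), 0.02)

  # bias-only model evaluated against itself reduces deviance by exactly 0
  dz <- d2; dz$X <- matrix(0L, nrow(d2$X), d2$n_lags); dz$y <- d2$y
  perf0 <- suppressWarnings(
    relative_deviance_reduction(dz, penalty_weight = 1, n_splits = 3,
                                seed = 1))
  expect_equal(perf0$relative_deviance_reduction, 0, tolerance = 1e-9)
})

test_that("filter peaks convert lags to milliseconds with a flagged tie-break", {
  expect_equal(as.numeric(filter_peak_lag(c(1, numeric(63)), fps = 60)),
               1000 / 60, tolerance = 1e-9)
  w <- numeric(64); w[12] <- 2
  expect_equal(as.numeric(filter_peak_lag(w, fps = 60)), 200)
  w2 <- numeric(64); w2[c(5, 9)] <- 1
  pk <- filter_peak_lag(w2, fps = 60)
  expect_equal(as.numeric(pk), 5 * 1000 / 60)
  expect_true(attr(pk, "tie"))
  pk0 <- filter_peak_lag(numeric(64), fps = 60)
  expect_true(is.na(pk0))
  expect_equal(attr(pk0, "flag"), "all_zero")
})

test_that("block bootstrap is reproducible and its s.e.m. shrinks with data", {
  set.seed(19)
  mk <- function(n) {
    b <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, plogis(-1.5 + 2 * c(rep(0, 4), b[1:(n - 4)])))
    d <- build_history_design(
      frames_from(list(b = b, target_song = y)), "b",
      target = "target_song", n_lags = 8)
    d
  }
  d <- mk(6000)
  b1 <- bootstrap_filters(d, n_boot = 25, penalty_weight = 1e-3, seed = 4)
  b2 <- bootstrap_filters(d, n_boot = 25, penalty_weight = 1e-3, seed = 4)
  expect_identical(b1, b2)

  sems <- vapply(c(4000, 8000, 16000), function(n)
    mean(bootstrap_filters(mk(n), n_boot = 20, penalty_weight = 1e-3,
                           seed = 5)$filter_sem$b), 0)
  expect_true(all(diff(sems) < 0))

  b3 <- bootstrap_filters(d, n_boot = 2, penalty_weight = 1e-3, seed = 1)
  expect_true(b3$low_n)
})

test_that("stepwise ranking prefers informative behaviors and flags redundancy", {
  set.seed(20)
  n <- 20000
  b1 <- rbinom(n, 1, 0.3)
  noise <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-2 + 3 * c(rep(0, 5), b1[1:(n - 5)])))
  fr <- frames_from(list(good = b1, noise = noise, copy = b1,
                         target_song = y))
  st <- stepwise_two_variable(fr, c("good", "noise"), target = "target_song",
                              n_lags = 16, n_splits = 3, seed = 1)
  expect_equal(st$best, "good")
  expect_lt(abs(st$pairs$abs_gain), 0.05)

  st2 <- stepwise_two_variable(fr, c("good", "copy"), target = "target_song",
                               n_lags = 16, n_splits = 3, seed = 1)
  expect_lt(abs(st2$pairs$abs_gain), 0.02)

  # two behaviors informative at disjoint lags beat either alone
  b2 <- rbinom(n, 1, 0.3)
  y2 <- rbinom(n, 1, plogis(-2.5 + 2 * c(rep(0, 3), b1[1:(n - 3)]) +
                              2 * c(rep(0, 10), b2[1:(n - 10)])))
  fr2 <- frames_from(list(a = b1, b = b2, target_song = y2))
  st3 <- stepwise_two_variable(fr2, c("a", "b"), target = "target_song",
                               n_lags = 16, n_splits = 3, seed = 1)
  expect_gt(st3$pairs$abs_gain, 0)
})

test_that("predictions are invariant to behavior order in the design", {
  trk <- fix_tracks()$tracks
  fr <- trk$frames[1:6000, ]
  d_ab <- build_history_design(fr, c("tarsal_vibration", "proboscis_lick"),
                               target = "male_song", n_lags = 16)
  d_ba <- build_history_design(fr, c("proboscis_lick", "tarsal_vibration"),
                               target = "male_song", n_lags = 16)
  f_ab <- fit_sparse_logistic(d_ab, penalty_weight = 1e-3)
  f_ba <- fit_sparse_logistic(d_ba, penalty_weight = 1e-3)
  expect_equal(predict(f_ab, d_ab), predict(f_ba, d_ba), tolerance = 1e-4)
  expect_equal(f_ab$filters$tarsal_vibration,
               f_ba$filters$tarsal_vibration, tolerance = 1e-3)
})
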