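test_that("fit_template recovers a planted mixture and keeps an orthonormal basis", {
  set.seed(31)
  n <- 400
  # 1-D two-component mixture embedded along one direction of a 10-D space
  comp <- sample(c(-3, 3), n, replace = TRUE)
  x1 <- comp + rnorm(n, sd = 0.5)
  dir <- rep(1 / sqrt(10), 10)
  spectra <- outer(x1, dir) + matrix(rnorm(n * 10, sd = 0.05), n, 10)
  tpl <- fit_template(spectra, "M", pca_dims = 2, gmm_components = 2,
                      seed = 1)
  G <- crossprod(tpl$basis)
  expect_lt(max(abs(G - diag(2))), 1e-8)
  # component means along the first axis: +/-3 up to the axis sign
  m <- sort(tpl$axis_densities[[1]]$means)
  expect_lt(abs(m[1] - (-3)), 0.3)
  expect_lt(abs(m[2] - 3), 0.3)
  expect_lt(abs((m[2] - m[1]) - 6), 0.3)
})

test_that("degenerate inputs hit the variance floor instead of crashing", {
  spectra <- matrix(1, nrow = 40, ncol = 6)
  w <- testthat::capture_warnings(
    tpl <- fit_template(spectra, "N", pca_dims = 2,
                        gmm_components = 2, seed = 1))
  expect_gt(length(w), 0)
  expect_true(all(vapply(tpl$axis_densities,
                         function(d) all(d$vars > 0), TRUE)))
  expect_warning(fit_template(matrix(rnorm(15 * 33), 15, 33), "M",
                              gmm_components = 1, pca_dims = 20, seed = 1),
                 "reducing")
})

test_that("classify matches a direct-probability oracle and normalizes rows", {
  # hand-built 5-D templates with known per-axis mixtures
  mk <- function(label, means) {
    basis <- diag(5)[, 1:2]
    structure(list(
      label = label, mean_spectrum = rep(0, 5), basis = basis,
      axis_densities = list(
        list(weights = c(0.4, 0.6), means = means, vars = c(1, 2)),
        list(weights = 1, means = 0, vars = 1.5)),
      n_train = 100), class = "song_template")
  }
  templates <- list(M = mk("M", c(-1, 2)), F = mk("F", c(0, 1)),
                    O = mk("O", c(2, -2)), N = mk("N", c(0, 0)))
  set.seed(4)
  mags <- matrix(rnorm(20 * 5), 20, 5)
  spec <- structure(list(magnitudes = mags, freqs_hz = 1:5, rate = 1000),
                    class = "wavelet_spectrogram")
  post <- classify(spec, templates)
  expect_true(all(abs(rowSums(post$posterior) - 1) < 1e-9))

  # brute-force direct-probability oracle
  direct <- sapply(templates, function(tpl) {
    proj <- mags %*% tpl$basis
    lik <- rep(1, nrow(mags))
    for (j in 1:2) {
      d <- tpl$axis_densities[[j]]
      lik <- lik * as.numeric(
        sapply(seq_along(d$weights), function(k)
          d$weights[k] * dnorm(proj[, j], d$means[k], sqrt(d$vars[k]))) |>
          matrix(nrow = nrow(mags)) |> rowSums())
    }
    lik
  })
  oracle <- direct / rowSums(direct)
  expect_lt(max(abs(post$posterior - oracle) / pmax(oracle, 1e-12)), 1e-10)
})

test_that("a point equidistant from two symmetric templates splits its posterior", {
  mk <- function(label, mu) structure(list(
    label = label, mean_spectrum = rep(0, 2), basis = diag(2),
    axis_densities = list(list(weights = 1, means = mu, vars = 1),
                          list(weights = 1, means = 0, vars = 1)),
    n_train = 10), class = "song_template")
  templates <- list(M = mk("M", 1), F = mk("F", -1),
                    O = mk("O", 5), N = mk("N", -5))
  spec <- structure(list(magnitudes = matrix(0, 1, 2), freqs_hz = 1:2,
                         rate = 1000), class = "wavelet_spectrogram")
  post <- classify(spec, templates)$posterior
  expect_equal(unname(post[1, "M"]), unname(post[1, "F"]), tolerance = 1e-12)
})

test_that("posterior is invariant to a constant shift of all log-likelihoods", {
  ll <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("M", "F", "O", "N")))
  p1 <- virduet:::softmax_rows(ll)
  p2 <- virduet:::softmax_rows(ll + 37.5)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("noise templates train on quiet stretches and flag noise correctly", {
  p <- fix_params()
  tpl <- fix_templates()
  # pure-noise trace: nearly all time points classified N
  set.seed(8)
  noise <- audio_trace(rnorm(2500 * 12, 0, p$noise_sd), 2500)
  spec <- wavelet_transform(noise)
  tplN <- fit_noise_template(spec = spec, seed = 1)
  post <- classify(spec, within(tpl, N <- tplN))
  labels <- colnames(post$posterior)[max.col(post$posterior)]
  expect_gt(mean(labels == "N"), 0.99)

  # selected training points exclude nearly all true pulse samples
  sim <- fix_sim()
  tr <- decimate_trace(sim$audio, 4)
  spec2 <- wavelet_transform(tr)
  bb <- rowSums(spec2$magnitudes)
  sel <- bb < quantile(bb, 0.5)
  pulse_rows <- round(sim$truth$pulses$center_s * 2500)
  pulse_rows <- pulse_rows[pulse_rows >= 1 & pulse_rows <= length(sel)]
  expect_gt(mean(!sel[pulse_rows]), 0.95)

  expect_error(fit_noise_template(spec = spec, low_amplitude_quantile = 1.2),
               "quantile")
  t1 <- fit_noise_template(spec = spec, seed = 3)
  t2 <- fit_noise_template(spec = spec, seed = 3)
  expect_identical(t1$axis_densities, t2$axis_densities)
})

test_that("template archives round-trip through JSON", {
  tpl <- fix_templates()
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_templates(tpl, tmp)
  back <- read_templates(tmp)
  expect_equal(attr(back, "analysis_rate"), attr(tpl, "analysis_rate"))
  for (cls in c("M", "F", "O", "N")) {
    expect_equal(back[[cls]]$mean_spectrum, tpl[[cls]]$mean_spectrum,
                 tolerance = 1e-12)
    expect_equal(back[[cls]]$basis, unname(tpl[[cls]]$basis),
                 tolerance = 1e-12)
    expect_equal(back[[cls]]$axis_densities, tpl[[cls]]$axis_densities,
                 tolerance = 1e-12)
  }
  # classification with reloaded templates is unchanged
  noise <- audio_trace(rnorm(2500 * 2, 0, 0.02), 2500)
  spec <- wavelet_transform(noise)
  expect_equal(classify(spec, back)$posterior,
               classify(spec, tpl)$posterior, tolerance = 1e-9)
  bad <- tempfile(fileext = ".json")
  writeLines("{}", bad)
  expect_error(read_templates(bad), "archive")
  unlink(bad)
})
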