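#' Fit a song-class template from annotated wavelet spectra
#'
#' A template is one song class's statistical signature in the wavelet
#' domain: the mean wavelet spectrum of its annotated examples, an
#' orthonormal basis from a principal-components rotation of the centered
#' spectra, and a 1-D Gaussian-mixture density (fit by EM) along each
#' retained axis. Classes are male pulse (M), female pulse (F), overlapping
#' pulse (O) and noise (N).
#'
#' @param spectra matrix of wavelet spectra (rows = annotated time points,
#'   columns = analysis frequencies).
#' @param label one of `"M"`, `"F"`, `"O"`, `"N"`.
#' @param pca_dims number of principal axes to keep; reduced with a warning
#'   when the data cannot support that many.
#' @param gmm_components mixture components per axis.
#' @param seed seed for the EM fit (the fit is deterministic given it).
#' @param variance_floor floor for degenerate component variances.
#' @return An object of class `song_template`: `label`, `mean_spectrum`,
#'   `basis` (freqs x pca_dims, orthonormal), `axis_densities` (list of
#'   per-axis `weights`, `means`, `vars`), `n_train`.
#' @export
fit_template <- function(spectra, label = c("M", "F", "O", "N"),
                         pca_dims = 8, gmm_components = 3, seed = 1,
                         variance_floor = 1e-12) {
  label <- match.arg(label)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 10 * gmm_components)
    stop("need at least 10 observations per mixture component")
  max_dims <- min(nrow(spectra) - 1L, ncol(spectra))
  if (pca_dims > max_dims) {
    warning("fewer spectra than requested axes; reducing pca_dims to ",
            max_dims)
    pca_dims <- max_dims
  }
  mean_spectrum <- colMeans(spectra)
  centered <- sweep(spectra, 2, mean_spectrum)
  pc <- prcomp(centered, center = FALSE, scale. = FALSE)
  basis <- pc$rotation[, seq_len(pca_dims), drop = FALSE]
  proj <- centered %*% basis

  axis_densities <- with_seed(seed, lapply(seq_len(pca_dims), function(j) {
    fit_axis_gmm(proj[, j], gmm_components, variance_floor)
  }))
  structure(list(label = label, mean_spectrum = mean_spectrum,
                 basis = basis, axis_densities = axis_densities,
                 n_train = nrow(spectra)),
            class = "song_template")
}

# EM Gaussian mixture on one projection axis (mclust), with degenerate-case
# fallbacks: near-constant data or failed fits collapse to a single floored
# component.
fit_axis_gmm <- function(x, g, variance_floor) {
  if (stats::var(x) < variance_floor || g == 1) {
    if (stats::var(x) < variance_floor && g > 1)
      warning("axis variance below floor; fitting a single component")
    return(list(weights = 1, means = mean(x),
                vars = max(stats::var(x), variance_floor)))
  }
  fit <- tryCatch(
    mclust::densityMclust(x, G = g, modelNames = "V", verbose = FALSE,
                          plot = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) {
    warning("EM fit degenerate; fitting a single component")
    return(list(weights = 1, means = mean(x),
                vars = max(stats::var(x), variance_floor)))
  }
  p <- fit$parameters
  vars <- p$variance$sigmasq
  if (length(vars) == 1) vars <- rep(vars, length(p$mean))
  low <- vars < variance_floor
  if (any(low)) {
    warning("mixture variance floored on ", sum(low), " component(s)")
    vars[low] <- variance_floor
  }
  list(weights = as.numeric(p$pro), means = as.numeric(p$mean),
       vars = as.numeric(vars))
}

#' @method print song_template
#' @export
print.song_template <- function(x, ...) {
  cat(sprintf("Song template '%s': %d frequencies, %d axes, %d-component mixtures, %d training spectra\n",
              x$label, length(x$mean_spectrum), ncol(x$basis),
              length(x$axis_densities[[1]]$weights), x$n_train))
  invisible(x)
}

#' Fit a noise template from low-amplitude stretches of a recording
#'
#' Noise statistics differ between recordings, so the noise (N) template is
#' refit per data set from time points whose broadband wavelet magnitude
#' falls below a quantile of the recording — i.e., from stretches where
#' nobody is singing.
#'
#' @param spec a `wavelet_spectrogram` of the recording (or `NULL` to
#'   compute it from `trace`).
#' @param trace an `audio_trace` (used when `spec` is `NULL`).
#' @param low_amplitude_quantile quantile of broadband magnitude below which
#'   time points are treated as noise; in (0, 1).
#' @param max_points cap on the number of training points (subsampled
#'   evenly).
#' @param ... passed to [fit_template()] (`pca_dims`, `gmm_components`,
#'   `seed`).
#' @return A `song_template` with label `"N"`.
#' @export
fit_noise_template <- function(spec = NULL, trace = NULL,
                               low_amplitude_quantile = 0.2,
                               max_points = 4000, ...) {
  if (low_amplitude_quantile <= 0 || low_amplitude_quantile >= 1)
    stop("low_amplitude_quantile must be inside (0, 1)")
  if (is.null(spec)) {
    stopifnot(!is.null(trace))
    if (length(trace$samples) / trace$rate < 10)
      stop("need at least 10 s of audio to estimate the noise template")
    spec <- wavelet_transform(trace)
  }
  bb <- rowSums(spec$magnitudes)
  sel <- which(bb < quantile(bb, low_amplitude_quantile))
  if (length(sel) > max_points)
    sel <- sel[round(seq(1, length(sel), length.out = max_points))]
  fit_template(spec$magnitudes[sel, , drop = FALSE], label = "N", ...)
}

#' Classify each time point against the four song templates
#'
#' For each time point the wavelet spectrum is projected into each
#' template's coordinate frame; the template log-likelihood is the sum over
#' axes of the log mixture density of the projections (axes treated as
#' independent). Under a uniform prior the posterior is proportional to the
#' likelihood, computed as a softmax over log-likelihoods for numerical
#' stability.
#'
#' @param spec a `wavelet_spectrogram`.
#' @param templates named list with elements `M`, `F`, `O`, `N`, each a
#'   `song_template` sharing `spec`'s frequency grid.
#' @return An object of class `posterior_track`: `posterior` (time x 4
#'   matrix, rows sum to 1, columns M/F/O/N), `loglik` (same shape), `rate`.
#' @export
classify <- function(spec, templates) {
  stopifnot(all(c("M", "F", "O", "N") %in% names(templates)))
  mags <- spec$magnitudes
  if (anyNA(mags) || any(!is.finite(mags)))
    stop("spectrogram contains non-finite values")
  ll <- sapply(c("M", "F", "O", "N"), function(lab) {
    template_loglik(templates[[lab]], mags)
  })
  if (is.null(dim(ll)))
    ll <- matrix(ll, nrow = 1, dimnames = list(NULL, c("M", "F", "O", "N")))
  post <- softmax_rows(ll)
  structure(list(posterior = post, loglik = ll, rate = spec$rate),
            class = "posterior_track")
}

template_loglik <- function(tpl, mags) {
  if (ncol(mags) != length(tpl$mean_spectrum))
    stop("template frequency grid does not match the spectrogram")
  proj <- sweep(mags, 2, tpl$mean_spectrum) %*% tpl$basis
  out <- numeric(nrow(mags))
  for (j in seq_len(ncol(proj))) {
    d <- tpl$axis_densities[[j]]
    dens <- matrix(0, nrow(proj), length(d$weights))
    for (k in seq_along(d$weights))
      dens[, k] <- d$weights[k] * dnorm(proj[, j], d$means[k], sqrt(d$vars[k]))
    out <- out + log(pmax(rowSums(dens), 1e-300))
  }
  out
}

softmax_rows <- function(ll) {
  m <- apply(ll, 1, max)
  e <- exp(ll - m)
  e / rowSums(e)
}

#' @method print posterior_track
#' @export
print.posterior_track <- function(x, ...) {
  frac <- colMeans(x$posterior)
  cat(sprintf("Posterior track: %d time points at %g Hz\n",
              nrow(x$posterior), x$rate))
  cat(sprintf("  mean posterior  M %.3f  F %.3f  O %.3f  N %.3f\n",
              frac[1], frac[2], frac[3], frac[4]))
  invisible(x)
}

#' Train the four song templates on labeled audio
#'
#' Builds a dedicated training recording: isolated male pulses, isolated
#' female pulses, and superimposed male+female pulses (the overlap class)
#' placed on a noise floor, each at known times; fits the M, F and O
#' templates from the wavelet spectra around those times and the N template
#' from the low-amplitude remainder.
#'
#' @param params a [duet_params()] object supplying carriers, durations,
#'   amplitudes, sampling rate and noise level.
#' @param cfg a [segmenter_config()].
#' @param seed integer seed.
#' @param n_each training pulses per class.
#' @param analysis_rate rate at which training audio is analyzed, Hz.
#' @return A named list of four `song_template`s (M, F, O, N) with the
#'   attribute `analysis_rate`.
#' @export
train_templates <- function(params = duet_params(), cfg = segmenter_config(),
                            seed = 1, n_each = 60, analysis_rate = 2500) {
  p <- params
  with_seed(seed, {
    spacing <- 0.25
    n_classes <- 3L
    total <- spacing * (n_each * n_classes + 2)
    rate <- analysis_rate
    x <- rnorm(round(total * rate), 0, max(p$noise_sd, 1e-4))
    wm <- render_pulse(p$male_carrier_hz, p$male_pulse_duration_ms,
                       p$male_pulse_amplitude, rate)
    wf <- render_pulse(p$female_carrier_hz, p$female_pulse_duration_ms,
                       p$female_pulse_amplitude, rate)
    centers <- list(M = numeric(0), F = numeric(0), O = numeric(0))
    k <- 1L
    for (i in seq_len(n_each)) {
      for (cls in names(centers)) {
        ct <- k * spacing
        centers[[cls]] <- c(centers[[cls]], ct)
        w <- switch(cls, M = wm, F = wf, O = add_waves(wm, wf))
        i0 <- round(ct * rate) - length(w) %/% 2
        idx <- i0 + seq_along(w)
        x[idx] <- x[idx] + w
        k <- k + 1L
      }
    }
    trace <- audio_trace(x, rate)
    spec <- wavelet_transform(trace, n_freqs = cfg$n_freqs,
                              order = cfg$fbsp_order,
                              bandwidth = cfg$fbsp_bandwidth,
                              center = cfg$fbsp_center)
    tpl <- list()
    for (cls in names(centers)) {
      rows <- spectra_rows_at(centers[[cls]], rate, nrow(spec$magnitudes))
      tpl[[cls]] <- fit_template(spec$magnitudes[rows, , drop = FALSE],
                                 label = cls, pca_dims = cfg$pca_dims,
                                 gmm_components = cfg$gmm_components,
                                 seed = seed,
                                 variance_floor = cfg$variance_floor)
    }
    tpl$N <- fit_noise_template(spec = spec, pca_dims = cfg$pca_dims,
                                gmm_components = cfg$gmm_components,
                                seed = seed)
    attr(tpl, "analysis_rate") <- rate
    tpl
  })
}

add_waves <- function(a, b) {
  n <- max(length(a), length(b))
  pad <- function(w) {
    lead <- (n - length(w)) %/% 2
    c(numeric(lead), w, numeric(n - length(w) - lead))
  }
  pad(a) + pad(b)
}

# sample rows at event centers plus small offsets (+/- 2 ms) for training
spectra_rows_at <- function(centers_s, rate, n_rows) {
  offs <- round(c(-0.002, -0.001, 0, 0.001, 0.002) * rate)
  rows <- as.vector(outer(round(centers_s * rate), offs, `+`))
  sort(unique(rows[rows >= 1 & rows <= n_rows]))
}

#' Save and load trained templates
#'
#' Templates are serialized to a single portable JSON file: metadata plus
#' the numeric arrays (mean spectra, bases, mixture parameters) of all four
#' song classes.
#'
#' @param templates named list of `song_template`s from [train_templates()].
#' @param path output file (JSON).
#' @return `write_templates`: `path`, invisibly. `read_templates`: the
#'   template list, with its `analysis_rate` attribute restored.
#' @export
write_templates <- function(templates, path) {
  payload <- list(
    format = "virduet-templates",
    version = 1L,
    analysis_rate = attr(templates, "analysis_rate"),
    templates = lapply(templates[c("M", "F", "O", "N")], function(t)
      list(label = t$label, mean_spectrum = t$mean_spectrum,
           basis = t$basis, axis_densities = t$axis_densities,
           n_train = t$n_train)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$format, "virduet-templates"))
    stop("not a virduet template archive: ", path)
  out <- lapply(raw$templates, function(t) {
    structure(list(
      label = t$label,
      mean_spectrum = as.numeric(unlist(t$mean_spectrum)),
      # jsonlite serializes matrices as arrays of rows
      basis = matrix(unlist(t$basis), ncol = length(t$basis[[1]]),
                     byrow = TRUE),
      axis_densities = lapply(t$axis_densities, function(d)
        list(weights = as.numeric(unlist(d$weights)),
             means = as.numeric(unlist(d$means)),
             vars = as.numeric(unlist(d$vars)))),
      n_train = t$n_train), class = "song_template")
  })
  attr(out, "analysis_rate") <- raw$analysis_rate
  out
}
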