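#' Duet response times
#'
#' Latencies between one singer's reference event and the partner's
#' answering event, within a 1.5-s window:
#' \describe{
#'   \item{`female_after_male_onset`}{for each male bout onset, latency to
#'     the next female pulse (overlapping regions included).}
#'   \item{`male_onset_after_female_pulse`}{for each male bout onset, latency
#'     back to the chosen pulse (`reference_pulse`: first, second,
#'     penultimate or last) of the preceding female train whose last pulse
#'     falls within the window before the onset.}
#'   \item{`female_after_male_offset`}{latency from male bout offset to the
#'     next female pulse — the playback variant, which ignores overlaps.}
#' }
#' Bouts with no qualifying partner event contribute nothing.
#'
#' @param male_bouts data.frame with `onset_s`, `offset_s` (male bouts).
#' @param female_pulses sorted female pulse center times, s.
#' @param direction one of the three directions above.
#' @param reference_pulse reference within the preceding female train (male
#'   direction only).
#' @param window_s latency window, s.
#' @param condition free-text condition label carried on the result.
#' @return An object of class `response_time_set`: `latencies` (s),
#'   `direction`, `reference_pulse`, `window_s`, `condition`, `n_bouts`.
#' @export
response_times <- function(male_bouts, female_pulses,
                           direction = c("female_after_male_onset",
                                         "male_onset_after_female_pulse",
                                         "female_after_male_offset"),
                           reference_pulse = c("last", "first", "second",
                                               "penultimate", "any"),
                           window_s = 1.5, condition = "") {
  direction <- match.arg(direction)
  reference_pulse <- match.arg(reference_pulse)
  fp <- sort(female_pulses)
  lat <- numeric(0)
  if (direction %in% c("female_after_male_onset", "female_after_male_offset")) {
    ref <- if (direction == "female_after_male_onset") male_bouts$onset_s
           else male_bouts$offset_s
    for (r in ref) {
      nxt <- fp[fp > r]
      if (length(nxt) && nxt[1] - r <= window_s)
        lat <- c(lat, nxt[1] - r)
    }
  } else {
    trains <- assemble_bouts(fp, "F")
    for (on in male_bouts$onset_s) {
      prev <- which(trains$offset_s < on &
                      on - trains$offset_s <= window_s)
      if (!length(prev)) next
      tr <- trains$pulse_centers[[prev[length(prev)]]]
      refp <- switch(reference_pulse,
        first = tr[1],
        second = if (length(tr) >= 2) tr[2] else NA_real_,
        penultimate = if (length(tr) >= 2) tr[length(tr) - 1] else NA_real_,
        last = tr[length(tr)],
        any = tr[length(tr)])
      if (is.na(refp)) next
      l <- on - refp
      if (l > 0 && l <= window_s) lat <- c(lat, l)
    }
  }
  structure(list(latencies = lat, direction = direction,
                 reference_pulse = reference_pulse, window_s = window_s,
                 condition = condition, n_bouts = nrow(male_bouts)),
            class = "response_time_set")
}

#' @method print response_time_set
#' @export
print.response_time_set <- function(x, ...) {
  cat(sprintf("Response times (%s%s): %d latencies from %d bouts, window %g s\n",
              x$direction,
              if (x$direction == "male_onset_after_female_pulse")
                paste0(", ref=", x$reference_pulse) else "",
              length(x$latencies), x$n_bouts, x$window_s))
  if (length(x$latencies))
    cat(sprintf("  median %.0f ms, IQR %.0f-%.0f ms\n",
                1000 * median(x$latencies),
                1000 * quantile(x$latencies, 0.25),
                1000 * quantile(x$latencies, 0.75)))
  invisible(x)
}

#' Interval-shuffled null for duet coordination
#'
#' Destroys the temporal coordination between the singers while preserving
#' each singer's interval statistics: the inter-event intervals of the
#' chosen type (female inter-pulse intervals, or male inter-bout intervals)
#' are permuted uniformly at random within the recording, the first event
#' time is preserved, and event times are rebuilt by cumulative sum. The
#' other sex is untouched. For male IBIs, whole bouts (with their pulses)
#' are rigidly shifted to the shuffled onsets.
#'
#' @param events for `female_ipis`: sorted female pulse times; for
#'   `male_ibis`: a data.frame of male bouts (`onset_s`, `offset_s`, and
#'   optionally `pulse_centers`).
#' @param which what to shuffle.
#' @param seed integer seed.
#' @return Same shape as `events`, with shuffled times.
#' @export
shuffle_null <- function(events, which = c("female_ipis", "male_ibis"),
                         seed = 1) {
  which <- match.arg(which)
  with_seed(seed, {
    if (which == "female_ipis") {
      x <- sort(events)
      if (length(x) < 3) {
        warning("too few events to shuffle; returning input")
        return(events)
      }
      ivals <- diff(x)
      x[1] + c(0, cumsum(sample(ivals)))
    } else {
      b <- events
      if (nrow(b) < 3) {
        warning("too few bouts to shuffle; returning input")
        return(events)
      }
      ibis <- diff(b$onset_s)
      new_on <- b$onset_s[1] + c(0, cumsum(sample(ibis)))
      shift <- new_on - b$onset_s
      b$onset_s <- b$onset_s + shift
      b$offset_s <- b$offset_s + shift
      if (!is.null(b$pulse_centers))
        b$pulse_centers <- lapply(seq_len(nrow(b)), function(i)
          b$pulse_centers[[i]] + shift[i])
      b <- b[order(b$onset_s), , drop = FALSE]
      rownames(b) <- NULL
      b
    }
  })
}

#' Summarize a response-time distribution
#'
#' Normalized histogram with bootstrap confidence bands and a
#' kernel-density peak. The 95% band is the percentile interval of the
#' per-bin density over `n_boot` resamples (with replacement) of the
#' latencies. The peak is the argmax of a Gaussian kernel density estimate
#' (bandwidth `kde_bw_ms`), reported in ms — more bin-robust than a
#' histogram argmax.
#'
#' @param rts a `response_time_set` (or numeric latencies, s).
#' @param bin_ms histogram bin width, ms.
#' @param n_boot bootstrap resamples for the confidence band.
#' @param seed integer seed for the bootstrap.
#' @param kde_bw_ms kernel bandwidth for the peak estimate, ms.
#' @param window_s histogram support, s (taken from `rts` if available).
#' @return An object of class `distribution_summary`: `bin_edges` (s),
#'   `density` (integrates to 1), `ci_lo`, `ci_hi`, `peak_latency_ms`, `n`,
#'   `low_n` flag.
#' @export
summarize_distribution <- function(rts, bin_ms = 50, n_boot = 500, seed = 1,
                                   kde_bw_ms = 25, window_s = NULL) {
  lat <- if (inherits(rts, "response_time_set")) rts$latencies else rts
  window_s <- window_s %||%
    (if (inherits(rts, "response_time_set")) rts$window_s else 1.5)
  n <- length(lat)
  low_n <- n < 20
  if (low_n) warning("fewer than 20 latencies; summary flagged low-n")
  if (!n) stop("no latencies to summarize")
  edges <- seq(0, window_s, by = bin_ms / 1000)
  if (edges[length(edges)] < window_s) edges <- c(edges, window_s)
  dens_of <- function(x) {
    h <- graphics::hist(x, breaks = edges, plot = FALSE)
    h$counts / length(x) / diff(edges)
  }
  d <- dens_of(lat)
  boot <- with_seed(seed, replicate(n_boot, dens_of(sample(lat, n,
                                                           replace = TRUE))))
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975))
  if (length(unique(lat)) == 1) {
    peak <- lat[1] * 1000
  } else {
    kd <- density(lat, bw = kde_bw_ms / 1000, from = 0, to = window_s,
                  n = 1024)
    peak <- kd$x[which.max(kd$y)] * 1000
  }
  structure(list(bin_edges = edges, density = d,
                 ci_lo = pmin(ci[1, ], d), ci_hi = pmax(ci[2, ], d),
                 peak_latency_ms = peak, n = n, low_n = low_n),
            class = "distribution_summary")
}

#' @method print distribution_summary
#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("Response-time distribution: n = %d, peak %.0f ms%s\n",
              x$n, x$peak_latency_ms, if (x$low_n) " (low n)" else ""))
  invisible(x)
}

#' @export
plot.distribution_summary <- function(x, main = "Response times", ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  plot(mids, x$density, type = "s", xlab = "latency (s)",
       ylab = "density (1/s)", main = main, ...)
  lines(mids, x$ci_lo, lty = 3)
  lines(mids, x$ci_hi, lty = 3)
  abline(v = x$peak_latency_ms / 1000, lty = 2)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of response-time sets
#'
#' @param a,b `response_time_set`s or numeric latency vectors (non-empty).
#' @return list `statistic` (max ECDF difference), `p` (asymptotic).
#' @export
ks_compare <- function(a, b) {
  xa <- if (inherits(a, "response_time_set")) a$latencies else a
  xb <- if (inherits(b, "response_time_set")) b$latencies else b
  if (!length(xa) || !length(xb)) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(xa, xb, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' D(a||b) = sum p_a log(p_a / p_b) over the shared bin grid, after adding
#' `epsilon` to every bin mass of both distributions and renormalizing
#' (guards against empty bins). Reported in nats.
#'
#' @param a,b `distribution_summary` objects on the same bin grid, or
#'   numeric probability vectors of equal length.
#' @param epsilon additive smoothing per bin.
#' @return list `kl` (nats), `units`, `epsilon`.
#' @export
kl_divergence <- function(a, b, epsilon = 1e-6) {
  to_p <- function(z) {
    if (inherits(z, "distribution_summary"))
      z$density * diff(z$bin_edges) else z / sum(z)
  }
  if (inherits(a, "distribution_summary") &&
      inherits(b, "distribution_summary") &&
      (length(a$bin_edges) != length(b$bin_edges) ||
       any(abs(a$bin_edges - b$bin_edges) > 1e-12)))
    stop("distributions are on different bin grids")
  pa <- to_p(a); pb <- to_p(b)
  if (length(pa) != length(pb)) stop("bin grids differ in length")
  pa <- pa + epsilon; pa <- pa / sum(pa)
  pb <- pb + epsilon; pb <- pb / sum(pb)
  nz <- pa > 0
  list(kl = sum(pa[nz] * log(pa[nz] / pb[nz])), units = "nats",
       epsilon = epsilon)
}
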