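#' Label song segments from a posterior track
#'
#' Applies the rule cascade: (1) zero out all time points with
#' p(N) > `noise_posterior_cutoff`; (2) for each connected run of non-noise
#' time points, assign M when the run's mean p(M)+p(O) exceeds its mean p(F)
#' and the run lasts at least `male_min_ms`; (3) assign remaining runs of at
#' least `female_min_ms` to F; (4) inside each M segment, mark pointwise runs
#' of p(F)+p(O) > `embedded_female_cutoff` lasting at least `embedded_min_ms`
#' as embedded female pulses. Segment-level M-vs-F comparison uses the mean
#' posterior over the run (robust and deterministic); the embedded-female
#' rule is pointwise, since it describes a sub-region.
#'
#' @param post a `posterior_track` from [classify()].
#' @param cfg a [segmenter_config()].
#' @return data.frame of class `labeled_segments`: `onset_s`, `offset_s`,
#'   `label` (`"M"`/`"F"`), and a list-column `embedded_female` of data.frames
#'   (`onset_s`, `offset_s`) for M rows. Intervals are half-open, sorted,
#'   non-overlapping at top level.
#' @export
label_segments <- function(post, cfg = segmenter_config()) {
  pp <- post$posterior
  rate <- post$rate
  if (!nrow(pp)) return(empty_segments())
  non_noise <- pp[, "N"] <= cfg$noise_posterior_cutoff
  runs <- true_runs(non_noise)
  if (!nrow(runs)) return(empty_segments())

  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]; e <- runs[i, 2]
    dur_ms <- (e - s + 1) / rate * 1000
    mean_post <- colMeans(pp[s:e, , drop = FALSE])
    is_male <- (mean_post[["M"]] + mean_post[["O"]] > mean_post[["F"]]) &&
      dur_ms >= cfg$male_min_ms
    if (is_male) {
      emb <- embedded_female_runs(pp[s:e, , drop = FALSE], rate, cfg, s)
      out[[length(out) + 1L]] <- list(onset = (s - 1) / rate,
                                      offset = e / rate, label = "M",
                                      emb = emb)
    } else if (dur_ms >= cfg$female_min_ms) {
      out[[length(out) + 1L]] <- list(onset = (s - 1) / rate,
                                      offset = e / rate, label = "F",
                                      emb = NULL)
    }
  }
  if (!length(out)) return(empty_segments())
  seg <- data.frame(
    onset_s = vapply(out, `[[`, 0, "onset"),
    offset_s = vapply(out, `[[`, 0, "offset"),
    label = vapply(out, `[[`, "", "label"))
  seg$embedded_female <- lapply(out, `[[`, "emb")
  class(seg) <- c("labeled_segments", "data.frame")
  seg
}

embedded_female_runs <- function(pp, rate, cfg, offset_idx) {
  fo <- pp[, "F"] + pp[, "O"] > cfg$embedded_female_cutoff
  runs <- true_runs(fo)
  if (!nrow(runs)) return(NULL)
  dur_ms <- (runs[, 2] - runs[, 1] + 1) / rate * 1000
  runs <- runs[dur_ms >= cfg$embedded_min_ms, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  data.frame(onset_s = (offset_idx + runs[, 1] - 2) / rate,
             offset_s = (offset_idx + runs[, 2] - 1) / rate)
}

empty_segments <- function() {
  seg <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    label = character(0))
  seg$embedded_female <- list()
  class(seg) <- c("labeled_segments", "data.frame")
  seg
}

#' Extract pulse events from labeled segments
#'
#' Within each segment, pulses are local maxima of the smoothed amplitude
#' envelope (moving average of the rectified trace) that exceed an adaptive
#' threshold (`peak_threshold_k` times the segment's median envelope), kept
#' greedily by height with a minimum separation of
#' `min_peak_sep_male_ms` (M) or `min_peak_sep_female_ms` (F). Embedded
#' female sub-intervals of male segments yield F pulses by the same rule.
#'
#' @param trace the analyzed `audio_trace` (same rate as the posterior).
#' @param segments `labeled_segments` from [label_segments()].
#' @param cfg a [segmenter_config()].
#' @return data.frame `center_s`, `sex`, `peak_amplitude`, sorted by time.
#' @export
extract_pulse_events <- function(trace, segments, cfg = segmenter_config()) {
  x <- trace$samples; rate <- trace$rate
  env <- moving_average(abs(x), round(cfg$envelope_smooth_ms / 1000 * rate))
  out <- list()
  pick <- function(on, off, sep_ms, sex) {
    i0 <- max(1L, floor(on * rate) + 1L)
    i1 <- min(length(env), ceiling(off * rate))
    if (i1 - i0 < 2) return()
    seg_env <- env[i0:i1]
    thr <- cfg$peak_threshold_k * median(seg_env)
    pk <- local_maxima(seg_env)
    pk <- pk[seg_env[pk] > thr]
    if (!length(pk)) return()
    pk <- enforce_separation(pk, seg_env[pk], round(sep_ms / 1000 * rate))
    out[[length(out) + 1L]] <<- data.frame(
      center_s = (i0 + pk - 2) / rate, sex = sex,
      peak_amplitude = env[i0 + pk - 1L])
  }
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    if (seg$label == "M") {
      pick(seg$onset_s, seg$offset_s, cfg$min_peak_sep_male_ms, "M")
      emb <- segments$embedded_female[[i]]
      if (!is.null(emb) && nrow(emb))
        for (j in seq_len(nrow(emb)))
          pick(emb$onset_s[j], emb$offset_s[j],
               cfg$min_peak_sep_female_ms, "F")
    } else {
      pick(seg$onset_s, seg$offset_s, cfg$min_peak_sep_female_ms, "F")
    }
  }
  if (!length(out))
    return(data.frame(center_s = numeric(0), sex = character(0),
                      peak_amplitude = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$center_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# greedy by height: keep the tallest peak, drop neighbors within min_sep
enforce_separation <- function(idx, heights, min_sep) {
  keep <- logical(length(idx))
  alive <- rep(TRUE, length(idx))
  ord <- order(heights, decreasing = TRUE)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[abs(idx - idx[i]) < min_sep] <- FALSE
  }
  sort(idx[keep])
}

#' Score predicted events against ground truth
#'
#' Greedy one-to-one matching of predicted to true event times within
#' `match_tol_ms`: predictions are scanned in time order and matched to the
#' nearest unmatched truth event. Sensitivity = TP/(TP+FN),
#' PPV = TP/(TP+FP), and f is their harmonic mean. When a denominator is
#' zero the value is reported as 0 and flagged `degenerate`.
#'
#' @param predicted,truth numeric vectors of event times (s), or data.frames
#'   with `center_s` and `sex` (scored per sex).
#' @param match_tol_ms matching tolerance, ms (non-negative).
#' @return For vector input, a list `sensitivity`, `ppv`, `f`, `tp`, `fp`,
#'   `fn`, `degenerate`; for data.frame input, a named list of such lists per
#'   sex.
#' @export
score_segmentation <- function(predicted, truth, match_tol_ms = 10) {
  if (match_tol_ms < 0) stop("match_tol_ms must be non-negative")
  if (is.data.frame(predicted) || is.data.frame(truth)) {
    sexes <- union(unique(as.data.frame(truth)$sex),
                   unique(as.data.frame(predicted)$sex))
    out <- lapply(sexes, function(sx) {
      score_segmentation(predicted$center_s[predicted$sex == sx],
                         truth$center_s[truth$sex == sx], match_tol_ms)
    })
    names(out) <- sexes
    return(out)
  }
  predicted <- sort(predicted); truth <- sort(truth)
  tol <- match_tol_ms / 1000
  matched <- logical(length(truth))
  tp <- 0L
  for (p in predicted) {
    cand <- which(!matched & abs(truth - p) <= tol)
    if (length(cand)) {
      best <- cand[which.min(abs(truth[cand] - p))]
      matched[best] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(predicted) - tp
  fn <- length(truth) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  list(sensitivity = sens, ppv = ppv, f = f, tp = tp, fp = fp, fn = fn,
       degenerate = (tp + fn == 0) || (tp + fp == 0))
}

#' Segment a recording end to end
#'
#' Convenience wrapper: decimate to the analysis rate, wavelet-transform,
#' classify against the templates, label segments, and extract pulse events.
#'
#' @param trace an `audio_trace`.
#' @param templates templates from [train_templates()] (or a compatible named
#'   list); their `analysis_rate` attribute sets the default analysis rate.
#' @param cfg a [segmenter_config()].
#' @param analysis_rate rate at which the trace is analyzed, Hz; the trace is
#'   decimated by an integer factor to reach (approximately) this rate.
#' @param refit_noise refit the noise template from this recording's
#'   low-amplitude stretches (the published procedure); set `FALSE` to reuse
#'   the trained one.
#' @return A list of class `segmentation`: `pulses` (data.frame `center_s`,
#'   `sex`, `peak_amplitude`), `segments`, `posterior`, `analysis_rate`.
#' @export
segment_audio <- function(trace, templates, cfg = segmenter_config(),
                          analysis_rate = NULL, refit_noise = TRUE) {
  analysis_rate <- analysis_rate %||% attr(templates, "analysis_rate") %||%
    trace$rate
  factor <- max(1L, round(trace$rate / analysis_rate))
  tr <- decimate_trace(trace, factor)
  spec <- wavelet_transform(tr, n_freqs = cfg$n_freqs,
                            order = cfg$fbsp_order,
                            bandwidth = cfg$fbsp_bandwidth,
                            center = cfg$fbsp_center)
  tpl <- templates
  if (refit_noise) {
    tpl$N <- tryCatch(
      fit_noise_template(spec = spec, pca_dims = cfg$pca_dims,
                         gmm_components = cfg$gmm_components, seed = 1),
      error = function(e) templates$N)
  }
  post <- classify(spec, tpl)
  segs <- label_segments(post, cfg)
  pulses <- extract_pulse_events(tr, segs, cfg)
  structure(list(pulses = pulses, segments = segs, posterior = post,
                 analysis_rate = tr$rate),
            class = "segmentation")
}

#' @method print segmentation
#' @export
print.segmentation <- function(x, ...) {
  tab <- table(factor(x$pulses$sex, c("M", "F")))
  cat(sprintf("Segmentation: %d segments, %d male and %d female pulses (analyzed at %g Hz)\n",
              nrow(x$segments), tab[["M"]], tab[["F"]], x$analysis_rate))
  invisible(x)
}
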