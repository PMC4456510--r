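#' Render a single song pulse
#'
#' A pulse is modeled as a sinusoid under a Gaussian envelope (a Gabor
#' atom): the waveform family is unconstrained by published recordings, which
#' characterize pulses only through their power spectra, so the simplest
#' band-limited transient with a controllable spectral peak is used.
#'
#' @param carrier_hz carrier frequency, Hz; must be below Nyquist.
#' @param duration_ms pulse duration, ms (the envelope sd is duration/6).
#' @param amplitude peak amplitude.
#' @param sample_rate sampling rate, Hz.
#' @return Numeric waveform of length `round(duration_ms * sample_rate / 1000)`.
#' @export
#' @examples
#' w <- render_pulse(400, 20, 1, 10000)
#' length(w)  # 200 samples
render_pulse <- function(carrier_hz, duration_ms, amplitude, sample_rate) {
  stopifnot(carrier_hz > 0, duration_ms > 0, sample_rate > 0)
  if (carrier_hz >= sample_rate / 2)
    stop("carrier_hz must be below the Nyquist frequency (sample_rate/2)")
  n <- round(duration_ms * sample_rate / 1000)
  t <- (seq_len(n) - (n + 1) / 2) / sample_rate
  env <- exp(-t^2 / (2 * (duration_ms / 6000)^2))
  amplitude * env * sin(2 * pi * carrier_hz * t)
}

#' Simulate a courtship duet recording
#'
#' Generates a two-singer recording as a sequence of exchanges: a male bout
#' of short-IPI pulses, then a female train whose first pulse follows the
#' male bout onset at a log-normal latency (mode `female_latency_mode`), then
#' the next male bout at a log-normal latency after the last female pulse
#' (mode `male_latency_mode`). Exchanges are occasionally separated by longer
#' exponential silent gaps. With probability `overlap_probability` per
#' exchange one female pulse is placed inside the male bout. Ground truth
#' records every pulse and bout exactly; the audio is the sum of the placed
#' Gabor pulses plus Gaussian background noise.
#'
#' @param params a [duet_params()] object.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param audio if `FALSE`, skip waveform synthesis (events only); the
#'   `audio` element is then `NULL`.
#' @return A list of class `duet_simulation` with elements
#'   \describe{
#'     \item{audio}{list(samples, rate) — the `AudioTrace`, or `NULL`.}
#'     \item{truth}{list of class `ground_truth`: `pulses` (data.frame
#'       `center_s`, `sex`), `bouts` (data.frame `onset_s`, `offset_s`,
#'       `sex`; onsets/offsets are first/last pulse centers), and
#'       `copulation_time` (NA unless set downstream).}
#'     \item{params, seed}{inputs, recorded for reproducibility.}
#'   }
#' @export
#' @examples
#' sim <- simulate_duet(duet_params(duration = 20), seed = 1)
#' head(sim$truth$pulses)
simulate_duet <- function(params = duet_params(), seed = 1, audio = TRUE) {
  stopifnot(inherits(params, "duet_params"))
  p <- params
  with_seed(seed, {
    t_now <- 0.5  # settle-in silence before the first bout
    m_pulses <- list(); f_pulses <- list()
    m_bouts <- list(); f_bouts <- list()
    repeat {
      # --- male bout ---
      n_m <- max(4L, as.integer(round(rnorm(1, p$male_pulses_per_bout_mean,
                                            p$male_pulses_per_bout_sd))))
      ipi_m <- rnorm_trunc(n_m - 1L, p$male_ipi_mean, p$male_ipi_sd,
                           lower = 1, upper = 25) / 1000
      mp <- t_now + c(0, cumsum(ipi_m))
      if (max(mp) + 0.5 > p$duration) break
      bout_on <- mp[1]; bout_off <- mp[n_m]
      m_pulses[[length(m_pulses) + 1L]] <- mp
      m_bouts[[length(m_bouts) + 1L]] <- c(bout_on, bout_off)

      # --- optional overlapping female pulse inside the male bout ---
      if (n_m >= 2 && runif(1) < p$overlap_probability) {
        fo <- runif(1, bout_on + 0.2 * (bout_off - bout_on),
                    bout_on + 0.8 * (bout_off - bout_on))
        f_pulses[[length(f_pulses) + 1L]] <- fo
        f_bouts[[length(f_bouts) + 1L]] <- c(fo, fo)
      }

      # --- female train ---
      lat_f <- rlnorm_mode(1, p$female_latency_mode, p$female_latency_spread) / 1000
      n_f <- max(1L, rnbinom_mu(1, p$female_pulses_per_bout_mean,
                                p$female_pulses_per_bout_sd))
      ipi_f <- rnorm_trunc(n_f - 1L, p$female_ipi_mean, p$female_ipi_sd,
                           lower = 5, upper = 100) / 1000
      fp <- bout_on + lat_f + c(0, cumsum(ipi_f))
      fp <- fp[fp + 0.3 <= p$duration]
      if (!length(fp)) break
      f_pulses[[length(f_pulses) + 1L]] <- fp
      f_bouts[[length(f_bouts) + 1L]] <- c(fp[1], fp[length(fp)])

      # --- next male bout onset ---
      lat_m <- rlnorm_mode(1, p$male_latency_mode, p$male_latency_spread) / 1000
      t_now <- fp[length(fp)] + lat_m
      if (runif(1) < p$inter_exchange_gap_prob)
        t_now <- t_now + rexp(1, 1 / p$inter_exchange_gap_mean)
    }

    if (!length(m_pulses)) {
      warning("duration too short for a single exchange; empty ground truth")
      truth <- empty_ground_truth()
    } else {
      pm <- unlist(m_pulses); pf <- unlist(f_pulses)
      pulses <- rbind(
        data.frame(center_s = pm, sex = "M", stringsAsFactors = FALSE),
        if (length(pf)) data.frame(center_s = pf, sex = "F",
                                   stringsAsFactors = FALSE)
      )
      pulses <- pulses[order(pulses$center_s), , drop = FALSE]
      rownames(pulses) <- NULL
      bouts <- rbind(
        do.call(rbind, lapply(m_bouts, function(b)
          data.frame(onset_s = b[1], offset_s = b[2], sex = "M"))),
        if (length(f_bouts)) do.call(rbind, lapply(f_bouts, function(b)
          data.frame(onset_s = b[1], offset_s = b[2], sex = "F")))
      )
      bouts <- bouts[order(bouts$onset_s), , drop = FALSE]
      rownames(bouts) <- NULL
      truth <- structure(list(pulses = pulses, bouts = bouts,
                              copulation_time = NA_real_),
                         class = "ground_truth")
    }

    trace <- NULL
    if (audio) {
      n <- round(p$duration * p$sample_rate)
      x <- if (p$noise_sd > 0) rnorm(n, 0, p$noise_sd) else numeric(n)
      place <- function(centers, carrier, dur, amp) {
        if (!length(centers)) return()
        w <- render_pulse(carrier, dur, amp, p$sample_rate)
        half <- length(w) %/% 2
        for (ct in centers) {
          i0 <- round(ct * p$sample_rate) - half
          idx <- i0 + seq_along(w)
          keep <- idx >= 1 & idx <= n
          x[idx[keep]] <<- x[idx[keep]] + w[keep]
        }
      }
      with(truth, {
        place(pulses$center_s[pulses$sex == "M"], p$male_carrier_hz,
              p$male_pulse_duration_ms, p$male_pulse_amplitude)
        place(pulses$center_s[pulses$sex == "F"], p$female_carrier_hz,
              p$female_pulse_duration_ms, p$female_pulse_amplitude)
      })
      trace <- audio_trace(x, p$sample_rate)
    }

    structure(list(audio = trace, truth = truth, params = p, seed = seed),
              class = "duet_simulation")
  })
}

# Negative binomial with target mean/sd; falls back to Poisson when the
# requested variance is at or below the mean.
rnbinom_mu <- function(n, mean, sd) {
  v <- sd^2
  if (v <= mean) return(stats::rpois(n, mean))
  size <- mean^2 / (v - mean)
  rnbinom(n, size = size, mu = mean)
}

empty_ground_truth <- function() {
  structure(list(
    pulses = data.frame(center_s = numeric(0), sex = character(0)),
    bouts = data.frame(onset_s = numeric(0), offset_s = numeric(0),
                       sex = character(0)),
    copulation_time = NA_real_), class = "ground_truth")
}

#' Construct an audio trace
#'
#' @param samples numeric amplitude vector (finite).
#' @param rate sampling rate, Hz.
#' @return A list of class `audio_trace` with elements `samples` and `rate`.
#' @export
audio_trace <- function(samples, rate) {
  stopifnot(rate > 0, is.numeric(samples))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("audio samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_trace")
}

#' @method print duet_simulation
#' @export
print.duet_simulation <- function(x, ...) {
  np <- table(factor(x$truth$pulses$sex, c("M", "F")))
  cat(sprintf("Simulated duet: %g s, seed %s\n", x$params$duration, x$seed))
  cat(sprintf("  %d male pulses, %d female pulses, %d bouts\n",
              np[["M"]], np[["F"]], nrow(x$truth$bouts)))
  cat(if (is.null(x$audio)) "  events only (no audio rendered)\n" else
    sprintf("  audio: %d samples at %g Hz\n",
            length(x$audio$samples), x$audio$rate))
  invisible(x)
}

#' Simulate behavior annotation tracks coupled to song
#'
#' Emulates manual 60 fps annotation of three male contact behaviors. Both
#' tarsal vibration and proboscis licking get one episode locked to each
#' female pulse train (shifted by `lick_female_lag_ms`) — male contact with
#' the female abdomen coincides with her song — plus one episode mirroring
#' each upcoming male bout, shifted earlier by `tarsal_lead_ms` /
#' `lick_lead_ms`, so each behavior leads the male song it predicts by
#' exactly the configured lead (at zero jitter, bout onset minus episode
#' onset equals the lead). Tarsal-pause episodes fill gaps between
#' successive vibration episodes.
#'
#' @param truth a `ground_truth` object from [simulate_duet()].
#' @param coupling a [coupling_params()] object.
#' @param fps frame rate for the rasterized tracks (Hz).
#' @param seed integer seed for the timing jitter.
#' @param duration recording length, s; defaults to just past the last event.
#' @return A list of class `behavior_tracks`:
#'   \describe{
#'     \item{intervals}{data.frame `onset_s`, `offset_s`, `behavior`.}
#'     \item{frames}{data.frame with columns `frame`, `time_s`,
#'       `tarsal_vibration`, `tarsal_pause`, `proboscis_lick`,
#'       `male_song`, `female_song` (0/1; sampled at frame centers).}
#'     \item{fps}{frame rate.}
#'   }
#' @export
simulate_behavior_tracks <- function(truth, coupling = coupling_params(),
                                     fps = 60, seed = 1, duration = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (fps <= 0) stop("fps must be positive")
  cp <- coupling
  mb <- truth$bouts[truth$bouts$sex == "M", , drop = FALSE]
  fb <- truth$bouts[truth$bouts$sex == "F", , drop = FALSE]
  # overlap-pulse "trains" are single points inside male bouts; they are song,
  # not separate contact episodes
  fb <- fb[fb$offset_s > fb$onset_s | !in_any_interval(
    fb$onset_s, mb$onset_s, mb$offset_s), , drop = FALSE]
  duration <- duration %||%
    (max(c(truth$bouts$offset_s, 1)) + 1)

  with_seed(seed, {
    jit <- function(n) rnorm(n, 0, cp$jitter_sd_ms) / 1000
    ivals <- list()
    add <- function(on, off, what) {
      if (!length(on)) return()
      keep <- off > 0 & on < duration
      on <- pmax(0, on[keep]); off <- pmin(duration, off[keep])
      ivals[[length(ivals) + 1L]] <<-
        data.frame(onset_s = on, offset_s = off, behavior = what)
    }
    if (nrow(mb)) {
      # episodes mirror the upcoming bout: duration-matched, led by the lead
      n <- nrow(mb)
      j <- jit(n)
      add(mb$onset_s - cp$tarsal_lead_ms / 1000 + j,
          mb$offset_s - cp$tarsal_lead_ms / 1000 + j, "tarsal_vibration")
      j <- jit(n)
      add(mb$onset_s - cp$lick_lead_ms / 1000 + j,
          mb$offset_s - cp$lick_lead_ms / 1000 + j, "proboscis_lick")
    }
    if (nrow(fb)) {
      lag <- cp$lick_female_lag_ms / 1000
      pad <- 1 / fps  # annotation granularity around the train
      for (beh in c("tarsal_vibration", "proboscis_lick")) {
        keep <- runif(nrow(fb)) < cp$train_lock_prob
        if (!any(keep)) next
        j <- jit(sum(keep))
        add(fb$onset_s[keep] - lag - pad + j,
            fb$offset_s[keep] - lag + pad + j, beh)
      }
    }
    intervals <- if (length(ivals)) do.call(rbind, ivals) else
      data.frame(onset_s = numeric(0), offset_s = numeric(0),
                 behavior = character(0))
    intervals <- merge_behavior_intervals(intervals)

    # pauses fill between successive vibration episodes
    vib <- intervals[intervals$behavior == "tarsal_vibration", , drop = FALSE]
    if (nrow(vib) > 1) {
      gaps_on <- vib$offset_s[-nrow(vib)]
      gaps_off <- vib$onset_s[-1]
      ok <- gaps_off > gaps_on
      intervals <- rbind(intervals, data.frame(
        onset_s = gaps_on[ok], offset_s = gaps_off[ok],
        behavior = "tarsal_pause"))
    }
    intervals <- intervals[order(intervals$onset_s), , drop = FALSE]
    rownames(intervals) <- NULL

    frames <- rasterize_tracks(intervals, truth, fps, duration)
    structure(list(intervals = intervals, frames = frames, fps = fps),
              class = "behavior_tracks")
  })
}

# union of overlapping intervals within each behavior label
merge_behavior_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  out <- lapply(split(iv, iv$behavior), function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    on <- d$onset_s; off <- d$offset_s
    keep_on <- on[1]; keep_off <- off[1]
    for (i in seq_len(nrow(d))[-1]) {
      k <- length(keep_on)
      if (on[i] <= keep_off[k]) keep_off[k] <- max(keep_off[k], off[i])
      else { keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i]) }
    }
    data.frame(onset_s = keep_on, offset_s = keep_off,
               behavior = d$behavior[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rasterize event intervals into framewise binary tracks
#'
#' Samples the half-open interval indicator of each behavior, and of male and
#' female song (bout intervals padded by half a pulse width), at frame
#' centers.
#'
#' @param intervals data.frame `onset_s`, `offset_s`, `behavior`.
#' @param truth `ground_truth` (for the song tracks); may be `NULL`.
#' @param fps frame rate, Hz.
#' @param duration length of the rasterized window, s.
#' @return data.frame of frames (see [simulate_behavior_tracks()]).
#' @export
rasterize_tracks <- function(intervals, truth = NULL, fps = 60,
                             duration = NULL) {
  if (fps <= 0) stop("fps must be positive")
  duration <- duration %||% max(c(intervals$offset_s, 1))
  n <- max(1L, floor(duration * fps))
  tt <- (seq_len(n) - 0.5) / fps
  beh <- c("tarsal_vibration", "tarsal_pause", "proboscis_lick")
  out <- data.frame(frame = seq_len(n), time_s = tt)
  for (b in beh) {
    d <- intervals[intervals$behavior == b, , drop = FALSE]
    out[[b]] <- as.integer(in_any_interval(tt, d$onset_s, d$offset_s))
  }
  if (!is.null(truth)) {
    # song presence = the bout interval (first to last pulse center); a frame
    # is song when its center falls inside a bout of that sex
    mb <- truth$bouts[truth$bouts$sex == "M", , drop = FALSE]
    fbb <- truth$bouts[truth$bouts$sex == "F", , drop = FALSE]
    out$male_song <- as.integer(
      in_any_interval(tt, mb$onset_s, mb$offset_s))
    out$female_song <- as.integer(
      in_any_interval(tt, fbb$onset_s, fbb$offset_s))
  }
  out
}

#' Construct a playback stimulus from one song bout
#'
#' Mirrors the playback protocol used for acoustically isolated pairs: the
#' bout waveform is smoothed with a 300 Hz Butterworth low-pass filter, a
#' stimulus group repeats it 6 times at 1.2-s onset intervals, and groups are
#' delivered every 30 s for 10 min (600 s), giving 120 bout onsets.
#'
#' @param bout_waveform numeric waveform of one bout (shorter than 1.2 s).
#' @param sample_rate sampling rate, Hz.
#' @param total_s,group_interval_s,bout_interval_s,bouts_per_group protocol
#'   constants; defaults are the published stimulus.
#' @param lowpass_hz Butterworth low-pass corner, Hz.
#' @return An `audio_trace` of length `total_s * sample_rate`.
#' @export
simulate_playback_stimulus <- function(bout_waveform, sample_rate,
                                       total_s = 600, group_interval_s = 30,
                                       bout_interval_s = 1.2,
                                       bouts_per_group = 6,
                                       lowpass_hz = 300) {
  if (!length(bout_waveform)) stop("bout waveform is empty")
  if (length(bout_waveform) / sample_rate > bout_interval_s)
    stop("bout longer than the within-group interval; stimuli would overlap")
  bf <- signal::butter(4, lowpass_hz / (sample_rate / 2), type = "low")
  smooth <- as.numeric(signal::filtfilt(bf, bout_waveform))
  n <- round(total_s * sample_rate)
  x <- numeric(n)
  group_onsets <- seq(0, total_s - 1e-9, by = group_interval_s)
  for (g in group_onsets) {
    for (b in seq_len(bouts_per_group) - 1L) {
      i0 <- round((g + b * bout_interval_s) * sample_rate)
      idx <- i0 + seq_along(smooth)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + smooth[keep]
    }
  }
  audio_trace(x, sample_rate)
}
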