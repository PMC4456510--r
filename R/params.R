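#' Parameters of the duet simulator
#'
#' Builds the parameter set consumed by [simulate_duet()]. Defaults follow the
#' wild-type song statistics of *D. virilis*: stereotyped male bouts of
#' 6.9 +/- 1.2 pulses at a 21.2 +/- 1.9 ms inter-pulse interval (IPI), more
#' variable female trains (7.2 +/- 6.2 pulses, IPI 55.2 +/- 26.3 ms), a female
#' response latency peaked at 409 ms after male bout onset, and a male
#' response latency peaked at 110 ms after the last female pulse. Carrier
#' frequencies have no published values; the 400/250 Hz defaults are chosen to
#' be well separated inside the segmenter's 100-900 Hz analysis band.
#'
#' Latencies are drawn from log-normal distributions parameterized by their
#' mode and log-scale spread, matching the unimodal right-skewed shape of
#' observed response-time distributions. Within-bout IPI draws are truncated
#' at the bout-definition thresholds (25 ms male, 100 ms female) so that
#' generated bouts are bouts under the same rules used to analyze them.
#'
#' @param sample_rate audio sampling rate, Hz.
#' @param duration recording length, s.
#' @param male_ipi_mean,male_ipi_sd male within-bout IPI distribution, ms.
#' @param male_pulses_per_bout_mean,male_pulses_per_bout_sd male pulse count
#'   per bout (Gaussian, rounded, floored at 4).
#' @param female_ipi_mean,female_ipi_sd female within-train IPI, ms.
#' @param female_pulses_per_bout_mean,female_pulses_per_bout_sd female pulse
#'   count per train (overdispersed negative binomial, floored at 1).
#' @param male_carrier_hz,female_carrier_hz pulse carrier frequencies, Hz;
#'   must lie within the 100-900 Hz analysis band.
#' @param male_pulse_duration_ms,female_pulse_duration_ms Gabor pulse
#'   durations, ms.
#' @param male_pulse_amplitude,female_pulse_amplitude pulse peak amplitudes.
#' @param female_latency_mode,female_latency_spread mode (ms) and log-sd of
#'   the female latency: first female pulse after male bout onset.
#' @param male_latency_mode,male_latency_spread mode (ms) and log-sd of the
#'   male latency: next male bout onset after the last female pulse.
#' @param inter_exchange_gap_mean mean of the exponential silent gap
#'   occasionally inserted between exchanges, s.
#' @param inter_exchange_gap_prob probability that an exchange is followed by
#'   such a gap (courtship contains long stretches of silence).
#' @param noise_sd standard deviation of additive Gaussian background noise.
#' @param overlap_probability per-exchange probability that one female pulse
#'   is placed inside the male bout (song overlap).
#'
#' @return An object of class `duet_params` (a validated list).
#' @seealso [simulate_duet()], [coupling_params()]
#' @export
#' @examples
#' p <- duet_params(duration = 30)
#' p$male_ipi_mean
duet_params <- function(sample_rate = 10000,
                        duration = 120,
                        male_ipi_mean = 21.2, male_ipi_sd = 1.9,
                        male_pulses_per_bout_mean = 6.9,
                        male_pulses_per_bout_sd = 1.2,
                        female_ipi_mean = 55.2, female_ipi_sd = 26.3,
                        female_pulses_per_bout_mean = 7.2,
                        female_pulses_per_bout_sd = 6.2,
                        male_carrier_hz = 400, female_carrier_hz = 250,
                        male_pulse_duration_ms = 12,
                        female_pulse_duration_ms = 20,
                        male_pulse_amplitude = 1,
                        female_pulse_amplitude = 0.8,
                        female_latency_mode = 409,
                        female_latency_spread = 0.25,
                        male_latency_mode = 110,
                        male_latency_spread = 0.3,
                        inter_exchange_gap_mean = 4,
                        inter_exchange_gap_prob = 0.1,
                        noise_sd = 0.02,
                        overlap_probability = 0.02) {
  p <- as.list(environment())
  stopifnot(
    p$sample_rate > 0, p$duration > 0,
    p$male_ipi_mean > 0, p$male_ipi_sd >= 0,
    p$female_ipi_mean > 0, p$female_ipi_sd >= 0,
    p$male_pulses_per_bout_mean > 0, p$female_pulses_per_bout_mean > 0,
    p$male_pulse_duration_ms > 0, p$female_pulse_duration_ms > 0,
    p$female_latency_mode > 0, p$male_latency_mode > 0,
    p$female_latency_spread > 0, p$male_latency_spread > 0,
    p$inter_exchange_gap_mean > 0,
    p$inter_exchange_gap_prob >= 0, p$inter_exchange_gap_prob <= 1,
    p$noise_sd >= 0,
    p$overlap_probability >= 0, p$overlap_probability <= 1
  )
  for (carrier in c(p$male_carrier_hz, p$female_carrier_hz)) {
    if (carrier < 100 || carrier > 900)
      stop("carrier frequencies must lie within the 100-900 Hz analysis band")
    if (carrier >= p$sample_rate / 2)
      stop("carrier frequency at or above Nyquist (sample_rate/2)")
  }
  if (p$female_ipi_mean <= p$male_ipi_mean)
    warning("female IPI mean not larger than male IPI mean; ",
            "sexes may be hard to separate by rhythm")
  structure(p, class = "duet_params")
}

#' @method print duet_params
#' @export
print.duet_params <- function(x, ...) {
  cat("Duet simulator parameters\n")
  cat(sprintf("  duration %g s at %g Hz\n", x$duration, x$sample_rate))
  cat(sprintf("  male:   IPI %g +/- %g ms, %g +/- %g pulses/bout, %g Hz carrier\n",
              x$male_ipi_mean, x$male_ipi_sd, x$male_pulses_per_bout_mean,
              x$male_pulses_per_bout_sd, x$male_carrier_hz))
  cat(sprintf("  female: IPI %g +/- %g ms, %g +/- %g pulses/train, %g Hz carrier\n",
              x$female_ipi_mean, x$female_ipi_sd, x$female_pulses_per_bout_mean,
              x$female_pulses_per_bout_sd, x$female_carrier_hz))
  cat(sprintf("  latency modes: female %g ms after male bout onset, male %g ms after last female pulse\n",
              x$female_latency_mode, x$male_latency_mode))
  cat(sprintf("  noise sd %g, overlap probability %g\n",
              x$noise_sd, x$overlap_probability))
  invisible(x)
}

#' Coupling between behavior annotations and song
#'
#' Parameters for [simulate_behavior_tracks()], which emulates frame-level
#' annotations of three male contact behaviors (tarsal vibration, tarsal
#' pause, proboscis licking) whose timing is coupled to song. The male's
#' courtship forms a behavioral sequence: he vibrates his tarsi on the
#' female abdomen and licks her while she sings, then produces his own bout.
#' Accordingly, each behavior gets (a) one episode locked to each female
#' pulse train (shifted by `lick_female_lag_ms`, near zero: contact
#' coincides with female song) and (b) one episode mirroring each upcoming
#' male bout — the bout interval shifted earlier by `tarsal_lead_ms` /
#' `lick_lead_ms`, so the episode leads the male song it predicts by exactly
#' the configured lead. Tarsal-pause episodes fill the gaps between
#' vibration episodes.
#'
#' @param tarsal_lead_ms lead of the bout-mirroring tarsal-vibration episode
#'   before the male bout, ms (episode onset = bout onset - lead).
#' @param lick_lead_ms same for proboscis licking, ms.
#' @param lick_female_lag_ms lag of train-locked behavior episodes relative
#'   to female song, ms (0 = coincident).
#' @param train_lock_prob probability that a female train is accompanied by
#'   contact episodes.
#' @param jitter_sd_ms Gaussian timing jitter applied to episode anchors, ms.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(tarsal_lead_ms = 200,
                            lick_lead_ms = 50,
                            lick_female_lag_ms = 0,
                            train_lock_prob = 1,
                            jitter_sd_ms = 8) {
  p <- as.list(environment())
  stopifnot(p$tarsal_lead_ms >= 0, p$lick_lead_ms >= 0,
            p$train_lock_prob >= 0, p$train_lock_prob <= 1,
            p$jitter_sd_ms >= 0)
  structure(p, class = "coupling_params")
}

#' Segmenter configuration
#'
#' Thresholds and model sizes for the wavelet-template segmenter. The rule
#' cascade's published constants are the defaults: time points with noise
#' posterior above 1/2 are zeroed; a connected non-noise segment is male if
#' its mean p(M)+p(O) exceeds its mean p(F) and it is at least 100 ms long;
#' remaining segments at least 15 ms long are female; within male segments a
#' pointwise run of p(F)+p(O) > 0.8 lasting at least 15 ms marks an embedded
#' female pulse.
#'
#' @param noise_posterior_cutoff posterior p(N) above which a time point is
#'   treated as noise.
#' @param male_min_ms minimum male segment duration, ms.
#' @param female_min_ms minimum female segment duration, ms.
#' @param embedded_female_cutoff pointwise p(F)+p(O) cutoff for embedded
#'   female pulses inside a male segment.
#' @param embedded_min_ms minimum embedded-female run length, ms.
#' @param n_freqs number of wavelet analysis frequencies (log-spaced over
#'   100-900 Hz).
#' @param pca_dims number of principal axes kept per template.
#' @param gmm_components Gaussian-mixture components per template axis.
#' @param fbsp_order,fbsp_bandwidth,fbsp_center frequency B-spline mother
#'   wavelet parameters (order m, bandwidth fb, center frequency fc).
#' @param min_peak_sep_male_ms,min_peak_sep_female_ms minimum pulse-peak
#'   separation during pulse extraction, ms.
#' @param envelope_smooth_ms moving-average width for the amplitude
#'   envelope, ms.
#' @param peak_threshold_k adaptive pulse threshold as a multiple of the
#'   segment's median envelope.
#' @param variance_floor floor applied to degenerate mixture variances.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(noise_posterior_cutoff = 0.5,
                             male_min_ms = 100,
                             female_min_ms = 15,
                             embedded_female_cutoff = 0.8,
                             embedded_min_ms = 15,
                             n_freqs = 33,
                             pca_dims = 8,
                             gmm_components = 3,
                             fbsp_order = 2,
                             fbsp_bandwidth = 0.3,
                             fbsp_center = 1,
                             min_peak_sep_male_ms = 10,
                             min_peak_sep_female_ms = 15,
                             envelope_smooth_ms = 2,
                             peak_threshold_k = 2,
                             variance_floor = 1e-12) {
  p <- as.list(environment())
  stopifnot(
    p$noise_posterior_cutoff > 0, p$noise_posterior_cutoff < 1,
    p$embedded_female_cutoff > 0, p$embedded_female_cutoff < 1,
    p$male_min_ms > 0, p$female_min_ms > 0, p$embedded_min_ms > 0,
    p$n_freqs >= 8, p$pca_dims >= 1, p$gmm_components >= 1,
    p$fbsp_order >= 1, p$fbsp_bandwidth > 0, p$fbsp_center > 0,
    p$variance_floor > 0
  )
  structure(p, class = "segmenter_config")
}
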