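#' Assemble pulses into bouts
#'
#' Male bouts are maximal runs of pulses with successive IPIs under 25 ms;
#' runs with fewer than four pulses are discarded. Female bouts (trains) are
#' maximal runs with IPIs under 100 ms, with no minimum count. Bout onset and
#' offset are the first and last pulse centers.
#'
#' @param pulses numeric vector of pulse center times (s) of one sex, sorted.
#' @param sex `"M"` or `"F"`.
#' @param male_ipi_max_ms,female_ipi_max_ms,male_min_pulses rule constants.
#' @return data.frame `onset_s`, `offset_s`, `n_pulses`, `sex`, with a
#'   list-column `pulse_centers`.
#' @export
#' @examples
#' assemble_bouts(c(0, 21, 42, 63, 84) / 1000, "M")  # one 5-pulse bout
assemble_bouts <- function(pulses, sex = c("M", "F"),
                           male_ipi_max_ms = 25, female_ipi_max_ms = 100,
                           male_min_pulses = 4) {
  sex <- match.arg(sex)
  if (is.unsorted(pulses)) stop("pulse times must be sorted")
  if (!length(pulses)) return(empty_bouts(sex))
  thr <- (if (sex == "M") male_ipi_max_ms else female_ipi_max_ms) / 1000
  brk <- c(0, cumsum(diff(pulses) >= thr))
  groups <- split(pulses, brk)
  if (sex == "M")
    groups <- groups[vapply(groups, length, 0L) >= male_min_pulses]
  if (!length(groups)) return(empty_bouts(sex))
  out <- data.frame(
    onset_s = vapply(groups, function(g) g[1], 0),
    offset_s = vapply(groups, function(g) g[length(g)], 0),
    n_pulses = vapply(groups, length, 0L),
    sex = sex)
  out$pulse_centers <- unname(groups)
  rownames(out) <- NULL
  out
}

empty_bouts <- function(sex) {
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    n_pulses = integer(0), sex = character(0))
  out$pulse_centers <- list()
  out
}

#' Median inter-pulse interval of one sex
#'
#' Successive pulse-time differences below the sex-specific threshold
#' (100 ms for males, 500 ms for females) are collected and their median
#' returned, matching the per-individual IPI reporting convention.
#'
#' @param pulses sorted pulse center times of one sex, s.
#' @param sex `"M"` or `"F"`.
#' @param male_thresh_ms,female_thresh_ms interval inclusion thresholds.
#' @return Median IPI in ms, or `NA` (with attribute `flag = "no_intervals"`)
#'   when no interval qualifies.
#' @export
median_ipi <- function(pulses, sex = c("M", "F"),
                       male_thresh_ms = 100, female_thresh_ms = 500) {
  sex <- match.arg(sex)
  if (length(pulses) < 2)
    return(structure(NA_real_, flag = "no_intervals"))
  thr <- (if (sex == "M") male_thresh_ms else female_thresh_ms) / 1000
  d <- diff(sort(pulses))
  d <- d[d < thr]
  if (!length(d)) return(structure(NA_real_, flag = "no_intervals"))
  median(d) * 1000
}

#' Build a courtship record from pulses
#'
#' @param pulses data.frame `center_s`, `sex` (`"M"`/`"F"`).
#' @param metadata optional list (manipulation codes, mating state, ...).
#' @param copulation_time copulation time, s, or `NA`.
#' @return A list of class `courtship_record`: `pulses`, `bouts` (both sexes,
#'   assembled), `total_courtship_time` (first to last pulse of either sex),
#'   `metadata`, `copulation_time`.
#' @export
courtship_record <- function(pulses, metadata = list(),
                             copulation_time = NA_real_) {
  stopifnot(all(c("center_s", "sex") %in% names(pulses)))
  pulses <- pulses[order(pulses$center_s), , drop = FALSE]
  bouts <- rbind(
    assemble_bouts(pulses$center_s[pulses$sex == "M"], "M"),
    assemble_bouts(pulses$center_s[pulses$sex == "F"], "F"))
  tct <- if (nrow(pulses) >= 2)
    max(pulses$center_s) - min(pulses$center_s) else 0
  structure(list(pulses = pulses, bouts = bouts,
                 total_courtship_time = tct, metadata = metadata,
                 copulation_time = copulation_time),
            class = "courtship_record")
}

#' Song rate of a courtship record
#'
#' Bout or pulse count divided by total courtship time (first to last pulse
#' of either sex), in Hz. Recordings with under 20 s of that sex's cumulative
#' song (summed bout spans) are assigned a rate of 0. A square-root transform
#' is available for presentation only; statistics are always computed on raw
#' rates.
#'
#' @param record a [courtship_record()].
#' @param sex `"M"` or `"F"`.
#' @param unit count `"bout"`s or `"pulse"`s.
#' @param min_song_s cumulative-song threshold below which the rate is 0.
#' @param sqrt_transform return `sqrt(rate)` (presentation flag).
#' @return Rate in Hz (possibly square-rooted); attribute `flag` set to
#'   `"short_song"` or `"no_courtship"` when forced to zero.
#' @export
song_rate <- function(record, sex = c("M", "F"), unit = c("bout", "pulse"),
                      min_song_s = 20, sqrt_transform = FALSE) {
  sex <- match.arg(sex); unit <- match.arg(unit)
  b <- record$bouts[record$bouts$sex == sex, , drop = FALSE]
  song_s <- sum(b$offset_s - b$onset_s)
  n <- if (unit == "bout") nrow(b) else
    sum(record$pulses$sex == sex)
  if (record$total_courtship_time <= 0)
    return(structure(0, flag = "no_courtship"))
  if (song_s < min_song_s)
    return(structure(0, flag = "short_song"))
  r <- n / record$total_courtship_time
  if (sqrt_transform) sqrt(r) else r
}

#' Percent of male bouts overlapped by female song
#'
#' 100 times the number of male bouts containing at least one female pulse,
#' divided by the number of male bouts.
#'
#' @param record a [courtship_record()].
#' @return Percentage in `[0, 100]`, or `NA` when there are no male bouts.
#' @export
percent_overlap <- function(record) {
  mb <- record$bouts[record$bouts$sex == "M", , drop = FALSE]
  if (!nrow(mb)) return(NA_real_)
  fp <- record$pulses$center_s[record$pulses$sex == "F"]
  overlapped <- vapply(seq_len(nrow(mb)), function(i)
    any(fp >= mb$onset_s[i] & fp <= mb$offset_s[i]), TRUE)
  100 * sum(overlapped) / nrow(mb)
}

#' Average pulse power spectral density
#'
#' Periodogram of a window around each pulse center, averaged across pulses
#' and normalized to unit total power. Pulses whose window would cross the
#' trace edges are skipped (count reported as an attribute).
#'
#' @param trace an `audio_trace`.
#' @param pulses numeric pulse center times, s.
#' @param window_ms analysis window length, ms.
#' @return data.frame `freq_hz`, `power` with attribute `n_skipped`;
#'   `NULL` when no pulse has a valid window.
#' @export
pulse_spectrum <- function(trace, pulses, window_ms = 40) {
  x <- trace$samples; rate <- trace$rate
  w <- round(window_ms / 1000 * rate)
  half <- w %/% 2
  acc <- NULL; used <- 0L; skipped <- 0L
  for (ct in pulses) {
    i0 <- round(ct * rate) - half
    if (i0 < 1 || i0 + w - 1 > length(x)) { skipped <- skipped + 1L; next }
    seg <- x[i0:(i0 + w - 1)]
    pg <- Mod(fft(seg))^2
    pg <- pg[seq_len(w %/% 2 + 1)]
    acc <- if (is.null(acc)) pg else acc + pg
    used <- used + 1L
  }
  if (!used) return(NULL)
  p <- acc / used
  p <- p / sum(p)
  structure(data.frame(freq_hz = (seq_along(p) - 1) * rate / w, power = p),
            n_skipped = skipped)
}

#' Female song build-up before copulation
#'
#' For each record with a copulation time, female pulses are counted in
#' `bin_s`-second bins over the `horizon_s` seconds before copulation and
#' normalized within the record (max = 1 by default; sum-normalization
#' available). The mean and s.e.m. across records are returned.
#'
#' @param records list of [courtship_record()]s.
#' @param bin_s bin width, s.
#' @param horizon_s how far before copulation to look, s.
#' @param normalize `"max"` or `"sum"` per-record normalization.
#' @return data.frame `bin_start_s` (relative to copulation, negative),
#'   `mean`, `sem`, `n_records`; attribute `n_excluded` counts records
#'   without a copulation time.
#' @export
pre_copulation_profile <- function(records, bin_s = 10, horizon_s = 400,
                                   normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  edges <- seq(-horizon_s, 0, by = bin_s)
  profs <- list(); excluded <- 0L
  for (rec in records) {
    cop <- rec$copulation_time
    if (is.na(cop)) { excluded <- excluded + 1L; next }
    fp <- rec$pulses$center_s[rec$pulses$sex == "F"] - cop
    counts <- graphics::hist(fp[fp >= -horizon_s & fp < 0],
                             breaks = edges, plot = FALSE)$counts
    denom <- if (normalize == "max") max(counts) else sum(counts)
    profs[[length(profs) + 1L]] <-
      if (denom > 0) counts / denom else counts  # all-zero record kept as 0s
  }
  if (!length(profs)) return(structure(NULL, n_excluded = excluded))
  m <- do.call(rbind, profs)
  structure(data.frame(
    bin_start_s = edges[-length(edges)],
    mean = colMeans(m),
    sem = apply(m, 2, sd) / sqrt(nrow(m)),
    n_records = nrow(m)), n_excluded = excluded)
}
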