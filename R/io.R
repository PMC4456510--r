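#' Read an event table with schema validation
#'
#' All event times are 0-based seconds; intervals are half-open
#' `[onset, offset)`. Malformed rows are reported with their line numbers.
#'
#' Schemas:
#' \describe{
#'   \item{pulses}{columns `center_s` (numeric >= 0), `sex` (`"M"`/`"F"`).}
#'   \item{intervals}{columns `onset_s`, `offset_s` (numeric,
#'     `offset_s >= onset_s`), `label`.}
#'   \item{frames}{column `frame` plus one or more 0/1 track columns.}
#' }
#'
#' @param path CSV file path.
#' @param schema one of `"pulses"`, `"intervals"`, `"frames"`.
#' @return Validated data.frame (possibly empty, with a warning).
#' @export
read_events <- function(path, schema = c("pulses", "intervals", "frames")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) {
    warning("empty event file: ", path)
    return(d)
  }
  bad_rows <- function(mask, why) {
    if (any(mask))
      stop("malformed ", schema, " rows (", why, ") at line(s): ",
           paste(which(mask) + 1L, collapse = ", "))
  }
  if (schema == "pulses") {
    need <- c("center_s", "sex")
    if (!all(need %in% names(d)))
      stop("pulse table must have columns: ", paste(need, collapse = ", "))
    bad_rows(!is.finite(d$center_s) | d$center_s < 0, "bad center_s")
    bad_rows(!d$sex %in% c("M", "F"), "sex not M/F")
  } else if (schema == "intervals") {
    need <- c("onset_s", "offset_s")
    if (!all(need %in% names(d)))
      stop("interval table must have columns: ", paste(need, collapse = ", "))
    bad_rows(!is.finite(d$onset_s) | !is.finite(d$offset_s), "non-finite")
    bad_rows(d$offset_s < d$onset_s, "offset before onset")
  } else {
    if (!"frame" %in% names(d)) stop("frames table must have column 'frame'")
    tracks <- setdiff(names(d), c("frame", "time_s"))
    if (!length(tracks)) stop("frames table has no track columns")
    for (tr in tracks)
      bad_rows(!d[[tr]] %in% c(0, 1), paste0("non-binary track '", tr, "'"))
  }
  d
}

#' Write an event table
#'
#' @param d data.frame (list-columns are dropped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(d, path) {
  keep <- !vapply(d, is.list, TRUE)
  write.csv(d[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML file with optional top-level sections `duet`, `coupling`,
#' `segmenter` (argument lists for [duet_params()], [coupling_params()] and
#' [segmenter_config()]) and `stages` (logical skip flags).
#'
#' @param path YAML file.
#' @return list with validated `duet`, `coupling`, `segmenter` objects and
#'   raw `stages`.
#' @export
#' @examples
#' demo <- system.file("extdata", "demo_config.yaml", package = "virduet")
#' cfg <- read_config(demo)
#' cfg$duet$duration
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    duet = do.call(duet_params, raw$duet %||% list()),
    coupling = do.call(coupling_params, raw$coupling %||% list()),
    segmenter = do.call(segmenter_config, raw$segmenter %||% list()),
    stages = raw$stages %||% list())
}

#' Run the full analysis pipeline on one simulated courtship
#'
#' Simulate (audio + ground truth + behavior tracks), optionally segment the
#' audio, assemble statistics, compute response-time distributions against a
#' shuffled null, and fit the history GLMs. Stages can be skipped; with
#' segmentation skipped the ground-truth pulses feed the downstream stages.
#' Every run emits a manifest (config snapshot, seeds, per-stage event
#' counts) sufficient to re-run bit-identically.
#'
#' @param params a [duet_params()].
#' @param coupling a [coupling_params()].
#' @param cfg a [segmenter_config()].
#' @param seed integer master seed; stage seeds derive from it.
#' @param segment run the segmenter (skip to use ground-truth pulses).
#' @param glm_timing fit the history GLMs.
#' @param out_dir if non-`NULL`, write stage outputs (CSV/JSON-free formats)
#'   under this directory.
#' @return list of class `pipeline_result`: `sim`, `tracks`, `pulses` (the
#'   table used downstream), `record`, `stats`, `response`, `glm`,
#'   `manifest`.
#' @export
run_pipeline <- function(params = duet_params(), coupling = coupling_params(),
                         cfg = segmenter_config(), seed = 1, segment = TRUE,
                         glm_timing = TRUE, out_dir = NULL) {
  t0 <- Sys.time()
  manifest <- list(seed = seed, params = unclass(params),
                   coupling = unclass(coupling), cfg = unclass(cfg),
                   version = as.character(utils::packageVersion("virduet")),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(..., at = format(Sys.time()))
  }

  sim <- simulate_duet(params, seed = seed, audio = segment)
  log_stage("simulate", n_pulses = nrow(sim$truth$pulses),
            n_bouts = nrow(sim$truth$bouts))
  tracks <- simulate_behavior_tracks(sim$truth, coupling, seed = seed + 1,
                                     duration = params$duration)
  log_stage("behavior", n_intervals = nrow(tracks$intervals),
            n_frames = nrow(tracks$frames))

  if (segment) {
    tpl <- train_templates(params, cfg, seed = seed + 2)
    seg <- segment_audio(sim$audio, tpl, cfg)
    pulses <- seg$pulses
    log_stage("segment", n_segments = nrow(seg$segments),
              n_pulses = nrow(pulses))
  } else {
    seg <- NULL
    pulses <- sim$truth$pulses
    log_stage("segment", skipped = TRUE)
  }

  record <- courtship_record(pulses)
  stats <- list(
    male_median_ipi_ms = median_ipi(pulses$center_s[pulses$sex == "M"], "M"),
    female_median_ipi_ms = median_ipi(pulses$center_s[pulses$sex == "F"], "F"),
    male_bout_rate_hz = song_rate(record, "M", "bout"),
    female_pulse_rate_hz = song_rate(record, "F", "pulse"),
    percent_overlap = percent_overlap(record),
    mean_male_pulses_per_bout =
      mean(record$bouts$n_pulses[record$bouts$sex == "M"]))
  log_stage("stats", computed = length(stats))

  mb <- record$bouts[record$bouts$sex == "M", , drop = FALSE]
  fp <- pulses$center_s[pulses$sex == "F"]
  response <- NULL
  if (nrow(mb) >= 3 && length(fp) >= 20) {
    rt_f <- response_times(mb, fp, "female_after_male_onset")
    rt_m <- response_times(mb, fp, "male_onset_after_female_pulse", "last")
    null_f <- response_times(mb, shuffle_null(fp, "female_ipis",
                                              seed = seed + 3),
                             "female_after_male_onset")
    response <- list(
      female = rt_f, male = rt_m, female_null = null_f,
      female_summary = if (length(rt_f$latencies) >= 20)
        summarize_distribution(rt_f, seed = seed + 4),
      male_summary = if (length(rt_m$latencies) >= 20)
        summarize_distribution(rt_m, seed = seed + 5),
      ks_female_vs_null = if (length(rt_f$latencies) && length(null_f$latencies))
        ks_compare(rt_f, null_f))
    log_stage("response", n_female_rt = length(rt_f$latencies),
              n_male_rt = length(rt_m$latencies))
  } else log_stage("response", skipped = TRUE)

  glm <- NULL
  if (glm_timing && sum(tracks$frames$female_song) > 50) {
    d <- build_history_design(tracks, "proboscis_lick", "female_song")
    glm <- list(lick_female = fit_sparse_logistic(d, seed = seed + 6))
    log_stage("glm_timing",
              peak_ms = as.numeric(filter_peak_lag(glm$lick_female)))
  } else log_stage("glm_timing", skipped = TRUE)

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(pulses, file.path(out_dir, "pulses.csv"))
    write_events(data.frame(onset_s = record$bouts$onset_s,
                            offset_s = record$bouts$offset_s,
                            label = record$bouts$sex),
                 file.path(out_dir, "bouts.csv"))
    write_events(tracks$frames, file.path(out_dir, "frames.csv"))
    if (segment) write_wav(sim$audio, file.path(out_dir, "audio.wav"))
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }

  structure(list(sim = sim, tracks = tracks, pulses = pulses,
                 record = record, stats = stats, response = response,
                 glm = glm, manifest = manifest),
            class = "pipeline_result")
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  %d pulses -> %d bouts; male median IPI %.1f ms; overlap %.1f%%\n",
              nrow(x$pulses), nrow(x$record$bouts),
              as.numeric(x$stats$male_median_ipi_ms),
              x$stats$percent_overlap))
  if (!is.null(x$response$female_summary))
    cat(sprintf("  female response peak %.0f ms; male %.0f ms\n",
                x$response$female_summary$peak_latency_ms,
                x$response$male_summary$peak_latency_ms))
  invisible(x)
}
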