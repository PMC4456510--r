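# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 60-s wild-type duet with audio, its trained templates and segmentation
fix_params <- function() duet_params(duration = 60)

fix_sim <- function() fixture("sim60", function() {
  simulate_duet(fix_params(), seed = 1)
})

fix_templates <- function() fixture("templates", function() {
  train_templates(fix_params(), segmenter_config(), seed = 42)
})

fix_segmentation <- function() fixture("seg60", function() {
  segment_audio(fix_sim()$audio, fix_templates())
})

# 600-s events-only duet with behavior tracks, for the history GLMs
fix_tracks <- function() fixture("tracks600", function() {
  sim <- simulate_duet(duet_params(duration = 600), seed = 7, audio = FALSE)
  list(sim = sim,
       tracks = simulate_behavior_tracks(sim$truth, coupling_params(),
                                         fps = 60, seed = 70,
                                         duration = 600))
})

# hand-made posterior track: blocks of given labels at 1 kHz
posterior_block <- function(labels, ms_each, probs) {
  rows <- do.call(rbind, lapply(seq_along(labels), function(i) {
    p <- probs[[labels[i]]]
    matrix(p, nrow = ms_each[i], ncol = 4, byrow = TRUE)
  }))
  colnames(rows) <- c("M", "F", "O", "N")
  structure(list(posterior = rows, loglik = log(rows + 1e-12), rate = 1000),
            class = "posterior_track")
}
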