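test_that("render_pulse produces a band-limited Gabor with the right length and carrier", {
  w <- render_pulse(400, 20, 1, 10000)
  expect_length(w, 200)
  # periodogram oracle: argmax within one bin of the carrier
  pg <- Mod(fft(w))^2
  pg <- pg[1:100]
  f_bin <- (which.max(pg) - 1) * 10000 / 200
  expect_lte(abs(f_bin - 400), 10000 / 200)

  expect_identical(render_pulse(400, 20, 0, 10000), rep(0, 200))
  expect_identical(render_pulse(400, 20, 1, 10000),
                   render_pulse(400, 20, 1, 10000))
  expect_error(render_pulse(6000, 20, 1, 10000), "Nyquist")
})

test_that("simulated ground truth matches the generating song parameters", {
  sim <- simulate_duet(duet_params(duration = 120), seed = 1, audio = FALSE)
  tr <- sim$truth
  expect_false(is.unsorted(tr$pulses$center_s))

  # male IPIs recover the generating mean at n >= 200 pulses
  mp <- tr$pulses$center_s[tr$pulses$sex == "M"]
  expect_gt(length(mp), 200)
  ipi <- diff(mp) * 1000
  ipi <- ipi[ipi < 100]
  expect_lt(abs(mean(ipi) - 21.2), 1)

  # female latency mode: first female pulse after each male bout onset
  mb <- tr$bouts[tr$bouts$sex == "M", ]
  fp <- tr$pulses$center_s[tr$pulses$sex == "F"]
  lat <- vapply(mb$onset_s, function(on) {
    nxt <- fp[fp > on]
    if (length(nxt)) nxt[1] - on else NA_real_
  }, 0)
  lat <- lat[!is.na(lat) & lat < 1.5]
  kd <- density(lat, bw = 0.025)
  expect_lt(abs(kd$x[which.max(kd$y)] * 1000 - 409), 25)

  # every pulse lies inside exactly one bout of its sex
  for (sx in c("M", "F")) {
    b <- tr$bouts[tr$bouts$sex == sx, ]
    px <- tr$pulses$center_s[tr$pulses$sex == sx]
    hits <- vapply(px, function(t)
      sum(t >= b$onset_s & t <= b$offset_s), 0)
    expect_true(all(hits == 1))
  }
  # male bouts disjoint
  mb <- tr$bouts[tr$bouts$sex == "M", ]
  expect_true(all(mb$onset_s[-1] > head(mb$offset_s, -1)))
})

test_that("overlap probability zero keeps all female pulses outside male bouts", {
  sim <- simulate_duet(duet_params(duration = 60, overlap_probability = 0),
                       seed = 3, audio = FALSE)
  mb <- sim$truth$bouts[sim$truth$bouts$sex == "M", ]
  fp <- sim$truth$pulses$center_s[sim$truth$pulses$sex == "F"]
  inside <- vapply(fp, function(t)
    any(t >= mb$onset_s & t <= mb$offset_s), TRUE)
  expect_false(any(inside))
})

test_that("noiseless audio is exactly the sum of placed pulse waveforms", {
  p <- duet_params(duration = 20, noise_sd = 0)
  sim <- simulate_duet(p, seed = 5)
  x <- numeric(length(sim$audio$samples))
  for (sx in c("M", "F")) {
    carrier <- if (sx == "M") p$male_carrier_hz else p$female_carrier_hz
    dur <- if (sx == "M") p$male_pulse_duration_ms else p$female_pulse_duration_ms
    amp <- if (sx == "M") p$male_pulse_amplitude else p$female_pulse_amplitude
    w <- render_pulse(carrier, dur, amp, p$sample_rate)
    half <- length(w) %/% 2
    for (ct in sim$truth$pulses$center_s[sim$truth$pulses$sex == sx]) {
      i0 <- round(ct * p$sample_rate) - half
      idx <- i0 + seq_along(w)
      keep <- idx >= 1 & idx <= length(x)
      x[idx[keep]] <- x[idx[keep]] + w[keep]
    }
  }
  expect_identical(sim$audio$samples, x)
})

test_that("fixed seed gives bit-identical simulations and short durations warn", {
  a <- simulate_duet(duet_params(duration = 30), seed = 11)
  b <- simulate_duet(duet_params(duration = 30), seed = 11)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_identical(a$truth$pulses, b$truth$pulses)
  expect_warning(s <- simulate_duet(duet_params(duration = 0.4), seed = 1),
                 "too short")
  expect_equal(nrow(s$truth$pulses), 0)
})

test_that("behavior episodes lead male bouts by the configured amount", {
  sim <- simulate_duet(duet_params(duration = 60), seed = 2, audio = FALSE)
  # isolate the bout-mirroring episodes: no jitter, no train-locked episodes
  cp <- coupling_params(jitter_sd_ms = 0, train_lock_prob = 0)
  trk <- simulate_behavior_tracks(sim$truth, cp, fps = 60, seed = 1,
                                  duration = 60)
  vib <- trk$intervals[trk$intervals$behavior == "tarsal_vibration", ]
  mb <- sim$truth$bouts[sim$truth$bouts$sex == "M", ]
  mb <- mb[mb$onset_s - 0.2 > 0 & mb$offset_s - 0.05 < 60, ]
  for (i in seq_len(nrow(mb))) {
    d <- mb$onset_s[i] - vib$onset_s
    expect_equal(min(abs(d - 0.2)), 0, tolerance = 1e-9)
  }
  lick <- trk$intervals[trk$intervals$behavior == "proboscis_lick", ]
  d1 <- mb$onset_s[1] - lick$onset_s
  expect_equal(min(abs(d1 - 0.05)), 0, tolerance = 1e-9)
  # pauses fill between vibration episodes
  pz <- trk$intervals[trk$intervals$behavior == "tarsal_pause", ]
  expect_gt(nrow(pz), 0)
  expect_true(all(pz$offset_s > pz$onset_s))
})

test_that("rasterized tracks count frames correctly and empty truth is empty", {
  iv <- data.frame(onset_s = 1, offset_s = 2, behavior = "tarsal_vibration")
  fr <- rasterize_tracks(iv, truth = NULL, fps = 60, duration = 4)
  expect_true(abs(sum(fr$tarsal_vibration) - 60) <= 1)

  empty <- simulate_behavior_tracks(
    structure(list(pulses = data.frame(center_s = numeric(0),
                                       sex = character(0)),
                   bouts = data.frame(onset_s = numeric(0),
                                      offset_s = numeric(0),
                                      sex = character(0)),
                   copulation_time = NA_real_), class = "ground_truth"),
    coupling_params(), fps = 60, seed = 1, duration = 2)
  expect_equal(nrow(empty$intervals), 0)
  expect_true(all(empty$frames$tarsal_vibration == 0))
  expect_error(simulate_behavior_tracks(fix_sim()$truth, coupling_params(),
                                        fps = -1), "fps")
})

test_that("playback stimulus follows the 6 x 1.2 s / every 30 s protocol", {
  rate <- 2000
  bout <- render_pulse(150, 100, 1, rate)
  stim <- simulate_playback_stimulus(bout, rate)
  expect_length(stim$samples, 600 * rate)
  # energy envelope per 1.2-s slot: exactly 6 active slots per 30-s group
  active <- which(abs(stim$samples) > 1e-3)
  onsets <- active[c(TRUE, diff(active) > rate * 0.5)]
  expect_length(onsets, 120)
  within_group <- diff(onsets)[diff(onsets) < rate * 2]
  expect_true(all(abs(within_group - 1.2 * rate) <= rate * 0.05))

  silent <- simulate_playback_stimulus(numeric(100), rate)
  expect_true(all(silent$samples == 0))
  expect_error(simulate_playback_stimulus(numeric(3 * rate), rate),
               "longer")
})
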