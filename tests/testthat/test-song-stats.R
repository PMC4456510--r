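test_that("bout assembly follows the IPI and minimum-count rules", {
  b <- assemble_bouts(c(0, 21, 42, 63, 84) / 1000, "M")
  expect_equal(nrow(b), 1)
  expect_equal(b$n_pulses, 5L)

  expect_equal(nrow(assemble_bouts(c(0, 21, 42) / 1000, "M")), 0)

  b <- assemble_bouts(c(0, 21, 42, 63, 200, 221, 242, 263) / 1000, "M")
  expect_equal(nrow(b), 2)
  expect_equal(b$n_pulses, c(4L, 4L))

  # female trains: IPI < 100 ms, no minimum count
  b <- assemble_bouts(c(0, 0.05, 0.12, 0.5) / 1, "F")
  expect_equal(nrow(b), 2)
  expect_equal(b$n_pulses, c(3L, 1L))
  expect_error(assemble_bouts(c(2, 1), "M"), "sorted")
})

test_that("bout assembly is stable under far-away noise pulses and keeps bouts disjoint", {
  core <- c(0, 21, 42, 63) / 1000
  far <- c(0.5, 1.2)  # farther than any IPI threshold
  b1 <- assemble_bouts(core, "M")
  b2 <- assemble_bouts(sort(c(core, far)), "M")
  expect_equal(b1$onset_s, b2$onset_s)
  expect_equal(b1$n_pulses, b2$n_pulses)
  sim <- simulate_duet(duet_params(duration = 60), seed = 9, audio = FALSE)
  mb <- assemble_bouts(sim$truth$pulses$center_s[sim$truth$pulses$sex == "M"],
                       "M")
  expect_true(all(mb$onset_s[-1] > head(mb$offset_s, -1)))
  # every pulse in a male bout has a neighbor within 25 ms
  for (g in mb$pulse_centers[1:5]) {
    gaps <- diff(g)
    expect_true(all(gaps < 0.025))
  }
})

test_that("median IPI uses sex-specific thresholds", {
  expect_equal(median_ipi(seq(0, 0.212, by = 0.0212), "M"), 21.2,
               tolerance = 1e-9)
  # 50 ms kept, 150 ms dropped at the 100 ms male threshold
  expect_equal(median_ipi(c(0, 0.05, 0.2), "M"), 50, tolerance = 1e-9)
  expect_true(is.na(median_ipi(0.5, "M")))
  # generator recovery within 2 s.e.
  sim <- simulate_duet(duet_params(duration = 120), seed = 13, audio = FALSE)
  for (sx in c("M", "F")) {
    px <- sim$truth$pulses$center_s[sim$truth$pulses$sex == sx]
    target <- if (sx == "M") 21.2 else 55.2
    spread <- if (sx == "M") 1.9 else 26.3
    n <- length(px)
    expect_lt(abs(median_ipi(px, sx) - target),
              max(2 * spread / sqrt(n) * 1.25, 2))
  }
})

test_that("song rates follow the count-over-courtship-time rule", {
  # 120 bouts of 10 pulses each over ~600 s (>= 20 s cumulative song)
  onsets <- seq(0, 595, by = 5)
  pulses <- data.frame(
    center_s = as.vector(outer(seq(0, 0.189, by = 0.021) + 0.2,
                               onsets, `+`)),
    sex = "M")
  pulses <- pulses[order(pulses$center_s), ]
  rec <- courtship_record(pulses)
  r <- song_rate(rec, "M", "bout")
  expect_equal(r, 120 / rec$total_courtship_time, tolerance = 1e-9)
  expect_equal(r, 0.2, tolerance = 0.01)
  expect_equal(song_rate(rec, "M", "bout", sqrt_transform = TRUE), sqrt(r))

  # under 20 s of cumulative song of that sex -> rate 0
  r0 <- song_rate(rec, "M", "bout", min_song_s = 20)
  expect_gt(sum(rec$bouts$offset_s - rec$bouts$onset_s), 0)
  short <- courtship_record(pulses[pulses$center_s < 100, ])
  expect_equal(as.numeric(song_rate(short, "M", "bout")), 0)
  expect_equal(attr(song_rate(short, "M", "bout"), "flag"), "short_song")

  none <- courtship_record(data.frame(center_s = numeric(0),
                                      sex = character(0)))
  expect_equal(as.numeric(song_rate(none, "F", "pulse")), 0)
})

test_that("percent overlap counts male bouts containing female pulses", {
  mk_rec <- function(f_centers) {
    mp <- as.vector(outer(c(0, 0.021, 0.042, 0.063), c(1, 2, 3, 4), `+`))
    pulses <- rbind(data.frame(center_s = mp, sex = "M"),
                    data.frame(center_s = f_centers, sex = "F"))
    courtship_record(pulses[order(pulses$center_s), ])
  }
  expect_equal(percent_overlap(mk_rec(c(1.5, 2.5))), 0)
  expect_equal(percent_overlap(mk_rec(c(1.02, 2.5))), 25)
  expect_equal(percent_overlap(mk_rec(c(1.02, 2.02, 3.02, 4.02))), 100)
  empty <- courtship_record(data.frame(center_s = 1, sex = "F"))
  expect_true(is.na(percent_overlap(empty)))
})

test_that("pulse spectra peak at the generating carriers", {
  p <- duet_params(duration = 30, noise_sd = 0.005)
  sim <- simulate_duet(p, seed = 21)
  tr <- sim$truth
  psd_m <- pulse_spectrum(sim$audio,
                          tr$pulses$center_s[tr$pulses$sex == "M"])
  psd_f <- pulse_spectrum(sim$audio,
                          tr$pulses$center_s[tr$pulses$sex == "F"])
  fm <- psd_m$freq_hz[which.max(psd_m$power)]
  ff <- psd_f$freq_hz[which.max(psd_f$power)]
  expect_lt(abs(fm - 400), 25 + 1e-9)
  expect_lt(abs(ff - 250), 25 + 1e-9)
  expect_gt(fm, ff)  # male pulses peak at higher frequency
  expect_equal(sum(psd_m$power), 1, tolerance = 1e-9)
  expect_null(pulse_spectrum(sim$audio, numeric(0)))
})

test_that("the pre-copulation profile tracks the female pulse rate shape", {
  mk_rec <- function(seed, rate_fun) {
    set.seed(seed)
    t <- seq(0, 400, by = 0.05)
    keep <- runif(length(t)) < rate_fun(t) * 0.05
    pulses <- data.frame(center_s = t[keep], sex = "F")
    courtship_record(pulses, copulation_time = 400)
  }
  # linearly increasing rate -> essentially monotone mean profile
  recs <- lapply(1:6, function(s) mk_rec(s, function(t) 0.2 + 1.8 * t / 400))
  prof <- pre_copulation_profile(recs)
  expect_equal(nrow(prof), 40)
  fit <- coef(lm(prof$mean ~ prof$bin_start_s))[2]
  expect_gt(fit, 0)
  expect_gt(cor(prof$bin_start_s, prof$mean), 0.8)

  # constant rate -> flat within noise
  recs <- lapply(1:6, function(s) mk_rec(100 + s, function(t) rep(1, length(t))))
  prof <- pre_copulation_profile(recs)
  expect_lt(abs(coef(lm(prof$mean ~ prof$bin_start_s))[2]), 5e-4)

  # records without copulation are excluded with a count
  recs2 <- c(recs, list(courtship_record(data.frame(center_s = 1, sex = "F"))))
  prof2 <- pre_copulation_profile(recs2)
  expect_equal(attr(prof2, "n_excluded"), 1L)
  expect_equal(prof2$n_records[1], 6)

  # a record with no pulses in the window keeps all-zero bins
  silent <- courtship_record(data.frame(center_s = 500, sex = "F"),
                             copulation_time = 1000)
  prof3 <- pre_copulation_profile(list(silent))
  expect_true(all(prof3$mean == 0))
})
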