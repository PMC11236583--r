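# Contour synthesis and trial-timeline construction.

test_that("PURR synthesis matches the closed-form harmonic sum", {
  # constant f0 = 1 Hz: phase at t is exactly 2*pi*t
  pt <- const_track(1, 1)
  w <- synthesize_purr(pt, 1000, amplitude = 1)
  expect_length(w, 1000)
  # t = 0.25 s -> sin(pi/2) + 1/4 sin(pi) + 1/16 sin(3pi/2) = 0.9375
  expect_equal(w[251], 0.9375, tolerance = 1e-9)
  t <- (0:999) / 1000
  expect_equal(w, sin(2 * pi * t) + sin(4 * pi * t) / 4 +
                 sin(6 * pi * t) / 16, tolerance = 1e-9)
})

test_that("PURR degenerate and error cases behave", {
  empty <- pitch_track(numeric(0), numeric(0))
  expect_length(synthesize_purr(empty, 8000), 0)
  bad <- pitch_track(c(0, 0.01), c(100, 100))
  bad$f0[2] <- -5
  expect_error(synthesize_purr(bad, 8000), "positive")
  expect_error(synthesize_purr(const_track(100, 0.1), 300), "aliasing|4 \\*")
})

test_that("PURR spectrum has three lines at f0, 2f0, 3f0 with 1:1/4:1/16 amplitudes", {
  f0 <- 136.5    # mean voice pitch lowered by 55 Hz
  fs <- 8000
  pt <- const_track(f0, 2, fs = 1000)
  w <- synthesize_purr(pt, fs)
  n <- length(w)
  spec <- Mod(stats::fft(w))[seq_len(n / 2)] * 2 / n
  freq <- (seq_len(n / 2) - 1) / (n / fs)
  # FFT-argmax oracle: fundamental dominates at f0
  expect_equal(freq[which.max(spec)], f0, tolerance = 1)
  line_amp <- function(f) max(spec[abs(freq - f) < 2])
  a <- c(line_amp(f0), line_amp(2 * f0), line_amp(3 * f0))
  expect_equal(a / a[1], c(1, 1 / 4, 1 / 16), tolerance = 0.02)
  # everything else is FFT leakage, far below the third harmonic
  rest <- spec[abs(freq - f0) > 5 & abs(freq - 2 * f0) > 5 &
                 abs(freq - 3 * f0) > 5]
  expect_lt(max(rest), a[3] / 2)
})

test_that("gap interpolation preserves voiced samples and fills gaps smoothly", {
  # fully voiced track is returned unchanged
  pt <- const_track(150, 0.5, fs = 200)
  expect_identical(interpolate_f0_gaps(pt), pt)
  # samples on a line: the spline reproduces the linear values in the gap
  t <- seq(0, 1, by = 0.01)
  f0 <- 100 + 50 * t
  voiced <- rep(TRUE, length(t)); voiced[40:60] <- FALSE
  g <- pitch_track(t, ifelse(voiced, f0, NA), voiced)
  out <- interpolate_f0_gaps(g)
  expect_equal(out$f0, f0, tolerance = 1e-6)
  expect_equal(out$voiced, voiced)
  # sinusoidal F0 with a 160 ms gap: error below 5% of the F0 range
  f0s <- 190 + 60 * sin(2 * pi * 1.2 * t)
  voiced2 <- !(t > 0.42 & t < 0.58)
  g2 <- pitch_track(t, ifelse(voiced2, f0s, NA), voiced2)
  out2 <- interpolate_f0_gaps(g2)
  expect_lt(max(abs(out2$f0 - f0s)), 0.05 * diff(range(f0s)))
  # fewer than two voiced samples is an error
  g3 <- pitch_track(t[1:3], c(100, NA, NA), c(TRUE, FALSE, FALSE))
  expect_error(interpolate_f0_gaps(g3), "two voiced")
})

test_that("synthetic contour F0 matches the reference voice statistics", {
  for (cond in c("SLOW", "FAST")) {
    cf <- contour_f0(cond, shift_hz = 0)
    expect_equal(min(cf$f0), 116, tolerance = 1e-6)
    expect_equal(max(cf$f0), 267, tolerance = 1e-6)
    expect_equal(mean(cf$f0), 191.5, tolerance = 0.01)
    dur <- length(cf) / 200
    expect_equal(dur, c(SLOW = 1.570, FAST = 0.942)[[cond]],
                 tolerance = 0.005)
  }
  # the -55 Hz presentation shift moves the whole track
  shifted <- contour_f0("SLOW")
  expect_equal(min(shifted$f0), 116 - 55, tolerance = 1e-6)
})

test_that("trial timelines implement the paradigm arithmetic", {
  s <- make_trial_schedule("SLOW", "LONG", jitter_seed = 1)
  sent <- s$events[s$events$label == "sentence_onset", ]
  expect_equal(sent$duration_ms, 1884)            # 314 ms x 6 words
  s2 <- make_trial_schedule("SLOW", "SHORT", jitter_seed = 1)
  won <- s2$events$onset_ms[s2$events$label == "word_onset"] -
    s2$sentence_onset_ms
  expect_equal(won, c(0, 314, 628, 942, 1256))
  expect_equal(s2$omission_ms - s2$sentence_onset_ms, 1570)
  expect_true(is.na(s$omission_ms))               # LONG has no omission
  # FAST lead pause equalizes the entrainment phases: 3x1730 - 3x1102
  s3 <- make_trial_schedule("FAST", "SHORT", jitter_seed = 1)
  lead <- s3$events[s3$events$label == "lead_pause", ]
  expect_equal(lead$duration_ms, 1884)
  expect_equal(s3$sentence_onset_ms, 5190)
  expect_equal(s$sentence_onset_ms, 5190)
  # per-repetition reading is selectable
  s4 <- make_trial_schedule("FAST", "SHORT", jitter_seed = 1,
                            fast_lead = "per_repetition")
  expect_equal(s4$events$duration_ms[s4$events$label == "lead_pause"], 628)
  # events are time-ordered and the jitter is on the sample grid
  for (x in list(s, s2, s3)) {
    expect_false(is.unsorted(x$events$onset_ms))
    expect_gte(x$jitter_ms, 0)
    expect_lte(x$jitter_ms, 250)
    expect_equal(x$jitter_ms %% 4, 0)
  }
})

test_that("cycle durations and rates round to the published values", {
  expect_equal(cycle_ms("SLOW"), 1730)
  expect_equal(cycle_ms("FAST"), 1102)
  expect_equal(cycle_rate_hz("SLOW"), 0.6)
  expect_equal(cycle_rate_hz("FAST"), 0.9)
  expect_equal(round(cycle_ms("FAST") / 1000, 1), 1.1)
})

test_that("session plans are balanced, non-repeating and deterministic", {
  plan <- generate_session_plan(300, 5, seed = 7)
  tab <- plan_table(plan)
  counts <- table(tab$condition, tab$length)
  expect_true(all(counts == 75))
  expect_equal(as.integer(table(tab$block)), rep(60L, 5))
  # adjacency constraint over several seeds
  for (seed in 1:5) {
    t2 <- plan_table(generate_session_plan(60, 2, seed = seed))
    cells <- paste(t2$condition, t2$length)
    expect_false(any(cells[-1] == cells[-length(cells)]))
  }
  # n_trials = 4: one permutation of the cells
  t4 <- plan_table(generate_session_plan(4, 1, seed = 1))
  expect_setequal(paste(t4$condition, t4$length),
                  c("SLOW SHORT", "SLOW LONG", "FAST SHORT", "FAST LONG"))
  # determinism
  p1 <- plan_table(generate_session_plan(40, 2, seed = 3))
  p2 <- plan_table(generate_session_plan(40, 2, seed = 3))
  expect_identical(p1, p2)
  expect_error(generate_session_plan(42, 2), "divisible by 4")
})

test_that("file interfaces round-trip F0 tracks, WAV audio and event tables", {
  td <- withr::local_tempdir()
  t <- seq(0, 0.5, by = 0.005)
  f0 <- 150 + 40 * sin(2 * pi * t)
  voiced <- t < 0.2 | t > 0.3
  pt <- pitch_track(t, ifelse(voiced, f0, NA), voiced)
  p <- file.path(td, "f0.tsv")
  write_f0_tsv(pt, p)
  back <- read_f0_tsv(p)
  expect_equal(back$times, pt$times)
  expect_equal(back$f0[voiced], pt$f0[voiced])
  expect_equal(back$voiced, voiced)

  w <- synthesize_purr(interpolate_f0_gaps(pt), 8000, amplitude = 0.8)
  pw <- file.path(td, "contour.wav")
  write_wav(w, pw, 8000)
  wav <- read_wav(pw)
  expect_equal(wav$sample_rate, 8000)
  expect_equal(wav$wave, w, tolerance = 1e-3)     # 16-bit quantization

  plan <- layout_session(generate_session_plan(8, 2, seed = 1))
  pe <- file.path(td, "events.tsv")
  write_events_tsv(plan, pe)
  ev <- read.delim(pe)
  expect_true(all(c("onset", "duration", "trial_type", "condition") %in%
                    names(ev)))
  expect_false(is.unsorted(ev$onset[ev$trial == 1]))
})
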