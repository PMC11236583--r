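# Stimulus construction: delexicalized prosodic contours (PURR harmonic
# resynthesis of an F0 track) and the trial timelines of the entrainment
# paradigm (SLOW/FAST contour cycles followed by a word-by-word sentence).

# Paradigm timing constants (ms)
CONTOUR_MS <- c(SLOW = 1570, FAST = 942)
PAUSE_MS <- 160
N_REPETITIONS <- 3L
WORD_MS <- 314
DELAY_MS <- 500
JITTER_MAX_MS <- 250
PITCH_SHIFT_HZ <- -55
HARMONIC_AMPS <- c(1, 1 / 4, 1 / 16)

# Pitch statistics of the reference female voice (Hz)
PITCH_MIN_HZ <- 116
PITCH_MAX_HZ <- 267
PITCH_MEAN_HZ <- 191.5

#' Cycle duration of a contour condition
#'
#' One cycle is the contour plus the 160 ms inter-repetition pause:
#' 1,730 ms for SLOW (rate ~0.6 Hz) and 1,102 ms for FAST (rate ~0.9 Hz).
#'
#' @param condition `"SLOW"` or `"FAST"`.
#' @return Cycle duration in milliseconds.
#' @export
cycle_ms <- function(condition) {
  condition <- match.arg(condition, c("SLOW", "FAST"))
  unname(CONTOUR_MS[condition] + PAUSE_MS)
}

#' Nominal cycle rate of a contour condition
#'
#' @param condition `"SLOW"` or `"FAST"`.
#' @param exact If `TRUE`, return the exact reciprocal of the cycle duration;
#'   otherwise round to one decimal (0.6 / 0.9 Hz), the analysis frequencies.
#' @return Rate in Hz.
#' @export
cycle_rate_hz <- function(condition, exact = FALSE) {
  r <- 1000 / cycle_ms(condition)
  if (exact) r else round(r, 1)
}

#' Construct a pitch track
#'
#' A `pitch_track` is a sampled fundamental-frequency trajectory: a strictly
#' increasing time grid, F0 in Hz (positive where voiced), and a logical
#' voicing mask. Unvoiced samples may hold `NA`.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param f0 F0 values in Hz.
#' @param voiced Logical voicing mask; defaults to finite, positive `f0`.
#' @return An object of class `pitch_track`.
#' @export
pitch_track <- function(times, f0, voiced = NULL) {
  stopifnot(length(times) == length(f0))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("pitch_track: `times` must be strictly increasing")
  }
  if (is.null(voiced)) voiced <- is.finite(f0) & f0 > 0
  stopifnot(length(voiced) == length(f0))
  if (any(voiced & (!is.finite(f0) | f0 <= 0))) {
    stop("pitch_track: voiced samples must have finite positive f0")
  }
  structure(list(times = as.numeric(times), f0 = as.numeric(f0),
                 voiced = as.logical(voiced)),
            class = "pitch_track")
}

#' @export
length.pitch_track <- function(x) length(x$times)

#' @export
print.pitch_track <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("pitch_track: %d samples, %.3f s, %d voiced (%.0f%%)\n",
              n, if (n) diff(range(x$times)) else 0,
              sum(x$voiced), if (n) 100 * mean(x$voiced) else 0))
  invisible(x)
}

#' Fill unvoiced gaps in a pitch track by cubic-spline interpolation
#'
#' Unvoiced samples (pauses, voiceless stretches) are replaced by a cubic
#' spline through the voiced samples; voiced samples are untouched. The
#' voicing mask is preserved so downstream code can still distinguish
#' measured from interpolated F0.
#'
#' @param pitch A [pitch_track()].
#' @return A `pitch_track` with finite `f0` everywhere.
#' @export
interpolate_f0_gaps <- function(pitch) {
  stopifnot(inherits(pitch, "pitch_track"))
  v <- pitch$voiced & is.finite(pitch$f0)
  if (sum(v) < 2) {
    stop("interpolate_f0_gaps: need at least two voiced samples")
  }
  if (all(v)) return(pitch)
  f0 <- pitch$f0
  fit <- stats::spline(pitch$times[v], f0[v], xout = pitch$times[!v],
                       method = "fmm")
  f0[!v] <- fit$y
  pitch_track(pitch$times, f0, pitch$voiced)
}

#' Synthesize a delexicalized contour by harmonic resynthesis (PURR)
#'
#' Renders an F0 track as audio using the fundamental plus its second
#' harmonic at 1/4 and third harmonic at 1/16 of the amplitude, so only the
#' pitch modulation of the source speech survives. The instantaneous phase is
#' the cumulative integral of F0, so pitch glides are rendered without phase
#' discontinuities:
#' \deqn{s(t) = A[\sin\phi(t) + \tfrac14 \sin 2\phi(t) + \tfrac1{16}\sin 3\phi(t)],
#'       \quad \phi(t) = 2\pi \int_0^t f_0(u)\,du.}
#'
#' @param pitch A fully voiced [pitch_track()] (interpolate gaps first).
#' @param sample_rate Audio sampling rate in Hz; must be at least 4 times the
#'   maximum F0 so the third harmonic stays below Nyquist.
#' @param amplitude Peak scale factor `A`.
#' @return Numeric waveform of length `round(duration * sample_rate)`, where
#'   the duration is the track's span extended by one F0 sample step.
#' @export
synthesize_purr <- function(pitch, sample_rate, amplitude = 1) {
  stopifnot(inherits(pitch, "pitch_track"))
  n <- length(pitch$times)
  if (n == 0) return(numeric(0))
  if (any(!is.finite(pitch$f0)) || any(pitch$f0 <= 0)) {
    stop("synthesize_purr: f0 must be finite and positive (interpolate gaps first)")
  }
  if (sample_rate < 4 * max(pitch$f0)) {
    stop("synthesize_purr: sample_rate must be >= 4 * max(f0) to avoid aliasing")
  }
  dt_track <- if (n > 1) pitch$times[2] - pitch$times[1] else 1 / sample_rate
  duration <- pitch$times[n] - pitch$times[1] + dt_track
  n_out <- round(duration * sample_rate)
  t <- pitch$times[1] + (seq_len(n_out) - 1) / sample_rate
  f0 <- stats::approx(pitch$times, pitch$f0, xout = t, rule = 2)$y
  # cumulative trapezoidal integral of f0 -> phase
  dphi <- c(0, (f0[-1] + f0[-n_out]) / 2) / sample_rate
  phi <- 2 * pi * cumsum(dphi)
  amplitude * (HARMONIC_AMPS[1] * sin(phi) +
               HARMONIC_AMPS[2] * sin(2 * phi) +
               HARMONIC_AMPS[3] * sin(3 * phi))
}

#' Synthetic contour F0 trajectory for one condition
#'
#' Deterministic smooth F0 trajectory standing in for the averaged natural
#' pitch contour of a condition. The shape (declination plus two accent
#' peaks) is rescaled so that its minimum, maximum and mean equal the pitch
#' statistics of the reference voice (116 / 267 / 191.5 Hz); an optional
#' shift (default -55 Hz) lowers the whole track as done for presentation.
#'
#' @param condition `"SLOW"` (1,570 ms) or `"FAST"` (942 ms).
#' @param sample_rate F0 sampling rate in Hz (track grid, not audio).
#' @param shift_hz Additive pitch shift in Hz applied after rescaling.
#' @return A fully voiced [pitch_track()] spanning the contour duration.
#' @export
contour_f0 <- function(condition, sample_rate = 200, shift_hz = PITCH_SHIFT_HZ) {
  condition <- match.arg(condition, c("SLOW", "FAST"))
  dur <- CONTOUR_MS[[condition]] / 1000
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  u <- t / dur
  # declination + two accents; different phase offsets per condition so the
  # two contours are not scaled copies of each other
  ph <- if (condition == "SLOW") c(0.4, 1.1) else c(1.3, 0.2)
  x <- -1.3 * u + 0.4 * sin(2 * pi * 1.9 * u + ph[1]) +
    0.22 * sin(2 * pi * 3.7 * u + ph[2])
  x <- (x - min(x)) / (max(x) - min(x))
  # monotone power warp so the mean lands on the voice's mean pitch
  target <- (PITCH_MEAN_HZ - PITCH_MIN_HZ) / (PITCH_MAX_HZ - PITCH_MIN_HZ)
  g <- stats::uniroot(function(g) mean(x^exp(g)) - target, c(-4, 4))$root
  x <- x^exp(g)
  f0 <- PITCH_MIN_HZ + x * (PITCH_MAX_HZ - PITCH_MIN_HZ) + shift_hz
  pitch_track(t, f0)
}

#' Repeated-contour pitch reference for one trial's entrainment phase
#'
#' Lays the condition contour out three times with 160 ms unvoiced pauses in
#' between (and after the last repetition, completing the third cycle). This
#' is the coherence reference signal; pauses are marked unvoiced and can be
#' filled with [interpolate_f0_gaps()].
#'
#' @param condition `"SLOW"` or `"FAST"`.
#' @param sample_rate Sampling rate of the returned track in Hz.
#' @param n_repetitions Number of contour cycles (default 3).
#' @param interpolate Fill pause gaps by spline interpolation (default TRUE).
#' @param shift_hz Pitch shift passed to [contour_f0()].
#' @return A `pitch_track` spanning `n_repetitions * cycle_ms(condition)`.
#' @export
repeated_contour_f0 <- function(condition, sample_rate = 250,
                                n_repetitions = N_REPETITIONS,
                                interpolate = TRUE,
                                shift_hz = PITCH_SHIFT_HZ) {
  condition <- match.arg(condition, c("SLOW", "FAST"))
  one <- contour_f0(condition, sample_rate, shift_hz)
  cyc_s <- cycle_ms(condition) / 1000
  n_total <- round(n_repetitions * cyc_s * sample_rate)
  t <- (seq_len(n_total) - 1) / sample_rate
  f0 <- rep(NA_real_, n_total)
  voiced <- rep(FALSE, n_total)
  n_con <- length(one)
  for (r in seq_len(n_repetitions)) {
    i0 <- round((r - 1) * cyc_s * sample_rate)
    idx <- i0 + seq_len(n_con)
    idx <- idx[idx <= n_total]
    f0[idx] <- stats::approx(one$times, one$f0,
                             xout = t[idx] - t[idx[1]], rule = 2)$y
    voiced[idx] <- TRUE
  }
  out <- pitch_track(t, f0, voiced)
  if (interpolate) out <- interpolate_f0_gaps(out)
  out
}

#' Build the event timeline of one trial
#'
#' Lays out the entrainment phase (for FAST, a lead-in pause equalizing total
#' entrainment duration across conditions, then three contour cycles), the
#' word-by-word visual sentence at 314 ms per word, and a jittered delay of
#' 500 + U(0, 250) ms. For SHORT sentences the omission point -- the
#' theoretical onset of the 6th word, which is never shown -- is at
#' `sentence_onset + 5 * 314` ms.
#'
#' @param contour_condition `"SLOW"` or `"FAST"`.
#' @param sentence_length `"SHORT"` (5 words) or `"LONG"` (6 words).
#' @param jitter_seed Integer seed for the delay jitter, or `NULL` to use the
#'   current RNG state.
#' @param fast_lead `"total"` (default): single lead pause equal to the total
#'   entrainment-duration difference (1,884 ms), making both conditions'
#'   entrainment phases last 5,190 ms; `"per_repetition"`: a single 628 ms
#'   pause matching one cycle-pair difference.
#' @param sample_rate Grid to which the jitter is quantized (Hz).
#' @return An object of class `trial_schedule`: the condition labels, an
#'   events data frame (`label`, `onset_ms`, `duration_ms`), and convenience
#'   fields `contour_onset_ms`, `sentence_onset_ms`, `omission_ms` (NA for
#'   LONG), `duration_ms`.
#' @export
make_trial_schedule <- function(contour_condition, sentence_length,
                                jitter_seed = NULL,
                                fast_lead = c("total", "per_repetition"),
                                sample_rate = 250) {
  contour_condition <- match.arg(contour_condition, c("SLOW", "FAST"))
  sentence_length <- match.arg(sentence_length, c("SHORT", "LONG"))
  fast_lead <- match.arg(fast_lead)
  n_words <- if (sentence_length == "SHORT") 5L else 6L

  slow_total <- N_REPETITIONS * cycle_ms("SLOW")
  fast_total <- N_REPETITIONS * cycle_ms("FAST")
  lead <- if (contour_condition == "FAST") {
    if (fast_lead == "total") slow_total - fast_total
    else (slow_total - fast_total) / N_REPETITIONS
  } else 0

  if (!is.null(jitter_seed)) {
    jitter <- withr::with_seed(as.integer(jitter_seed),
                               stats::runif(1, 0, JITTER_MAX_MS))
  } else {
    jitter <- stats::runif(1, 0, JITTER_MAX_MS)
  }
  # quantize to the sample grid
  step_ms <- 1000 / sample_rate
  jitter <- round(jitter / step_ms) * step_ms

  ev <- list()
  add <- function(label, onset, duration) {
    ev[[length(ev) + 1L]] <<- data.frame(label = label, onset_ms = onset,
                                         duration_ms = duration)
  }
  t <- 0
  if (lead > 0) {
    add("lead_pause", t, lead)
    t <- t + lead
  }
  contour_onset <- t
  con <- unname(CONTOUR_MS[contour_condition])
  for (r in seq_len(N_REPETITIONS)) {
    add("cycle_onset", t, con)
    add("cycle_offset", t + con, 0)
    add("pause", t + con, PAUSE_MS)
    t <- t + con + PAUSE_MS
  }
  sentence_onset <- t
  add("sentence_onset", t, n_words * WORD_MS)
  for (w in seq_len(n_words)) {
    add("word_onset", sentence_onset + (w - 1) * WORD_MS, WORD_MS)
  }
  omission <- NA_real_
  if (sentence_length == "SHORT") {
    omission <- sentence_onset + 5 * WORD_MS
    add("omission_point", omission, 0)
  }
  t <- sentence_onset + n_words * WORD_MS
  add("delay", t, DELAY_MS + jitter)
  t <- t + DELAY_MS + jitter
  add("question_onset", t, 0)

  events <- do.call(rbind, ev)
  stopifnot(!is.unsorted(events$onset_ms))
  structure(list(contour_condition = contour_condition,
                 sentence_length = sentence_length,
                 n_words = n_words,
                 jitter_ms = jitter,
                 events = events,
                 contour_onset_ms = contour_onset,
                 sentence_onset_ms = sentence_onset,
                 omission_ms = omission,
                 duration_ms = t),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("trial_schedule: %s x %s, %.0f ms total, %d events\n",
              x$contour_condition, x$sentence_length, x$duration_ms,
              nrow(x$events)))
  invisible(x)
}

#' Generate a counterbalanced session plan
#'
#' Equal numbers of trials in the four condition cells (SLOW/FAST crossed
#' with SHORT/LONG), in an order where the same cell never occupies two
#' adjacent trials, split into equally sized blocks. Deterministic under
#' `seed`.
#'
#' @param n_trials Total number of trials; must be divisible by 4 (and by
#'   `n_blocks`).
#' @param n_blocks Number of blocks.
#' @param seed Integer seed.
#' @param fast_lead Passed to [make_trial_schedule()].
#' @return A list of `trial_schedule` objects with `$block` set, of class
#'   `session_plan`.
#' @export
generate_session_plan <- function(n_trials = 300, n_blocks = 5, seed = 1,
                                  fast_lead = "total") {
  if (n_trials %% 4 != 0) {
    stop("generate_session_plan: n_trials must be divisible by 4")
  }
  if (n_trials %% n_blocks != 0) {
    stop("generate_session_plan: n_trials must be divisible by n_blocks")
  }
  cells <- expand.grid(condition = c("SLOW", "FAST"),
                       length = c("SHORT", "LONG"),
                       stringsAsFactors = FALSE)
  withr::with_seed(as.integer(seed), {
    labels <- rep(seq_len(4), each = n_trials / 4)
    ord <- sample(labels)
    # repair adjacent repeats by swapping with a compatible later position
    repeat {
      bad <- which(diff(ord) == 0)
      if (length(bad) == 0) break
      i <- bad[1] + 1L
      ok <- which(ord != ord[i] &
                  c(ord[-1], -1) != ord[i] &
                  c(-1, ord[-length(ord)]) != ord[i])
      ok <- setdiff(ok, i)
      if (length(ok) == 0) { # reshuffle (vanishingly rare at these sizes)
        ord <- sample(labels)
        next
      }
      j <- ok[sample.int(length(ok), 1)]
      tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
    }
    plan <- vector("list", n_trials)
    per_block <- n_trials / n_blocks
    for (k in seq_len(n_trials)) {
      sch <- make_trial_schedule(cells$condition[ord[k]],
                                 cells$length[ord[k]],
                                 fast_lead = fast_lead)
      sch$block <- ((k - 1) %/% per_block) + 1L
      sch$trial <- k
      plan[[k]] <- sch
    }
    structure(plan, class = "session_plan")
  })
}

#' @export
print.session_plan <- function(x, ...) {
  tab <- table(vapply(x, function(s)
    paste(s$contour_condition, s$sentence_length, sep = "x"), ""))
  cat(sprintf("session_plan: %d trials\n", length(x)))
  print(tab)
  invisible(x)
}

#' Tabulate a session plan's condition cells
#'
#' @param plan A `session_plan`.
#' @return Data frame with one row per trial: `trial`, `block`, `condition`,
#'   `length`, `duration_ms`.
#' @export
plan_table <- function(plan) {
  do.call(rbind, lapply(plan, function(s) {
    data.frame(trial = s$trial, block = s$block,
               condition = s$contour_condition,
               length = s$sentence_length,
               duration_ms = s$duration_ms)
  }))
}
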