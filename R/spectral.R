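# Frequency-domain estimation: epoch extraction, Hann-tapered zero-padded
# FFT on the 0.1 Hz analysis grid, pitch-MEG coherence and power spectra.

#' Construct an epoch set
#'
#' Container for epoched multichannel data: a trials x channels x samples
#' array with sampling rate, epoch start time `t0` (s, relative to the
#' alignment event) and a per-trial metadata data frame.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sample_rate Sampling rate in Hz.
#' @param t0 Time of the first sample relative to the alignment event (s).
#' @param meta Data frame with one row per trial.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sample_rate, t0 = 0, meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(meta)) {
    meta <- data.frame(trial = seq_len(dim(data)[1]))
  }
  stopifnot(nrow(meta) == dim(data)[1])
  structure(list(data = data, sample_rate = sample_rate, t0 = t0,
                 meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoch_set: %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
    d[1], d[2], d[3], x$sample_rate, x$t0))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Analysis frequency grid after zero padding
#'
#' The analysis band 0--3 Hz at 0.1 Hz resolution, attained by zero-padding
#' each epoch to `pad_s` seconds: 31 bins for the sensor analyses (10 s
#' padding). Every grid frequency must be exactly representable on the
#' padded DFT grid (`f * pad_s` integer).
#'
#' @param pad_s Padded duration in seconds (10 for sensor analyses, 20 for
#'   source CSDs).
#' @param fmin,fmax Band edges in Hz.
#' @param resolution Grid step in Hz.
#' @return Object of class `spectral_grid` with `frequencies`, `pad_s`,
#'   `resolution`, `n_bins`.
#' @export
spectral_grid <- function(pad_s = 10, fmin = 0, fmax = 3, resolution = 0.1) {
  if (abs(pad_s * resolution - round(pad_s * resolution)) > 1e-9) {
    stop("spectral_grid: resolution must be a multiple of 1/pad_s")
  }
  freqs <- seq(fmin, fmax, by = resolution)
  k <- freqs * pad_s
  if (any(abs(k - round(k)) > 1e-9)) {
    stop("spectral_grid: grid frequencies not representable at padded resolution")
  }
  structure(list(frequencies = freqs, pad_s = pad_s, resolution = resolution,
                 n_bins = length(freqs), fmin = fmin, fmax = fmax),
            class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("spectral_grid: %d bins, %g-%g Hz @ %g Hz (pad %g s)\n",
              x$n_bins, x$fmin, x$fmax, x$resolution, x$pad_s))
  invisible(x)
}

# Epoch duration (s) for a phase/condition; entrainment = 3 contour cycles,
# target = one cycle, erf = omission window [-0.25, 1] s.
phase_epoch_s <- function(phase, condition) {
  switch(phase,
         entrainment = N_REPETITIONS * cycle_ms(condition) / 1000,
         target = cycle_ms(condition) / 1000,
         erf = 1.25,
         stop("unknown phase: ", phase))
}

#' Cut phase-specific epochs out of a continuous recording
#'
#' Entrainment epochs run from contour onset (after any lead pause) for
#' three contour cycles (5.19 s SLOW, 3.306 s FAST); target epochs run from
#' visual sentence onset for one contour cycle (1.73 s SLOW, 1.102 s FAST);
#' `erf` epochs cover -250 ms to 1 s around the omission point of SHORT
#' trials. Sample counts are floored to the grid; each epoch is demeaned per
#' channel.
#'
#' @param recording A `meg_recording` (see [simulate_subject()]): list with
#'   `data` (channels x samples), `sample_rate`, and a laid-out `plan`
#'   carrying per-trial `onset_s`.
#' @param plan Session plan with absolute trial onsets; defaults to
#'   `recording$plan`.
#' @param phase `"entrainment"`, `"target"` or `"erf"`.
#' @param condition Restrict to `"SLOW"` or `"FAST"` trials; required for
#'   phases whose epoch length is condition specific (entrainment, target).
#' @param sentence_length Optionally restrict to `"SHORT"` or `"LONG"`
#'   trials; `erf` epochs always use SHORT trials only.
#' @param demean Subtract the per-channel epoch mean (default TRUE).
#' @return An [epoch_set()] with trial metadata.
#' @export
extract_epochs <- function(recording, plan = recording$plan,
                           phase = c("entrainment", "target", "erf"),
                           condition = NULL, sentence_length = NULL,
                           demean = TRUE) {
  phase <- match.arg(phase)
  fs <- recording$sample_rate
  if (phase == "erf") sentence_length <- "SHORT"
  if (phase != "erf" && is.null(condition)) {
    stop("extract_epochs: `condition` is required for ", phase,
         " epochs (condition-specific length)")
  }
  keep <- vapply(plan, function(s) {
    (is.null(condition) || s$contour_condition == condition) &&
      (is.null(sentence_length) || s$sentence_length == sentence_length)
  }, logical(1))
  trials <- plan[keep]
  n_chan <- nrow(recording$data)
  if (length(trials) == 0) {
    return(epoch_set(array(0, c(0, n_chan, 0)), fs,
                     meta = data.frame(trial = integer(0))))
  }
  cond0 <- trials[[1]]$contour_condition
  dur_s <- phase_epoch_s(phase, cond0)
  n_samp <- floor(dur_s * fs)
  t0 <- if (phase == "erf") -0.25 else 0
  data <- array(NA_real_, c(length(trials), n_chan, n_samp))
  meta <- data.frame(trial = integer(length(trials)),
                     condition = character(length(trials)),
                     sentence_length = character(length(trials)),
                     phase = phase)
  for (i in seq_along(trials)) {
    s <- trials[[i]]
    if (is.null(s$onset_s)) {
      stop("extract_epochs: plan has no absolute onsets; run layout_session()")
    }
    anchor_ms <- switch(phase,
                        entrainment = s$contour_onset_ms,
                        target = s$sentence_onset_ms,
                        erf = s$omission_ms)
    start <- round((s$onset_s + anchor_ms / 1000 + t0) * fs) + 1L
    idx <- start:(start + n_samp - 1L)
    if (idx[1] < 1 || idx[length(idx)] > ncol(recording$data)) {
      stop("extract_epochs: epoch exceeds recording bounds at trial ",
           s$trial)
    }
    seg <- recording$data[, idx, drop = FALSE]
    if (demean) seg <- seg - rowMeans(seg)
    data[i, , ] <- seg
    meta$trial[i] <- s$trial
    meta$condition[i] <- s$contour_condition
    meta$sentence_length[i] <- s$sentence_length
  }
  epoch_set(data, fs, t0, meta)
}

# Hann taper of length n (periodic-symmetric form used for spectral tapers)
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Hann-tapered, zero-padded Fourier coefficients on the analysis grid
#'
#' Each epoch is tapered with a Hann window over its data length, zero-padded
#' to `grid$pad_s` seconds, Fourier transformed, and the complex coefficients
#' are returned at the grid frequencies only.
#'
#' @param epochs An [epoch_set()] (or a trials x samples matrix for a
#'   single-channel reference signal).
#' @param grid A [spectral_grid()].
#' @param sample_rate Required if `epochs` is a bare matrix.
#' @return Complex array trials x channels x bins (trials x bins for a
#'   matrix input), with attribute `frequencies`.
#' @export
spectrum_hann_padded <- function(epochs, grid = spectral_grid(),
                                 sample_rate = NULL) {
  single <- !inherits(epochs, "epoch_set")
  if (single) {
    stopifnot(!is.null(sample_rate))
    x <- epochs
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    fs <- sample_rate
    n_trial <- nrow(x); n_chan <- 1L; n_samp <- ncol(x)
    data <- array(x, c(n_trial, 1L, n_samp))
  } else {
    data <- epochs$data
    fs <- epochs$sample_rate
    n_trial <- dim(data)[1]; n_chan <- dim(data)[2]; n_samp <- dim(data)[3]
  }
  n_pad <- round(grid$pad_s * fs)
  if (n_samp > n_pad) {
    stop("spectrum_hann_padded: epoch longer than pad duration")
  }
  bins <- round(grid$frequencies * grid$pad_s) + 1L
  w <- hann_window(n_samp)
  out <- array(complex(real = 0), c(n_trial, n_chan, grid$n_bins))
  if (n_trial == 0 || n_samp == 0) {
    attr(out, "frequencies") <- grid$frequencies
    return(if (single) out[, 1, , drop = TRUE] else out)
  }
  buf <- matrix(0, n_pad, n_chan)
  for (k in seq_len(n_trial)) {
    buf[] <- 0
    buf[seq_len(n_samp), ] <- t(data[k, , , drop = FALSE][1, , ]) * w
    co <- stats::mvfft(buf)
    out[k, , ] <- t(co[bins, , drop = FALSE])
  }
  attr(out, "frequencies") <- grid$frequencies
  if (single) {
    res <- out[, 1, , drop = FALSE]
    dim(res) <- c(n_trial, grid$n_bins)
    attr(res, "frequencies") <- grid$frequencies
    res
  } else {
    out
  }
}

#' Pitch--MEG coherence spectrum across trials
#'
#' Magnitude-squared coherence between a reference signal (the interpolated
#' F0 track resampled to the MEG rate) and every channel, estimated across
#' trials at each grid frequency:
#' \deqn{C(f) = \frac{|\sum_k X_k(f) \overline{Y_k(f)}|^2}
#'                   {\sum_k |X_k(f)|^2 \sum_k |Y_k(f)|^2}.}
#'
#' @param reference_epochs Trials x samples matrix of the reference signal
#'   (same trial count and length as `meg_epochs`), or a single vector
#'   recycled for all trials.
#' @param meg_epochs An [epoch_set()].
#' @param grid A [spectral_grid()].
#' @return Object of class `coherence_spectrum`: `values` (channels x bins in
#'   \[0, 1\]), `frequencies`, `n_trials`.
#' @export
coherence_spectrum <- function(reference_epochs, meg_epochs,
                               grid = spectral_grid()) {
  d <- dim(meg_epochs$data)
  if (is.null(dim(reference_epochs))) {
    reference_epochs <- matrix(reference_epochs, nrow = d[1],
                               ncol = length(reference_epochs), byrow = TRUE)
  }
  if (nrow(reference_epochs) != d[1] || ncol(reference_epochs) != d[3]) {
    stop("coherence_spectrum: reference and MEG epochs must match in trials and samples")
  }
  if (d[1] < 2) stop("coherence_spectrum: need at least 2 trials")
  ref <- reference_epochs - rowMeans(reference_epochs)
  X <- spectrum_hann_padded(ref, grid, sample_rate = meg_epochs$sample_rate)
  Y <- spectrum_hann_padded(meg_epochs, grid)
  n_chan <- d[2]; n_bins <- grid$n_bins
  vals <- matrix(NA_real_, n_chan, n_bins)
  sxx <- colSums(abs(X)^2)                       # bins
  for (c in seq_len(n_chan)) {
    Yc <- Y[, c, , drop = FALSE]; dim(Yc) <- c(d[1], n_bins)
    sxy <- colSums(X * Conj(Yc))
    syy <- colSums(abs(Yc)^2)
    vals[c, ] <- Mod(sxy)^2 / (sxx * syy)
  }
  vals[!is.finite(vals)] <- 0
  structure(list(values = vals, frequencies = grid$frequencies,
                 n_trials = d[1]),
            class = c("coherence_spectrum", "channel_spectrum"))
}

#' Trial-averaged power spectrum
#'
#' Squared magnitude of the Hann-tapered, zero-padded Fourier coefficients,
#' averaged over trials, per channel and grid bin.
#'
#' @param meg_epochs An [epoch_set()].
#' @param grid A [spectral_grid()].
#' @return Object of class `power_spectrum`: `values` (channels x bins),
#'   `frequencies`, `n_trials`.
#' @export
power_spectrum <- function(meg_epochs, grid = spectral_grid()) {
  d <- dim(meg_epochs$data)
  if (d[1] < 1) stop("power_spectrum: need at least 1 trial")
  Y <- spectrum_hann_padded(meg_epochs, grid)
  vals <- apply(abs(Y)^2, c(2, 3), mean)
  structure(list(values = vals, frequencies = grid$frequencies,
                 n_trials = d[1]),
            class = c("power_spectrum", "channel_spectrum"))
}

#' @export
print.channel_spectrum <- function(x, ...) {
  cat(sprintf("%s: %d channels x %d bins (%g-%g Hz), %d trials\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              min(x$frequencies), max(x$frequencies), x$n_trials))
  invisible(x)
}

#' Peak frequency of a channel-averaged spectrum
#'
#' Frequency of the maximal channel-mean value within a band; ties are
#' broken toward the lower frequency.
#'
#' @param spectrum A `coherence_spectrum` or `power_spectrum` (or any list
#'   with `values` channels x bins and `frequencies`).
#' @param band Length-2 numeric, band limits in Hz (inclusive).
#' @param exclude_dc Drop the 0 Hz bin (default TRUE).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, band = c(0, 1.5), exclude_dc = TRUE) {
  f <- spectrum$frequencies
  sel <- f >= band[1] & f <= band[2]
  if (exclude_dc) sel <- sel & f > 0
  if (!any(sel)) stop("peak_frequency: empty band")
  m <- colMeans(spectrum$values)[sel]
  f[sel][which.max(m)]
}

#' Group-average spectra across subjects
#'
#' @param spectra List of `coherence_spectrum`/`power_spectrum` objects with
#'   identical grids.
#' @return Object of the same class with `values` averaged elementwise.
#' @export
group_average_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  vals <- Reduce(`+`, lapply(spectra, `[[`, "values")) / length(spectra)
  out <- spectra[[1]]
  out$values <- vals
  out$n_trials <- sum(vapply(spectra, `[[`, 0L, "n_trials"))
  out
}

#' Long-format export of a channel spectrum
#'
#' @param spectrum A `channel_spectrum`.
#' @param path Output TSV path, or `NULL` to just return the data frame.
#' @param subject,condition Optional annotation columns.
#' @return Data frame (`subject`, `condition`, `channel`, `frequency`,
#'   `value`), invisibly if written.
#' @export
spectrum_to_tsv <- function(spectrum, path = NULL, subject = NA,
                            condition = NA) {
  d <- data.frame(subject = subject, condition = condition,
                  channel = rep(seq_len(nrow(spectrum$values)),
                                times = ncol(spectrum$values)),
                  frequency = rep(spectrum$frequencies,
                                  each = nrow(spectrum$values)),
                  value = as.vector(spectrum$values))
  if (!is.null(path)) {
    utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(d))
  }
  d
}
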