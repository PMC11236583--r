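# Orchestration: trial quality control, per-subject sensor and source
# analyses, group statistics, and report generation tying together the
# three analyses (entrainment coherence, sustained target-phase power,
# omission evoked field).

#' Analysis run configuration
#'
#' Bundles the simulation settings, analysis settings and QC thresholds.
#' QC thresholds are expressed in simulation units (sensor noise sd = 1);
#' the absolute-amplitude bound is the analog of the +-6 pT criterion used
#' on physical recordings.
#'
#' @param sim A [sim_config()].
#' @param n_perm Permutations for all cluster/permutation tests.
#' @param cluster_alpha Cluster-forming (and reporting) alpha.
#' @param min_channels Minimum cluster extent.
#' @param lambda Regularization fraction for the frequency-domain (DICS)
#'   beamformer (see [dics_common_filter()]).
#' @param lambda_lcmv Regularization fraction for the time-domain (LCMV)
#'   beamformer, whose broadband covariance is well conditioned.
#' @param erf_window,erf_early_window ERF analysis windows in ms.
#' @param qc_amp_threshold Absolute amplitude bound (simulation units).
#' @param qc_jump_z Median-filter-residual z threshold for jump artifacts.
#' @param qc_muscle_z Band-amplitude z threshold for muscle artifacts.
#' @param qc_muscle_band High-frequency band in Hz for the muscle rule.
#' @param seed Master seed for analysis randomness (permutations).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), n_perm = 1000,
                       cluster_alpha = 0.05, min_channels = 3,
                       lambda = 0.5, lambda_lcmv = 0.05,
                       erf_window = c(300, 600),
                       erf_early_window = c(0, 120),
                       qc_amp_threshold = 30, qc_jump_z = 75,
                       qc_muscle_z = 20, qc_muscle_band = c(110, 124),
                       seed = 1) {
  structure(list(sim = sim, n_perm = n_perm, cluster_alpha = cluster_alpha,
                 min_channels = min_channels, lambda = lambda,
                 lambda_lcmv = lambda_lcmv,
                 erf_window = erf_window,
                 erf_early_window = erf_early_window,
                 qc_amp_threshold = qc_amp_threshold, qc_jump_z = qc_jump_z,
                 qc_muscle_z = qc_muscle_z, qc_muscle_band = qc_muscle_band,
                 seed = seed),
            class = "run_config")
}

# robust max-deviation z of a vector: max |x - median| / mad
robust_max_z <- function(x) {
  m <- stats::mad(x)
  if (m == 0) return(Inf)
  max(abs(x - stats::median(x))) / m
}

# ideal bandpass by FFT masking (the epoch is implicitly zero-padded to the
# FFT length, avoiding edge wrap of a recursive filter); x is a vector or a
# samples x channels matrix
fft_bandpass <- function(x, fs, band) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  n_pad <- stats::nextn(2 * n, 2)
  X <- stats::mvfft(rbind(x, matrix(0, n_pad - n, ncol(x))))
  f <- (seq_len(n_pad) - 1) / n_pad * fs
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2], ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE) / n_pad)[seq_len(n), , drop = FALSE]
  if (vec) y[, 1] else y
}

#' Threshold-based trial rejection
#'
#' Removes trials failing any of three rules: (a) absolute amplitude beyond
#' the configured bound; (b) jump artifacts -- the residual of a 9-sample
#' running median has robust max z above `qc_jump_z` on any channel; (c)
#' muscle-band artifacts -- the 110--124 Hz band signal (ideal FFT bandpass
#' on the zero-padded epoch) has robust max z above `qc_muscle_z`.
#'
#' @param epochs An [epoch_set()].
#' @param config A [run_config()] (or list with the `qc_*` fields).
#' @return List `epochs` (retained trials) and `log` (data frame: trial,
#'   rule, statistic for each rejection).
#' @export
reject_trials_qc <- function(epochs, config = run_config()) {
  d <- dim(epochs$data)
  fs <- epochs$sample_rate
  log <- list()
  bad <- logical(d[1])
  for (k in seq_len(d[1])) {
    seg <- epochs$data[k, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = d[2])
    amp <- max(abs(seg))
    if (amp > config$qc_amp_threshold) {
      bad[k] <- TRUE
      log[[length(log) + 1L]] <- data.frame(trial = k, rule = "amplitude",
                                            statistic = amp)
      next
    }
    jz <- max(apply(seg, 1, function(x) {
      robust_max_z(x - stats::runmed(x, 9))
    }))
    if (jz > config$qc_jump_z) {
      bad[k] <- TRUE
      log[[length(log) + 1L]] <- data.frame(trial = k, rule = "jump",
                                            statistic = jz)
      next
    }
    if (config$qc_muscle_band[2] < fs / 2) {
      bp <- fft_bandpass(t(seg), fs, config$qc_muscle_band)
      mz <- max(apply(bp, 2, robust_max_z))
      if (mz > config$qc_muscle_z) {
        bad[k] <- TRUE
        log[[length(log) + 1L]] <- data.frame(trial = k, rule = "muscle",
                                              statistic = mz)
      }
    }
  }
  if (all(bad)) stop("reject_trials_qc: all trials rejected (empty data)")
  kept <- epoch_set(epochs$data[!bad, , , drop = FALSE], fs, epochs$t0,
                    epochs$meta[!bad, , drop = FALSE])
  list(epochs = kept,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(trial = integer(0), rule = character(0),
                             statistic = numeric(0)))
}

#' Pitch reference matched to the entrainment epochs
#'
#' The interpolated repeated-contour F0 track at the MEG sampling rate,
#' truncated or edge-padded to exactly `n_samples`.
#'
#' @param condition `"SLOW"` or `"FAST"`.
#' @param n_samples Epoch length in samples.
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`.
#' @export
entrainment_reference <- function(condition, n_samples, sample_rate = 250) {
  track <- repeated_contour_f0(condition, sample_rate)
  f0 <- track$f0
  if (length(f0) >= n_samples) f0[seq_len(n_samples)]
  else c(f0, rep(f0[length(f0)], n_samples - length(f0)))
}

#' Per-subject sensor spectra for both phases
#'
#' Extracts entrainment and target epochs per condition, applies QC, and
#' computes the pitch--MEG coherence spectrum (entrainment phase) and the
#' trial-averaged power spectrum (target phase) on the 31-bin grid.
#'
#' @param recording A `meg_recording`.
#' @param config A [run_config()].
#' @param grid A [spectral_grid()].
#' @param qc Apply [reject_trials_qc()] (default TRUE).
#' @return List per condition: `coherence`, `power`, `n_rejected`.
#' @export
subject_spectra <- function(recording, config = run_config(),
                            grid = spectral_grid(), qc = TRUE) {
  out <- list()
  for (cond in c("SLOW", "FAST")) {
    ent <- extract_epochs(recording, phase = "entrainment",
                          condition = cond)
    tgt <- extract_epochs(recording, phase = "target", condition = cond)
    n_rej <- 0L
    if (qc) {
      r1 <- reject_trials_qc(ent, config); ent <- r1$epochs
      r2 <- reject_trials_qc(tgt, config); tgt <- r2$epochs
      n_rej <- nrow(r1$log) + nrow(r2$log)
    }
    ref <- entrainment_reference(cond, dim(ent)[3],
                                 recording$sample_rate)
    out[[cond]] <- list(coherence = coherence_spectrum(ref, ent, grid),
                        power = power_spectrum(tgt, grid),
                        n_rejected = n_rej)
  }
  out
}

#' Channel values of a spectrum at one grid frequency
#'
#' @param spectrum A `coherence_spectrum` or `power_spectrum`.
#' @param f Frequency in Hz; must match a grid bin.
#' @return Numeric vector, one value per channel.
#' @export
spectrum_at <- function(spectrum, f) {
  i <- which(abs(spectrum$frequencies - f) < 1e-9)
  stopifnot(length(i) == 1)
  spectrum$values[, i]
}

#' Per-subject source-space ROI responses (DICS, common filters)
#'
#' For each analysis frequency (0.6, 0.9 Hz) builds the condition-pooled
#' CSD, derives the common DICS filter, applies it to the per-condition
#' CSDs, and averages node coherence (entrainment phase, with the pitch
#' reference) and power (target phase) over the labelled regions.
#'
#' @param recording A `meg_recording`.
#' @param model The `sensor_model`.
#' @param config A [run_config()].
#' @return List of two data frames (`coherence`, `power`) in ROI-response
#'   format: `condition`, `frequency`, `roi`, `hemisphere`, `R`.
#' @export
subject_source_responses <- function(recording, model,
                                     config = run_config()) {
  fs <- recording$sample_rate
  eps <- list(); refs <- list(); tgts <- list()
  for (cond in c("SLOW", "FAST")) {
    eps[[cond]] <- extract_epochs(recording, phase = "entrainment",
                                  condition = cond)
    refs[[cond]] <- entrainment_reference(cond, dim(eps[[cond]])[3], fs)
    tgts[[cond]] <- extract_epochs(recording, phase = "target",
                                   condition = cond)
  }
  coh_rows <- list(); pow_rows <- list()
  for (f in c(0.6, 0.9)) {
    # entrainment phase: coherence maps
    csd <- lapply(c(SLOW = "SLOW", FAST = "FAST"), function(cond) {
      compute_csd(eps[[cond]], refs[[cond]], f = f)
    })
    pooled <- csd$SLOW
    w <- c(csd$SLOW$n_trials, csd$FAST$n_trials)
    ns <- nrow(csd$SLOW$matrix)
    pooled$matrix <- (csd$SLOW$matrix * w[1] + csd$FAST$matrix * w[2]) /
      sum(w)
    filt <- dics_common_filter(pooled, model, lambda = config$lambda)
    for (cond in c("SLOW", "FAST")) {
      map <- apply_filter(filt, csd[[cond]])
      roi <- roi_average(map, model)
      coh_rows[[length(coh_rows) + 1L]] <-
        data.frame(condition = cond, frequency = f, roi = roi$roi,
                   hemisphere = roi$hemisphere, R = roi$coherence)
    }
    # target phase: power maps (no reference)
    csd_t <- lapply(c(SLOW = "SLOW", FAST = "FAST"), function(cond) {
      compute_csd(tgts[[cond]], NULL, f = f)
    })
    pooled_t <- csd_t$SLOW
    wt <- c(csd_t$SLOW$n_trials, csd_t$FAST$n_trials)
    pooled_t$matrix <- (csd_t$SLOW$matrix * wt[1] +
                        csd_t$FAST$matrix * wt[2]) / sum(wt)
    filt_t <- dics_common_filter(pooled_t, model, lambda = config$lambda)
    for (cond in c("SLOW", "FAST")) {
      map <- apply_filter(filt_t, csd_t[[cond]])
      roi <- roi_average(map, model)
      pow_rows[[length(pow_rows) + 1L]] <-
        data.frame(condition = cond, frequency = f, roi = roi$roi,
                   hemisphere = roi$hemisphere, R = roi$power)
    }
  }
  list(coherence = do.call(rbind, coh_rows),
       power = do.call(rbind, pow_rows))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates `config$sim$n_subjects` subjects and runs, in order: sensor
#' coherence (entrainment phase) and power (target phase) spectra with QC;
#' cluster-based permutation tests of 0.6 vs 0.9 Hz within SLOW, within
#' FAST, and of the difference of differences, for both measures; source
#' ROI responses with the RSR index and interaction contrasts; and the
#' omission ERF contrast in the late and early windows, with LCMV source
#' localization of the late window. Deterministic under the master seed.
#'
#' @param config A [run_config()].
#' @param model Optional prebuilt `sensor_model`.
#' @param sources Run the beamformer stage (default TRUE).
#' @param verbose Print stage timings.
#' @return Object of class `entrainment_report` (a list of tables and test
#'   objects) with `meta` (seed, sizes, timings).
#' @export
run_pipeline <- function(config = run_config(), model = NULL,
                         sources = TRUE, verbose = FALSE) {
  t_start <- Sys.time()
  sim <- config$sim
  if (is.null(model)) model <- build_sensor_model(seed = sim$seed + 1000L)
  grid <- spectral_grid()
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, what) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[what]] <<- dt
    if (verbose) message(sprintf("%-24s %6.1f s", what, dt))
  }

  # per-subject reductions (recordings are not retained)
  t0 <- tic()
  per_subject <- vector("list", sim$n_subjects)
  for (i in seq_len(sim$n_subjects)) {
    sseed <- (sim$seed * 1000L + i) %% .Machine$integer.max
    plan <- layout_session(generate_session_plan(sim$n_trials,
                                                 sim$n_blocks,
                                                 seed = sseed))
    rec <- simulate_subject(sim, plan, model, subject_seed = sseed + 1L)
    spec <- subject_spectra(rec, config, grid)
    src <- if (sources) subject_source_responses(rec, model, config)
           else NULL
    om <- omission_epochs(rec)
    om <- reject_trials_qc(om, config)$epochs
    erf <- condition_erf(om)
    lcmv <- if (sources) {
      covp <- erf_covariance(om)
      lcmv_filter_apply(covp, model, config$lambda_lcmv, erf,
                        window = config$erf_window)
    } else NULL
    per_subject[[i]] <- list(spectra = spec, source = src, erf = erf,
                             lcmv = lcmv)
    rm(rec)
  }
  toc(t0, "simulate+reduce")

  report <- list()
  report$group_coherence <- lapply(c(SLOW = "SLOW", FAST = "FAST"),
    function(cond) group_average_spectrum(
      lapply(per_subject, function(s) s$spectra[[cond]]$coherence)))
  report$group_power <- lapply(c(SLOW = "SLOW", FAST = "FAST"),
    function(cond) group_average_spectrum(
      lapply(per_subject, function(s) s$spectra[[cond]]$power)))
  report$peaks <- data.frame(
    measure = rep(c("coherence", "power"), each = 2),
    condition = rep(c("SLOW", "FAST"), 2),
    peak_hz = c(peak_frequency(report$group_coherence$SLOW),
                peak_frequency(report$group_coherence$FAST),
                peak_frequency(report$group_power$SLOW),
                peak_frequency(report$group_power$FAST)))

  # sensor cluster statistics at the two frequencies of interest
  t0 <- tic()
  get_map <- function(measure, cond, f) {
    t(vapply(per_subject, function(s)
      spectrum_at(s$spectra[[cond]][[measure]], f),
      numeric(nrow(model$adjacency))))
  }
  cluster_tests <- list()
  for (measure in c("coherence", "power")) {
    m <- list(slow06 = get_map(measure, "SLOW", 0.6),
              slow09 = get_map(measure, "SLOW", 0.9),
              fast06 = get_map(measure, "FAST", 0.6),
              fast09 = get_map(measure, "FAST", 0.9))
    cluster_tests[[measure]] <- list(
      slow = cluster_permutation(m$slow06, m$slow09, model$adjacency,
                                 n_perm = config$n_perm,
                                 cluster_alpha = config$cluster_alpha,
                                 min_channels = config$min_channels,
                                 seed = config$seed),
      fast = cluster_permutation(m$fast06, m$fast09, model$adjacency,
                                 n_perm = config$n_perm,
                                 cluster_alpha = config$cluster_alpha,
                                 min_channels = config$min_channels,
                                 seed = config$seed + 1L),
      interaction = cluster_permutation(m$slow06 - m$slow09,
                                        m$fast06 - m$fast09,
                                        model$adjacency,
                                        n_perm = config$n_perm,
                                        cluster_alpha = config$cluster_alpha,
                                        min_channels = config$min_channels,
                                        seed = config$seed + 2L))
  }
  report$cluster_tests <- cluster_tests
  toc(t0, "sensor clusters")

  # source ROI statistics
  if (sources) {
    t0 <- tic()
    roi_tab <- function(measure) {
      do.call(rbind, lapply(seq_along(per_subject), function(i) {
        d <- per_subject[[i]]$source[[measure]]
        d$subject <- i
        d
      }))
    }
    report$roi_responses <- list(coherence = roi_tab("coherence"),
                                 power = roi_tab("power"))
    report$rsr <- lapply(report$roi_responses, rsr_index)
    report$interaction <- lapply(report$roi_responses, interaction_contrast,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 3L)
    # LCMV node contrast across subjects (SLOW vs FAST window amplitude)
    A <- t(vapply(per_subject, function(s) s$lcmv$values$amplitude_slow,
                  numeric(nrow(model$nodes))))
    B <- t(vapply(per_subject, function(s) s$lcmv$values$amplitude_fast,
                  numeric(nrow(model$nodes))))
    tmap <- paired_t_map(A, B)
    report$lcmv_contrast <- data.frame(node = seq_len(ncol(A)),
                                       roi = model$nodes$roi,
                                       hemisphere = model$nodes$hemisphere,
                                       t = as.numeric(tmap),
                                       p = 2 * stats::pt(-abs(tmap),
                                                         attr(tmap, "df")))
    toc(t0, "source stats")
  }

  # omission ERF contrasts
  t0 <- tic()
  erfs <- lapply(per_subject, `[[`, "erf")
  report$erf_late <- window_contrast(erfs, config$erf_window,
                                     model$adjacency,
                                     n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha,
                                     min_channels = config$min_channels,
                                     seed = config$seed + 4L)
  report$erf_early <- window_contrast(erfs, config$erf_early_window,
                                      model$adjacency,
                                      n_perm = config$n_perm,
                                      cluster_alpha = config$cluster_alpha,
                                      min_channels = config$min_channels,
                                      seed = config$seed + 5L)
  toc(t0, "erf contrasts")

  report$meta <- list(seed = config$seed, sim_seed = sim$seed,
                      n_subjects = sim$n_subjects,
                      n_trials = sim$n_trials, n_perm = config$n_perm,
                      timings_s = as.list(timings),
                      total_s = as.numeric(difftime(Sys.time(), t_start,
                                                    units = "secs")),
                      r_version = as.character(getRversion()))
  class(report) <- "entrainment_report"
  report
}

#' @export
print.entrainment_report <- function(x, ...) {
  cat("entrainment_report\n")
  cat("  peak frequencies:\n")
  print(x$peaks, row.names = FALSE)
  for (measure in names(x$cluster_tests)) {
    for (ctr in names(x$cluster_tests[[measure]])) {
      ct <- x$cluster_tests[[measure]][[ctr]]
      sig <- significant_clusters(ct)
      cat(sprintf("  %s %s: %d significant cluster(s)\n", measure, ctr,
                  length(sig)))
    }
  }
  if (!is.null(x$rsr)) {
    for (measure in names(x$rsr)) {
      cat(sprintf("  mean RSR (%s): %.4g\n", measure,
                  mean(x$rsr[[measure]]$rsr)))
    }
  }
  cat(sprintf("  omission ERF late window: %d significant cluster(s)\n",
              length(significant_clusters(x$erf_late))))
  invisible(x)
}

#' Write a report's tables to disk
#'
#' TSV for tabular components, JSON for cluster tests and metadata, plus a
#' machine-readable `summary.json`.
#'
#' @param report An `entrainment_report`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    message("write_report: created ", outdir)
  }
  paths <- c()
  wt <- function(d, name) {
    p <- file.path(outdir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$peaks, "peaks.tsv")
  for (cond in names(report$group_coherence)) {
    wt(spectrum_to_tsv(report$group_coherence[[cond]], condition = cond),
       sprintf("coherence_%s.tsv", tolower(cond)))
    wt(spectrum_to_tsv(report$group_power[[cond]], condition = cond),
       sprintf("power_%s.tsv", tolower(cond)))
  }
  for (measure in names(report$cluster_tests)) {
    for (ctr in names(report$cluster_tests[[measure]])) {
      p <- file.path(outdir, sprintf("clusters_%s_%s.json", measure, ctr))
      clusters_to_json(report$cluster_tests[[measure]][[ctr]], p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$rsr)) {
    for (measure in names(report$rsr)) {
      wt(report$rsr[[measure]], sprintf("rsr_%s.tsv", measure))
      wt(report$interaction[[measure]],
         sprintf("interaction_%s.tsv", measure))
    }
    wt(report$lcmv_contrast, "lcmv_contrast.tsv")
  }
  p <- file.path(outdir, "clusters_erf_late.json")
  clusters_to_json(report$erf_late, p); paths <- c(paths, p)
  p <- file.path(outdir, "clusters_erf_early.json")
  clusters_to_json(report$erf_early, p); paths <- c(paths, p)
  summary <- list(
    peaks = report$peaks,
    n_significant = list(
      coherence_slow = length(significant_clusters(
        report$cluster_tests$coherence$slow)),
      coherence_fast = length(significant_clusters(
        report$cluster_tests$coherence$fast)),
      power_slow = length(significant_clusters(
        report$cluster_tests$power$slow)),
      power_fast = length(significant_clusters(
        report$cluster_tests$power$fast)),
      erf_late = length(significant_clusters(report$erf_late))),
    mean_rsr = if (!is.null(report$rsr))
      lapply(report$rsr, function(d) mean(d$rsr)) else NULL,
    meta = report$meta)
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
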