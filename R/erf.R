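# Omission evoked-field analysis: epoch SHORT trials around the theoretical
# onset of the never-presented 6th word, baseline-correct, average per
# prosodic condition, and contrast SLOW vs FAST in a-priori windows.

#' Epoch SHORT trials around the omission point
#'
#' Cuts -250 ms to +1,000 ms epochs aligned to the theoretical onset of the
#' missing verb in SHORT sentences of both prosodic conditions, and
#' baseline-corrects each epoch by the mean of the 250 ms pre-onset
#' interval.
#'
#' @param recording A `meg_recording`.
#' @param plan Laid-out plan; defaults to `recording$plan`.
#' @return An [epoch_set()] with `t0 = -0.25` and condition metadata.
#' @export
omission_epochs <- function(recording, plan = recording$plan) {
  ep <- extract_epochs(recording, plan, phase = "erf", demean = FALSE)
  if (dim(ep)[1] == 0) stop("omission_epochs: plan contains no SHORT trials")
  fs <- ep$sample_rate
  base <- seq_len(floor(0.25 * fs))
  for (k in seq_len(dim(ep)[1])) {
    seg <- ep$data[k, , , drop = FALSE][1, , ]
    ep$data[k, , ] <- seg - rowMeans(seg[, base, drop = FALSE])
  }
  ep
}

#' Per-condition evoked-field averages
#'
#' Trial averages within each prosodic condition for one subject.
#'
#' @param epochs Baseline-corrected omission [epoch_set()].
#' @return Object of class `erf_set`: `erf` (named list of channels x
#'   samples matrices, one per condition), `times` (s), `sample_rate`.
#' @export
condition_erf <- function(epochs) {
  conds <- unique(epochs$meta$condition)
  d <- dim(epochs$data)
  out <- list()
  for (cond in conds) {
    sel <- which(epochs$meta$condition == cond)
    if (length(sel) == 0) stop("condition_erf: empty condition ", cond)
    sub <- epochs$data[sel, , , drop = FALSE]
    out[[cond]] <- apply(sub, c(2, 3), mean)
  }
  times <- epochs$t0 + (seq_len(d[3]) - 1) / epochs$sample_rate
  structure(list(erf = out, times = times,
                 sample_rate = epochs$sample_rate,
                 n_trials = table(epochs$meta$condition)),
            class = "erf_set")
}

#' @export
print.erf_set <- function(x, ...) {
  cat(sprintf("erf_set: conditions %s, %d channels x %d samples\n",
              paste(names(x$erf), collapse = "/"),
              nrow(x$erf[[1]]), ncol(x$erf[[1]])))
  invisible(x)
}

#' Windowed SLOW-vs-FAST omission contrast across subjects
#'
#' Averages each subject's condition ERFs over an a-priori time window per
#' channel and submits the SLOW and FAST maps to the cluster-based sign-flip
#' permutation test. Cluster polarity is not interpreted as effect
#' direction; the returned condition means over the significant clusters'
#' channels establish direction.
#'
#' @param erfs List of `erf_set` objects, one per subject, each containing
#'   `SLOW` and `FAST` averages.
#' @param window Length-2 window in ms (default `c(300, 600)`; the early
#'   analysis uses `c(0, 120)`).
#' @param adjacency Channel adjacency matrix or `sensor_model`.
#' @param n_perm,cluster_alpha,min_channels,seed Passed to
#'   [cluster_permutation()].
#' @return A `cluster_test` with an extra `direction` data frame: per
#'   significant cluster, mean windowed amplitude per condition over its
#'   channels.
#' @export
window_contrast <- function(erfs, window = c(300, 600), adjacency,
                            n_perm = 5000, cluster_alpha = 0.05,
                            min_channels = 3, seed = 1) {
  stopifnot(length(erfs) >= 2)
  times_ms <- erfs[[1]]$times * 1000
  if (window[1] < min(times_ms) || window[2] > max(times_ms)) {
    stop("window_contrast: window outside epoch")
  }
  sel <- times_ms >= window[1] & times_ms <= window[2]
  wmean <- function(e, cond) rowMeans(e$erf[[cond]][, sel, drop = FALSE])
  A <- t(vapply(erfs, wmean, numeric(nrow(erfs[[1]]$erf[[1]])), "SLOW"))
  B <- t(vapply(erfs, wmean, numeric(nrow(erfs[[1]]$erf[[1]])), "FAST"))
  test <- cluster_permutation(A, B, adjacency, n_perm = n_perm,
                              cluster_alpha = cluster_alpha,
                              min_channels = min_channels, seed = seed)
  dir <- do.call(rbind, lapply(seq_along(test$clusters), function(i) {
    ch <- test$clusters[[i]]$members
    data.frame(cluster = i, polarity = test$clusters[[i]]$polarity,
               p_mc = test$clusters[[i]]$p_mc,
               mean_slow = mean(A[, ch]), mean_fast = mean(B[, ch]),
               abs_slow = mean(abs(A[, ch])), abs_fast = mean(abs(B[, ch])))
  }))
  test$window_ms <- window
  test$direction <- dir
  test
}

#' Post-onset to baseline RMS ratio (rough epoch SNR)
#'
#' A simple quality metric: RMS over the post-onset interval divided by RMS
#' over the baseline, averaged over channels. This is a guess at an epoch
#' SNR estimator and is provided for QC only.
#'
#' @param epochs Omission [epoch_set()].
#' @return Numeric vector, one ratio per trial.
#' @export
epoch_snr <- function(epochs) {
  fs <- epochs$sample_rate
  base <- seq_len(floor(-epochs$t0 * fs))
  post <- setdiff(seq_len(dim(epochs)[3]), base)
  vapply(seq_len(dim(epochs)[1]), function(k) {
    seg <- epochs$data[k, , , drop = FALSE][1, , ]
    sqrt(mean(seg[, post]^2)) / sqrt(mean(seg[, base]^2))
  }, numeric(1))
}

#' Export ERF traces as long-format TSV
#'
#' @param erfs List of `erf_set` per subject.
#' @param path Output path or `NULL`.
#' @return Data frame (`subject`, `condition`, `channel`, `time`,
#'   `amplitude`).
#' @export
erf_to_tsv <- function(erfs, path = NULL) {
  rows <- list()
  for (s in seq_along(erfs)) {
    for (cond in names(erfs[[s]]$erf)) {
      m <- erfs[[s]]$erf[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cond,
        channel = rep(seq_len(nrow(m)), times = ncol(m)),
        time = rep(erfs[[s]]$times, each = nrow(m)),
        amplitude = as.vector(m))
    }
  }
  d <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(d))
  }
  d
}
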