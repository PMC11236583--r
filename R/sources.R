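# Toy-forward-model beamforming: frequency-domain DICS with common spatial
# filters (coherence/power maps), time-domain LCMV for the omission field,
# and ROI averaging of node values.

#' Cross-spectral density matrix at one frequency
#'
#' Trial-averaged outer product of the Hann-tapered, zero-padded (20 s)
#' Fourier coefficients of all sensors plus the pitch-reference channel,
#' appended as the last row/column.
#'
#' @param epochs An [epoch_set()] (sensors).
#' @param reference Trials x samples matrix (or vector) of the reference
#'   signal, same trial count and length; `NULL` for a sensors-only CSD.
#' @param f Frequency in Hz; must lie on the padded grid (multiple of
#'   `1/pad_s`).
#' @param pad_s Padded duration in seconds (default 20).
#' @return Object of class `csd_matrix`: complex `matrix`
#'   ((sensors + ref) x (sensors + ref), conjugate symmetric), `frequency`,
#'   `n_trials`, `has_reference`.
#' @export
compute_csd <- function(epochs, reference = NULL, f, pad_s = 20) {
  if (abs(f * pad_s - round(f * pad_s)) > 1e-9) {
    stop("compute_csd: frequency not on the padded grid")
  }
  d <- dim(epochs$data)
  grid <- spectral_grid(pad_s = pad_s, fmin = f, fmax = f,
                        resolution = 1 / pad_s)
  Y <- spectrum_hann_padded(epochs, grid)          # trials x chan x 1
  V <- matrix(Y[, , 1], d[1], d[2])
  if (!is.null(reference)) {
    if (is.null(dim(reference))) {
      reference <- matrix(reference, nrow = d[1], ncol = length(reference),
                          byrow = TRUE)
    }
    reference <- reference - rowMeans(reference)
    X <- spectrum_hann_padded(reference, grid, sample_rate = epochs$sample_rate)
    V <- cbind(V, X[, 1])
  }
  C <- (Conj(t(V)) %*% V) / d[1]
  structure(list(matrix = C, frequency = f, n_trials = d[1],
                 has_reference = !is.null(reference)),
            class = "csd_matrix")
}

#' @export
print.csd_matrix <- function(x, ...) {
  cat(sprintf("csd_matrix: %d x %d at %g Hz (%d trials%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$frequency, x$n_trials,
              if (x$has_reference) ", + reference" else ""))
  invisible(x)
}

# sensor block (dropping the reference row/column if present)
csd_sensor_block <- function(csd) {
  n <- nrow(csd$matrix) - as.integer(csd$has_reference)
  csd$matrix[seq_len(n), seq_len(n), drop = FALSE]
}

# beamformer weights from an inverse "covariance" (real matrix) and leadfield
beamformer_weights <- function(Creal, leadfield, lambda) {
  reg <- Creal + lambda * mean(diag(Creal)) * diag(nrow(Creal))
  Ci <- tryCatch(solve(reg), error = function(e) {
    stop("singular matrix; increase regularization lambda (> 0)")
  })
  CiL <- Ci %*% leadfield
  denom <- colSums(leadfield * CiL)
  t(CiL) / denom                               # nodes x sensors
}

#' DICS common spatial filter
#'
#' Builds beamformer weights from a condition-pooled CSD at one frequency,
#' for reuse on the per-condition CSDs (common-filter approach, avoiding
#' single-condition bias). Per node j with leadfield column L_j:
#' \deqn{w_j = (L_j^T C^{-1} L_j)^{-1} L_j^T C^{-1},}
#' where C is the real part of the sensor CSD, diagonally regularized by
#' `lambda * mean(diag(C))`.
#'
#' @param csd_pooled A `csd_matrix` pooled over conditions.
#' @param leadfield Sensors x nodes gain matrix (or a `sensor_model`).
#' @param lambda Regularization fraction of the mean diagonal. The default
#'   (0.5) is deliberately strong: a CSD sampled at a single frequency from
#'   K trials has rank at most K, usually far below the channel count, and
#'   a weakly regularized adaptive filter then cancels most of the sampled
#'   data subspace, leaving per-condition power estimates dominated by
#'   small-sample structure. Values near 0.05 behave classically when the
#'   CSD is (near) full rank.
#' @return Object of class `spatial_filter`: `weights` (nodes x sensors),
#'   `frequency`, `lambda`.
#' @export
dics_common_filter <- function(csd_pooled, leadfield, lambda = 0.5) {
  if (inherits(leadfield, "sensor_model")) leadfield <- leadfield$leadfield
  Cs <- Re(csd_sensor_block(csd_pooled))
  stopifnot(nrow(Cs) == nrow(leadfield))
  W <- beamformer_weights(Cs, leadfield, lambda)
  structure(list(weights = W, frequency = csd_pooled$frequency,
                 lambda = lambda),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("spatial_filter: %d nodes x %d sensors%s (lambda = %g)\n",
              nrow(x$weights), ncol(x$weights),
              if (!is.null(x$frequency)) sprintf(" at %g Hz", x$frequency)
              else "", x$lambda))
  invisible(x)
}

#' Apply a DICS filter to a condition CSD
#'
#' Node power is `Re(w C w^H)` over the sensor block; when the CSD carries
#' the pitch-reference channel, node--reference magnitude-squared coherence
#' is `|w c_ref|^2 / (power * S_ref)`.
#'
#' @param filter A `spatial_filter` from [dics_common_filter()].
#' @param csd_condition A `csd_matrix` at the same frequency.
#' @return Object of class `source_map`: data frame `node`, `power`, and
#'   `coherence` (NA without a reference), plus `frequency`.
#' @export
apply_filter <- function(filter, csd_condition) {
  if (!is.null(filter$frequency) &&
      abs(filter$frequency - csd_condition$frequency) > 1e-9) {
    stop("apply_filter: frequency mismatch between filter and CSD")
  }
  W <- filter$weights
  Cs <- csd_sensor_block(csd_condition)
  WC <- W %*% Cs
  power <- Re(rowSums(WC * Conj(W)))
  coherence <- rep(NA_real_, nrow(W))
  if (csd_condition$has_reference) {
    n <- nrow(Cs)
    c_ref <- csd_condition$matrix[seq_len(n), n + 1L]
    s_ref <- Re(csd_condition$matrix[n + 1L, n + 1L])
    cross <- as.vector(W %*% c_ref)
    coherence <- Mod(cross)^2 / (power * s_ref)
    coherence[!is.finite(coherence)] <- 0
  }
  structure(list(values = data.frame(node = seq_len(nrow(W)),
                                     power = power,
                                     coherence = coherence),
                 frequency = csd_condition$frequency),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("source_map: %d nodes%s\n", nrow(x$values),
              if (!is.null(x$frequency)) sprintf(" at %g Hz", x$frequency)
              else ""))
  invisible(x)
}

#' LCMV beamforming of condition ERFs
#'
#' Time-domain analog of the DICS pipeline: weights are computed from the
#' covariance of the pooled SHORT-trial epochs (both conditions) with the
#' same regularized inversion, applied to each condition's evoked average,
#' and the node time courses are averaged over the analysis window.
#'
#' @param covariance_pooled Sensors x sensors covariance matrix of the
#'   pooled epochs (see [erf_covariance()]).
#' @param leadfield Sensors x nodes matrix or `sensor_model`.
#' @param lambda Regularization fraction (default 0.05).
#' @param erf_by_condition An `erf_set` (channels x samples per condition).
#' @param window Analysis window in ms (default `c(300, 600)`).
#' @return Object of class `source_map` with one `amplitude_<condition>`
#'   column per condition (windowed node means) plus `window_ms`.
#' @export
lcmv_filter_apply <- function(covariance_pooled, leadfield, lambda = 0.05,
                              erf_by_condition, window = c(300, 600)) {
  if (inherits(leadfield, "sensor_model")) leadfield <- leadfield$leadfield
  W <- beamformer_weights(covariance_pooled, leadfield, lambda)
  times_ms <- erf_by_condition$times * 1000
  sel <- times_ms >= window[1] & times_ms <= window[2]
  if (!any(sel)) stop("lcmv_filter_apply: window outside ERF epoch")
  out <- data.frame(node = seq_len(nrow(W)))
  for (cond in names(erf_by_condition$erf)) {
    tc <- W %*% erf_by_condition$erf[[cond]]     # nodes x samples
    out[[paste0("amplitude_", tolower(cond))]] <-
      rowMeans(tc[, sel, drop = FALSE])
  }
  structure(list(values = out, frequency = NULL, window_ms = window),
            class = "source_map")
}

#' Pooled epoch covariance for LCMV
#'
#' Covariance of the sensor signals over all epochs and time points.
#'
#' @param epochs An [epoch_set()] (e.g. pooled SHORT trials).
#' @return Sensors x sensors covariance matrix.
#' @export
erf_covariance <- function(epochs) {
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2, 1, 3)), d[2], d[1] * d[3])
  X <- X - rowMeans(X)
  (X %*% t(X)) / (ncol(X) - 1)
}

#' Average a source map over atlas regions
#'
#' Mean node value per region and hemisphere for every numeric column of
#' the map.
#'
#' @param map A `source_map`.
#' @param model The `sensor_model` providing node labels.
#' @param drop_fillers Exclude unlabelled filler nodes (default TRUE).
#' @return Data frame `roi`, `hemisphere`, one column per measure.
#' @export
roi_average <- function(map, model, drop_fillers = TRUE) {
  nodes <- model$nodes
  stopifnot(nrow(nodes) == nrow(map$values))
  if (any(is.na(nodes$roi))) stop("roi_average: unlabelled node")
  keep <- if (drop_fillers) nodes$roi != "filler" else rep(TRUE, nrow(nodes))
  vals <- map$values[keep, setdiff(names(map$values), "node"), drop = FALSE]
  g <- interaction(nodes$roi[keep], nodes$hemisphere[keep], drop = TRUE)
  agg <- stats::aggregate(vals, by = list(group = g), FUN = mean)
  parts <- do.call(rbind, strsplit(as.character(agg$group), ".", fixed = TRUE))
  out <- data.frame(roi = parts[, 1], hemisphere = parts[, 2],
                    agg[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Export a source map as TSV
#'
#' @param map A `source_map`.
#' @param model A `sensor_model` for node labels.
#' @param path Output path or `NULL`.
#' @return The long table, invisibly if written.
#' @export
source_map_to_tsv <- function(map, model, path = NULL) {
  d <- data.frame(node = map$values$node,
                  label = model$nodes$label,
                  roi = model$nodes$roi,
                  hemisphere = model$nodes$hemisphere,
                  map$values[setdiff(names(map$values), "node")])
  if (!is.null(path)) {
    utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(d))
  }
  d
}
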