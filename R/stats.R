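# Sensor-space statistics: channel-wise paired t maps, cluster-based
# sign-flip permutation tests over the sensor adjacency graph, the
# rate-specific response (RSR) index, and within-subject interaction
# contrasts on ROI responses.

#' Channel-wise paired t map
#'
#' Classical paired-samples t statistic per channel with df = n - 1.
#' Channels whose paired differences have zero variance get a signed
#' infinite t (with a warning), or 0 if the differences are identically 0.
#'
#' @param valuesA,valuesB Subject x channel matrices, matched shapes.
#' @return Numeric vector of t values (one per channel) with attribute `df`.
#' @export
paired_t_map <- function(valuesA, valuesB) {
  stopifnot(identical(dim(valuesA), dim(valuesB)), nrow(valuesA) >= 2)
  d <- valuesA - valuesB
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  # zero variance up to floating-point noise relative to the data scale
  zero <- s <= 1e-12 * sqrt(colMeans(d^2) + as.numeric(colMeans(d^2) == 0))
  if (any(zero)) {
    t[zero] <- ifelse(m[zero] == 0, 0, sign(m[zero]) * Inf)
    if (any(m[zero] != 0)) {
      warning("paired_t_map: zero-variance differences; t set to signed Inf")
    }
  }
  attr(t, "df") <- n - 1L
  t
}

# connected components of the channel subgraph induced by `members`
# (indices into the adjacency matrix); returns list of index vectors
graph_components <- function(members, adjacency) {
  comp <- list()
  remaining <- members
  while (length(remaining) > 0) {
    queue <- remaining[1]
    seen <- queue
    remaining <- remaining[-1]
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- remaining[adjacency[v, remaining]]
      if (length(nb) > 0) {
        seen <- c(seen, nb)
        queue <- c(queue, nb)
        remaining <- setdiff(remaining, nb)
      }
    }
    comp[[length(comp) + 1L]] <- sort(seen)
  }
  comp
}

# suprathreshold clusters of a t map: per polarity, connected components of
# |t| > threshold with >= min_channels members; returns list of lists
# (members, mass, polarity, peak, peak_t)
find_clusters <- function(tvals, threshold, adjacency, min_channels) {
  out <- list()
  for (pol in c(1, -1)) {
    sup <- which(pol * tvals > threshold)
    if (length(sup) == 0) next
    for (comp in graph_components(sup, adjacency)) {
      if (length(comp) < min_channels) next
      mass <- sum(tvals[comp])
      pk <- comp[which.max(pol * tvals[comp])]
      out[[length(out) + 1L]] <- list(members = comp, mass = mass,
                                      polarity = if (pol > 0) "+" else "-",
                                      peak = pk, peak_t = tvals[pk])
    }
  }
  out
}

# sign matrix for the permutation null: full enumeration of the 2^n flip
# patterns when feasible, otherwise n_perm random rows of +-1
sign_flip_matrix <- function(n_subjects, n_perm) {
  if (2^n_subjects <= n_perm) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_subjects)))
    dimnames(m) <- NULL
    attr(m, "enumerated") <- TRUE
    m
  } else {
    m <- matrix(sample(c(-1, 1), n_perm * n_subjects, replace = TRUE),
                n_perm, n_subjects)
    attr(m, "enumerated") <- FALSE
    m
  }
}

#' Cluster-based sign-flip permutation test over the sensor graph
#'
#' Paired comparison of two subject x channel maps. Channels whose paired t
#' exceeds the two-tailed cluster-forming threshold (quantile of t at
#' `cluster_alpha`) are grouped into connected components per polarity;
#' clusters smaller than `min_channels` are discarded; each cluster's mass
#' is the sum of its member t values. Null distributions of the maximal
#' cluster mass are built per polarity (largest positive mass, largest
#' negative magnitude) by random within-subject sign flips of the paired
#' differences (full enumeration when `2^n <= n_perm`); each observed
#' cluster is compared against its own tail's null and gets the Monte-Carlo
#' p value `(r + 1) / (n_perm + 1)`. By the correct-tail convention a
#' cluster is significant when its p is below `cluster_alpha / 2`;
#' [significant_clusters()] supports both that and the plain
#' `cluster_alpha` reading.
#'
#' @param valuesA,valuesB Subject x channel matrices.
#' @param adjacency Logical channel adjacency matrix (symmetric,
#'   irreflexive), or a `sensor_model`.
#' @param n_perm Number of permutations (default 5000).
#' @param cluster_alpha Two-tailed cluster-forming alpha (default 0.05).
#' @param min_channels Minimum cluster extent in channels (default 3).
#' @param seed Integer seed for the sign flips.
#' @return Object of class `cluster_test`: `clusters` (list with `members`,
#'   `mass`, `polarity`, `p_mc`, `peak`, `peak_t`), `t` (observed map),
#'   `df`, `threshold`, `null_max_mass`, `n_perm` (actual rows used),
#'   `enumerated`.
#' @export
cluster_permutation <- function(valuesA, valuesB, adjacency, n_perm = 5000,
                                cluster_alpha = 0.05, min_channels = 3,
                                seed = 1) {
  if (inherits(adjacency, "sensor_model")) adjacency <- adjacency$adjacency
  stopifnot(ncol(valuesA) == nrow(adjacency))
  if (n_perm < 100) warning("cluster_permutation: n_perm < 100 is unreliable")
  n <- nrow(valuesA)
  d <- valuesA - valuesB
  tobs <- paired_t_map(valuesA, valuesB)
  df <- attr(tobs, "df")
  threshold <- stats::qt(1 - cluster_alpha / 2, df)
  clusters <- find_clusters(tobs, threshold, adjacency, min_channels)

  # permutation null of the maximal |mass|; sign flips leave sum(d^2)
  # per channel unchanged, so t for all flips comes from one matrix product
  ss <- colSums(d^2)
  perm <- withr::with_seed(as.integer(seed), {
    S <- sign_flip_matrix(n, n_perm)
    M <- (S %*% d) / n
    null_max <- apply(M, 1, function(m) {
      s2 <- (ss - n * m^2) / (n - 1)
      tp <- m / sqrt(s2 / n)
      tp[!is.finite(tp)] <- 0
      sup <- find_clusters(tp, threshold, adjacency, min_channels)
      if (length(sup) == 0) return(c(pos = 0, neg = 0))
      mass <- vapply(sup, `[[`, 0, "mass")
      c(pos = max(c(mass[mass > 0], 0)), neg = max(c(-mass[mass < 0], 0)))
    })
    list(null_pos = null_max["pos", ], null_neg = null_max["neg", ],
         enumerated = isTRUE(attr(S, "enumerated")))
  })
  n_used <- length(perm$null_pos)
  for (i in seq_along(clusters)) {
    null_tail <- if (clusters[[i]]$polarity == "+") perm$null_pos
                 else perm$null_neg
    r <- sum(null_tail >= abs(clusters[[i]]$mass))
    clusters[[i]]$p_mc <- (r + 1) / (n_used + 1)
  }
  structure(list(clusters = clusters, t = as.numeric(tobs), df = df,
                 threshold = threshold,
                 null_max_mass = pmax(perm$null_pos, perm$null_neg),
                 null_pos = perm$null_pos, null_neg = perm$null_neg,
                 n_perm = n_used, enumerated = perm$enumerated),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster_test: %d cluster(s), threshold |t| > %.2f (df = %d), %d perms%s\n",
              length(x$clusters), x$threshold, x$df, x$n_perm,
              if (x$enumerated) " (enumerated)" else ""))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %d channels, mass = %.2f, peak t = %.2f, p = %.4f\n",
                cl$polarity, length(cl$members), cl$mass, cl$peak_t, cl$p_mc))
  }
  invisible(x)
}

#' Select significant clusters
#'
#' @param test A `cluster_test`.
#' @param alpha Nominal two-tailed alpha (default 0.05).
#' @param per_tail If `TRUE` (default), compare each cluster's p to
#'   `alpha / 2` (correct-tail convention); otherwise to `alpha`.
#' @return Subset of `test$clusters`.
#' @export
significant_clusters <- function(test, alpha = 0.05, per_tail = TRUE) {
  thr <- if (per_tail) alpha / 2 else alpha
  Filter(function(cl) cl$p_mc <= thr, test$clusters)
}

#' Serialize cluster results to JSON
#'
#' @param test A `cluster_test`.
#' @param path Output path.
#' @export
clusters_to_json <- function(test, path) {
  obj <- list(threshold = test$threshold, df = test$df,
              n_perm = test$n_perm,
              clusters = lapply(test$clusters, function(cl) {
                list(members = cl$members, mass = cl$mass,
                     polarity = cl$polarity, p_mc = cl$p_mc,
                     peak = cl$peak, peak_t = cl$peak_t)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# validate/complete an ROI response table: subject x condition x frequency x
# roi x hemisphere with response column R
check_roi_response <- function(responses) {
  need <- c("subject", "condition", "frequency", "roi", "hemisphere", "R")
  if (!all(need %in% names(responses))) {
    stop("ROI responses need columns: ", paste(need, collapse = ", "))
  }
  cells <- with(responses, table(subject, condition, frequency, roi,
                                 hemisphere))
  if (any(cells != 1)) {
    stop("ROI responses: incomplete or duplicated crossing ",
         "(missing-cell error)")
  }
  invisible(responses)
}

#' Rate-specific response (RSR) index
#'
#' For each subject, region and hemisphere,
#' \deqn{RSR = (R_{0.6,SLOW} - R_{0.6,FAST}) + (R_{0.9,FAST} - R_{0.9,SLOW}),}
#' where R is the response measure (coherence or power) at the two analysis
#' frequencies. RSR > 0 indicates responses that follow the stimulation
#' rate.
#'
#' @param responses Data frame with columns `subject`, `condition`
#'   (SLOW/FAST), `frequency` (0.6/0.9), `roi`, `hemisphere`, `R`; the
#'   crossing must be complete.
#' @return Data frame `subject`, `roi`, `hemisphere`, `rsr`.
#' @export
rsr_index <- function(responses) {
  check_roi_response(responses)
  get <- function(df, f, cond) df$R[df$frequency == f & df$condition == cond]
  out <- do.call(rbind, by(responses,
                           responses[c("subject", "roi", "hemisphere")],
                           function(df) {
    data.frame(subject = df$subject[1], roi = df$roi[1],
               hemisphere = df$hemisphere[1],
               rsr = (get(df, 0.6, "SLOW") - get(df, 0.6, "FAST")) +
                     (get(df, 0.9, "FAST") - get(df, 0.9, "SLOW")))
  }))
  rownames(out) <- NULL
  stopifnot(all(is.finite(out$rsr)))
  out
}

# one-sample sign-flip permutation p for a vector of subject values
sign_flip_p <- function(x, n_perm, seed) {
  n <- length(x)
  tobs <- mean(x) / (stats::sd(x) / sqrt(n))
  if (!is.finite(tobs)) tobs <- 0
  withr::with_seed(as.integer(seed), {
    S <- sign_flip_matrix(n, n_perm)
    m <- (S %*% x) / n
    ss <- sum(x^2)
    s2 <- (ss - n * m^2) / (n - 1)
    tp <- m / sqrt(s2 / n)
    tp[!is.finite(tp)] <- 0
    p <- (sum(abs(tp) >= abs(tobs)) + 1) / (length(tp) + 1)
  })
  list(t = tobs, p = p)
}

#' Condition-by-frequency interaction contrast per region
#'
#' Within-subject difference of differences
#' \eqn{(R_{0.6,SLOW} - R_{0.9,SLOW}) - (R_{0.6,FAST} - R_{0.9,FAST})},
#' tested against zero by a sign-flip permutation per region and
#' hemisphere. The returned table also carries the post-hoc within-condition
#' 0.6-vs-0.9 paired t tests.
#'
#' @param responses ROI response table as in [rsr_index()].
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return Data frame per roi x hemisphere: `contrast` (mean), `t`,
#'   `p_perm`, and post-hoc `t_slow`, `p_slow`, `t_fast`, `p_fast`.
#' @export
interaction_contrast <- function(responses, n_perm = 5000, seed = 1) {
  check_roi_response(responses)
  if (length(unique(responses$subject)) < 2) {
    stop("interaction_contrast: need at least 2 subjects")
  }
  out <- do.call(rbind, by(responses, responses[c("roi", "hemisphere")],
                           function(df) {
    # build per-subject cells explicitly (robust to row order)
    cell <- function(f, cond) {
      x <- df[df$frequency == f & df$condition == cond, ]
      x$R[order(x$subject)]
    }
    d_slow <- cell(0.6, "SLOW") - cell(0.9, "SLOW")
    d_fast <- cell(0.6, "FAST") - cell(0.9, "FAST")
    cst <- d_slow - d_fast
    perm <- sign_flip_p(cst, n_perm, seed)
    ts <- stats::t.test(d_slow)
    tf <- stats::t.test(d_fast)
    data.frame(roi = df$roi[1], hemisphere = df$hemisphere[1],
               contrast = mean(cst), t = perm$t, p_perm = perm$p,
               t_slow = unname(ts$statistic), p_slow = ts$p.value,
               t_fast = unname(tf$statistic), p_fast = tf$p.value)
  }))
  rownames(out) <- NULL
  out
}
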