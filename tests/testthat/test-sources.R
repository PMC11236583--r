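# DICS/LCMV beamforming on the toy forward model.

# direct sensor simulation of one oscillating node plus white noise
planted_epochs <- function(model, node, f, amp = 6, K = 20, dur = 5.19,
                           fs = 250, phase_sd = 0, seed = 1) {
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  data <- array(0, c(K, nrow(model$leadfield), n))
  withr::with_seed(seed, {
    for (k in seq_len(K)) {
      ph <- stats::rnorm(1, 0, phase_sd)
      src <- amp * sin(2 * pi * f * t + ph)
      data[k, , ] <- outer(model$leadfield[, node], src) +
        matrix(stats::rnorm(nrow(model$leadfield) * n),
               nrow(model$leadfield))
    }
  })
  list(epochs = epoch_set(data, fs),
       reference = matrix(sin(2 * pi * f * t), K, n, byrow = TRUE))
}

test_that("the CSD matrix matches a direct per-trial loop oracle", {
  m <- build_sensor_model(n_sensors = 12, n_nodes = 16, seed = 2)
  pe <- planted_epochs(m, 3, 0.6, K = 5, dur = 2, seed = 7)
  csd <- compute_csd(pe$epochs, pe$reference, f = 0.6)
  expect_true(csd$has_reference)
  # independent oracle: direct single-bin DFT sums (taper then implicit
  # zero padding), then the trial-averaged outer product
  d <- dim(pe$epochs$data)
  n <- d[3]; fs <- 250
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  kbin <- 0.6 * 20          # bin index at 20 s padding
  e <- exp(-2i * pi * kbin * (seq_len(n) - 1) / (20 * fs))
  V <- matrix(0i, d[1], d[2] + 1)
  for (k in seq_len(d[1])) {
    for (c in seq_len(d[2])) V[k, c] <- sum(pe$epochs$data[k, c, ] * w * e)
    r <- (pe$reference[k, ] - mean(pe$reference[k, ])) * w
    V[k, d[2] + 1] <- sum(r * e)
  }
  C_o <- (Conj(t(V)) %*% V) / d[1]
  expect_lt(max(Mod(csd$matrix - C_o)), 1e-10 * max(Mod(C_o)))
  # conjugate symmetry and a real non-negative diagonal
  expect_lt(max(Mod(csd$matrix - Conj(t(csd$matrix)))), 1e-10)
  expect_true(all(Re(diag(csd$matrix)) >= 0))
  expect_lt(max(abs(Im(diag(csd$matrix)))), 1e-10)
  expect_error(compute_csd(pe$epochs, pe$reference, f = 0.617), "grid")
})

test_that("noiseless single-source CSD is rank one and reference cross-terms match", {
  m <- build_sensor_model(n_sensors = 12, n_nodes = 16, seed = 2)
  fs <- 250; n <- 500; K <- 6
  t <- (seq_len(n) - 1) / fs
  data <- array(0, c(K, 12, n))
  for (k in seq_len(K)) {
    data[k, , ] <- outer(m$leadfield[, 2], sin(2 * pi * 0.5 * t + k / 3))
  }
  csd <- compute_csd(epoch_set(data, fs), NULL, f = 0.5)
  ev <- eigen(csd$matrix, only.values = TRUE)$values
  expect_lt(Re(ev[2]) / Re(ev[1]), 1e-10)
  # a reference identical to one sensor reproduces that sensor's auto-term
  ref <- matrix(data[, 1, ], K, n)
  ref <- ref - rowMeans(ref)   # compute_csd demeans the reference
  data2 <- data
  for (k in seq_len(K)) data2[k, 1, ] <- ref[k, ]
  csd2 <- compute_csd(epoch_set(data2, fs), ref, f = 0.5)
  ns <- 12
  expect_equal(csd2$matrix[1, ns + 1], csd2$matrix[1, 1], tolerance = 1e-9)
  expect_equal(Re(csd2$matrix[ns + 1, ns + 1]), Re(csd2$matrix[1, 1]),
               tolerance = 1e-9)
})

test_that("DICS weights have the closed form for an identity CSD", {
  m <- build_sensor_model(n_sensors = 20, n_nodes = 16, seed = 4)
  csd <- structure(list(matrix = diag(20) + 0i, frequency = 0.6,
                        n_trials = 10, has_reference = FALSE),
                   class = "csd_matrix")
  filt <- dics_common_filter(csd, m, lambda = 0)
  # w_j proportional to L_j^T when C = I (unit-norm columns: exactly L_j^T)
  for (j in c(1, 5, 10)) {
    expect_equal(as.numeric(filt$weights[j, ]),
                 as.numeric(m$leadfield[, j]), tolerance = 1e-9)
  }
})

test_that("common filters applied to identical condition CSDs give identical maps", {
  m <- build_sensor_model(n_sensors = 20, n_nodes = 16, seed = 4)
  pe <- planted_epochs(m, 4, 0.6, K = 10, dur = 2, seed = 9)
  csd <- compute_csd(pe$epochs, pe$reference, f = 0.6)
  filt <- dics_common_filter(csd, m)
  m1 <- apply_filter(filt, csd)
  m2 <- apply_filter(filt, csd)
  expect_identical(m1$values, m2$values)
  expect_true(all(m1$values$coherence >= 0 & m1$values$coherence <= 1))
  expect_error(apply_filter(filt, compute_csd(pe$epochs, pe$reference,
                                              f = 0.9)), "mismatch")
  # zero CSD gives a zero map
  csd0 <- csd; csd0$matrix[] <- 0i
  map0 <- apply_filter(filt, csd0)
  expect_true(all(map0$values$power == 0))
  expect_true(all(map0$values$coherence == 0))
})

test_that("DICS localizes a planted source and controls depth bias", {
  m <- cached_model()
  node <- roi_nodes(m, "EAC", "R")[1]
  hits <- 0
  for (seed in 1:5) {
    pe <- planted_epochs(m, node, 0.6, phase_sd = 0.4, seed = seed)
    csd <- compute_csd(pe$epochs, pe$reference, f = 0.6)
    filt <- dics_common_filter(csd, m)
    map <- apply_filter(filt, csd)
    top <- which.max(map$values$coherence)
    d <- sqrt(sum((m$nodes[top, c("x", "y", "z")] -
                     m$nodes[node, c("x", "y", "z")])^2))
    if (top == node || d < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # two equal sources at different depths: map values within a factor of 2
  deep <- which.min(sqrt(rowSums(m$nodes[, c("x", "y", "z")]^2)))
  shallow <- which.max(m$nodes$z)
  vals <- vapply(c(deep, shallow), function(j) {
    pe <- planted_epochs(m, j, 0.6, seed = 11)
    csd <- compute_csd(pe$epochs, pe$reference, f = 0.6)
    filt <- dics_common_filter(csd, m)
    apply_filter(filt, csd)$values$power[j]
  }, numeric(1))
  expect_lt(max(vals) / min(vals), 2)
})

test_that("LCMV contrasts vanish for identical ERFs and localize planted ones", {
  m <- cached_model()
  fs <- 250; n <- floor(1.25 * fs)
  times <- -0.25 + (seq_len(n) - 1) / fs
  set.seed(3)
  cov_p <- crossprod(matrix(rnorm(400 * 102), 400)) / 400
  erf <- structure(list(erf = list(SLOW = matrix(rnorm(102 * n), 102),
                                   FAST = NULL),
                        times = times, sample_rate = fs),
                   class = "erf_set")
  erf$erf$FAST <- erf$erf$SLOW
  map <- lcmv_filter_apply(cov_p, m, 0.05, erf, c(300, 600))
  expect_equal(map$values$amplitude_slow, map$values$amplitude_fast)
  # planted node deflection in SLOW only
  node <- roi_nodes(m, "DLPFC", "L")[1]
  lobe <- ifelse(times > 0.3 & times < 0.5,
                 sin(pi * (times - 0.3) / 0.2)^2, 0)
  K <- 30
  data <- array(0, c(K, 102, n))
  for (k in seq_len(K)) {
    data[k, , ] <- matrix(rnorm(102 * n), 102)
    if (k <= K / 2) data[k, , ] <- data[k, , ] +
        outer(m$leadfield[, node], 8 * lobe)
  }
  ep <- epoch_set(data, fs, t0 = -0.25)
  covm <- erf_covariance(ep)
  erf2 <- erf
  erf2$erf$SLOW <- apply(data[seq_len(K / 2), , , drop = FALSE],
                         c(2, 3), mean)
  erf2$erf$FAST <- apply(data[(K / 2 + 1):K, , , drop = FALSE],
                         c(2, 3), mean)
  map2 <- lcmv_filter_apply(covm, m, 0.05, erf2, c(300, 600))
  contrast <- abs(map2$values$amplitude_slow - map2$values$amplitude_fast)
  top <- which.max(contrast)
  d <- sqrt(sum((m$nodes[top, c("x", "y", "z")] -
                   m$nodes[node, c("x", "y", "z")])^2))
  expect_lt(d, 0.3)
})

test_that("ROI averaging reduces node maps correctly", {
  m <- cached_model()
  vals <- data.frame(node = seq_len(nrow(m$nodes)),
                     power = rep(3, nrow(m$nodes)),
                     coherence = rep(0.25, nrow(m$nodes)))
  map <- structure(list(values = vals, frequency = 0.6),
                   class = "source_map")
  roi <- roi_average(map, m)
  # a uniform map averages to the constant in every region
  expect_true(all(roi$power == 3))
  expect_true(all(roi$coherence == 0.25))
  expect_setequal(unique(roi$roi),
                  c("EAC", "STG", "IFG", "FOP", "BA4", "BA6", "DLPFC",
                    "TPOJ"))
  # single-node region equals that node's value
  node <- roi_nodes(m, "TPOJ", "R")
  map$values$power[node] <- 9
  roi2 <- roi_average(map, m)
  expect_equal(roi2$power[roi2$roi == "TPOJ" & roi2$hemisphere == "R"], 9)
  # fillers can be retained, labelled as their own group
  roi3 <- roi_average(map, m, drop_fillers = FALSE)
  expect_true("filler" %in% roi3$roi)
})
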