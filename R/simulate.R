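# Synthetic MEG sessions: a toy spherical sensor array and source space,
# a linear forward model, and planted entrained / sustained / omission
# sources mixed into 1/f sensor noise, with ground truth for recovery tests.

ROI_LABELS <- c("EAC", "STG", "IFG", "FOP", "BA4", "BA6", "DLPFC", "TPOJ")

# canonical ROI seed positions (x: left -/right +, y: posterior -/anterior +,
# z: up), radius ~0.7 inside the unit sensor sphere
roi_seed_positions <- function() {
  p <- rbind(
    EAC   = c(0.62, -0.05, 0.15),
    STG   = c(0.68, -0.15, 0.05),
    IFG   = c(0.55,  0.45, 0.10),
    FOP   = c(0.48,  0.35, 0.00),
    BA4   = c(0.35,  0.00, 0.60),
    BA6   = c(0.30,  0.20, 0.58),
    DLPFC = c(0.40,  0.50, 0.35),
    TPOJ  = c(0.58, -0.45, 0.25)
  )
  colnames(p) <- c("x", "y", "z")
  p
}

# Fibonacci spiral on the upper hemisphere, radius r
hemisphere_points <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # cos(theta) in (0, 1): upper hemisphere
  theta <- acos(z)
  phi <- pi * (1 + sqrt(5)) * i
  r * cbind(x = sin(theta) * cos(phi), y = sin(theta) * sin(phi),
            z = cos(theta))
}

#' Build the toy sensor array and source space
#'
#' 102 sensors on the upper unit hemisphere with a k-nearest-neighbour
#' adjacency graph, and ~90 labelled source nodes inside the sphere. Each of
#' the regions EAC, STG, IFG, FOP, BA4, BA6, DLPFC and TPOJ gets `nodes_per_roi`
#' nodes per hemisphere near a canonical position; remaining nodes are
#' unlabelled fillers. The leadfield maps each node to the sensors with an
#' inverse-square distance falloff times a random fixed-orientation gain;
#' columns are then normalized to unit norm to remove depth bias.
#'
#' @param n_sensors Number of sensors (default 102).
#' @param n_nodes Total number of source nodes (default 90).
#' @param k_neighbors Neighbours per sensor in the adjacency graph.
#' @param nodes_per_roi Nodes per labelled region and hemisphere.
#' @param seed Integer seed (node placement and orientations).
#' @return Object of class `sensor_model`: `sensors` (positions), `nodes`
#'   (data frame with positions, `roi`, `hemisphere`, `label`), `leadfield`
#'   (sensors x nodes, unit-norm columns), `adjacency` (logical sensors x
#'   sensors, symmetric, irreflexive).
#' @export
build_sensor_model <- function(n_sensors = 102, n_nodes = 90,
                               k_neighbors = 6, nodes_per_roi = 1,
                               seed = 42) {
  stopifnot(n_sensors >= 4, n_nodes >= 4)
  sensors <- hemisphere_points(n_sensors, r = 1)
  withr::with_seed(as.integer(seed), {
    seeds <- roi_seed_positions()
    labelled <- list()
    for (roi in rownames(seeds)) {
      for (hemi in c("L", "R")) {
        base <- seeds[roi, ]
        if (hemi == "L") base["x"] <- -base["x"]
        for (j in seq_len(nodes_per_roi)) {
          pos <- base + stats::rnorm(3, 0, 0.05)
          pos["z"] <- abs(pos["z"])
          labelled[[length(labelled) + 1L]] <-
            data.frame(x = pos[1], y = pos[2], z = pos[3], roi = roi,
                       hemisphere = hemi)
        }
      }
    }
    lab <- do.call(rbind, labelled)
    n_fill <- n_nodes - nrow(lab)
    if (n_fill < 0) stop("build_sensor_model: n_nodes too small for ROI set")
    fill <- NULL
    if (n_fill > 0) {
      # fillers uniform in the upper half-ball, radius 0.3-0.8
      u <- matrix(stats::rnorm(3 * n_fill), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- stats::runif(n_fill, 0.3, 0.8)
      pos <- u * rad
      pos[, 3] <- abs(pos[, 3])
      fill <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         roi = "filler",
                         hemisphere = ifelse(pos[, 1] < 0, "L", "R"))
    }
    nodes <- rbind(lab, fill)
    rownames(nodes) <- NULL
    nodes$label <- paste0(ifelse(nodes$roi == "filler", "", tolower(nodes$hemisphere)),
                          nodes$roi,
                          stats::ave(seq_len(nrow(nodes)),
                                     paste(nodes$roi, nodes$hemisphere),
                                     FUN = seq_along))
    # leadfield: inverse-square falloff times fixed random orientation gain
    L <- matrix(0, n_sensors, nrow(nodes))
    for (j in seq_len(nrow(nodes))) {
      o <- stats::rnorm(3); o <- o / sqrt(sum(o^2))
      d <- sweep(sensors, 2, as.numeric(nodes[j, c("x", "y", "z")]))
      dist <- sqrt(rowSums(d^2))
      gain <- (d %*% o) / dist / dist^2
      L[, j] <- gain
    }
    L <- sweep(L, 2, sqrt(colSums(L^2)), "/")   # depth-bias removal
  })
  # k-nearest adjacency, symmetrized
  dd <- as.matrix(stats::dist(sensors))
  adj <- matrix(FALSE, n_sensors, n_sensors)
  for (i in seq_len(n_sensors)) {
    nb <- order(dd[i, ])[2:(k_neighbors + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  structure(list(sensors = sensors, nodes = nodes, leadfield = L,
                 adjacency = adj),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("sensor_model: %d sensors, %d nodes (%d labelled)\n",
              nrow(x$leadfield), ncol(x$leadfield),
              sum(x$nodes$roi != "filler")))
  invisible(x)
}

#' Nodes belonging to a region
#'
#' @param model A `sensor_model`.
#' @param roi Region label (e.g. `"EAC"`).
#' @param hemisphere `"L"` or `"R"`.
#' @return Integer node indices.
#' @export
roi_nodes <- function(model, roi, hemisphere) {
  which(model$nodes$roi == roi & model$nodes$hemisphere == hemisphere)
}

#' Simulation configuration
#'
#' Source amplitudes are in sensor-noise units (the sensor noise standard
#' deviation is 1 by default; physical pT scales do not survive synthesis).
#' Defaults are calibrated so that a 20-subject cohort shows the planted
#' entrainment, sustained-power and omission effects at conventional
#' significance.
#'
#' @param n_subjects Number of virtual subjects.
#' @param n_trials Trials per subject (divisible by 4).
#' @param n_blocks Blocks per session.
#' @param sample_rate Sampling rate in Hz.
#' @param entrain_amp Amplitude of the cycle-locked entrainment source
#'   (right EAC/STG) active during contour presentation.
#' @param sustain_amp Amplitude of the sustained oscillation (left FOP/EAC)
#'   continuing the cycle rate into the sentence phase.
#' @param omission_amp Amplitude of the biphasic omission deflection
#'   (left DLPFC / right TPOJ) in SHORT-after-SLOW trials.
#' @param word_evoked_amp Amplitude of word-onset evoked impulses
#'   (~3.18 Hz confound); 0 disables.
#' @param noise_exponent 1/f^a noise exponent.
#' @param sensor_noise_sd Per-channel noise standard deviation.
#' @param phase_jitter_sd Per-trial entrainment phase jitter (radians at the
#'   cycle rate).
#' @param sustain_phase_sd Per-trial phase drift of the sustained source
#'   relative to the final entrainment cycle (radians); `Inf` (the
#'   default) draws the phase uniformly. The sustained rhythm keeps the
#'   contour *rate* but not a trial-consistent phase: endogenous
#'   oscillations slip phase over seconds, which is also why the sentence
#'   phase is analyzed with power rather than stimulus-locked coherence.
#'   A trial-coherent sustained residual would additionally leak a
#'   condition difference into the omission-window averages, contaminating
#'   the omission contrast's null.
#' @param node_phase_sd Additional per-node, per-trial phase jitter of the
#'   entrained response (radians). Distinct cortical generators are not
#'   perfectly mutually coherent; without this variation an adaptive
#'   beamformer cancels the (then fully correlated) sources.
#' @param amp_jitter_sd Log-normal sd of per-node, per-trial amplitude
#'   gain.
#' @param omission_latency_sd Per-node, per-trial latency jitter of the
#'   omission deflection (s).
#' @param seed Master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20, n_trials = 80, n_blocks = 4,
                       sample_rate = 250,
                       entrain_amp = 6, sustain_amp = 8, omission_amp = 6,
                       word_evoked_amp = 0, noise_exponent = 1,
                       sensor_noise_sd = 1, phase_jitter_sd = 0.4,
                       sustain_phase_sd = Inf, node_phase_sd = 0.7,
                       amp_jitter_sd = 0.3, omission_latency_sd = 0.03,
                       seed = 1) {
  stopifnot(entrain_amp >= 0, sustain_amp >= 0, omission_amp >= 0,
            word_evoked_amp >= 0, sensor_noise_sd >= 0)
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 n_blocks = n_blocks, sample_rate = sample_rate,
                 entrain_amp = entrain_amp, sustain_amp = sustain_amp,
                 omission_amp = omission_amp,
                 word_evoked_amp = word_evoked_amp,
                 noise_exponent = noise_exponent,
                 sensor_noise_sd = sensor_noise_sd,
                 phase_jitter_sd = phase_jitter_sd,
                 sustain_phase_sd = sustain_phase_sd,
                 node_phase_sd = node_phase_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 omission_latency_sd = omission_latency_sd, seed = seed),
            class = "sim_config")
}

#' Lay a session plan out on a continuous timeline
#'
#' Assigns each trial an absolute onset: trials are concatenated in order
#' with a fixed inter-trial interval.
#'
#' @param plan A `session_plan`.
#' @param iti_s Inter-trial interval in seconds.
#' @param edge_s Padding before the first and after the last trial.
#' @return The plan with `$onset_s` set per trial and attributes
#'   `total_duration_s`.
#' @export
layout_session <- function(plan, iti_s = 0.5, edge_s = 2) {
  t <- edge_s
  for (k in seq_along(plan)) {
    plan[[k]]$onset_s <- t
    t <- t + plan[[k]]$duration_ms / 1000 + iti_s
  }
  attr(plan, "total_duration_s") <- t + edge_s
  plan
}

# 1/f^a noise, unit sd, by spectral shaping of white noise; synthesized at
# the next power-of-two length (fast FFT) and truncated to n samples
pink_noise <- function(n, exponent = 1) {
  n2 <- stats::nextn(n, 2)
  nf <- n2 / 2
  f <- seq_len(nf)
  mag <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(real = numeric(n2))
  full[2:(nf + 1)] <- spec
  full[n2:(n2 - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# smooth Hann bump of given center/width (s) sampled on t (s)
hann_bump <- function(t, center, width) {
  u <- (t - center) / width + 0.5
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- 0.5 - 0.5 * cos(2 * pi * u[inside])
  out
}

# unit-RMS cycle-locked source kernel for one condition: the contour's own
# demeaned F0 modulation repeated per cycle (zeros in the pauses), so the
# source has energy at the cycle rate and its harmonics
entrain_kernel <- function(condition, fs) {
  one <- contour_f0(condition, fs)
  mod <- one$f0 - mean(one$f0)
  mod <- mod / sqrt(mean(mod^2))
  cyc_n <- round(cycle_ms(condition) / 1000 * fs)
  k <- numeric(N_REPETITIONS * cyc_n)
  for (r in seq_len(N_REPETITIONS)) {
    k[(r - 1) * cyc_n + seq_along(mod)] <- mod
  }
  k
}

#' Simulate one subject's continuous MEG-like recording
#'
#' Plants, per trial: (i) a cycle-locked periodic source at the right
#' EAC/STG nodes during contour presentation (the contour's own F0
#' modulation repeated each cycle, with per-trial phase jitter), (ii) a
#' sinusoid at the cycle rate at the left FOP/EAC nodes during the sentence
#' phase, continuing the contour-cycle phase up to a zero-mean per-trial
#' drift, (iii) for SHORT
#' sentences after SLOW contours, a biphasic omission deflection (early lobe
#' peaking ~60 ms, late lobe ~400 ms) at left DLPFC / right TPOJ nodes, and
#' optionally (iv) word-onset evoked impulses at posterior filler nodes.
#' Sources are mixed to the sensors through the leadfield and 1/f-plus-white
#' noise is added per channel.
#'
#' @param config A [sim_config()].
#' @param plan A laid-out `session_plan` (see [layout_session()]); a plain
#'   plan is laid out automatically.
#' @param model A [build_sensor_model()] sensor model.
#' @param subject_seed Seed for this subject's noise and jitter.
#' @return Object of class `meg_recording`: `data` (channels x samples),
#'   `sample_rate`, `plan` (laid out), `ground_truth` (active nodes per
#'   phase, condition rates, omission trials, per-trial phase shifts).
#' @export
simulate_subject <- function(config, plan, model,
                             subject_seed = config$seed) {
  fs <- config$sample_rate
  if (fs <= 2 * 3.5) stop("simulate_subject: sample_rate too low")
  if (length(plan) == 0) stop("simulate_subject: empty plan")
  if (is.null(plan[[1]]$onset_s)) plan <- layout_session(plan)
  n_samp <- ceiling(attr(plan, "total_duration_s") * fs)
  n_sens <- nrow(model$leadfield)

  nodes <- list(entrain = c(roi_nodes(model, "EAC", "R"),
                            roi_nodes(model, "STG", "R")),
                sustain = c(roi_nodes(model, "FOP", "L"),
                            roi_nodes(model, "EAC", "L")),
                omission = c(roi_nodes(model, "DLPFC", "L"),
                             roi_nodes(model, "TPOJ", "R")))
  post <- which(model$nodes$roi == "filler")
  nodes$word <- post[order(model$nodes$y[post])[seq_len(min(4, length(post)))]]

  kernels <- list(SLOW = entrain_kernel("SLOW", fs),
                  FAST = entrain_kernel("FAST", fs))

  withr::with_seed(as.integer(subject_seed), {
    src <- matrix(0, length(unique(unlist(nodes))), n_samp)
    src_idx <- unique(unlist(nodes))
    row_of <- function(j) match(j, src_idx)
    phase_shift <- numeric(length(plan))

    for (k in seq_along(plan)) {
      s <- plan[[k]]
      cond <- s$contour_condition
      rate <- cycle_rate_hz(cond, exact = TRUE)
      con_on <- round((s$onset_s + s$contour_onset_ms / 1000) * fs)
      kern <- kernels[[cond]]
      # stimulus-locked phase jitter shared by all generators of the trial,
      # plus per-node jitter and gain (distinct cortical generators are not
      # perfectly mutually coherent)
      dt <- stats::rnorm(1, 0, config$phase_jitter_sd / (2 * pi * rate))
      phase_shift[k] <- dt
      gain <- function() exp(stats::rnorm(1, 0, config$amp_jitter_sd))
      if (config$entrain_amp > 0) {
        for (j in nodes$entrain) {
          dt_n <- dt + stats::rnorm(1, 0,
                                    config$node_phase_sd / (2 * pi * rate))
          idx <- con_on + round(dt_n * fs) + seq_along(kern)
          ok <- idx >= 1 & idx <= n_samp
          src[row_of(j), idx[ok]] <- src[row_of(j), idx[ok]] +
            config$entrain_amp * gain() * kern[ok]
        }
      }
      # sustained oscillation continuing the cycle rate into the sentence
      if (config$sustain_amp > 0) {
        sen_on <- round((s$onset_s + s$sentence_onset_ms / 1000) * fs)
        sen_len <- round((s$duration_ms - s$sentence_onset_ms) / 1000 * fs)
        tt <- (seq_len(sen_len) - 1 + sen_on - con_on) / fs
        idx2 <- sen_on + seq_len(sen_len)
        ok2 <- idx2 >= 1 & idx2 <= n_samp
        for (j in nodes$sustain) {
          drift <- if (is.finite(config$sustain_phase_sd)) {
            stats::rnorm(1, 0, config$sustain_phase_sd)
          } else {
            stats::runif(1, 0, 2 * pi)
          }
          wave <- sin(2 * pi * rate * tt + drift)
          src[row_of(j), idx2[ok2]] <- src[row_of(j), idx2[ok2]] +
            config$sustain_amp * gain() * wave[ok2]
        }
      }
      # omission deflection: SHORT sentence after SLOW contour
      if (config$omission_amp > 0 && s$sentence_length == "SHORT" &&
          cond == "SLOW") {
        om_on <- round((s$onset_s + s$omission_ms / 1000) * fs)
        tt <- (seq_len(round(0.8 * fs)) - 1) / fs
        for (j in nodes$omission) {
          lat <- stats::rnorm(1, 0, config$omission_latency_sd)
          lobe <- hann_bump(tt, 0.06 + lat, 0.12) -
            1.6 * hann_bump(tt, 0.4 + lat, 0.3)
          idx3 <- om_on + seq_along(tt)
          ok3 <- idx3 >= 1 & idx3 <= n_samp
          src[row_of(j), idx3[ok3]] <- src[row_of(j), idx3[ok3]] +
            config$omission_amp * gain() * lobe[ok3]
        }
      }
      # word-evoked impulses (~3.18 Hz during the sentence)
      if (config$word_evoked_amp > 0) {
        won <- s$events[s$events$label == "word_onset", "onset_ms"]
        tt <- (seq_len(round(0.25 * fs)) - 1) / fs
        resp <- hann_bump(tt, 0.1, 0.12)
        for (w in won) {
          w_on <- round((s$onset_s + w / 1000) * fs)
          idx4 <- w_on + seq_along(tt)
          ok4 <- idx4 >= 1 & idx4 <= n_samp
          for (j in nodes$word) {
            src[row_of(j), idx4[ok4]] <- src[row_of(j), idx4[ok4]] +
              config$word_evoked_amp * resp[ok4]
          }
        }
      }
    }

    data <- model$leadfield[, src_idx, drop = FALSE] %*% src
    if (config$sensor_noise_sd > 0) {
      for (ch in seq_len(n_sens)) {
        noise <- 0.9 * pink_noise(n_samp, config$noise_exponent) +
          0.45 * stats::rnorm(n_samp)
        data[ch, ] <- data[ch, ] + config$sensor_noise_sd * noise
      }
    }
  })

  gt <- list(nodes = nodes,
             rates = c(SLOW = cycle_rate_hz("SLOW", exact = TRUE),
                       FAST = cycle_rate_hz("FAST", exact = TRUE)),
             omission_trials = which(vapply(plan, function(s)
               s$sentence_length == "SHORT" &&
                 s$contour_condition == "SLOW", logical(1))),
             phase_shift_s = phase_shift)
  structure(list(data = data, sample_rate = fs, plan = plan,
                 ground_truth = gt),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("meg_recording: %d channels x %d samples @ %g Hz (%d trials)\n",
              nrow(x$data), ncol(x$data), x$sample_rate, length(x$plan)))
  invisible(x)
}

#' Simulate a cohort of virtual subjects
#'
#' Subjects share the design (trial counts, conditions) but have independent
#' trial orders, phase jitter and noise; per-subject seeds are derived from
#' the master seed.
#'
#' @param config A [sim_config()].
#' @param model A sensor model; built with defaults if omitted.
#' @param keep_recordings If `FALSE`, apply `fun` to each recording and keep
#'   only its value (memory-friendly for large cohorts).
#' @param fun Per-subject reduction function `function(recording, subject)`.
#' @return List with `model`, `config` and `subjects` (recordings or `fun`
#'   values).
#' @export
simulate_cohort <- function(config, model = NULL, keep_recordings = TRUE,
                            fun = NULL) {
  stopifnot(config$n_subjects >= 2)
  if (is.null(model)) model <- build_sensor_model(seed = config$seed + 1000L)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sseed <- (config$seed * 1000L + i) %% .Machine$integer.max
    plan <- layout_session(generate_session_plan(config$n_trials,
                                                 config$n_blocks,
                                                 seed = sseed))
    rec <- simulate_subject(config, plan, model, subject_seed = sseed + 1L)
    subjects[[i]] <- if (is.null(fun)) rec else fun(rec, i)
    if (!keep_recordings && is.null(fun)) {
      stop("simulate_cohort: keep_recordings = FALSE requires `fun`")
    }
  }
  list(model = model, config = config, subjects = subjects)
}
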