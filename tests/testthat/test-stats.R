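# Cluster-based sign-flip permutation machinery, RSR and interaction
# contrasts.

make_roi_responses <- function(n_subjects, effect = 0, sd = 1, seed = 1,
                               rois = c("EAC", "STG")) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(n_subjects),
                      condition = c("SLOW", "FAST"),
                      frequency = c(0.6, 0.9), roi = rois,
                      hemisphere = c("L", "R"),
                      stringsAsFactors = FALSE)
  grid$R <- rnorm(nrow(grid), 0, sd)
  # rate-following effect: boost matched condition/frequency pairs
  match <- (grid$condition == "SLOW" & grid$frequency == 0.6) |
    (grid$condition == "FAST" & grid$frequency == 0.9)
  grid$R[match] <- grid$R[match] + effect
  grid
}

test_that("the paired t map equals the classical formula", {
  set.seed(11)
  A <- matrix(rnorm(20 * 15), 20); B <- matrix(rnorm(20 * 15), 20)
  t1 <- paired_t_map(A, B)
  t2 <- vapply(seq_len(15), function(j)
    unname(stats::t.test(A[, j], B[, j], paired = TRUE)$statistic),
    numeric(1))
  expect_equal(as.numeric(t1), t2, tolerance = 1e-12)
  expect_equal(attr(t1, "df"), 19L)
  # identical inputs give zero t
  expect_true(all(paired_t_map(A, A) == 0))
  # constant nonzero differences give a signed infinite sentinel
  A2 <- B; A2[, 3] <- B[, 3] + 1
  expect_warning(t3 <- paired_t_map(A2, B), "zero-variance")
  expect_identical(t3[3], Inf)
})

test_that("cluster permutation finds planted patches and nothing in null data", {
  m <- cached_model()
  # null: no suprathreshold structure survives
  set.seed(21)
  A <- matrix(rnorm(10 * 102), 10)
  ct0 <- cluster_permutation(A, A, m$adjacency, n_perm = 200, seed = 1)
  expect_length(ct0$clusters, 0)
  # planted connected patch, d = 1.5
  patch <- c(7, which(m$adjacency[7, ]))
  for (seed in 1:3) {
    set.seed(100 + seed)
    A <- matrix(rnorm(20 * 102), 20); B <- matrix(rnorm(20 * 102), 20)
    A[, patch] <- A[, patch] + 1.5
    ct <- cluster_permutation(A, B, m$adjacency, n_perm = 1000,
                              seed = seed)
    sig <- significant_clusters(ct)
    expect_gte(length(sig), 1)
    big <- sig[[which.max(vapply(sig, function(cl) abs(cl$mass), 0))]]
    expect_gte(length(intersect(big$members, patch)),
               ceiling(0.8 * length(patch)))
    expect_lte(big$p_mc, 0.01)
    expect_equal(big$polarity, "+")
  }
})

test_that("cluster detection is invariant to channel order and global sign", {
  m <- build_sensor_model(n_sensors = 30, n_nodes = 20, seed = 3)
  set.seed(33)
  patch <- c(4, which(m$adjacency[4, ]))
  A <- matrix(rnorm(15 * 30), 15); B <- matrix(rnorm(15 * 30), 15)
  A[, patch] <- A[, patch] + 1.2
  ct <- cluster_permutation(A, B, m$adjacency, n_perm = 500, seed = 5)
  # reorder channels by a fixed permutation
  perm <- sample(30)
  adj2 <- m$adjacency[perm, perm]
  ct2 <- cluster_permutation(A[, perm], B[, perm], adj2, n_perm = 500,
                             seed = 5)
  mass1 <- sort(vapply(ct$clusters, `[[`, 0, "mass"))
  mass2 <- sort(vapply(ct2$clusters, `[[`, 0, "mass"))
  expect_equal(mass1, mass2, tolerance = 1e-9)
  # global sign flip swaps polarity, preserves |mass| and p
  ct3 <- cluster_permutation(-A, -B, m$adjacency, n_perm = 500, seed = 5)
  expect_equal(sort(abs(vapply(ct3$clusters, `[[`, 0, "mass"))),
               sort(abs(mass1)), tolerance = 1e-9)
  pol <- vapply(ct$clusters, `[[`, "", "polarity")
  pol3 <- vapply(ct3$clusters, `[[`, "", "polarity")
  expect_equal(sort(pol3), sort(ifelse(pol == "+", "-", "+")))
})

test_that("full enumeration agrees with Monte-Carlo sampling within binomial error", {
  m <- build_sensor_model(n_sensors = 30, n_nodes = 20, seed = 3)
  set.seed(44)
  patch <- c(9, which(m$adjacency[9, ]))
  A <- matrix(rnorm(8 * 30), 8); B <- matrix(rnorm(8 * 30), 8)
  A[, patch] <- A[, patch] + 1.4
  ct_full <- cluster_permutation(A, B, m$adjacency, n_perm = 5000, seed = 1)
  expect_true(ct_full$enumerated)          # 2^8 = 256 <= 5000
  expect_equal(ct_full$n_perm, 256)
  suppressWarnings(
    ct_mc <- cluster_permutation(A, B, m$adjacency, n_perm = 200, seed = 2))
  expect_false(ct_mc$enumerated)
  skip_if(length(ct_full$clusters) == 0, "no cluster formed in this draw")
  p_full <- ct_full$clusters[[1]]$p_mc
  p_mc <- ct_mc$clusters[[1]]$p_mc
  se <- sqrt(p_full * (1 - p_full) / 200)
  expect_lt(abs(p_mc - p_full), 3 * se + 1 / 200)
})

test_that("RSR applies the index formula with its symmetries", {
  r <- expand.grid(subject = 1, condition = c("SLOW", "FAST"),
                   frequency = c(0.6, 0.9), roi = "EAC", hemisphere = "R",
                   stringsAsFactors = FALSE)
  r$R <- with(r, ifelse(frequency == 0.6 & condition == "SLOW", 2,
                 ifelse(frequency == 0.6 & condition == "FAST", 1,
                 ifelse(frequency == 0.9 & condition == "FAST", 2, 1))))
  expect_equal(rsr_index(r)$rsr, 2)
  r$R <- 3
  expect_equal(rsr_index(r)$rsr, 0)
  # swapping condition labels negates the index exactly
  r2 <- make_roi_responses(6, effect = 0.4, seed = 2)
  swapped <- r2
  swapped$condition <- ifelse(r2$condition == "SLOW", "FAST", "SLOW")
  expect_equal(rsr_index(swapped)$rsr, -rsr_index(r2)$rsr)
  # missing cell is an explicit error
  expect_error(rsr_index(r2[-1, ]), "missing-cell|incomplete")
})

test_that("interaction contrast recovers planted rate-specific structure", {
  # entrained responses: interaction significant in every region
  r <- make_roi_responses(14, effect = 1.2, sd = 0.5, seed = 3)
  out <- interaction_contrast(r, n_perm = 1000, seed = 1)
  expect_true(all(out$p_perm < 0.05))
  expect_true(all(out$contrast > 0))
  # post-hoc signs mirror the published tables: 0.6 > 0.9 in SLOW, reverse in FAST
  expect_true(all(out$t_slow > 0))
  expect_true(all(out$t_fast < 0))
  # null responses: mean contrast near zero, p not systematically small
  r0 <- make_roi_responses(14, effect = 0, seed = 4)
  out0 <- interaction_contrast(r0, n_perm = 1000, seed = 1)
  expect_lt(mean(abs(out0$contrast)), 1)
  expect_gt(mean(out0$p_perm), 0.2)
  # a single subject is refused
  expect_error(interaction_contrast(make_roi_responses(1, seed = 5)),
               "2 subjects")
})

test_that("permutation p values are valid under the null", {
  # one-channel analog: sign-flip p for zero-mean data is uniform-ish
  set.seed(55)
  n_rep <- 400
  p <- vapply(seq_len(n_rep), function(r) {
    x <- rnorm(10)
    sign_flip_p(x, n_perm = 400, seed = r)$p
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(p <= alpha), alpha + 2.5 * sqrt(alpha / n_rep) + 0.01)
  }
})

test_that("the permutation interaction agrees with a mixed-model cross-check", {
  skip_if_not_installed("lme4")
  r <- make_roi_responses(12, effect = 1, sd = 0.6, seed = 6,
                          rois = "EAC")
  sub <- r[r$roi == "EAC" & r$hemisphere == "R", ]
  out <- interaction_contrast(sub, n_perm = 2000, seed = 2)
  fit <- lme4::lmer(R ~ condition * frequency + (1 | subject), data = sub,
                    REML = TRUE)
  cf <- coef(summary(fit))
  tval <- cf[grep("condition.*frequency", rownames(cf)), "t value"]
  # same hypothesis: both detect the interaction; with treatment coding and
  # FAST as the baseline, the SLOW:frequency slope opposes the contrast
  expect_lt(out$p_perm, 0.05)
  expect_gt(abs(tval), 2)
  expect_equal(sign(out$contrast), -sign(tval))
})
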