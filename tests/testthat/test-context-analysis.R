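traj_set <- function(...) {
  structure(list(...), class = "context_trajectory_set")
}

test_that("pairwise context similarity averages over all unordered pairs", {
  a <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(pairwise_context_similarity(traj_set(a, b), 0), 1)
  expect_equal(pairwise_context_similarity(traj_set(a, b), 1), 1)
  c2 <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(pairwise_context_similarity(traj_set(a, c2), 0), 0)
  # three hand-set vectors: mean of the three pairwise cosines
  v1 <- c(1, 0); v2 <- c(0, 1); v3 <- c(sqrt(2) / 2, sqrt(2) / 2)
  ts3 <- traj_set(rbind(v1), rbind(v2), rbind(v3))
  expect_equal(pairwise_context_similarity(ts3, 0),
               mean(c(0, sqrt(2) / 2, sqrt(2) / 2)))
  expect_error(pairwise_context_similarity(traj_set(a), 0), "2 agents")
  expect_error(pairwise_context_similarity(traj_set(a, b), 5), "exceeds")
})

test_that("context convergence is the late-minus-early similarity difference", {
  # static trajectories converge by 0
  a <- matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE)
  b <- matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE)
  expect_equal(context_convergence(traj_set(a, b), early = 0, late = 2), 0)
  # trajectories drifting toward a common direction converge positively
  t1 <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)), c(0, 1))
  t2 <- rbind(c(-1, 0), c(-sqrt(0.5), sqrt(0.5)), c(0, 1))
  conv <- context_convergence(traj_set(t1, t2), early = 0, late = 2)
  expect_equal(conv, 1 - (-1))
  # toy difference of hand-computed means
  expect_equal(context_convergence(traj_set(t1, t2), early = 0, late = 1),
               0 - (-1))
  expect_error(context_convergence(traj_set(t1, t2), late = 7), "exceeds")
})

test_that("within-subject similarity follows the closed drift form on orthogonal inputs", {
  expect_equal(within_subject_similarity(rbind(c(1, 0), c(1, 0)), after = 1), 1)
  expect_equal(within_subject_similarity(rbind(c(1, 0), c(0, 1)), after = 1), 0)
  # k successive drifts toward mutually orthogonal inputs shrink the starting
  # component by sqrt(1 - beta^2) each step
  beta <- 0.45; k <- 6
  d <- k + 1
  ctx <- c(rep(0, k), 1)
  traj <- matrix(NA_real_, k + 1, d)
  traj[1, ] <- ctx
  for (i in 1:k) {
    cin <- rep(0, d); cin[i] <- 1
    ctx <- drift_context(ctx, cin, beta)
    traj[i + 1, ] <- ctx
  }
  expect_equal(within_subject_similarity(traj, after = k),
               (1 - beta^2)^(k / 2), tolerance = 1e-9)
  expect_error(within_subject_similarity(traj, after = k + 1), "too short")
})

test_that("condition x output ANOVA flags interactions and is calibrated under the null", {
  make_df <- function(mu, n = 10, sd = 0.05, seed = 1) {
    set.seed(seed)
    grid <- expand.grid(condition = c("nominal", "collaborative"),
                        output = c("early", "late"))
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      data.frame(similarity = rnorm(n, mu[i], sd),
                 condition = grid$condition[i], output = grid$output[i])
    }))
  }
  # additive shifts only: big main effects, small interaction
  add <- make_df(c(0.2, 0.5, 0.4, 0.7), n = 50, seed = 2)
  r_add <- condition_output_anova(add)
  expect_gt(r_add$condition$F, 100)
  expect_gt(r_add$output$F, 100)
  expect_gt(r_add$interaction_p, 0.01)
  # crossing pattern (collaborative late boosted): significant interaction
  sig <- vapply(1:100, function(s) {
    condition_output_anova(make_df(c(0.3, 0.3, 0.3, 0.6), n = 20,
                                   seed = 100 + s))$interaction_p < 0.001
  }, logical(1))
  expect_gte(mean(sig), 0.99)
  # null calibration: interaction rejection rate ~ alpha
  rej <- vapply(1:1000, function(s) {
    condition_output_anova(make_df(rep(0.4, 4), n = 8,
                                   seed = 5000 + s))$interaction_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_error(condition_output_anova(add[1, ]), "cell")
})

test_that("group-size permutation test matches exhaustive enumeration for 5 labels", {
  inh <- c(0.01, 0.03, 0.05, 0.08, 0.12)
  sim <- c(0.50, 0.55, 0.61, 0.66, 0.70)   # perfectly concordant
  r <- groupsize_permutation_test(inh, sim, n_perm = 1000)
  expect_true(r$exhaustive)
  expect_identical(r$n_perm, 120L)
  expect_equal(r$statistic, 1)
  expect_equal(r$p, 2 / 120)   # identity and full reversal are the extremes
  # anti-concordant series: same extreme two-sided p
  r2 <- groupsize_permutation_test(inh, rev(sim), n_perm = 1000)
  expect_equal(r2$statistic, -1)
  expect_equal(r2$p, 2 / 120)

  # independent oracle: enumerate all 120 permutations by brute force
  perms <- oracle_all_perms(5)
  stats_all <- apply(perms, 1, function(pm)
    cor(inh[pm], sim, method = "spearman"))
  expect_equal(r$p, mean(abs(stats_all) >= abs(r$statistic) - 1e-12))

  # a middling series reproduces the oracle p exactly as well
  inh2 <- c(0.05, 0.01, 0.08, 0.03, 0.12)
  r3 <- groupsize_permutation_test(inh2, sim, n_perm = 1000)
  stats3 <- apply(perms, 1, function(pm) cor(inh2[pm], sim, method = "spearman"))
  expect_equal(r3$p, mean(abs(stats3) >= abs(r3$statistic) - 1e-12))
  expect_error(groupsize_permutation_test(inh[1:2], sim[1:2]), "at least 3")
})

test_that("sampled permutation p-values are null-calibrated with add-one smoothing", {
  # 8 labels: 8! > 1000 forces the sampled branch
  set.seed(606)
  ps <- vapply(1:200, function(i) {
    r <- groupsize_permutation_test(rnorm(8), rnorm(8), n_perm = 199,
                                    seed = 10000 + i)
    expect_false(r$exhaustive)
    r$p
  }, numeric(1))
  # p approximately uniform: mean near 0.5, mass below 0.25 near a quarter
  expect_lt(abs(mean(ps) - 0.5), 0.09)
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("at p_cue = 0 nominal and collaborative end-of-session context similarity agree", {
  # nominal and collaborative trajectories are aligned on different scales
  # (own recalls vs group events), so the comparable quantity is the pairwise
  # similarity of the final contexts, which is distribution-equal at p_cue = 0
  space <- generate_synthetic_space(20, 16, 4, 0.25, seed = 42)
  p <- cmr_params(p_cue = 0)
  end_sim <- function(t) {
    ctx <- t(vapply(t$trajectories, function(m) m[nrow(m), ],
                    numeric(ncol(t$trajectories[[1]]))))
    s <- tcrossprod(ctx / sqrt(rowSums(ctx^2)))
    mean(s[upper.tri(s)])
  }
  n <- 120L
  d <- vapply(seq_len(n), function(s) {
    end_sim(simulate_nominal_group(space, p, 4, seed = 6000 + s)) -
      end_sim(simulate_collaborative_group(space, p, 4, seed = 6000 + s))
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(n))
})

test_that("trajectory extraction pads by carrying the final context forward", {
  space <- generate_synthetic_space(12, 8, 3, 0.2, seed = 8)
  p <- cmr_params()
  t <- simulate_nominal_group(space, p, 3, seed = 2)
  ts <- context_trajectories(t, length_out = 10)
  for (m in ts) expect_identical(nrow(m), 11L)
  k <- nrow(t$trajectories[[1]])
  if (k < 11) {
    expect_identical(ts[[1]][11, ], t$trajectories[[1]][k, ])
  }
  tc <- simulate_collaborative_group(space, p, 3, seed = 2)
  tsc <- context_trajectories(tc)
  expect_identical(nrow(tsc[[1]]), nrow(tc$events) + 1L)
})
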