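test_that("cmr_params validates bounds and round-trips through JSON", {
  p <- cmr_params()
  expect_s3_class(p, "cmr_params")
  expect_error(cmr_params(beta_enc = 1.2), "beta_enc")
  expect_error(cmr_params(eps_d = 0), "eps_d")
  expect_error(cmr_params(tau = -1), "tau")
  expect_error(cmr_params(p_cue = 2), "p_cue")
  expect_error(update_params(p, bogus = 1), "unknown")

  path <- withr::local_tempfile(fileext = ".json")
  write_cmr_params(update_params(p, beta_rec = 0.31), path)
  p2 <- read_cmr_params(path)
  expect_equal(unclass(p2), unclass(update_params(p, beta_rec = 0.31)))
  jsonlite::write_json(list(beta_enc = 0.5, nonsense = 1), path, auto_unbox = TRUE)
  expect_error(read_cmr_params(path), "nonsense")
})

test_that("init_agent builds the pre-experimental state", {
  # two items at cosine 0.9 plus an orthogonal pair
  v1 <- c(1, 0, 0, 0)
  v2 <- c(0.9, sqrt(1 - 0.81), 0, 0)
  space <- semantic_space(c("a", "b", "c", "d"), rbind(v1, v2, diag(4)[3:4, ]))
  p <- cmr_params(s_sem = 1)
  ag <- init_agent(space, p)
  expect_equal(vnorm_test(ag$context), 1, tolerance = 1e-12)
  # context aligned with item 1: activation of item 2 is s_sem * 0.9, of item 3 is 0
  ctx <- c(v1, 0)
  a <- as.vector(ag$m_cf %*% ctx)
  expect_equal(a[2], 0.9, tolerance = 1e-9)
  expect_equal(a[3], 0.0, tolerance = 1e-12)
  # m_fc retrieves an item's own semantic direction
  expect_equal(unname(ag$m_fc[, 2]), c(v2, 0), tolerance = 1e-12)
  # zero semantic scaling floors all pre-experimental activations
  ag0 <- init_agent(space, cmr_params(s_sem = 0))
  expect_true(all(ag0$m_cf == 0))
  expect_equal(retrieval_activations(ag0), rep(1e-7, 4))
})

test_that("drift_context matches the closed form and preserves unit norm", {
  c0 <- c(1, 0, 0); cin <- c(0, 1, 0)
  expect_equal(drift_context(c0, cin, 0), c0)
  expect_equal(drift_context(c0, cin, 1), cin, tolerance = 1e-12)
  expect_equal(drift_context(c0, cin, 0.5), c(sqrt(0.75), 0.5, 0),
               tolerance = 1e-12)
  expect_error(drift_context(c0, cin, 1.5), "beta")
  expect_error(drift_context(c0, 2 * cin, 0.5), "unit")

  # property: norm preserved for random states, inputs, betas
  set.seed(401)
  for (i in 1:500) {
    d <- sample(2:10, 1)
    a <- rnorm(d); a <- a / vnorm_test(a)
    b <- rnorm(d); b <- b / vnorm_test(b)
    expect_equal(vnorm_test(drift_context(a, b, runif(1))), 1, tolerance = 1e-9)
  }
})

test_that("encode_list applies Hebbian updates with pre-drift context and primacy weighting", {
  space <- orthogonal_space(3)
  p <- cmr_params(gamma_fc = 0, gamma_cf = 0, beta_enc = 0.5)
  ag0 <- init_agent(space, p)
  ag <- encode_list(ag0, c(2, 1, 3), p)
  expect_equal(ag$m_fc, ag0$m_fc)        # zero learning: matrices untouched
  expect_equal(ag$m_cf, ag0$m_cf)
  expect_false(isTRUE(all.equal(ag$context, ag0$context)))  # context drifted
  expect_error(encode_list(ag0, c(1, 1, 2), p), "permutation")

  # no primacy: each studied item's experimental m_cf row gains a unit-norm
  # context, so all rows have equal norm
  p1 <- cmr_params(phi_s = 0, s_sem = 0, gamma_cf = 1)
  ag1 <- encode_list(init_agent(space, p1), 1:3, p1)
  expect_equal(diff(range(sqrt(rowSums(ag1$m_cf^2)))), 0, tolerance = 1e-9)
  # with primacy, earlier positions are boosted
  p2 <- update_params(p1, phi_s = 2, phi_d = 1)
  ag2 <- encode_list(init_agent(space, p2), 1:3, p2)
  rn <- sqrt(rowSums(ag2$m_cf^2))
  expect_true(all(diff(rn) < 0))

  # 2-item closed form: orthogonal items, beta_enc = 0.5, gamma_cf = 1,
  # s_sem = 0 -> end-of-list activations computed by hand matrix algebra
  sp2 <- orthogonal_space(2)
  p3 <- cmr_params(beta_enc = 0.5, gamma_cf = 1, gamma_fc = 0.4, s_sem = 0,
                   phi_s = 0)
  ag3 <- encode_list(init_agent(sp2, p3), 1:2, p3)
  c0 <- c(0, 0, 1)
  c1 <- sqrt(0.75) * c0 + 0.5 * c(1, 0, 0)
  c2 <- sqrt(0.75) * c1 + 0.5 * c(0, 1, 0)
  expect_equal(ag3$context, c2, tolerance = 1e-12)
  a <- retrieval_activations(ag3)
  expect_equal(a, c(sum(c0 * c2), sum(c1 * c2)), tolerance = 1e-12)
})

test_that("retrieval_activations equals the direct matrix-vector product", {
  space <- generate_synthetic_space(3, 4, 3, seed = 5)
  p <- cmr_params()
  ag <- encode_list(init_agent(space, p), c(3, 1, 2), p)
  expect_equal(retrieval_activations(ag),
               pmax(as.vector(ag$m_cf %*% ag$context), 1e-7))
})

test_that("sample_recall follows the power-law Luce rule", {
  set.seed(402)
  draws <- replicate(50000, sample_recall(c(1, 2, 1), tau = 1))
  freq <- tabulate(draws, 3) / 50000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 50000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  # symmetry at equal activations
  draws2 <- replicate(10000, sample_recall(c(2, 2), tau = 3.7))
  expect_lt(abs(mean(draws2 == 1) - 0.5), 3 * sqrt(0.25 / 10000))

  # large tau concentrates on the argmax
  draws3 <- replicate(2000, sample_recall(c(1, 1.5, 1), tau = 80))
  expect_gt(mean(draws3 == 2), 0.999)

  expect_equal(sample_recall(c(1, 5, 1), excluded = c(1, 2), tau = 1), 3)
  expect_error(sample_recall(c(1, 1), excluded = 1:2, tau = 1), "available")
})

test_that("stop_probability has the stated scaling, growth, and cap", {
  p <- cmr_params(eps_d = 0.4, theta_r = 0.1)
  p2 <- update_params(p, eps_d = 0.8)
  expect_equal(stop_probability(3, p2), stop_probability(3, p) / 2)
  pflat <- cmr_params(eps_d = 0.4, theta_r = 0)
  expect_equal(stop_probability(0:10, pflat), rep(0.05 / 0.4, 11))
  pcap <- cmr_params(eps_d = 0.05, theta_r = 0)
  expect_equal(stop_probability(0:5, pcap), rep(1, 6))
  expect_true(all(diff(stop_probability(0:20, p)) >= 0))
  expect_error(stop_probability(-1, p), "output_pos")
})

test_that("recall_item_update drifts toward the item's blended context input", {
  space <- orthogonal_space(4)
  p <- cmr_params(beta_rec = 0.4)
  ag <- encode_list(init_agent(space, p), 1:4, p)
  cin <- ag$m_fc[, 2] / vnorm_test(ag$m_fc[, 2])
  before <- sum(ag$context * cin)
  ag0 <- recall_item_update(ag, 2, update_params(p, beta_rec = 0))
  expect_equal(ag0$context, ag$context)
  ag1 <- recall_item_update(ag, 2, p)
  expect_gt(sum(ag1$context * cin), before)
  # repeated updates converge monotonically to the input direction
  cur <- ag; last <- before
  for (i in 1:25) {
    cur <- recall_item_update(cur, 2, p)
    now <- sum(cur$context * cin)
    expect_gte(now, last - 1e-12)
    last <- now
  }
  expect_gt(last, 0.999)
})

test_that("end-of-list context shows the closed-form recency gradient on orthogonal lists", {
  n <- 8L
  space <- orthogonal_space(n)
  for (beta in c(0.3, 0.6, 0.9)) {
    p <- cmr_params(beta_enc = beta)
    ag <- encode_list(init_agent(space, p), 1:n, p)
    sims <- vapply(1:n, function(i) sum(ag$context * ag$sem[i, ]), numeric(1))
    rho <- sqrt(1 - beta^2)
    expect_equal(sims, beta * rho^(n - (1:n)), tolerance = 1e-9)
    expect_true(all(diff(sims) > 0))
  }
})

test_that("simulate_individual_recall respects the stopping rule edge cases", {
  space <- generate_synthetic_space(6, 8, 2, 0.1, seed = 9)
  # stop probability 1 at position 0 -> empty recall
  p_stop <- cmr_params(eps_d = 0.05, theta_r = 0)
  ag <- encode_list(init_agent(space, p_stop), sample(6), p_stop)
  res <- withr::with_seed(1, simulate_individual_recall(ag, p_stop))
  expect_length(res$recalls, 0)
  expect_identical(nrow(res$trajectory), 1L)
  # stop probability ~0 -> exhaustive recall, a permutation of all items
  p_go <- cmr_params(eps_d = 1e9, theta_r = 0)
  ag2 <- encode_list(init_agent(space, p_go), sample(6), p_go)
  res2 <- withr::with_seed(2, simulate_individual_recall(ag2, p_go))
  expect_setequal(res2$recalls, 1:6)
  expect_identical(anyDuplicated(res2$recalls), 0L)
  expect_identical(nrow(res2$trajectory), 7L)
})

test_that("Monte-Carlo recall distributions match exact enumeration on a 3-item list", {
  vectors <- rbind(c(1, 0, 0), c(0.6, 0.8, 0), c(0, 0, 1))
  space <- semantic_space(c("a", "b", "c"), vectors)
  par <- cmr_params(beta_enc = 0.6, beta_rec = 0.5, gamma_fc = 0.4,
                    gamma_cf = 1, s_sem = 1, tau = 1.5, eps_d = 0.3,
                    theta_r = 0.2)
  order <- c(2L, 3L, 1L)
  exact <- oracle_enumerate_sequences(space$vectors, order, par)
  expect_equal(sum(exact), 1, tolerance = 1e-9)

  n_runs <- 20000L
  ag <- encode_list(init_agent(space, par), order, par)
  keys <- withr::with_seed(707, vapply(seq_len(n_runs), function(i) {
    oracle_key(simulate_individual_recall(ag, par)$recalls)
  }, character(1)))
  # full-sequence distribution within 3 binomial s.e. per outcome
  for (key in names(exact)) {
    pr <- exact[[key]]
    se <- sqrt(pr * (1 - pr) / n_runs)
    expect_lt(abs(mean(keys == key) - pr), max(3 * se, 1e-4))
  }
  # first-recall distribution
  first_exact <- oracle_first_recall(exact, 3L)
  first_mc <- vapply(keys, function(k) {
    parts <- strsplit(k, "-")[[1]]
    if (length(parts) == 1L) 0L else as.integer(parts[2])
  }, integer(1))
  for (i in 0:3) {
    pr <- first_exact[[i + 1L]]
    se <- sqrt(pr * (1 - pr) / n_runs)
    expect_lt(abs(mean(first_mc == i) - pr), max(3 * se, 1e-4))
  }
})

test_that("recall sampling shifts toward items whose contexts are near the last recall", {
  # three items: 1 and 2 semantically close, 3 far; after recalling item 1
  # the exact next-recall probability of item 2 exceeds item 3's
  vectors <- rbind(c(1, 0, 0), c(0.95, sqrt(1 - 0.95^2), 0), c(0, 0, 1))
  space <- semantic_space(c("a", "b", "c"), vectors)
  par <- cmr_params(beta_rec = 0.7, s_sem = 2, tau = 2)
  ag <- encode_list(init_agent(space, par), 1:3, par)
  ratio_23 <- function(agent) {
    w <- retrieval_activations(agent)[2:3]^par$tau
    w[1] / sum(w)
  }
  before <- ratio_23(ag)
  after <- ratio_23(recall_item_update(ag, 1, par))
  expect_gt(after, before)
  expect_gt(after, 0.5)
})
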