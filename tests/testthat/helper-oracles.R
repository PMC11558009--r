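# Independent oracles used by the tests. These deliberately re-derive the
# model math from the written formulas (not from package internals) so that
# the Monte-Carlo simulators can be checked against exact enumeration.

# --- tiny fixture spaces -----------------------------------------------------

# Orthonormal space: item i = e_i in R^n (all pairwise cosines 0).
orthogonal_space <- function(n) {
  semantic_space(sprintf("o%02d", seq_len(n)), diag(n))
}

# Two tight clusters of items in a low-dimensional space.
two_cluster_space <- function(per_cluster = 3L, dim = 8L, spread = 0.05,
                              seed = 11L) {
  generate_synthetic_space(2L * per_cluster, dim, n_clusters = 2L,
                           cluster_spread = spread, seed = seed)
}

# --- independent model enumeration ------------------------------------------

oracle_drift <- function(ctx, cin, beta) {
  cd <- sum(ctx * cin)
  rho <- sqrt(1 + beta^2 * (cd^2 - 1)) - beta * cd
  v <- rho * ctx + beta * cin
  v / sqrt(sum(v * v))
}

# Encode a study list from scratch, straight from the update equations.
oracle_encode <- function(vectors, order, par) {
  n <- nrow(vectors); d <- ncol(vectors)
  sem <- cbind(vectors, 0)
  m_fc <- t(sem)
  m_cf <- par$s_sem * sem
  ctx <- c(rep(0, d), 1)
  for (p in seq_along(order)) {
    i <- order[[p]]
    m_fc[, i] <- m_fc[, i] + par$gamma_fc * ctx
    phi <- 1 + par$phi_s * exp(-par$phi_d * (p - 1))
    m_cf[i, ] <- m_cf[i, ] + phi * par$gamma_cf * ctx
    ctx <- oracle_drift(ctx, sem[i, ], par$beta_enc)
  }
  list(m_fc = m_fc, m_cf = m_cf, ctx = ctx, sem = sem)
}

oracle_stop_p <- function(pos, par) {
  min(1, (par$theta0 / par$eps_d) * exp(par$theta_r * pos))
}

# Exact probability of every possible recall sequence (including the empty
# one) for a small list, by exhaustive enumeration of the generative process.
# Returns a named numeric vector; names are "-"-joined item sequences
# prefixed with "k" (so the empty sequence is "k"); see oracle_key().
oracle_key <- function(recalls) paste(c("k", recalls), collapse = "-")

oracle_enumerate_sequences <- function(vectors, order, par, a_min = 1e-7) {
  st <- oracle_encode(vectors, order, par)
  n <- nrow(vectors)
  probs <- new.env(parent = emptyenv())
  add <- function(key, p) {
    assign(key, p + (if (exists(key, envir = probs)) get(key, envir = probs) else 0),
           envir = probs)
  }
  recurse <- function(ctx, recalled, prob, pos) {
    key <- oracle_key(recalled)
    if (length(recalled) >= n) { add(key, prob); return(invisible()) }
    ps <- oracle_stop_p(pos, par)
    add(key, prob * ps)
    if (ps >= 1) return(invisible())
    a <- pmax(as.vector(st$m_cf %*% ctx), a_min)
    avail <- setdiff(seq_len(n), recalled)
    w <- a[avail]^par$tau
    w <- w / sum(w)
    for (k in seq_along(avail)) {
      i <- avail[[k]]
      cin <- st$m_fc[, i] / sqrt(sum(st$m_fc[, i]^2))
      recurse(oracle_drift(ctx, cin, par$beta_rec), c(recalled, i),
              prob * (1 - ps) * w[[k]], pos + 1L)
    }
  }
  recurse(st$ctx, integer(0), 1, 0L)
  vapply(ls(probs, all.names = TRUE), get, numeric(1L), envir = probs)
}

# First-recall distribution implied by the exact sequence enumeration
# (index 0 = stopped before any recall).
oracle_first_recall <- function(seq_probs, n) {
  first <- numeric(n + 1L)
  for (key in names(seq_probs)) {
    parts <- strsplit(key, "-")[[1L]]
    if (length(parts) == 1L) {
      first[[1L]] <- first[[1L]] + seq_probs[[key]]
    } else {
      i <- as.integer(parts[[2L]])
      first[[i + 1L]] <- first[[i + 1L]] + seq_probs[[key]]
    }
  }
  first
}

# --- independent permutation enumeration -------------------------------------

# All permutations of 1:k via expand.grid filtering (independent of the
# package's recursive generator).
oracle_all_perms <- function(k) {
  g <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  g[apply(g, 1L, function(r) length(unique(r)) == k), , drop = FALSE]
}

vnorm_test <- function(x) sqrt(sum(x^2))

# --- misc --------------------------------------------------------------------

# Build a transcript by hand (for metric oracles).
make_transcript <- function(condition, list_length, study_orders, recalls,
                            trajectories = NULL) {
  events <- do.call(rbind, lapply(seq_along(recalls), function(a) {
    r <- recalls[[a]]
    if (length(r) == 0L) return(NULL)
    data.frame(round = seq_along(r), turn = 0L, agent = a, action = "recall",
               item = r, novel = NA, stringsAsFactors = FALSE)
  }))
  if (is.null(events)) events <- comra:::empty_events()
  events$novel <- !duplicated(events$item)
  comra:::new_group_transcript(condition, length(study_orders), list_length,
                               events, study_orders, trajectories,
                               stop_round = lengths(recalls))
}
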