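# Context-dynamics analyses: how similar group members' mental contexts are
# across recall outputs, how much they converge, how much context space one
# individual traverses, and how these quantities relate to performance.

#' Extract aligned context trajectories from a transcript
#'
#' Returns a `context_trajectory_set`: one matrix per agent whose row `k + 1`
#' is the agent's context at output position `k` (row 1 = start of recall).
#' Nominal agents are aligned by their own recall count; collaborative agents
#' by the group's recall-event count (contexts evolve per condition at those
#' granularities). Trajectories are padded by carrying the final context
#' forward — after an agent stops, its context no longer changes — and, if
#' `length_out` is given, padded/truncated to exactly `length_out + 1` rows.
#'
#' @param transcript A `group_transcript` carrying trajectories.
#' @param length_out Optional last output position to align to.
#' @return A list of (T+1) x (d+1) matrices, class `context_trajectory_set`.
#' @export
context_trajectories <- function(transcript, length_out = NULL) {
  stopifnot(inherits(transcript, "group_transcript"))
  if (is.null(transcript$trajectories)) {
    stop_arg("transcript carries no context trajectories")
  }
  trajs <- transcript$trajectories
  target <- if (is.null(length_out)) {
    max(vapply(trajs, nrow, integer(1L)))
  } else check_count(length_out, "length_out", min = 0L) + 1L
  out <- lapply(trajs, function(m) {
    if (nrow(m) < target) {
      pad <- matrix(m[nrow(m), ], target - nrow(m), ncol(m), byrow = TRUE)
      m <- rbind(m, pad)
    }
    m[seq_len(target), , drop = FALSE]
  })
  structure(out, class = "context_trajectory_set")
}

check_trajectory_set <- function(ts) {
  if (!inherits(ts, "context_trajectory_set")) {
    stopifnot(is.list(ts))
    lens <- vapply(ts, nrow, integer(1L))
    if (length(unique(lens)) != 1L) {
      stop_arg("trajectories must share alignment length")
    }
    ts <- structure(ts, class = "context_trajectory_set")
  }
  ts
}

#' Mean pairwise between-member context similarity at an output position
#'
#' Mean cosine over all unordered agent pairs between their context vectors
#' at the given output position (0 = start of recall).
#'
#' @param ts A `context_trajectory_set` (or list of aligned matrices).
#' @param output_pos Output position, 0-based.
#' @return Mean cosine.
#' @export
pairwise_context_similarity <- function(ts, output_pos) {
  ts <- check_trajectory_set(ts)
  if (length(ts) < 2L) stop_arg("need at least 2 agents for pairwise similarity")
  output_pos <- check_count(output_pos, "output_pos", min = 0L)
  T_max <- nrow(ts[[1L]]) - 1L
  if (output_pos > T_max) {
    stop_arg("output_pos %d exceeds trajectory length %d", output_pos, T_max)
  }
  ctx <- t(vapply(ts, function(m) m[output_pos + 1L, ], numeric(ncol(ts[[1L]]))))
  ctx <- ctx / sqrt(rowSums(ctx^2))
  sim <- tcrossprod(ctx)
  mean(sim[upper.tri(sim)])
}

#' Context convergence of a group
#'
#' Change in mean pairwise context similarity from an early to a late output
#' position (defaults 0 and 10): how much closer group members' contexts got
#' over the first stretch of recall.
#'
#' @inheritParams pairwise_context_similarity
#' @param early,late Output positions (late > early; late must not exceed the
#'   trajectory length).
#' @return `pairwise_context_similarity(ts, late) -
#'   pairwise_context_similarity(ts, early)`.
#' @export
context_convergence <- function(ts, early = 0L, late = 10L) {
  pairwise_context_similarity(ts, late) - pairwise_context_similarity(ts, early)
}

#' Within-subject context similarity
#'
#' Cosine between one agent's start-of-recall context and its context after
#' `after` output positions. Higher similarity means less of the context
#' space was traversed during recall.
#'
#' @param trajectory A (T+1) x (d+1) snapshot matrix for one agent.
#' @param after Output position to compare against the start (default 10).
#' @return Cosine in \[-1, 1\].
#' @export
within_subject_similarity <- function(trajectory, after = 10L) {
  trajectory <- as.matrix(trajectory)
  after <- check_count(after, "after", min = 1L)
  if (nrow(trajectory) < after + 1L) {
    stop_arg("trajectory too short: need %d snapshots, have %d",
             after + 1L, nrow(trajectory))
  }
  a <- unit(trajectory[1L, ]); b <- unit(trajectory[after + 1L, ])
  sum(a * b)
}

#' Two-way ANOVA of context similarity by condition and output position
#'
#' Fixed-effects ANOVA with interaction on per-group similarity values
#' labeled by condition and output stage (early/late). The interaction term
#' tests whether the early-to-late similarity change differs across
#' conditions.
#'
#' @param data data.frame with numeric `similarity` and factors `condition`
#'   and `output` (each >= 2 observations per cell).
#' @return List with a row per term (`condition`, `output`,
#'   `condition:output`), each holding `F`, `df1`, `df2`, `p`; the
#'   interaction is also exposed as `interaction_F` / `interaction_p`.
#' @export
condition_output_anova <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("similarity", "condition", "output")
  if (!all(need %in% names(data))) {
    stop_arg("`data` must have columns: %s", paste(need, collapse = ", "))
  }
  data$condition <- factor(data$condition)
  data$output <- factor(data$output)
  cells <- table(data$condition, data$output)
  if (any(cells < 2L)) stop_arg("every condition x output cell needs >= 2 observations")
  fit <- stats::aov(similarity ~ condition * output, data = data)
  tab <- summary(fit)[[1L]]
  terms <- trimws(rownames(tab))
  df2 <- tab[terms == "Residuals", "Df"]
  get_term <- function(nm) {
    i <- which(terms == nm)
    list(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = df2,
         p = tab[i, "Pr(>F)"])
  }
  out <- list(condition = get_term("condition"),
              output = get_term("output"),
              interaction = get_term("condition:output"))
  out$interaction_F <- out$interaction$F
  out$interaction_p <- out$interaction$p
  out
}

#' Convergence-performance correlation across groups
#'
#' Simulates `n_groups` collaborative groups whose listening probability is
#' drawn uniformly from \[0, 1\] (one draw per group), computes each group's
#' context convergence (output 0 to `late`) and proportion recalled, and
#' returns the Spearman rank correlation between the two.
#'
#' @param space A [semantic_space()].
#' @param params A [cmr_params()] (its `p_cue` is overridden per group).
#' @param group_size Collaborative group size (>= 2).
#' @param n_groups Number of groups (>= 10).
#' @param late Late output position for convergence (default 10).
#' @param seed Integer seed.
#' @return List with `rho`, `p`, and `data` (per-group `p_cue`,
#'   `convergence`, `prop_recalled`).
#' @export
convergence_performance_correlation <- function(space, params, group_size,
                                                n_groups = 100L, late = 10L,
                                                seed = NULL) {
  n_groups <- check_count(n_groups, "n_groups", min = 10L)
  with_seed(seed, {
    p_cues <- stats::runif(n_groups)
    conv <- numeric(n_groups); perf <- numeric(n_groups)
    for (g in seq_len(n_groups)) {
      t <- simulate_collaborative_group(space,
                                        update_params(params, p_cue = p_cues[[g]]),
                                        group_size)
      ts <- context_trajectories(t, length_out = late)
      conv[[g]] <- context_convergence(ts, early = 0L, late = late)
      perf[[g]] <- proportion_recalled(t)
    }
    ct <- suppressWarnings(stats::cor.test(conv, perf, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value,
         data = data.frame(p_cue = p_cues, convergence = conv,
                           prop_recalled = perf))
  })
}

#' Permutation test of the inhibition / within-subject-similarity association
#'
#' Observed statistic: Spearman correlation between per-group-size mean
#' inhibition and per-group-size mean within-subject context similarity. The
#' null distribution shuffles the group-size labels of one series. When all
#' `factorial(n)` label permutations fit within `n_perm` the test enumerates
#' them exhaustively (p = fraction of permutations with `|stat| >= |observed|`,
#' identity included); otherwise it samples `n_perm` permutations and applies
#' add-one smoothing: `p = (1 + #extreme) / (1 + n_perm)`. Two-sided.
#'
#' @param inhibition Per-size mean inhibition (>= 3 sizes).
#' @param similarity Per-size mean within-subject similarity, same order.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (sampled variant only).
#' @return List with `statistic` (observed Spearman rho), `p`, `exhaustive`,
#'   and `n_perm` (permutations actually used).
#' @export
groupsize_permutation_test <- function(inhibition, similarity,
                                       n_perm = 1000L, seed = NULL) {
  if (length(inhibition) != length(similarity)) {
    stop_arg("series must have equal length")
  }
  k <- length(inhibition)
  if (k < 3L) stop_arg("need at least 3 group sizes")
  n_perm <- check_count(n_perm, "n_perm")
  obs <- stats::cor(inhibition, similarity, method = "spearman")
  stat_for <- function(perm) {
    stats::cor(inhibition[perm], similarity, method = "spearman")
  }
  n_total <- factorial(k)
  if (n_total <= n_perm) {
    perms <- all_permutations(k)
    stats_all <- vapply(perms, stat_for, numeric(1L))
    p <- mean(abs(stats_all) >= abs(obs) - 1e-12)
    list(statistic = obs, p = p, exhaustive = TRUE, n_perm = length(perms))
  } else {
    p <- with_seed(seed, {
      extreme <- 0L
      for (i in seq_len(n_perm)) {
        if (abs(stat_for(sample.int(k))) >= abs(obs) - 1e-12) {
          extreme <- extreme + 1L
        }
      }
      (1 + extreme) / (1 + n_perm)
    })
    list(statistic = obs, p = p, exhaustive = FALSE, n_perm = n_perm)
  }
}

# All permutations of 1:k as a list (k small; used for exhaustive tests).
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (s in sub) {
      out[[idx]] <- c(i, rest[s])
      idx <- idx + 1L
    }
  }
  out
}
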