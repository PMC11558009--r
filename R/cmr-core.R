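# Individual-level retrieved-context model: a slowly drifting context vector
# is bound to items at study by Hebbian outer-product learning and cues
# retrieval at test. The context lives in R^(d+1): the item-embedding
# dimensions plus one extra "start-of-session" dimension, orthogonal to every
# item, so the first studied item has a well-defined association target.

#' Initialize an agent
#'
#' Builds the pre-experimental state of one simulated individual over a
#' semantic space: a unit start-of-session context orthogonal to all item
#' directions; a feature-to-context matrix `m_fc` whose column i is item i's
#' semantic direction (an item's feature retrieves its own meaning); and a
#' context-to-item matrix `m_cf` pre-loaded with scaled semantic
#' associations, so that a context aligned with item i activates item j by
#' `s_sem * cosine(i, j)`.
#'
#' @param space A [semantic_space()].
#' @param params A [cmr_params()].
#' @return An object of class `cmr_agent` with fields `context` (unit vector,
#'   length d + 1), `m_fc` ((d+1) x n), `m_cf` (n x (d+1)), `sem` (the item
#'   semantic directions, n x (d+1)), `recalled_own`, `heard`, `stopped`,
#'   and `study_order` (set by [encode_list()]).
#' @export
init_agent <- function(space, params) {
  stopifnot(inherits(space, "semantic_space"), inherits(params, "cmr_params"))
  n <- n_items(space)
  d <- ncol(space$vectors)
  sem <- cbind(space$vectors, 0)            # n x (d+1): items span dims 1..d
  context <- c(rep(0, d), 1)                # start-of-session direction
  structure(list(
    context = context,
    m_fc = t(sem),                          # (d+1) x n
    m_cf = params$s_sem * sem,              # n x (d+1)
    sem = sem,
    recalled_own = integer(0),
    heard = integer(0),
    stopped = FALSE,
    study_order = NULL,
    n = n
  ), class = "cmr_agent")
}

#' @export
print.cmr_agent <- function(x, ...) {
  cat(sprintf("<cmr_agent> %d items, %s, %d own recalls\n", x$n,
              if (is.null(x$study_order)) "not encoded" else "encoded",
              length(x$recalled_own)))
  invisible(x)
}

#' Drift a context vector toward an input
#'
#' Implements the norm-preserving context update
#' `c_new = rho * c + beta * c_in` with
#' `rho = sqrt(1 + beta^2 * ((c . c_in)^2 - 1)) - beta * (c . c_in)`,
#' so that `||c_new|| = 1` whenever `c` and `c_in` are unit vectors.
#' `beta = 0` leaves the context unchanged; `beta = 1` with orthogonal input
#' replaces it entirely.
#'
#' @param context Unit context vector.
#' @param c_in Unit input vector of the same length.
#' @param beta Drift rate in \[0, 1\].
#' @return The updated unit context vector.
#' @export
drift_context <- function(context, c_in, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop_arg("`beta` must be a single number in [0, 1]")
  }
  if (length(context) != length(c_in)) {
    stop_arg("`context` and `c_in` must have the same length")
  }
  if (abs(vnorm(c_in) - 1) > 1e-6) stop_arg("`c_in` must be a unit vector")
  cdot <- sum(context * c_in)
  rho <- sqrt(pmax(0, 1 + beta^2 * (cdot^2 - 1))) - beta * cdot
  out <- rho * context + beta * c_in
  # guard against accumulated rounding over long sessions
  out / vnorm(out)
}

#' Encode a study list
#'
#' Presents the items in `order` one at a time. For the item at position p:
#' `m_fc[, item] += gamma_fc * context` and
#' `m_cf[item, ] += phi(p) * gamma_cf * context`, with primacy boost
#' `phi(p) = 1 + phi_s * exp(-phi_d * (p - 1))`, both using the context
#' *before* the drift for that item; the context then drifts toward the
#' item's semantic direction at rate `beta_enc`.
#'
#' @param agent A `cmr_agent` from [init_agent()].
#' @param order Integer permutation of `1:n` — this agent's randomized study
#'   order.
#' @param params A [cmr_params()].
#' @return The updated agent, with `study_order` recorded.
#' @export
encode_list <- function(agent, order, params) {
  stopifnot(inherits(agent, "cmr_agent"), inherits(params, "cmr_params"))
  order <- as.integer(order)
  if (length(order) != agent$n || !setequal(order, seq_len(agent$n))) {
    stop_arg("`order` must be a permutation of 1:%d", agent$n)
  }
  ctx <- agent$context
  for (p in seq_along(order)) {
    i <- order[[p]]
    agent$m_fc[, i] <- agent$m_fc[, i] + params$gamma_fc * ctx
    phi <- 1 + params$phi_s * exp(-params$phi_d * (p - 1))
    agent$m_cf[i, ] <- agent$m_cf[i, ] + phi * params$gamma_cf * ctx
    ctx <- drift_context(ctx, agent$sem[i, ], params$beta_enc)
  }
  agent$context <- ctx
  agent$study_order <- order
  agent
}

#' Context-cued item activations
#'
#' `a = m_cf %*% context`, combining experimental and pre-experimental
#' (semantic) support, floored elementwise at `a_min` so the sampling rule
#' stays well-defined.
#'
#' @param agent An encoded `cmr_agent`.
#' @param a_min Small positive activation floor.
#' @return Nonnegative numeric vector of length n.
#' @export
retrieval_activations <- function(agent, a_min = 1e-7) {
  stopifnot(inherits(agent, "cmr_agent"))
  a <- as.vector(agent$m_cf %*% agent$context)
  pmax(a, a_min)
}

#' Sample the next recall
#'
#' Power-law Luce choice: item i is drawn with probability
#' `a_i^tau / sum_j a_j^tau` over the non-excluded items. Uses the current
#' RNG stream.
#'
#' @param a Nonnegative activation vector.
#' @param excluded Integer indices unavailable for recall (e.g. the agent's
#'   own prior recalls).
#' @param tau Choice sensitivity (> 0).
#' @return The sampled item index.
#' @export
sample_recall <- function(a, excluded = integer(0), tau = 1) {
  if (tau <= 0) stop_arg("`tau` must be positive")
  avail <- setdiff(seq_along(a), excluded)
  if (length(avail) == 0L) stop_arg("no items available to recall")
  if (length(avail) == 1L) return(avail)
  w <- (a[avail] / max(a[avail]))^tau
  avail[sample.int(length(avail), 1L, prob = w)]
}

#' Stopping probability at an output position
#'
#' `min(1, (theta0 / eps_d) * exp(theta_r * output_pos))`: strictly
#' decreasing in `eps_d` (below the cap) and nondecreasing in output
#' position. Smaller `eps_d` means a larger stopping probability and fewer
#' recalls.
#'
#' @param output_pos Number of recall attempts already made (>= 0).
#' @param params A [cmr_params()] (uses `eps_d`, `theta_r`, `theta0`).
#' @return A probability.
#' @export
stop_probability <- function(output_pos, params) {
  stopifnot(inherits(params, "cmr_params"))
  if (any(output_pos < 0)) stop_arg("`output_pos` must be >= 0")
  pmin(1, (params$theta0 / params$eps_d) * exp(params$theta_r * output_pos))
}

# Retrieved context input for an item: its semantic direction blended with
# the study context(s) stored in m_fc, normalized to unit length.
context_input <- function(agent, item) {
  unit(agent$m_fc[, item], what = sprintf("context input of item %d", item))
}

#' Update context after recalling or attending to an item
#'
#' Drifts the agent's context toward the item's retrieved context input
#' (the unit-normalized column of `m_fc`: semantic direction blended with
#' stored study context) at rate `beta_rec`. This same pathway is used both
#' when the agent recalls the item itself and when it attends to another
#' group member's recall as a listener — that shared pathway is the model's
#' central collaborative mechanism.
#'
#' @param agent An encoded `cmr_agent`.
#' @param item Item index.
#' @param params A [cmr_params()].
#' @return The updated agent.
#' @export
recall_item_update <- function(agent, item, params) {
  stopifnot(inherits(agent, "cmr_agent"), inherits(params, "cmr_params"))
  item <- check_count(item, "item")
  if (item > agent$n) stop_arg("item index out of range (n = %d)", agent$n)
  agent$context <- drift_context(agent$context, context_input(agent, item),
                                 params$beta_rec)
  agent
}

#' Simulate one individual's recall session
#'
#' Starting from the end-of-study context, repeatedly: stop with
#' [stop_probability()] at the current output position; otherwise sample one
#' not-yet-recalled item via [sample_recall()], append it, and drift context
#' toward it with [recall_item_update()]. Recall also ends when the list is
#' exhausted. Uses the current RNG stream.
#'
#' @param agent An encoded `cmr_agent`.
#' @param params A [cmr_params()].
#' @param stop_uniforms Optional pre-drawn uniforms, one per potential output
#'   position (length >= n): the agent stops at position k when
#'   `stop_uniforms[k + 1] < stop_probability(k, params)`. Pre-drawing the
#'   stop stream is distributionally identical to drawing it live and lets
#'   paired nominal/collaborative simulations share stop decisions (common
#'   random numbers).
#' @return A list with `recalls` (integer vector, no duplicates), `agent`
#'   (final state, `stopped = TRUE`), and `trajectory` (a (k+1) x (d+1)
#'   matrix of context snapshots: start of recall, then after each recall).
#' @export
simulate_individual_recall <- function(agent, params, stop_uniforms = NULL) {
  stopifnot(inherits(agent, "cmr_agent"), inherits(params, "cmr_params"))
  if (is.null(agent$study_order)) stop_arg("agent has not encoded a list")
  n <- agent$n
  if (!is.null(stop_uniforms) && length(stop_uniforms) < n) {
    stop_arg("`stop_uniforms` must have length >= %d", n)
  }
  traj <- matrix(NA_real_, n + 1L, length(agent$context))
  traj[1L, ] <- agent$context
  recalls <- integer(0)
  pos <- 0L
  repeat {
    if (length(recalls) >= n) break
    u <- if (is.null(stop_uniforms)) stats::runif(1L) else stop_uniforms[[pos + 1L]]
    if (u < stop_probability(pos, params)) break
    a <- retrieval_activations(agent)
    item <- sample_recall(a, excluded = recalls, tau = params$tau)
    recalls <- c(recalls, item)
    agent <- recall_item_update(agent, item, params)
    traj[length(recalls) + 1L, ] <- agent$context
    pos <- pos + 1L
  }
  agent$recalled_own <- recalls
  agent$stopped <- TRUE
  list(recalls = recalls, agent = agent,
       trajectory = traj[seq_len(length(recalls) + 1L), , drop = FALSE])
}
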