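# Group-level simulation of the turn-taking free-recall protocol: nominal
# groups (independent individuals, later pooled) and collaborative groups
# (rounds of turns; each novel recall is broadcast and probabilistically
# attended to by the other active members).

new_group_transcript <- function(condition, group_size, list_length, events,
                                 study_orders, trajectories, stop_round) {
  structure(list(
    condition = condition,
    group_size = as.integer(group_size),
    list_length = as.integer(list_length),
    events = events,
    study_orders = study_orders,
    trajectories = trajectories,
    stop_round = stop_round
  ), class = "group_transcript")
}

#' @export
print.group_transcript <- function(x, ...) {
  cat(sprintf("<group_transcript> %s, size %d, L = %d, %d recall events, %d unique\n",
              x$condition, x$group_size, x$list_length, nrow(x$events),
              length(pooled_unique_recall(x))))
  invisible(x)
}

empty_events <- function() {
  data.frame(round = integer(0), turn = integer(0), agent = integer(0),
             action = character(0), item = integer(0), novel = logical(0),
             stringsAsFactors = FALSE)
}

# Draw each agent's randomized study order and its stop-decision uniforms in
# one fixed pattern. Both group simulators consume this identical RNG prefix,
# so a nominal group and a collaborative group run at the same seed share
# study orders and stop decisions exactly (paired common random numbers,
# mirroring the paired nominal/collaborative participants of the protocol);
# each condition's marginal distribution is unchanged.
draw_agent_inputs <- function(n, group_size) {
  orders <- vector("list", group_size)
  stop_u <- vector("list", group_size)
  for (a in seq_len(group_size)) {
    orders[[a]] <- sample.int(n)
    stop_u[[a]] <- stats::runif(n)
  }
  list(orders = orders, stop_u = stop_u)
}

#' Simulate a nominal group
#'
#' `group_size` independent individuals study the same list, each in its own
#' freshly randomized order, and recall alone ([simulate_individual_recall()]).
#' Their sequences are concatenated (agent-tagged) into one transcript; the
#' `novel` flag marks the first occurrence of each item in that pooled order.
#'
#' Study orders and stop decisions are pre-drawn in a fixed pattern shared
#' with [simulate_collaborative_group()], so the two conditions run at the
#' same seed form a matched pair (common random numbers).
#'
#' @param space A [semantic_space()].
#' @param params A [cmr_params()].
#' @param group_size Number of individuals (>= 1).
#' @param seed Integer seed; the transcript is deterministic given the seed.
#' @return A `group_transcript` with per-agent `study_orders`, `trajectories`
#'   (context snapshots aligned to the agent's own output positions), and
#'   `stop_round` (the agent's own output position at which it stopped).
#' @export
simulate_nominal_group <- function(space, params, group_size, seed = NULL) {
  stopifnot(inherits(space, "semantic_space"), inherits(params, "cmr_params"))
  group_size <- check_count(group_size, "group_size", min = 1L)
  n <- n_items(space)
  with_seed(seed, {
    inputs <- draw_agent_inputs(n, group_size)
    orders <- inputs$orders
    trajectories <- vector("list", group_size)
    stop_round <- integer(group_size)
    ev <- vector("list", group_size)
    for (a in seq_len(group_size)) {
      agent <- encode_list(init_agent(space, params), orders[[a]], params)
      res <- simulate_individual_recall(agent, params,
                                        stop_uniforms = inputs$stop_u[[a]])
      trajectories[[a]] <- res$trajectory
      stop_round[[a]] <- length(res$recalls)
      k <- length(res$recalls)
      ev[[a]] <- if (k > 0L) {
        data.frame(round = seq_len(k), turn = 0L, agent = a,
                   action = "recall", item = res$recalls, novel = NA,
                   stringsAsFactors = FALSE)
      } else empty_events()
    }
    events <- do.call(rbind, ev)
    if (is.null(events) || nrow(events) == 0L) events <- empty_events()
    events$novel <- !duplicated(events$item)
    rownames(events) <- NULL
    new_group_transcript("nominal", group_size, n, events, orders,
                         trajectories, stop_round)
  })
}

#' Simulate a collaborative group
#'
#' Recall proceeds in rounds; within each round the not-yet-stopped agents
#' act in a fresh random order. On its turn an agent first draws a stop
#' decision from [stop_probability()] evaluated at its own count of overt
#' recalls — stopping is permanent (the "I can't recall anymore" option).
#' Otherwise it samples one item, excluding only its *own* prior recalls
#' (members can and do re-produce others' words), and emits a recall event.
#' The recaller always drifts its own context toward the item. If the item
#' is novel to the group, every other non-stopped agent independently attends
#' with probability `p_cue` and applies the same context update
#' ([recall_item_update()]); attended items are neither added to the
#' listener's exclusion set nor counted as its recalls — the mechanism is
#' purely contextual. The session ends when every agent has stopped.
#'
#' @inheritParams simulate_nominal_group
#' @param group_size Number of members (>= 2).
#' @return A `group_transcript`; `trajectories[[a]]` holds agent a's context
#'   after every group recall event (row 1 = start of recall), so snapshots
#'   align one-to-one with `events`.
#' @export
simulate_collaborative_group <- function(space, params, group_size, seed = NULL) {
  stopifnot(inherits(space, "semantic_space"), inherits(params, "cmr_params"))
  group_size <- check_count(group_size, "group_size", min = 2L)
  n <- n_items(space)
  with_seed(seed, {
    inputs <- draw_agent_inputs(n, group_size)
    orders <- inputs$orders
    agents <- vector("list", group_size)
    for (a in seq_len(group_size)) {
      agents[[a]] <- encode_list(init_agent(space, params), orders[[a]], params)
    }
    max_events <- group_size * n
    d1 <- length(agents[[1L]]$context)
    traj <- lapply(seq_len(group_size), function(a) {
      m <- matrix(NA_real_, max_events + 1L, d1)
      m[1L, ] <- agents[[a]]$context
      m
    })
    ev_round <- integer(max_events); ev_turn <- integer(max_events)
    ev_agent <- integer(max_events); ev_item <- integer(max_events)
    ev_novel <- logical(max_events)
    n_ev <- 0L
    group_record <- logical(n)   # items submitted by anyone so far
    own_count <- integer(group_size)
    stop_round <- rep(NA_integer_, group_size)
    active <- rep(TRUE, group_size)
    round_i <- 0L
    while (any(active)) {
      round_i <- round_i + 1L
      act_now <- which(active)
      turn_order <- if (length(act_now) == 1L) act_now else sample(act_now)
      for (t_i in seq_along(turn_order)) {
        a <- turn_order[[t_i]]
        if (!active[[a]]) next
        if (length(agents[[a]]$recalled_own) >= n ||
            inputs$stop_u[[a]][[own_count[[a]] + 1L]] <
              stop_probability(own_count[[a]], params)) {
          active[[a]] <- FALSE
          agents[[a]]$stopped <- TRUE
          stop_round[[a]] <- round_i
          next
        }
        act <- retrieval_activations(agents[[a]])
        item <- sample_recall(act, excluded = agents[[a]]$recalled_own,
                              tau = params$tau)
        novel <- !group_record[[item]]
        group_record[[item]] <- TRUE
        agents[[a]]$recalled_own <- c(agents[[a]]$recalled_own, item)
        own_count[[a]] <- own_count[[a]] + 1L
        agents[[a]] <- recall_item_update(agents[[a]], item, params)
        if (novel && group_size > 1L) {
          for (b in seq_len(group_size)) {
            if (b == a || !active[[b]]) next
            if (stats::runif(1L) < params$p_cue) {
              agents[[b]] <- recall_item_update(agents[[b]], item, params)
              agents[[b]]$heard <- c(agents[[b]]$heard, item)
            }
          }
        }
        n_ev <- n_ev + 1L
        ev_round[[n_ev]] <- round_i; ev_turn[[n_ev]] <- t_i
        ev_agent[[n_ev]] <- a; ev_item[[n_ev]] <- item
        ev_novel[[n_ev]] <- novel
        for (b in seq_len(group_size)) traj[[b]][n_ev + 1L, ] <- agents[[b]]$context
      }
    }
    keep <- seq_len(n_ev)
    events <- data.frame(round = ev_round[keep], turn = ev_turn[keep],
                         agent = ev_agent[keep], action = rep("recall", n_ev),
                         item = ev_item[keep], novel = ev_novel[keep],
                         stringsAsFactors = FALSE)
    trajectories <- lapply(traj, function(m) m[seq_len(n_ev + 1L), , drop = FALSE])
    new_group_transcript("collaborative", group_size, n, events, orders,
                         trajectories, stop_round)
  })
}

#' Pooled unique recall of a group
#'
#' The set of distinct items across all recall events — the summed recalls of
#' the group after excluding duplicates.
#'
#' @param transcript A `group_transcript`.
#' @return Sorted integer vector of distinct recalled item indices.
#' @export
pooled_unique_recall <- function(transcript) {
  stopifnot(inherits(transcript, "group_transcript"))
  ev <- transcript$events
  sort(unique(ev$item[ev$action == "recall"]))
}

# Own recall sequence of one agent, in output order.
own_recalls <- function(transcript, agent) {
  ev <- transcript$events
  ev$item[ev$action == "recall" & ev$agent == agent]
}
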