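# Behavioral summary statistics of free recall: serial position curve,
# probability of first recall, semantic similarity by output lag (own and
# group scope), proportion recalled, and collaborative inhibition by group
# size. All statistics attribute recalls to the recalling agent and use that
# agent's own randomized study order, so nominal and collaborative conditions
# are computed identically.

as_transcript_list <- function(transcripts) {
  if (inherits(transcripts, "group_transcript")) return(list(transcripts))
  stopifnot(is.list(transcripts), length(transcripts) > 0L)
  lapply(transcripts, function(t) {
    stopifnot(inherits(t, "group_transcript")); t
  })
}

check_study_orders <- function(transcripts) {
  for (t in transcripts) {
    if (is.null(t$study_orders)) {
      stop_arg("transcript lacks per-agent study orders (needed for position-based metrics)")
    }
  }
  L <- unique(vapply(transcripts, function(t) t$list_length, integer(1L)))
  if (length(L) != 1L) stop_arg("all transcripts must share the same list length")
  L
}

#' Serial position curve
#'
#' For each study position p, the fraction of (agent, position-p item) pairs
#' in which the agent itself recalled the item it studied at position p.
#' Positions refer to each agent's own randomized study order; in the
#' collaborative condition an item counts for an agent only if that agent
#' overtly recalled it.
#'
#' @param transcripts A `group_transcript` or list of them (shared L).
#' @return Numeric vector of length L of recall probabilities.
#' @export
serial_position_curve <- function(transcripts) {
  transcripts <- as_transcript_list(transcripts)
  L <- check_study_orders(transcripts)
  hits <- numeric(L); n_agents <- 0L
  for (t in transcripts) {
    for (a in seq_len(t$group_size)) {
      rec <- unique(own_recalls(t, a))
      ord <- t$study_orders[[a]]
      hits <- hits + as.numeric(ord %in% rec)
      n_agents <- n_agents + 1L
    }
  }
  if (n_agents == 0L) return(numeric(L))
  hits / n_agents
}

#' Probability of first recall
#'
#' Distribution over the study position (in the recaller's own order) of each
#' agent's first own recall. Agents with no recalls contribute nothing; with
#' no recalls at all the vector is all zeros.
#'
#' @inheritParams serial_position_curve
#' @return Numeric vector of length L summing to 1 (or all zeros).
#' @export
probability_first_recall <- function(transcripts) {
  transcripts <- as_transcript_list(transcripts)
  L <- check_study_orders(transcripts)
  counts <- numeric(L); total <- 0L
  for (t in transcripts) {
    for (a in seq_len(t$group_size)) {
      rec <- own_recalls(t, a)
      if (length(rec) == 0L) next
      pos <- match(rec[[1L]], t$study_orders[[a]])
      counts[[pos]] <- counts[[pos]] + 1
      total <- total + 1L
    }
  }
  if (total == 0L) return(numeric(L))
  counts / total
}

#' Semantic similarity by output lag
#'
#' Mean cosine similarity between pairs of recalled items `k` output
#' positions apart, for `k = 1, ..., max_lag`. With `scope = "own"` pairs
#' come from each agent's own recall sequence; with `scope = "group"` from
#' the group's pooled chronological output order (all recall events in
#' transcript order). Sequences shorter than `k + 1` contribute nothing at
#' lag `k`.
#'
#' @inheritParams serial_position_curve
#' @param space The [semantic_space()] the items live in.
#' @param max_lag Largest lag (>= 1); the clustering analyses use lags 1-4.
#' @param scope `"own"` or `"group"`.
#' @param return_pairs If TRUE, also return the raw per-pair cosines by lag
#'   (used by [lag1_vs_lag4_test()]).
#' @return A data.frame with columns `lag`, `mean`, `se`, `n_pairs`; if
#'   `return_pairs`, a list with that data.frame (`summary`) and a list
#'   `pairs` of cosines per lag.
#' @export
semantic_similarity_by_lag <- function(transcripts, space, max_lag = 4L,
                                       scope = c("own", "group"),
                                       return_pairs = FALSE) {
  transcripts <- as_transcript_list(transcripts)
  scope <- match.arg(scope)
  max_lag <- check_count(max_lag, "max_lag")
  stopifnot(inherits(space, "semantic_space"))
  sequences <- list()
  for (t in transcripts) {
    if (scope == "own") {
      for (a in seq_len(t$group_size)) {
        sequences[[length(sequences) + 1L]] <- own_recalls(t, a)
      }
    } else {
      ev <- t$events
      sequences[[length(sequences) + 1L]] <- ev$item[ev$action == "recall"]
    }
  }
  pairs <- vector("list", max_lag)
  for (k in seq_len(max_lag)) {
    vals <- numeric(0)
    for (s in sequences) {
      m <- length(s)
      if (m < k + 1L) next
      idx <- seq_len(m - k)
      vals <- c(vals, space$similarity[cbind(s[idx + k], s[idx])])
    }
    pairs[[k]] <- vals
  }
  summ <- data.frame(
    lag = seq_len(max_lag),
    mean = vapply(pairs, function(v) if (length(v)) mean(v) else NA_real_, numeric(1L)),
    se = vapply(pairs, se_mean, numeric(1L)),
    n_pairs = vapply(pairs, length, integer(1L))
  )
  if (return_pairs) list(summary = summ, pairs = pairs) else summ
}

#' Proportion of the list recalled by a group
#'
#' `|pooled unique recall| / L`.
#'
#' @param transcript A `group_transcript`.
#' @return A number in \[0, 1\].
#' @export
proportion_recalled <- function(transcript) {
  stopifnot(inherits(transcript, "group_transcript"))
  length(pooled_unique_recall(transcript)) / transcript$list_length
}

#' Collaborative inhibition by group size
#'
#' For each group size, the mean proportion of words recalled by nominal
#' groups minus the mean for collaborative groups, with the pooled standard
#' error of the difference.
#'
#' @param nominal,collaborative Named lists keyed by group size (e.g.
#'   `"3"`), each element a list of `group_transcript`s of that size.
#' @return data.frame with columns `group_size`, `inhibition`, `se`,
#'   `nominal_mean`, `collaborative_mean`, `n_nominal`, `n_collaborative`.
#' @export
collaborative_inhibition <- function(nominal, collaborative) {
  sizes <- names(nominal)
  if (!setequal(sizes, names(collaborative))) {
    stop_arg("nominal and collaborative must cover the same group sizes")
  }
  sizes <- sizes[order(as.integer(sizes))]
  rows <- lapply(sizes, function(s) {
    pn <- vapply(as_transcript_list(nominal[[s]]), proportion_recalled, numeric(1L))
    pc <- vapply(as_transcript_list(collaborative[[s]]), proportion_recalled, numeric(1L))
    data.frame(group_size = as.integer(s),
               inhibition = mean(pn) - mean(pc),
               se = sqrt(se_mean(pn)^2 + se_mean(pc)^2),
               nominal_mean = mean(pn), collaborative_mean = mean(pc),
               n_nominal = length(pn), n_collaborative = length(pc))
  })
  do.call(rbind, rows)
}

#' Welch t test of lag-1 versus lag-4 semantic similarity
#'
#' Two-sample unequal-variance comparison of the per-pair cosine populations
#' at output lag 1 and lag 4 — the semantic-clustering contrast.
#'
#' @param lag1,lag4 Numeric vectors of per-pair cosines (>= 2 values each).
#' @return List with `t`, `df`, `p`.
#' @export
lag1_vs_lag4_test <- function(lag1, lag4) {
  if (length(lag1) < 2L || length(lag4) < 2L) {
    stop_arg("need at least 2 cosine values per lag")
  }
  if (stats::var(lag1) < 1e-14 && stats::var(lag4) < 1e-14) {
    stop_arg("degenerate (zero) variance in both lag populations")
  }
  tt <- stats::t.test(lag1, lag4, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Behavioral summary of a set of transcripts
#'
#' Bundles the fitting surfaces: serial position curve, probability of first
#' recall, own-scope and (for collaborative transcripts) group-scope semantic
#' similarity by lag, and mean proportion recalled.
#'
#' @inheritParams semantic_similarity_by_lag
#' @param group_scope Include the group-scope lag curve (default: TRUE when
#'   any transcript is collaborative).
#' @return An object of class `behavioral_summary`: list with `spc`, `pfr`,
#'   `sem_by_lag_own`, `sem_by_lag_group` (or NULL), `prop_recalled`.
#' @export
behavioral_summary <- function(transcripts, space, max_lag = 4L,
                               group_scope = NULL) {
  transcripts <- as_transcript_list(transcripts)
  if (is.null(group_scope)) {
    group_scope <- any(vapply(transcripts, function(t) t$condition == "collaborative",
                              logical(1L)))
  }
  structure(list(
    spc = serial_position_curve(transcripts),
    pfr = probability_first_recall(transcripts),
    sem_by_lag_own = semantic_similarity_by_lag(transcripts, space, max_lag, "own"),
    sem_by_lag_group = if (group_scope)
      semantic_similarity_by_lag(transcripts, space, max_lag, "group"),
    prop_recalled = mean(vapply(transcripts, proportion_recalled, numeric(1L)))
  ), class = "behavioral_summary")
}

#' Temporal lag-CRP (auxiliary)
#'
#' Conditional response probability by study-position lag: for successive own
#' recalls, the probability of a transition at lag `l` given that lag was
#' available, aggregated over agents. Provided as a utility for temporal
#' contiguity checks; the core analyses do not use it.
#'
#' @inheritParams serial_position_curve
#' @param max_lag Largest |lag| to report.
#' @return data.frame with columns `lag` (-max_lag..-1, 1..max_lag) and `crp`.
#' @export
lag_crp <- function(transcripts, max_lag = 5L) {
  transcripts <- as_transcript_list(transcripts)
  L <- check_study_orders(transcripts)
  max_lag <- check_count(max_lag, "max_lag")
  lags <- c(seq.int(-max_lag, -1L), seq_len(max_lag))
  num <- stats::setNames(numeric(length(lags)), lags)
  den <- num
  for (t in transcripts) {
    for (a in seq_len(t$group_size)) {
      rec <- own_recalls(t, a)
      if (length(rec) < 2L) next
      pos <- match(rec, t$study_orders[[a]])
      for (i in seq_len(length(rec) - 1L)) {
        prev <- pos[[i]]
        done <- pos[seq_len(i)]
        avail <- setdiff(seq_len(L), done) - prev
        actual <- pos[[i + 1L]] - prev
        for (l in lags) {
          key <- as.character(l)
          if (l %in% avail) den[[key]] <- den[[key]] + 1
          if (l == actual) num[[key]] <- num[[key]] + 1
        }
      }
    }
  }
  data.frame(lag = lags, crp = ifelse(den > 0, num / den, NA_real_))
}
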