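# Experiment orchestration: full study-matched designs and a reduced "desk"
# preset, paired nominal/collaborative simulation, and the figure-style
# summary bundle (behavioral curves, inhibition by size, context-similarity
# curves, convergence-performance correlation, stopping-parameter sweep).

#' Experiment configuration
#'
#' The default mirrors the reference study design: 60-item uncategorized
#' lists (every item its own cluster) and, per condition, 48 groups of size
#' 2, 32 of 3, 24 of 4, and 12 each of 8 and 16.
#'
#' @param list_length List length L.
#' @param group_sizes Group sizes to simulate.
#' @param groups_per_size Groups per size and condition (same length).
#' @param params A [cmr_params()].
#' @param space_spec List with `dim`, `n_clusters`, `cluster_spread` for
#'   [generate_synthetic_space()].
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(list_length = 60L,
                              group_sizes = c(2L, 3L, 4L, 8L, 16L),
                              groups_per_size = c(48L, 32L, 24L, 12L, 12L),
                              params = cmr_params(),
                              space_spec = list(dim = 32L,
                                                n_clusters = list_length,
                                                cluster_spread = 0.25),
                              seed = 1L) {
  list_length <- check_count(list_length, "list_length", min = 2L)
  group_sizes <- vapply(group_sizes, check_count, integer(1L), name = "group_sizes")
  groups_per_size <- vapply(groups_per_size, check_count, integer(1L),
                            name = "groups_per_size")
  if (length(group_sizes) != length(groups_per_size)) {
    stop_arg("group_sizes and groups_per_size must have the same length")
  }
  stopifnot(inherits(params, "cmr_params"))
  structure(list(list_length = list_length, group_sizes = group_sizes,
                 groups_per_size = groups_per_size, params = params,
                 space_spec = space_spec, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Reduced desk-scale configuration
#'
#' A down-scaled stated world for tests and quick runs: 20-item lists over a
#' clustered semantic space (4 clusters, spread 0.25 — enough structure for
#' the semantic-lag metric to detect) and 20 groups per condition and size.
#'
#' @param groups_per_size Groups per size/condition (scalar, recycled).
#' @param seed Master seed.
#' @param params A [cmr_params()].
#' @return An `experiment_config`.
#' @export
desk_preset <- function(groups_per_size = 20L, seed = 1L,
                        params = cmr_params()) {
  experiment_config(
    list_length = 20L,
    group_sizes = c(2L, 3L, 4L, 8L, 16L),
    groups_per_size = rep(check_count(groups_per_size, "groups_per_size"), 5L),
    params = params,
    space_spec = list(dim = 16L, n_clusters = 4L, cluster_spread = 0.25),
    seed = seed
  )
}

config_space <- function(config) {
  generate_synthetic_space(config$list_length, config$space_spec$dim,
                           config$space_spec$n_clusters,
                           config$space_spec$cluster_spread,
                           seed = config$seed)
}

#' Simulate a full nominal + collaborative experiment
#'
#' For each group size, simulates matched nominal and collaborative groups
#' over the same semantic space with paired seeds (group g of size s uses the
#' same base seed in both conditions; study orders are freshly sampled per
#' group from that seed). Deterministic given `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param space Optional pre-built [semantic_space()]; by default generated
#'   from `config$space_spec`.
#' @return List with `nominal` and `collaborative` (lists keyed by group
#'   size, each a list of `group_transcript`s) and `space`.
#' @export
generate_experiment <- function(config, space = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(space)) space <- config_space(config)
  nominal <- list(); collaborative <- list()
  for (si in seq_along(config$group_sizes)) {
    s <- config$group_sizes[[si]]
    ng <- config$groups_per_size[[si]]
    key <- as.character(s)
    seeds <- config$seed + 10000L * si + seq_len(ng)
    nominal[[key]] <- lapply(seeds, function(sd)
      simulate_nominal_group(space, config$params, s, seed = sd))
    collaborative[[key]] <- lapply(seeds, function(sd)
      simulate_collaborative_group(space, config$params, s, seed = sd))
  }
  list(nominal = nominal, collaborative = collaborative, space = space)
}

#' Run the full figure-style summary suite
#'
#' Produces, from simulation alone: per-condition serial position, first
#' recall and semantic-lag curves; the inhibition-by-group-size table;
#' between-member context-similarity-by-output curves for
#' `p_cue` in {0, 0.3, 0.6, 1.0}; the convergence-performance Spearman
#' correlation; the within-subject-similarity-by-size table; and
#' inhibition-by-size curves under the stopping-parameter sweep
#' `eps_d` in {0.05, 0.5, 5.0}. Deterministic given `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param p_cue_values Listening probabilities for the similarity curves.
#' @param eps_sweep Stopping-scale values for the ceiling analysis.
#' @param similarity_positions Output positions for similarity curves.
#' @param corr_group_size,corr_n_groups Design of the convergence-performance
#'   correlation.
#' @return A named list of data.frames (`summary_bundle`).
#' @export
run_figure_suite <- function(config,
                             p_cue_values = c(0, 0.3, 0.6, 1.0),
                             eps_sweep = c(0.05, 0.5, 5.0),
                             similarity_positions = 0:10,
                             corr_group_size = 16L,
                             corr_n_groups = 100L) {
  stopifnot(inherits(config, "experiment_config"))
  space <- config_space(config)
  exp <- generate_experiment(config, space = space)
  all_nom <- unlist(exp$nominal, recursive = FALSE)
  all_col <- unlist(exp$collaborative, recursive = FALSE)

  curve_df <- function(transcripts, condition) {
    spc <- serial_position_curve(transcripts)
    pfr <- probability_first_recall(transcripts)
    rbind(
      data.frame(condition = condition, metric = "spc",
                 position = seq_along(spc), value = spc),
      data.frame(condition = condition, metric = "pfr",
                 position = seq_along(pfr), value = pfr)
    )
  }
  curves <- rbind(curve_df(all_nom, "nominal"), curve_df(all_col, "collaborative"))

  lag_df <- rbind(
    cbind(condition = "nominal", scope = "own",
          semantic_similarity_by_lag(all_nom, space, 4L, "own")),
    cbind(condition = "collaborative", scope = "own",
          semantic_similarity_by_lag(all_col, space, 4L, "own")),
    cbind(condition = "collaborative", scope = "group",
          semantic_similarity_by_lag(all_col, space, 4L, "group"))
  )

  inhibition <- collaborative_inhibition(exp$nominal, exp$collaborative)

  # Between-member context similarity by output position, per p_cue.
  max_pos <- max(similarity_positions)
  sim_rows <- list()
  n_sim_groups <- max(config$groups_per_size)
  for (pc in p_cue_values) {
    p <- update_params(config$params, p_cue = pc)
    sims <- matrix(NA_real_, n_sim_groups, length(similarity_positions))
    for (g in seq_len(n_sim_groups)) {
      t <- simulate_collaborative_group(space, p, corr_group_size,
                                        seed = config$seed + 900000L +
                                          g + round(1000 * pc))
      ts <- context_trajectories(t, length_out = max_pos)
      sims[g, ] <- vapply(similarity_positions, function(k)
        pairwise_context_similarity(ts, k), numeric(1L))
    }
    sim_rows[[length(sim_rows) + 1L]] <- data.frame(
      p_cue = pc, output = similarity_positions,
      similarity = colMeans(sims), se = apply(sims, 2L, se_mean))
  }
  # nominal reference curve
  sims <- matrix(NA_real_, n_sim_groups, length(similarity_positions))
  for (g in seq_len(n_sim_groups)) {
    t <- simulate_nominal_group(space, config$params, corr_group_size,
                                seed = config$seed + 950000L + g)
    ts <- context_trajectories(t, length_out = max_pos)
    sims[g, ] <- vapply(similarity_positions, function(k)
      pairwise_context_similarity(ts, k), numeric(1L))
  }
  similarity_curves <- rbind(
    data.frame(p_cue = NA_real_, output = similarity_positions,
               similarity = colMeans(sims), se = apply(sims, 2L, se_mean)),
    do.call(rbind, sim_rows))
  similarity_curves$condition <- ifelse(is.na(similarity_curves$p_cue),
                                        "nominal", "collaborative")

  corr <- convergence_performance_correlation(space, config$params,
                                              corr_group_size,
                                              n_groups = corr_n_groups,
                                              seed = config$seed + 77L)

  # Within-subject similarity by group size (collaborative condition).
  wss <- vapply(names(exp$collaborative), function(key) {
    vals <- unlist(lapply(exp$collaborative[[key]], function(t) {
      ts <- context_trajectories(t, length_out = 10L)
      vapply(ts, within_subject_similarity, numeric(1L), after = 10L)
    }))
    mean(vals)
  }, numeric(1L))
  within_subject <- data.frame(group_size = as.integer(names(wss)),
                               similarity = unname(wss))
  within_subject <- within_subject[order(within_subject$group_size), ]

  # Stopping-parameter sweep: inhibition by size per eps_d.
  sweep_rows <- list()
  for (eps in eps_sweep) {
    cfg_eps <- config
    cfg_eps$params <- update_params(config$params, eps_d = eps)
    cfg_eps$seed <- config$seed + round(1000L * eps)
    exp_eps <- generate_experiment(cfg_eps, space = space)
    inh <- collaborative_inhibition(exp_eps$nominal, exp_eps$collaborative)
    inh$eps_d <- eps
    sweep_rows[[length(sweep_rows) + 1L]] <- inh
  }
  eps_sweep_df <- do.call(rbind, sweep_rows)

  structure(list(
    curves = curves,
    semantic_lag = lag_df,
    inhibition = inhibition,
    similarity_curves = similarity_curves,
    convergence_correlation = data.frame(rho = corr$rho, p = corr$p,
                                         group_size = corr_group_size,
                                         n_groups = corr_n_groups),
    within_subject = within_subject,
    eps_sweep = eps_sweep_df
  ), class = "summary_bundle")
}

#' Write a summary bundle as CSV files plus a JSON index
#'
#' @param bundle A `summary_bundle` from [run_figure_suite()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_summary_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "summary_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(bundle)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  jsonlite::write_json(list(tables = files), file.path(dir, "index.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
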