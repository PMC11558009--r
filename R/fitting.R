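# Parameter fitting. The model is fit to nominal-condition behavioral
# summaries by minimizing a range-normalized RMSE with a sequential
# model-based optimizer; the one collaborative parameter, p_cue, is fit
# afterwards by grid search with everything else inherited.

#' Fit targets
#'
#' The behavioral surfaces a fit is scored against: serial position curve,
#' probability of first recall, own-scope semantic-similarity-by-lag means,
#' and optionally the group-scope lag curve (used when fitting p_cue).
#'
#' @param spc,pfr Probability vectors of length L.
#' @param sem_own Own-scope per-lag mean cosines (lags 1..4).
#' @param sem_group Optional group-scope per-lag mean cosines.
#' @param weights Named nonnegative weights per component (normalized
#'   internally); not all zero.
#' @return An object of class `fit_targets`.
#' @export
fit_targets <- function(spc, pfr, sem_own, sem_group = NULL,
                        weights = c(spc = 1, pfr = 1, sem_own = 1,
                                    sem_group = 1)) {
  comp <- list(spc = as.numeric(spc), pfr = as.numeric(pfr),
               sem_own = as.numeric(sem_own))
  if (!is.null(sem_group)) comp$sem_group <- as.numeric(sem_group)
  for (nm in names(comp)) {
    if (anyNA(comp[[nm]]) || any(!is.finite(comp[[nm]]))) {
      stop_arg("target `%s` must be finite", nm)
    }
  }
  w <- weights[names(comp)]
  names(w) <- names(comp)
  w[is.na(w)] <- 0
  if (any(w < 0)) stop_arg("weights must be nonnegative")
  if (sum(w) <= 0) stop_arg("weights must not all be zero")
  structure(list(components = comp, weights = w / sum(w)), class = "fit_targets")
}

#' Targets extracted from a behavioral summary
#'
#' @param summary A [behavioral_summary()].
#' @param group_scope Include the group-scope lag component.
#' @param weights Passed to [fit_targets()].
#' @return A `fit_targets`.
#' @export
targets_from_summary <- function(summary, group_scope = !is.null(summary$sem_by_lag_group),
                                 weights = c(spc = 1, pfr = 1, sem_own = 1,
                                             sem_group = 1)) {
  stopifnot(inherits(summary, "behavioral_summary"))
  fit_targets(summary$spc, summary$pfr, summary$sem_by_lag_own$mean,
              sem_group = if (group_scope) summary$sem_by_lag_group$mean,
              weights = weights)
}

summary_component <- function(summary, nm) {
  switch(nm,
         spc = summary$spc,
         pfr = summary$pfr,
         sem_own = summary$sem_by_lag_own$mean,
         sem_group = summary$sem_by_lag_group$mean,
         stop_arg("unknown component `%s`", nm))
}

#' Normalized root-mean-square error between model curves and targets
#'
#' Per component: `RMSE / range(target)`; the objective is the weighted mean
#' over components (weights normalized, so doubling all weights changes
#' nothing). Nonnegative, zero iff every curve matches its target exactly.
#'
#' @param model A [behavioral_summary()] (or list with matching components).
#' @param targets A [fit_targets()].
#' @return Nonnegative scalar.
#' @export
nrmse <- function(model, targets) {
  stopifnot(inherits(targets, "fit_targets"))
  total <- 0
  for (nm in names(targets$components)) {
    w <- targets$weights[[nm]]
    if (w == 0) next
    target <- targets$components[[nm]]
    curve <- as.numeric(summary_component(model, nm))
    if (length(curve) != length(target)) {
      stop_arg("component `%s`: model length %d != target length %d",
               nm, length(curve), length(target))
    }
    rng <- diff(range(target))
    if (rng <= 0) stop_arg("component `%s` has zero range", nm)
    if (anyNA(curve)) stop_arg("component `%s`: model curve has NA", nm)
    total <- total + w * sqrt(mean((curve - target)^2)) / rng
  }
  total
}

new_fit_result <- function(best_params, objective_value, log, seed,
                           n_sims_per_eval) {
  structure(list(best_params = best_params, objective_value = objective_value,
                 evaluation_log = log, seed = seed,
                 n_sims_per_eval = n_sims_per_eval), class = "cmr_fit")
}

#' @export
print.cmr_fit <- function(x, ...) {
  cat(sprintf("<cmr_fit> %d evaluations, best objective %.4f\n",
              nrow(x$evaluation_log), x$objective_value))
  invisible(x)
}

# Evaluate the nominal objective at one candidate, under common random
# numbers (the same eval_seed for every candidate).
eval_nominal_objective <- function(cand, base_params, targets, space,
                                   n_sims, eval_seed) {
  params <- do.call(update_params, c(list(base_params), as.list(cand)))
  with_seed(eval_seed, {
    ts <- lapply(seq_len(n_sims), function(i)
      simulate_nominal_group(space, params, group_size = 1L))
    nrmse(behavioral_summary(ts, space, group_scope = FALSE), targets)
  })
}

#' Fit model parameters to nominal-condition targets
#'
#' Sequential model-based minimization of [nrmse()]. Candidates are drawn in
#' the unit-scaled box given by `bounds`; after a random initial design, each
#' iteration fits a Gaussian-kernel (Nadaraya-Watson) surrogate over all
#' evaluations and proposes the candidate from a fresh random pool that
#' minimizes predicted objective minus an exploration bonus proportional to
#' the distance from previous evaluations. Every objective evaluation
#' averages `n_sims_per_eval` simulated individuals at a fixed per-run seed
#' (common random numbers), so candidates are compared on the same noise.
#'
#' @param targets A [fit_targets()] (no group-scope component is used).
#' @param space A [semantic_space()].
#' @param bounds Named list of `c(lower, upper)` intervals for the parameters
#'   to fit (any subset of [cmr_params()] fields); must satisfy the parameter
#'   invariants.
#' @param base_params Parameters held fixed at these values when not fitted.
#' @param budget Total number of objective evaluations (>= 10).
#' @param n_sims_per_eval Simulated individuals per evaluation.
#' @param seed Integer seed for the whole fit.
#' @return A `cmr_fit`: `best_params`, `objective_value`, `evaluation_log`
#'   (one row per evaluation: candidate + objective), `seed`,
#'   `n_sims_per_eval`.
#' @export
fit_nominal <- function(targets, space, bounds, base_params = cmr_params(),
                        budget = 30L, n_sims_per_eval = 20L, seed = NULL) {
  stopifnot(inherits(targets, "fit_targets"), inherits(space, "semantic_space"),
            inherits(base_params, "cmr_params"))
  budget <- check_count(budget, "budget", min = 10L)
  n_sims_per_eval <- check_count(n_sims_per_eval, "n_sims_per_eval")
  if (!is.list(bounds) || is.null(names(bounds)) || length(bounds) < 1L) {
    stop_arg("`bounds` must be a non-empty named list of c(lower, upper)")
  }
  pn <- names(bounds)
  unknown <- setdiff(pn, .param_names)
  if (length(unknown) > 0L) {
    stop_arg("unknown parameter(s) in bounds: %s", paste(unknown, collapse = ", "))
  }
  lo <- vapply(bounds, function(b) b[[1L]], numeric(1L))
  hi <- vapply(bounds, function(b) b[[2L]], numeric(1L))
  if (any(hi <= lo)) stop_arg("each bound must satisfy lower < upper")
  # bounds must themselves be legal parameter values
  validate_cmr_params(utils::modifyList(unclass(base_params), as.list(stats::setNames(lo, pn))))
  validate_cmr_params(utils::modifyList(unclass(base_params), as.list(stats::setNames(hi, pn))))
  k <- length(pn)
  with_seed(seed, {
    eval_seed <- sample.int(.Machine$integer.max, 1L)
    X <- matrix(NA_real_, budget, k, dimnames = list(NULL, pn)) # unit scale
    y <- rep(NA_real_, budget)
    unscale <- function(u) stats::setNames(lo + u * (hi - lo), pn)
    # fixed-size initial design, so a longer budget at the same seed extends
    # the shorter run's evaluation sequence (monotone best-so-far)
    n_init <- min(10L, budget)
    for (i in seq_len(budget)) {
      u <- if (i <= n_init) {
        stats::runif(k)
      } else {
        propose_candidate(X[seq_len(i - 1L), , drop = FALSE], y[seq_len(i - 1L)])
      }
      X[i, ] <- u
      y[i] <- eval_nominal_objective(unscale(u), base_params, targets, space,
                                     n_sims_per_eval, eval_seed)
    }
    best <- which.min(y)
    log <- as.data.frame(sweep(sweep(X, 2L, hi - lo, "*"), 2L, lo, "+"))
    names(log) <- pn
    log$objective <- y
    best_params <- do.call(update_params,
                           c(list(base_params), as.list(unscale(X[best, ]))))
    new_fit_result(best_params, y[best], log, seed, n_sims_per_eval)
  })
}

# SMBO proposal: Nadaraya-Watson surrogate on evaluated points plus a
# distance-based exploration bonus, minimized over a random candidate pool.
propose_candidate <- function(X, y, pool = 256L, bandwidth = 0.25,
                              kappa = 0.5) {
  k <- ncol(X)
  cand <- matrix(stats::runif(pool * k), pool, k)
  d2 <- outer(rowSums(cand^2), rowSums(X^2), "+") - 2 * tcrossprod(cand, X)
  d2[d2 < 0] <- 0
  w <- exp(-d2 / (2 * bandwidth^2 * k))
  pred <- (w %*% y) / pmax(rowSums(w), 1e-12)
  mindist <- sqrt(apply(d2, 1L, min))
  sdy <- stats::sd(y); if (!is.finite(sdy) || sdy == 0) sdy <- 1
  acq <- pred - kappa * sdy * mindist
  cand[which.min(acq), ]
}

#' Fit the listening probability by grid search
#'
#' Holds every model parameter fixed (inherited from the nominal fit) and
#' evaluates `p_cue` over the grid `seq(0, 1, by = grid_step)`, simulating
#' `n_sims_per_eval` collaborative groups per value (common random numbers)
#' and scoring [nrmse()] against collaborative targets, which should include
#' the group-scope semantic-lag component.
#'
#' @param params A [cmr_params()] with all non-`p_cue` values fixed.
#' @param collab_targets A [fit_targets()] for the collaborative condition.
#' @param space A [semantic_space()].
#' @param group_size Collaborative group size to simulate (>= 2).
#' @param grid_step Grid increment in (0, 1\] (default 0.1).
#' @param n_sims_per_eval Simulated groups per grid value.
#' @param seed Integer seed.
#' @param grid Optional explicit grid of p_cue values (overrides `grid_step`).
#' @return A `cmr_fit` whose `best_params$p_cue` is the grid argmin.
#' @export
fit_pcue <- function(params, collab_targets, space, group_size = 3L,
                     grid_step = 0.1, n_sims_per_eval = 20L, seed = NULL,
                     grid = NULL) {
  stopifnot(inherits(params, "cmr_params"),
            inherits(collab_targets, "fit_targets"),
            inherits(space, "semantic_space"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1) {
    stop_arg("`grid_step` must be in (0, 1]")
  }
  group_size <- check_count(group_size, "group_size", min = 2L)
  n_sims_per_eval <- check_count(n_sims_per_eval, "n_sims_per_eval")
  if (is.null(grid)) grid <- seq(0, 1, by = grid_step)
  if (any(grid < 0 | grid > 1)) stop_arg("`grid` values must lie in [0, 1]")
  with_seed(seed, {
    eval_seed <- sample.int(.Machine$integer.max, 1L)
    y <- vapply(grid, function(pc) {
      p <- update_params(params, p_cue = pc)
      with_seed(eval_seed, {
        ts <- lapply(seq_len(n_sims_per_eval), function(i)
          simulate_collaborative_group(space, p, group_size))
        nrmse(behavioral_summary(ts, space, group_scope = TRUE), collab_targets)
      })
    }, numeric(1L))
    best <- which.min(y)
    log <- data.frame(p_cue = grid, objective = y)
    new_fit_result(update_params(params, p_cue = grid[best]), y[best], log,
                   seed, n_sims_per_eval)
  })
}

#' Serialize / load a fit result (JSON, with full evaluation log)
#'
#' @param fit A `cmr_fit`.
#' @param path JSON path.
#' @return `path` invisibly (writer); a `cmr_fit` (reader).
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "cmr_fit"))
  jsonlite::write_json(list(
    best_params = unclass(fit$best_params),
    objective_value = fit$objective_value,
    evaluation_log = fit$evaluation_log,
    seed = fit$seed,
    n_sims_per_eval = fit$n_sims_per_eval
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  if (!file.exists(path)) stop_arg("fit result not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_fit_result(do.call(cmr_params, as.list(obj$best_params)),
                 obj$objective_value,
                 as.data.frame(obj$evaluation_log),
                 obj$seed, obj$n_sims_per_eval)
}
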