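# Model parameters. One shared parameter set is used across all simulated
# individuals (pooled fitting; no per-subject variability), and the
# collaborative model inherits every parameter from individual recall except
# the listening probability p_cue.

.param_names <- c("beta_enc", "beta_rec", "gamma_fc", "gamma_cf", "s_sem",
                  "tau", "eps_d", "theta_r", "phi_s", "phi_d", "p_cue",
                  "theta0")

#' Parameters of the retrieved-context recall model
#'
#' Defaults were calibrated once, at the reduced "desk" scale (20-item
#' clustered lists), to place the model in the empirically observed regime:
#' strong recency in the serial position curve and probability of first
#' recall, semantic clustering (higher output-lag-1 than lag-4 similarity),
#' sub-ceiling individual recall, and collaborative inhibition for all
#' positive listening probabilities. See the package vignette for the
#' calibration rationale.
#'
#' @param beta_enc Context drift rate during study, in \[0, 1\].
#' @param beta_rec Context drift rate during recall and listening, in \[0, 1\].
#'   Recalled and attended-to items update context through the same pathway.
#' @param gamma_fc Learning rate for item-feature -> context associations,
#'   in \[0, 1\].
#' @param gamma_cf Learning rate for context -> item associations, nonnegative.
#' @param s_sem Scaling of pre-experimental (semantic) associations,
#'   nonnegative: the context-cued activation of item j when context aligns
#'   with item i is `s_sem * cosine(i, j)` before any study.
#' @param tau Choice sensitivity (> 0): retrieval samples item i with
#'   probability proportional to `activation_i ^ tau`.
#' @param eps_d Stopping-scale parameter (> 0). Smaller values raise the
#'   probability of terminating recall at every output position and so reduce
#'   the recall amount.
#' @param theta_r Growth rate of the stopping hazard with output position,
#'   nonnegative.
#' @param phi_s,phi_d Primacy boost magnitude and decay, nonnegative. The
#'   boost at study position p is `1 + phi_s * exp(-phi_d * (p - 1))`.
#'   Defaults to no primacy (`phi_s = 0`), matching data that show recency
#'   but no primacy on long lists.
#' @param p_cue Probability that a listener attends to another group member's
#'   novel recall and drifts their own context toward it, in \[0, 1\].
#' @param theta0 Fixed base constant of the stopping hazard (default 0.05);
#'   the stop probability at output position k is
#'   `min(1, (theta0 / eps_d) * exp(theta_r * k))`.
#' @return An object of class `cmr_params` (a validated named list).
#' @export
cmr_params <- function(beta_enc = 0.75, beta_rec = 0.9, gamma_fc = 0.3,
                       gamma_cf = 1.0, s_sem = 3.0, tau = 6,
                       eps_d = 0.4, theta_r = 0.05, phi_s = 0, phi_d = 1,
                       p_cue = 0.2, theta0 = 0.05) {
  p <- list(beta_enc = beta_enc, beta_rec = beta_rec, gamma_fc = gamma_fc,
            gamma_cf = gamma_cf, s_sem = s_sem, tau = tau, eps_d = eps_d,
            theta_r = theta_r, phi_s = phi_s, phi_d = phi_d, p_cue = p_cue,
            theta0 = theta0)
  validate_cmr_params(p)
}

validate_cmr_params <- function(p) {
  for (nm in .param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
      stop_arg("parameter `%s` must be a single finite number", nm)
    }
    p[[nm]] <- as.numeric(v)
  }
  in01 <- function(nm) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop_arg("`%s` must lie in [0, 1]", nm)
  }
  nonneg <- function(nm) {
    if (p[[nm]] < 0) stop_arg("`%s` must be nonnegative", nm)
  }
  in01("beta_enc"); in01("beta_rec"); in01("gamma_fc"); in01("p_cue")
  nonneg("gamma_cf"); nonneg("s_sem"); nonneg("theta_r")
  nonneg("phi_s"); nonneg("phi_d")
  if (p$tau <= 0) stop_arg("`tau` must be positive")
  if (p$eps_d <= 0) stop_arg("`eps_d` must be positive")
  if (p$theta0 <= 0) stop_arg("`theta0` must be positive")
  structure(p[.param_names], class = "cmr_params")
}

#' Modify a parameter set
#'
#' @param params A `cmr_params` object.
#' @param ... Named parameter replacements.
#' @return A revalidated `cmr_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cmr_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), .param_names)
  if (length(unknown) > 0L) {
    stop_arg("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_cmr_params(p)
}

#' @export
print.cmr_params <- function(x, ...) {
  cat("<cmr_params>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a parameter set as flat JSON
#'
#' The serialization is a flat key -> value JSON object. Unknown keys are
#' rejected on read; missing keys fall back to the defaults of
#' [cmr_params()].
#'
#' @param path JSON file path.
#' @return `read_cmr_params` returns a `cmr_params`; `write_cmr_params`
#'   returns `path` invisibly.
#' @export
read_cmr_params <- function(path) {
  if (!file.exists(path)) stop_arg("parameter file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) && !is.numeric(raw)) stop_arg("malformed parameter JSON")
  raw <- as.list(raw)
  unknown <- setdiff(names(raw), .param_names)
  if (length(unknown) > 0L) {
    stop_arg("unknown parameter key(s) in %s: %s", path,
             paste(unknown, collapse = ", "))
  }
  do.call(cmr_params, raw)
}

#' @rdname read_cmr_params
#' @param params A `cmr_params` object to serialize.
#' @export
write_cmr_params <- function(params, path) {
  stopifnot(inherits(params, "cmr_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
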