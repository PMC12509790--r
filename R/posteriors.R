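# Posterior draws per arm on the natural outcome scale.

#' Posterior draws for one arm under a conjugate beta-binomial model
#'
#' With a `Beta(prior_alpha, prior_beta)` prior and `events` events among `n`
#' participants with data, the posterior is
#' `Beta(prior_alpha + events, prior_beta + n - events)`; draws are returned
#' on the event-probability scale. An arm with no observations yields pure
#' prior draws.
#'
#' @param events Number of events (0 to `n`).
#' @param n Number of participants with outcome data.
#' @param prior_alpha,prior_beta Positive beta prior parameters.
#' @param n_draws Number of posterior draws.
#' @return Numeric vector of `n_draws` values in (0, 1).
#' @export
#' @examples
#' set.seed(1)
#' mean(beta_binomial_draws(25, 100, 1, 1, 10000)) # ~ 26 / 102
beta_binomial_draws <- function(events, n, prior_alpha = 1, prior_beta = 1,
                                n_draws = 5000) {
  if (prior_alpha <= 0 || prior_beta <= 0) {
    stop_field("prior_alpha", "beta prior parameters must be positive")
  }
  if (n < 0 || events < 0 || events > n) {
    stop_field("events", "must satisfy 0 <= events <= n")
  }
  if (n_draws < 1) stop_field("n_draws", "must be at least 1")
  rbeta(n_draws, prior_alpha + events, prior_beta + n - events)
}

#' Posterior draws for one arm mean under a normal approximation
#'
#' Draws from a Gaussian centred at the sample mean with scale
#' `sd(values) / sqrt(n)`; no prior information is used. At least two
#' observations are required (the scale is otherwise undefined); identical
#' values give degenerate draws at their common value.
#'
#' @param values Raw outcome values for the arm.
#' @param n_draws Number of posterior draws.
#' @return Numeric vector of `n_draws` values.
#' @export
normal_approx_draws <- function(values, n_draws = 5000) {
  n <- length(values)
  if (n < 2) {
    stop_field("values", "at least 2 observations are needed for the normal approximation")
  }
  if (n_draws < 1) stop_field("n_draws", "must be at least 1")
  rnorm(n_draws, mean = mean(values), sd = sd(values) / sqrt(n))
}

#' Posterior draws for all active arms
#'
#' Produces the draw matrix used by every adaptive analysis: one column per
#' active arm, `spec$n_draws` rows, values on the natural (absolute) outcome
#' scale (event probabilities for binary outcomes, means for continuous
#' outcomes). The default model follows `spec$outcome_type`; a user-supplied
#' `draw_hook` on the spec replaces it, allowing any estimation method and
#' priors.
#'
#' Hook contract: called as `hook(arms, arm_data, n_draws)` where `arms` is
#' the character vector of active arm labels and `arm_data` a named list with
#' elements `n` (participants with data), `sum_ys` (summed outcomes) and, for
#' continuous outcomes, `values` (list of raw value vectors). It must return
#' an `n_draws` x `length(arms)` numeric matrix of finite values with one
#' column per arm in the given order; output shape and finiteness are
#' validated.
#'
#' @param spec A `trial_spec`.
#' @param arm_data Named list with `n`, `sum_ys` (numeric vectors over active
#'   arms) and optionally `values`.
#' @param arms Labels of the active arms (defaults to `names(arm_data$n)`).
#' @return Numeric matrix (`n_draws` rows) with arm labels as column names.
#' @export
posterior_draws <- function(spec, arm_data, arms = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  arms <- arms %||% names(arm_data$n)
  if (is.null(arms) || length(arms) < 1) {
    stop_field("arm_data", "at least one active arm is required")
  }
  n_draws <- spec$n_draws
  if (!is.null(spec$draw_hook)) {
    draws <- spec$draw_hook(arms, arm_data, n_draws)
    if (!is.matrix(draws) || nrow(draws) != n_draws ||
        ncol(draws) != length(arms)) {
      stop_field("draw_hook", sprintf(
        "hook must return a %d x %d matrix (one column per active arm)",
        n_draws, length(arms)))
    }
    if (!all(is.finite(draws))) {
      stop_field("draw_hook", "hook returned non-finite posterior draws")
    }
    colnames(draws) <- arms
    return(draws)
  }
  draws <- if (spec$outcome_type == "binary") {
    vapply(seq_along(arms), function(j) {
      beta_binomial_draws(arm_data$sum_ys[[j]], arm_data$n[[j]],
                          spec$prior_alpha, spec$prior_beta, n_draws)
    }, numeric(n_draws))
  } else {
    vapply(seq_along(arms), function(j) {
      normal_approx_draws(arm_data$values[[j]], n_draws)
    }, numeric(n_draws))
  }
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = n_draws)
  colnames(draws) <- arms
  draws
}
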