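# Trial-design specifications: construction, validation, threshold expansion,
# scenario grids, fingerprinting and (de)serialisation.

#' Expand a scalar decision threshold to a per-look vector
#'
#' Probability thresholds (and the softening exponent) may either be constant
#' across all adaptive analyses or vary per look. This helper broadcasts a
#' scalar to a vector of length `n_looks` and validates the length of vector
#' input. Values are never altered, only recycled.
#'
#' @param value Scalar or numeric vector of length `n_looks`.
#' @param n_looks Number of adaptive analyses.
#' @param field Field name used in error messages.
#'
#' @return Numeric vector of length `n_looks`.
#' @export
#' @examples
#' expand_thresholds(0.99, 5)
#' expand_thresholds(ifelse(seq(500, 2000, 500) < 1500, 1, 0.9), 4)
expand_thresholds <- function(value, n_looks, field = "threshold") {
  if (is.null(value)) return(NULL)
  if (!is.numeric(value)) stop_field(field, "must be numeric")
  if (length(value) == 1) return(rep(as.numeric(value), n_looks))
  if (length(value) != n_looks) {
    stop_field(field, sprintf("length %d does not match the %d analyses",
                              length(value), n_looks))
  }
  as.numeric(value)
}

#' Specify a multi-arm, multi-stage adaptive trial design
#'
#' Defines a complete, validated trial design: arms and true outcome
#' parameters, an optional common control, the analysis schedule (participants
#' with outcome data and participants randomised at each adaptive analysis),
#' allocation rules (initial/fixed/minimum/maximum allocation probabilities,
#' softening of response-adaptive randomisation, control-allocation rules,
#' rescaling of limits after arm dropping), per-look decision thresholds for
#' superiority/inferiority and optional practical-equivalence and futility
#' rules, the analysis model (conjugate beta-binomial by default, or a
#' user-supplied posterior-draw hook), and the number of posterior draws.
#'
#' Superiority and inferiority rules are mandatory; equivalence is optional,
#' and futility additionally requires a common control. Any per-look threshold
#' can be disabled at individual analyses by setting it to 1 (equivalence,
#' futility, superiority) or 0 (inferiority), which can never be exceeded.
#'
#' @param arms Character vector of arm labels (at least 2).
#' @param true_ys True outcome parameter per arm; event probabilities in
#'   \[0, 1\] for binary outcomes, means for continuous outcomes.
#' @param control Optional label of the common control arm.
#' @param outcome_type `"binary"` (binomial outcome, conjugate beta-binomial
#'   analysis) or `"continuous"` (normally distributed outcome, normal
#'   approximation of the posterior).
#' @param highest_is_best Are higher outcome values desirable?
#' @param start_probs Initial allocation probabilities (default equal).
#' @param fixed_probs Optional fixed allocation probability per arm (`NA` for
#'   arms that follow response-adaptive randomisation).
#' @param min_probs,max_probs Optional per-arm limits on allocation
#'   probabilities (`NA` where unrestricted).
#' @param rescale_probs `"none"` or `"limits"`: whether min/max limits are
#'   rescaled by (initial arms / active arms) when an arm is dropped.
#' @param soften_power Softening exponent in \[0, 1\] applied to the raw
#'   probabilities of being best before renormalisation; 0 forces equal
#'   allocation, 1 applies no restriction. Scalar or one value per look.
#' @param control_prob_rule Optional control-allocation rule used with a
#'   common control: `"none"`, `"sqrt_ratio"` (control share of
#'   sqrt(number of non-control arms) relative to 1 per non-control arm) or
#'   `"match_highest"` (control probability matches the highest non-control
#'   probability).
#' @param data_looks Strictly increasing cumulative numbers of participants
#'   \emph{with outcome data} at each adaptive analysis.
#' @param randomised_at_looks Cumulative numbers of participants
#'   \emph{randomised} when each analysis is conducted; elementwise at least
#'   `data_looks`, with equal final elements. Defaults to `data_looks`
#'   (no outcome-data lag).
#' @param inferiority,superiority Per-look probability thresholds (scalars are
#'   broadcast). Without a common control they apply to each arm's probability
#'   of being overall best; with a control, to pairwise probabilities against
#'   the control.
#' @param equivalence_prob Optional per-look probability threshold for
#'   practical equivalence (1 disables a look).
#' @param equivalence_diff Absolute-scale equivalence margin (> 0).
#' @param equivalence_only_first With a common control: assess equivalence
#'   only against the first (original) control.
#' @param futility_prob,futility_diff,futility_only_first Optional futility
#'   rule (requires a common control), analogous to equivalence.
#' @param prior_alpha,prior_beta Beta prior parameters for binary outcomes
#'   (default `Beta(1, 1)`, i.e. flat).
#' @param true_sds True standard deviation per arm for continuous outcomes
#'   (default 1).
#' @param n_draws Number of posterior draws per arm per analysis.
#' @param draw_hook Optional function generating posterior draws; see
#'   [posterior_draws()] for the contract.
#' @param label Optional scenario label; auto-generated from `true_ys` if
#'   omitted.
#'
#' @return An object of class `trial_spec`.
#' @seealso [setup_trial_binom()], [setup_trial_norm()], [run_trial()],
#'   [run_trials()], [scenario_grid()]
#' @export
setup_trial <- function(arms,
                        true_ys,
                        control = NULL,
                        outcome_type = c("binary", "continuous"),
                        highest_is_best = FALSE,
                        start_probs = NULL,
                        fixed_probs = NULL,
                        min_probs = NULL,
                        max_probs = NULL,
                        rescale_probs = c("none", "limits"),
                        soften_power = 1,
                        control_prob_rule = c("none", "sqrt_ratio", "match_highest"),
                        data_looks,
                        randomised_at_looks = NULL,
                        inferiority = 0,
                        superiority = 1,
                        equivalence_prob = NULL,
                        equivalence_diff = NULL,
                        equivalence_only_first = FALSE,
                        futility_prob = NULL,
                        futility_diff = NULL,
                        futility_only_first = FALSE,
                        prior_alpha = 1,
                        prior_beta = 1,
                        true_sds = NULL,
                        n_draws = 5000,
                        draw_hook = NULL,
                        label = NULL) {
  outcome_type <- match.arg(outcome_type)
  rescale_probs <- match.arg(rescale_probs)
  control_prob_rule <- match.arg(control_prob_rule)

  if (missing(arms) || length(arms) < 2) {
    stop_field("arms", "at least two arm labels are required")
  }
  arms <- as.character(arms)
  if (anyDuplicated(arms)) stop_field("arms", "labels must be unique")
  k <- length(arms)

  if (missing(true_ys) || length(true_ys) != k) {
    stop_field("true_ys", sprintf("one true outcome parameter per arm (%d) required", k))
  }
  true_ys <- as.numeric(true_ys)
  if (outcome_type == "binary" && (any(true_ys < 0) || any(true_ys > 1))) {
    stop_field("true_ys", "binary event probabilities must lie in [0, 1]")
  }

  if (!is.null(control)) {
    if (!control %in% arms) stop_field("control", "must be one of the arm labels")
  }

  if (is.null(start_probs)) start_probs <- rep(1 / k, k)
  start_probs <- as.numeric(start_probs)
  if (length(start_probs) != k) stop_field("start_probs", "one value per arm required")
  if (any(start_probs < 0) || any(start_probs > 1)) {
    stop_field("start_probs", "values must lie in [0, 1]")
  }
  if (abs(sum(start_probs) - 1) > 1e-9) {
    stop_field("start_probs", "values must sum to 1")
  }

  check_constraint <- function(x, field) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) == 1) x <- rep(x, k)
    if (length(x) != k) stop_field(field, "one value per arm (NA allowed) required")
    if (any(x < 0 | x > 1, na.rm = TRUE)) stop_field(field, "values must lie in [0, 1]")
    if (all(is.na(x))) return(NULL)
    x
  }
  fixed_probs <- check_constraint(fixed_probs, "fixed_probs")
  min_probs <- check_constraint(min_probs, "min_probs")
  max_probs <- check_constraint(max_probs, "max_probs")

  if (!is.null(fixed_probs)) {
    clash <- !is.na(fixed_probs) &
      ((!is.null(min_probs) & !is.na(min_probs %||% rep(NA_real_, k))) |
       (!is.null(max_probs) & !is.na(max_probs %||% rep(NA_real_, k))))
    if (any(clash)) {
      stop_field("fixed_probs", "an arm cannot have both a fixed probability and min/max limits")
    }
    if (sum(fixed_probs, na.rm = TRUE) > 1 + 1e-9) {
      stop_field("fixed_probs", "fixed allocation probabilities sum to more than 1")
    }
  }
  if (!is.null(min_probs) && sum(min_probs, na.rm = TRUE) > 1 + 1e-9) {
    stop_field("min_probs", sprintf(
      "minimum allocation probabilities sum to %.4g > 1 (infeasible)",
      sum(min_probs, na.rm = TRUE)))
  }
  if (!is.null(min_probs) && !is.null(max_probs)) {
    both <- !is.na(min_probs) & !is.na(max_probs)
    if (any(max_probs[both] < min_probs[both])) {
      stop_field("max_probs", "max_probs must be >= min_probs elementwise")
    }
  }

  data_looks <- as.numeric(data_looks)
  if (length(data_looks) < 1 || any(data_looks <= 0)) {
    stop_field("data_looks", "a positive, strictly increasing schedule is required")
  }
  if (any(diff(data_looks) <= 0)) {
    stop_field("data_looks", "must be strictly increasing")
  }
  n_looks <- length(data_looks)
  if (is.null(randomised_at_looks)) randomised_at_looks <- data_looks
  randomised_at_looks <- as.numeric(randomised_at_looks)
  if (length(randomised_at_looks) != n_looks) {
    stop_field("randomised_at_looks", "must have the same length as data_looks")
  }
  if (any(diff(randomised_at_looks) <= 0)) {
    stop_field("randomised_at_looks", "must be strictly increasing")
  }
  if (any(randomised_at_looks < data_looks)) {
    stop_field("randomised_at_looks",
               "cannot be smaller than data_looks at any analysis")
  }
  if (randomised_at_looks[n_looks] != data_looks[n_looks]) {
    stop_field("randomised_at_looks",
               "the final numbers randomised and with data must be equal")
  }

  inferiority <- expand_thresholds(inferiority, n_looks, "inferiority")
  superiority <- expand_thresholds(superiority, n_looks, "superiority")
  check_prob_vec <- function(x, field) {
    if (any(x < 0 | x > 1)) stop_field(field, "probabilities must lie in [0, 1]")
  }
  check_prob_vec(inferiority, "inferiority")
  check_prob_vec(superiority, "superiority")
  if (any(superiority <= inferiority)) {
    stop_field("superiority", "must exceed inferiority at every analysis")
  }

  soften_power <- expand_thresholds(soften_power, n_looks, "soften_power")
  if (any(soften_power < 0 | soften_power > 1)) {
    stop_field("soften_power", "softening exponents must lie in [0, 1]")
  }

  equivalence_prob <- expand_thresholds(equivalence_prob, n_looks, "equivalence_prob")
  if (!is.null(equivalence_prob)) {
    check_prob_vec(equivalence_prob, "equivalence_prob")
    if (is.null(equivalence_diff) || equivalence_diff <= 0) {
      stop_field("equivalence_diff", "a positive equivalence margin is required")
    }
    if (equivalence_only_first && is.null(control)) {
      stop_field("equivalence_only_first", "requires a common control arm")
    }
  } else {
    equivalence_diff <- NULL
    equivalence_only_first <- FALSE
  }

  futility_prob <- expand_thresholds(futility_prob, n_looks, "futility_prob")
  if (!is.null(futility_prob)) {
    if (is.null(control)) {
      stop_field("futility_prob", "futility rules require a common control arm")
    }
    check_prob_vec(futility_prob, "futility_prob")
    if (is.null(futility_diff) || futility_diff < 0) {
      stop_field("futility_diff", "a non-negative futility margin is required")
    }
  } else {
    futility_diff <- NULL
    futility_only_first <- FALSE
  }

  if (control_prob_rule != "none" && is.null(control)) {
    stop_field("control_prob_rule", "requires a common control arm")
  }

  if (outcome_type == "binary") {
    if (prior_alpha <= 0 || prior_beta <= 0) {
      stop_field("prior_alpha", "beta prior parameters must be positive")
    }
    true_sds <- NULL
  } else {
    if (is.null(true_sds)) true_sds <- rep(1, k)
    true_sds <- as.numeric(true_sds)
    if (length(true_sds) == 1) true_sds <- rep(true_sds, k)
    if (length(true_sds) != k || any(true_sds < 0)) {
      stop_field("true_sds", "one non-negative standard deviation per arm required")
    }
  }

  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1) stop_field("n_draws", "must be a positive integer")
  if (n_draws < 1000) {
    warning(sprintf(
      paste0("n_draws = %d: with fewer than 1000 posterior draws the minimum ",
             "non-zero difference between estimated probabilities exceeds ",
             "0.1%%-points, which is coarse for strict stopping thresholds"),
      n_draws), call. = FALSE)
  }

  if (!is.null(draw_hook) && !is.function(draw_hook)) {
    stop_field("draw_hook", "must be a function")
  }

  spec <- structure(list(
    arms = arms,
    control = control,
    true_ys = true_ys,
    outcome_type = outcome_type,
    highest_is_best = isTRUE(highest_is_best),
    start_probs = start_probs,
    fixed_probs = fixed_probs,
    min_probs = min_probs,
    max_probs = max_probs,
    rescale_probs = rescale_probs,
    soften_power = soften_power,
    control_prob_rule = control_prob_rule,
    data_looks = data_looks,
    randomised_at_looks = randomised_at_looks,
    n_looks = n_looks,
    inferiority = inferiority,
    superiority = superiority,
    equivalence_prob = equivalence_prob,
    equivalence_diff = equivalence_diff,
    equivalence_only_first = isTRUE(equivalence_only_first),
    futility_prob = futility_prob,
    futility_diff = futility_diff,
    futility_only_first = isTRUE(futility_only_first),
    prior_alpha = prior_alpha,
    prior_beta = prior_beta,
    true_sds = true_sds,
    n_draws = n_draws,
    draw_hook = draw_hook,
    label = label %||% paste(format(true_ys, trim = TRUE), collapse = "/")
  ), class = "trial_spec")
  spec
}

#' Specify a trial with a binary, binomially distributed outcome
#'
#' Convenience wrapper around [setup_trial()] with a conjugate beta-binomial
#' analysis model and flat `Beta(1, 1)` priors by default (equivalent to two
#' pseudo-participants, one with and one without the event).
#'
#' @inheritParams setup_trial
#' @param ... Passed on to [setup_trial()].
#' @return A `trial_spec`.
#' @export
#' @examples
#' spec <- setup_trial_binom(
#'   arms = c("Arm A", "Arm B", "Arm C"),
#'   true_ys = c(0.25, 0.25, 0.25),
#'   highest_is_best = FALSE,
#'   min_probs = 0.25, rescale_probs = "limits", soften_power = 0.5,
#'   data_looks = seq(500, 2000, by = 500),
#'   inferiority = 0.01, superiority = 0.99,
#'   n_draws = 1000
#' )
#' spec
setup_trial_binom <- function(arms, true_ys, ...) {
  setup_trial(arms = arms, true_ys = true_ys, outcome_type = "binary", ...)
}

#' Specify a trial with a continuous, normally distributed outcome
#'
#' Convenience wrapper around [setup_trial()] using a normal approximation of
#' the posterior for each arm mean (centred at the sample mean with scale
#' sample SD / sqrt(n)); no prior information is used.
#'
#' @inheritParams setup_trial
#' @param true_sds True standard deviation per arm used to generate outcomes.
#' @param ... Passed on to [setup_trial()].
#' @return A `trial_spec`.
#' @export
setup_trial_norm <- function(arms, true_ys, true_sds = 1, ...) {
  setup_trial(arms = arms, true_ys = true_ys, true_sds = true_sds,
              outcome_type = "continuous", ...)
}

#' Deterministic fingerprint of a trial specification
#'
#' Hash of a canonical serialisation (sorted field names, fixed floating-point
#' formatting) of all design fields. Used to detect spec/result mismatches
#' when simulation batches are persisted and reloaded: reusing a results file
#' produced under a different design is an error, never silent.
#'
#' Note that a user-supplied `draw_hook` participates only as an opaque
#' marker; two specs differing only in hook internals share a fingerprint.
#'
#' @param spec A `trial_spec`.
#' @return A character scalar (MD5 hex digest).
#' @export
spec_fingerprint <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  fields <- spec[setdiff(names(spec), c("draw_hook", "label"))]
  fields$has_hook <- !is.null(spec$draw_hook)
  hash_string(canonical_string(fields))
}

#' Build the grid of clinical scenarios around a reference outcome
#'
#' Generates one trial specification per unique unordered combination of true
#' outcome values for the varying arms, drawn from the reference value and the
#' reference shifted by each delta in both directions. Arms not in
#' `varying_arms` are held at `reference`. Because only unordered value
#' combinations are distinct for designs without a common control, a grid with
#' two varying arms over deltas {0.025, 0.05} has exactly 15 scenarios.
#'
#' @param base_spec A `trial_spec`; all non-outcome fields are reused as-is.
#' @param reference Reference outcome parameter (e.g. the null event
#'   probability).
#' @param deltas Non-negative offsets; each contributes `reference - delta`
#'   and `reference + delta` to the candidate value set.
#' @param varying_arms Arm labels whose true values vary; must leave at least
#'   one arm at the reference.
#'
#' @return List of `trial_spec` objects with auto-generated scenario labels.
#' @export
#' @examples
#' spec <- setup_trial_binom(
#'   arms = c("Arm A", "Arm B", "Arm C"), true_ys = rep(0.25, 3),
#'   data_looks = c(500, 1000), superiority = 0.99, inferiority = 0.01,
#'   n_draws = 1000
#' )
#' grid <- scenario_grid(spec, reference = 0.25, deltas = c(0.025, 0.05),
#'                       varying_arms = c("Arm B", "Arm C"))
#' length(grid) # 15
scenario_grid <- function(base_spec, reference, deltas = numeric(),
                          varying_arms = NULL) {
  stopifnot(inherits(base_spec, "trial_spec"))
  arms <- base_spec$arms
  if (is.null(varying_arms)) varying_arms <- arms[-1]
  if (!all(varying_arms %in% arms)) {
    stop_field("varying_arms", "labels must be existing arms")
  }
  if (length(setdiff(arms, varying_arms)) < 1) {
    stop_field("varying_arms", "at least one arm must stay at the reference value")
  }
  deltas <- sort(unique(abs(as.numeric(deltas))))
  deltas <- deltas[deltas > 0]
  values <- sort(unique(c(reference, reference - deltas, reference + deltas)))
  if (base_spec$outcome_type == "binary" && (any(values < 0) || any(values > 1))) {
    stop_field("deltas", "generated event probabilities fall outside [0, 1]")
  }
  m <- length(varying_arms)
  combos <- combn_with_replacement(values, m)
  lapply(seq_len(nrow(combos)), function(i) {
    true_ys <- rep(reference, length(arms))
    names(true_ys) <- arms
    true_ys[varying_arms] <- combos[i, ]
    spec <- base_spec
    spec$true_ys <- unname(true_ys)
    spec$label <- paste(format(unname(true_ys), trim = TRUE), collapse = "/")
    spec
  })
}

# All unordered m-combinations with repetition of `values` (rows sorted
# ascending); C(length(values) + m - 1, m) rows.
combn_with_replacement <- function(values, m) {
  if (m == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  idx <- do.call(expand.grid, rep(list(seq_along(values)), m))
  keep <- apply(idx, 1, function(r) all(diff(as.numeric(r)) >= 0))
  idx <- as.matrix(idx[keep, , drop = FALSE])
  matrix(values[idx], ncol = m)
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("Trial specification: %d arms (%s outcome, %s is better)\n",
              length(x$arms), x$outcome_type,
              if (x$highest_is_best) "higher" else "lower"))
  cat(sprintf("  scenario: %s\n", x$label))
  cat(sprintf("  arms: %s%s\n", paste(x$arms, collapse = ", "),
              if (!is.null(x$control)) sprintf(" (control: %s)", x$control) else ""))
  cat(sprintf("  analyses: %d (data %g..%g; randomised %g..%g)\n",
              x$n_looks, x$data_looks[1], x$data_looks[x$n_looks],
              x$randomised_at_looks[1], x$randomised_at_looks[x$n_looks]))
  cat(sprintf("  superiority %s / inferiority %s\n",
              format_range(x$superiority), format_range(x$inferiority)))
  if (!is.null(x$equivalence_prob)) {
    cat(sprintf("  equivalence: prob %s, margin %g\n",
                format_range(x$equivalence_prob), x$equivalence_diff))
  }
  if (!is.null(x$futility_prob)) {
    cat(sprintf("  futility: prob %s, margin %g\n",
                format_range(x$futility_prob), x$futility_diff))
  }
  cat(sprintf("  softening %s; %d posterior draws\n",
              format_range(x$soften_power), x$n_draws))
  invisible(x)
}

format_range <- function(v) {
  if (length(unique(v)) == 1) format(v[1]) else
    sprintf("%s..%s (varying)", format(min(v)), format(max(v)))
}

#' Convert a trial specification to / from a plain configuration list
#'
#' `spec_to_config()` returns a plain named list mirroring the `trial_spec`
#' fields (suitable for YAML/JSON serialisation); `spec_from_config()`
#' rebuilds a validated spec from such a list. Look schedules may be given as
#' a `{from, to, by}` mapping instead of an explicit vector, and round-trips
#' are lossless: the rebuilt spec has an identical fingerprint.
#'
#' @param spec A `trial_spec`.
#' @param config A named list (e.g. parsed from a YAML file).
#' @return A list, or a `trial_spec` respectively.
#' @export
spec_to_config <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  out <- spec[setdiff(names(spec), c("n_looks", "draw_hook"))]
  out[!vapply(out, is.null, logical(1))]
}

#' @rdname spec_to_config
#' @export
spec_from_config <- function(config) {
  if (!is.list(config)) stop_field("config", "must be a named list")
  expand_seq <- function(x, field) {
    if (is.list(x) && all(c("from", "to", "by") %in% names(x))) {
      return(seq(from = x$from, to = x$to, by = x$by))
    }
    if (is.list(x)) return(unlist(x))
    x
  }
  for (f in c("data_looks", "randomised_at_looks")) {
    if (!is.null(config[[f]])) config[[f]] <- expand_seq(config[[f]], f)
  }
  # `randomised_at_looks` may carry an explicit trailing maximum after a
  # {from,to,by} triple, e.g. list(from=700, to=9950, by=250, then=10000)
  if (is.list(config$randomised_at_looks_then %||% NULL)) {
    config$randomised_at_looks <- c(config$randomised_at_looks,
                                    unlist(config$randomised_at_looks_then))
    config$randomised_at_looks_then <- NULL
  }
  known <- names(formals(setup_trial))
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop_field(extra[1], "unknown trial specification field")
  }
  missing_req <- setdiff(c("arms", "true_ys", "data_looks"), names(config))
  if (length(missing_req)) {
    stop_field(missing_req[1], "required field is missing")
  }
  do.call(setup_trial, config)
}

#' Read / write a trial configuration file
#'
#' Trial designs can be kept in declarative YAML (or JSON) files mirroring the
#' [setup_trial()] arguments verbatim; `read_trial_config()` parses and
#' validates one into a `trial_spec`, and `write_trial_config()` serialises a
#' spec losslessly (modulo any draw hook, which cannot be represented in a
#' declarative file).
#'
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   otherwise YAML).
#' @param spec A `trial_spec`.
#' @return A `trial_spec`; `write_trial_config()` returns `path` invisibly.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop_field("config", sprintf("file not found: %s", path))
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec_from_config(config)
}

#' @rdname read_trial_config
#' @export
write_trial_config <- function(spec, path) {
  config <- spec_to_config(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else {
    # full precision so probabilities like 1/3 survive the round-trip
    yaml::write_yaml(config, path, precision = 15)
  }
  invisible(path)
}
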