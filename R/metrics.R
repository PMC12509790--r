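# Operating characteristics: per-simulation extraction, arm selection
# strategies, summary performance metrics, bootstrap CIs and the ideal
# design percentage.

#' Select an arm for a single simulated trial
#'
#' Trials stopped for superiority always select the declared superior arm.
#' For other trials the selection depends on the strategy: `"superiority_only"`
#' selects no arm; `"control_if_undeclared"` selects the original common
#' control if it was never dropped; `"prespecified_arm"` selects a named arm;
#' `"best_at_final"` selects the arm with the highest probability of being
#' best at the last analysis conducted.
#'
#' @param result A `trial_result`.
#' @param strategy One of `"superiority_only"`, `"control_if_undeclared"`,
#'   `"prespecified_arm"`, `"best_at_final"`.
#' @param prespecified Arm label (required for `"prespecified_arm"`).
#' @return Arm label, or `NA_character_` when no arm is selected.
#' @export
select_arm <- function(result,
                       strategy = c("superiority_only", "control_if_undeclared",
                                    "prespecified_arm", "best_at_final"),
                       prespecified = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(result$superior_arm)) return(result$superior_arm)
  a <- result$arms
  switch(strategy,
    superiority_only = NA_character_,
    control_if_undeclared = {
      if (!any(a$is_control)) {
        stop_field("strategy", "control_if_undeclared requires a common control arm")
      }
      ctrl <- a$arm[a$is_control]
      if (a$status[a$is_control] %in% c("active")) ctrl else NA_character_
    },
    prespecified_arm = {
      if (is.null(prespecified) || !prespecified %in% a$arm) {
        stop_field("prespecified", "a valid arm label is required for prespecified_arm")
      }
      prespecified
    },
    best_at_final = {
      pb <- a$prob_best
      if (all(is.na(pb))) NA_character_ else a$arm[which.max(pb)]
    }
  )
}

#' Extract per-simulation results as a data frame
#'
#' One row per simulation: final status, stopping look, sample size, summed
#' outcome, outcome/sample-size ratio, superior and selected arms (under the
#' given selection strategy), the selected arm's posterior estimate at the
#' final analysis, its true value, the estimation error
#' `err = estimate - truth`, and — when a reference arm is available — the
#' intervention-effect error
#' `err_effect = (estimate - ref_estimate) - (truth - ref_truth)`, defined
#' only when a non-reference arm is selected.
#'
#' @param batch A `trial_results` object.
#' @param select_strategy Passed to [select_arm()].
#' @param prespecified Passed to [select_arm()].
#' @param reference Reference arm for intervention-effect errors; defaults to
#'   the common control when present.
#' @param estimator `"mean"` (default) or `"median"`: which posterior central
#'   estimate is used (the median requires draws and is approximated by the
#'   stored posterior mean for conjugate models; kept as an explicit option
#'   for hook-based models that store medians).
#' @return A data frame of class `sim_results`.
#' @export
extract_results <- function(batch, select_strategy = "superiority_only",
                            prespecified = NULL, reference = NULL,
                            estimator = c("mean", "median")) {
  stopifnot(inherits(batch, "trial_results"))
  estimator <- match.arg(estimator)
  spec <- batch$spec
  reference <- reference %||% spec$control

  rows <- lapply(seq_along(batch$results), function(i) {
    r <- batch$results[[i]]
    sel <- select_arm(r, select_strategy, prespecified)
    est <- truth <- err <- err_effect <- NA_real_
    if (!is.na(sel)) {
      j <- match(sel, r$arms$arm)
      est <- r$arms$post_mean[j]
      truth <- r$arms$true_y[j]
      err <- est - truth
      if (!is.null(reference) && !identical(sel, reference)) {
        jr <- match(reference, r$arms$arm)
        ref_est <- r$arms$post_mean[jr]
        if (!is.na(ref_est)) {
          err_effect <- (est - ref_est) - (truth - r$arms$true_y[jr])
        }
      }
    }
    data.frame(
      sim = i,
      final_status = r$final_status,
      stop_look = r$stop_look,
      sample_size = r$n_randomised,
      sum_ys = r$sum_ys,
      ratio_ys = r$sum_ys / r$n_randomised,
      superior_arm = r$superior_arm %||% NA_character_,
      selected_arm = sel,
      est_selected = est,
      true_selected = truth,
      err = err,
      err_effect = err_effect,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  attr(out, "select_strategy") <- select_strategy
  class(out) <- c("sim_results", "data.frame")
  out
}

#' Ideal design percentage
#'
#' Locates the expected true outcome among selected arms between the worst
#' and best true arm values on a 0-100 scale: with `E(y)` the mean true value
#' of the selected arms across simulations, the IDP for desirable outcomes is
#' `(E(y) - min) / (max - min) * 100`; for undesirable outcomes the
#' complement (`100 - ...`) is returned, so 100 always means the truly best
#' arm was selected in every simulation. Undefined (error) when all arms
#' share the same true value or no simulation selected an arm.
#'
#' @param selected_truths True outcome values of the selected arm per
#'   simulation (drop non-selections first).
#' @param true_ys True values of all arms.
#' @param highest_is_best Are higher values desirable?
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' idp(c(0.20, 0.20, 0.25, 0.25), c(0.25, 0.20, 0.30), highest_is_best = FALSE)
idp <- function(selected_truths, true_ys, highest_is_best = FALSE) {
  selected_truths <- selected_truths[!is.na(selected_truths)]
  if (!length(selected_truths)) {
    stop_field("selected_truths", "no simulations with a selected arm")
  }
  x_min <- min(true_ys); x_max <- max(true_ys)
  if (x_max - x_min <= 0) {
    stop_field("true_ys", "IDP is undefined when all arms share the same true value")
  }
  e_y <- mean(selected_truths)
  idp_desirable <- (e_y - x_min) / (x_max - x_min) * 100
  if (highest_is_best) idp_desirable else 100 - idp_desirable
}

metric_quantile <- function(x, p) {
  # linear-interpolation quantiles (type 7), the documented convention
  unname(quantile(x, p, type = 7, na.rm = TRUE))
}

# Point estimates of every performance metric from a sim_results table.
compute_metrics <- function(rows, spec) {
  summarise_dist <- function(x, prefix) {
    out <- c(mean(x), sd(x), median(x), metric_quantile(x, 0.25),
             metric_quantile(x, 0.75), min(x), max(x))
    names(out) <- paste0(prefix, c("_mean", "_sd", "_median", "_p25", "_p75",
                                   "_min", "_max"))
    out
  }
  n <- nrow(rows)
  st <- rows$final_status
  p_sup <- mean(st == "superiority")
  p_equ <- mean(st == "equivalence")
  p_fut <- mean(st == "futility")
  p_max <- mean(st == "max")

  sel_frac <- vapply(spec$arms, function(a)
    mean(!is.na(rows$selected_arm) & rows$selected_arm == a), numeric(1))
  names(sel_frac) <- paste0("prob_select_", gsub("[^A-Za-z0-9]+", "_", spec$arms))

  # erroneous superiority: declared arm is not the unique truly best arm
  best_val <- if (spec$highest_is_best) max(spec$true_ys) else min(spec$true_ys)
  best_arms <- spec$arms[spec$true_ys == best_val]
  sup_rows <- st == "superiority"
  err_sup <- if (length(best_arms) > 1) {
    mean(sup_rows)
  } else {
    mean(sup_rows & rows$superior_arm != best_arms)
  }

  errs <- rows$err[!is.na(rows$err)]
  rmse <- if (length(errs)) sqrt(mean(errs^2)) else NA_real_
  mae <- if (length(errs)) median(abs(errs)) else NA_real_
  errs_te <- rows$err_effect[!is.na(rows$err_effect)]
  rmse_te <- if (length(errs_te)) sqrt(mean(errs_te^2)) else NA_real_
  mae_te <- if (length(errs_te)) median(abs(errs_te)) else NA_real_

  idp_val <- if (length(unique(spec$true_ys)) > 1 &&
                 any(!is.na(rows$true_selected))) {
    idp(rows$true_selected, spec$true_ys, spec$highest_is_best)
  } else NA_real_

  c(
    summarise_dist(rows$sample_size, "size"),
    summarise_dist(rows$sum_ys, "sum_ys"),
    summarise_dist(rows$ratio_ys, "ratio_ys"),
    prob_conclusive = p_sup + p_equ + p_fut,
    prob_superior = p_sup,
    prob_equivalence = p_equ,
    prob_futility = p_fut,
    prob_max = p_max,
    sel_frac,
    prob_select_none = mean(is.na(rows$selected_arm)),
    prob_err_superior = err_sup,
    rmse = rmse,
    mae = mae,
    rmse_te = rmse_te,
    mae_te = mae_te,
    idp = idp_val
  )
}

#' Summarise performance metrics across a batch of simulations
#'
#' Computes the full suite of operating characteristics: sample-size, summed
#' outcome and outcome-ratio summaries (mean, SD, median, 25%/75% quantiles,
#' range); probabilities of conclusiveness, superiority, equivalence,
#' futility and of reaching the maximum sample size without stopping; per-arm
#' selection probabilities (and no selection) under the chosen strategy;
#' probability of an erroneous overall superiority decision (declaring an arm
#' superior that is not the \emph{unique} truly best arm); RMSE and median
#' absolute error of the selected arm's posterior estimate and of the
#' intervention effect against a reference arm; and the ideal design
#' percentage. Optional percentile bootstrap confidence intervals resample
#' whole simulations with replacement.
#'
#' @param batch A `trial_results` object (or a `sim_results` data frame from
#'   [extract_results()]).
#' @param select_strategy,prespecified,reference,estimator Passed to
#'   [extract_results()] when `batch` is a `trial_results`.
#' @param uncertainty Compute bootstrap CIs?
#' @param n_boot Number of bootstrap resamples.
#' @param ci_width Coverage of the percentile interval (in (0, 1)).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A data frame of class `trial_performance` with columns `metric`,
#'   `est` and, with `uncertainty`, `ci_lo` / `ci_hi`.
#' @export
check_performance <- function(batch, select_strategy = "superiority_only",
                              prespecified = NULL, reference = NULL,
                              estimator = "mean",
                              uncertainty = FALSE, n_boot = 5000,
                              ci_width = 0.95, boot_seed = NULL) {
  rows <- if (inherits(batch, "sim_results")) batch else {
    extract_results(batch, select_strategy, prespecified, reference, estimator)
  }
  if (!nrow(rows)) stop_field("batch", "no simulations to summarise")
  spec <- attr(rows, "spec")
  est <- compute_metrics(rows, spec)
  out <- data.frame(metric = names(est), est = unname(est),
                    stringsAsFactors = FALSE)
  if (uncertainty) {
    if (ci_width <= 0 || ci_width >= 1) {
      stop_field("ci_width", "must lie strictly between 0 and 1")
    }
    if (n_boot < 1) stop_field("n_boot", "must be at least 1")
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    if (!is.null(boot_seed)) set.seed(boot_seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample.int(nrow(rows), replace = TRUE)
      compute_metrics(rows[take, , drop = FALSE], spec)
    }, numeric(length(est)))
    alpha <- (1 - ci_width) / 2
    out$ci_lo <- apply(boots, 1, function(v) metric_quantile(v, alpha))
    out$ci_hi <- apply(boots, 1, function(v) metric_quantile(v, 1 - alpha))
  }
  class(out) <- c("trial_performance", "data.frame")
  out
}

#' @export
print.trial_performance <- function(x, digits = 4, ...) {
  cat("Performance metrics across simulations\n")
  y <- x
  y$est <- signif(y$est, digits)
  if ("ci_lo" %in% names(y)) {
    y$ci_lo <- signif(y$ci_lo, digits)
    y$ci_hi <- signif(y$ci_hi, digits)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Summarise the combinations of arms remaining at the final analysis
#'
#' Tabulates, across simulations, which combination of arms was still active
#' at the last analysis conducted (arms dropped at the stopping analysis
#' itself, e.g. the declared superior arm or arms declared equivalent, count
#' as remaining at that analysis), together with the final status of each
#' arm. Proportions sum to 1.
#'
#' @param batch A `trial_results` object.
#' @return Data frame with columns `arms_remaining`, `statuses`, `n`,
#'   `proportion`, ordered by decreasing proportion.
#' @export
check_remaining_arms <- function(batch) {
  stopifnot(inherits(batch, "trial_results"))
  combos <- vapply(batch$results, function(r) {
    a <- r$arms
    # an arm counts as remaining if it entered the final analysis, i.e. it
    # was never dropped, or its status was set at the stopping analysis
    stay <- a$status == "active" |
      (!is.na(a$status_look) & a$status_look == r$stop_look)
    paste0(paste(a$arm[stay], collapse = " + "), "|",
           paste(a$status[stay], collapse = " + "))
  }, character(1))
  tab <- sort(table(combos), decreasing = TRUE)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(
    arms_remaining = vapply(parts, `[`, character(1), 1),
    statuses = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                      character(1)),
    n = as.integer(tab),
    proportion = as.numeric(tab) / batch$n_rep,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
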