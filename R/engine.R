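# Single-trial simulation engine: accrual with outcome-data lag, posterior
# probabilities, decision rules with priority ordering, control promotion,
# arm dropping and response-adaptive allocation updates.

#' Probability of each arm being best
#'
#' For every draw index, the optimum (highest or lowest value, by
#' desirability) across arms is found; each arm's probability of being best is
#' the fraction of draw indices at which it attains the optimum. Ties within
#' a draw are split equally among the tied arms, so the probabilities always
#' sum to 1. A single-arm matrix returns 1.
#'
#' @param draws Draw matrix (rows = draws, columns = arms, see
#'   [posterior_draws()]).
#' @param highest_is_best Are higher values desirable?
#' @return Named numeric vector of probabilities summing to 1.
#' @export
prob_best <- function(draws, highest_is_best = FALSE) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 1 || nrow(draws) < 1) stop_field("draws", "empty draw matrix")
  if (ncol(draws) == 1) {
    return(setNames(1, colnames(draws)))
  }
  n <- nrow(draws)
  k <- ncol(draws)
  # argmax per draw via max.col (C-level); fall back to fractional tie
  # splitting only when ties actually occur
  mc <- max.col(if (highest_is_best) draws else -draws, ties.method = "first")
  opt <- draws[cbind(seq_len(n), mc)]
  at_opt <- draws == opt
  ties <- rowSums(at_opt)
  p <- if (all(ties == 1L)) {
    tabulate(mc, nbins = k) / n
  } else {
    colSums(at_opt / ties) / n
  }
  setNames(p, colnames(draws))
}

#' Pairwise probability of beating the common control
#'
#' For each non-control arm, the fraction of draw indices where its value is
#' strictly better (by desirability) than the control's.
#'
#' @inheritParams prob_best
#' @param control Label of the control arm (must be a column of `draws`).
#' @return Named numeric vector over non-control arms.
#' @export
prob_better_than_control <- function(draws, control, highest_is_best = FALSE) {
  draws <- as.matrix(draws)
  if (!control %in% colnames(draws)) {
    stop_field("control", "control arm not present in the draw matrix")
  }
  others <- setdiff(colnames(draws), control)
  ctrl <- draws[, control]
  vapply(others, function(a) {
    if (highest_is_best) mean(draws[, a] > ctrl) else mean(draws[, a] < ctrl)
  }, numeric(1))
}

#' Probability that all arms are practically equivalent
#'
#' Fraction of draw indices at which the largest absolute difference between
#' any two arms (i.e. the range across arms) is smaller than the margin.
#'
#' @inheritParams prob_best
#' @param margin Positive absolute-scale equivalence margin.
#' @return Probability in \[0, 1\].
#' @export
prob_all_equivalent <- function(draws, margin) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop_field("draws", "equivalence needs at least 2 arms")
  if (margin <= 0) stop_field("margin", "must be positive")
  cols <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  hi <- do.call(pmax, cols)
  lo <- do.call(pmin, cols)
  mean((hi - lo) < margin)
}

#' Pairwise probability of practical equivalence with the control
#'
#' @param arm_draws,control_draws Draw vectors for one arm and the control.
#' @param margin Positive absolute-scale equivalence margin.
#' @return Probability in \[0, 1\].
#' @export
prob_equiv_vs_control <- function(arm_draws, control_draws, margin) {
  if (margin <= 0) stop_field("margin", "must be positive")
  mean(abs(arm_draws - control_draws) < margin)
}

#' Pairwise probability of futility against the control
#'
#' Probability that the arm is \emph{not} sufficiently better than the
#' control: the fraction of draw indices where the arm's improvement over the
#' control, signed toward desirability, is smaller than the margin (which
#' includes every draw where the arm is worse).
#'
#' @inheritParams prob_equiv_vs_control
#' @param highest_is_best Are higher values desirable?
#' @param margin Non-negative margin for a relevant improvement.
#' @return Probability in \[0, 1\].
#' @export
prob_futile_vs_control <- function(arm_draws, control_draws, margin,
                                   highest_is_best = FALSE) {
  if (margin < 0) stop_field("margin", "must be non-negative")
  improvement <- if (highest_is_best) arm_draws - control_draws
                 else control_draws - arm_draws
  mean(improvement < margin)
}

#' Randomise a block of participants
#'
#' Allocates `n_new` participants to arms by independent draws from the given
#' allocation probabilities and returns per-arm counts (multinomially
#' distributed). Arms with probability 0 receive no participants.
#'
#' @param alloc_probs Allocation probabilities (summing to 1).
#' @param n_new Number of participants to randomise.
#' @return Integer vector of counts summing to `n_new`.
#' @export
randomise_block <- function(alloc_probs, n_new) {
  if (n_new < 0) stop_field("n_new", "must be non-negative")
  if (abs(sum(alloc_probs) - 1) > 1e-6) {
    stop_field("alloc_probs", "must sum to 1")
  }
  tabulate(assign_arms(alloc_probs, n_new), nbins = length(alloc_probs))
}

# Participant-level arm assignment preserving randomisation order (needed to
# mask lagged outcome data at each analysis).
assign_arms <- function(alloc_probs, n_new) {
  if (n_new == 0) return(integer(0))
  pos <- which(alloc_probs > 0)
  if (length(pos) == 1) return(rep(pos, n_new))
  sample(pos, n_new, replace = TRUE, prob = alloc_probs[pos])
}

#' Generate outcomes for newly randomised participants
#'
#' Binary outcomes are Bernoulli draws coded 0/1 (1 = event); continuous
#' outcomes are normal draws with the arm's true mean and SD.
#'
#' @param true_y True event probability (binary) or mean (continuous).
#' @param n Number of participants.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param true_sd True SD (continuous outcomes only).
#' @return Numeric vector of `n` outcomes.
#' @export
generate_outcomes <- function(true_y, n, outcome_type = "binary", true_sd = 1) {
  if (outcome_type == "binary") {
    if (true_y < 0 || true_y > 1) stop_field("true_y", "must lie in [0, 1]")
    rbinom(n, 1, true_y)
  } else {
    rnorm(n, true_y, true_sd)
  }
}

#' Update allocation probabilities by restricted response-adaptive
#' randomisation
#'
#' Computes the allocation probabilities in force for the next accrual block:
#' raw probabilities of being best are raised to the softening exponent for
#' the current look and renormalised; fixed-probability arms are pinned;
#' an optional control-allocation rule is applied; and minimum/maximum limits
#' are enforced by iterative clamp-and-renormalise. When arms have been
#' dropped and `rescale_probs = "limits"`, limits are first rescaled by
#' (initial arms / active arms), with rescaled minima capped at
#' 1 / (active arms) and maxima capped at 1 to preserve feasibility.
#'
#' @param p_best Named probabilities of being best over \emph{active} arms.
#' @param spec A `trial_spec`.
#' @param look Look index (selects the softening exponent).
#' @param active_idx Indices of active arms within `spec$arms`.
#' @param control Label of the current control arm, or `NULL`.
#' @return Named allocation probabilities over the active arms (sum 1).
#' @export
update_allocation <- function(p_best, spec, look, active_idx = NULL,
                              control = NULL) {
  arms <- names(p_best)
  if (is.null(active_idx)) active_idx <- match(arms, spec$arms)
  k_act <- length(arms)
  if (k_act == 1) return(setNames(1, arms))

  soften <- spec$soften_power[min(look, spec$n_looks)]
  raw <- if (soften == 0) rep(1, k_act) else as.numeric(p_best)^soften
  if (sum(raw) <= 0) raw <- rep(1, k_act)
  w <- raw / sum(raw)
  names(w) <- arms

  fixed <- spec$fixed_probs[active_idx] %||% rep(NA_real_, k_act)
  mins <- spec$min_probs[active_idx] %||% rep(NA_real_, k_act)
  maxs <- spec$max_probs[active_idx] %||% rep(NA_real_, k_act)

  # rescale limits when arms have been dropped
  k_init <- length(spec$arms)
  if (spec$rescale_probs == "limits" && k_act < k_init) {
    scale <- k_init / k_act
    mins <- pmin(mins * scale, 1 / k_act)
    maxs <- pmin(maxs * scale, 1)
  }
  if (sum(mins, na.rm = TRUE) > 1 + 1e-9) {
    stop_field("min_probs", sprintf(
      "rescaled minimum allocation probabilities are infeasible at analysis %d", look))
  }

  # control-allocation rule (applied before limits)
  if (!is.null(control) && control %in% arms &&
      spec$control_prob_rule != "none") {
    m <- k_act - 1
    ctrl_share <- if (spec$control_prob_rule == "sqrt_ratio") {
      sqrt(m) / (sqrt(m) + m)
    } else { # match_highest
      nc <- setdiff(arms, control)
      ph <- max(w[nc])
      ph / (ph + sum(w[nc]))
    }
    nc <- setdiff(arms, control)
    w[control] <- ctrl_share
    w[nc] <- w[nc] / sum(w[nc]) * (1 - ctrl_share)
  }

  clamp_renormalise(w, fixed, mins, maxs)
}

# Clamp-and-renormalise: allocations are val_i = clip(c * w_i, min_i, max_i)
# for the common scale c that makes the free (non-fixed) arms absorb the mass
# left by fixed arms; sum(clip(c * w)) is continuous and non-decreasing in c,
# so c is found by bisection. Arms clamped at a limit sit exactly on it and
# the rest stay proportional to their weights.
clamp_renormalise <- function(w, fixed, mins, maxs) {
  k <- length(w)
  val <- numeric(k)
  has_fixed <- !is.na(fixed)
  val[has_fixed] <- fixed[has_fixed]
  free <- which(!has_fixed)
  mass <- 1 - sum(val[has_fixed])
  if (length(free)) {
    lo <- ifelse(is.na(mins[free]), 0, mins[free])
    hi <- ifelse(is.na(maxs[free]), 1, maxs[free])
    wf <- w[free]
    if (sum(wf) <= 0) wf <- rep(1, length(free))
    if (sum(lo) > mass + 1e-9) {
      stop_field("min_probs", "minimum allocation probabilities are infeasible")
    }
    if (sum(hi) < mass - 1e-9) {
      stop_field("max_probs", "maximum allocation probabilities are infeasible")
    }
    cc <- solve_clip_scale(wf, lo, hi, mass)
    val[free] <- pmin(pmax(cc * wf, lo), hi)
    # spread any residual rounding error over the unclamped arms
    at_limit <- val[free] <= lo + 1e-12 | val[free] >= hi - 1e-12
    resid <- mass - sum(val[free])
    if (abs(resid) > 0 && any(!at_limit)) {
      prop <- val[free][!at_limit]
      val[free][!at_limit] <- prop + resid * prop / sum(prop)
    }
  }
  setNames(pmax(val, 0), names(w))
}

# Exact solve of sum(clip(c * w, lo, hi)) = mass for the scalar c: the sum is
# piecewise linear and non-decreasing in c with breakpoints at lo/w and hi/w,
# so walking the sorted breakpoints and interpolating is exact.
solve_clip_scale <- function(wf, lo, hi, mass) {
  pos <- wf > 0
  if (!all(pos)) {
    # zero-weight arms sit at their lower bound for every c
    mass <- mass - sum(lo[!pos])
    wf <- wf[pos]; lo <- lo[pos]; hi <- hi[pos]
    if (!length(wf)) return(0)
  }
  total <- function(c) sum(pmin(pmax(c * wf, lo), hi))
  bps <- sort(unique(c(lo / wf, hi / wf)))
  prev_c <- 0
  prev_t <- sum(lo)
  for (b in bps) {
    tb <- total(b)
    if (tb >= mass - 1e-15) {
      if (tb <= prev_t) return(b)
      return(prev_c + (mass - prev_t) * (b - prev_c) / (tb - prev_t))
    }
    prev_c <- b
    prev_t <- tb
  }
  bps[length(bps)] # mass == sum(hi) up to rounding (feasibility pre-checked)
}

# -- decision rules ----------------------------------------------------------

#' Apply the stopping and arm-dropping rules at one adaptive analysis
#'
#' Rules are evaluated in strict priority order: (a) superiority/inferiority,
#' (b) practical equivalence, (c) futility. Without a common control,
#' superiority/inferiority are based on each active arm's probability of
#' being overall best, and equivalence on the probability that the largest
#' absolute difference between all active arms is below the margin. With a
#' common control, all probabilities are pairwise against the control; a
#' superior non-control arm replaces the control (ties broken by the highest
#' probability of being overall best) and pairwise comparisons are
#' immediately recomputed against the remaining arms before any further
#' accrual.
#'
#' @param draws Draw matrix over the active arms.
#' @param look Look index.
#' @param spec A `trial_spec`.
#' @param control Label of the current control arm, or `NULL`.
#' @param first_control Label of the original control arm (for the
#'   `*_only_first` flags), or `NULL`.
#' @return A list with `stop` (logical), `final_status`, `superior_arm`,
#'   `dropped` (named character vector: status per dropped arm),
#'   `new_control`, and `p_best` (probabilities of being best over the arms
#'   active at entry).
#' @export
apply_decision_rules <- function(draws, look, spec, control = NULL,
                                 first_control = NULL) {
  arms <- colnames(draws)
  hib <- spec$highest_is_best
  dropped <- character(0)
  new_control <- NULL
  p_best <- prob_best(draws, hib)

  sup_thr <- spec$superiority[look]
  inf_thr <- spec$inferiority[look]

  if (is.null(control)) {
    # superiority: only the overall-best candidate can trigger a stop
    if (max(p_best) > sup_thr) {
      winner <- arms[which.max(p_best)]
      return(list(stop = TRUE, final_status = "superiority",
                  superior_arm = winner, dropped = dropped,
                  new_control = NULL, p_best = p_best))
    }
    # inferiority: drop arms unlikely to be best; the current best arm is
    # never dropped (relevant only for lax thresholds >= 1/#arms)
    inf_arms <- setdiff(arms[p_best < inf_thr], arms[which.max(p_best)])
    if (length(inf_arms)) {
      dropped[inf_arms] <- "inferior"
      arms <- setdiff(arms, inf_arms)
      if (length(arms) == 1) {
        return(list(stop = TRUE, final_status = "superiority",
                    superior_arm = arms, dropped = dropped,
                    new_control = NULL, p_best = p_best))
      }
      draws <- draws[, arms, drop = FALSE]
    }
    # equivalence across all remaining arms
    if (!is.null(spec$equivalence_prob) && spec$equivalence_prob[look] < 1) {
      p_eq <- prob_all_equivalent(draws, spec$equivalence_diff)
      if (p_eq > spec$equivalence_prob[look]) {
        return(list(stop = TRUE, final_status = "equivalence",
                    superior_arm = NULL, dropped = dropped,
                    new_control = NULL, p_best = p_best))
      }
    }
    return(list(stop = FALSE, final_status = NULL, superior_arm = NULL,
                dropped = dropped, new_control = NULL, p_best = p_best))
  }

  # ---- common-control path: pairwise comparisons, recomputed after any
  # control promotion at the same analysis ----
  repeat {
    non_ctrl <- setdiff(arms, control)
    if (!length(non_ctrl)) break
    p_vs <- prob_better_than_control(draws[, arms, drop = FALSE], control, hib)
    sup_arms <- non_ctrl[p_vs[non_ctrl] > sup_thr]
    if (length(sup_arms)) {
      promoted <- if (length(sup_arms) == 1) sup_arms else {
        pb <- prob_best(draws[, arms, drop = FALSE], hib)
        sup_arms[which.max(pb[sup_arms])]
      }
      dropped[control] <- "control_replaced"
      arms <- setdiff(arms, control)
      control <- promoted
      new_control <- promoted
      if (length(arms) == 1) {
        return(list(stop = TRUE, final_status = "superiority",
                    superior_arm = control, dropped = dropped,
                    new_control = new_control, p_best = p_best))
      }
      next # immediate re-comparison against the new control
    }
    inf_arms <- non_ctrl[p_vs[non_ctrl] < inf_thr]
    if (length(inf_arms)) {
      dropped[inf_arms] <- "inferior"
      arms <- setdiff(arms, inf_arms)
      if (length(arms) == 1) {
        return(list(stop = TRUE, final_status = "superiority",
                    superior_arm = control, dropped = dropped,
                    new_control = new_control, p_best = p_best))
      }
    }
    break
  }

  # equivalence / futility vs control (drop non-control arms; stop when only
  # the control remains)
  ctrl_draws <- draws[, control]
  check_pairwise_rule <- function(arms, prob_vec, margin, only_first, status,
                                  prob_fun) {
    if (only_first && !identical(control, first_control)) return(character(0))
    if (is.null(prob_vec) || prob_vec[look] >= 1) return(character(0))
    non_ctrl <- setdiff(arms, control)
    hits <- vapply(non_ctrl, function(a) {
      prob_fun(draws[, a]) > prob_vec[look]
    }, logical(1))
    non_ctrl[hits]
  }

  eq_arms <- check_pairwise_rule(arms, spec$equivalence_prob,
                                 spec$equivalence_diff,
                                 spec$equivalence_only_first, "equivalence",
                                 function(d) prob_equiv_vs_control(d, ctrl_draws, spec$equivalence_diff))
  if (length(eq_arms)) {
    dropped[eq_arms] <- "equivalence"
    arms <- setdiff(arms, eq_arms)
    if (length(arms) == 1) {
      return(list(stop = TRUE, final_status = "equivalence",
                  superior_arm = NULL, dropped = dropped,
                  new_control = new_control, p_best = p_best))
    }
  }

  fut_arms <- check_pairwise_rule(arms, spec$futility_prob,
                                  spec$futility_diff,
                                  spec$futility_only_first, "futility",
                                  function(d) prob_futile_vs_control(d, ctrl_draws, spec$futility_diff, hib))
  if (length(fut_arms)) {
    dropped[fut_arms] <- "futility"
    arms <- setdiff(arms, fut_arms)
    if (length(arms) == 1) {
      return(list(stop = TRUE, final_status = "futility",
                  superior_arm = NULL, dropped = dropped,
                  new_control = new_control, p_best = p_best))
    }
  }

  list(stop = FALSE, final_status = NULL, superior_arm = NULL,
       dropped = dropped, new_control = new_control, p_best = p_best)
}

# -- single-trial loop -------------------------------------------------------

#' Simulate a single adaptive trial
#'
#' Runs one trial under the design: at each adaptive analysis, participants
#' are randomised up to the scheduled cumulative number under the allocation
#' probabilities in force for the block, outcomes are generated immediately
#' but only the first `data_looks[i]` randomised participants are analysed
#' (the remainder model the outcome-data lag), posterior draws are computed
#' for the active arms, decision rules applied in priority order, and — if
#' the trial continues — allocation probabilities updated by restricted
#' response-adaptive randomisation. Reaching the final analysis without
#' triggering any rule gives final status `"max"`. Deterministic given
#' `(spec, seed)`.
#'
#' @param spec A `trial_spec`.
#' @param seed Integer seed for this trial (ignored when an explicit RNG
#'   `stream` is supplied by the batch runner).
#' @param stream Optional `.Random.seed` vector (L'Ecuyer-CMRG stream).
#' @return An object of class `trial_result`: final status (`"superiority"`,
#'   `"equivalence"`, `"futility"` or `"max"`), stopping look, numbers
#'   randomised/analysed, the superior arm (if any), total summed outcome
#'   over all randomised participants, and a per-arm summary data frame
#'   (status, status look, counts, summed outcomes, final posterior mean,
#'   probability of being best, allocation probability).
#' @export
#' @examples
#' spec <- setup_trial_binom(
#'   arms = c("A", "B"), true_ys = c(0.2, 0.3), highest_is_best = FALSE,
#'   data_looks = c(200, 400), superiority = 0.975, inferiority = 0.025,
#'   n_draws = 1000
#' )
#' run_trial(spec, seed = 1)
run_trial <- function(spec, seed = NULL, stream = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  if (!is.null(stream)) {
    return(with_stream(stream, run_trial_impl(spec)))
  }
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  if (!is.null(seed)) set.seed(seed)
  run_trial_impl(spec)
}

run_trial_impl <- function(spec) {
  k <- length(spec$arms)
  arms <- spec$arms
  ctrl <- spec$control
  first_ctrl <- ctrl
  active <- rep(TRUE, k)
  status <- rep("active", k)
  status_look <- rep(NA_integer_, k)
  alloc <- spec$start_probs

  # participant-level records in randomisation order
  max_n <- spec$randomised_at_looks[spec$n_looks]
  assign_vec <- integer(max_n)
  outcome_vec <- numeric(max_n)
  n_total <- 0L

  # per-arm analysed counts, updated incrementally
  n_analysed <- integer(k)
  sum_analysed <- numeric(k)
  d_prev <- 0L

  final_status <- "max"
  superior_arm <- NULL
  stop_look <- spec$n_looks
  last_p_best <- setNames(rep(NA_real_, k), arms)
  last_post_mean <- setNames(rep(NA_real_, k), arms)

  for (i in seq_len(spec$n_looks)) {
    # accrue the block for this analysis under the current allocation
    n_target <- spec$randomised_at_looks[i]
    n_new <- as.integer(n_target - n_total)
    if (n_new > 0) {
      idx <- (n_total + 1L):n_target
      a <- assign_arms(alloc, n_new)
      assign_vec[idx] <- a
      outcome_vec[idx] <- if (spec$outcome_type == "binary") {
        rbinom(n_new, 1, spec$true_ys[a])
      } else {
        rnorm(n_new, spec$true_ys[a], spec$true_sds[a])
      }
      n_total <- n_target
    }

    # analysable data: first data_looks[i] randomised participants
    d_i <- as.integer(spec$data_looks[i])
    if (d_i > d_prev) {
      new_idx <- (d_prev + 1L):d_i
      n_analysed <- n_analysed + tabulate(assign_vec[new_idx], nbins = k)
      add <- vapply(seq_len(k), function(j)
        sum(outcome_vec[new_idx][assign_vec[new_idx] == j]), numeric(1))
      sum_analysed <- sum_analysed + add
      d_prev <- d_i
    }

    act_idx <- which(active)
    arm_data <- list(
      n = setNames(n_analysed[act_idx], arms[act_idx]),
      sum_ys = setNames(sum_analysed[act_idx], arms[act_idx])
    )
    if (spec$outcome_type == "continuous") {
      arm_data$values <- lapply(act_idx, function(j)
        outcome_vec[seq_len(d_i)][assign_vec[seq_len(d_i)] == j])
      names(arm_data$values) <- arms[act_idx]
    }
    draws <- posterior_draws(spec, arm_data, arms[act_idx])

    dec <- apply_decision_rules(draws, i, spec, control = ctrl,
                                first_control = first_ctrl)
    last_p_best[] <- NA_real_
    last_p_best[names(dec$p_best)] <- dec$p_best
    pm <- colMeans(draws)
    last_post_mean[] <- NA_real_
    last_post_mean[names(pm)] <- pm

    if (length(dec$dropped)) {
      di <- match(names(dec$dropped), arms)
      active[di] <- FALSE
      status[di] <- dec$dropped
      status_look[di] <- i
    }
    if (!is.null(dec$new_control)) ctrl <- dec$new_control

    if (dec$stop) {
      final_status <- dec$final_status
      superior_arm <- dec$superior_arm
      stop_look <- i
      if (!is.null(superior_arm)) {
        si <- match(superior_arm, arms)
        status[si] <- "superior"
        status_look[si] <- i
      } else if (final_status == "equivalence" && is.null(ctrl)) {
        # whole-trial equivalence: every surviving arm is equivalent
        surv <- which(status == "active")
        status[surv] <- "equivalence"
        status_look[surv] <- i
      }
      break
    }

    if (i == spec$n_looks) break

    # response-adaptive allocation for the next block; reuse the decision
    # step's probabilities of being best unless the active set changed
    act_idx <- which(active)
    pb_act <- if (!length(dec$dropped)) dec$p_best else {
      prob_best(draws[, arms[act_idx], drop = FALSE], spec$highest_is_best)
    }
    alloc_act <- update_allocation(pb_act, spec, i, active_idx = act_idx,
                                   control = ctrl)
    alloc <- numeric(k)
    alloc[act_idx] <- alloc_act
  }

  used <- seq_len(n_total)
  n_rand_arm <- tabulate(assign_vec[used], nbins = k)
  sum_all_arm <- vapply(seq_len(k), function(j)
    sum(outcome_vec[used][assign_vec[used] == j]), numeric(1))

  arms_df <- data.frame(
    arm = arms,
    true_y = spec$true_ys,
    is_control = if (is.null(first_ctrl)) FALSE else arms == first_ctrl,
    final_control = if (is.null(ctrl)) FALSE else arms == ctrl,
    status = status,
    status_look = status_look,
    n_randomised = n_rand_arm,
    n_analysed = n_analysed,
    sum_ys_analysed = sum_analysed,
    sum_ys_all = sum_all_arm,
    post_mean = unname(last_post_mean),
    prob_best = unname(last_p_best),
    stringsAsFactors = FALSE
  )

  structure(list(
    final_status = final_status,
    stop_look = stop_look,
    n_randomised = n_total,
    n_analysed = as.integer(spec$data_looks[stop_look]),
    superior_arm = superior_arm,
    sum_ys = sum(sum_all_arm),
    arms = arms_df
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Single simulated trial: %s at analysis %d (%d randomised, %d analysed)\n",
              x$final_status, x$stop_look, x$n_randomised, x$n_analysed))
  if (!is.null(x$superior_arm)) cat(sprintf("  superior arm: %s\n", x$superior_arm))
  cat(sprintf("  total summed outcome: %g (ratio %.4f)\n",
              x$sum_ys, x$sum_ys / x$n_randomised))
  print(x$arms, row.names = FALSE)
  invisible(x)
}
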