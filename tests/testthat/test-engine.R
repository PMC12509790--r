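# Engine operations: posterior probabilities, allocation updates, decision
# rules and the single-trial loop.

test_that("randomise_block allocates participants by the given probabilities", {
  set.seed(1)
  expect_equal(randomise_block(c(1, 0, 0), 10), c(10, 0, 0))
  expect_equal(randomise_block(c(0.5, 0.5), 0), c(0, 0))
  counts <- randomise_block(rep(1 / 3, 3), 300)
  expect_equal(sum(counts), 300)
  expect_true(all(abs(counts - 100) < 4 * sqrt(300 * (1 / 3) * (2 / 3))))
  expect_error(randomise_block(c(0.5, 0.5), -1), "n_new")
  expect_error(randomise_block(c(0.5, 0.4), 10), "alloc_probs")
})

test_that("generate_outcomes draws Bernoulli events at the true rate", {
  set.seed(2)
  expect_equal(generate_outcomes(0, 50), rep(0, 50))
  expect_equal(generate_outcomes(1, 50), rep(1, 50))
  y <- generate_outcomes(0.25, 10000)
  expect_true(all(y %in% 0:1))
  expect_lt(abs(mean(y) - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
  expect_error(generate_outcomes(1.2, 10), "true_y")
})

test_that("prob_best matches a per-draw counting oracle and splits ties", {
  expect_equal(unname(prob_best(matrix(runif(5), ncol = 1))), 1)
  # dominance, lower is best
  m <- cbind(A = rep(0.2, 10), B = rep(0.3, 10))
  expect_equal(prob_best(m, FALSE), c(A = 1, B = 0))
  # hand-listed 3 arms x 5 draws, lower is best
  m <- cbind(A = c(0.10, 0.30, 0.20, 0.25, 0.15),
             B = c(0.20, 0.10, 0.20, 0.20, 0.25),
             C = c(0.30, 0.20, 0.30, 0.15, 0.10))
  # per-draw argmin: A, B, A&B tie, C, C
  expect_equal(prob_best(m, FALSE),
               c(A = 1.5 / 5, B = 1.5 / 5, C = 2 / 5))
  # brute-force oracle over random matrices, both directions
  set.seed(33)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    m <- matrix(sample(seq(0.1, 0.9, 0.1), 6 * k, replace = TRUE), ncol = k)
    colnames(m) <- letters[1:k]
    for (hib in c(TRUE, FALSE)) {
      oracle <- numeric(k)
      for (i in seq_len(nrow(m))) {
        opt <- if (hib) max(m[i, ]) else min(m[i, ])
        at <- which(m[i, ] == opt)
        oracle[at] <- oracle[at] + 1 / length(at)
      }
      oracle <- oracle / nrow(m)
      expect_equal(unname(prob_best(m, hib)), oracle)
      expect_equal(sum(prob_best(m, hib)), 1)
    }
  }
})

test_that("pairwise probabilities against the control use strict comparison", {
  m <- cbind(ctrl = c(0.25, 0.25, 0.25), arm = c(0.25, 0.25, 0.25))
  expect_equal(prob_better_than_control(m, "ctrl", FALSE), c(arm = 0))
  m <- cbind(ctrl = rep(0.25, 4), arm = rep(0.20, 4))
  expect_equal(prob_better_than_control(m, "ctrl", FALSE), c(arm = 1))
  m <- cbind(ctrl = c(0.20, 0.25, 0.30, 0.25, 0.22, 0.27),
             arm  = c(0.25, 0.20, 0.25, 0.25, 0.23, 0.20))
  # manual count, lower is best: arm < ctrl at draws 2, 3, 6
  expect_equal(prob_better_than_control(m, "ctrl", FALSE), c(arm = 3 / 6))
  expect_equal(prob_better_than_control(m, "ctrl", TRUE), c(arm = 2 / 6))
  expect_error(prob_better_than_control(m, "nope", FALSE), "control")
})

test_that("equivalence probabilities count draws with range below the margin", {
  m <- cbind(a = c(0.2, 0.3), b = c(0.2, 0.3), c = c(0.2, 0.3))
  expect_equal(prob_all_equivalent(m, 0.01), 1)
  m <- cbind(a = rep(0.20, 5), b = rep(0.30, 5))
  expect_equal(prob_all_equivalent(m, 0.025), 0)
  # hand-listed 3 x 5: ranges 0.04, 0.10, 0.02, 0.06, 0.01
  m <- cbind(a = c(0.20, 0.20, 0.25, 0.25, 0.250),
             b = c(0.22, 0.30, 0.24, 0.31, 0.241),
             c = c(0.24, 0.25, 0.23, 0.27, 0.248))
  expect_equal(prob_all_equivalent(m, 0.05), 3 / 5)
  expect_error(prob_all_equivalent(m[, 1, drop = FALSE], 0.05), "draws")
  expect_error(prob_all_equivalent(m, 0), "margin")
  # range criterion coincides with the max pairwise distance criterion
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(runif(40), ncol = 4)
    margin <- runif(1, 0.05, 0.5)
    pairwise <- mean(apply(m, 1, function(r)
      max(as.matrix(dist(r))) < margin))
    expect_equal(prob_all_equivalent(m, margin), pairwise)
  }
})

test_that("pairwise equivalence and futility probabilities follow their definitions", {
  x <- rep(0.2, 6); y <- rep(0.3, 6)
  expect_equal(prob_equiv_vs_control(x, x, 0.05), 1)
  expect_equal(prob_equiv_vs_control(x, y, 0.05), 0)
  arm <- c(0.20, 0.26, 0.24, 0.30, 0.21, 0.25)
  ctrl <- c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25)
  expect_equal(prob_equiv_vs_control(arm, ctrl, 0.025),
               mean(abs(arm - ctrl) < 0.025))
  # futility, lower is best: improvement = ctrl - arm
  expect_equal(prob_futile_vs_control(ctrl, ctrl, 0.025, FALSE), 1)
  expect_equal(prob_futile_vs_control(rep(0.20, 6), ctrl, 0.025, FALSE), 0)
  expect_equal(prob_futile_vs_control(arm, ctrl, 0.025, FALSE),
               mean((ctrl - arm) < 0.025))
})

test_that("softening exponents 0 and 1 give equal and identity allocation", {
  spec <- quick_spec(soften_power = 0)
  p <- c(A = 0.64, B = 0.32, C = 0.04)
  expect_equal(update_allocation(p, spec, 1), c(A = 1, B = 1, C = 1) / 3)
  spec <- quick_spec(soften_power = 1)
  expect_equal(update_allocation(p, spec, 1), p)
})

test_that("minimum limits are enforced by clamp-and-renormalise", {
  spec <- quick_spec(soften_power = 0.5, min_probs = rep(0.25, 3))
  p <- c(A = 0.64, B = 0.32, C = 0.04)
  got <- update_allocation(p, spec, 1)
  # softened: (0.8, 0.5657, 0.2)/1.5657; C clamped to 0.25; A and B share
  # the remaining 0.75 proportionally to their softened weights
  w <- unname(sqrt(p))
  expect_equal(unname(got),
               c(w[1] / (w[1] + w[2]) * 0.75, w[2] / (w[1] + w[2]) * 0.75, 0.25),
               tolerance = 1e-10)
  expect_equal(sum(got), 1)
})

test_that("allocation respects constraints over randomised inputs", {
  set.seed(99)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    arms <- letters[1:k]
    mins <- rep(round(runif(1, 0, 1 / k - 0.01), 3), k)
    maxs <- rep(round(runif(1, 1 / k + 0.05, 1), 3), k)
    soften <- runif(1)
    spec <- setup_trial_binom(arms = arms, true_ys = rep(0.2, k),
                              data_looks = c(100, 200),
                              min_probs = mins, max_probs = maxs,
                              soften_power = soften, superiority = 0.99,
                              inferiority = 0.01, n_draws = 1000)
    raw <- runif(k); raw <- raw / sum(raw)
    alloc <- update_allocation(setNames(raw, arms), spec, 1)
    expect_equal(sum(alloc), 1, tolerance = 1e-9)
    expect_true(all(alloc >= mins - 1e-9))
    expect_true(all(alloc <= maxs + 1e-9))
  }
})

test_that("limits are rescaled when arms have been dropped", {
  spec <- quick_spec(min_probs = rep(0.25, 3), rescale_probs = "limits")
  # two active arms: rescale factor 3/2, min 0.375
  p <- c(A = 0.9, B = 0.1)
  alloc <- update_allocation(p, spec, 1, active_idx = c(1, 2))
  expect_equal(sum(alloc), 1)
  expect_gte(alloc[["B"]], 0.375 - 1e-9)
  # without rescaling the original limit applies
  spec2 <- quick_spec(min_probs = rep(0.25, 3), rescale_probs = "none")
  alloc2 <- update_allocation(p, spec2, 1, active_idx = c(1, 2))
  expect_gte(alloc2[["B"]], 0.25 - 1e-9)
  expect_lt(alloc2[["B"]], 0.375)
})

test_that("fixed allocation probabilities are pinned", {
  spec <- quick_spec(fixed_probs = c(0.5, NA, NA))
  alloc <- update_allocation(c(A = 0.05, B = 0.15, C = 0.8), spec, 1)
  expect_equal(alloc[["A"]], 0.5)
  expect_equal(sum(alloc), 1)
})

test_that("decision rules fire in priority order without a control", {
  spec <- quick_spec()
  n_draws <- spec$n_draws
  mk_draws <- function(vals) {
    m <- vapply(vals, function(v) rep(v, n_draws), numeric(n_draws))
    colnames(m) <- names(vals)
    m
  }
  # disabled thresholds: nothing fires
  spec_off <- quick_spec(superiority = 1, inferiority = 0)
  dec <- apply_decision_rules(mk_draws(c(A = 0.1, B = 0.3, C = 0.5)), 1, spec_off)
  expect_false(dec$stop)
  expect_length(dec$dropped, 0)

  # forced superiority via near-degenerate probabilities
  set.seed(5)
  m <- cbind(A = rbeta(n_draws, 2, 60), B = rbeta(n_draws, 30, 70),
             C = rbeta(n_draws, 35, 65))
  dec <- apply_decision_rules(m, 1, spec)
  expect_true(dec$stop)
  expect_equal(dec$final_status, "superiority")
  expect_equal(dec$superior_arm, "A")

  # inferiority dropping keeps the trial running with >= 2 arms
  m <- cbind(A = rbeta(n_draws, 30, 70), B = rbeta(n_draws, 31, 69),
             C = rbeta(n_draws, 80, 20))
  dec <- apply_decision_rules(m, 1, spec)
  expect_false(dec$stop)
  expect_equal(dec$dropped, c(C = "inferior"))

  # dropping all but one arm stops the trial with that arm superior, even
  # when the superiority rule itself is disabled
  spec_inf_only <- quick_spec(superiority = 1, inferiority = 0.01)
  m <- cbind(A = rbeta(n_draws, 30, 70), B = rbeta(n_draws, 90, 10),
             C = rbeta(n_draws, 85, 15))
  dec <- apply_decision_rules(m, 1, spec_inf_only)
  expect_true(dec$stop)
  expect_equal(dec$final_status, "superiority")
  expect_equal(dec$superior_arm, "A")
  expect_equal(sort(names(dec$dropped)), c("B", "C"))
})

test_that("equivalence stops the whole trial without a control", {
  spec <- quick_spec(equivalence_prob = 0.9, equivalence_diff = 0.025)
  m <- matrix(0.25, nrow = spec$n_draws, ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  dec <- apply_decision_rules(m, 1, spec)
  expect_true(dec$stop)
  expect_equal(dec$final_status, "equivalence")
  # equivalence disabled at a look via threshold 1
  spec_off <- quick_spec(equivalence_prob = c(1, 0.9, 0.9),
                         equivalence_diff = 0.025)
  dec <- apply_decision_rules(m, 1, spec_off)
  expect_false(dec$stop)
  dec <- apply_decision_rules(m, 2, spec_off)
  expect_true(dec$stop)
})

test_that("a superior arm replaces the control and is compared on afresh", {
  # lower is best; B clearly better than control A; C clearly worse than B
  spec <- quick_spec(control = "A",
                     draw_hook = constant_hook(c(A = 0.30, B = 0.10, C = 0.28)))
  m <- posterior_draws(spec, list(n = c(A = 1, B = 1, C = 1),
                                  sum_ys = c(A = 0, B = 0, C = 0)))
  dec <- apply_decision_rules(m, 1, spec, control = "A", first_control = "A")
  expect_true(dec$stop)
  expect_equal(dec$final_status, "superiority")
  expect_equal(dec$superior_arm, "B")
  expect_equal(dec$dropped[["A"]], "control_replaced")
  expect_equal(dec$dropped[["C"]], "inferior")
  expect_equal(dec$new_control, "B")
})

test_that("equivalence and futility drop arms pairwise against the control", {
  # superiority/inferiority disabled so the lower-priority rules are reached
  hook <- constant_hook(c(A = 0.25, B = 0.251, C = 0.25))
  spec <- quick_spec(control = "A", draw_hook = hook,
                     superiority = 1, inferiority = 0,
                     equivalence_prob = 0.9, equivalence_diff = 0.025)
  m <- posterior_draws(spec, list(n = c(A = 1, B = 1, C = 1),
                                  sum_ys = c(A = 0, B = 0, C = 0)))
  dec <- apply_decision_rules(m, 1, spec, control = "A", first_control = "A")
  expect_true(dec$stop)
  expect_equal(dec$final_status, "equivalence")
  expect_setequal(names(dec$dropped), c("B", "C"))

  # futility: no arm beats the control by the margin
  spec <- quick_spec(control = "A", draw_hook = hook,
                     superiority = 1, inferiority = 0,
                     futility_prob = 0.9, futility_diff = 0.025)
  dec <- apply_decision_rules(m, 1, spec, control = "A", first_control = "A")
  expect_true(dec$stop)
  expect_equal(dec$final_status, "futility")
  expect_setequal(names(dec$dropped), c("B", "C"))
})

test_that("a trial with all rules disabled runs to the maximum sample size", {
  spec <- quick_spec(superiority = 1, inferiority = 0,
                     data_looks = c(100, 200, 300))
  r <- run_trial(spec, seed = 1)
  expect_equal(r$final_status, "max")
  expect_equal(r$n_randomised, 300)
  expect_equal(r$stop_look, 3)
  expect_true(all(r$arms$status == "active"))
})

test_that("overwhelming separation stops at the first analysis", {
  # lower is best, true rates 0 vs 1: posteriors Beta(1, 251) vs Beta(251, 1)
  spec <- setup_trial_binom(
    arms = c("A", "B"), true_ys = c(0, 1), highest_is_best = FALSE,
    data_looks = c(500, 1000), randomised_at_looks = c(700, 1000),
    superiority = 0.99, inferiority = 0.01, n_draws = 1000
  )
  r <- run_trial(spec, seed = 1)
  expect_equal(r$final_status, "superiority")
  expect_equal(r$superior_arm, "A")
  expect_equal(r$stop_look, 1)
  expect_equal(r$n_randomised, 700)
  # lagged participants still count toward totals
  expect_equal(sum(r$arms$n_randomised), 700)
  expect_equal(r$n_analysed, 500)
})

test_that("a trial is bit-identical when re-run with the same seed", {
  spec <- reference_spec(n_draws = 1000)
  r1 <- run_trial(spec, seed = 77)
  r2 <- run_trial(spec, seed = 77)
  expect_identical(r1, r2)
})

test_that("raising the superiority threshold cannot increase stopping (CRN)", {
  mk <- function(sup) setup_trial_binom(
    arms = c("A", "B"), true_ys = c(0.18, 0.25), highest_is_best = FALSE,
    data_looks = c(100, 200, 300), superiority = sup, inferiority = 1 - sup,
    n_draws = 1000
  )
  count_sup <- function(sup) {
    streams <- trial_streams(2024, 60)
    sum(vapply(streams, function(s)
      run_trial(mk(sup), stream = s)$final_status == "superiority", logical(1)))
  }
  n_loose <- count_sup(0.9)
  n_strict <- count_sup(0.999)
  expect_lte(n_strict, n_loose)
})

test_that("an extreme equivalence margin stops every trial at the first look", {
  spec <- quick_spec(equivalence_prob = 0.5, equivalence_diff = 0.999)
  for (s in 1:5) {
    r <- run_trial(spec, seed = s)
    expect_equal(r$final_status, "equivalence")
    expect_equal(r$stop_look, 1)
  }
})

test_that("outcome-data lag masks recent participants from the analysis", {
  # all events: analysed events at the stopping look equal data_looks[stop]
  spec <- setup_trial_binom(
    arms = c("A", "B"), true_ys = c(1, 1), highest_is_best = FALSE,
    data_looks = c(100, 200), randomised_at_looks = c(150, 200),
    superiority = 1, inferiority = 0, n_draws = 1000
  )
  r <- run_trial(spec, seed = 3)
  expect_equal(sum(r$arms$n_analysed), 200)
  expect_equal(sum(r$arms$sum_ys_analysed), 200)
  expect_equal(r$sum_ys, 200)
})
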