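# Shared fixtures: small trial specs and hand-built results, all constructed
# in code.

# Minimal fast 3-arm spec; arguments override the defaults.
quick_spec <- function(...) {
  args <- list(
    arms = c("A", "B", "C"),
    true_ys = c(0.25, 0.25, 0.25),
    highest_is_best = FALSE,
    data_looks = c(100, 200, 300),
    superiority = 0.99,
    inferiority = 0.01,
    n_draws = 1000
  )
  args <- utils::modifyList(args, list(...))
  do.call(setup_trial_binom, args)
}

# The reference 3-arm design used in the worked example: no common control,
# undesirable binary outcome at 25%, RAR restricted by 25% minimum limits
# with rescaling and softening 0.5, looks every 250 participants from 500 to
# 10000 with a 200-participant outcome-data lag, symmetric stopping rules
# and an equivalence rule (margin 2.5 %-points) active from 1500 analysed.
reference_spec <- function(superiority = 0.99, true_ys = c(0.25, 0.25, 0.25),
                           n_draws = 10000) {
  looks <- seq(500, 10000, by = 250)
  setup_trial_binom(
    arms = c("Arm A", "Arm B", "Arm C"),
    true_ys = true_ys,
    highest_is_best = FALSE,
    start_probs = rep(1 / 3, 3),
    min_probs = rep(0.25, 3),
    rescale_probs = "limits",
    soften_power = 0.5,
    data_looks = looks,
    randomised_at_looks = c(seq(700, 9950, by = 250), 10000),
    inferiority = 1 - superiority,
    superiority = superiority,
    equivalence_prob = ifelse(looks < 1500, 1, 0.9),
    equivalence_diff = 0.025,
    n_draws = n_draws
  )
}

# Draw hook returning constant values per arm (forces deterministic
# decisions in engine tests).
constant_hook <- function(values) {
  force(values)
  function(arms, arm_data, n_draws) {
    m <- vapply(arms, function(a) rep(values[[a]], n_draws), numeric(n_draws))
    matrix(m, nrow = n_draws, dimnames = list(NULL, arms))
  }
}

# Hand-built trial_result for metrics tests.
make_result <- function(final_status, arms, true_ys, post_means,
                        superior_arm = NULL, n_randomised = 300,
                        sum_ys = 75, stop_look = 1, prob_best = NULL,
                        statuses = NULL, status_looks = NULL,
                        is_control = NULL) {
  k <- length(arms)
  structure(list(
    final_status = final_status,
    stop_look = stop_look,
    n_randomised = n_randomised,
    n_analysed = n_randomised,
    superior_arm = superior_arm,
    sum_ys = sum_ys,
    arms = data.frame(
      arm = arms,
      true_y = true_ys,
      is_control = is_control %||% rep(FALSE, k),
      final_control = rep(FALSE, k),
      status = statuses %||% rep("active", k),
      status_look = status_looks %||% rep(NA_integer_, k),
      n_randomised = rep(n_randomised %/% k, k),
      n_analysed = rep(n_randomised %/% k, k),
      sum_ys_analysed = rep(sum_ys / k, k),
      sum_ys_all = rep(sum_ys / k, k),
      post_mean = post_means,
      prob_best = prob_best %||% rep(NA_real_, k),
      stringsAsFactors = FALSE
    )
  ), class = "trial_result")
}

# Wrap hand-built results as a trial_results batch.
make_batch <- function(results, spec) {
  structure(list(
    spec = spec,
    fingerprint = spec_fingerprint(spec),
    base_seed = 1L,
    n_rep = length(results),
    results = results,
    version = 1L
  ), class = "trial_results")
}
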