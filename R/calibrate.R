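# Calibration of stopping thresholds (or another scalar design parameter) to
# a target performance metric, using noisy Monte-Carlo evaluations guided by
# a Gaussian-process surrogate with a monotone-bisection fallback.

#' Install symmetric superiority/inferiority thresholds into a spec
#'
#' Sets the superiority threshold to `x` at every analysis and the
#' inferiority threshold to `1 - x` (the usual symmetric convention). This is
#' the default "install parameter" function used by [calibrate_trial()].
#'
#' @param spec A `trial_spec`.
#' @param x Superiority threshold in (0, 1).
#' @return The modified `trial_spec`.
#' @export
install_symmetric_thresholds <- function(spec, x) {
  stopifnot(inherits(spec, "trial_spec"))
  spec$superiority <- rep(as.numeric(x), spec$n_looks)
  spec$inferiority <- rep(1 - as.numeric(x), spec$n_looks)
  spec
}

# Default metric: probability of stopping for superiority (the Bayesian
# analogue of the type-1 error rate in a null scenario).
metric_prob_superiority <- function(batch) {
  mean(vapply(batch$results, function(r) r$final_status == "superiority",
              logical(1)))
}

#' Calibrate a scalar design parameter to a target performance metric
#'
#' Iteratively evaluates candidate values of a scalar design parameter
#' (by default the constant, symmetric superiority/inferiority stopping
#' threshold) by simulating `n_rep` trials per evaluation and computing a
#' scalar metric (by default the probability of stopping for superiority,
#' i.e. the type-1 error rate when the spec encodes a null scenario).
#' The search stops as soon as the metric falls in the acceptance band —
#' `[target - tol, target]` for `dir = -1`, `[target, target + tol]` for
#' `dir = +1`, `[target - tol, target + tol]` for `dir = 0` — or when
#' `iter_max` evaluations have been spent.
#'
#' After evaluating the two endpoints of `search_range`, the next candidate
#' is proposed where the posterior mean of a Gaussian-process regression of
#' metric on parameter (squared-exponential kernel with a noise term) crosses
#' the target, clipped to the search range; whenever the surrogate proposal
#' repeats a previous candidate within machine tolerance, the proposal falls
#' back to bisection of the bracketing interval, which guarantees progress.
#'
#' Per-evaluation seeds derive deterministically from
#' `(base_seed, evaluation index)`, so the calibration path is reproducible;
#' common random numbers across evaluations are not used unless
#' `common_seeds = TRUE`.
#'
#' @param spec A `trial_spec` (typically encoding the null scenario).
#' @param target Target metric value.
#' @param search_range Numeric length-2 interval for the parameter.
#' @param tol Acceptance tolerance around `target`.
#' @param dir -1 (accept only values at or below target), +1 (at or above) or
#'   0 (either side).
#' @param iter_max Maximum number of evaluations.
#' @param n_rep Simulations per evaluation.
#' @param base_seed Integer base seed.
#' @param workers Parallel workers per batch.
#' @param metric Function of a `trial_results` batch returning a scalar.
#' @param install Function `(spec, x)` returning the spec with candidate `x`
#'   installed.
#' @param evaluator Optional function `(x, spec, n_rep, seed)` returning the
#'   metric directly, replacing simulation entirely (used for noise-free
#'   stubs and testing).
#' @param common_seeds Reuse the same base seed for every evaluation?
#' @return An object of class `trial_calibration`: the evaluation trace
#'   (data frame `evals` with `iter`, `x`, `y`, `n_rep`, `seed`), `best_x`,
#'   `best_y`, `converged`, and `best_spec` (spec with `best_x` installed).
#' @export
calibrate_trial <- function(spec, target = 0.05, search_range = c(0.9, 1),
                            tol = 0.001, dir = -1, iter_max = 25L,
                            n_rep = 1000L, base_seed = NULL, workers = 1L,
                            metric = metric_prob_superiority,
                            install = install_symmetric_thresholds,
                            evaluator = NULL, common_seeds = FALSE) {
  stopifnot(inherits(spec, "trial_spec"))
  if (length(search_range) != 2 || diff(search_range) <= 0) {
    stop_field("search_range", "must be an increasing length-2 interval")
  }
  if (iter_max < 1) stop_field("iter_max", "must be at least 1")
  if (n_rep < 1) stop_field("n_rep", "must be at least 1")
  if (!dir %in% c(-1, 0, 1)) stop_field("dir", "must be -1, 0 or +1")
  if (is.null(base_seed)) base_seed <- sample.int(.Machine$integer.max, 1)
  base_seed <- as.integer(base_seed)

  eval_seed <- function(i) {
    if (common_seeds) base_seed
    else as.integer((as.numeric(base_seed) + 104729 * i) %% 2147483647L)
  }
  eval_fn <- evaluator %||% function(x, spec, n_rep, seed) {
    metric(run_trials(install(spec, x), n_rep = n_rep, base_seed = seed,
                      workers = workers))
  }
  in_band <- function(y) {
    if (dir < 0) y >= target - tol && y <= target
    else if (dir > 0) y >= target && y <= target + tol
    else abs(y - target) <= tol
  }

  xs <- numeric(0); ys <- numeric(0); seeds <- integer(0)
  evaluate <- function(x) {
    i <- length(xs) + 1L
    s <- eval_seed(i)
    y <- eval_fn(x, spec, n_rep, s)
    xs[[i]] <<- x; ys[[i]] <<- y; seeds[[i]] <<- s
    y
  }

  converged <- FALSE
  # endpoints first, then surrogate-guided proposals
  for (x0 in c(search_range[1], search_range[2])) {
    if (length(xs) >= iter_max) break
    if (in_band(evaluate(x0))) { converged <- TRUE; break }
  }
  while (!converged && length(xs) < iter_max) {
    x_new <- propose_next(xs, ys, target, search_range, n_rep)
    if (min(abs(x_new - xs)) < 1e-12) {
      x_new <- bisect_proposal(xs, ys, target, search_range)
      if (is.na(x_new) || min(abs(x_new - xs)) < 1e-12) break
    }
    if (in_band(evaluate(x_new))) converged <- TRUE
  }

  ok <- if (dir < 0) ys <= target else if (dir > 0) ys >= target else rep(TRUE, length(ys))
  cand <- if (any(ok)) which(ok) else seq_along(ys)
  best_i <- cand[which.min(abs(ys[cand] - target))]

  structure(list(
    evals = data.frame(iter = seq_along(xs), x = xs, y = ys, n_rep = n_rep,
                       seed = seeds),
    best_x = xs[best_i],
    best_y = ys[best_i],
    converged = converged,
    target = target, tol = tol, dir = dir,
    base_seed = base_seed,
    best_spec = install(spec, xs[best_i])
  ), class = "trial_calibration")
}

# GP-regression proposal: posterior mean of y over a fine grid; the candidate
# is the grid point whose predicted mean is closest to the target (the
# crossing point for monotone responses).
propose_next <- function(xs, ys, target, search_range, n_rep) {
  n <- length(xs)
  x_sc <- (xs - search_range[1]) / diff(search_range)
  len <- 0.25
  s2 <- max(var(ys), 1e-10)
  # noise floor from binomial sampling error at the target level
  noise <- max(target * (1 - target) / n_rep, 1e-12)
  K <- s2 * exp(-0.5 * (outer(x_sc, x_sc, "-") / len)^2) + diag(noise, n)
  grid <- seq(0, 1, length.out = 401)
  Ks <- s2 * exp(-0.5 * (outer(grid, x_sc, "-") / len)^2)
  alpha <- tryCatch(solve(K, ys - mean(ys)), error = function(e) NULL)
  if (is.null(alpha)) return(mean(search_range))
  mu <- mean(ys) + as.numeric(Ks %*% alpha)
  x_star <- grid[which.min(abs(mu - target))]
  search_range[1] + x_star * diff(search_range)
}

# Monotone bisection fallback: midpoint of the tightest bracket of evaluated
# points straddling the target (assuming the metric is monotone in x); when
# no bracket exists, the midpoint of the widest unexplored gap.
bisect_proposal <- function(xs, ys, target, search_range) {
  ord <- order(xs)
  x_o <- xs[ord]; y_o <- ys[ord]
  above <- y_o >= target
  cross <- which(above[-1] != above[-length(above)])
  if (length(cross)) {
    i <- cross[which.min(x_o[cross + 1] - x_o[cross])]
    return((x_o[i] + x_o[i + 1]) / 2)
  }
  pts <- sort(unique(c(search_range, x_o)))
  gaps <- diff(pts)
  if (!length(gaps) || max(gaps) < 1e-12) return(NA_real_)
  i <- which.max(gaps)
  (pts[i] + pts[i + 1]) / 2
}

#' Round a calibrated threshold and install it for re-evaluation
#'
#' Practical stopping rules use a limited number of digits; this rounds the
#' calibrated parameter to the stated number of significant digits and
#' installs it (symmetrically, by default) into the calibrated spec. The
#' rounded design should be re-evaluated with a large simulation batch, since
#' rounding changes the operating characteristics slightly.
#'
#' @param calibration A converged `trial_calibration`.
#' @param digits Number of significant digits (>= 1).
#' @param install Install function, as in [calibrate_trial()].
#' @return A `trial_spec` with the rounded parameter installed.
#' @export
install_rounded_threshold <- function(calibration, digits = 4,
                                      install = install_symmetric_thresholds) {
  stopifnot(inherits(calibration, "trial_calibration"))
  if (digits < 1) stop_field("digits", "must be at least 1")
  if (!calibration$converged) {
    warning("calibration did not converge; rounding the best evaluation anyway",
            call. = FALSE)
  }
  install(calibration$best_spec, signif(calibration$best_x, digits))
}

#' @export
print.trial_calibration <- function(x, ...) {
  cat(sprintf("Calibration %s after %d evaluations\n",
              if (x$converged) "converged" else "did NOT converge",
              nrow(x$evals)))
  cat(sprintf("  target %g (tol %g, dir %+d); best_x = %.6g, best_y = %.6g\n",
              x$target, x$tol, x$dir, x$best_x, x$best_y))
  print(x$evals, row.names = FALSE)
  invisible(x)
}

#' Write the calibration evaluation trace to CSV
#'
#' @param calibration A `trial_calibration`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_trace <- function(calibration, path) {
  write.csv(calibration$evals, path, row.names = FALSE)
  invisible(path)
}
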