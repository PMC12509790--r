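# Reproducible batches of trial simulations, optionally parallel, with
# persistence guarded by the spec fingerprint.

BATCH_FORMAT_VERSION <- 1L

#' Run a batch of independent trial simulations
#'
#' Simulates `n_rep` trials under the design. Each trial uses its own random
#' stream derived deterministically from `(base_seed, trial index)`
#' (L'Ecuyer-CMRG sub-streams), so results are bit-identical for any number
#' of workers and independent of execution order. When `path` is given and
#' the file already holds a batch whose spec fingerprint, base seed and
#' replication count match, the stored batch is reloaded instead of
#' recomputed; any mismatch is an error, never silent reuse.
#'
#' @param spec A `trial_spec`.
#' @param n_rep Number of simulations (>= 1).
#' @param base_seed Integer base seed.
#' @param workers Number of parallel workers (forked; serial on Windows or
#'   when 1).
#' @param path Optional RDS file used to persist/reload the batch.
#' @return An object of class `trial_results` holding the spec, its
#'   fingerprint, the base seed and one `trial_result` per simulation.
#' @seealso [extend_trials()], [extract_results()], [check_performance()]
#' @export
run_trials <- function(spec, n_rep, base_seed = NULL, workers = 1L,
                       path = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  n_rep <- as.integer(n_rep)
  if (is.na(n_rep) || n_rep < 1) stop_field("n_rep", "must be at least 1")
  if (is.null(base_seed)) base_seed <- sample.int(.Machine$integer.max, 1)
  fp <- spec_fingerprint(spec)

  if (!is.null(path) && file.exists(path)) {
    stored <- readRDS(path)
    check_batch_compatible(stored, fp, base_seed)
    if (stored$n_rep != n_rep) {
      stop(sprintf(
        "stored batch at '%s' has n_rep = %d, requested %d; refusing to reuse",
        path, stored$n_rep, n_rep), call. = FALSE)
    }
    return(stored)
  }

  results <- simulate_indices(spec, base_seed, seq_len(n_rep), workers)
  batch <- structure(list(
    spec = spec,
    fingerprint = fp,
    base_seed = as.integer(base_seed),
    n_rep = n_rep,
    results = results,
    version = BATCH_FORMAT_VERSION
  ), class = "trial_results")
  if (!is.null(path)) saveRDS(batch, path)
  batch
}

#' Extend a batch with additional simulations
#'
#' Appends simulations using the child streams for trial indices beyond the
#' original count, leaving the first `n_rep` results bit-identical.
#'
#' @param batch A `trial_results` object.
#' @param n_extra Additional number of simulations (0 leaves the batch
#'   unchanged).
#' @param workers Parallel workers.
#' @param path Optional RDS path to persist the extended batch.
#' @return The extended `trial_results`.
#' @export
extend_trials <- function(batch, n_extra, workers = 1L, path = NULL) {
  stopifnot(inherits(batch, "trial_results"))
  n_extra <- as.integer(n_extra)
  if (is.na(n_extra) || n_extra < 0) stop_field("n_extra", "must be non-negative")
  if (spec_fingerprint(batch$spec) != batch$fingerprint) {
    stop("batch fingerprint does not match its spec; refusing to extend",
         call. = FALSE)
  }
  if (n_extra == 0) return(batch)
  idx <- batch$n_rep + seq_len(n_extra)
  extra <- simulate_indices(batch$spec, batch$base_seed, idx, workers)
  batch$results <- c(batch$results, extra)
  batch$n_rep <- batch$n_rep + n_extra
  if (!is.null(path)) saveRDS(batch, path)
  batch
}

simulate_indices <- function(spec, base_seed, indices, workers) {
  offset <- min(indices) - 1L
  streams <- trial_streams(base_seed, length(indices), offset = offset)
  runner <- function(j) run_trial(spec, stream = streams[[j]])
  workers <- max(1L, as.integer(workers))
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(indices), runner, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(indices), runner)
  }
}

check_batch_compatible <- function(stored, fingerprint, base_seed) {
  if (!inherits(stored, "trial_results")) {
    stop("stored file does not contain a trial_results batch", call. = FALSE)
  }
  if (stored$fingerprint != fingerprint) {
    stop("stored batch was produced under a different trial specification ",
         "(fingerprint mismatch); refusing to reuse", call. = FALSE)
  }
  if (!is.null(base_seed) && stored$base_seed != as.integer(base_seed)) {
    stop("stored batch was produced with a different base seed; refusing to reuse",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.trial_results <- function(x, ...) {
  cat(sprintf("Batch of %d simulated trials (base seed %d)\n",
              x$n_rep, x$base_seed))
  cat(sprintf("  scenario: %s; fingerprint %s\n", x$spec$label,
              substr(x$fingerprint, 1, 12)))
  st <- vapply(x$results, function(r) r$final_status, character(1))
  tab <- table(factor(st, levels = c("superiority", "equivalence",
                                     "futility", "max")))
  for (nm in names(tab)) {
    cat(sprintf("  %-12s %6.1f%% (%d)\n", nm, 100 * tab[[nm]] / x$n_rep, tab[[nm]]))
  }
  ss <- vapply(x$results, function(r) r$n_randomised, numeric(1))
  cat(sprintf("  mean sample size: %.0f (SD %.0f; range %d-%d)\n",
              mean(ss), sd(ss), min(ss), max(ss)))
  invisible(x)
}

#' @export
summary.trial_results <- function(object, select_strategy = "superiority_only",
                                  ...) {
  check_performance(object, select_strategy = select_strategy, ...)
}
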