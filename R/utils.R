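# Internal helpers: canonical serialisation/fingerprinting and reproducible
# per-trial random streams.

#' @importFrom stats rbeta rbinom rnorm rmultinom quantile sd var median setNames
#' @importFrom utils head write.csv read.csv modifyList
NULL

# Canonical, locale-independent string form of an R object restricted to the
# types used in trial specifications (NULL, logical, numeric, character, list).
# Numbers are formatted with 15 significant digits so that fingerprints are
# stable across platforms while still distinguishing genuinely different specs.
canonical_string <- function(x) {
  if (is.null(x)) return("~")
  if (is.function(x)) return("<function>")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) {
      ord <- order(nm)
      parts <- vapply(ord, function(i) {
        paste0(nm[i], "=", canonical_string(x[[i]]))
      }, character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, canonical_string, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.numeric(x)) {
    return(paste0("(", paste(sprintf("%.15g", x), collapse = ","), ")"))
  }
  if (is.logical(x)) return(paste0("(", paste(ifelse(x, "T", "F"), collapse = ","), ")"))
  paste0("(", paste(x, collapse = ","), ")")
}

# MD5 of the canonical string (via a temp file; tools::md5sum is file-based).
hash_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

# L'Ecuyer-CMRG random streams for trials `offset + 1, ..., offset + n`,
# derived deterministically from the base seed alone so that results are
# independent of execution order and the number of workers.
trial_streams <- function(base_seed, n, offset = 0) {
  stopifnot(n >= 0, offset >= 0)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(base_seed), kind = "L'Ecuyer-CMRG")
  s <- .Random.seed
  total <- offset + n
  streams <- vector("list", n)
  for (i in seq_len(total)) {
    s <- parallel::nextRNGStream(s)
    if (i > offset) streams[[i - offset]] <- s
  }
  streams
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run `expr` under a specific RNG state (a .Random.seed vector), restoring the
# caller's state afterwards.
with_stream <- function(stream, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set_rng_state(stream)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
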