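# Internal helpers: seeded RNG isolation, sub-stream seed derivation, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All randomized operations in the package route their draws through this
#' helper so that a function called with an explicit `seed` neither depends on
#' nor disturbs the global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Deterministic, collision-light mapping (master seed, stream name) -> seed
#' in [1, 2^31 - 2]. Used so that e.g. the perturbation stream and the null
#' stream of a robustness run are independent but both reproducible from one
#' master seed.
#'
#' @param seed master integer seed.
#' @param name character stream label.
#' @return integer seed strictly below 2^31.
#' @keywords internal
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.double(seed)) * 7919 + h) %% 2147483629 + 1)
}

# Log levels in increasing verbosity.
.log_levels <- c(error = 1L, warn = 2L, info = 3L, debug = 4L)

cs_log <- function(level, ...) {
  threshold <- getOption("corestab.log_level", "info")
  if (.log_levels[[level]] <= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

age_group_levels <- c("I", "A", "E")

as_age_group <- function(x) {
  f <- factor(as.character(x), levels = age_group_levels)
  if (anyNA(f)) {
    stopf("invalid age group value(s): %s (must be one of I, A, E)",
          paste(unique(setdiff(as.character(x), age_group_levels)),
                collapse = ", "))
  }
  f
}
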