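# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state. All stochastic functions in this package take an explicit seed and
#' route through this helper, so nothing depends on the global RNG state.
#'
#' @param seed single finite integer-valued number.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Round half away from zero
#'
#' Reporting convention for percentages: 98.85 rounds to 98.9, not 98.8
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Probability-in-[0,1] check with a named error.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1] (got %s)",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Coerce a prediction/reference/rating vector to 0/1 integers, erroring on
# anything that is not binary.
as_binary <- function(x, name = deparse(substitute(x))) {
  if (is.logical(x)) x <- as.integer(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    x <- match(tolower(x), c("0", "1", "no", "yes", "false", "true")) - 1L
    x <- x %% 2L
  }
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1, logical, or yes/no) with no missing values", name),
         call. = FALSE)
  }
  as.integer(x)
}
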