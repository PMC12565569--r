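# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package operations never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer `seed` is mandatory for stochastic operations",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; keeps values well
# inside 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Population variance (divide by N): gliding-box statistics are moments of
# the realized mass distribution, not sample estimates.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

#' Format a proportion as a percentage string
#'
#' @param x Proportion in \[0, 1\].
#' @param digits Decimal places kept.
#' @param mode Rounding convention: `"half-up"` (default), `"half-down"`, or
#'   `"truncate"`. Published cohort tables are not consistent about the
#'   half-way case, so all three are available.
#' @return Numeric percentage rounded per `mode` (not a string).
#' @export
#' @examples
#' percent_value(19 / 85)                     # 22.4
#' percent_value(19 / 85, mode = "half-down") # 22.3
percent_value <- function(x, digits = 1, mode = c("half-up", "half-down", "truncate")) {
  mode <- match.arg(mode)
  p <- x * 100
  f <- 10^digits
  switch(mode,
    "half-up"   = floor(p * f + 0.5) / f,
    "half-down" = ceiling(p * f - 0.5) / f,
    "truncate"  = trunc(p * f) / f
  )
}
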