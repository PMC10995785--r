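#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), ties go away from zero:
#' `round_half_up(0.0005, 3)` is `0.001`. This is the rounding convention used
#' for all reported table cells and percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(0.0675, 3)  # 0.068
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw n integers from a distribution spec: a single integer (fixed value),
# a length-2 integer vector (inclusive uniform range), or a function(n).
draw_int_spec <- function(spec, n, what = "value") {
  out <- if (is.function(spec)) {
    spec(n)
  } else if (is.numeric(spec) && length(spec) == 1) {
    rep(as.integer(spec), n)
  } else if (is.numeric(spec) && length(spec) == 2) {
    sample(seq.int(spec[1], spec[2]), n, replace = TRUE)
  } else {
    stop("invalid distribution spec for ", what,
         ": give an integer, a length-2 range, or a function(n)", call. = FALSE)
  }
  out <- as.integer(out)
  if (any(out < 1)) stop(what, " must be >= 1", call. = FALSE)
  out
}
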