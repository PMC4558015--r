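#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to base R's round-half-to-even.
#' Used for all reported integer percentages so that, e.g., 64.5 prints as 65.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with the offending field name, for spec-style validation errors
check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("'%s' must be numeric and >= 0", field), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field) {
  check_nonneg(x, field)
  if (any(x != floor(x))) {
    stop(sprintf("'%s' must be a non-negative integer", field), call. = FALSE)
  }
  invisible(x)
}

check_range <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2 || anyNA(x) || x[1] > x[2]) {
    stop(sprintf("'%s' must be a numeric (low, high) pair with low <= high",
                 field), call. = FALSE)
  }
  invisible(x)
}

# Euclidean distance between rows of (x, y) coordinate pairs
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
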