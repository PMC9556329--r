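#' Derive a module-level seed from the run seed
#'
#' All stochastic operations in the package draw their RNG state from a
#' single integer run seed. Each module derives its own stream with a tag,
#' so stages can be re-run independently and still reproduce a full
#' pipeline run bit for bit.
#'
#' @param seed integer run seed.
#' @param tag character scalar naming the consumer (e.g. `"cohort"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' deriveSeed(1L, "cohort")
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# stop() with a message naming the offending field; used by validators
.checkProportion <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("field '%s' must be a single proportion in [0, 1]", field),
         call. = FALSE)
  invisible(x)
}

.checkWeights <- function(w, field, tol = 1e-9) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0))
    stop(sprintf("field '%s' must be finite nonnegative weights", field),
         call. = FALSE)
  if (abs(sum(w) - 1) > tol)
    stop(sprintf("field '%s' must sum to 1 (got %.12f)", field, sum(w)),
         call. = FALSE)
  invisible(w)
}

#' Round half away from zero
#'
#' The rounding convention used for reported whole-percent rates
#' (unlike [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))  # 1 2 3
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
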