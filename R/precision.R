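#' A-priori half-width of a single-proportion confidence interval
#'
#' For a planned sample of size `n` and an anticipated proportion
#' `p_expected`, the two-sided large-sample normal-approximation interval
#' extends `z * sqrt(p (1 - p) / n)` either side of the observed
#' proportion. Study planning uses this to check that the interval will be
#' tight enough: e.g. at `n = 400` and any proportion up to 0.5 the
#' half-width stays below 0.05.
#'
#' @param p_expected Anticipated proportion in `[0, 1]`.
#' @param n Planned number of samples (`>= 1`).
#' @param level Confidence level, default 0.95.
#' @param z Normal quantile to use; default the exact two-sided quantile
#'   for `level`. Pass `z = 1.96` to match hand calculations.
#' @return The half-width, on the proportion scale.
#' @examples
#' ci_half_width(0.4, 400)          # 0.0480 < 0.05
#' ci_half_width(0.5, 400)          # worst case, 0.0490
#' @export
ci_half_width <- function(p_expected, n, level = 0.95, z = NULL) {
  if (any(n < 1)) {
    rlang::abort("n must be >= 1", class = "carryprev_validation_error")
  }
  if (any(p_expected < 0) || any(p_expected > 1)) {
    rlang::abort("p_expected must lie in [0, 1]",
                 class = "carryprev_validation_error")
  }
  if (is.null(z)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
  }
  z * sqrt(p_expected * (1 - p_expected) / n)
}

#' Smallest sample size achieving a target CI half-width
#'
#' Inverts [ci_half_width()]: the smallest integer `n` whose planned
#' half-width does not exceed the target. Computed in closed form as
#' `ceiling(z^2 p (1 - p) / w^2)` with an exact boundary check, so the
#' returned `n` satisfies the bound and `n - 1` does not (unless the bound
#' already holds at `n = 1`).
#'
#' @param p_expected Anticipated proportion in `[0, 1]`.
#' @param target_half_width Required half-width (`> 0`), proportion scale.
#' @param level Confidence level.
#' @return Integer sample size.
#' @examples
#' min_n_for_half_width(0.4, 0.05) # 369
#' @export
min_n_for_half_width <- function(p_expected, target_half_width, level = 0.95) {
  if (target_half_width <= 0) {
    rlang::abort("target_half_width must be positive",
                 class = "carryprev_validation_error")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- max(1L, as.integer(ceiling(z^2 * p_expected * (1 - p_expected) /
                                    target_half_width^2)))
  # guard against floating-point edge: walk to the exact boundary
  while (ci_half_width(p_expected, n, level) > target_half_width) {
    n <- n + 1L
  }
  while (n > 1L && ci_half_width(p_expected, n - 1L, level) <= target_half_width) {
    n <- n - 1L
  }
  n
}
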