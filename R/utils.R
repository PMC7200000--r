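#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats median qlogis plogis qchisq qnorm quantile rbinom rnorm
#'   runif sd var lm coef optim setNames update
#' @importFrom utils head tail
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' of most published tables), unlike [round()] which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  length(x) / sum(1 / x)
}

# shared validation helper: a single positive integer-ish scalar
assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}
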