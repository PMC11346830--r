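#' Accumulated generating operation (AGO)
#'
#' The first-order AGO transforms a raw series `x0` into its running
#' cumulative sum `x1`, the smoother sequence on which the grey differential
#' equation is posed.  For strictly positive input the result is strictly
#' increasing.
#'
#' @param x0 Numeric vector, the raw series.
#' @return Numeric vector of the same length: `x1[k] = sum(x0[1:k])`.
#' @seealso [iago()] for the inverse, [mean_sequence()] for the next modelling
#'   step.
#' @examples
#' ago(c(1, 2, 3))
#' @export
ago <- function(x0) {
  if (length(x0) < 1) {
    rlang::abort("`x0` must have at least one element.",
                 class = "greycast_validation_error")
  }
  cumsum(x0)
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First differencing with the initial value retained: recovers the raw
#' series from its accumulation, so `iago(ago(x)) == x` exactly.  Applied to
#' time-response predictions it converts accumulated forecasts back to the
#' original level.
#'
#' @param x1 Numeric vector, an accumulated series.
#' @return Numeric vector of the same length.
#' @examples
#' iago(c(1, 3, 6))
#' @export
iago <- function(x1) {
  if (length(x1) < 1) {
    rlang::abort("`x1` must have at least one element.",
                 class = "greycast_validation_error")
  }
  c(x1[1], diff(x1))
}

#' Mean-value (background) sequence
#'
#' Equal-weight averages of consecutive accumulated values,
#' `z1[k] = 0.5 * (x1[k] + x1[k + 1])`.  This background sequence is the
#' regressor in the grey difference equation `x0[k] + a * z1[k - 1] = b`.
#'
#' @param x1 Numeric vector of length at least 2, an accumulated series.
#' @return Numeric vector of length `length(x1) - 1`.
#' @examples
#' mean_sequence(c(1, 3, 6))
#' @export
mean_sequence <- function(x1) {
  n <- length(x1)
  if (n < 2) {
    rlang::abort("`x1` must have at least two elements.",
                 class = "greycast_validation_error")
  }
  0.5 * (x1[-n] + x1[-1])
}
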