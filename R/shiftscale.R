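# Per-dimension linear shift-and-scale layer mapping each marginal variable
# into the fixed spline working interval [-1, 1]. Fitted once, from the
# min/max over the entire data set (train + validation), with a small margin
# so validation extremes stay strictly inside the spline domain. Dimensions
# with a known natural range (hyperspherical angles) use that range instead
# of data-driven bounds; the periodic theta2 dimensions map [0, 2pi) onto
# the half-open interval [-1, 1).

#' Fit the shift-scale layer
#'
#' @param X matrix n x D of marginal variables.
#' @param margin fractional margin added beyond the observed min/max
#'   (default 1%).
#' @param fixed_ranges optional D x 2 matrix of (lo, hi); rows with finite
#'   entries override the data-driven bounds (used for angle dimensions).
#' @return object of class `shift_scale` with per-dim `lo`, `hi`, gains and
#'   the forward (data-to-model) log-volume `sum(log gain)`.
#' @export
fit_shift_scale <- function(X, margin = 0.01, fixed_ranges = NULL) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  pad <- (hi - lo) * margin
  pad[pad == 0] <- 1e-6
  lo <- lo - pad
  hi <- hi + pad
  if (!is.null(fixed_ranges)) {
    use <- is.finite(fixed_ranges[, 1]) & is.finite(fixed_ranges[, 2])
    lo[use] <- fixed_ranges[use, 1]
    hi[use] <- fixed_ranges[use, 2]
  }
  gain <- 2 / (hi - lo)
  if (any(gain <= 0)) abort("shift-scale gains must be strictly positive")
  structure(
    list(lo = lo, hi = hi, gain = gain, log_volume = sum(log(gain))),
    class = "shift_scale"
  )
}

#' Apply / invert the shift-scale layer
#'
#' @param ss a fitted `shift_scale`.
#' @param X matrix in data units (for `shift_scale_forward`) or in model
#'   units (for `shift_scale_inverse`).
#' @return list with the transformed matrix `y` (or `x`) and the per-frame
#'   `log_volume` of that direction; the two directions cancel exactly.
#' @export
shift_scale_forward <- function(ss, X) {
  y <- sweep(sweep(X, 2, ss$lo), 2, ss$gain, "*") - 1
  list(y = y, log_volume = ss$log_volume)
}

#' @rdname shift_scale_forward
#' @export
shift_scale_inverse <- function(ss, X) {
  x <- sweep(sweep(X + 1, 2, ss$gain, "/"), 2, ss$lo, "+")
  list(x = x, log_volume = -ss$log_volume)
}
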