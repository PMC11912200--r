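# Finite-size extrapolation: free-energy differences at several supercell
# sizes are extrapolated to the thermodynamic limit as the intercept of an
# unweighted ordinary-least-squares fit of delta f against 1/n_mol.
# Unweighted OLS is deliberate: inverse-variance weighting changes the
# intercept, while the plain fit is exact on noise-free data linear in
# 1/n_mol and invariant to reordering.

#' Extrapolate a size series to the thermodynamic limit
#'
#' @param series a data frame with columns `n_mol`, `delta_f` and
#'   (optionally) `se`; at least two distinct sizes.
#' @return object of class `thermo_limit_fit` with the intercept (the
#'   thermodynamic-limit estimate), its standard error from propagating the
#'   per-point errors through the fixed OLS coefficients, the slope, and
#'   residuals.
#' @export
#' @examples
#' extrapolate_thermo_limit(
#'   tibble::tibble(n_mol = c(16, 32, 64), delta_f = c(9.27, 14.25, 16.95))
#' )
extrapolate_thermo_limit <- function(series) {
  series <- as_tibble(series)
  if (!all(c("n_mol", "delta_f") %in% names(series))) {
    abort("series needs columns n_mol and delta_f")
  }
  if (anyDuplicated(series$n_mol)) abort("duplicate n_mol in size series")
  if (nrow(series) < 2) abort("need at least 2 sizes")
  if (!"se" %in% names(series)) series$se <- NA_real_
  x <- 1 / series$n_mol
  fit <- lm(delta_f ~ x, data = tibble(delta_f = series$delta_f, x = x))
  X <- cbind(1, x)
  Ci <- solve(crossprod(X)) %*% t(X)   # coefficient weights: beta = Ci %*% y
  se_int <- if (all(is.finite(series$se))) {
    sqrt(sum((Ci[1, ] * series$se)^2))
  } else NA_real_
  structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         se_intercept = se_int, series = series,
         residuals = unname(fit$residuals)),
    class = "thermo_limit_fit"
  )
}

#' @export
print.thermo_limit_fit <- function(x, ...) {
  cat(sprintf(
    "<thermo_limit_fit> intercept %.4f%s, slope %.4f (%d sizes)\n",
    x$intercept,
    if (is.finite(x$se_intercept)) sprintf(" +/- %.4f", x$se_intercept) else "",
    x$slope, nrow(x$series)
  ))
  invisible(x)
}

#' @export
tidy.thermo_limit_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, NA_real_)
  )
}

#' @export
glance.thermo_limit_fit <- function(x, ...) {
  tibble(
    intercept = x$intercept, se_intercept = x$se_intercept,
    slope = x$slope, n_sizes = nrow(x$series),
    max_abs_residual = max(abs(x$residuals))
  )
}

#' @export
autoplot.thermo_limit_fit <- function(object, ...) {
  df <- object$series
  df$inv_n <- 1 / df$n_mol
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inv_n, y = .data$delta_f)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$delta_f - ifelse(is.na(.data$se), 0, .data$se),
      ymax = .data$delta_f + ifelse(is.na(.data$se), 0, .data$se)
    )) +
    ggplot2::annotate("point", x = 0, y = object$intercept, shape = 5, size = 3) +
    ggplot2::labs(x = expression(1 / n[mol]),
                  y = expression(Delta * f ~ "(" * k[B] * T * ")"),
                  title = "Extrapolation to the thermodynamic limit") +
    ggplot2::theme_minimal()
}
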