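# broom-style accessors for the remaining result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.ecm_result <- function(x, ...) {
  x$pairs
}

#' @export
glance.ecm_result <- function(x, ...) {
  tibble(
    f = x$f, se = x$se, f0 = x$f0,
    n_pairs = nrow(x$pairs), n_flagged = sum(x$pairs$flagged)
  )
}

#' @export
autoplot.ecm_result <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda_hi, y = .data$delta_f)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$delta_f - .data$se, ymax = .data$delta_f + .data$se
    )) +
    ggplot2::labs(x = expression(lambda), y = expression(Delta * f[i]),
                  title = "Pairwise window free-energy increments") +
    ggplot2::theme_minimal()
}
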