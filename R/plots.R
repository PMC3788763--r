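# ggplot2 displays for the fitted objects.

#' @export
autoplot.abc_model_choice <- function(object, ...) {
  res <- object$result
  ggplot2::ggplot(res, ggplot2::aes(x = .data$scenario, y = .data$prob)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq_direct),
                        colour = "firebrick", shape = 1) +
    ggplot2::labs(x = NULL, y = "Posterior probability",
                  title = "ABC scenario choice",
                  subtitle = "bars: logistic regression (95% CI); circles: direct rejection frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abc_posterior <- function(object, ...) {
  samples <- object$samples
  w <- object$weights / sum(object$weights)
  long <- tidyr::pivot_longer(dplyr::mutate(samples, .w = w),
                              -".w", names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     weight = .data$.w)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "Posterior density",
                  title = paste("Adjusted posterior,", object$scenario)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abc_model_check <- function(object, ...) {
  sims <- as_tibble(as.data.frame(object$predictive))
  long <- tidyr::pivot_longer(sims, dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  obs <- object$result[, c("statistic", "observed")]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "Pseudo-observed datasets",
                  title = paste("Posterior-predictive check,", object$scenario)) +
    ggplot2::theme_minimal()
}

#' @export
plot.abc_model_choice <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.abc_posterior <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.abc_model_check <- function(x, ...) print(autoplot(x, ...))
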