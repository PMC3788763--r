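#' Posterior-predictive model checking
#'
#' Draws parameter sets from the weighted posterior sample, simulates a
#' pseudo-observed dataset from each, and locates every observed summary
#' statistic within its posterior-predictive distribution. The reported
#' `tail_prob` is the mid-p position P(sim < obs) + 0.5 P(sim = obs);
#' `p_two_sided = 2 min(tail_prob, 1 - tail_prob)` flags statistics the
#' fitted scenario cannot reproduce.
#'
#' @param spec The fitted `scenario_spec`.
#' @param posterior An [abc_estimate()] result for `spec`.
#' @param observed The observed summary vector.
#' @param config A [sample_config()].
#' @param n_pod Number of pseudo-observed datasets (>= 1).
#' @param seed Optional RNG seed.
#' @return An `abc_model_check` object whose `result` tibble has one row per
#'   summary statistic.
#' @export
abc_model_check <- function(spec, posterior, observed,
                            config = sample_config(), n_pod = 1000,
                            seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(posterior, "abc_posterior"))
  if (n_pod < 1) abort("`n_pod` must be at least 1")
  if (nrow(posterior$samples) == 0) abort("empty posterior sample")
  if (!is.null(seed)) set.seed(seed)
  stat_cols <- summary_stat_names(spec$populations)
  obs <- as_observed_vector(observed, stat_cols)
  w <- posterior$weights
  # regression adjustment preserves prior bounds but not the inequality
  # constraints; draws that violate them cannot be simulated, so they are
  # rejected and redrawn from the weighted posterior
  ok <- rowSums(!constraint_matrix(posterior$samples,
                                   spec$constraints)) == 0
  if (!any(ok))
    abort("no posterior draw satisfies the scenario constraints")
  prob <- (w / sum(w)) * ok
  idx <- sample.int(nrow(posterior$samples), n_pod, replace = TRUE,
                    prob = prob / sum(prob))
  sims <- matrix(NA_real_, n_pod, length(stat_cols),
                 dimnames = list(NULL, stat_cols))
  for (i in seq_len(n_pod)) {
    draw <- posterior$samples[idx[i], , drop = FALSE]
    sims[i, ] <- sim_summary_once(spec, draw, config)
  }
  res <- dplyr::bind_rows(lapply(stat_cols, function(s) {
    x <- sims[, s]
    p_mid <- (sum(x < obs[s]) + 0.5 * sum(x == obs[s])) / n_pod
    tibble(statistic = s, observed = unname(obs[s]),
           predictive_mean = mean(x),
           tail_prob = p_mid,
           p_two_sided = min(1, 2 * min(p_mid, 1 - p_mid)))
  }))
  structure(list(result = res, predictive = sims, n_pod = n_pod,
                 scenario = spec$id),
            class = "abc_model_check")
}

#' @export
print.abc_model_check <- function(x, ...) {
  cat("Posterior-predictive check for ", x$scenario, " (", x$n_pod,
      " pseudo-observed datasets)\n", sep = "")
  print(x$result)
  invisible(x)
}

#' @export
tidy.abc_model_check <- function(x, ...) x$result

#' @export
glance.abc_model_check <- function(x, ...) {
  tibble(scenario = x$scenario, n_pod = x$n_pod,
         n_extreme = sum(x$result$p_two_sided < 0.05))
}
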