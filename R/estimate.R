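logit_bounded <- function(x, low, high, eps = 1e-9) {
  q <- pmin(pmax((x - low) / (high - low), eps), 1 - eps)
  stats::qlogis(q)
}

inv_logit_bounded <- function(y, low, high) {
  low + (high - low) * stats::plogis(y)
}

#' Posterior parameter estimation by local-linear regression adjustment
#'
#' Beaumont-style regression ABC on the selected simulations of one
#' scenario: each parameter is mapped to an unbounded scale by a logit
#' transform over its prior interval, regressed (weighted local-linear,
#' Epanechnikov kernel over the rejection distance) on the standardized
#' deviations of the statistics from the observed vector, and the residuals
#' around the fit at the observed point are kept as the adjusted posterior
#' sample. The back-transform guarantees adjusted values inside the prior
#' bounds. Per-parameter summaries report the weighted mean, median, mode
#' (Gaussian kernel density, Silverman bandwidth) and 2.5%/97.5% quantiles.
#'
#' @param selected Output of [rejection_select()]; all records must belong
#'   to `spec`'s scenario.
#' @param spec The `scenario_spec` the parameters belong to.
#' @param adjust Apply the regression adjustment (default TRUE). With
#'   `adjust = FALSE` the weighted accepted draws are summarized as-is.
#' @return An `abc_posterior` object: adjusted draws, kernel weights and a
#'   summary tibble. See [tidy()], [glance()], [autoplot()],
#'   [posterior_times()].
#' @export
abc_estimate <- function(selected, spec, adjust = TRUE) {
  stopifnot(inherits(selected, "abc_selected"), inherits(spec, "scenario_spec"))
  if (!all(selected$scenario == spec$id))
    abort("all selected records must come from the target scenario; filter or rebuild the selection from a single-scenario table")
  params <- intersect(scenario_params(spec), names(selected))
  pr <- spec$priors[match(params, spec$priors$param), ]
  stat_cols <- attr(selected, "stat_cols")
  obs <- attr(selected, "observed")
  scl <- attr(selected, "scale")
  n <- nrow(selected)
  if (n == 0) abort("no selected records")

  d <- selected$.dist
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, n)   # Epanechnikov
  if (sum(w) <= 0) w <- rep(1, n)

  theta <- as.matrix(as_tibble(selected)[, params, drop = FALSE])
  Y <- vapply(seq_along(params), function(j)
    logit_bounded(theta[, j], pr$low[j], pr$high[j]), numeric(n))
  if (n == 1) Y <- matrix(Y, nrow = 1)
  colnames(Y) <- params

  if (adjust && n > ncol(Y) + 1) {
    X <- sweep(sweep(as.matrix(as_tibble(selected)[, stat_cols, drop = FALSE]),
                     2L, obs), 2L, scl, "/")
    Xd <- cbind(1, X)
    XtW <- t(Xd * w)
    A <- XtW %*% Xd
    B <- tryCatch(solve(A, XtW %*% Y), error = function(e) NULL)
    if (is.null(B)) {
      warn("singular local-linear design; using a ridge-regularized solve")
      lam <- 1e-6 * mean(diag(A))
      B <- solve(A + diag(lam, nrow(A)), XtW %*% Y)
    }
    slopes <- B[-1, , drop = FALSE]
    Yadj <- Y - X %*% slopes     # residuals shifted to the observed point
  } else {
    Yadj <- Y
  }
  adj <- vapply(seq_along(params), function(j)
    inv_logit_bounded(Yadj[, j], pr$low[j], pr$high[j]), numeric(n))
  if (n == 1) adj <- matrix(adj, nrow = 1)
  colnames(adj) <- params

  summary <- dplyr::bind_rows(lapply(seq_along(params), function(j) {
    x <- adj[, j]
    md <- if (n >= 2 && stats::sd(x) > 0) {
      dens <- stats::density(x, weights = w / sum(w),
                             bw = stats::bw.nrd0(x))
      dens$x[which.max(dens$y)]
    } else x[1]
    qs <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
    tibble(term = params[j], mean = weighted_mean(x, w), median = qs[2],
           mode = md, q025 = qs[1], q975 = qs[3])
  }))

  structure(list(scenario = spec$id,
                 samples = as_tibble(adj),
                 raw = as_tibble(theta),
                 weights = w,
                 summary = summary,
                 priors = pr,
                 adjusted = adjust,
                 observed = obs),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC posterior for scenario ", x$scenario, " (",
      nrow(x$samples), " weighted draws",
      if (x$adjusted) ", regression-adjusted" else "", ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' @export
glance.abc_posterior <- function(x, ...) {
  w <- x$weights / sum(x$weights)
  tibble(scenario = x$scenario, n_draws = nrow(x$samples),
         ess = 1 / sum(w^2), adjusted = x$adjusted)
}

#' Posterior split-time summaries in generations and calendar years
#'
#' Converts the posterior summaries of every time parameter (names starting
#' `t_`) from generations to years using the life-history generation time,
#' mirroring the side-by-side generations/years presentation of divergence
#' time estimates.
#'
#' @param posterior An `abc_posterior`.
#' @param life A [life_history()].
#' @return A tibble with one generations row and one years row per time
#'   parameter.
#' @export
posterior_times <- function(posterior, life = life_history()) {
  stopifnot(inherits(posterior, "abc_posterior"))
  tm <- posterior$summary[grepl("^t_", posterior$summary$term), ]
  if (nrow(tm) == 0) return(tm)
  cols <- c("mean", "median", "mode", "q025", "q975")
  yr <- tm
  yr[cols] <- lapply(tm[cols], generations_to_years, life = life)
  tm$unit <- "generations"
  yr$unit <- "years"
  dplyr::arrange(dplyr::bind_rows(tm, yr), .data$term, .data$unit)
}
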