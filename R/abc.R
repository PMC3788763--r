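as_observed_vector <- function(observed, stat_cols) {
  if (is.data.frame(observed)) {
    if (nrow(observed) != 1) abort("`observed` must be a single summary vector")
    observed <- unlist(observed[intersect(names(observed), stat_cols)])
  }
  if (is.null(names(observed)) && length(observed) == length(stat_cols))
    names(observed) <- stat_cols
  missing <- setdiff(stat_cols, names(observed))
  if (length(missing))
    abort(paste0("observed summary is missing statistic(s): ",
                 paste(missing, collapse = ", ")))
  observed[stat_cols]
}

# per-statistic normalization constants from the full reference table
ref_scale <- function(stats_mat, method = c("sd", "mad")) {
  method <- match.arg(method)
  s <- apply(stats_mat, 2L, if (method == "sd") sd else stats::mad)
  s[s == 0 | !is.finite(s)] <- 1  # constant statistic carries no signal
  s
}

#' Rejection step: keep the simulations closest to the observed data
#'
#' Statistics are standardized by their reference-table standard deviation
#' (or MAD), distances are Euclidean, and the `ceiling(fraction * n)`
#' closest records are retained; ties break by record index.
#'
#' @param table A `ref_tbl` from [build_reference_table()].
#' @param observed Observed summary vector ([summary_vector()] output, or a
#'   named numeric vector).
#' @param fraction Fraction of the table to keep, in (0, 1].
#' @param scale_method `"sd"` (default) or `"mad"`.
#' @return The selected records with an extra `.dist` column, carrying the
#'   scaling constants and observed vector as attributes.
#' @export
rejection_select <- function(table, observed, fraction = 0.01,
                             scale_method = c("sd", "mad")) {
  if (nrow(table) == 0) abort("empty reference table")
  if (!(fraction > 0 && fraction <= 1)) abort("`fraction` must be in (0, 1]")
  stats_mat <- ref_stat_matrix(table)
  obs <- as_observed_vector(observed, colnames(stats_mat))
  scl <- ref_scale(stats_mat, match.arg(scale_method))
  dev <- sweep(sweep(stats_mat, 2L, obs), 2L, scl, "/")
  dist <- sqrt(rowSums(dev^2))
  k <- ceiling(fraction * nrow(table))
  sel_idx <- order(dist)[seq_len(k)]  # stable: ties keep record order
  out <- as_tibble(table)[sel_idx, , drop = FALSE]
  out$.dist <- dist[sel_idx]
  structure(out,
            scenarios = sort(unique(table$scenario)),
            stat_cols = attr(table, "stat_cols"),
            populations = attr(table, "populations"),
            scale = scl, observed = obs, fraction = fraction,
            n_ref = nrow(table),
            class = c("abc_selected", class(tibble())))
}

#' Scenario choice by multinomial logistic regression
#'
#' Among the selected simulations, scenario identity is regressed on the
#' standardized deviations of the summary statistics from the observed
#' vector; the fitted scenario probabilities are evaluated at the observed
#' point (deviation zero, where the linear predictor reduces to the
#' intercepts). 95% confidence intervals come from the asymptotic
#' covariance of the maximum-likelihood estimator by the delta method. The
#' raw scenario frequencies among selected records (the direct rejection
#' estimate) are reported alongside.
#'
#' @param selected Output of [rejection_select()].
#' @param level Confidence level (default 0.95).
#' @return An `abc_model_choice` object; see [tidy()] / [autoplot()].
#' @export
abc_model_choice <- function(selected, level = 0.95) {
  stopifnot(inherits(selected, "abc_selected"))
  stat_cols <- attr(selected, "stat_cols")
  obs <- attr(selected, "observed")
  scl <- attr(selected, "scale")
  all_scenarios <- attr(selected, "scenarios") %||%
    sort(unique(selected$scenario))
  scenarios <- sort(unique(selected$scenario))
  freq <- table(factor(selected$scenario, levels = scenarios))
  if (length(scenarios) == 1) {
    res <- tibble(scenario = scenarios, n_selected = as.integer(freq),
                  freq_direct = 1, prob = 1, conf_low = 1, conf_high = 1)
    return(new_model_choice(pad_absent(res, all_scenarios), selected,
                            degenerate = TRUE))
  }
  X <- sweep(sweep(as.matrix(as_tibble(selected)[, stat_cols]), 2L, obs),
             2L, scl, "/")
  dat <- data.frame(scenario = factor(selected$scenario, levels = scenarios), X)
  fit <- nnet::multinom(scenario ~ ., data = dat, trace = FALSE, maxit = 500)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V)))) {
    warn("ill-conditioned multinomial fit (possible separation); refitting with weak regularization")
    fit <- nnet::multinom(scenario ~ ., data = dat, trace = FALSE,
                          maxit = 500, decay = 0.01)
    V <- stats::vcov(fit)
  }
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(scenarios[2], names(co)))
  a <- c(0, co[, "(Intercept)"])          # baseline intercept is 0
  p <- exp(a - max(a)); p <- p / sum(p)
  # delta method: dp_k/da_j = p_k (1{k=j} - p_j) over non-baseline intercepts
  int_names <- paste0(scenarios[-1], ":(Intercept)")
  if (!all(int_names %in% rownames(V)))
    int_names <- grep("\\(Intercept\\)", rownames(V), value = TRUE)
  Vi <- V[int_names, int_names, drop = FALSE]
  se <- vapply(seq_along(scenarios), function(k) {
    grad <- p[k] * ((as.numeric(seq_along(scenarios)[-1] == k)) - p[-1])
    sqrt(max(0, drop(t(grad) %*% Vi %*% grad)))
  }, numeric(1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- tibble(scenario = scenarios,
                n_selected = as.integer(freq),
                freq_direct = as.numeric(freq) / sum(freq),
                prob = p,
                conf_low = pmax(0, p - z * se),
                conf_high = pmin(1, p + z * se))
  new_model_choice(pad_absent(res, all_scenarios), selected,
                   degenerate = FALSE)
}

# scenarios present in the table but absent from the selection get
# probability zero rather than silently disappearing
pad_absent <- function(res, all_scenarios) {
  absent <- setdiff(all_scenarios, res$scenario)
  if (length(absent))
    res <- dplyr::bind_rows(res, tibble(
      scenario = absent, n_selected = 0L, freq_direct = 0,
      prob = 0, conf_low = 0, conf_high = 0))
  dplyr::arrange(res, .data$scenario)
}

new_model_choice <- function(res, selected, degenerate) {
  structure(list(result = res,
                 fraction = attr(selected, "fraction"),
                 n_ref = attr(selected, "n_ref"),
                 n_selected = nrow(selected),
                 degenerate = degenerate),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (logistic regression on ", x$n_selected,
      " of ", x$n_ref, " simulations)\n", sep = "")
  print(x$result)
  invisible(x)
}

#' @export
tidy.abc_model_choice <- function(x, ...) x$result

#' @export
glance.abc_model_choice <- function(x, ...) {
  best <- x$result$scenario[which.max(x$result$prob)]
  tibble(n_ref = x$n_ref, n_selected = x$n_selected,
         fraction = x$fraction, best_scenario = best,
         best_prob = max(x$result$prob))
}
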