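#' Draw parameter sets from a scenario's constrained joint prior
#'
#' Samples every scenario parameter independently from its uniform (or
#' log-uniform) interval and rejects draws violating the scenario's
#' inequality constraints, so accepted draws follow the joint prior
#' truncated to the constraint region. Deterministic given the RNG state
#' (use `set.seed()`).
#'
#' @param spec A `scenario_spec`.
#' @param n Number of accepted draws required.
#' @param max_tries Cap on rejection rounds (each round proposes `n` to
#'   `10n` candidate draws); exceeded only when the constraint region has
#'   (near-)zero prior mass.
#' @return A tibble with `n` rows, one column per scenario parameter.
#' @examples
#' set.seed(1)
#' draws <- sample_prior_draws(build_scenario("Sc1"), 100)
#' all(draws$t_2 < draws$t_3)
#' @export
sample_prior_draws <- function(spec, n, max_tries = 1000L) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 1)
  pr <- spec$priors
  pars <- scenario_params(spec)
  pr <- pr[match(pars, pr$param), , drop = FALSE]
  out <- vector("list", 0L)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort(paste0("constraint set appears to have zero prior mass: ",
                   "no accepted draw in ", max_tries, " rounds"))
    m <- min(10L * n, max(n, 1000L))
    block <- lapply(seq_len(nrow(pr)), function(i) {
      if (isTRUE(pr$log_scale[i]))
        exp(runif(m, log(pr$low[i]), log(pr$high[i])))
      else runif(m, pr$low[i], pr$high[i])
    })
    names(block) <- pr$param
    block <- as_tibble(block)
    keep <- rowSums(!constraint_matrix(block, spec$constraints)) == 0
    if (any(keep)) {
      out[[length(out) + 1L]] <- block[keep, , drop = FALSE]
      got <- got + sum(keep)
    }
  }
  draws <- dplyr::bind_rows(out)
  draws[seq_len(n), , drop = FALSE]
}

#' List the constraint and interval violations of a parameter draw
#'
#' @param spec A `scenario_spec`.
#' @param draw A named list, named numeric vector or one-row data frame with
#'   a value for every scenario parameter.
#' @return Character vector describing each violated relation or interval
#'   bound; empty when the draw is valid. Missing parameters are an error.
#' @examples
#' spec <- build_scenario("Sc1")
#' set.seed(1)
#' d <- sample_prior_draws(spec, 1)
#' validate_draw(spec, d)   # character(0)
#' @export
validate_draw <- function(spec, draw) {
  stopifnot(inherits(spec, "scenario_spec"))
  draw <- as.list(draw)
  pars <- scenario_params(spec)
  missing <- setdiff(pars, names(draw))
  if (length(missing))
    abort(paste0("draw is missing parameter(s): ",
                 paste(missing, collapse = ", ")))
  d1 <- as_tibble(draw[pars])
  viol <- character(0)
  pr <- spec$priors
  for (i in seq_len(nrow(pr))) {
    v <- d1[[pr$param[i]]]
    if (v < pr$low[i] || v > pr$high[i])
      viol <- c(viol, paste0(pr$param[i], " = ", format(v),
                             " outside prior [", pr$low[i], ", ",
                             pr$high[i], "]"))
  }
  ok <- constraint_matrix(d1, spec$constraints)[1, ]
  cs <- spec$constraints
  bad <- which(!ok)
  if (length(bad))
    viol <- c(viol, paste0("violates ", cs$lhs[bad], " ", cs$op[bad], " ",
                           cs$rhs[bad]))
  viol
}
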