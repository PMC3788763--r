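#' Adult life-history parameters for the generation-time model
#'
#' Generation time is modelled as the adult age at maturity plus the expected
#' adult residual lifespan under geometric daily survival,
#' \eqn{T = \alpha + s/(1 - s)} days. The default survival probability
#' (s = 0.798) is the screwworm-fly field estimate; with alpha = 20 days it
#' gives T = 23.95 days, the value used to convert coalescent split times
#' from generations into years.
#'
#' @param alpha_days Adult age at maturity, in days. Must be positive.
#' @param survival_s Daily adult survival probability, in `[0, 1)`.
#' @param days_per_year Days per year used for calendar conversion.
#'
#' @return An object of class `life_history`.
#' @examples
#' generation_time(life_history())          # 23.95 days
#' generations_to_years(233000)             # ~15,278 years
#' @export
life_history <- function(alpha_days = 20, survival_s = 0.798,
                         days_per_year = 365.25) {
  if (!is.numeric(alpha_days) || length(alpha_days) != 1 || alpha_days <= 0)
    abort("`alpha_days` must be a single positive number")
  if (!is.numeric(survival_s) || length(survival_s) != 1 ||
      survival_s < 0 || survival_s >= 1)
    abort("`survival_s` must lie in [0, 1): the geometric residual lifespan s/(1-s) diverges at s = 1")
  if (!is.numeric(days_per_year) || days_per_year <= 0)
    abort("`days_per_year` must be positive")
  structure(list(alpha_days = alpha_days, survival_s = survival_s,
                 days_per_year = days_per_year),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history> alpha =", x$alpha_days, "d, s =", x$survival_s,
      "-> T =", round(generation_time(x), 2), "d/generation\n")
  invisible(x)
}

#' Generation time in days
#'
#' @param life A [life_history()] object.
#' @return Days per generation, \eqn{\alpha + s/(1-s)}. Full precision is
#'   kept; round only for display.
#' @export
generation_time <- function(life = life_history()) {
  stopifnot(inherits(life, "life_history"))
  life$alpha_days + life$survival_s / (1 - life$survival_s)
}

#' Convert between generations and calendar years
#'
#' @param generations Number of generations (nonnegative).
#' @param years Number of years (nonnegative).
#' @param life A [life_history()] object.
#' @return `generations_to_years()` returns years; `years_to_generations()`
#'   is its exact inverse.
#' @export
generations_to_years <- function(generations, life = life_history()) {
  if (any(generations < 0)) abort("`generations` must be nonnegative")
  generations * generation_time(life) / life$days_per_year
}

#' @rdname generations_to_years
#' @export
years_to_generations <- function(years, life = life_history()) {
  if (any(years < 0)) abort("`years` must be nonnegative")
  years * life$days_per_year / generation_time(life)
}
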