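#' Substitution-model settings (HKY + invariant sites + gamma rates)
#'
#' The simulated locus evolves under HKY with a proportion `p_invariant` of
#' sites fixed at rate zero and the remaining sites assigned gamma(shape,
#' shape) relative rates (mean 1 before rescaling). The HKY generator is
#' scaled to one expected substitution per site per unit of mu x rate x
#' time, so the drawn `mu` is the realized mean per-site rate. Defaults
#' follow the simulation design (92% invariant sites, gamma shape 2);
#' `kappa = 2` and equal base frequencies are this package's defaults since
#' the original design states only "HKY". Use `gamma_shape = Inf` for
#' rate-homogeneous variable sites.
#'
#' @param p_invariant Proportion of invariant sites, in `[0, 1]`.
#' @param gamma_shape Gamma shape for site-rate heterogeneity (> 0; `Inf`
#'   means no heterogeneity).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Stationary base frequencies (A, C, G, T), summing to 1.
#' @return A `substitution_settings` object.
#' @export
substitution_settings <- function(p_invariant = 0.92, gamma_shape = 2,
                                  kappa = 2, base_freqs = rep(0.25, 4)) {
  if (p_invariant < 0 || p_invariant > 1) abort("`p_invariant` must be in [0, 1]")
  if (!(gamma_shape > 0)) abort("`gamma_shape` must be positive")
  if (!(kappa > 0)) abort("`kappa` must be positive")
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-12)
    abort("`base_freqs` must be 4 nonnegative values summing to 1")
  structure(list(p_invariant = p_invariant, gamma_shape = gamma_shape,
                 kappa = kappa, base_freqs = base_freqs),
            class = "substitution_settings")
}

#' Empirical base frequencies of an alignment
#'
#' Convenience for parameterizing [substitution_settings()] from observed
#' data.
#'
#' @param aln A haplotype alignment tibble (columns `id`, `pop`, `seq`).
#' @return Numeric vector of A, C, G, T frequencies.
#' @export
empirical_base_freqs <- function(aln) {
  mat <- seq_to_matrix(aln$seq)
  as.numeric(tabulate(as.vector(mat) + 1L, 4L) / length(mat))
}

#' Draw per-site relative rates
#'
#' Each site is independently invariant (rate 0) with probability
#' `p_invariant`, otherwise its rate is gamma-distributed; rates are then
#' rescaled so the mean over all `L` sites is 1 (when any site is
#' variable). Rates are drawn once per dataset and shared across branches.
#'
#' @param L Number of sites (>= 1).
#' @param settings A [substitution_settings()].
#' @return Numeric vector of length `L`.
#' @export
draw_site_rates <- function(L, settings = substitution_settings()) {
  if (L < 1) abort("`L` must be at least 1")
  stopifnot(inherits(settings, "substitution_settings"))
  variable <- runif(L) >= settings$p_invariant
  rates <- numeric(L)
  nv <- sum(variable)
  if (nv > 0) {
    rates[variable] <- if (is.infinite(settings$gamma_shape)) 1
      else rgamma(nv, shape = settings$gamma_shape, rate = settings$gamma_shape)
    rates <- rates / mean(rates)
  }
  rates
}

#' Evolve sequences along a genealogy
#'
#' The root sequence is drawn from the stationary base frequencies; each
#' site then evolves independently along every branch as a continuous-time
#' HKY chain at rate `mu` times its site rate. Exact event-level simulation
#' (no time discretization): a Poisson/jump-chain sampler when base
#' frequencies are equal, otherwise per-branch Gillespie with
#' state-dependent leaving rates.
#'
#' @param g A `genealogy`.
#' @param mu Mean mutation rate per site per generation.
#' @param settings A [substitution_settings()].
#' @param site_rates Optional precomputed [draw_site_rates()] vector;
#'   drawn internally when `NULL`.
#' @param locus_length Number of sites (used only when `site_rates` is
#'   `NULL`).
#' @return A haplotype alignment tibble with columns `id`, `pop`, `seq`.
#' @examples
#' spec <- build_scenario("Sc1")
#' set.seed(11)
#' d <- sample_prior_draws(spec, 1)
#' g <- simulate_genealogy(spec, d, sample_config(c(SAG = 4, NAG = 3, NC = 2),
#'                                                locus_length = 100))
#' aln <- evolve_alignment(g, mu = 1e-6, locus_length = 100)
#' @export
evolve_alignment <- function(g, mu, settings = substitution_settings(),
                             site_rates = NULL, locus_length = 1752) {
  stopifnot(inherits(g, "genealogy"), inherits(settings, "substitution_settings"))
  if (mu < 0) abort("`mu` must be nonnegative")
  if (is.null(site_rates)) site_rates <- draw_site_rates(locus_length, settings)
  res <- evolve_cpp(g$parent, g$node_time, g$n_tips, site_rates, mu,
                    settings$kappa, settings$base_freqs)
  n <- g$n_tips
  L <- length(site_rates)
  mat <- matrix(rep(res$root_seq, each = n), nrow = n)
  if (length(res$var_sites)) mat[, res$var_sites] <- res$tip_var
  haplotype_alignment(tibble(
    id = paste0(as.character(g$tip_pop), "_",
                sprintf("%03d", stats::ave(seq_len(n), g$tip_pop, FUN = seq_along))),
    pop = as.character(g$tip_pop),
    seq = matrix_to_seq(mat)))
}
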