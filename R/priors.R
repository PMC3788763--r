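#' Default prior system for the shipped divergence/admixture scenarios
#'
#' Independent uniform priors in native units: effective sizes are haploid
#' numbers of mtDNA gene copies (maternal lineages), times are generations
#' before present, `mu` is the mean mutation rate per site per generation,
#' and admixture rates are dimensionless proportions. The mutation-rate prior
#' is uniform on the rate itself; set `log_mu = TRUE` for a log-uniform
#' alternative.
#'
#' @param log_mu Draw `mu` log-uniformly over its interval instead of
#'   uniformly (default `FALSE`, the rate-scale prior).
#' @return A tibble with columns `param`, `low`, `high`, `log_scale`.
#' @export
default_priors <- function(log_mu = FALSE) {
  pr <- tribble(
    ~param,     ~low,   ~high,
    "N_anc",    1000,   60000,
    "N_SAG",    1e5,    3.6e6,
    "N_NAG",    1.5e5,  8e5,
    "N_NC",     4e4,    1.5e5,
    "N1",       100,    2e5,
    "N2",       100,    2e5,
    "N3",       100,    2e5,
    "N4",       100,    2e5,
    "N5",       100,    2e5,
    "N6",       100,    2e5,
    "N7",       100,    2e5,
    "N8",       100,    2e5,
    "t_exp",    6e4,    4.5e5,
    "t_expNAG", 6e4,    4.5e5,
    "t_expSAG", 6e4,    4.5e5,
    "t_expNC",  6e4,    4.5e5,
    "t_adm1",   2e4,    3e5,
    "t_adm2",   2e4,    3e5,
    "t_2",      5e4,    3.5e5,
    "t_3",      1e5,    1e6,
    "mu",       1e-11,  1e-7,
    "ra",       0.01,   0.99,
    "rb",       0.01,   0.99,
    "rc",       0.01,   0.99
  )
  pr$log_scale <- log_mu & pr$param == "mu"
  pr
}

#' Default inequality constraints among prior parameters
#'
#' Encodes the joint-prior conditions: every expansion time is at most the
#' younger split (`t_exp <= t_2`), the splits are ordered (`t_2 < t_3`),
#' present-day sizes are ordered (`N_anc < N_NC <= N_NAG <= N_SAG`) and the
#' intermediate epoch sizes exceed the ancestral size (`N1..N8 > N_anc`).
#' Admixture-time constraints (`t_adm1 < t_2`; `t_2 < t_adm2 < t_3`) are
#' added by the scenarios that use them.
#'
#' @return A tibble with columns `lhs`, `op`, `rhs`; `op` is one of
#'   `"<"`, `"<="`, `">"`, `">="` and both sides are parameter names.
#' @export
default_constraints <- function() {
  tribble(
    ~lhs,       ~op,  ~rhs,
    "t_exp",    "<=", "t_2",
    "t_expNAG", "<=", "t_2",
    "t_expSAG", "<=", "t_2",
    "t_expNC",  "<=", "t_2",
    "t_2",      "<",  "t_3",
    "N_anc",    "<",  "N_NC",
    "N_NC",     "<=", "N_NAG",
    "N_NAG",    "<=", "N_SAG",
    "N1",       ">",  "N_anc",
    "N2",       ">",  "N_anc",
    "N3",       ">",  "N_anc",
    "N4",       ">",  "N_anc",
    "N5",       ">",  "N_anc",
    "N6",       ">",  "N_anc",
    "N7",       ">",  "N_anc",
    "N8",       ">",  "N_anc",
    "t_adm1",   "<",  "t_2",
    "t_adm2",   ">",  "t_2",
    "t_adm2",   "<",  "t_3"
  )
}

validate_priors <- function(priors) {
  need <- c("param", "low", "high")
  if (!all(need %in% names(priors))) abort("priors need columns param, low, high")
  if (anyDuplicated(priors$param)) abort("duplicated prior parameter names")
  bad <- priors$param[priors$low > priors$high]
  if (length(bad))
    abort(paste0("prior interval must have low <= high for: ",
                 paste(bad, collapse = ", ")))
  invisible(priors)
}

# Restrict a constraint table to relations whose parameters all exist.
restrict_constraints <- function(constraints, params) {
  constraints[constraints$lhs %in% params & constraints$rhs %in% params, ,
              drop = FALSE]
}

# Evaluate constraints on a draws tibble -> logical matrix (rows x relations).
constraint_matrix <- function(draws, constraints) {
  if (nrow(constraints) == 0)
    return(matrix(TRUE, nrow = nrow(draws), ncol = 0))
  ok <- vapply(seq_len(nrow(constraints)), function(i) {
    lhs <- draws[[constraints$lhs[i]]]
    rhs <- draws[[constraints$rhs[i]]]
    switch(constraints$op[i],
           "<"  = lhs <  rhs,
           "<=" = lhs <= rhs,
           ">"  = lhs >  rhs,
           ">=" = lhs >= rhs,
           abort(paste0("unknown constraint operator '", constraints$op[i], "'")))
  }, logical(nrow(draws)))
  if (nrow(draws) == 1L) ok <- matrix(ok, nrow = 1L)
  ok
}
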