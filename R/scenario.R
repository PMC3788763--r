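#' Demographic scenarios as time-ordered backward event lists
#'
#' A scenario is a demographic history over the three sampled populations
#' SAG (south Amazon), NAG (north Amazon) and NC (North/Central America),
#' written backward in time as a list of events:
#'
#' * `merge`: all lineages of `pop` move into `pop2` (a forward-time split);
#' * `admix`: each lineage of `pop` moves to `pop2` independently with the
#'   probability named by `param` (a forward-time admixture pulse into `pop`);
#' * `resize`: `pop`'s haploid size becomes the value named by `param`
#'   (a forward-time stepwise expansion when the new size is smaller).
#'
#' Event times are parameter names; the realized order comes from the drawn
#' values, with ties broken by listed order. Ancestral-branch lineages keep
#' living in the label of the population they merged into, so three labels
#' suffice for every shipped scenario.
#'
#' The eight shipped scenarios:
#'
#' * `Sc1`-`Sc3`: the oldest split (`t_3`) separates NC from the common South
#'   American ancestor; NAG and SAG split at `t_2`. `Sc1` has one shared
#'   expansion time `t_exp`; `Sc2` has independent per-population expansion
#'   times; `Sc3` ties expansions to the divergence events themselves.
#' * `Sc4`-`Sc6`: mirror histories with the south-first order (oldest split
#'   separates SAG; NC and NAG split at `t_2`).
#' * `Sc7`: `Sc1` plus an admixture pulse at `t_adm1 < t_2` in which SAG
#'   receives a fraction `ra` of its lineages from NAG.
#' * `Sc8`: the older-admixture alternative — SAG is founded at `t_adm2`
#'   (between the expansions and the root) as an admixture (rate `rb`) of
#'   the NAG lineage and the ancestor's direct continuation, carried below
#'   `t_3` by the NC branch; the admixed founding replaces the `t_2` split
#'   and the SAG branch terminates there, as admixture events do in the
#'   standard scenario grammar.
#'
#' The pre-expansion epoch sizes use slots `N1`-`N3` (per-population) and
#' `N4` (ancestral branch between the splits); slots `N5`-`N8` remain in the
#' prior system for user-defined scenarios.
#'
#' @param id One of `"Sc1"`..`"Sc8"`, or a path to a YAML scenario file
#'   written by [write_scenario()].
#' @return A `scenario_spec` object.
#' @examples
#' build_scenario("Sc1")
#' @export
build_scenario <- function(id) {
  if (length(id) != 1 || !is.character(id)) abort("`id` must be a single string")
  if (file.exists(id)) return(read_scenario(id))
  builders <- shipped_scenarios()
  if (!id %in% names(builders))
    abort(paste0("unknown scenario '", id, "'; available: ",
                 paste(names(builders), collapse = ", "),
                 " (or a path to a scenario YAML file)"))
  builders[[id]]()
}

#' Construct a scenario specification
#'
#' Lower-level constructor used by [build_scenario()] and by user YAML
#' configs. See [build_scenario()] for the event grammar.
#'
#' @param id Scenario identifier.
#' @param populations Character vector of sampled population labels; the
#'   order fixes the summary-statistic order.
#' @param initial_sizes Named character vector mapping each population to the
#'   parameter holding its present-day haploid size.
#' @param events Tibble with columns `time` (time-parameter name), `kind`
#'   (`"merge"`, `"admix"`, `"resize"`), `pop`, `pop2` (merge destination or
#'   admixture donor, `NA` for resize) and `param` (size or rate parameter,
#'   `NA` for merge).
#' @param priors,constraints Prior interval table and inequality constraints
#'   ([default_priors()], [default_constraints()]); automatically restricted
#'   to the parameters the scenario names.
#' @param mutation_param Name of the mutation-rate parameter.
#' @return A validated `scenario_spec`.
#' @export
scenario_spec <- function(id, populations, initial_sizes, events,
                          priors = default_priors(),
                          constraints = default_constraints(),
                          mutation_param = "mu") {
  events <- as_tibble(events)
  need <- c("time", "kind", "pop", "pop2", "param")
  if (!all(need %in% names(events)))
    abort("`events` needs columns time, kind, pop, pop2, param")
  spec <- structure(
    list(id = id, populations = populations,
         initial_sizes = initial_sizes,
         events = events[need],
         priors = validate_priors(as_tibble(priors)),
         constraints = as_tibble(constraints),
         mutation_param = mutation_param),
    class = "scenario_spec")
  spec$priors <- spec$priors[spec$priors$param %in% scenario_params(spec), ,
                             drop = FALSE]
  spec$constraints <- restrict_constraints(spec$constraints,
                                           scenario_params(spec))
  validate_scenario(spec)
  spec
}

#' Parameters named by a scenario
#' @param spec A `scenario_spec`.
#' @return Character vector of parameter names, in a fixed order.
#' @export
scenario_params <- function(spec) {
  ev <- spec$events
  unique(c(unname(spec$initial_sizes),
           ev$time,
           ev$param[!is.na(ev$param)],
           spec$mutation_param))
}

#' Validate a scenario specification
#'
#' Checks the event grammar: known populations, known event kinds, every
#' named parameter present in the prior table, and a merge structure that
#' leaves exactly one lineage-bearing population (each population is merged
#' away at most once and the merge graph joins all populations).
#'
#' @param spec A `scenario_spec`.
#' @return `spec`, invisibly; aborts with the offending event on failure.
#' @export
validate_scenario <- function(spec) {
  pops <- spec$populations
  if (length(pops) < 1 || anyDuplicated(pops))
    abort("populations must be distinct labels")
  if (!identical(sort(names(spec$initial_sizes)), sort(pops)))
    abort("`initial_sizes` must name every population exactly once")
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    where <- paste0("event ", i, " (", ev$kind[i], " at ", ev$time[i], ")")
    if (!ev$kind[i] %in% c("merge", "admix", "resize"))
      abort(paste0(where, ": unknown event kind '", ev$kind[i], "'"))
    if (!ev$pop[i] %in% pops)
      abort(paste0(where, ": unknown population '", ev$pop[i], "'"))
    if (ev$kind[i] %in% c("merge", "admix")) {
      if (is.na(ev$pop2[i]) || !ev$pop2[i] %in% pops)
        abort(paste0(where, ": merge/admix needs a valid `pop2`"))
      if (ev$pop2[i] == ev$pop[i])
        abort(paste0(where, ": `pop` and `pop2` must differ"))
    }
    if (ev$kind[i] %in% c("admix", "resize") && is.na(ev$param[i]))
      abort(paste0(where, ": admix/resize needs a `param`"))
  }
  pars <- scenario_params(spec)
  missing <- setdiff(pars, spec$priors$param)
  if (length(missing))
    abort(paste0("no prior interval for parameter(s): ",
                 paste(missing, collapse = ", ")))
  merges <- ev[ev$kind == "merge", , drop = FALSE]
  if (anyDuplicated(merges$pop))
    abort("a population can be merged away only once")
  if (length(pops) > 1) {
    if (nrow(merges) != length(pops) - 1)
      abort(paste0("need exactly ", length(pops) - 1,
                   " merge events to end with a single ancestral population"))
    # union-find connectivity of the merge graph
    comp <- seq_along(pops); names(comp) <- pops
    find <- function(x) { while (comp[x] != comp[comp[x]]) comp[x] <<- comp[comp[x]]; comp[x] }
    for (i in seq_len(nrow(merges)))
      comp[find(merges$pop[i])] <- find(merges$pop2[i])
    roots <- vapply(pops, find, numeric(1))
    if (length(unique(roots)) != 1)
      abort("merge events do not join all populations into one ancestor")
  }
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$id, "\n", sep = "")
  cat("  populations: ", paste(x$populations, collapse = ", "), "\n", sep = "")
  cat("  present-day sizes: ",
      paste(names(x$initial_sizes), "=", x$initial_sizes, collapse = ", "),
      "\n  events (backward in time):\n", sep = "")
  ev <- x$events
  for (i in seq_len(nrow(ev))) {
    desc <- switch(ev$kind[i],
      merge  = paste0("merge ", ev$pop[i], " -> ", ev$pop2[i]),
      admix  = paste0("admix ", ev$pop[i], " <- ", ev$pop2[i],
                      " (rate ", ev$param[i], ")"),
      resize = paste0("resize ", ev$pop[i], " to ", ev$param[i]))
    cat("    at ", ev$time[i], ": ", desc, "\n", sep = "")
  }
  cat("  parameters: ", paste(scenario_params(x), collapse = ", "), "\n", sep = "")
  cat("  constraints: ",
      paste(x$constraints$lhs, x$constraints$op, x$constraints$rhs,
            collapse = "; "), "\n", sep = "")
  invisible(x)
}

ev_row <- function(time, kind, pop, pop2 = NA_character_,
                   param = NA_character_) {
  tibble(time = time, kind = kind, pop = pop, pop2 = pop2, param = param)
}

ev_constraint <- function(lhs, op, rhs) tibble(lhs = lhs, op = op, rhs = rhs)

std_sizes <- c(SAG = "N_SAG", NAG = "N_NAG", NC = "N_NC")

shared_expansion <- function(tp = "t_exp") {
  dplyr::bind_rows(ev_row(tp, "resize", "SAG", param = "N1"),
                   ev_row(tp, "resize", "NAG", param = "N2"),
                   ev_row(tp, "resize", "NC",  param = "N3"))
}

independent_expansion <- function() {
  dplyr::bind_rows(ev_row("t_expSAG", "resize", "SAG", param = "N1"),
                   ev_row("t_expNAG", "resize", "NAG", param = "N2"),
                   ev_row("t_expNC",  "resize", "NC",  param = "N3"))
}

# north-first backbone: NAG/SAG split at t_2, NC split at t_3
north_first_merges <- function() {
  dplyr::bind_rows(ev_row("t_2", "merge",  "NAG", "SAG"),
                   ev_row("t_2", "resize", "SAG", param = "N4"),
                   ev_row("t_3", "merge",  "SAG", "NC"),
                   ev_row("t_3", "resize", "NC",  param = "N_anc"))
}

# south-first backbone: NC/NAG split at t_2, SAG split at t_3
south_first_merges <- function() {
  dplyr::bind_rows(ev_row("t_2", "merge",  "NC",  "NAG"),
                   ev_row("t_2", "resize", "NAG", param = "N4"),
                   ev_row("t_3", "merge",  "NAG", "SAG"),
                   ev_row("t_3", "resize", "SAG", param = "N_anc"))
}

shipped_scenarios <- function() {
  mk <- function(id, events) {
    function() scenario_spec(id, c("SAG", "NAG", "NC"), std_sizes, events)
  }
  list(
    Sc1 = mk("Sc1", dplyr::bind_rows(shared_expansion(), north_first_merges())),
    Sc2 = mk("Sc2", dplyr::bind_rows(independent_expansion(), north_first_merges())),
    Sc3 = mk("Sc3", north_first_merges()),
    Sc4 = mk("Sc4", dplyr::bind_rows(shared_expansion(), south_first_merges())),
    Sc5 = mk("Sc5", dplyr::bind_rows(independent_expansion(), south_first_merges())),
    Sc6 = mk("Sc6", south_first_merges()),
    Sc7 = mk("Sc7", dplyr::bind_rows(
      shared_expansion(),
      ev_row("t_adm1", "admix", "SAG", "NAG", "ra"),
      north_first_merges())),
    # Sc8: SAG is founded at t_adm2 (older than the expansions) as an
    # admixture of the NAG lineage (rate rb) and the ancestor's direct
    # continuation, carried below t_3 by the NC branch; the SAG branch
    # terminates at its admixed founding, as in the standard scenario
    # grammar for admixture events
    Sc8 = function() scenario_spec(
      "Sc8", c("SAG", "NAG", "NC"), std_sizes,
      dplyr::bind_rows(
        shared_expansion(),
        ev_row("t_adm2", "admix", "SAG", "NAG", "rb"),
        ev_row("t_adm2", "merge", "SAG", "NC"),
        ev_row("t_3",    "merge", "NAG", "NC"),
        ev_row("t_3",    "resize", "NC", param = "N_anc")),
      constraints = dplyr::bind_rows(
        default_constraints(),
        ev_constraint("t_exp", "<=", "t_adm2")))
  )
}

#' Read or write a scenario configuration file
#'
#' Scenario files are versioned YAML documents holding the identifier,
#' population labels, present-day size parameters, the backward event list
#' and the prior intervals/constraints for the parameters the scenario
#' names.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `read_scenario()` returns a validated `scenario_spec`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  doc <- list(
    schema_version = 1L,
    id = spec$id,
    populations = as.list(spec$populations),
    initial_sizes = as.list(spec$initial_sizes),
    mutation_param = spec$mutation_param,
    events = lapply(seq_len(nrow(spec$events)), function(i)
      as.list(spec$events[i, ])),
    priors = lapply(seq_len(nrow(spec$priors)), function(i)
      list(param = spec$priors$param[i], low = spec$priors$low[i],
           high = spec$priors$high[i],
           log_scale = isTRUE(spec$priors$log_scale[i]))),
    constraints = lapply(seq_len(nrow(spec$constraints)), function(i)
      as.list(spec$constraints[i, ])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    abort("unsupported or missing scenario schema_version (expected 1)")
  ev <- dplyr::bind_rows(lapply(doc$events, function(e)
    tibble(time = e$time, kind = e$kind, pop = e$pop,
           pop2 = e$pop2 %||% NA_character_,
           param = e$param %||% NA_character_)))
  pr <- dplyr::bind_rows(lapply(doc$priors, function(p)
    tibble(param = p$param, low = p$low, high = p$high,
           log_scale = isTRUE(p$log_scale))))
  cn <- dplyr::bind_rows(lapply(doc$constraints, function(k)
    tibble(lhs = k$lhs, op = k$op, rhs = k$rhs)))
  scenario_spec(doc$id, unlist(doc$populations),
                unlist(doc$initial_sizes), ev,
                priors = pr, constraints = cn,
                mutation_param = doc$mutation_param %||% "mu")
}
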