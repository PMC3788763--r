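#' Sampling configuration for simulated datasets
#'
#' @param sample_sizes Named integer vector of haploid sample sizes per
#'   population; defaults to the study design (SAG 249, NAG 53, NC 15).
#' @param locus_length Number of aligned sites (default 1752, the combined
#'   CR + COI + COII mtDNA fragment length).
#' @param settings A [substitution_settings()] object.
#' @return A `sample_config` object.
#' @export
sample_config <- function(sample_sizes = c(SAG = 249, NAG = 53, NC = 15),
                          locus_length = 1752,
                          settings = substitution_settings()) {
  if (is.null(names(sample_sizes)) || any(names(sample_sizes) == ""))
    abort("`sample_sizes` must be named by population")
  if (any(sample_sizes < 0) || sum(sample_sizes) < 1)
    abort("sample sizes must be nonnegative with at least one lineage overall")
  if (locus_length < 1) abort("`locus_length` must be at least 1")
  structure(list(sample_sizes = sample_sizes,
                 locus_length = as.integer(locus_length),
                 settings = settings),
            class = "sample_config")
}

# Translate a scenario + draw into the numeric event matrix the C++
# simulator consumes: columns (time, type, a, b, value), sorted by drawn
# time with ties kept in listed order.
event_matrix <- function(spec, draw, config) {
  draw <- as.list(draw)
  pops <- spec$populations
  ev <- spec$events
  n_ev <- nrow(ev)
  mat <- matrix(0, nrow = n_ev, ncol = 5)
  for (i in seq_len(n_ev)) {
    mat[i, 1] <- draw[[ev$time[i]]]
    mat[i, 2] <- match(ev$kind[i], c("merge", "admix", "resize"))
    mat[i, 3] <- match(ev$pop[i], pops)
    mat[i, 4] <- if (is.na(ev$pop2[i])) 0 else match(ev$pop2[i], pops)
    mat[i, 5] <- if (is.na(ev$param[i])) 0 else draw[[ev$param[i]]]
  }
  mat[order(mat[, 1]), , drop = FALSE]
}

sizes_for <- function(spec, draw, config) {
  draw <- as.list(draw)
  sizes <- vapply(spec$populations,
                  function(p) draw[[spec$initial_sizes[[p]]]], numeric(1))
  samples <- integer(length(spec$populations))
  names(samples) <- spec$populations
  known <- intersect(names(config$sample_sizes), spec$populations)
  if (length(known) == 0) abort("no sampled population matches the scenario")
  samples[known] <- config$sample_sizes[known]
  list(samples = samples, sizes = sizes)
}

#' Simulate a gene genealogy under a demographic scenario
#'
#' Structured-coalescent realization: within each population of haploid size
#' N every lineage pair coalesces at rate 1/N per generation; merge events
#' move all lineages of the source into the destination, admixture pulses
#' reassign each target lineage to the donor independently with the drawn
#' rate, resize events change sizes stepwise. Continuous-time approximation
#' (no discrete generations); exact exponential waiting times between
#' demographic events.
#'
#' @param spec A `scenario_spec`.
#' @param draw A parameter draw valid for `spec` (see [sample_prior_draws()]).
#' @param config A [sample_config()].
#' @param validate Check the draw against the scenario first (default TRUE).
#' @return A `genealogy`: list with `n_tips`, `parent` (1-based, 0 at the
#'   root), `node_time` (generations before present), `tip_pop` (factor).
#' @examples
#' spec <- build_scenario("Sc1")
#' set.seed(7)
#' d <- sample_prior_draws(spec, 1)
#' g <- simulate_genealogy(spec, d, sample_config(c(SAG = 5, NAG = 3, NC = 2)))
#' genealogy_stats(g)
#' @export
simulate_genealogy <- function(spec, draw, config = sample_config(),
                               validate = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(config, "sample_config"))
  if (validate) {
    viol <- validate_draw(spec, draw)
    if (length(viol))
      abort(paste0("draw is invalid for scenario ", spec$id, ": ",
                   paste(viol, collapse = "; ")))
  }
  sv <- sizes_for(spec, draw, config)
  res <- sim_genealogy_cpp(as.integer(sv$samples), sv$sizes,
                           event_matrix(spec, draw, config))
  structure(list(n_tips = res$n_tips,
                 parent = res$parent,
                 node_time = res$node_time,
                 tip_pop = factor(spec$populations[res$tip_pop],
                                  levels = spec$populations)),
            class = "genealogy")
}

#' Height and length of a genealogy
#'
#' @param g A `genealogy`.
#' @return One-row tibble with `tmrca` (root time, generations) and
#'   `total_branch_length` (sum of branch durations, generations); both 0
#'   for a single-leaf genealogy.
#' @export
genealogy_stats <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  if (g$n_tips == 1)
    return(tibble(tmrca = 0, total_branch_length = 0))
  notroot <- g$parent != 0
  tibble(tmrca = max(g$node_time),
         total_branch_length = sum(g$node_time[g$parent[notroot]] -
                                     g$node_time[notroot]))
}

#' @export
print.genealogy <- function(x, ...) {
  st <- genealogy_stats(x)
  cat("<genealogy> ", x$n_tips, " tips (",
      paste(levels(x$tip_pop), table(x$tip_pop), sep = ":", collapse = ", "),
      "), TMRCA = ", signif(st$tmrca, 4), " generations\n", sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape phylo tree
#'
#' Branch lengths are in generations. Use [ape::write.tree()] for Newick
#' export.
#'
#' @param x A `genealogy`.
#' @param ... Ignored.
#' @return An [ape::as.phylo] object with tip labels `<pop>_<index>`.
#' @export
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tips
  if (n < 2) abort("a phylo tree needs at least two tips")
  n_nodes <- 2L * n - 1L
  internal <- (n + 1L):n_nodes
  # ape wants the root numbered n+1; renumber internals by decreasing age
  ord <- internal[order(x$node_time[internal], decreasing = TRUE)]
  newid <- integer(n_nodes)
  newid[seq_len(n)] <- seq_len(n)
  newid[ord] <- (n + 1L):n_nodes
  child <- which(x$parent != 0)
  edge <- cbind(newid[x$parent[child]], newid[child])
  len <- x$node_time[x$parent[child]] - x$node_time[child]
  tip_lab <- paste0(as.character(x$tip_pop),
                    "_", stats::ave(seq_len(n), x$tip_pop, FUN = seq_along))
  tr <- list(edge = edge, edge.length = len, tip.label = tip_lab,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo
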