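# Fast path for reference-table simulation: genealogy + mutations +
# 12-statistic summary without materializing character sequences. Invariant
# columns contribute nothing to any statistic, so only variable sites are
# carried.
sim_summary_once <- function(spec, draw, config) {
  sv <- sizes_for(spec, draw, config)
  g <- sim_genealogy_cpp(as.integer(sv$samples), sv$sizes,
                         event_matrix(spec, draw, config))
  rates <- draw_site_rates(config$locus_length, config$settings)
  res <- evolve_cpp(g$parent, g$node_time, g$n_tips, rates,
                    as.list(draw)[[spec$mutation_param]],
                    config$settings$kappa, config$settings$base_freqs)
  sumstats_cpp(res$tip_var, g$tip_pop, length(spec$populations))
}

#' Build an ABC reference table by prior simulation
#'
#' For every scenario, repeats draw-from-prior, coalescent simulation,
#' sequence evolution and summary-statistic computation `n_per_scenario`
#' times. The result is the bank of (scenario, parameters, statistics)
#' records that rejection, model choice and estimation operate on.
#'
#' @param specs A `scenario_spec` or list of them (e.g.
#'   `lapply(paste0("Sc", 1:8), build_scenario)`).
#' @param n_per_scenario Simulations per scenario.
#' @param config A [sample_config()].
#' @param seed Optional integer seed (sets the RNG before simulating, making
#'   the table reproducible).
#' @param progress Print a line per scenario.
#' @return A tibble of class `ref_tbl`: column `scenario`, one column per
#'   parameter (NA where a scenario does not use it) and the 12 statistic
#'   columns; attributes record the statistic columns, populations, seed and
#'   counts. Tables built with compatible configurations can be concatenated
#'   with [bind_reference_tables()] (checkpoint/append).
#' @export
build_reference_table <- function(specs, n_per_scenario,
                                  config = sample_config(), seed = NULL,
                                  progress = FALSE) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  stopifnot(n_per_scenario >= 1)
  if (!is.null(seed)) set.seed(seed)
  pops <- specs[[1]]$populations
  stat_names <- summary_stat_names(pops)
  blocks <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    if (!identical(spec$populations, pops))
      abort("all scenarios in one table must share the same populations")
    draws <- sample_prior_draws(spec, n_per_scenario)
    stats <- matrix(NA_real_, n_per_scenario, length(stat_names),
                    dimnames = list(NULL, stat_names))
    for (i in seq_len(n_per_scenario)) {
      stats[i, ] <- tryCatch(
        sim_summary_once(spec, draws[i, ], config),
        error = function(e) abort(paste0(
          "simulation failed for scenario ", spec$id, ", record ", i, ": ",
          conditionMessage(e))))
    }
    blocks[[k]] <- dplyr::bind_cols(tibble(scenario = spec$id), draws,
                                    as_tibble(stats))
    if (progress)
      message("scenario ", spec$id, ": ", n_per_scenario, " records")
  }
  tbl <- dplyr::bind_rows(blocks)
  new_ref_tbl(tbl, stat_names, pops, seed,
              setNames(rep(n_per_scenario, length(specs)),
                       vapply(specs, function(s) s$id, character(1))))
}

new_ref_tbl <- function(tbl, stat_names, populations, seed, counts) {
  structure(tbl,
            stat_cols = stat_names,
            populations = populations,
            seed = seed,
            counts = counts,
            class = c("ref_tbl", class(tibble())))
}

#' @export
#' @rdname build_reference_table
#' @param ... `ref_tbl` objects with identical columns.
bind_reference_tables <- function(...) {
  tbls <- list(...)
  stopifnot(length(tbls) >= 1)
  sc <- attr(tbls[[1]], "stat_cols")
  for (t in tbls) {
    if (!inherits(t, "ref_tbl")) abort("all inputs must be reference tables")
    if (!identical(attr(t, "stat_cols"), sc))
      abort("reference tables have different statistic columns")
  }
  out <- dplyr::bind_rows(lapply(tbls, as_tibble))
  all_counts <- lapply(tbls, attr, "counts")
  ids <- unique(unlist(lapply(all_counts, names)))
  counts <- setNames(vapply(ids, function(id)
    sum(vapply(all_counts, function(cc)
      if (id %in% names(cc)) cc[[id]] else 0, numeric(1))), numeric(1)), ids)
  new_ref_tbl(out, sc, attr(tbls[[1]], "populations"), NULL, counts)
}

ref_stat_matrix <- function(table) {
  sc <- attr(table, "stat_cols") %||% abort("not a reference table")
  as.matrix(as_tibble(table)[, sc, drop = FALSE])
}

ref_param_cols <- function(table) {
  setdiff(names(table), c("scenario", attr(table, "stat_cols"), ".dist"))
}

#' Write or read a reference table as CSV with a manifest header
#'
#' The manifest is a block of `#`-prefixed key:value lines (schema version,
#' seed, per-scenario counts, populations, statistic columns) ahead of a
#' plain CSV body, so tables stay both machine- and human-readable.
#'
#' @param table A `ref_tbl`.
#' @param path File path.
#' @return `read_reference_table()` returns the `ref_tbl`;
#'   `write_reference_table()` returns `path` invisibly.
#' @export
write_reference_table <- function(table, path) {
  stopifnot(inherits(table, "ref_tbl"))
  counts <- attr(table, "counts")
  hdr <- c("# coalabc_ref_tbl_schema: 1",
           paste0("# seed: ", attr(table, "seed") %||% "NA"),
           paste0("# populations: ",
                  paste(attr(table, "populations"), collapse = ",")),
           paste0("# stat_cols: ",
                  paste(attr(table, "stat_cols"), collapse = ",")),
           paste0("# counts: ",
                  paste(names(counts), unname(counts), sep = "=",
                        collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as_tibble(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- sub("^# *", "", lines[hdr])
  kv <- strsplit(meta, ": *")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  if (!"coalabc_ref_tbl_schema" %in% keys)
    abort("not a coalabc reference table (missing schema line)")
  body <- read.csv(textConnection(lines[-hdr]), stringsAsFactors = FALSE)
  counts_str <- strsplit(vals[keys == "counts"], ",")[[1]]
  counts_kv <- strsplit(counts_str, "=")
  counts <- setNames(as.numeric(vapply(counts_kv, `[`, character(1), 2)),
                     vapply(counts_kv, `[`, character(1), 1))
  seed <- vals[keys == "seed"]
  new_ref_tbl(as_tibble(body),
              strsplit(vals[keys == "stat_cols"], ",")[[1]],
              strsplit(vals[keys == "populations"], ",")[[1]],
              if (seed == "NA") NULL else as.integer(seed),
              counts)
}

#' @export
print.ref_tbl <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<ref_tbl> ", nrow(x), " records (",
      paste(names(counts), unname(counts), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  NextMethod()
}
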