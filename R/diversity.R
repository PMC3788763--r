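# AMOVA variance components from a pairwise-difference matrix and group
# labels (pairwise differences enter as squared distances, the convention
# for nucleotide data).
phi_st_from_dist <- function(d, labels) {
  groups <- unique(labels)
  n <- length(labels)
  g <- length(groups)
  ssd_total <- sum(d[lower.tri(d)]) / n
  ssd_within <- 0
  for (grp in groups) {
    idx <- which(labels == grp)
    if (length(idx) > 1)
      ssd_within <- ssd_within + sum(d[idx, idx][lower.tri(d[idx, idx])]) /
        length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  ng <- as.numeric(table(factor(labels, levels = groups)))
  s2w <- ssd_within / (n - g)
  n0 <- (n - sum(ng^2) / n) / (g - 1)
  s2a <- (ssd_among / (g - 1) - s2w) / n0
  if (s2a + s2w <= 0) return(0)
  s2a / (s2a + s2w)
}

hamming_dist_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  d
}

#' AMOVA-style pairwise Phi_ST with a permutation test
#'
#' Phi_ST is the among-group proportion of molecular variance computed from
#' the pairwise-difference matrix of two populations. The p-value is the
#' proportion of random label permutations with a statistic at least as
#' large as the observed one (with add-one correction), or the exact
#' proportion over all distinct label assignments when `exact = TRUE`.
#'
#' @param aln An alignment tibble.
#' @param pop_a,pop_b Population labels (>= 2 sequences each).
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param exact Enumerate all `choose(n, n_a)` label assignments instead of
#'   sampling; feasible for small samples only.
#' @return One-row tibble with `phi_st`, `p_value`, `n_perm`.
#' @export
phi_st_permutation <- function(aln, pop_a, pop_b, n_perm = 999,
                               exact = FALSE) {
  ma <- pop_submatrix(aln, pop_a, min_n = 2)
  mb <- pop_submatrix(aln, pop_b, min_n = 2)
  mat <- rbind(ma, mb)
  labels <- rep(c("a", "b"), c(nrow(ma), nrow(mb)))
  d <- hamming_dist_matrix(mat)
  obs <- phi_st_from_dist(d, labels)
  eps <- 1e-12
  if (exact) {
    n <- length(labels)
    picks <- combn(n, nrow(ma))
    stats <- apply(picks, 2L, function(idx) {
      lab <- rep("b", n); lab[idx] <- "a"
      phi_st_from_dist(d, lab)
    })
    p <- mean(stats >= obs - eps)
    n_used <- ncol(picks)
  } else {
    if (n_perm < 1) abort("`n_perm` must be at least 1")
    stats <- vapply(seq_len(n_perm), function(i)
      phi_st_from_dist(d, sample(labels)), numeric(1))
    p <- (1 + sum(stats >= obs - eps)) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble(phi_st = obs, p_value = p, n_perm = n_used)
}

# Nei (1987) sampling variances used by the descriptive report.
haplotype_diversity_sd <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  s2 <- sum(p^2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  sqrt(max(v, 0))
}

nucleotide_diversity_sd <- function(pi, n, L) {
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  sqrt(max(v, 0))
}

#' Descriptive diversity report
#'
#' Per-population sample size, haplotype count, haplotype diversity and
#' per-site nucleotide diversity with their standard deviations (Nei's
#' estimators), plus the pairwise Phi_ST matrix with permutation p-values.
#' Any set of population labels is supported, so regional groupings beyond
#' the three ABC populations can be summarized with the same population
#' map.
#'
#' @param aln An alignment tibble.
#' @param populations Populations to report (default: all, in order of
#'   appearance).
#' @param n_perm Permutations for the Phi_ST tests.
#' @return A list of class `diversity_report` with tibbles `diversity` and
#'   `phi_st`.
#' @export
diversity_report <- function(aln, populations = NULL, n_perm = 999) {
  aln <- haplotype_alignment(aln)
  populations <- populations %||% unique(aln$pop)
  L <- locus_length(aln)
  div <- dplyr::bind_rows(lapply(populations, function(p) {
    counts <- as.numeric(table(aln$seq[aln$pop == p]))
    n <- sum(counts)
    pi <- nucleotide_diversity(aln, p)
    tibble(pop = p, n = n, n_hap = n_haplotypes(aln, p),
           hap_div = haplotype_diversity(aln, p),
           hap_div_sd = haplotype_diversity_sd(counts),
           nuc_div = pi,
           nuc_div_sd = nucleotide_diversity_sd(pi, n, L))
  }))
  pairs <- combn(populations, 2)
  phi <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    res <- phi_st_permutation(aln, pairs[1, k], pairs[2, k], n_perm = n_perm)
    tibble(pop_a = pairs[1, k], pop_b = pairs[2, k],
           phi_st = res$phi_st, p_value = res$p_value)
  }))
  structure(list(diversity = div, phi_st = phi), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Genetic diversity by population:\n")
  print(x$diversity)
  cat("\nPairwise Phi_ST (permutation p-values):\n")
  print(x$phi_st)
  invisible(x)
}
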