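pop_submatrix <- function(aln, pop, min_n = 1) {
  if (!pop %in% aln$pop)
    abort(paste0("population '", pop, "' not present in the alignment"))
  rows <- aln$pop == pop
  if (sum(rows) < min_n)
    abort(paste0("population '", pop, "' needs at least ", min_n,
                 " sequences"))
  seq_to_matrix(aln$seq[rows])
}

#' Per-population summary statistics
#'
#' Building blocks of the 12-statistic ABC summary and of the descriptive
#' diversity report:
#'
#' * `n_haplotypes()`: distinct full-length sequences (exact string
#'   identity; simulated data contain no gaps or ambiguity codes).
#' * `segregating_sites()`: alignment columns with two or more states.
#' * `mean_pairwise_diff()`: average Hamming distance over unordered pairs.
#' * `haplotype_diversity()`: \eqn{\hat H = n(1 - \sum p_i^2)/(n-1)}.
#' * `nucleotide_diversity()`: mean pairwise differences per site.
#'
#' @param aln An alignment tibble (columns `id`, `pop`, `seq`).
#' @param pop Population label.
#' @return A single number.
#' @examples
#' aln <- haplotype_alignment(tibble::tibble(
#'   id = c("a", "b", "c"), pop = "SAG", seq = c("AAT", "ACT", "GCT")))
#' segregating_sites(aln, "SAG")   # 2
#' mean_pairwise_diff(aln, "SAG")  # 4/3
#' @export
n_haplotypes <- function(aln, pop) {
  if (!pop %in% aln$pop)
    abort(paste0("population '", pop, "' not present in the alignment"))
  dplyr::n_distinct(aln$seq[aln$pop == pop])
}

#' @rdname n_haplotypes
#' @export
segregating_sites <- function(aln, pop) {
  mat <- pop_submatrix(aln, pop)
  sum(matrixStats_col_distinct(mat) >= 2L)
}

matrixStats_col_distinct <- function(mat) {
  apply(mat, 2L, function(col) length(unique(col)))
}

# per-column allele counts (states are 0-based, hence the +1 for tabulate)
allele_counts <- function(mat) {
  counts <- apply(mat, 2L, function(col) tabulate(col + 1L, nbins = 4L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 4L)
  counts
}

# within-population sum of pairwise differences via per-column allele counts
pairwise_diff_sum <- function(mat) {
  n <- nrow(mat)
  sum((n^2 - colSums(allele_counts(mat)^2)) / 2)
}

#' @rdname n_haplotypes
#' @export
mean_pairwise_diff <- function(aln, pop) {
  mat <- pop_submatrix(aln, pop, min_n = 2)
  n <- nrow(mat)
  pairwise_diff_sum(mat) / (n * (n - 1) / 2)
}

#' @rdname n_haplotypes
#' @export
haplotype_diversity <- function(aln, pop) {
  if (!pop %in% aln$pop)
    abort(paste0("population '", pop, "' not present in the alignment"))
  counts <- table(aln$seq[aln$pop == pop])
  n <- sum(counts)
  if (n < 2) abort("haplotype diversity needs at least two sequences")
  p <- as.numeric(counts) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' @rdname n_haplotypes
#' @export
nucleotide_diversity <- function(aln, pop) {
  mean_pairwise_diff(aln, pop) / locus_length(aln)
}

#' Hudson-style pairwise F_ST
#'
#' \eqn{F_{ST} = 1 - H_w/H_b}, where Hw is the unweighted mean of the two
#' within-population mean pairwise differences and Hb the mean pairwise
#' difference between populations. Returns 0 when Hb = 0. Negative
#' estimates are reported as computed; clamp for display only.
#'
#' @param aln An alignment tibble.
#' @param pop_a,pop_b Population labels (each with at least two sequences).
#' @return The F_ST estimate (symmetric in its arguments).
#' @export
pairwise_fst <- function(aln, pop_a, pop_b) {
  ma <- pop_submatrix(aln, pop_a, min_n = 2)
  mb <- pop_submatrix(aln, pop_b, min_n = 2)
  na <- nrow(ma); nb <- nrow(mb)
  ca <- allele_counts(ma)
  cb <- allele_counts(mb)
  hb <- sum(na * nb - colSums(ca * cb)) / (na * nb)
  if (hb == 0) return(0)
  hw <- 0.5 * (pairwise_diff_sum(ma) / (na * (na - 1) / 2) +
               pairwise_diff_sum(mb) / (nb * (nb - 1) / 2))
  1 - hw / hb
}

#' The fixed-order 12-statistic ABC summary vector
#'
#' Per population (in `populations` order): number of haplotypes, number of
#' segregating sites, mean pairwise differences; then Hudson F_ST for every
#' unordered population pair in order (1,2), (1,3), (2,3). With the default
#' three populations this is exactly 12 statistics.
#'
#' @param aln An alignment tibble containing every listed population with at
#'   least two sequences each.
#' @param populations Population labels fixing the statistic order.
#' @return A one-row tibble with named statistic columns (e.g. `nhap_SAG`,
#'   `segs_NAG`, `mpd_NC`, `fst_SAG_NAG`).
#' @export
summary_vector <- function(aln, populations = c("SAG", "NAG", "NC")) {
  aln <- haplotype_alignment(aln)
  missing <- setdiff(populations, unique(aln$pop))
  if (length(missing))
    abort(paste0("alignment is missing population(s): ",
                 paste(missing, collapse = ", ")))
  pop_idx <- match(aln$pop, populations)
  keep <- !is.na(pop_idx)
  mat <- seq_to_matrix(aln$seq[keep])
  stats <- sumstats_cpp(mat, as.integer(pop_idx[keep]), length(populations))
  as_tibble(as.list(setNames(stats, summary_stat_names(populations))))
}

summary_stat_names <- function(populations = c("SAG", "NAG", "NC")) {
  pairs <- combn(populations, 2)
  c(paste0("nhap_", populations),
    paste0("segs_", populations),
    paste0("mpd_", populations),
    paste0("fst_", pairs[1, ], "_", pairs[2, ]))
}
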