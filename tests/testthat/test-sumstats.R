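aln_of <- function(seqs, pops = rep("SAG", length(seqs))) {
  haplotype_alignment(tibble::tibble(
    id = paste0("i", seq_along(seqs)), pop = pops, seq = seqs))
}

test_that("per-population statistics match hand-enumerated cases", {
  a <- aln_of(c("AAT", "AAT", "ACT", "ACC"))
  expect_equal(n_haplotypes(a, "SAG"), 3)
  b <- aln_of(c("AAT", "ACT", "GCT"))
  expect_equal(segregating_sites(b, "SAG"), 2)
  expect_equal(mean_pairwise_diff(b, "SAG"), 4 / 3)
  expect_equal(nucleotide_diversity(b, "SAG"), 4 / 9)
  mono <- aln_of(c("AAA", "AAA", "AAA"))
  expect_equal(n_haplotypes(mono, "SAG"), 1)
  expect_equal(segregating_sites(mono, "SAG"), 0)
  expect_equal(mean_pairwise_diff(mono, "SAG"), 0)
  # haplotype frequencies (2,1,1), n = 4
  expect_equal(haplotype_diversity(a, "SAG"), 4 / 3 * (1 - 6 / 16))
  all_distinct <- aln_of(c("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(haplotype_diversity(all_distinct, "SAG"), 1)
  expect_equal(haplotype_diversity(mono, "SAG"), 0)
})

test_that("Hudson F_ST matches hand enumeration and is symmetric", {
  ab <- aln_of(c("AA", "AT", "TT", "TT"), c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(ab, "A", "B"), 2 / 3)   # Hw = 0.5, Hb = 1.5
  expect_equal(pairwise_fst(ab, "B", "A"), 2 / 3)
  fixed <- aln_of(c("AA", "AA", "TT", "TT"), c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(fixed, "A", "B"), 1)
  # two big samples from one pool: estimate near 0 (slightly negative by the
  # n/(n-1) within-population correction)
  same <- aln_of(rep(c("AA", "AT"), each = 50),
                 rep(c("A", "B"), times = 50))
  expect_lt(abs(pairwise_fst(same, "A", "B")), 0.025)
  mono2 <- aln_of(c("AA", "AA", "AA", "AA"), c("A", "A", "B", "B"))
  expect_equal(pairwise_fst(mono2, "A", "B"), 0)    # Hb = 0 convention
})

test_that("the summary vector has the documented order and degenerate form", {
  pops <- c(rep("SAG", 3), rep("NAG", 2), rep("NC", 2))
  mono <- aln_of(rep("ACGT", 7), pops)
  sv <- summary_vector(mono)
  expect_named(sv, c("nhap_SAG", "nhap_NAG", "nhap_NC",
                     "segs_SAG", "segs_NAG", "segs_NC",
                     "mpd_SAG", "mpd_NAG", "mpd_NC",
                     "fst_SAG_NAG", "fst_SAG_NC", "fst_NAG_NC"))
  expect_equal(unlist(sv), c(nhap_SAG = 1, nhap_NAG = 1, nhap_NC = 1,
                             segs_SAG = 0, segs_NAG = 0, segs_NC = 0,
                             mpd_SAG = 0, mpd_NAG = 0, mpd_NC = 0,
                             fst_SAG_NAG = 0, fst_SAG_NC = 0, fst_NAG_NC = 0))
  expect_error(summary_vector(aln_of(c("AA", "AA"), c("SAG", "SAG"))),
               "missing population")
})

test_that("statistics are invariant to row order", {
  set.seed(51)
  a <- random_alignment(c(SAG = 4, NAG = 3, NC = 3), L = 15)
  sv1 <- summary_vector(a)
  sv2 <- summary_vector(a[sample(nrow(a)), ])
  expect_equal(sv1, sv2)
})

test_that("every statistic matches the brute-force oracle on random data", {
  set.seed(52)
  for (case in 1:200) {
    sizes <- c(SAG = sample(2:4, 1), NAG = sample(2:4, 1),
               NC = sample(2:4, 1))
    a <- random_alignment(sizes, L = sample(3:25, 1),
                          n_states = sample(2:4, 1))
    sv <- summary_vector(a)
    expect_equal(sv$nhap_NAG, oracle_n_haplotypes(a, "NAG"))
    expect_equal(sv$segs_SAG, oracle_segregating_sites(a, "SAG"))
    expect_equal(sv$mpd_NC, oracle_mean_pairwise_diff(a, "NC"))
    expect_equal(sv$fst_SAG_NAG, oracle_fst(a, "SAG", "NAG"))
    expect_equal(sv$fst_NAG_NC, oracle_fst(a, "NAG", "NC"))
    expect_equal(haplotype_diversity(a, "SAG"),
                 oracle_hap_diversity(a, "SAG"))
    expect_equal(mean_pairwise_diff(a, "SAG"),
                 oracle_mean_pairwise_diff(a, "SAG"))
  }
})

test_that("preconditions are enforced", {
  a <- aln_of(c("AAT", "ACT"), c("SAG", "SAG"))
  expect_error(n_haplotypes(a, "NC"), "not present")
  expect_error(mean_pairwise_diff(aln_of("AAT"), "SAG"), "at least 2")
  expect_error(haplotype_alignment(tibble::tibble(
    id = c("a", "b"), pop = "X", seq = c("AC", "ACG"))), "same aligned length")
  expect_error(haplotype_alignment(tibble::tibble(
    id = c("a", "b"), pop = "X", seq = c("AC", "AN"))), "only A, C, G, T")
})
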