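# Independent brute-force oracles. These deliberately use naive loops and
# their own arithmetic so they share no code path with the package.

random_alignment <- function(n_per_pop = c(SAG = 3, NAG = 3, NC = 2),
                             L = 20, n_states = 4) {
  pops <- rep(names(n_per_pop), n_per_pop)
  seqs <- vapply(seq_along(pops), function(i)
    paste(sample(c("A", "C", "G", "T")[seq_len(n_states)], L, replace = TRUE),
          collapse = ""), character(1))
  tibble::tibble(id = paste0("ind", seq_along(pops)), pop = pops, seq = seqs)
}

split_chars <- function(s) strsplit(s, "")[[1]]

oracle_n_haplotypes <- function(aln, pop) {
  length(unique(aln$seq[aln$pop == pop]))
}

oracle_segregating_sites <- function(aln, pop) {
  seqs <- lapply(aln$seq[aln$pop == pop], split_chars)
  L <- length(seqs[[1]])
  count <- 0
  for (s in seq_len(L)) {
    col <- vapply(seqs, `[`, character(1), s)
    if (length(unique(col)) > 1) count <- count + 1
  }
  count
}

oracle_mean_pairwise_diff <- function(aln, pop) {
  seqs <- lapply(aln$seq[aln$pop == pop], split_chars)
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(seqs[[i]] != seqs[[j]])
  tot / (n * (n - 1) / 2)
}

oracle_cross_diff <- function(aln, pop_a, pop_b) {
  sa <- lapply(aln$seq[aln$pop == pop_a], split_chars)
  sb <- lapply(aln$seq[aln$pop == pop_b], split_chars)
  tot <- 0
  for (i in seq_along(sa))
    for (j in seq_along(sb))
      tot <- tot + sum(sa[[i]] != sb[[j]])
  tot / (length(sa) * length(sb))
}

oracle_fst <- function(aln, pop_a, pop_b) {
  hb <- oracle_cross_diff(aln, pop_a, pop_b)
  if (hb == 0) return(0)
  hw <- (oracle_mean_pairwise_diff(aln, pop_a) +
           oracle_mean_pairwise_diff(aln, pop_b)) / 2
  1 - hw / hb
}

oracle_hap_diversity <- function(aln, pop) {
  seqs <- aln$seq[aln$pop == pop]
  n <- length(seqs)
  p <- as.numeric(table(seqs)) / n
  n / (n - 1) * (1 - sum(p^2))
}

# two-group Phi_ST from first principles (explicit sums of squared
# deviations on the pairwise-difference matrix)
oracle_phi_st <- function(aln_mat, labels) {
  n <- nrow(aln_mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sum(aln_mat[i, ] != aln_mat[j, ])
  groups <- unique(labels)
  ssd_t <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) ssd_t <- ssd_t + d[i, j]
  ssd_t <- ssd_t / (2 * n)
  ssd_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + d[i, j]
    ssd_w <- ssd_w + acc / (2 * length(idx))
  }
  ng <- as.numeric(table(factor(labels, levels = groups)))
  k <- length(groups)
  s2w <- ssd_w / (n - k)
  msa <- (ssd_t - ssd_w) / (k - 1)
  n0 <- (n - sum(ng^2) / n) / (k - 1)
  s2a <- (msa - s2w) / n0
  if (s2a + s2w <= 0) return(0)
  s2a / (s2a + s2w)
}

# brute-force draw from the constrained Sc1 prior: sample the unconstrained
# joint and filter (independent of the package's sampler)
oracle_sc1_prior <- function(n) {
  got <- list()
  total <- 0
  while (total < n) {
    m <- 5000
    d <- data.frame(
      N_SAG = runif(m, 1e5, 3.6e6), N_NAG = runif(m, 1.5e5, 8e5),
      N_NC = runif(m, 4e4, 1.5e5), N1 = runif(m, 100, 2e5),
      N2 = runif(m, 100, 2e5), N3 = runif(m, 100, 2e5),
      N4 = runif(m, 100, 2e5), N_anc = runif(m, 1000, 60000),
      t_exp = runif(m, 6e4, 4.5e5), t_2 = runif(m, 5e4, 3.5e5),
      t_3 = runif(m, 1e5, 1e6), mu = runif(m, 1e-11, 1e-7))
    keep <- with(d, t_exp <= t_2 & t_2 < t_3 &
                   N_anc < N_NC & N_NC <= N_NAG & N_NAG <= N_SAG &
                   N1 > N_anc & N2 > N_anc & N3 > N_anc & N4 > N_anc)
    got[[length(got) + 1]] <- d[keep, ]
    total <- total + sum(keep)
  }
  out <- do.call(rbind, got)
  out[seq_len(n), ]
}

# a Sc1 parameter set with a strong shared-expansion signature, used as
# ground truth in recovery experiments
sc1_separated_params <- function() {
  tibble::tibble(N_SAG = 2e6, N_NAG = 5e5, N_NC = 1e5,
                 N1 = 5000, N2 = 4000, N3 = 3000, N4 = 5000, N_anc = 1500,
                 t_exp = 7e4, t_2 = 2.5e5, t_3 = 7e5, mu = 2e-8)
}

# small-scale sampling design used by fast tests
tiny_config <- function(L = 300)
  coalabc::sample_config(c(SAG = 10, NAG = 6, NC = 4), locus_length = L)

# single-population constant-size scenario with point-mass parameters
panmictic_spec <- function(N, mu = 1e-8) {
  coalabc::scenario_spec(
    "panmictic", "A", c(A = "N_A"),
    tibble::tibble(time = character(0), kind = character(0),
                   pop = character(0), pop2 = character(0),
                   param = character(0)),
    priors = tibble::tibble(param = c("N_A", "mu"), low = c(N, mu),
                            high = c(N, mu), log_scale = FALSE),
    constraints = tibble::tibble(lhs = character(0), op = character(0),
                                 rhs = character(0)))
}

point_draw <- function(spec) coalabc::sample_prior_draws(spec, 1)

# two populations, admixture pulse A <- B at t_adm with rate r, merge at
# t_merge; point-mass priors
admix_spec <- function(NA_ = 1e12, NB = 1, r = 0.3, t_adm = 1,
                       t_merge = 1e6, mu = 0) {
  coalabc::scenario_spec(
    "admixtest", c("A", "B"), c(A = "N_A", B = "N_B"),
    tibble::tibble(
      time = c("t_adm", "t_merge"),
      kind = c("admix", "merge"),
      pop = c("A", "A"),
      pop2 = c("B", "B"),
      param = c("r", NA)),
    priors = tibble::tibble(
      param = c("N_A", "N_B", "r", "t_adm", "t_merge", "mu"),
      low = c(NA_, NB, r, t_adm, t_merge, mu),
      high = c(NA_, NB, r, t_adm, t_merge, mu), log_scale = FALSE),
    constraints = tibble::tibble(lhs = character(0), op = character(0),
                                 rhs = character(0)))
}

# hand-built two-tip genealogy coalescing at time t
two_tip_genealogy <- function(t, pop = "A") {
  structure(list(n_tips = 2L, parent = c(3L, 3L, 0L),
                 node_time = c(0, 0, t),
                 tip_pop = factor(c(pop, pop))),
            class = "genealogy")
}
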