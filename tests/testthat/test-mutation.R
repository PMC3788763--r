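test_that("site rates honour the invariant proportion and mean-1 scaling", {
  set.seed(41)
  r_all_inv <- draw_site_rates(50, substitution_settings(p_invariant = 1))
  expect_equal(r_all_inv, rep(0, 50))
  r_const <- draw_site_rates(50, substitution_settings(p_invariant = 0,
                                                       gamma_shape = Inf))
  expect_equal(r_const, rep(1, 50))
  r <- draw_site_rates(10000, substitution_settings())
  frac0 <- mean(r == 0)
  expect_lt(abs(frac0 - 0.92), 4 * sqrt(0.92 * 0.08 / 10000))
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_error(draw_site_rates(0), "at least 1")
})

test_that("zero mutation rate yields identical sequences", {
  spec <- build_scenario("Sc1")
  set.seed(42)
  d <- sample_prior_draws(spec, 1)
  g <- simulate_genealogy(spec, d, tiny_config())
  aln <- evolve_alignment(g, mu = 0, locus_length = 100)
  expect_equal(length(unique(aln$seq)), 1)
  expect_equal(nchar(aln$seq[1]), 100)
})

test_that("pairwise differences follow the Poisson expectation", {
  # two tips at distance 2t; with mean-1 rates E[diffs] ~ 2t * mu * L
  t <- 50; mu <- 1e-4; L <- 500
  st <- substitution_settings(p_invariant = 0, gamma_shape = Inf)
  set.seed(43)
  diffs <- replicate(400, {
    aln <- evolve_alignment(two_tip_genealogy(t), mu, st, locus_length = L)
    sum(split_chars(aln$seq[1]) != split_chars(aln$seq[2]))
  })
  lambda <- 2 * t * mu * L
  expect_lt(abs(mean(diffs) - lambda), 4 * sqrt(lambda / length(diffs)))
})

test_that("the +I+G machinery leaves the realized mean rate at mu", {
  # 92% invariant sites, gamma rates: rescaling keeps E[diffs] = 2 t mu L
  # (mu small enough that multiple hits on fast sites are negligible)
  t <- 50; mu <- 2e-5; L <- 600
  st <- substitution_settings()   # 0.92 invariant, shape 2
  set.seed(44)
  diffs <- replicate(800, {
    rates <- draw_site_rates(L, st)
    aln <- evolve_alignment(two_tip_genealogy(t), mu, st, site_rates = rates)
    sum(split_chars(aln$seq[1]) != split_chars(aln$seq[2]))
  })
  lambda <- 2 * t * mu * L
  expect_lt(abs(mean(diffs) - lambda), 5 * sqrt(lambda / length(diffs)))
})

test_that("kappa = 1 with equal frequencies reproduces Jukes-Cantor", {
  # JC with total leave rate 1: P(tips differ) = 3/4 (1 - exp(-4/3 * d))
  t <- 0.15; mu <- 1; L <- 4000
  st <- substitution_settings(p_invariant = 0, gamma_shape = Inf, kappa = 1)
  set.seed(45)
  aln <- evolve_alignment(two_tip_genealogy(t), mu, st, locus_length = L)
  p_hat <- mean(split_chars(aln$seq[1]) != split_chars(aln$seq[2]))
  p_jc <- 0.75 * (1 - exp(-4 / 3 * 2 * t))
  expect_lt(abs(p_hat - p_jc), 4 * sqrt(p_jc * (1 - p_jc) / L))
})

test_that("transition bias follows kappa", {
  t <- 0.05; mu <- 1; L <- 6000
  st <- substitution_settings(p_invariant = 0, gamma_shape = Inf, kappa = 8)
  set.seed(46)
  aln <- evolve_alignment(two_tip_genealogy(t), mu, st, locus_length = L)
  a <- split_chars(aln$seq[1]); b <- split_chars(aln$seq[2])
  diff <- which(a != b)
  is_transition <- (a[diff] %in% c("A", "G") & b[diff] %in% c("A", "G")) |
    (a[diff] %in% c("C", "T") & b[diff] %in% c("C", "T"))
  # single-hit expectation: kappa / (kappa + 2)
  p_ts <- 8 / 10
  expect_lt(abs(mean(is_transition) - p_ts),
            4 * sqrt(p_ts * (1 - p_ts) / length(diff)) + 0.02)
})

test_that("unequal base frequencies reach their stationary composition", {
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  st <- substitution_settings(p_invariant = 0, gamma_shape = Inf,
                              base_freqs = freqs)
  set.seed(47)
  aln <- evolve_alignment(two_tip_genealogy(500), mu = 0.05, st,
                          locus_length = 4000)
  obs <- empirical_base_freqs(aln)
  expect_lt(max(abs(obs - freqs)), 0.03)
  # realized mean rate stays near mu on the general (Gillespie) path too
  t <- 50; mu <- 1e-4; L <- 500
  set.seed(48)
  diffs <- replicate(300, {
    a <- evolve_alignment(two_tip_genealogy(t), mu, st, locus_length = L)
    sum(split_chars(a$seq[1]) != split_chars(a$seq[2]))
  })
  lambda <- 2 * t * mu * L
  expect_lt(abs(mean(diffs) - lambda), 5 * sqrt(lambda / length(diffs)))
})

test_that("sequence evolution is reproducible under a fixed seed", {
  spec <- build_scenario("Sc1")
  set.seed(49)
  d <- sample_prior_draws(spec, 1)
  g <- simulate_genealogy(spec, d, tiny_config())
  set.seed(7)
  a1 <- evolve_alignment(g, mu = 1e-6, locus_length = 200)
  set.seed(7)
  a2 <- evolve_alignment(g, mu = 1e-6, locus_length = 200)
  expect_identical(a1, a2)
})
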