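test_that("a single sampled lineage yields a degenerate genealogy", {
  spec <- panmictic_spec(1000)
  g <- simulate_genealogy(spec, point_draw(spec), sample_config(c(A = 1)))
  expect_equal(g$n_tips, 1)
  expect_equal(genealogy_stats(g), tibble::tibble(tmrca = 0,
                                                  total_branch_length = 0))
})

test_that("genealogies are binary, ultrametric and time-ordered", {
  spec <- build_scenario("Sc1")
  set.seed(21)
  d <- sample_prior_draws(spec, 1)
  g <- simulate_genealogy(spec, d, tiny_config())
  n <- g$n_tips
  expect_equal(n, 20)
  expect_equal(length(g$node_time), 2 * n - 1)
  expect_true(all(g$node_time[seq_len(n)] == 0))
  expect_equal(sum(g$parent == 0), 1)            # one root
  expect_equal(unname(table(g$parent[g$parent != 0])),
               rep(2L, n - 1), ignore_attr = TRUE)  # strictly binary
  child <- which(g$parent != 0)
  expect_true(all(g$node_time[g$parent[child]] > g$node_time[child] |
                    g$node_time[child] == 0))
  ph <- as.phylo(g)
  expect_equal(ape::Ntip(ph), n)
  expect_true(ape::is.ultrametric(ph, tol = 1e-6))
  nwk <- ape::write.tree(ph)
  expect_match(nwk, "^\\(.*;$")
})

test_that("pairwise coalescence time has mean N in a constant population", {
  N <- 1000
  spec <- panmictic_spec(N)
  d <- point_draw(spec)
  cfg <- sample_config(c(A = 2))
  set.seed(31)
  tm <- replicate(2000, genealogy_stats(simulate_genealogy(
    spec, d, cfg, validate = FALSE))$tmrca)
  se <- N / sqrt(length(tm))            # sd of Exp(1/N) is N
  expect_lt(abs(mean(tm) - N), 3 * se)
})

test_that("total branch length matches the coalescent expectation", {
  N <- 500
  n <- 10
  spec <- panmictic_spec(N)
  d <- point_draw(spec)
  cfg <- sample_config(c(A = n))
  set.seed(32)
  tbl <- replicate(1500, genealogy_stats(simulate_genealogy(
    spec, d, cfg, validate = FALSE))$total_branch_length)
  expected <- 2 * N * sum(1 / (1:(n - 1)))
  # var of total length = sum over k of (k * 2N/(k(k-1)))^2 = (2N)^2 * sum 1/(k-1)^2
  sd_theory <- 2 * N * sqrt(sum(1 / (1:(n - 1))^2))
  expect_lt(abs(mean(tbl) - expected), 3 * sd_theory / sqrt(length(tbl)))
})

test_that("admixture pulses reassign lineages at the drawn rate", {
  r <- 0.3
  spec <- admix_spec(r = r)
  d <- point_draw(spec)
  cfg <- sample_config(c(A = 2, B = 0))
  set.seed(33)
  early <- replicate(1500, genealogy_stats(simulate_genealogy(
    spec, d, cfg, validate = FALSE))$tmrca < 1000)
  # both lineages must take the pulse (prob r^2) to coalesce early
  p_hat <- mean(early)
  se <- sqrt(r^2 * (1 - r^2) / length(early))
  expect_lt(abs(p_hat - r^2), 4 * se)
})

test_that("no cross-population coalescence precedes the populations' merge", {
  spec <- build_scenario("Sc1")
  set.seed(34)
  for (rep in 1:5) {
    d <- sample_prior_draws(spec, 1)
    g <- simulate_genealogy(spec, d, tiny_config())
    n <- g$n_tips
    # propagate the tip-descendant sets up the tree
    desc <- lapply(seq_len(2 * n - 1), function(i) integer(0))
    for (i in seq_len(n)) desc[[i]] <- i
    ord <- order(g$node_time[(n + 1):(2 * n - 1)]) + n
    for (nd in ord) {
      kids <- which(g$parent == nd)
      desc[[nd]] <- c(desc[[kids[1]]], desc[[kids[2]]])
      pops <- unique(g$tip_pop[desc[[nd]]])
      if ("NC" %in% pops && length(pops) > 1)
        expect_gt(g$node_time[nd], d$t_3)
      if (setequal(pops, c("SAG", "NAG")))
        expect_gt(g$node_time[nd], d$t_2)
    }
  }
})

test_that("genealogy simulation is reproducible under a fixed seed", {
  spec <- build_scenario("Sc7")
  set.seed(35)
  d <- sample_prior_draws(spec, 1)
  set.seed(99)
  g1 <- simulate_genealogy(spec, d, tiny_config())
  set.seed(99)
  g2 <- simulate_genealogy(spec, d, tiny_config())
  expect_identical(g1, g2)
})

test_that("isolated populations that never merge are an error", {
  spec <- admix_spec(NA_ = 10, NB = 10, r = 0.5, t_adm = 1, t_merge = 1e6)
  # drop the merge event entirely -> validation refuses it
  expect_error(scenario_spec("iso", c("A", "B"), c(A = "N_A", B = "N_B"),
                             spec$events[spec$events$kind == "admix", ],
                             priors = spec$priors,
                             constraints = spec$constraints),
               "merge")
})
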