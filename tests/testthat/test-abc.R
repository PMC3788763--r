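make_small_table <- function(seed = 81, n = 400, scenarios = c("Sc1", "Sc4")) {
  build_reference_table(lapply(scenarios, build_scenario), n,
                        tiny_config(200), seed = seed)
}

test_that("rejection keeps the closest records, matching a full-sort oracle", {
  tbl <- make_small_table(81, 100)
  stat_cols <- attr(tbl, "stat_cols")
  obs <- tibble::as_tibble(tbl)[7, stat_cols]
  all_sel <- rejection_select(tbl, obs, fraction = 1)
  expect_equal(nrow(all_sel), nrow(tbl))
  sel <- rejection_select(tbl, obs, fraction = 0.1)
  expect_equal(nrow(sel), 20)
  expect_equal(min(sel$.dist), 0)      # the observed record itself
  # oracle: standardize and sort from scratch
  m <- as.matrix(tibble::as_tibble(tbl)[, stat_cols])
  sds <- apply(m, 2, sd); sds[sds == 0] <- 1
  z <- sweep(sweep(m, 2, unlist(obs)), 2, sds, "/")
  d_or <- sqrt(rowSums(z^2))
  idx_or <- order(d_or)[1:20]
  expect_equal(sort(sel$.dist), sort(d_or[idx_or]))
  expect_error(rejection_select(tbl, obs, fraction = 0), "fraction")
})

test_that("model choice is coherent and degenerates gracefully", {
  tbl <- make_small_table(82, 300)
  obs <- tibble::as_tibble(tbl)[5, attr(tbl, "stat_cols")]
  mc <- abc_model_choice(rejection_select(tbl, obs, fraction = 0.2))
  res <- tidy(mc)
  expect_equal(sum(res$prob), 1, tolerance = 1e-9)
  expect_true(all(res$conf_low <= res$prob + 1e-12 &
                    res$prob <= res$conf_high + 1e-12))
  expect_true(all(res$conf_low >= 0 & res$conf_high <= 1))
  expect_equal(sum(res$freq_direct), 1, tolerance = 1e-12)
  # single-scenario selection -> probability one
  t1 <- build_reference_table(build_scenario("Sc1"), 50, tiny_config(200),
                              seed = 83)
  mc1 <- abc_model_choice(rejection_select(t1, obs, fraction = 0.5))
  expect_equal(tidy(mc1)$prob, 1)
  expect_equal(tidy(mc1)$conf_low, 1)
})

test_that("adjusted posteriors respect prior bounds; no adjustment returns the draws", {
  t1 <- build_reference_table(build_scenario("Sc1"), 400, tiny_config(200),
                              seed = 84)
  spec <- build_scenario("Sc1")
  obs <- tibble::as_tibble(t1)[3, attr(t1, "stat_cols")]
  sel <- rejection_select(t1, obs, fraction = 0.1)
  post <- abc_estimate(sel, spec)
  pr <- post$priors
  for (j in seq_len(nrow(pr))) {
    x <- post$samples[[pr$param[j]]]
    expect_true(all(x > pr$low[j] & x < pr$high[j]))
  }
  raw <- abc_estimate(sel, spec, adjust = FALSE)
  expect_equal(as.matrix(raw$samples),
               as.matrix(tibble::as_tibble(sel)[, pr$param]),
               ignore_attr = TRUE, tolerance = 1e-9)
  s <- tidy(post)
  expect_true(all(s$q025 <= s$median & s$median <= s$q975))
  expect_error(abc_estimate(rejection_select(make_small_table(85, 50), obs,
                                             fraction = 1), spec),
               "single-scenario|target scenario")
})

test_that("posterior summaries convert split times to years consistently", {
  t1 <- build_reference_table(build_scenario("Sc1"), 200, tiny_config(200),
                              seed = 86)
  spec <- build_scenario("Sc1")
  obs <- tibble::as_tibble(t1)[1, attr(t1, "stat_cols")]
  post <- abc_estimate(rejection_select(t1, obs, fraction = 0.2), spec)
  yrs <- posterior_times(post)
  expect_setequal(unique(yrs$term), c("t_exp", "t_2", "t_3"))
  gen <- yrs[yrs$term == "t_3" & yrs$unit == "generations", ]
  yr <- yrs[yrs$term == "t_3" & yrs$unit == "years", ]
  expect_equal(yr$median, generations_to_years(gen$median))
})

test_that("model checking reports one calibrated tail per statistic", {
  spec <- build_scenario("Sc1")
  t1 <- build_reference_table(spec, 300, tiny_config(200), seed = 87)
  obs <- tibble::as_tibble(t1)[10, attr(t1, "stat_cols")]
  post <- abc_estimate(rejection_select(t1, obs, fraction = 0.1), spec)
  chk <- abc_model_check(spec, post, obs, tiny_config(200), n_pod = 40,
                         seed = 88)
  res <- tidy(chk)
  expect_equal(nrow(res), 12)
  expect_true(all(res$tail_prob >= 0 & res$tail_prob <= 1))
  expect_true(all(res$p_two_sided >= 0 & res$p_two_sided <= 1))
  chk1 <- abc_model_check(spec, post, obs, tiny_config(200), n_pod = 1,
                          seed = 89)
  expect_true(all(tidy(chk1)$tail_prob %in% c(0, 0.5, 1)))
})

test_that("a fixed seed makes the whole analysis deterministic", {
  run <- function() {
    spec <- build_scenario("Sc1")
    tbl <- build_reference_table(spec, 150, tiny_config(150), seed = 90)
    obs <- tibble::as_tibble(tbl)[2, attr(tbl, "stat_cols")]
    sel <- rejection_select(tbl, obs, fraction = 0.2)
    post <- abc_estimate(sel, spec)
    list(tidy(post), post$weights)
  }
  expect_identical(run(), run())
})
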