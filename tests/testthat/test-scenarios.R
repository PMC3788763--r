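test_that("all eight shipped scenarios build and validate", {
  for (id in paste0("Sc", 1:8)) {
    spec <- build_scenario(id)
    expect_s3_class(spec, "scenario_spec")
    expect_setequal(spec$populations, c("SAG", "NAG", "NC"))
    expect_true(all(scenario_params(spec) %in% spec$priors$param))
  }
  sc1 <- build_scenario("Sc1")
  expect_equal(sum(sc1$events$kind == "merge"), 2)
  expect_setequal(unique(sc1$events$time[sc1$events$kind == "resize"]),
                  c("t_exp", "t_2", "t_3"))
  sc2 <- build_scenario("Sc2")
  expect_true(all(c("t_expSAG", "t_expNAG", "t_expNC") %in% sc2$events$time))
  sc7 <- build_scenario("Sc7")
  adm <- sc7$events[sc7$events$kind == "admix", ]
  expect_equal(adm$param, "ra")
  expect_true(all(c("t_adm1 < t_2") %in%
                    paste(sc7$constraints$lhs, sc7$constraints$op,
                          sc7$constraints$rhs)))
  sc8 <- build_scenario("Sc8")
  expect_equal(sc8$events$param[sc8$events$kind == "admix"], "rb")
})

test_that("unknown scenario ids fail listing the alternatives", {
  expect_error(build_scenario("Sc9"), "Sc1.*Sc8")
})

test_that("default priors encode the intended intervals", {
  pr <- default_priors()
  expect_true(all(pr$low < pr$high))
  get <- function(p) unlist(pr[pr$param == p, c("low", "high")], use.names = FALSE)
  expect_equal(get("N_anc"), c(1000, 60000))
  expect_equal(get("t_3"), c(1e5, 1e6))
  expect_equal(get("mu"), c(1e-11, 1e-7))
  expect_equal(get("ra"), c(0.01, 0.99))
})

test_that("prior draws satisfy every constraint and respect the seed", {
  spec <- build_scenario("Sc1")
  set.seed(101)
  d <- sample_prior_draws(spec, 2000)
  expect_true(all(d$t_exp <= d$t_2))
  expect_true(all(d$t_2 < d$t_3))
  expect_true(all(d$N_anc < d$N_NC & d$N_NC <= d$N_NAG & d$N_NAG <= d$N_SAG))
  expect_true(all(d$N1 > d$N_anc & d$N4 > d$N_anc))
  set.seed(101)
  expect_identical(sample_prior_draws(spec, 2000), d)
})

test_that("accepted-draw marginals match a brute-force rejection oracle", {
  spec <- build_scenario("Sc1")
  set.seed(202)
  mine <- sample_prior_draws(spec, 4000)
  theirs <- oracle_sc1_prior(4000)
  expect_gt(stats::ks.test(mine$t_2, theirs$t_2)$p.value, 1e-3)
  expect_gt(stats::ks.test(mine$N_SAG, theirs$N_SAG)$p.value, 1e-3)
  expect_gt(stats::ks.test(mine$N_anc, theirs$N_anc)$p.value, 1e-3)
})

test_that("point-mass priors return the constant draw", {
  ref <- sc1_reference_params()
  spec <- build_scenario("Sc1")
  pr <- spec$priors
  for (p in names(ref)) pr$low[pr$param == p] <- pr$high[pr$param == p] <- ref[[p]]
  pt <- scenario_spec("Sc1pt", spec$populations, spec$initial_sizes,
                      spec$events, priors = pr,
                      constraints = spec$constraints)
  set.seed(3)
  d <- sample_prior_draws(pt, 3)
  for (p in names(ref)) expect_equal(unique(d[[p]]), ref[[p]])
})

test_that("validate_draw distinguishes strict from non-strict relations", {
  spec <- build_scenario("Sc1")
  set.seed(4)
  d <- as.list(sample_prior_draws(spec, 1))
  expect_length(validate_draw(spec, d), 0)
  d_eq <- d; d_eq$t_exp <- d_eq$t_2
  expect_length(validate_draw(spec, d_eq), 0)      # t_exp <= t_2 allows equality
  d_bad <- d; d_bad$t_2 <- d_bad$t_3
  expect_match(validate_draw(spec, d_bad), "t_2 < t_3", all = FALSE)
  d_miss <- d; d_miss$t_3 <- NULL
  expect_error(validate_draw(spec, d_miss), "t_3")
})

test_that("scenario YAML configs round-trip", {
  spec <- build_scenario("Sc7")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(spec, path)
  back <- read_scenario(path)
  expect_equal(back$id, spec$id)
  expect_equal(back$events, spec$events)
  expect_equal(back$priors$param, spec$priors$param)
  expect_equal(back$priors$low, spec$priors$low)
  expect_equal(back$constraints, spec$constraints)
})

test_that("malformed scenarios are rejected with the offending event named", {
  ok <- build_scenario("Sc1")
  ev_bad <- ok$events
  ev_bad$pop[1] <- "XX"
  expect_error(scenario_spec("bad", ok$populations, ok$initial_sizes, ev_bad),
               "event 1.*XX")
  ev2 <- ok$events[ok$events$kind != "merge", ]
  expect_error(scenario_spec("bad2", ok$populations, ok$initial_sizes, ev2),
               "merge")
})
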