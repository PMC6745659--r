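# Within-season demography: emergence, germination, herbicide action,
# regrowth, fecundity, and the asexual pipeline.

make_cohort <- function(n, emg = 150, gt = 0L, lnpz = log(1719), rhiz = 0L) {
  plant_cohort(rep_len(emg, n), rep_len(gt, n), rep_len(lnpz, n),
               rep_len(rhiz, n))
}

test_that("emergence dates follow the Weibull phenology", {
  set.seed(10)
  x <- sample_emergence_dates(2e4, 10.5, 169)
  expect_true(all(x >= 0))
  expect_equal(mean(x), 169 * gamma(1 + 1 / 10.5), tolerance = 0.005)
  # CDF at the scale parameter is 1 - exp(-1) for any shape
  expect_equal(mean(x <= 169), 1 - exp(-1), tolerance = 0.02)
  expect_gt(stats::ks.test(x, stats::pweibull, 10.5, 169)$p.value, 1e-3)
  y <- sample_emergence_dates(2e4, 6.5, 160)
  expect_gt(stats::ks.test(y, stats::pweibull, 6.5, 160)$p.value, 1e-3)
  # k = 1 reduces to the exponential
  set.seed(11)
  z <- sample_emergence_dates(2e4, 1, 50)
  expect_gt(stats::ks.test(z, stats::pexp, 1 / 50)$p.value, 1e-3)
  expect_error(sample_emergence_dates(10, -1, 169), "positive")
})

test_that("germination is a Bernoulli thinning of the seedbank", {
  set.seed(12)
  bank <- propagule_pool(rep(0L, 10000), rnorm(10000))
  g <- germinate(bank, 0.26)
  expect_equal(pool_size(g$seedlings), 2600, tolerance = 0.06)
  expect_equal(pool_size(g$seedbank), 0)  # non-emerged seeds are lost
  expect_equal(pool_size(germinate(propagule_pool(), 0.26)$seedlings), 0)
  expect_equal(pool_size(germinate(bank, 1)$seedlings), 10000)
  expect_error(germinate(bank, 1.2), "\\[0, 1\\]")
})

test_that("pre-plant removal uses a strict cutoff at sowing", {
  co <- plant_cohort(c(100, 150, 138), rep(0L, 3), rep(0, 3), rep(0L, 3))
  rp <- remove_preplant(co, 138)
  expect_equal(sort(rp$plants$emg), c(138, 150))  # boundary day retained
  expect_equal(rp$killed$emg, 100)
})

test_that("foliar survival of a sensitive cohort is binomial at 1 - efficacy", {
  set.seed(13)
  ev <- application_event(168, "early_post",
                          herbicide_spec("ACCase", "single_gene"))
  co <- make_cohort(1e4, emg = 150, gt = 0L, lnpz = log(1719))
  surv <- apply_foliar_herbicide(co, ev)$survivors
  n <- n_plants(surv)
  expect_equal(n, 1e4 * 0.05, tolerance = 0.2)
  expect_gt(stats::binom.test(n, 1e4, 0.05)$p.value, 1e-4)
  # resistant genotypes survive with certainty
  rr <- make_cohort(500, gt = 2L)
  expect_equal(n_plants(apply_foliar_herbicide(rr, ev)$survivors), 500)
  rs <- make_cohort(500, gt = 1L)
  expect_equal(n_plants(apply_foliar_herbicide(rs, ev)$survivors), 500)
})

test_that("quantitative resistance protects plants with Pz at or above dose", {
  set.seed(14)
  ev <- application_event(168, "late_post",
                          herbicide_spec("glyphosate", "quantitative",
                                         dose = 1120))
  hi <- make_cohort(300, lnpz = log(1500))
  expect_equal(n_plants(apply_foliar_herbicide(hi, ev)$survivors), 300)
  at <- make_cohort(300, lnpz = log(1120))  # boundary: Pz >= dose survives
  expect_equal(n_plants(apply_foliar_herbicide(at, ev)$survivors), 300)
  lo <- make_cohort(2000, lnpz = log(1119))
  expect_equal(n_plants(apply_foliar_herbicide(lo, ev)$survivors),
               2000 * 0.10, tolerance = 0.4)
})

test_that("mixture components act independently", {
  set.seed(15)
  ev <- application_event(168, "early_post", list(
    herbicide_spec("glyphosate", "quantitative", dose = 1120),
    herbicide_spec("ACCase", "single_gene")))
  # SS and Pz-sensitive: survival 0.05 * 0.05
  both <- make_cohort(4e4, gt = 0L, lnpz = log(100))
  expect_equal(n_plants(apply_foliar_herbicide(both, ev)$survivors),
               4e4 * 0.0025, tolerance = 0.5)
  # SS but Pz-resistant: only the ACCase component bites
  pzr <- make_cohort(1e4, gt = 0L, lnpz = log(2000))
  expect_equal(n_plants(apply_foliar_herbicide(pzr, ev)$survivors),
               1e4 * 0.05, tolerance = 0.25)
})

test_that("early POST targets only plants emerged by the event date", {
  set.seed(16)
  ev <- application_event(168, "early_post",
                          herbicide_spec("ACCase", "single_gene",
                                         foliar_efficacy_early = 1))
  co <- plant_cohort(c(rep(160, 100), rep(180, 100)), rep(0L, 200),
                     rep(0, 200), rep(0L, 200))
  surv <- apply_foliar_herbicide(co, ev)$survivors
  expect_equal(n_plants(surv), 100)
  expect_true(all(surv$emg == 180))
  # late POST covers everyone
  ev_late <- application_event(198, "late_post",
                               herbicide_spec("ACCase", "single_gene",
                                              foliar_efficacy_late = 1))
  expect_equal(n_plants(apply_foliar_herbicide(co, ev_late)$survivors), 0)
})

test_that("rhizome herbicide kill rates follow the tillage setting", {
  set.seed(17)
  ev <- application_event(168, "early_post",
                          herbicide_spec("ACCase", "single_gene"))
  rz <- rhizome_state(rep(0L, 1e4), rep(log(1719), 1e4), rep(3L, 1e4),
                      rep(3L, 1e4), rep(TRUE, 1e4))
  expect_equal(sum(apply_rhizome_herbicide(rz, ev, FALSE)$alive),
               7500, tolerance = 0.03)
  expect_equal(sum(apply_rhizome_herbicide(rz, ev, TRUE)$alive),
               5000, tolerance = 0.03)
  rzR <- rhizome_state(rep(2L, 1000), rep(log(1719), 1000), rep(3L, 1000),
                       rep(3L, 1000), rep(TRUE, 1000))
  expect_equal(sum(apply_rhizome_herbicide(rzR, ev, TRUE)$alive), 1000)
})

test_that("tiller regrowth respects apical dominance and meristem reserves", {
  set.seed(18)
  rz <- rhizome_state(gt = 0L, lnpz = log(1719), nodes = 3L, mer = 3L,
                      alive = TRUE)
  killed <- plant_cohort(150, 0L, log(1719), 1L)
  rg <- regrow_tillers(rz, killed, 168)
  expect_equal(n_plants(rg$plants), 1)
  expect_equal(rg$plants$emg, 189)           # three weeks after the kill
  expect_equal(rg$rhizomes$mer, 2L)
  # no reserves -> no regrowth
  rz0 <- rhizome_state(0L, log(1719), 3L, 0L, TRUE)
  expect_equal(n_plants(regrow_tillers(rz0, killed, 168)$plants), 0)
  # dead rhizome -> no regrowth
  rzd <- rhizome_state(0L, log(1719), 3L, 3L, FALSE)
  expect_equal(n_plants(regrow_tillers(rzd, killed, 168)$plants), 0)
  # surviving tillers trigger nothing
  expect_equal(n_plants(regrow_tillers(rz, plant_cohort(), 168)$plants), 0)
  # regrowths per rhizome never exceed killed tillers or reserves
  rz2 <- rhizome_state(0L, log(1719), 3L, 2L, TRUE)
  killed3 <- plant_cohort(rep(150, 3), rep(0L, 3), rep(log(1719), 3),
                          rep(1L, 3))
  rg2 <- regrow_tillers(rz2, killed3, 168)
  expect_equal(n_plants(rg2$plants), 2)
  expect_equal(rg2$rhizomes$mer, 0L)
})

test_that("fecundity declines exponentially with emergence date and is capped", {
  fec <- fecundity_params(298660, -0.066, 356)
  expect_equal(seeds_per_plant(0, fec), 356L)     # cap binds at day 0
  expect_equal(seeds_per_plant(168, fec), 5L)     # ~ 4.57 rounds to 5
  expect_true(seeds_per_plant(100, fec) <= 356L)
  flat <- fecundity_params(1000, 0, 356)
  expect_equal(seeds_per_plant(c(0, 50, 200), flat), rep(356L, 3))
  # stochastic rounding preserves the expectation
  set.seed(19)
  draws <- seeds_per_plant(rep(168, 2e4), fec, method = "stochastic")
  expect_equal(mean(draws), 298660 * exp(-0.066 * 168), tolerance = 0.01)
})

test_that("sexual reproduction tallies selfing and clones no one", {
  set.seed(20)
  adults <- make_cohort(200, emg = 140, gt = 1L)
  seeds <- reproduce_sexually(adults, 0.95, quant_trait_model(1719),
                              fitness_cost("none"),
                              fecundity_params(298660, -0.066, 356))
  # RS parents selfing at 0.95: offspring R-allele frequency stays 0.5
  expect_equal(mean(seeds$gt) / 2, 0.5, tolerance = 0.02)
  expect_gt(pool_size(seeds), 0)
  expect_equal(pool_size(reproduce_sexually(plant_cohort(), 0.95,
                                            quant_trait_model(1719),
                                            fitness_cost("none"),
                                            fecundity_params(1, 0, 10))), 0)
  # all-SS adults give all-SS seeds
  ss <- reproduce_sexually(make_cohort(50, emg = 140, gt = 0L), 0.95,
                           quant_trait_model(1719), fitness_cost("none"),
                           fecundity_params(298660, -0.066, 356))
  expect_true(all(ss$gt == 0L))
})

test_that("the asexual pipeline multiplies by branches and nodes", {
  set.seed(21)
  prim <- propagule_pool(rep(0L, 10000), rep(log(1719), 10000))
  sec <- produce_secondary_rhizomes(prim, 2, 3)
  expect_equal(length(sec$gt), 20000, tolerance = 0.02)
  expect_equal(mean(sec$nodes), 3, tolerance = 0.02)
  # every node crown fields one tiller: ~ 6 per primary
  sp <- sprout_tillers(sec, 6.5, 160)
  expect_equal(n_plants(sp$plants), 60000, tolerance = 0.02)
  expect_true(all(sp$plants$rhiz > 0))
  # clonal identity through the pipeline
  expect_true(all(sp$plants$gt == 0L))
  expect_true(all(sp$plants$lnpz == log(1719)))
  expect_equal(length(produce_secondary_rhizomes(prim, 0, 3)$gt), 0)
})

test_that("tertiary rhizomes are clones and overwintering is Bernoulli", {
  set.seed(22)
  adults <- plant_cohort(rep(150, 1000), rep(2L, 1000),
                         rep(log(42), 1000), rep(0L, 1000))
  tert <- produce_tertiary_rhizomes(adults, 1)
  expect_equal(pool_size(tert), 1000, tolerance = 0.12)
  expect_true(all(tert$gt == 2L))
  expect_true(all(tert$lnpz == log(42)))   # Pz copied exactly
  expect_equal(pool_size(produce_tertiary_rhizomes(plant_cohort(), 1)), 0)
  surv <- overwinter(tert, 0.25)
  expect_equal(pool_size(surv), 0.75 * pool_size(tert), tolerance = 0.08)
  expect_equal(pool_size(overwinter(tert, 1)), 0)
  expect_equal(pool_size(overwinter(tert, 0)), pool_size(tert))
  expect_error(overwinter(tert, 1.5), "\\[0, 1\\]")
})
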