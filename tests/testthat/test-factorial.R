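scenarios <- read.csv(fq_example("scenario_energies.csv"))
compost <- read.csv(fq_example("compost_design.csv"))
field <- read_design_table(fq_example("field_measures.csv"))

test_that("binding improvement uses magnitudes of negative energies", {
  expect_equal(binding_improvement(-102.160, -113.825), 11.42)
  expect_equal(binding_improvement(-49.445, -73.608), 48.87)
  expect_equal(binding_improvement(-80, -80), 0)
  expect_error(binding_improvement(10, -20), "negative")
})

test_that("scenario reports flag beneficial additive groups", {
  s2 <- scenario_report(scenarios[scenarios$scenario == 2, ],
                        design = compost)
  expect_setequal(s2$beneficial, c("G1", "G3", "G5", "G8"))
  expect_equal(s2$range, c(21.26, 31.74))
  # additive mapping follows the design table (G1 = OM, ...)
  expect_setequal(s2$beneficial_additives, c("OM", "WV", "AP", "MS"))
  s1 <- scenario_report(scenarios[scenarios$scenario == 1, ],
                        design = compost)
  expect_equal(s1$table$improvement, 11.42)
  expect_setequal(s1$beneficial_additives, "AP")
  s3 <- scenario_report(scenarios[scenarios$scenario == 3, ])
  expect_length(s3$beneficial, 0)
  expect_equal(s3$range, c(0, 0))
  # all groups equal to blank: empty set, 0-0% range
  flat <- data.frame(group = c("G0", "G1", "G2"), energy = rep(-50, 3))
  sf <- scenario_report(flat)
  expect_length(sf$beneficial, 0)
  expect_equal(sf$range, c(0, 0))
  expect_error(scenario_report(flat, blank = "G9"), "not found")
})

test_that("marginal means reproduce the field-measure trial", {
  expect_equal(marginal_mean(field, "organic_fertilizer", 1), -93.266)
  expect_equal(marginal_mean(field, "straw_returning", 1), -90.919)
  expect_equal(marginal_mean(field, "plowing", 1), -92.778)
  one <- data.frame(group = "r1", a = 1, energy = -7.5)
  expect_equal(marginal_mean(one, "a", 1), -7.5)
  expect_error(marginal_mean(one, "a", 0), "no runs")
})

test_that("factorial effects follow the Yates contrast convention", {
  eff <- factorial_effects(field)
  est <- function(tm) eff$estimate[eff$term == tm]
  # main effect equals the difference of marginal means
  expect_equal(est("plowing"),
               marginal_mean(field, "plowing", 1, digits = NULL) -
                 marginal_mean(field, "plowing", 0, digits = NULL),
               tolerance = 1e-12)
  expect_equal(est("plowing"), -9.4735, tolerance = 1e-10)
  for (f in c("organic_fertilizer", "straw_returning")) {
    expect_equal(est(f),
                 marginal_mean(field, f, 1, digits = NULL) -
                   marginal_mean(field, f, 0, digits = NULL),
                 tolerance = 1e-12)
  }
  # additive noiseless response y = 10 + 3A - 2B recovers (3, -2, 0)
  add <- sim_factorial_response(c("A", "B"), effects = c(A = 3, B = -2),
                                intercept = 10, sigma = 0, seed = 1)
  ea <- factorial_effects(add)
  expect_equal(ea$estimate, c(3, -2, 0), tolerance = 1e-12)
  # incomplete (one-factor-at-a-time) designs are rejected
  ofat <- cbind(compost, energy = rnorm(9))
  expect_error(factorial_effects(ofat), "incomplete")
})

test_that("effects equal twice the +/-1-coded least-squares coefficients", {
  for (k in c(3L, 4L)) {
    d <- sim_factorial_response(LETTERS[1:k],
                                effects = c(A = 2, B = -1, `A:B` = 0.5),
                                intercept = 5, sigma = 1, seed = 10 + k)
    eff <- factorial_effects(d)
    ora <- oracle_effects_lm(d)
    expect_equal(eff$estimate, unname(ora[match(eff$term, names(ora))]),
                 tolerance = 1e-10)
  }
})

test_that("effects are linear and invariant to run order", {
  d1 <- sim_factorial_response(c("A", "B", "C"), effects = c(A = 1, C = -2),
                               sigma = 0.5, seed = 3)
  d2 <- sim_factorial_response(c("A", "B", "C"), effects = c(B = 4),
                               sigma = 0.5, seed = 4)
  dsum <- d1
  dsum$energy <- d1$energy + d2$energy
  e1 <- factorial_effects(d1)$estimate
  e2 <- factorial_effects(d2)$estimate
  expect_equal(factorial_effects(dsum)$estimate, e1 + e2, tolerance = 1e-12)
  perm <- d1[sample(nrow(d1)), ]
  expect_equal(factorial_effects(perm)$estimate, e1, tolerance = 1e-12)
})

test_that("replicated designs average cells before contrasting", {
  d <- sim_factorial_response(c("A", "B"), effects = c(A = 2), sigma = 0,
                              replicates = 3, seed = 6)
  eff <- factorial_effects(d)
  expect_equal(eff$estimate[eff$term == "A"], 2, tolerance = 1e-12)
})

test_that("significance screening controls type I error and finds signal", {
  # null: all effects zero, pure noise, unreplicated 2^4
  flags <- vapply(1:200, function(seed) {
    d <- sim_factorial_response(LETTERS[1:4], sigma = 1, seed = seed)
    sc <- significance_screen(factorial_effects(d), method = "lenth")
    mean(sc$significant)
  }, numeric(1))
  expect_lte(mean(flags), 0.05)
  # one huge effect (10 sigma) is found essentially always
  found <- vapply(1:100, function(seed) {
    d <- sim_factorial_response(LETTERS[1:4], effects = c(A = 10), sigma = 1,
                                seed = seed)
    sc <- significance_screen(factorial_effects(d), method = "lenth")
    sc$significant[sc$term == "A"]
  }, logical(1))
  expect_gte(mean(found), 0.99)
})

test_that("screening methods respect their data-shape contracts", {
  d <- sim_factorial_response(c("A", "B", "C"), effects = c(A = 5),
                              sigma = 0.3, seed = 8)
  eff <- factorial_effects(d)
  expect_error(significance_screen(eff, method = "replicated-anova",
                                   design = d), "replicates")
  pooled <- significance_screen(eff, method = "pool-high-order")
  expect_true(is.na(pooled$significant[pooled$order == 3]))
  expect_true(pooled$significant[pooled$term == "A"])
  drep <- sim_factorial_response(c("A", "B"), effects = c(A = 5), sigma = 0.3,
                                 replicates = 4, seed = 9)
  sc <- significance_screen(factorial_effects(drep),
                            method = "replicated-anova", design = drep)
  expect_true(sc$significant[sc$term == "A"])
})

test_that("injected factorial effects are recovered within tolerance", {
  hits <- vapply(1:100, function(seed) {
    d <- sim_factorial_response(LETTERS[1:4],
                                effects = c(A = 3, B = -2, `A:B` = 1.5),
                                sigma = 0.5, replicates = 20, seed = seed)
    eff <- factorial_effects(d)
    all(abs(eff$estimate[match(c("A", "B", "A:B"), eff$term)] -
              c(3, -2, 1.5)) < 0.2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
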