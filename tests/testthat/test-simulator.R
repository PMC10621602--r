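test_that("census family sizes follow the renormalized distribution", {
  x <- census_family_sizes(40000, seed = 71)
  expect_true(all(x %in% 1:4))
  expect_lt(abs(mean(x == 1) - 0.48 / 1.02), 0.01)
  expect_lt(abs(mean(x == 4) - 0.03 / 1.02), 0.005)
  expect_identical(census_family_sizes(50, seed = 3),
                   census_family_sizes(50, seed = 3))
})

test_that("simulated datasets have the configured structure", {
  cfg <- sim_config(n_families = 15, persons = 3, subunits = 2,
                    prevalence = 0.3)
  d <- simulate_hier_data(cfg, seed = 72)
  expect_equal(nrow(d), 15 * 3 * 2)
  expect_equal(length(unique(d$family)), 15)
  expect_equal(nrow(pair_counts(d)$persons), 45)
  expect_identical(as.data.frame(simulate_hier_data(cfg, seed = 72)),
                   as.data.frame(d))
})

test_that("the event effect and implied shift match the generating model", {
  cfg <- sim_config(n_families = 400)
  expect_equal(cfg$mu, 1.5 / sqrt(10))
  expect_equal(cfg$rho_s, 0.8)
  expect_equal(cfg$rho_f, 0.5)
  set.seed(73)
  diffs <- replicate(30, {
    d <- simulate_hier_data(cfg)
    mean(d$score[d$event == 1]) - mean(d$score[d$event == 0])
  })
  expect_equal(mean(diffs), 1.5, tolerance = 0.05)
})

test_that("turning off shared effects removes within-person correlation", {
  cfg <- sim_config(n_families = 800, var_family = 0, var_person = 0,
                    var_subunit = 2)
  d <- simulate_hier_data(cfg, seed = 74)
  resid <- d$score - cfg$b1 * d$event
  m <- matrix(resid, ncol = 2, byrow = TRUE)  # two subunits per person
  expect_equal(cor(m[, 1], m[, 2]), 0, tolerance = 0.08)
})

test_that("scenario modifiers apply: binning, deletion, measurement error", {
  d_bin <- simulate_hier_data(sim_config(n_families = 40, bins = 5), seed = 75)
  expect_lte(length(unique(d_bin$score)), 5)
  d_miss <- simulate_hier_data(sim_config(n_families = 100,
                                          missing_fraction = 0.1), seed = 76)
  expect_equal(nrow(d_miss), 400 - 20)  # 10% of 200 persons lose one of two
  k <- table(paste(d_miss$family, d_miss$person))
  expect_equal(sum(k == 1), 20)
  cfg_err <- sim_config(n_families = 40, error_sd = 0.5)
  expect_false(anyDuplicated(simulate_hier_data(cfg_err, seed = 77)$score) > 0)
})

test_that("expected estimator value reproduces the balanced design and its variants", {
  expect_equal(round(expected_theta3(sim_config(n_families = 20)), 3), 0.634)
  expect_equal(round(expected_theta3(sim_config(n_families = 50)), 3), 0.633)
  expect_equal(round(expected_theta3(sim_config(n_families = 100)), 3), 0.632)
  # census and deletion variants stay near the balanced value
  e3 <- expected_theta3(sim_config(n_families = 50, persons = "census"))
  expect_equal(e3, 0.633, tolerance = 0.001)
  e4 <- expected_theta3(sim_config(n_families = 50, missing_fraction = 0.1))
  expect_equal(e4, 0.633, tolerance = 0.001)
})

test_that("scenario settings enumerate the standard parameterizations", {
  expect_equal(nrow(scenario_settings(1)), 12)
  expect_equal(nrow(scenario_settings(2)), 6)
  expect_equal(nrow(scenario_settings(3)), 2)
  expect_equal(nrow(scenario_settings(4)), 4)
  expect_equal(nrow(scenario_settings(5)), 6)
  expect_error(scenario_settings(7), "scenario")
})

test_that("scenario runs are reproducible and sane under the null", {
  st <- scenario_settings(1)[2, ]
  st$config[[1]] <- sim_config(n_families = 30, b1 = 0)  # no discrimination
  r1 <- run_scenario(st, n_reps = 150, seed = 78)
  r2 <- run_scenario(st, n_reps = 150, seed = 78)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$expected_theta, 0.5)
  expect_equal(r1$mean_theta, 0.5, tolerance = 0.03)
  expect_gte(r1$coverage, 0.9)
})

test_that("family-level bootstrap comparator produces covering intervals", {
  st <- scenario_settings(1)[1, ]
  r <- run_scenario(st, n_reps = 40, seed = 79, bootstrap = TRUE)
  expect_true(is.finite(r$coverage_boot))
  expect_gte(r$coverage_boot, 0.75)
})
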