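test_that("probit-scale interval has the closed-form pieces", {
  ci <- probit_ci(0.5, 0, alpha = 0.05)
  expect_equal(c(ci$lower, ci$upper), c(0.5, 0.5))
  s <- 0.03
  ci <- probit_ci(0.5, s^2)
  expect_equal(ci$se_omega, s / dnorm(0))
  expect_equal(ci$lower, pnorm(qnorm(0.975) * -s / dnorm(0)))
})

test_that("intervals respect the parameter space and cover the estimate", {
  set.seed(51)
  for (i in 1:25) {
    th <- runif(1, 0.02, 0.98)
    v <- runif(1, 0, 0.05)^2
    ci <- probit_ci(th, v)
    expect_true(0 <= ci$lower && ci$lower <= ci$upper && ci$upper <= 1)
    expect_true(ci$lower <= th && th <= ci$upper)
  }
})

test_that("boundary estimates are truncated with a warning", {
  expect_warning(ci <- probit_ci(1, 1e-4, n_pairs = 50), "boundary")
  expect_lt(ci$upper, 1)
  expect_error(probit_ci(1, 1e-4), "n_pairs")
})

test_that("full fit on the worked example is reproducible end to end", {
  d <- toy_two_family()
  # the toy's between-family component sits on the boundary, so the shift
  # fit warns about truncation
  fit <- suppressWarnings(hier_auc(d))
  expect_s3_class(fit, "hier_auc")
  expect_equal(unname(coef(fit)), 0.75)
  expect_equal(fit$theta, fit$decomposition$theta_hat)
  expect_true(fit$ci[["lower"]] <= 0.75 && 0.75 <= fit$ci[["upper"]])
  ci95 <- confint(fit)
  expect_equal(unname(ci95[1, ]), unname(fit$ci))
  ci80 <- confint(fit, level = 0.8)
  expect_true(ci80[1] > ci95[1] && ci80[2] < ci95[2])
  expect_equal(unname(vcov(fit)[1, 1]), fit$var_theta)
  expect_output(print(summary(fit)), "Shift model")
})

test_that("pooled tie-breaking on tie-free data equals the single pass", {
  set.seed(52)
  d <- random_hier_data(20, n_families = 4)
  f1 <- hier_auc(d)
  for (L in c(2, 10)) {
    f2 <- hier_auc(d, ties = "pool", L = L)
    expect_identical(f2$theta, f1$theta)
    expect_identical(f2$var_theta, f1$var_theta)
    expect_identical(f2$ties$between_var, 0)
  }
})

test_that("pooling adds between-iteration variance under ties", {
  set.seed(53)
  cfg <- sim_config(n_families = 25, bins = 5)
  d <- simulate_hier_data(cfg)
  expect_error(hier_auc(d, ties = "error"), "tied")
  expect_error(hier_auc(d, ties = "pool", L = 1), "L >= 2")
  fit <- hier_auc(d, ties = "pool", L = 10, seed = 7)
  expect_equal(fit$ties$L, 10L)
  expect_gte(fit$var_theta, fit$ties$within_var)
  expect_equal(fit$var_theta,
               fit$ties$within_var + (1 + 1 / 10) * fit$ties$between_var)
  expect_equal(fit$theta, mean(fit$ties$theta_iter))
  # pooled estimate is an AUC and the CI is ordered
  expect_true(fit$ci[["lower"]] < fit$theta && fit$theta < fit$ci[["upper"]])
})

test_that("tie-pooled fits are deterministic given a seed", {
  set.seed(54)
  cfg <- sim_config(n_families = 20, bins = 10)
  d <- simulate_hier_data(cfg)
  j1 <- hier_auc_json(hier_auc(d, seed = 99))
  j2 <- hier_auc_json(hier_auc(d, seed = 99))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("single-pass tie breaking is available for sparse ties", {
  set.seed(55)
  d <- random_hier_data(20, n_families = 4)
  d$score[2] <- d$score[1]
  fit <- hier_auc(d, ties = "single", seed = 3)
  expect_false(fit$ties$pooled)
  expect_equal(fit$ties$n_tied, 2L)
})
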