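test_that("bivariate normal CDF matches a 1-D quadrature representation", {
  oracle <- function(h, k, r)
    integrate(function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2)),
              -9, h, rel.tol = 1e-12)$value
  set.seed(41)
  for (i in 1:60) {
    h <- runif(1, -3.5, 3.5); k <- runif(1, -3.5, 3.5)
    r <- runif(1, -0.999, 0.999)
    expect_equal(pbvnorm(h, k, r), oracle(h, k, r), tolerance = 1e-10)
  }
  # independence factorization to 1e-10
  h <- seq(-3, 3, by = 0.5)
  expect_equal(pbvnorm(h, rev(h), 0), pnorm(h) * pnorm(rev(h)),
               tolerance = 1e-10)
  # comonotone / antithetic limits
  expect_equal(pbvnorm(0.7, -0.2, 1), pnorm(-0.2))
  expect_equal(pbvnorm(0.7, -0.2, -1), pnorm(0.7) + pnorm(-0.2) - 1)
  expect_error(pbvnorm(0, 0, 1.5), "correlation")
})

test_that("grouped variance equals the literal quadruple-sum oracle", {
  set.seed(42)
  for (i in 1:40) {
    d <- random_hier_data(sample(6:16, 1), n_families = sample(2:4, 1),
                          max_persons = sample(1:3, 1))
    mu <- runif(1, -0.5, 1.5)
    rho_s <- runif(1, 0, 0.95)
    rho_f <- runif(1, 0, rho_s)
    m <- shift_model(mu, rho_s, rho_f)
    expect_equal(theta3_variance(d, m), theta3_variance_brute(d, m),
                 tolerance = 1e-12)
  }
})

test_that("independent data under the null recover the Wilcoxon variance", {
  for (n in c(8, 14, 30)) {
    ev <- rep(c(0, 1), length.out = n)
    d <- hier_data(data.frame(family = seq_len(n), person = 1, subunit = 1,
                              score = seq_len(n) / n, event = ev))
    Fn <- sum(ev); Gn <- n - Fn
    m <- shift_model(0, 0.6, 0.2)  # correlations are irrelevant across families
    expect_equal(theta3_variance(d, m), (Fn + Gn + 1) / (12 * Fn * Gn),
                 tolerance = 1e-12)
  }
})

test_that("one person per family reduces to a two-level evaluation", {
  set.seed(43)
  d <- random_hier_data(18, n_families = 6, max_persons = 1)
  expect_equal(auc_decomposition(d)$nB, 0)
  m1 <- shift_model(0.5, 0.7, 0.35)
  m2 <- shift_model(0.5, 0.7, 0.0)
  # with no between-person-within-family pairs, rho_f cannot enter
  expect_equal(theta3_variance(d, m1), theta3_variance(d, m2),
               tolerance = 1e-14)
  # relabeling persons as their own families with rho_s as the cluster
  # correlation is the same model
  d2 <- d
  d2$family <- paste(d$family, d$person)
  expect_equal(theta3_variance(d2, m1), theta3_variance(d, m1),
               tolerance = 1e-14)
})

test_that("variance is positive and shrinks with the number of families", {
  set.seed(44)
  m <- shift_model(0.474, 0.8, 0.5)
  v <- vapply(c(10, 40, 160), function(I) {
    d <- simulate_hier_data(sim_config(n_families = I))
    zd <- d; zd$score <- probit_transform(d$score)$z
    theta3_variance(zd, m)
  }, numeric(1))
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
})
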