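test_that("single-person dataset gives the within-person AUC", {
  d <- hier_data(data.frame(family = 1, person = 1, subunit = 1:2,
                            score = c(1, 2), event = c(0, 1)))
  dec <- auc_decomposition(d)
  expect_equal(dec$A, 1)
  expect_equal(dec$nA, 1)
  expect_equal(dec$theta_hat, 1)
})

test_that("two-family worked example decomposes as enumerated", {
  dec <- auc_decomposition(toy_two_family())
  expect_equal(dec$theta_hat, 3 / 4)
  expect_equal(unname(component_aucs(dec)),
               c(1 / 2, NA, 1))
  expect_equal(dec$nA + dec$nB + dec$nC, dec$F * dec$G)
})

test_that("negating scores reflects the estimate about one half", {
  set.seed(21)
  for (i in 1:10) {
    d <- random_hier_data(sample(8:24, 1))
    d2 <- d; d2$score <- -d2$score
    expect_equal(auc_decomposition(d2)$theta_hat,
                 1 - auc_decomposition(d)$theta_hat)
  }
})

test_that("swapping event labels and negating scores leaves the estimate unchanged", {
  set.seed(22)
  for (i in 1:10) {
    d <- random_hier_data(sample(8:24, 1))
    d2 <- d; d2$score <- -d2$score; d2$event <- 1L - d2$event
    expect_equal(auc_decomposition(d2)$theta_hat,
                 auc_decomposition(d)$theta_hat)
  }
})

test_that("rank-based counting equals the literal double sum", {
  set.seed(23)
  for (i in 1:30) {
    d <- random_hier_data(sample(6:30, 1), n_families = sample(2:5, 1),
                          max_persons = sample(1:3, 1))
    dec <- auc_decomposition(d)
    ref <- brute_decomposition(d)
    expect_equal(dec[c("A", "B", "C", "nA", "nB", "nC", "theta_hat")],
                 ref[c("A", "B", "C", "nA", "nB", "nC", "theta_hat")])
  }
})

test_that("shift model reproduces the default-parameterization constants", {
  m <- shift_model(mu = 1.5 / sqrt(10), rho_s = 0.8, rho_f = 0.5)
  expect_equal(round(m$mu, 3), 0.474)
  expect_equal(round(m$theta_s, 3), 0.773)
  expect_equal(round(m$theta_f, 3), 0.682)
  expect_equal(round(m$theta, 3), 0.631)
})

test_that("fitting the shift model inverts the component AUCs exactly", {
  mu <- 1.5 / sqrt(10)
  dec <- list(A = NA, B = NA, C = NA, nA = 100, nB = 100, nC = 100)
  dec$A <- 100 * pnorm(mu / sqrt(2 * 0.2))
  dec$B <- 100 * pnorm(mu / sqrt(2 * 0.5))
  dec$C <- 100 * pnorm(mu / sqrt(2))
  class(dec) <- "auc_decomposition"
  m <- fit_shift_model(dec)
  expect_equal(m$mu, mu, tolerance = 1e-12)
  expect_equal(m$rho_s, 0.8, tolerance = 1e-12)
  expect_equal(m$rho_f, 0.5, tolerance = 1e-12)
})

test_that("degenerate or strained components are boundary-handled", {
  dec <- list(A = 40, B = 50, C = 70, nA = 100, nB = 100, nC = 100)
  class(dec) <- "auc_decomposition"
  expect_warning(m <- fit_shift_model(dec), "wrong side")
  expect_equal(m$rho_s, 0)  # clipped into the parameter space
  expect_equal(m$rho_f, 0)
  dec$nC <- 0
  expect_error(fit_shift_model(dec), "between-family")
  dec2 <- list(A = 98, B = 90, C = 100, nA = 100, nB = 100, nC = 100)
  class(dec2) <- "auc_decomposition"
  expect_warning(m2 <- fit_shift_model(dec2), "boundary")
  expect_equal(m2$mu, sqrt(2) * qnorm(1 - 1 / 200))
})

test_that("a zero shift implies component AUCs of one half", {
  m <- shift_model(0, 0.8, 0.5)
  expect_equal(c(m$theta_s, m$theta_f, m$theta), rep(0.5, 3))
  expect_equal(expected_auc(m, list(within_person = 3, between_person = 7,
                                    total = 50)), 0.5)
})

test_that("composite expectation matches the balanced-design value", {
  m <- shift_model(1.5 / sqrt(10), 0.8, 0.5)
  e <- expected_auc(m, list(within_person = 20, between_person = 40,
                            total = 1600))
  expect_equal(round(e, 3), 0.634)
  # weights collapse: single family, single person
  expect_equal(expected_auc(m, list(within_person = 6, between_person = 0,
                                    total = 6)), m$theta_s)
})

test_that("composite expectation is monotone in each component AUC", {
  w <- list(within_person = 10, between_person = 20, total = 100)
  base <- expected_auc(shift_model(0.4, 0.6, 0.3), w)
  expect_gt(expected_auc(shift_model(0.5, 0.6, 0.3), w), base)  # all thetas up
  m2 <- shift_model(0.4, 0.7, 0.3)   # only theta_s up
  expect_gt(expected_auc(m2, w), base)
  m3 <- shift_model(0.4, 0.6, 0.4)   # only theta_f up
  expect_gt(expected_auc(m3, w), base)
})

test_that("realized pair-count weights agree with the composite expectation on data", {
  set.seed(24)
  d <- random_hier_data(24, n_families = 4, max_persons = 3)
  m <- shift_model(0.5, 0.7, 0.4)
  pc <- pair_counts(d)
  dec <- auc_decomposition(d)
  manual <- (m$theta_s * dec$nA + m$theta_f * dec$nB + m$theta * dec$nC) /
    (dec$F * dec$G)
  expect_equal(expected_auc(m, pc), manual)
})
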