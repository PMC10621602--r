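# Variance of the three-level Mann-Whitney AUC estimator.
#
# Each discordant (nonevent a, event b) comparison has indicator
# I = 1(Z_a < Z_b) = 1(D > 0) with D = Z_b - Z_a ~ N(mu, 2(1 - rho_ab)),
# rho_ab in {rho_s, rho_f, 0} by the relationship of a and b.  For a pair of
# comparisons, (D1, D2) is bivariate normal with
#   cov(D1, D2) = r(b1,b2) - r(b1,a2) - r(a1,b2) + r(a1,a2),
# where r(x,y) is 1 for the same subunit, rho_s for two subunits of one
# person, rho_f for two persons of one family, and 0 across families.  So
#   Cov(I1, I2) = P(D1 > 0, D2 > 0) - theta_{L1} theta_{L2},
# nonzero only when the two comparisons share a family.  VAR(theta3_hat) is
# the sum over all ordered pairs of comparisons divided by (FG)^2.
#
# The production evaluator groups the (FG)^2 ordered pairs into 25
# relationship classes whose counts are polynomial identities in the
# per-person counts {f_p, g_p}; the bivariate normal CDF is evaluated once
# per class.  theta3_variance_brute() is the literal double sum, kept as the
# arbiter of correctness for the grouping (equality to 1e-10 is asserted in
# the test suite on randomized small datasets).

# per-family aggregates of per-person counts
.var_aggregates <- function(f_p, g_p, person_fam) {
  agg <- function(x) as.vector(rowsum(x, person_fam))
  f_i    <- agg(f_p)
  g_i    <- agg(g_p)
  list(
    f_i = f_i, g_i = g_i,
    sfg    = agg(f_p * g_p),
    sfsq   = agg(f_p^2),
    sgsq   = agg(g_p^2),
    sff2   = agg(f_p * (f_p - 1)),
    sgg2   = agg(g_p * (g_p - 1)),
    sgff2  = agg(g_p * f_p * (f_p - 1)),
    sfgg2  = agg(f_p * g_p * (g_p - 1)),
    sffg   = agg(f_p^2 * g_p),
    sggf   = agg(g_p^2 * f_p),
    sfgsq  = agg((f_p * g_p)^2),
    sff2gg2 = agg(f_p * (f_p - 1) * g_p * (g_p - 1))
  )
}

# class table: level pair, covariance of (D1, D2), ordered-pair count
.variance_classes <- function(f_p, g_p, person_fam, rho_s, rho_f) {
  a <- .var_aggregates(f_p, g_p, person_fam)
  f_i <- a$f_i; g_i <- a$g_i
  Fn <- sum(f_i); Gn <- sum(g_i)
  s <- rho_s; f <- rho_f
  Tgf <- g_i * f_i - a$sfg
  Tff <- f_i^2 - a$sfsq
  Tgg <- g_i^2 - a$sgsq
  # per-person family-aligned vectors
  pf  <- person_fam
  fFam <- f_i[pf]; gFam <- g_i[pf]
  sfsqFam <- a$sfsq[pf]; sgsqFam <- a$sgsq[pf]; sfgFam <- a$sfg[pf]
  EDPff <- (fFam - f_p)^2 - (sfsqFam - f_p^2)  # ordered distinct-person f-pairs excl. p
  EDPgg <- (gFam - g_p)^2 - (sgsqFam - g_p^2)
  # cross-family exclusive ordered pair counts
  Sf2 <- sum(f_i^2); Sg2 <- sum(g_i^2); Sfg_fam <- sum(f_i * g_i)
  EE2x <- (Fn - f_i)^2 - (Sf2 - f_i^2)
  GG2x <- (Gn - g_i)^2 - (Sg2 - g_i^2)
  FG2x <- (Fn - f_i) * (Gn - g_i) - (Sfg_fam - f_i * g_i)
  cross <- function(x, y) sum(x) * sum(y) - sum(x * y)

  lev <- character(0); cov <- numeric(0); cnt <- numeric(0); mult <- numeric(0)
  add <- function(l, cv, n, m = 1) {
    lev <<- c(lev, l); cov <<- c(cov, cv); cnt <<- c(cnt, n); mult <<- c(mult, m)
  }
  # same person, shared subunit on one side
  add("SS", 1 - s, sum(a$sgff2) + sum(a$sfgg2))
  # within-person comparison sharing a subunit with a between-person one
  add("SF", 1 - s, sum(f_p * g_p * (fFam - f_p + gFam - g_p)), 2)
  # within-person comparison sharing a subunit with a between-family one
  add("SX", 1 - s, sum(a$sfg * (Fn - f_i + Gn - g_i)), 2)
  # both between-person, same family
  add("FF", 1 - f,      sum(g_p * EDPff) + sum(f_p * EDPgg))
  add("FF", s - f,      sum(g_p * (g_p - 1) * EDPff) + sum(f_p * (f_p - 1) * EDPgg))
  add("FF", 1 + s - 2 * f,
      sum(g_i * a$sff2 - a$sgff2) + sum(f_i * a$sgg2 - a$sfgg2))
  add("FF", 2 * s - 2 * f, sum(a$sgg2 * a$sff2 - a$sff2gg2))
  add("FF", f - s,
      2 * sum(g_p * f_p * ((fFam - f_p) * (gFam - g_p) - (sfgFam - f_p * g_p))))
  add("FF", 2 * f - 2 * s, sum(a$sfg^2 - a$sfgsq))
  # between-person with between-family
  add("FX", 1 - f, sum(Tgf * (Fn - f_i + Gn - g_i)), 2)
  add("FX", s - f,
      sum((Fn - f_i) * (a$sgg2 * f_i - a$sfgg2) +
          (Gn - g_i) * (g_i * a$sff2 - a$sgff2)), 2)
  add("FX", f - s,
      sum((Fn - f_i) * (g_i * a$sfg - a$sggf) +
          (Gn - g_i) * (f_i * a$sfg - a$sffg)), 2)
  # both between-family, sharing one family on the same role side
  add("XX", 1, sum(g_i * EE2x) + sum(f_i * GG2x))
  add("XX", s, sum(a$sgg2 * EE2x) + sum(a$sff2 * GG2x))
  add("XX", f, sum(Tgg * EE2x) + sum(Tff * GG2x))
  # both between-family, sharing one family on opposite role sides
  add("XX", -s, 2 * sum(a$sfg * FG2x))
  add("XX", -f, 2 * sum(Tgf * FG2x))
  # both between-family, nonevents sharing one family and events another
  add("XX", 1 + s, cross(g_i, a$sff2) + cross(a$sgg2, f_i))
  add("XX", 1 + f, cross(g_i, Tff) + cross(Tgg, f_i))
  add("XX", 2 * s, cross(a$sgg2, a$sff2))
  add("XX", s + f, cross(a$sgg2, Tff) + cross(Tgg, a$sff2))
  add("XX", 2 * f, cross(Tgg, Tff))
  # both between-family, each comparison straddling the two shared families
  add("XX", -2 * s, cross(a$sfg, a$sfg))
  add("XX", -s - f, 2 * (sum(a$sfg) * sum(Tgf) - sum(a$sfg * Tgf)))
  add("XX", -2 * f, cross(Tgf, Tgf))

  data.frame(lev = lev, cov = cov, count = cnt * mult)
}

.theta3_var_impl <- function(f_p, g_p, person_fam, mu, rho_s, rho_f) {
  Fn <- sum(f_p); Gn <- sum(g_p)
  if (Fn == 0 || Gn == 0) stop("no discordant pairs: variance undefined")
  sd_of <- c(S = sqrt(2 * (1 - rho_s)), F = sqrt(2 * (1 - rho_f)), X = sqrt(2))
  th_of <- pnorm(mu / sd_of)
  cl <- .variance_classes(f_p, g_p, person_fam, rho_s, rho_f)
  cl <- cl[cl$count > 0 & cl$cov != 0, , drop = FALSE]
  acc <- 0
  if (nrow(cl)) {
    l1 <- substr(cl$lev, 1, 1); l2 <- substr(cl$lev, 2, 2)
    sd1 <- sd_of[l1]; sd2 <- sd_of[l2]
    rho <- cl$cov / (sd1 * sd2)
    if (any(abs(rho) > 1 + 1e-10))
      stop("internal error: comparison-pair correlation outside [-1, 1]")
    rho <- pmin(1, pmax(-1, rho))
    p11 <- pbvnorm(mu / sd1, mu / sd2, rho)
    acc <- sum(cl$count * (p11 - th_of[l1] * th_of[l2]))
  }
  # identical comparisons: Cov(I, I) = theta_level (1 - theta_level)
  nA <- sum(f_p * g_p)
  f_i <- as.vector(rowsum(f_p, person_fam))
  g_i <- as.vector(rowsum(g_p, person_fam))
  nB <- sum(f_i * g_i) - nA
  nC <- Fn * Gn - nA - nB
  diag_term <- nA * th_of["S"] * (1 - th_of["S"]) +
    nB * th_of["F"] * (1 - th_of["F"]) +
    nC * th_of["X"] * (1 - th_of["X"])
  v <- (acc + diag_term) / (Fn * Gn)^2
  if (v < -1e-12) stop("internal error: negative variance")
  max(unname(v), 0)
}

#' Closed-form variance of the three-level AUC estimator
#'
#' Evaluates \eqn{VAR(\hat\theta_3)} under the probit location-shift working
#' model by summing the covariance of concordance indicators over all ordered
#' pairs of discordant comparisons, grouped into relationship classes whose
#' counts are polynomial identities in the per-person event/nonevent counts
#' (one bivariate normal CDF evaluation per class).
#'
#' @param data a [hier_data] object.
#' @param model a [shift_model] with the plug-in \eqn{(\mu, \rho_s, \rho_f)};
#'   typically [fit_shift_model()] applied to the decomposition of the
#'   probit-transformed data.
#' @return The variance, a nonnegative scalar.
#' @seealso [theta3_variance_brute()] for the literal double-sum reference
#'   evaluator, [hier_auc()] for the full pipeline.
#' @export
theta3_variance <- function(data, model) {
  idx <- .index_data(data)
  .theta3_var_impl(idx$f_p, idx$g_p, idx$person_fam,
                   model$mu, model$rho_s, model$rho_f)
}

#' Brute-force reference variance (literal quadruple sum)
#'
#' Literal \eqn{O((FG)^2)} evaluation of the same variance: enumerates every
#' ordered pair of discordant comparisons, derives the covariance of the two
#' indicator variables from the pairwise relationships of the four subunits,
#' and sums.  Exponential in cost; intended for validating
#' [theta3_variance()] on small datasets, which the test suite does.
#'
#' @inheritParams theta3_variance
#' @return The variance, a nonnegative scalar.
#' @export
theta3_variance_brute <- function(data, model) {
  idx <- .index_data(data)
  mu <- model$mu; s <- model$rho_s; f <- model$rho_f
  ne <- which(data$event == 0L); ev <- which(data$event == 1L)
  if (!length(ne) || !length(ev)) stop("no discordant pairs")
  cmp <- expand.grid(a = ne, b = ev)  # all discordant comparisons
  rel <- function(x, y) {  # pairwise covariance of transformed scores
    ifelse(x == y, 1,
           ifelse(idx$pid[x] == idx$pid[y], s,
                  ifelse(idx$fam[x] == idx$fam[y], f, 0)))
  }
  m <- nrow(cmp)
  pr <- expand.grid(c1 = seq_len(m), c2 = seq_len(m))
  a1 <- cmp$a[pr$c1]; b1 <- cmp$b[pr$c1]
  a2 <- cmp$a[pr$c2]; b2 <- cmp$b[pr$c2]
  var1 <- 2 - 2 * rel(a1, b1)  # a and b are always distinct subunits
  var2 <- 2 - 2 * rel(a2, b2)
  cv <- rel(b1, b2) - rel(b1, a2) - rel(a1, b2) + rel(a1, a2)
  sd1 <- sqrt(var1); sd2 <- sqrt(var2)
  rho <- pmin(1, pmax(-1, cv / (sd1 * sd2)))
  # identical comparisons: D1 = D2 exactly, so rho is structurally 1 (the
  # float ratio can land an ulp below, where the CDF's rho-derivative is
  # unbounded)
  rho[a1 == a2 & b1 == b2] <- 1
  p11 <- pbvnorm(mu / sd1, mu / sd2, rho)
  th1 <- pnorm(mu / sd1); th2 <- pnorm(mu / sd2)
  sum(p11 - th1 * th2) / m^2
}
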