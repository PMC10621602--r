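# Extended Mann-Whitney AUC for three-level data: the A/B/C decomposition of
# concordant discordant pairs (within person / within family between persons /
# between families), component AUCs, and the probit location-shift working
# model (mu, rho_s, rho_f) with its implied component AUCs
# theta_s = Phi(mu / sqrt(2 (1 - rho_s))), theta_f, theta.

# integer indexing of a hier_data table: family and person indices per
# record, person -> family map, per-person and per-family event counts
.index_data <- function(data) {
  fam <- match(data$family, unique(data$family))
  pkey <- paste(fam, data$person, sep = "\r")
  pid <- match(pkey, unique(pkey))
  first <- !duplicated(pid)
  person_fam <- fam[first][order(pid[first])]
  f_p <- as.vector(rowsum(data$event, pid))
  g_p <- as.vector(rowsum(1L - data$event, pid))
  list(fam = fam, pid = pid, person_fam = person_fam, f_p = f_p, g_p = g_p,
       F = sum(f_p), G = sum(g_p))
}

# concordance counts on tie-free scores, given integer indices
.count_abc <- function(fam, pid, score, event, idx) {
  Fn <- idx$F; Gn <- idx$G
  r <- rank(score)
  U <- sum(r[event == 1]) - Fn * (Fn + 1) / 2  # all concordant discordant pairs
  A <- 0; B <- 0
  f_i <- as.vector(rowsum(idx$f_p, idx$person_fam))
  g_i <- as.vector(rowsum(idx$g_p, idx$person_fam))
  mixed <- which(f_i > 0 & g_i > 0)
  if (length(mixed)) {
    by_fam <- split(seq_along(fam), fam)
    for (i in mixed) {
      ii <- by_fam[[i]]
      ev <- event[ii] == 1L
      s_ne <- score[ii][!ev]; s_ev <- score[ii][ev]
      p_ne <- pid[ii][!ev];   p_ev <- pid[ii][ev]
      conc <- outer(s_ne, s_ev, "<")
      same <- outer(p_ne, p_ev, "==")
      A <- A + sum(conc & same)
      B <- B + sum(conc) - sum(conc & same)
    }
  }
  nA <- sum(idx$f_p * idx$g_p)
  nB <- sum(f_i * g_i) - nA
  nC <- Fn * Gn - nA - nB
  list(A = A, B = B, C = U - A - B, nA = nA, nB = nB, nC = nC,
       f_i = f_i, g_i = g_i)
}

#' Extended Mann-Whitney AUC and its three-level decomposition
#'
#' Counts concordances over every discordant (nonevent, event) subunit pair,
#' split by the relationship of the two subunits: `A` within the same person,
#' `B` between persons of the same family, `C` between families, with
#' denominators `nA`, `nB`, `nC` (`nA + nB + nC = F * G`).  The point
#' estimate is \eqn{\hat\theta_3 = (A + B + C) / (F G)}.  The rank-sum
#' shortcut used for the between-family count equals the literal double sum
#' over all pairs (verified exhaustively in the test suite).
#'
#' @param data a [hier_data] object (or data.frame with its columns) with
#'   tie-free scores; route tied data through `hier_auc(ties = "pool")`.
#' @return An object of class `"auc_decomposition"`: a list with `A`, `B`,
#'   `C`, `nA`, `nB`, `nC`, `theta_hat`, `F`, `G`.
#' @seealso [component_aucs()], [fit_shift_model()], [hier_auc()]
#' @export
auc_decomposition <- function(data) {
  if (anyDuplicated(data$score))
    stop("tied scores; use hier_auc(ties = \"pool\") or jitter_ties()")
  idx <- .index_data(data)
  if (idx$F == 0 || idx$G == 0)
    stop("AUC undefined: need at least one event and one nonevent subunit")
  cnt <- .count_abc(idx$fam, idx$pid, data$score, data$event, idx)
  out <- list(A = cnt$A, B = cnt$B, C = cnt$C,
              nA = cnt$nA, nB = cnt$nB, nC = cnt$nC,
              theta_hat = (cnt$A + cnt$B + cnt$C) / (idx$F * idx$G),
              F = idx$F, G = idx$G)
  class(out) <- "auc_decomposition"
  out
}

#' @export
print.auc_decomposition <- function(x, ...) {
  cat("Three-level Mann-Whitney AUC decomposition\n")
  cat(sprintf("  within person:          %d / %d\n", x$A, x$nA))
  cat(sprintf("  within family, between: %d / %d\n", x$B, x$nB))
  cat(sprintf("  between families:       %d / %d\n", x$C, x$nC))
  cat(sprintf("  theta3_hat = %.4f  (F = %d events, G = %d nonevents)\n",
              x$theta_hat, x$F, x$G))
  invisible(x)
}

#' Component AUCs of the decomposition
#'
#' @param dec an [auc_decomposition] object.
#' @return Named numeric vector `c(within_person, between_person,
#'   between_family)` of `A/nA`, `B/nB`, `C/nC`; components with a zero
#'   denominator are `NA`.
#' @export
component_aucs <- function(dec) {
  c(within_person  = if (dec$nA > 0) dec$A / dec$nA else NA_real_,
    between_person = if (dec$nB > 0) dec$B / dec$nB else NA_real_,
    between_family = if (dec$nC > 0) dec$C / dec$nC else NA_real_)
}

#' Probit location-shift model for transformed scores
#'
#' Container for the working model under which transformed nonevent scores
#' are N(0, 1) and event scores N(\eqn{\mu}, 1), with exchangeable
#' correlations \eqn{\rho_s} (two subunits of one person) and \eqn{\rho_f}
#' (subunits of two persons in one family).  The implied component AUCs are
#' \eqn{\theta_s = \Phi(\mu/\sqrt{2(1-\rho_s)})},
#' \eqn{\theta_f = \Phi(\mu/\sqrt{2(1-\rho_f)})} and
#' \eqn{\theta = \Phi(\mu/\sqrt{2})}.
#'
#' @param mu location shift of transformed event scores.
#' @param rho_s,rho_f within-person and within-family correlations in
#'   \eqn{[0, 1)}.
#' @return An object of class `"shift_model"` with fields `mu`, `rho_s`,
#'   `rho_f`, `theta_s`, `theta_f`, `theta`.
#' @export
shift_model <- function(mu, rho_s, rho_f) {
  stopifnot(is.finite(mu), rho_s >= 0, rho_s < 1, rho_f >= 0, rho_f < 1)
  out <- list(mu = mu, rho_s = rho_s, rho_f = rho_f,
              theta_s = pnorm(mu / sqrt(2 * (1 - rho_s))),
              theta_f = pnorm(mu / sqrt(2 * (1 - rho_f))),
              theta   = pnorm(mu / sqrt(2)))
  class(out) <- "shift_model"
  out
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf(
    "Probit shift model: mu = %.4f, rho_s = %.4f, rho_f = %.4f\n",
    x$mu, x$rho_s, x$rho_f))
  cat(sprintf("  implied AUCs: theta_s = %.4f, theta_f = %.4f, theta = %.4f\n",
              x$theta_s, x$theta_f, x$theta))
  invisible(x)
}

# invert a component AUC for its correlation given mu:
# comp = Phi(mu / sqrt(2 (1 - rho)))  =>  rho = 1 - mu^2 / (2 qnorm(comp)^2)
.rho_from_component <- function(comp, mu, label) {
  if (is.na(comp)) return(NA_real_)
  if (mu == 0) return(0)
  q <- qnorm(comp)
  if (q * mu < 0) {
    warning("component AUC ", label, " on the wrong side of 0.5 for the ",
            "fitted shift; correlation clipped to 0")
    return(0)
  }
  rho <- if (is.infinite(q)) 1 else 1 - mu^2 / (2 * q^2)
  # a component AUC between 0.5 and the between-family AUC implies a
  # (sampling-noise) negative correlation; clip to the parameter space
  min(max(rho, 0), 1 - 1e-6)
}

#' Fit the shift model from the AUC decomposition
#'
#' Method-of-moments fit through the probit link: the between-family
#' component AUC identifies the shift, \eqn{\hat\mu = \sqrt 2\,
#' \Phi^{-1}(C/n_C)}, and the within-person and between-person component
#' AUCs are inverted for \eqn{\hat\rho_s} and \eqn{\hat\rho_f}.  Estimated
#' correlations are clipped to \eqn{[0, 1 - 10^{-6}]}; a component AUC on
#' the wrong side of 0.5 relative to \eqn{\hat\mu} (model strain) yields a
#' clipped 0 with a warning.  When a component has no pairs (`nA` or `nB`
#' zero) its correlation falls back to the next coarser level
#' (\eqn{\hat\rho_s \leftarrow \hat\rho_f}, \eqn{\hat\rho_f \leftarrow 0}).
#'
#' @param dec an [auc_decomposition] object with `nC > 0`.  A between-family
#'   component AUC of exactly 0 or 1 is truncated half a pair inward with a
#'   warning before inversion.
#' @return A [shift_model] object.
#' @export
fit_shift_model <- function(dec) {
  if (dec$nC <= 0)
    stop("no between-family discordant pairs; shift not identifiable")
  cmp <- component_aucs(dec)
  theta_c <- cmp[["between_family"]]
  if (theta_c <= 0 || theta_c >= 1) {
    # boundary component: truncate half a pair inward so the probit inverse
    # stays finite
    warning("between-family component AUC on the boundary (", theta_c,
            "); truncated by half a pair")
    eps <- 1 / (2 * dec$nC)
    theta_c <- min(max(theta_c, eps), 1 - eps)
  }
  mu <- sqrt(2) * qnorm(theta_c)
  rho_f <- .rho_from_component(cmp[["between_person"]], mu, "B/nB")
  rho_s <- .rho_from_component(cmp[["within_person"]], mu, "A/nA")
  if (is.na(rho_f)) rho_f <- 0
  if (is.na(rho_s)) rho_s <- rho_f
  # nesting implies at least as much correlation within person
  if (rho_s < rho_f) rho_s <- rho_f
  shift_model(mu, rho_s, rho_f)
}

#' Composite expectation of the three-level AUC estimator
#'
#' The expectation of \eqn{\hat\theta_3} is a weighted average of the three
#' component AUCs, with weights equal to the numbers of within-person,
#' within-family between-person, and between-family discordant pairs:
#' \deqn{E(\hat\theta_3) = \frac{\theta_s w_s + \theta_f w_f +
#'   \theta\,(FG - w_s - w_f)}{FG}.}
#'
#' @param model a [shift_model] object.
#' @param weights either the result of [pair_counts()] (realized integer
#'   weights are derived from it) or a list with elements `within_person`
#'   (\eqn{w_s}), `between_person` (\eqn{w_f}) and `total` (\eqn{FG}); the
#'   latter form admits non-integer expected weights.
#' @return The expectation, a scalar in \eqn{[0, 1]}.
#' @export
expected_auc <- function(model, weights) {
  if (!is.null(weights$persons)) {
    p <- weights$persons
    w_s <- sum(p$f * p$g)
    fam_f <- rowsum(p$f, p$family); fam_g <- rowsum(p$g, p$family)
    w_f <- sum(fam_f * fam_g) - w_s
    total <- weights$F * weights$G
  } else {
    w_s <- weights$within_person
    w_f <- weights$between_person
    total <- weights$total
  }
  if (total <= 0) stop("no discordant pairs: expectation undefined")
  (model$theta_s * w_s + model$theta_f * w_f +
      model$theta * (total - w_s - w_f)) / total
}
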