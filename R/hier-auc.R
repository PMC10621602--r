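# Main fitting pipeline: probit transform -> decomposition -> shift model ->
# closed-form variance -> probit-scale delta-method confidence interval,
# with repeated random tie-breaking and Rubin-rules pooling for tied scores.

#' Probit-scale delta-method confidence interval for an AUC
#'
#' Applies the probit transform \eqn{\omega = \Phi^{-1}(\theta)}, propagates
#' the variance by the delta method,
#' \eqn{SE(\omega) = SE(\theta) / \phi(\Phi^{-1}(\theta))}, forms the Wald
#' interval on the \eqn{\omega} scale and back-transforms, which keeps the
#' interval inside \eqn{[0, 1]}.
#'
#' @param theta_hat AUC estimate in \eqn{(0, 1)}.  Estimates exactly 0 or 1
#'   are truncated half a discordant pair from the boundary (requires
#'   `n_pairs`) with a warning.
#' @param var_theta nonnegative variance of the estimate.
#' @param alpha two-sided error rate, default 0.05.
#' @param n_pairs total number of discordant pairs \eqn{F G}, used only for
#'   boundary truncation.
#' @return List with `omega`, `se_omega`, `lower`, `upper`, `alpha`.
#' @export
probit_ci <- function(theta_hat, var_theta, alpha = 0.05, n_pairs = NULL) {
  stopifnot(alpha > 0, alpha < 1, var_theta >= 0)
  if (theta_hat <= 0 || theta_hat >= 1) {
    if (is.null(n_pairs))
      stop("theta_hat on the boundary; supply n_pairs for truncation")
    warning("AUC estimate on the boundary; truncated by half a pair")
    eps <- 1 / (2 * n_pairs)
    theta_hat <- min(max(theta_hat, eps), 1 - eps)
  }
  omega <- qnorm(theta_hat)
  se_omega <- sqrt(var_theta) / dnorm(omega)
  z <- qnorm(1 - alpha / 2)
  list(omega = omega, se_omega = se_omega,
       lower = pnorm(omega - z * se_omega),
       upper = pnorm(omega + z * se_omega),
       alpha = alpha)
}

# single tie-free pass: transform, decompose, fit, variance
.fit_once <- function(data) {
  z <- probit_transform(data$score)$z
  zdata <- data
  zdata$score <- z
  dec <- auc_decomposition(zdata)
  model <- fit_shift_model(dec)
  var_theta <- theta3_variance(zdata, model)
  list(dec = dec, model = model, theta = dec$theta_hat, var_theta = var_theta)
}

#' Dependency-adjusted AUC for three-level hierarchical data
#'
#' Fits the full inference pipeline for the area under the ROC curve with
#' subunits nested in persons nested in families: a rank-preserving probit
#' transformation of the prediction scores, the extended Mann-Whitney point
#' estimate \eqn{\hat\theta_3}, a method-of-moments fit of the probit
#' location-shift working model \eqn{(\mu, \rho_s, \rho_f)}, the closed-form
#' variance built from bivariate-normal concordance probabilities, and a
#' delta-method confidence interval on the probit scale.
#'
#' Tied prediction scores cannot enter the pipeline directly.  With
#' `ties = "pool"` (the default resolution under `"auto"` when ties are
#' present), each of `L` iterations breaks ties by a uniform jitter on
#' \eqn{(-\Delta, \Delta)}, runs the pipeline, and the results are pooled by
#' Rubin's rules: \eqn{\hat\theta_3^* = \bar\theta_\ell},
#' \eqn{\omega_3^* = \bar\omega_\ell}, and
#' \eqn{VAR^* = \overline{VAR_\ell} + (1 + 1/L)\, B} with \eqn{B} the
#' between-iteration variance of \eqn{\hat\theta_\ell}.
#'
#' @param data a [hier_data] object, or a data.frame from which one is built
#'   using the column names below.
#' @param family,person,subunit,score,event column names, used when `data`
#'   is not already a `hier_data`.
#' @param alpha two-sided error rate for the confidence interval.
#' @param ties one of `"auto"` (pool when ties are present, single pass
#'   otherwise), `"pool"`, `"single"` (one random tie-break), `"error"`.
#' @param L number of tie-breaking iterations for pooling (\eqn{\ge 2}).
#' @param delta jitter half-width; default [default_tie_delta()].
#' @param seed optional integer seed governing the tie-breaking draws.
#' @return An object of class `"hier_auc"`; see [print.hier_auc()],
#'   [summary.hier_auc()], [coef.hier_auc()], [confint.hier_auc()],
#'   [vcov.hier_auc()].
#' @examples
#' d <- simulate_hier_data(sim_config(n_families = 30), seed = 1)
#' fit <- hier_auc(d)
#' fit
#' confint(fit)
#' @export
hier_auc <- function(data, family = "family", person = "person",
                     subunit = "subunit", score = "score", event = "event",
                     alpha = 0.05, ties = c("auto", "pool", "single", "error"),
                     L = 10, delta = NULL, seed = NULL) {
  ties <- match.arg(ties)
  if (!inherits(data, "hier_data"))
    data <- hier_data(data, family = family, person = person,
                      subunit = subunit, score = score, event = event)
  n_tied <- sum(data$score %in% data$score[duplicated(data$score)])
  has_ties <- n_tied > 0
  if (has_ties && ties == "error")
    stop(n_tied, " records have tied scores; use ties = \"pool\"")
  if (is.null(delta)) delta <- default_tie_delta(data$score)
  if (!is.null(seed)) set.seed(seed)

  pooled <- has_ties && ties %in% c("auto", "pool")
  if (pooled && L < 2) stop("pooled tie-breaking requires L >= 2")

  if (!has_ties) {
    one <- .fit_once(data)
    theta <- one$theta; var_theta <- one$var_theta
    omega <- qnorm(theta)
    model <- one$model; dec <- one$dec
    tie_info <- list(pooled = FALSE, n_tied = 0L, L = 1L, delta = delta,
                     within_var = var_theta, between_var = 0,
                     theta_iter = theta)
  } else if (!pooled) {             # ties == "single"
    data2 <- data
    data2$score <- jitter_ties(data$score, delta)
    one <- .fit_once(data2)
    theta <- one$theta; var_theta <- one$var_theta
    omega <- qnorm(theta)
    model <- one$model; dec <- one$dec
    tie_info <- list(pooled = FALSE, n_tied = n_tied, L = 1L, delta = delta,
                     within_var = var_theta, between_var = 0,
                     theta_iter = theta)
  } else {
    th <- om <- vr <- mu <- rs <- rf <- numeric(L)
    dec <- NULL
    for (l in seq_len(L)) {
      data2 <- data
      data2$score <- jitter_ties(data$score, delta)
      one <- .fit_once(data2)
      th[l] <- one$theta; om[l] <- qnorm(one$theta); vr[l] <- one$var_theta
      mu[l] <- one$model$mu; rs[l] <- one$model$rho_s; rf[l] <- one$model$rho_f
      if (is.null(dec)) dec <- one$dec
    }
    theta <- mean(th)
    omega <- mean(om)
    within <- mean(vr)
    between <- sum((th - theta)^2) / (L - 1)
    var_theta <- within + (1 + 1 / L) * between
    model <- shift_model(mean(mu), mean(rs), mean(rf))
    tie_info <- list(pooled = TRUE, n_tied = n_tied, L = L, delta = delta,
                     within_var = within, between_var = between,
                     theta_iter = th)
  }

  z <- qnorm(1 - alpha / 2)
  se_omega <- sqrt(var_theta) / dnorm(omega)
  ci <- c(lower = pnorm(omega - z * se_omega),
          upper = pnorm(omega + z * se_omega))
  pc <- pair_counts(data)
  out <- list(theta = theta, var_theta = var_theta,
              omega = omega, se_omega = se_omega, ci = ci, alpha = alpha,
              decomposition = dec, shift = model, counts = pc,
              ties = tie_info,
              n = c(subunits = nrow(data), persons = nrow(pc$persons),
                    families = length(unique(data$family))),
              call = match.call())
  class(out) <- "hier_auc"
  out
}

#' @export
print.hier_auc <- function(x, digits = 4, ...) {
  cat("Dependency-adjusted AUC for three-level hierarchical data\n\n")
  cat(sprintf("  AUC (theta3_hat): %.*f\n", digits, x$theta))
  cat(sprintf("  %d%% CI: (%.*f, %.*f)   [probit-scale delta method]\n",
              round(100 * (1 - x$alpha)), digits, x$ci[["lower"]],
              digits, x$ci[["upper"]]))
  cat(sprintf("  %d subunits, %d persons, %d families; F = %d events, G = %d nonevents\n",
              x$n[["subunits"]], x$n[["persons"]], x$n[["families"]],
              x$counts$F, x$counts$G))
  if (x$ties$pooled)
    cat(sprintf("  ties: %d tied records pooled over L = %d tie-breaking iterations\n",
                x$ties$n_tied, x$ties$L))
  invisible(x)
}

#' @rdname print.hier_auc
#' @param object,x a fitted `"hier_auc"` object.
#' @param digits number of digits to print.
#' @param ... unused.
#' @export
summary.hier_auc <- function(object, ...) {
  structure(object, class = c("summary.hier_auc", "hier_auc"))
}

#' @export
print.summary.hier_auc <- function(x, digits = 4, ...) {
  print.hier_auc(x, digits = digits)
  cat(sprintf("\n  VAR(theta3_hat) = %.3e;  omega3 = %.*f (SE %.*f)\n",
              x$var_theta, digits, x$omega, digits, x$se_omega))
  cat("\nShift model (probit scale):\n")
  cat(sprintf("  mu = %.*f, rho_s = %.*f, rho_f = %.*f\n", digits,
              x$shift$mu, digits, x$shift$rho_s, digits, x$shift$rho_f))
  cat(sprintf("  implied component AUCs: theta_s = %.*f, theta_f = %.*f, theta = %.*f\n",
              digits, x$shift$theta_s, digits, x$shift$theta_f,
              digits, x$shift$theta))
  if (!is.null(x$decomposition)) {
    cmp <- component_aucs(x$decomposition)
    cat("\nObserved component AUCs",
        if (x$ties$pooled) " (first tie-breaking iteration)", ":\n", sep = "")
    cat(sprintf("  within person %s, between person %s, between family %s\n",
                formatC(cmp[1], digits = digits, format = "f"),
                formatC(cmp[2], digits = digits, format = "f"),
                formatC(cmp[3], digits = digits, format = "f")))
  }
  if (x$ties$pooled)
    cat(sprintf("\nTie pooling: within-variance %.3e, between-variance %.3e (x %.2f)\n",
                x$ties$within_var, x$ties$between_var, 1 + 1 / x$ties$L))
  invisible(x)
}

#' @rdname print.hier_auc
#' @export
coef.hier_auc <- function(object, ...) c(theta3 = object$theta)

#' @rdname print.hier_auc
#' @param parm,level standard [stats::confint()] arguments; the single
#'   parameter is the AUC and `level` overrides the fitted `alpha`.
#' @export
confint.hier_auc <- function(object, parm = "theta3", level = 1 - object$alpha,
                             ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pnorm(object$omega + c(-1, 1) * z * object$se_omega)
  m <- matrix(ci, nrow = 1,
              dimnames = list("theta3",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' @rdname print.hier_auc
#' @export
vcov.hier_auc <- function(object, ...) {
  matrix(object$var_theta, 1, 1, dimnames = list("theta3", "theta3"))
}

#' JSON report of a fitted hierarchical AUC
#'
#' Serializes the quantities a downstream consumer needs: the estimate,
#' variance, confidence interval, fitted shift model, pair counts and tie
#' diagnostics.
#'
#' @param fit a [hier_auc] object.
#' @param pretty passed to [jsonlite::toJSON()].
#' @return A JSON string (class `json`).
#' @export
hier_auc_json <- function(fit, pretty = TRUE) {
  jsonlite::toJSON(list(
    theta_hat = fit$theta,
    var_theta = fit$var_theta,
    ci = unname(fit$ci),
    alpha = fit$alpha,
    mu = fit$shift$mu, rho_s = fit$shift$rho_s, rho_f = fit$shift$rho_f,
    theta_s = fit$shift$theta_s, theta_f = fit$shift$theta_f,
    theta = fit$shift$theta,
    F = fit$counts$F, G = fit$counts$G,
    n = as.list(fit$n),
    ties = fit$ties[c("pooled", "n_tied", "L", "delta", "within_var",
                      "between_var")]
  ), auto_unbox = TRUE, digits = NA, pretty = pretty)
}
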