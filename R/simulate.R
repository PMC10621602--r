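# Monte Carlo harness: three-level clustered prediction scores from a nested
# random-intercept model, scenario modifiers (binning into quantile bins,
# census-distributed family sizes, random subunit deletion, additive
# measurement error), and replication loops reporting bias, variance
# calibration and confidence-interval coverage.

#' Simulation configuration
#'
#' Describes one parameterization of the score-generating model
#' \deqn{Y_{ijk} = B_1\,\mathrm{event}_{ijk} + u_i + v_{ij} + e_{ijk},}
#' with independent zero-mean normal random intercepts for family
#' (\eqn{u_i}), person (\eqn{v_{ij}}) and a subunit residual
#' (\eqn{e_{ijk}}), and event status Bernoulli(prevalence) independently per
#' subunit.  The default variance components (5, 3, 2) with \eqn{B_1 = 1.5}
#' imply intra-class correlations \eqn{\rho_s = 0.80} at the subunit level
#' and \eqn{\rho_f = 0.50} at the person level, and a probit shift
#' \eqn{\mu = B_1/\sqrt{10} = 0.474}.
#'
#' @param n_families number of families (the independent units).
#' @param persons persons per family, or `"census"` to draw each family's
#'   size from the 2012 US census child-count distribution
#'   ([census_family_sizes()]).
#' @param subunits subunits per person.
#' @param prevalence event probability per subunit.
#' @param b1 fixed effect of event status on the score.
#' @param var_family,var_person,var_subunit variance components.
#' @param bins optional number of equal-probability quantile bins; binned
#'   scores (bin midpoints) are tied and trigger pooled tie-breaking.
#' @param missing_fraction fraction of persons that lose one randomly chosen
#'   subunit (deleted, not imputed).
#' @param error_sd standard deviation of additive normal measurement error
#'   applied to the scores after generation.
#' @param L tie-breaking iterations used when `bins` produces ties.
#' @return A list of class `"sim_config"`, including the implied true shift
#'   model parameters `mu`, `rho_s`, `rho_f`.
#' @export
sim_config <- function(n_families = 50, persons = 2, subunits = 2,
                       prevalence = 0.5, b1 = 1.5, var_family = 5,
                       var_person = 3, var_subunit = 2, bins = NULL,
                       missing_fraction = 0, error_sd = 0, L = 10) {
  stopifnot(n_families >= 1, subunits >= 1,
            prevalence > 0, prevalence < 1,
            var_family >= 0, var_person >= 0, var_subunit > 0,
            missing_fraction >= 0, missing_fraction <= 1, error_sd >= 0)
  census <- identical(persons, "census")
  if (!census) stopifnot(is.numeric(persons), persons >= 1)
  vtot <- var_family + var_person + var_subunit
  out <- list(n_families = n_families, persons = persons, subunits = subunits,
              prevalence = prevalence, b1 = b1, var_family = var_family,
              var_person = var_person, var_subunit = var_subunit,
              bins = bins, missing_fraction = missing_fraction,
              error_sd = error_sd, L = L, census = census,
              mu = b1 / sqrt(vtot),
              rho_s = (var_family + var_person) / vtot,
              rho_f = var_family / vtot)
  class(out) <- "sim_config"
  out
}

#' Family sizes from the 2012 US census child-count distribution
#'
#' Draws numbers of persons per family from the empirical distribution of
#' children per family (families with children): probabilities 0.48, 0.36,
#' 0.15, 0.03 for 1-4 children.  The reported census probabilities sum to 1.02
#' (the tail beyond 4 is truncated), so they are renormalized.
#'
#' @param n_families number of draws.
#' @param seed optional integer seed.
#' @return Integer vector of family sizes in `1:4`.
#' @export
census_family_sizes <- function(n_families, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(0.48, 0.36, 0.15, 0.03) / 1.02
  sample(1:4, n_families, replace = TRUE, prob = probs)
}

#' Simulate one three-level clustered dataset
#'
#' Generates scores from the nested random-intercept model of the
#' configuration, then applies the scenario modifiers in order: census
#' family sizes, quantile binning (ties), random subunit deletion, additive
#' measurement error.
#'
#' @param config a [sim_config] object.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [hier_data] object.
#' @export
simulate_hier_data <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  I <- config$n_families
  J <- if (config$census) census_family_sizes(I) else rep(config$persons, I)
  K <- config$subunits
  n_persons <- sum(J)
  fam_of_person <- rep(seq_len(I), J)
  fam <- rep(fam_of_person, each = K)
  per <- rep(seq_len(n_persons), each = K)
  sub <- rep(seq_len(K), n_persons)
  n <- length(fam)
  event <- rbinom(n, 1, config$prevalence)
  u <- rnorm(I, 0, sqrt(config$var_family))
  v <- rnorm(n_persons, 0, sqrt(config$var_person))
  e <- rnorm(n, 0, sqrt(config$var_subunit))
  y <- config$b1 * event + u[fam] + v[per] + e
  if (!is.null(config$bins)) {
    brk <- quantile(y, probs = seq(0, 1, length.out = config$bins + 1),
                    names = FALSE)
    bin <- findInterval(y, brk, rightmost.closed = TRUE, all.inside = TRUE)
    y <- (brk[bin] + brk[bin + 1]) / 2
  }
  keep <- rep(TRUE, n)
  if (config$missing_fraction > 0 && K >= 2) {
    n_miss <- round(config$missing_fraction * n_persons)
    hit <- sample.int(n_persons, n_miss)
    drop_sub <- sample.int(K, n_miss, replace = TRUE)
    keep[match(paste(hit, drop_sub), paste(per, sub))] <- FALSE
  }
  if (config$error_sd > 0) y <- y + rnorm(n, 0, config$error_sd)
  per_label <- seq_len(n_persons) - c(0L, cumsum(J))[fam_of_person]
  hier_data(data.frame(family = fam, person = per_label[per], subunit = sub,
                       score = y, event = event)[keep, , drop = FALSE])
}

#' Expectation of the three-level AUC estimator under a configuration
#'
#' Evaluates the composite expectation with *expected* pair-count weights:
#' within-person weight \eqn{I\,E[J]\,E[K(K-1)]\,\pi(1-\pi)}, between-person
#' weight \eqn{I\,E[J(J-1)]\,E[K]^2\,\pi(1-\pi)} and total
#' \eqn{E[F]\,E[G]}, with moments of \eqn{J} and \eqn{K} taken over the
#' census and subunit-deletion distributions where applicable.  Binning and
#' measurement error do not move this target: they perturb the analyzed
#' scores, and coverage under them measures robustness against the
#' unperturbed expectation.
#'
#' @param config a [sim_config] object.
#' @return The expectation, a scalar.
#' @export
expected_theta3 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$census) {
    probs <- c(0.48, 0.36, 0.15, 0.03) / 1.02
    EJ <- sum((1:4) * probs)
    EJJ1 <- sum((1:4) * (0:3) * probs)
  } else {
    EJ <- config$persons
    EJJ1 <- config$persons * (config$persons - 1)
  }
  K <- config$subunits
  mf <- config$missing_fraction
  EK <- K - mf
  EKK1 <- (1 - mf) * K * (K - 1) + mf * (K - 1) * (K - 2)
  p <- config$prevalence
  I <- config$n_families
  w_s <- I * EJ * EKK1 * p * (1 - p)
  w_f <- I * EJJ1 * EK^2 * p * (1 - p)
  total <- (I * EJ * EK)^2 * p * (1 - p)
  model <- shift_model(config$mu, config$rho_s, config$rho_f)
  expected_auc(model, list(within_person = w_s, between_person = w_f,
                           total = total))
}

#' Parameterizations of the five simulation scenarios
#'
#' Returns the standard parameterization table for a scenario: (1) balanced
#' designs varying families, persons and prevalence; (2) tied scores from
#' quantile binning; (3) census-distributed family sizes; (4) 10% of
#' persons missing one subunit; (5) additive measurement error.
#'
#' @param scenario integer 1-5.
#' @return A data.frame, one row per parameterization, with a list-column
#'   `config` of [sim_config] objects.
#' @export
scenario_settings <- function(scenario) {
  grid <- switch(as.character(scenario),
    "1" = expand.grid(n_families = c(20, 50, 100), persons = c(2, 3),
                      prevalence = c(0.5, 0.25)),
    "2" = expand.grid(n_families = c(20, 50), bins = c(5, 10, 20),
                      prevalence = 0.5),
    "3" = expand.grid(n_families = 50, persons = "census",
                      prevalence = c(0.25, 0.5), stringsAsFactors = FALSE),
    "4" = expand.grid(n_families = 50, persons = c(2, 3),
                      prevalence = c(0.5, 0.25), missing_fraction = 0.1),
    "5" = expand.grid(n_families = 50, persons = c(2, 3), prevalence = 0.5,
                      error_sd = c(0.1, 0.25, 0.5)),
    stop("scenario must be 1..5"))
  grid$config <- lapply(seq_len(nrow(grid)), function(r) {
    args <- as.list(grid[r, setdiff(names(grid), "config"), drop = FALSE])
    args <- lapply(args, function(x) if (is.factor(x)) as.character(x) else x)
    do.call(sim_config, args)
  })
  grid
}

# derive a per-replicate seed below 2^31 from master seed, setting, replicate
.rep_seed <- function(seed, setting, rep) {
  as.integer((as.double(seed %% 100000L) * 1009 + setting * 99991 +
                rep * 7919) %% 2147483647)
}

# analyze one simulated dataset; returns estimate, theoretical variance, CIs
.sim_analyze <- function(d, config, alpha, bootstrap = FALSE) {
  fit <- suppressWarnings(hier_auc(d, alpha = alpha, ties = "auto",
                                   L = config$L))
  dl <- delong_auc(d$score, d$event, alpha = alpha)
  out <- list(theta = fit$theta, var = fit$var_theta, ci = fit$ci, dl_ci = dl$ci)
  if (bootstrap) {
    fams <- unique(d$family)
    by_fam <- split(seq_len(nrow(d)), d$family)
    th <- vapply(seq_len(100), function(b) {
      pick <- sample(fams, length(fams), replace = TRUE)
      idx <- unlist(by_fam[pick], use.names = FALSE)
      # midrank Mann-Whitney proportion (resampling duplicates scores)
      s <- d$score[idx]; ev <- d$event[idx] == 1
      m <- sum(ev); n0 <- sum(!ev)
      if (m == 0 || n0 == 0) return(NA_real_)
      (sum(rank(s)[ev]) - m * (m + 1) / 2) / (m * n0)
    }, numeric(1))
    out$boot_ci <- quantile(th, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                            names = FALSE)
  }
  out
}

#' Run one simulation scenario
#'
#' For each parameterization: simulates `n_reps` datasets, runs the full
#' inference pipeline (with pooled tie-breaking when binning produces ties)
#' and the DeLong comparator on each, and aggregates the mean estimate, the
#' bias against [expected_theta3()], the ratio of the mean theoretical
#' variance to the empirical across-replicate variance, and the empirical
#' coverage of the nominal \eqn{100(1-\alpha)\%} intervals.  Replicates that
#' are degenerate (a single outcome class, or a boundary between-family
#' component) are redrawn and counted.
#'
#' @param scenario integer 1-5, or a data.frame from [scenario_settings()]
#'   (possibly subset) for custom runs.
#' @param n_reps replicates per parameterization.
#' @param seed master seed; replicate seeds are derived from it by a
#'   counter scheme, so results are reproducible and independent of
#'   execution order.
#' @param alpha two-sided error rate of the intervals.
#' @param bootstrap also compute a family-level percentile bootstrap CI
#'   (100 resamples) per replicate and report its coverage.
#' @return A data.frame of class `"sim_report"`, one row per
#'   parameterization, with the aggregate columns described above.
#' @export
run_scenario <- function(scenario, n_reps = 1000, seed = 1, alpha = 0.05,
                         bootstrap = FALSE) {
  settings <- if (is.data.frame(scenario)) scenario
              else scenario_settings(scenario)
  rows <- vector("list", nrow(settings))
  for (s in seq_len(nrow(settings))) {
    cfg <- settings$config[[s]]
    target <- expected_theta3(cfg)
    th <- vr <- numeric(n_reps)
    cov_p <- cov_d <- cov_b <- logical(n_reps)
    n_redraw <- 0L
    for (r in seq_len(n_reps)) {
      set.seed(.rep_seed(seed, s, r))
      res <- NULL
      for (attempt in 1:100) {
        d <- simulate_hier_data(cfg)
        res <- tryCatch(.sim_analyze(d, cfg, alpha, bootstrap),
                        error = function(e) NULL)
        if (!is.null(res)) break
        n_redraw <- n_redraw + 1L
      }
      if (is.null(res)) stop("replicate failed after 100 redraws")
      th[r] <- res$theta; vr[r] <- res$var
      cov_p[r] <- res$ci[1] <= target && target <= res$ci[2]
      cov_d[r] <- res$dl_ci[1] <= target && target <= res$dl_ci[2]
      if (bootstrap)
        cov_b[r] <- !anyNA(res$boot_ci) &&
          res$boot_ci[1] <= target && target <= res$boot_ci[2]
    }
    rows[[s]] <- data.frame(
      families = cfg$n_families,
      persons = if (cfg$census) NA_integer_ else cfg$persons,
      subunits = cfg$subunits, prevalence = cfg$prevalence,
      bins = if (is.null(cfg$bins)) NA_integer_ else cfg$bins,
      missing_fraction = cfg$missing_fraction, error_sd = cfg$error_sd,
      mean_theta = mean(th), expected_theta = target,
      bias = mean(th) - target,
      var_ratio = mean(vr) / var(th),
      coverage = mean(cov_p), coverage_delong = mean(cov_d),
      coverage_boot = if (bootstrap) mean(cov_b) else NA_real_,
      n_reps = n_reps, n_redraws = n_redraw)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sim_report", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
print.sim_report <- function(x, digits = 3, ...) {
  cat("Simulation report (", nrow(x), " parameterizations, ",
      x$n_reps[1], " replicates each)\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf(
    "\nMeans: bias %+.3f, variance ratio %.3f, coverage %.3f (DeLong %.3f)\n",
    mean(x$bias), mean(x$var_ratio), mean(x$coverage),
    mean(x$coverage_delong)))
  invisible(x)
}
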