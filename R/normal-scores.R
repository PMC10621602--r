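# Rank-preserving probit (normal-scores) transformation, and the uniform
# jitter used to break tied prediction scores before transformation.

#' Probit transformation of prediction scores
#'
#' Maps scores to normal scores \eqn{Z = \Phi^{-1}(\hat F(S))}, where
#' \eqn{\hat F} is the pooled empirical distribution function over all
#' records (events and nonevents together) evaluated with the
#' \eqn{\mathrm{rank}/(N+1)} convention, which keeps every transformed value
#' finite.  The transformation is strictly rank-preserving, so any strictly
#' increasing rescaling of the input yields the same normal scores.
#'
#' Ties cannot be transformed (the location-shift working model requires a
#' strict ordering); break them first with [jitter_ties()] or use the pooled
#' tie-breaking pipeline in [hier_auc()].
#'
#' @param scores numeric vector of finite prediction scores with no ties.
#' @return A list with components `z` (normal scores) and `ecdf_value`
#'   (values of \eqn{\hat F(S)} in \eqn{(0,1)}).
#' @examples
#' probit_transform(c(10, 20, 30))$z   # approx c(-0.6745, 0, 0.6745)
#' @export
probit_transform <- function(scores) {
  if (length(scores) == 0) stop("empty score vector")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (anyDuplicated(scores))
    stop("tied scores cannot be probit-transformed; ",
         "break ties first (see jitter_ties or hier_auc(ties = \"pool\"))")
  n <- length(scores)
  u <- rank(scores) / (n + 1)
  list(z = qnorm(u), ecdf_value = u)
}

# decimal resolution of a numeric vector: smallest d <= 8 such that
# round(x, d) reproduces x to within floating tolerance
.decimal_resolution <- function(x) {
  for (d in 0:8) {
    if (max(abs(x - round(x, d))) < 1e-9 * max(1, max(abs(x)))) return(d)
  }
  8L
}

#' Default tie-breaking half-width
#'
#' The default jitter half-width \eqn{\Delta} is one decimal place finer than
#' the detected resolution of the scores, capped at half the smallest nonzero
#' gap between distinct scores so that originally distinct scores can never
#' be reordered.
#'
#' @param scores numeric vector of scores (ties allowed).
#' @return A positive scalar \eqn{\Delta}.
#' @export
default_tie_delta <- function(scores) {
  d <- .decimal_resolution(scores)
  delta <- 10^(-(d + 1))
  gaps <- diff(sort(unique(scores)))
  if (length(gaps)) delta <- min(delta, min(gaps) / 2)
  delta
}

#' Break tied scores by uniform jitter
#'
#' Every score tied with at least one other score receives an independent
#' Uniform\eqn{(-\Delta, \Delta)} perturbation; untied scores are returned
#' unchanged.  On the (measure-zero) event that a tie survives, the affected
#' scores are re-drawn.  With \eqn{\Delta} smaller than half the minimum gap
#' between distinct scores (the default guarantees this) the relative order
#' of originally distinct scores is preserved.
#'
#' @param scores numeric vector.
#' @param delta positive jitter half-width; default [default_tie_delta()].
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of tie-free scores.
#' @export
jitter_ties <- function(scores, delta = default_tie_delta(scores), seed = NULL) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) || delta <= 0)
    stop("delta must be a positive number")
  if (!is.null(seed)) set.seed(seed)
  out <- scores
  tied <- scores %in% scores[duplicated(scores)]
  if (!any(tied)) return(out)
  repeat {
    out[tied] <- scores[tied] + runif(sum(tied), -delta, delta)
    if (!anyDuplicated(out)) break
  }
  out
}
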