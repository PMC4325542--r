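#' Beta-binomial probability mass function
#'
#' Density of the number of successes in `size` Bernoulli trials whose
#' success probability is Beta(a, b)-distributed:
#' C(size, k) * B(k + a, size - k + b) / B(a, b). Computed in log space for
#' stability at extreme shapes; as a + b grows at fixed mean a/(a+b) the
#' distribution converges to Binomial(size, a/(a+b)).
#'
#' @param k integer vector of counts in `0..size`.
#' @param size number of trials (predictors voting).
#' @param a,b positive shape parameters.
#' @param log return log-probabilities.
#' @export
dbetabinom <- function(k, size, a, b, log = FALSE) {
  if (any(a <= 0) || any(b <= 0)) stop("shape parameters must be positive")
  size <- as.integer(size)
  if (size < 0) stop("size must be non-negative")
  if (any(k != floor(k)) || any(k < 0) || any(k > size))
    stop("k must be integers within 0..size")
  lp <- lchoose(size, k) + lbeta(k + a, size - k + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Parameters of the two-component beta-binomial vote-count mixture
#'
#' Component 1 models the vote counts of true edges (per-predictor
#' true-positive rate Beta(a1, b1)); component 2 those of false edges
#' (false-positive rate Beta(a2, b2)). `pi1` is the prior probability that
#' an edge is true, i.e. the expected fraction of true edges E/N.
#'
#' @param a1,b1,a2,b2 positive shapes; component means are
#'   `a/(a + b)`.
#' @param pi1 mixing weight in (0, 1).
#' @param M number of predictors (votes range over `0..M`).
#' @return Object of class `mixture_params`.
#' @export
mixture_params <- function(a1, b1, a2, b2, pi1, M) {
  if (any(c(a1, b1, a2, b2) <= 0)) stop("shape parameters must be positive")
  if (pi1 <= 0 || pi1 >= 1) stop("pi1 must lie strictly in (0, 1)")
  M <- as.integer(M)
  if (M < 1) stop("M must be at least 1")
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, pi1 = pi1, M = M,
                 mu1 = a1 / (a1 + b1), mu2 = a2 / (a2 + b2)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Beta-binomial mixture (M = %d):\n", x$M))
  cat(sprintf("  true-edge component:  a1 = %.4g, b1 = %.4g (mean %.3f)\n",
              x$a1, x$b1, x$mu1))
  cat(sprintf("  false-edge component: a2 = %.4g, b2 = %.4g (mean %.3f)\n",
              x$a2, x$b2, x$mu2))
  cat(sprintf("  Pr(edge true) = %.3f\n", x$pi1))
  invisible(x)
}

as_mixture_params <- function(params) {
  if (inherits(params, "bbmix")) params$params
  else if (inherits(params, "mixture_params")) params
  else stop("expected a mixture_params or fitted bbmix object")
}

#' Vote-count mixture probability mass function
#'
#' pi1 * Pr(X = k | true edge) + (1 - pi1) * Pr(X = k | false edge), the
#' marginal distribution of the number of predictors voting for an edge.
#' The degenerate binomial components (fixed per-predictor rates rather
#' than Beta-distributed ones) are obtained as the large-concentration
#' limit of the beta-binomial components.
#'
#' @param k integer vote counts in `0..M`.
#' @param params a [mixture_params()] object (or fitted [bbmix()] model).
#' @param log return log-probabilities.
#' @export
dvotemix <- function(k, params, log = FALSE) {
  p <- as_mixture_params(params)
  l1 <- dbetabinom(k, p$M, p$a1, p$b1, log = TRUE) + log(p$pi1)
  l2 <- dbetabinom(k, p$M, p$a2, p$b2, log = TRUE) + log1p(-p$pi1)
  lp <- log_sum_exp2(l1, l2)
  if (log) lp else exp(lp)
}

#' Binomial-limit mixture parameters from fixed predictor rates
#'
#' Convenience constructor for the degenerate model in which every
#' predictor shares the same true-positive rate `p_t` and false-positive
#' rate `p_f` (binomial components), encoded as beta-binomial shapes at a
#' very large concentration.
#'
#' @param p_t,p_f per-predictor true/false-positive rates in (0, 1).
#' @param pi1 prior probability that an edge is true.
#' @param M predictor count.
#' @param concentration shape scale of the point-mass approximation.
#' @export
binomial_limit_params <- function(p_t, p_f, pi1, M, concentration = 1e8) {
  mixture_params(p_t * concentration, (1 - p_t) * concentration,
                 p_f * concentration, (1 - p_f) * concentration, pi1, M)
}
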