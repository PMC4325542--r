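#' Fit the two-component beta-binomial mixture to vote counts
#'
#' Models the per-edge vote count X (out of M voters) as a mixture of two
#' beta-binomial distributions: a high-mean component for true edges, whose
#' per-predictor inclusion probability P_T varies across predictors as
#' Beta(a1, b1), and a low-mean component for false edges with rate P_F ~
#' Beta(a2, b2). The mixing weight pi1 = Pr(edge true) = E/N is profiled
#' over a fixed grid ("different mixing constants"); for each grid value
#' the four shapes are fitted by maximum likelihood in a
#' (mean, concentration) re-parameterization on logit/log scales (the
#' concentration is capped, and hitting the cap is reported as a
#' binomial-limit component rather than an overflow), with seeded
#' multi-start L-BFGS-B plus a warm start from the neighbouring grid point.
#' The reported fit is the grid point with the highest likelihood.
#'
#' Component 1 is, by convention, the component with the larger mean; if
#' the data favour the opposite orientation the components are swapped
#' (pi1 becomes 1 - pi1) and the fit is flagged `"orientation_swapped"`.
#'
#' @param votes a [vote_counts()] object, or an integer vector of vote
#'   counts (then `M` must be given).
#' @param M number of voters when `votes` is a bare vector.
#' @param pi_grid grid of candidate mixing weights in (0, 1).
#' @param n_starts random restarts per grid point (in addition to a
#'   moment-based start and the warm start).
#' @param seed seed for the restart stream.
#' @param max_concentration upper bound on a + b per component; a
#'   component whose fitted concentration is large enough to act as a
#'   point mass (1e5 and above, or the cap) is flagged
#'   `"binomial_limit"` rather than reported as an overflow.
#' @param control passed to [stats::optim()] (method L-BFGS-B).
#' @return Object of class `bbmix`: list with `params`
#'   ([mixture_params()]), `logLik`, `profile` (per-grid-point maximized
#'   log-likelihood), `votes`, `M`, `n`, `flags`, `convergence`, `call`.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict` (posterior
#'   Pr(true | k), density, or components), `plot`, `simulate`,
#'   `residuals`.
#' @examples
#' truth <- c(rep(1, 30), rep(0, 170))
#' set.seed(1)
#' k <- rbinom(200, 12, ifelse(truth == 1, 0.8, 0.25))
#' fit <- bbmix(vote_counts(k, 12), pi_grid = seq(0.05, 0.4, by = 0.05),
#'              n_starts = 2, seed = 1)
#' fit
#' optimal_threshold(fit)
#' @export
bbmix <- function(votes, M = NULL, pi_grid = seq(0.01, 0.5, by = 0.01),
                  n_starts = 8, seed = 1, max_concentration = 1e9,
                  control = list(maxit = 300)) {
  if (inherits(votes, "vote_counts")) {
    k <- votes$k
    M <- votes$M
  } else {
    if (is.null(M)) stop("M must be supplied when votes is a bare vector")
    k <- as.integer(votes)
  }
  if (any(k < 0) || any(k > M)) stop("vote counts must lie within 0..M")
  if (length(unique(k)) < 2L)
    stop("degenerate vote counts: all edges received the same number of votes")
  if (!length(pi_grid) || any(pi_grid <= 0) || any(pi_grid >= 1))
    stop("pi_grid values must lie strictly in (0, 1)")

  tab <- tabulate(k + 1L, nbins = M + 1L)  # counts of k = 0..M
  ks <- 0:M
  log_s_max <- log(max_concentration)

  comp_logpmf <- function(mu, s) {
    dbetabinom(ks, M, mu * s, (1 - mu) * s, log = TRUE)
  }
  nll <- function(theta, pi1) {
    mu1 <- plogis(theta[1L]); s1 <- exp(theta[2L])
    mu2 <- plogis(theta[3L]); s2 <- exp(theta[4L])
    lmix <- log_sum_exp2(log(pi1) + comp_logpmf(mu1, s1),
                         log1p(-pi1) + comp_logpmf(mu2, s2))
    v <- -sum(tab * lmix)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(-12, log(1e-2), -12, log(1e-2))
  upper <- c(12, log_s_max, 12, log_s_max)

  # moment start: split counts at the overall mean vote fraction
  p_bar <- mean(k) / M
  hi <- k / M >= p_bar
  mu1_0 <- min(max(mean(k[hi]) / M, 0.05), 0.95)
  mu2_0 <- min(max(if (any(!hi)) mean(k[!hi]) / M else p_bar / 2, 0.02), 0.9)
  moment_start <- c(qlogis(mu1_0), log(20), qlogis(mu2_0), log(20))
  rand_starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    c(qlogis(runif(1, 0.5, 0.95)), log(exp(runif(1, log(5), log(500)))),
      qlogis(runif(1, 0.02, 0.5)), log(exp(runif(1, log(5), log(500)))))
  }))

  profile <- data.frame(pi1 = pi_grid, logLik = NA_real_)
  best <- list(value = Inf)
  warm <- NULL
  for (g in seq_along(pi_grid)) {
    pi1 <- pi_grid[g]
    starts <- c(list(moment_start), rand_starts,
                if (!is.null(warm)) list(warm))
    g_best <- list(value = Inf)
    for (st in starts) {
      fit <- tryCatch(
        optim(st, nll, pi1 = pi1, method = "L-BFGS-B",
              lower = lower, upper = upper, control = control),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < g_best$value) g_best <- fit
    }
    if (!is.finite(g_best$value)) next
    profile$logLik[g] <- -g_best$value
    warm <- g_best$par
    if (g_best$value < best$value) {
      best <- g_best
      best$pi1 <- pi1
    }
  }
  if (!is.finite(best$value))
    stop("mixture fit failed to converge from any start")

  th <- best$par
  mu1 <- plogis(th[1L]); s1 <- exp(th[2L])
  mu2 <- plogis(th[3L]); s2 <- exp(th[4L])
  pi1 <- best$pi1
  flags <- character()
  if (mu1 < mu2) {
    tmp <- c(mu1, s1); mu1 <- mu2; s1 <- s2; mu2 <- tmp[1L]; s2 <- tmp[2L]
    pi1 <- 1 - pi1
    flags <- c(flags, "orientation_swapped")
  }
  # a concentration this large is a point mass at any realistic M: the
  # votes carry no information beyond the component mean
  if (max(s1, s2) >= min(1e5, max_concentration * 0.99))
    flags <- c(flags, "binomial_limit")
  if (pi1 <= min(pi_grid) + 1e-12 || pi1 >= max(pi_grid) - 1e-12)
    flags <- c(flags, "pi_grid_boundary")

  structure(list(
    params = mixture_params(mu1 * s1, (1 - mu1) * s1,
                            mu2 * s2, (1 - mu2) * s2, pi1, M),
    logLik = -best$value,
    profile = profile,
    votes = k, M = as.integer(M), n = length(k),
    counts = tab,
    flags = flags,
    convergence = best$convergence %||% NA_integer_,
    call = match.call()
  ), class = "bbmix")
}

#' Smallest vote count at which an edge is more likely true than false
#'
#' Solves for the smallest k in 0..M with
#' Pr(Y = 1 | X = k) > Pr(Y = 0 | X = k), i.e.
#' pi1 * Pr(X = k | true) > (1 - pi1) * Pr(X = k | false), by direct
#' log-space evaluation of both sides at every k. Ties (posterior ratio
#' exactly 1) do not satisfy the strict inequality. If no k qualifies the
#' result is flagged `"no_threshold"`; if the condition is non-monotone
#' in k (possible for components with very different concentrations) the
#' minimum satisfying k is still returned, with a `"non_monotone"` flag
#' so the user can inspect the full condition vector; a false-edge
#' component voting more often than the true-edge one is flagged
#' `"reversed_components"`.
#'
#' @param params a [mixture_params()] object or fitted [bbmix()] model.
#' @return List of class `vote_threshold`: `k_star` (integer or `NA`),
#'   `condition` (logical over k = 0..M), `flags`.
#' @export
optimal_threshold <- function(params) {
  p <- as_mixture_params(params)
  ks <- 0:p$M
  lhs <- log(p$pi1) + dbetabinom(ks, p$M, p$a1, p$b1, log = TRUE)
  rhs <- log1p(-p$pi1) + dbetabinom(ks, p$M, p$a2, p$b2, log = TRUE)
  cond <- lhs > rhs
  flags <- character()
  if (p$mu1 < p$mu2) flags <- c(flags, "reversed_components")
  if (!any(cond)) {
    return(structure(list(k_star = NA_integer_, condition = cond,
                          flags = c(flags, "no_threshold")),
                     class = "vote_threshold"))
  }
  if (length(rle(cond)$lengths) > 2L) flags <- c(flags, "non_monotone")
  k_star <- ks[which(cond)[1L]]
  structure(list(k_star = as.integer(k_star), condition = cond, flags = flags),
            class = "vote_threshold")
}

#' @export
print.vote_threshold <- function(x, ...) {
  if (is.na(x$k_star)) cat("Optimal vote threshold: none")
  else cat(sprintf("Optimal vote threshold: k* = %d", x$k_star))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.bbmix <- function(x, ...) {
  cat(sprintf("Beta-binomial vote-count mixture fit (n = %d edges, M = %d voters)\n",
              x$n, x$M))
  print(x$params)
  cat(sprintf("  log-likelihood: %.2f\n", x$logLik))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.bbmix <- function(object, ...) {
  p <- object$params
  c(a1 = p$a1, b1 = p$b1, a2 = p$a2, b2 = p$b2, pi1 = p$pi1,
    mu1 = p$mu1, mu2 = p$mu2)
}

#' @export
logLik.bbmix <- function(object, ...) {
  structure(object$logLik, df = 5L, nobs = object$n, class = "logLik")
}

#' Posterior edge probabilities and fitted densities from a vote-count fit
#'
#' @param object fitted [bbmix()] model.
#' @param k vote counts to evaluate (default 0..M).
#' @param type `"posterior"` for Pr(edge true | X = k), `"density"` for the
#'   fitted marginal pmf, `"components"` for the two weighted component
#'   pmfs.
#' @param ... unused.
#' @export
predict.bbmix <- function(object, k = 0:object$M,
                          type = c("posterior", "density", "components"),
                          ...) {
  type <- match.arg(type)
  p <- object$params
  l1 <- log(p$pi1) + dbetabinom(k, p$M, p$a1, p$b1, log = TRUE)
  l2 <- log1p(-p$pi1) + dbetabinom(k, p$M, p$a2, p$b2, log = TRUE)
  switch(type,
         posterior = setNames(exp(l1 - log_sum_exp2(l1, l2)), k),
         density = setNames(exp(log_sum_exp2(l1, l2)), k),
         components = cbind(k = k, true = exp(l1), false = exp(l2)))
}

#' @export
summary.bbmix <- function(object, ...) {
  th <- optimal_threshold(object)
  expected <- object$n * predict(object, type = "density")
  # independence diagnostic: observed vs model-implied vote-count variance
  p <- object$params
  mom <- function(mu, s) mu * (1 - mu) * object$M *
    (1 + (object$M - 1) / (s + 1)) + (mu * object$M)^2
  m1 <- p$pi1 * p$mu1 * object$M + (1 - p$pi1) * p$mu2 * object$M
  m2 <- p$pi1 * mom(p$mu1, p$a1 + p$b1) + (1 - p$pi1) * mom(p$mu2, p$a2 + p$b2)
  structure(list(fit = object, threshold = th,
                 observed = object$counts, expected = expected,
                 var_observed = var(object$votes),
                 var_model = m2 - m1^2),
            class = "summary.bbmix")
}

#' @export
print.summary.bbmix <- function(x, ...) {
  print(x$fit)
  print(x$threshold)
  cat(sprintf("  vote-count variance: observed %.3f, model-implied %.3f\n",
              x$var_observed, x$var_model))
  tab <- data.frame(k = seq_along(x$observed) - 1L, observed = x$observed,
                    expected = round(x$expected, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bbmix <- function(x, ...) {
  ks <- 0:x$M
  obs <- x$counts / x$n
  dens <- predict(x, type = "density")
  comps <- predict(x, type = "components")
  ylim <- c(0, max(obs, dens) * 1.05)
  graphics::barplot(obs, names.arg = ks, ylim = ylim, col = "grey85",
                    border = "grey60", xlab = "votes per edge (k)",
                    ylab = "fraction of edges", ...)
  at <- seq_along(ks) * 1.2 - 0.5  # barplot bar centres
  graphics::lines(at, dens, col = "red", lwd = 2)
  graphics::lines(at, comps[, "true"], col = "black", lty = 2)
  graphics::lines(at, comps[, "false"], col = "black", lty = 3)
  th <- optimal_threshold(x)
  if (!is.na(th$k_star))
    graphics::abline(v = at[th$k_star + 1L] - 0.6, col = "blue", lty = 2)
  graphics::legend("topright", bty = "n", lwd = c(2, 1, 1),
                   lty = c(1, 2, 3), col = c("red", "black", "black"),
                   legend = c("fitted mixture", "true-edge component",
                              "false-edge component"))
  invisible(x)
}

#' @export
simulate.bbmix <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$params
  with_seed(seed, {
    out <- replicate(nsim, {
      truth <- rbinom(object$n, 1L, p$pi1)
      rate <- ifelse(truth == 1L, rbeta(object$n, p$a1, p$b1),
                     rbeta(object$n, p$a2, p$b2))
      rbinom(object$n, object$M, rate)
    })
    as.data.frame(out)
  })
}

#' @export
residuals.bbmix <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  expected <- object$n * predict(object, type = "density")
  raw <- object$counts - expected
  if (type == "raw") return(setNames(raw, 0:object$M))
  setNames(raw / sqrt(pmax(expected, .Machine$double.eps)), 0:object$M)
}
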