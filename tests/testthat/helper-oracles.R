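# Independent oracles, deliberately written as plain brute-force code so
# they share no internals with the implementation they check.

# exhaustive minimization over all 2^|E| kept-edge subsets; node states are
# recomputed with a naive repeated-sweep closure
oracle_prune <- function(net, disc, eps = 1 / (10 * nrow(net$edges))) {
  ids <- net$nodes$id
  edges <- net$edges
  m <- nrow(edges)
  naive_states <- function(kept_rows, stimuli) {
    active <- ids %in% stimuli
    names(active) <- ids
    repeat {
      changed <- FALSE
      for (r in kept_rows) {
        if (active[edges$source[r]] && !active[edges$target[r]]) {
          active[edges$target[r]] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    active
  }
  mism_of <- function(kept_rows) {
    total <- 0
    for (e in seq_len(nrow(disc$values))) {
      st <- naive_states(kept_rows, disc$stimuli[[e]])
      for (v in colnames(disc$values)) {
        call <- disc$values[e, v]
        if (is.na(call)) next
        want <- if (call == 1) TRUE else FALSE
        if (st[v] != want) total <- total + 1
      }
    }
    total
  }
  best <- Inf
  best_mism <- NA
  for (code in 0:(2^m - 1)) {
    kept_rows <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    obj <- mism_of(kept_rows) + eps * length(kept_rows)
    if (obj < best) {
      best <- obj
      best_mism <- mism_of(kept_rows)
    }
  }
  list(objective = best, mismatches = best_mism)
}

# brute-force smallest k with pi1 * Pr(k | true) > (1 - pi1) * Pr(k | false),
# with the beta-binomial pmf written out directly
oracle_threshold <- function(a1, b1, a2, b2, pi1, M) {
  pmf <- function(k, a, b) choose(M, k) * beta(k + a, M - k + b) / beta(a, b)
  for (k in 0:M) {
    if (pi1 * pmf(k, a1, b1) > (1 - pi1) * pmf(k, a2, b2)) return(k)
  }
  NA_integer_
}

# same brute force in the fixed-rate (binomial) limit, for shape scales
# where beta() itself underflows
oracle_threshold_binom <- function(p_t, p_f, pi1, M) {
  for (k in 0:M) {
    if (pi1 * dbinom(k, M, p_t) > (1 - pi1) * dbinom(k, M, p_f)) return(k)
  }
  NA_integer_
}

# exact null mean/sd of the Jaccard similarity by enumerating every
# size-preserving resample of the predicted set (tiny universes only)
oracle_jaccard_null <- function(prediction, standard) {
  N <- length(prediction)
  p <- sum(prediction)
  s_idx <- which(standard == 1)
  draws <- apply(combn(N, p), 2, function(idx) {
    inter <- length(intersect(idx, s_idx))
    inter / (p + length(s_idx) - inter)
  })
  c(mean = mean(draws), sd = sd(draws) * sqrt((length(draws) - 1) /
                                                length(draws)))
}
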