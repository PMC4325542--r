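# Run expr with a temporarily-seeded RNG, restoring the caller's stream so
# generator calls do not perturb each other (splittable-seed discipline).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stage-specific sub-seed from a master seed, kept inside the
# 32-bit integer range. Distinct labels give distinct, reproducible streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

log_sum_exp2 <- function(la, lb) {
  m <- pmax(la, lb)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(la - m) + exp(lb - m)))
}
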