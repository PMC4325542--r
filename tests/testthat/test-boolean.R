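chain_net <- function() {
  network(data.frame(source = c("S", "A"), target = c("A", "B")),
          nodes = data.frame(id = c("S", "A", "B"),
                             layer = c("stimulus", "signaling", "signaling"),
                             measured = c(FALSE, TRUE, TRUE)))
}

chain_disc <- function(calls) {
  # one experiment with S active; `calls` is a named vector over A/B
  structure(list(values = matrix(calls, nrow = length(calls) / 2,
                                 ncol = 2, byrow = TRUE,
                                 dimnames = list(NULL, c("A", "B"))),
                 thresholds = default_thresholds(),
                 stimuli = rep(list("S"), length(calls) / 2),
                 data_type = c(A = "phospho_residual",
                               B = "phospho_residual")),
            class = "discretized_panel")
}

test_that("double-threshold discretization is inclusive and odd-symmetric", {
  panel <- experiment_panel(
    matrix(c(2.5, -3.5, 1.0, 2.0), 1, 4,
           dimnames = list(NULL, c("g1", "p1", "p2", "c1"))),
    stimuli = list(e1 = "S"),
    data_type = c(g1 = "expression_foldchange", p1 = "phospho_residual",
                  p2 = "phospho_residual", c1 = "cytokine_residual"))
  d <- discretize(panel)
  expect_equal(unname(d$values[1, ]), c(1, -1, 0, 1))

  # odd symmetry at every data type and several thresholds
  set.seed(3)
  for (i in 1:20) {
    v <- runif(1, -5, 5)
    for (ty in names(default_thresholds())) {
      p_pos <- experiment_panel(matrix(v, 1, 1, dimnames = list(NULL, "x")),
                                list("S"), setNames(ty, "x"))
      p_neg <- experiment_panel(matrix(-v, 1, 1, dimnames = list(NULL, "x")),
                                list("S"), setNames(ty, "x"))
      expect_equal(discretize(p_neg)$values[1, 1],
                   -discretize(p_pos)$values[1, 1])
    }
  }

  # missing values propagate; unknown types are rejected
  pna <- experiment_panel(matrix(NA_real_, 1, 1, dimnames = list(NULL, "x")),
                          list("S"), c(x = "phospho_residual"))
  expect_true(is.na(discretize(pna)$values[1, 1]))
  expect_error(experiment_panel(matrix(1, 1, 1, dimnames = list(NULL, "x")),
                                list("S"), c(x = "weird_type")),
               "unknown data type")
  expect_error(discretize(panel, thresholds = c(expression_foldchange = -1,
                                                phospho_residual = 3,
                                                cytokine_residual = 2)),
               "positive")
})

test_that("Boolean OR-propagation follows kept-edge reachability", {
  net <- chain_net()
  expect_equal(propagate(net, "S"), c(S = 1L, A = 1L, B = 1L))
  expect_equal(propagate(net, "S", kept = "S->A"), c(S = 1L, A = 1L, B = 0L))

  diamond <- network(data.frame(source = c("S", "S", "A", "B"),
                                target = c("A", "B", "C", "C")),
                     nodes = data.frame(id = c("S", "A", "B", "C"),
                                        layer = c("stimulus", "signaling",
                                                  "signaling", "signaling"),
                                        measured = c(FALSE, TRUE, TRUE, TRUE)))
  st <- propagate(diamond, "S", kept = c("S->A", "A->C", "B->C"))
  expect_equal(st[["C"]], 1L)  # active via A even with S->B removed
  expect_equal(st[["B"]], 0L)

  expect_error(propagate(net, "ZZ"), "unknown stimulus")
})

test_that("pruning removes exactly the data-contradicted reactions", {
  net <- chain_net()

  # B called absent: keeping both edges forces B = 1 (one mismatch), so the
  # optimum cuts the chain once for zero mismatches
  res0 <- prune_ilp(net, chain_disc(c(1, 0)))
  expect_equal(res0$mismatches, 0L)
  oracle <- oracle_prune(net, chain_disc(c(1, 0)))
  expect_equal(res0$objective, oracle$objective, tolerance = 1e-9)
  expect_lt(nrow(res0$kept), 2)

  # B called present: both edges kept, zero mismatches
  res1 <- prune_ilp(net, chain_disc(c(1, 1)))
  expect_equal(res1$mismatches, 0L)
  expect_equal(nrow(res1$kept), 2)

  # two experiments contradicting each other on B: one mismatch is
  # unavoidable (confirmed by the exhaustive oracle)
  contra <- chain_disc(c(1, 1, 1, 0))
  res2 <- prune_ilp(net, contra)
  expect_equal(res2$mismatches, 1L)
  expect_equal(res2$objective, oracle_prune(net, contra)$objective,
               tolerance = 1e-9)
})

test_that("branch-and-bound matches exhaustive enumeration on toy instances", {
  for (seed in 1:25) {
    inst <- random_ilp_instance(seed, flip_rate = 0.15)
    res <- prune_ilp(inst$net, inst$disc)
    oracle <- oracle_prune(inst$net, inst$disc)
    expect_equal(res$objective, oracle$objective, tolerance = 1e-9)
    expect_equal(res$mismatches, oracle$mismatches)
    # reported mismatch count agrees with the fitted states
    recount <- 0L
    for (e in seq_len(nrow(inst$disc$values))) {
      calls <- inst$disc$values[e, ]
      want <- as.integer(calls == 1)
      got <- res$states[e, colnames(inst$disc$values)]
      recount <- recount + sum(got != want, na.rm = TRUE)
    }
    expect_equal(res$mismatches, recount)
  }
})

test_that("noise-free data from a known sub-network is perfectly fit", {
  for (seed in 1:10) {
    inst <- random_ilp_instance(seed, flip_rate = 0)
    res <- prune_ilp(inst$net, inst$disc)
    expect_equal(res$mismatches, 0L)
  }
})

test_that("removing an experiment never increases the optimal mismatch", {
  for (seed in 1:8) {
    inst <- random_ilp_instance(seed, flip_rate = 0.3)
    full <- prune_ilp(inst$net, inst$disc)$mismatches
    if (nrow(inst$disc$values) < 2) next
    drop1 <- inst$disc
    drop1$values <- drop1$values[-1, , drop = FALSE]
    drop1$stimuli <- drop1$stimuli[-1]
    expect_lte(prune_ilp(inst$net, drop1)$mismatches, full)
  }
})

test_that("the search budget error carries the best incumbent", {
  inst <- random_ilp_instance(4, flip_rate = 0.2)
  err <- tryCatch(prune_ilp(inst$net, inst$disc, max_iter = 3),
                  error = function(e) e)
  expect_match(conditionMessage(err), "budget")
})

test_that("threshold sensitivity reports Jaccard overlap with the base run", {
  net <- chain_net()
  # A sits firmly above any phospho threshold; B at 2.5 is borderline:
  # called present at t = 2, absent at t = 3
  panel <- experiment_panel(
    matrix(c(5, 2.5), 1, 2, dimnames = list(NULL, c("A", "B"))),
    stimuli = list(e1 = "S"),
    data_type = c(A = "phospho_residual", B = "phospho_residual"))

  base_only <- sensitivity_sweep(net, panel,
                                 threshold_grid = list(phospho_residual = 3))
  expect_equal(base_only$jaccard_to_base, 1)

  sweep <- sensitivity_sweep(net, panel,
                             threshold_grid = list(phospho_residual = c(2, 3)))
  # t = 3: B absent -> chain cut (keep S->A); t = 2: B present -> both kept
  expect_equal(sweep$jaccard_to_base[sweep$phospho_residual == 3], 1)
  expect_equal(sweep$n_kept, c(2, 1))
  expect_equal(sweep$jaccard_to_base[sweep$phospho_residual == 2], 0.5)

  # far from any threshold the kept set is grid-invariant
  panel2 <- experiment_panel(
    matrix(c(9, 9), 1, 2, dimnames = list(NULL, c("A", "B"))),
    stimuli = list(e1 = "S"),
    data_type = c(A = "phospho_residual", B = "phospho_residual"))
  sweep2 <- sensitivity_sweep(net, panel2,
                              threshold_grid = list(phospho_residual = c(2, 3, 4)))
  expect_true(all(sweep2$jaccard_to_base == 1))
})
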