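test_that("contingency counts match direct set arithmetic", {
  ct <- contingency(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(ct)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))

  ct2 <- contingency(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(with(ct2, c(tp, fn, fp, tn)), c(1, 1, 1, 1))

  # restriction to the first two (reference) indices recounts there only
  ref <- network(data.frame(source = c("a", "b"), target = c("b", "c")))
  u <- build_universe(ref, data.frame(source = c("a", "c"),
                                      target = c("c", "a")))
  ct3 <- contingency(c(1, 0, 1, 0), c(1, 1, 0, 0), u,
                     restrict_to_reference = TRUE)
  expect_equal(with(ct3, c(tp, fn, fp, tn)), c(1, 1, 0, 0))

  expect_error(contingency(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("jaccard, mcc and tpr-fpr give their closed-form values", {
  # {1,2,3} vs {2,3,4}
  ct <- contingency(c(1, 1, 1, 0), c(0, 1, 1, 1))
  expect_equal(jaccard(ct), 0.5)
  expect_equal(jaccard(contingency(c(1, 1), c(1, 1))), 1)
  expect_equal(jaccard(contingency(c(1, 0), c(0, 1))), 0)
  expect_true(is.na(jaccard(contingency(c(0, 0), c(0, 0)))))

  ct46 <- structure(list(tp = 4L, fp = 1L, fn = 1L, tn = 4L),
                    class = "contingency")
  expect_equal(mcc(ct46), 0.6)
  expect_equal(as.numeric(mcc(contingency(c(1, 0), c(1, 0)))), 1)
  expect_equal(as.numeric(mcc(contingency(c(1, 0), c(0, 1)))), -1)

  # degenerate margins: 0 by convention, flagged, never an error
  for (std in list(c(1, 1, 1), c(0, 0, 0))) {
    res <- mcc(contingency(c(1, 0, 1), std))
    expect_equal(as.numeric(res), 0)
    expect_true(attr(res, "degenerate"))
  }

  ct3131 <- structure(list(tp = 3L, fn = 1L, fp = 1L, tn = 3L),
                      class = "contingency")
  expect_equal(tpr_minus_fpr(ct3131), 0.5)
  expect_equal(tpr_minus_fpr(contingency(c(1, 0), c(1, 0))), 1)
  expect_equal(tpr_minus_fpr(contingency(c(1, 1), c(1, 0))), 0)
  expect_true(is.na(tpr_minus_fpr(contingency(c(1, 0), c(0, 0)))))
})

test_that("metrics agree with direct counting and ignore index order", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    pred <- rbinom(n, 1, 0.4)
    std <- rbinom(n, 1, 0.3)
    ct <- contingency(pred, std)
    tp <- sum(pred & std); fp <- sum(pred & !std)
    tn <- sum(!pred & !std); fn <- sum(!pred & std)
    expect_equal(with(ct, c(tp, fp, tn, fn)), c(tp, fp, tn, fn))
    perm <- sample(n)
    ct_p <- contingency(pred[perm], std[perm])
    expect_equal(as.numeric(mcc(ct_p)), as.numeric(mcc(ct)))
    expect_equal(tpr_minus_fpr(ct_p), tpr_minus_fpr(ct))
  }
})

test_that("jaccard z-score matches the exhaustive resampling null", {
  # universe of 6, |standard| = 2, |prediction| = 2
  pred <- c(1, 1, 0, 0, 0, 0)
  std <- c(0, 1, 1, 0, 0, 0)
  oracle <- oracle_jaccard_null(pred, std)

  exact <- jaccard_zscore(pred, std, method = "exact")
  expect_equal(exact$null_mean, unname(oracle["mean"]), tolerance = 1e-12)
  expect_equal(exact$null_sd, unname(oracle["sd"]), tolerance = 1e-12)

  mc <- jaccard_zscore(pred, std, n_null = 20000, seed = 9)
  se <- oracle["sd"] / sqrt(20000)
  expect_lt(abs(mc$null_mean - oracle["mean"]), 3 * se)
  expect_equal(mc$js, 1 / 3)

  # same fixed seed, same z
  expect_equal(jaccard_zscore(pred, std, seed = 7)$z,
               jaccard_zscore(pred, std, seed = 7)$z)
})

test_that("jaccard z-score flags degenerate nulls and rewards identity", {
  # prediction = standard in a large sparse universe: strongly positive z
  pred <- c(rep(1, 3), rep(0, 60))
  res <- jaccard_zscore(pred, pred, n_null = 2000, seed = 2)
  expect_gt(res$z, 2)

  # all-edges prediction: every resample identical, null sd = 0
  res2 <- jaccard_zscore(c(1, 1, 1), c(1, 0, 1), n_null = 200, seed = 1)
  expect_false(res2$defined)
  expect_true(is.na(res2$z))

  expect_error(jaccard_zscore(c(0, 0), c(1, 0)), "positive")
})

test_that("rank aggregation averages per-metric ranks with mid-rank ties", {
  one <- data.frame(submission = c("s1", "s2", "s3"),
                    m = c(0.9, 0.5, 0.1))
  expect_equal(rank_aggregate(one)$rank_m, c(1, 2, 3))

  # reversed orders over two submissions tie
  two <- data.frame(submission = c("s1", "s2"),
                    a = c(1, 0), b = c(0, 1))
  res <- rank_aggregate(two)
  expect_equal(res$mean_rank, c(1.5, 1.5))
  expect_equal(res$final_rank, c(1.5, 1.5))

  # metric A ranks (1,2,3), metric B ranks (2,1,3)
  three <- data.frame(submission = c("s1", "s2", "s3"),
                      a = c(3, 2, 1), b = c(2, 3, 1))
  res3 <- rank_aggregate(three)
  expect_equal(res3$mean_rank[match(c("s1", "s2", "s3"), res3$submission)],
               c(1.5, 1.5, 3))
  expect_equal(res3$submission[3], "s3")

  expect_error(rank_aggregate(data.frame(submission = character(),
                                         m = numeric())), "empty")
})

test_that("final ordering is invariant to monotone metric transforms", {
  set.seed(11)
  scores <- data.frame(submission = paste0("s", 1:6),
                       a = runif(6), b = runif(6), c = runif(6))
  base <- rank_aggregate(scores)
  warped <- scores
  warped$b <- exp(5 * warped$b)   # strictly monotone
  warped$c <- rank(warped$c)
  res <- rank_aggregate(warped)
  expect_equal(res$submission, base$submission)
  expect_equal(res$final_rank, base$final_rank)
})

test_that("undefined metrics are excluded pairwise with a warning", {
  scores <- data.frame(submission = c("s1", "s2"),
                       a = c(0.9, 0.4), b = c(NA, 0.2))
  expect_warning(res <- rank_aggregate(scores), "undefined")
  expect_equal(res$mean_rank[res$submission == "s1"], 1)  # rank from a only
})

test_that("score_submissions ranks a crowd against a standard", {
  net <- toy_reference()
  u <- build_universe(net)
  truth <- as_standard_vector(u$labels[1:2], u)
  vals <- rbind(good = truth,
                bad = 1 - truth,
                partial = c(1, 0, 0, 0, 1))
  preds <- prediction_matrix(vals, u, c("good", "bad", "partial"))
  rep <- score_submissions(preds, u$labels[1:2], n_null = 500, seed = 3)
  expect_equal(rep$submission[1], "good")
  expect_equal(rep$final_rank[rep$submission == "bad"], 3)
  expect_equal(rep$mcc[rep$submission == "good"], 1)
})
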