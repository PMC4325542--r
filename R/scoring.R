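#' Contingency counts of a binary edge prediction against a standard
#'
#' Counts true/false positives/negatives over the candidate-edge universe.
#' When `restrict_to_reference` is `TRUE` only the positions of
#' reference-network edges contribute (submissions are scored on the part
#' of the universe that intersects the reference map).
#'
#' @param prediction,standard 0/1 vectors of equal length over the same
#'   universe.
#' @param universe optional [build_universe()] object; required for
#'   `restrict_to_reference`.
#' @param restrict_to_reference restrict counting to reference-edge indices.
#' @return List of class `contingency` with integer fields `tp`, `fp`,
#'   `tn`, `fn` (summing to the size of the scoring index set).
#' @export
contingency <- function(prediction, standard, universe = NULL,
                        restrict_to_reference = FALSE) {
  if (length(prediction) != length(standard))
    stop("prediction and standard must have equal length")
  if (!all(prediction %in% c(0, 1)) || !all(standard %in% c(0, 1)))
    stop("prediction and standard must be binary 0/1 vectors")
  if (restrict_to_reference) {
    if (is.null(universe)) stop("restrict_to_reference requires a universe")
    if (length(prediction) != length(universe))
      stop("vectors do not match the universe size")
    idx <- seq_len(universe$n_ref)
    prediction <- prediction[idx]
    standard <- standard[idx]
  }
  p <- as.integer(prediction); s <- as.integer(standard)
  structure(list(tp = sum(p == 1L & s == 1L), fp = sum(p == 1L & s == 0L),
                 tn = sum(p == 0L & s == 0L), fn = sum(p == 0L & s == 1L)),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Jaccard similarity of the predicted and standard edge sets
#'
#' tp / (tp + fp + fn); `NA` when both sets are empty.
#'
#' @param ct a [contingency()] table.
#' @export
jaccard <- function(ct) {
  denom <- ct$tp + ct$fp + ct$fn
  if (denom == 0) return(NA_real_)
  ct$tp / denom
}

#' Matthews correlation coefficient
#'
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), with the standard
#' convention that a zero factor in the denominator (degenerate margins)
#' yields 0 rather than an error; the convention is signalled via the
#' `"degenerate"` attribute.
#'
#' @param ct a [contingency()] table.
#' @export
mcc <- function(ct) {
  f <- c(ct$tp + ct$fp, ct$tp + ct$fn, ct$tn + ct$fp, ct$tn + ct$fn)
  if (any(f == 0)) return(structure(0, degenerate = TRUE))
  num <- as.numeric(ct$tp) * ct$tn - as.numeric(ct$fp) * ct$fn
  num / exp(sum(log(f)) / 2)
}

#' True-positive rate minus false-positive rate
#'
#' A Youden-style summary: tp/(tp+fn) - fp/(fp+tn). `NA` when either class
#' is empty in the standard.
#'
#' @param ct a [contingency()] table.
#' @export
tpr_minus_fpr <- function(ct) {
  if (ct$tp + ct$fn == 0 || ct$fp + ct$tn == 0) return(NA_real_)
  ct$tp / (ct$tp + ct$fn) - ct$fp / (ct$fp + ct$tn)
}

#' z-score of the Jaccard similarity under a size-preserving random null
#'
#' The observed Jaccard similarity between the predicted and standard edge
#' sets is standardized against the null in which the predicted set is
#' resampled uniformly at random among the universe positions with its size
#' preserved (the standard fixed). Under that null the overlap is
#' hypergeometric, so the Monte-Carlo resampling draws the overlap count
#' directly; `method = "exact"` instead computes the null mean and standard
#' deviation by summing over the full hypergeometric support (exact for any
#' universe size).
#'
#' @param prediction,standard 0/1 vectors over the same universe.
#' @param n_null number of Monte-Carlo resamples (>= 100).
#' @param seed integer seed for the resampling stream.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @return List with `z` (`NA` and `defined = FALSE` when the null is
#'   degenerate), `js`, `null_mean`, `null_sd`, `method`, `defined`.
#' @export
jaccard_zscore <- function(prediction, standard, n_null = 10000, seed = 1,
                           method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  if (length(prediction) != length(standard))
    stop("prediction and standard must have equal length")
  N <- length(prediction)
  p <- sum(prediction == 1)
  s <- sum(standard == 1)
  if (p == 0) stop("prediction must contain at least one positive")
  obs <- jaccard(contingency(prediction, standard))
  js_of_overlap <- function(t) t / (p + s - t)
  if (method == "exact") {
    supp <- max(0, p + s - N):min(p, s)
    w <- dhyper(supp, s, N - s, p)
    m <- sum(w * js_of_overlap(supp))
    v <- sum(w * (js_of_overlap(supp) - m)^2)
    sdv <- sqrt(v)
  } else {
    if (n_null < 100) stop("n_null must be at least 100")
    t <- with_seed(seed, rhyper(n_null, s, N - s, p))
    draws <- js_of_overlap(t)
    m <- mean(draws)
    sdv <- sd(draws)
  }
  defined <- is.finite(sdv) && sdv > 0
  list(z = if (defined) (obs - m) / sdv else NA_real_,
       js = obs, null_mean = m, null_sd = sdv,
       method = method, defined = defined)
}

#' Aggregate per-metric scores into final ranks
#'
#' For each metric, submissions are ranked with rank 1 best (higher score
#' better) and ties receiving the mean of the tied ranks; the final rank
#' orders submissions by the mean of their per-metric ranks. Undefined
#' (NA) metric values are excluded pairwise with a warning, so a degenerate
#' submission remains visible rather than silently scoring zero.
#'
#' @param scores data.frame with a `submission` column and one numeric
#'   column per metric.
#' @return data.frame with the input scores, `rank_<metric>` columns, the
#'   mean rank (`mean_rank`) and the final rank (`final_rank`, ascending
#'   mean rank, ties averaged).
#' @export
rank_aggregate <- function(scores) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0) stop("empty score report")
  if (!"submission" %in% names(scores))
    stop("scores must have a submission column")
  metrics <- setdiff(names(scores), "submission")
  metrics <- metrics[vapply(scores[metrics], is.numeric, TRUE)]
  if (!length(metrics)) stop("no numeric metric columns to rank")
  ranks <- sapply(metrics, function(mname) {
    v <- scores[[mname]]
    if (anyNA(v))
      warning("metric '", mname, "' undefined for some submissions; ",
              "excluded pairwise from their mean rank")
    rank(-v, ties.method = "average", na.last = "keep")
  })
  ranks <- matrix(ranks, nrow = nrow(scores),
                  dimnames = list(NULL, paste0("rank_", metrics)))
  mean_rank <- rowMeans(ranks, na.rm = TRUE)
  out <- cbind(scores, as.data.frame(ranks))
  out$mean_rank <- mean_rank
  out$final_rank <- rank(mean_rank, ties.method = "average")
  out[order(out$final_rank), , drop = FALSE]
}

#' Score all submissions against a standard and aggregate ranks
#'
#' Computes the Jaccard similarity, its z-score under the size-preserving
#' null, the Matthews correlation coefficient and TPR-FPR for each
#' submission against a standard network, then aggregates the per-metric
#' ranks with [rank_aggregate()].
#'
#' @param predictions a [prediction_matrix()].
#' @param standard the standard: a [network()], edge-label vector or 0/1
#'   vector (see [as_standard_vector()]).
#' @param restrict_to_reference score only reference-universe positions
#'   (default `TRUE`, matching the convention that only subnetworks
#'   intersecting the reference map are scored).
#' @param n_null,seed Monte-Carlo settings for [jaccard_zscore()].
#' @return The [rank_aggregate()] report, one row per submission.
#' @export
score_submissions <- function(predictions, standard,
                              restrict_to_reference = TRUE,
                              n_null = 10000, seed = 1) {
  stopifnot(inherits(predictions, "prediction_matrix"))
  y <- as_standard_vector(standard, predictions$universe)
  idx <- if (restrict_to_reference) seq_len(predictions$universe$n_ref)
         else seq_along(y)
  rows <- lapply(seq_len(nrow(predictions$values)), function(j) {
    x <- predictions$values[j, ]
    ct <- contingency(x, y, predictions$universe, restrict_to_reference)
    jz <- if (sum(x[idx]) > 0)
      jaccard_zscore(x[idx], y[idx], n_null = n_null, seed = seed + j)$z
    else NA_real_
    data.frame(submission = predictions$submissions[j],
               jaccard = jaccard(ct), jaccard_z = jz,
               mcc = as.numeric(mcc(ct)), tpr_minus_fpr = tpr_minus_fpr(ct))
  })
  rank_aggregate(do.call(rbind, rows))
}
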