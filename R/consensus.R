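#' Per-edge vote counts
#'
#' @param k integer vector of votes per candidate edge (each in `0..M`).
#' @param M number of voters contributing.
#' @param universe optional [build_universe()] object the counts refer to.
#' @return Object of class `vote_counts`.
#' @export
vote_counts <- function(k, M, universe = NULL) {
  k <- as.integer(k)
  M <- as.integer(M)
  if (M < 1) stop("M must be at least 1")
  if (any(k < 0) || any(k > M)) stop("vote counts must lie within 0..M")
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "edge_universe"))
    if (length(k) != length(universe))
      stop("vote vector length does not match the universe")
    names(k) <- universe$labels
  }
  structure(list(k = k, M = M, universe = universe), class = "vote_counts")
}

#' @export
print.vote_counts <- function(x, ...) {
  cat(sprintf("Vote counts: %d edges, M = %d voters\n", length(x$k), x$M))
  print(table(votes = x$k))
  invisible(x)
}

#' Count per-edge votes across submissions
#'
#' Tallies, for every candidate edge, how many retained submissions include
#' it; optionally a standard network (e.g. a silver standard) is added as
#' one extra voter, and named submissions can be excluded (e.g. to drop a
#' near-duplicate entry that would bias the consensus).
#'
#' @param predictions a [prediction_matrix()].
#' @param exclude character vector of submission ids to drop.
#' @param include_standard optional standard to add as one voter: a
#'   [network()], edge-label vector or 0/1 vector (see
#'   [as_standard_vector()]).
#' @return A [vote_counts()] object with `M` = retained submissions
#'   (+ 1 if a standard was included).
#' @export
count_votes <- function(predictions, exclude = NULL, include_standard = NULL) {
  stopifnot(inherits(predictions, "prediction_matrix"))
  keep <- predictions$submissions
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, keep)
    if (length(unknown))
      stop("unknown submission id(s) in exclude: ",
           paste(unknown, collapse = ", "))
    keep <- setdiff(keep, exclude)
  }
  if (!length(keep)) stop("no submissions left after exclusion")
  vals <- predictions$values[keep, , drop = FALSE]
  k <- colSums(vals)
  M <- length(keep)
  if (!is.null(include_standard)) {
    y <- as_standard_vector(include_standard, predictions$universe)
    k <- k + y
    M <- M + 1L
  }
  vote_counts(k, M, predictions$universe)
}

#' Build the consensus network at a vote threshold
#'
#' Keeps every candidate edge voted for by at least `threshold` voters.
#' Consensus edge sets are nested: raising the threshold never adds an
#' edge.
#'
#' @param votes a [vote_counts()] object.
#' @param threshold integer in `0..M`.
#' @param universe universe to resolve edges against; defaults to the one
#'   carried by `votes`.
#' @return A [network()] whose nodes are inherited from the universe's
#'   parent network and whose edges are the surviving candidates.
#' @export
build_consensus <- function(votes, threshold, universe = votes$universe) {
  stopifnot(inherits(votes, "vote_counts"))
  threshold <- as.integer(threshold)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0L || threshold > votes$M)
    stop("threshold must be a single integer within 0..M")
  if (is.null(universe)) stop("votes must carry an edge universe")
  keep <- votes$k >= threshold
  network(universe$edges[keep, , drop = FALSE],
          nodes = universe$network$nodes)
}

#' Per-edge consensus scores
#'
#' The consensus score of an edge is the fraction of voters that included
#' it, k/M.
#'
#' @param votes a [vote_counts()] object.
#' @return Named numeric vector in `[0, 1]` (names are edge labels when the
#'   votes carry a universe).
#' @export
consensus_scores <- function(votes) {
  stopifnot(inherits(votes, "vote_counts"))
  votes$k / votes$M
}

#' Mean consensus score between consecutive network layers
#'
#' Groups scored edges by (source layer -> target layer) and reports the
#' mean consensus score with its standard error for every consecutive pair
#' of the cascade (stimulus -> receptor -> adaptor -> signaling -> tf ->
#' target -> cytokine). Edges between non-consecutive layers (or touching
#' latent nodes) are collected in an `"other"` group with a warning. A
#' single-edge group has an undefined standard error (`NA`).
#'
#' @param net a [network()] carrying layer annotations for every scored
#'   edge endpoint.
#' @param scores named consensus-score vector (names `"source->target"`),
#'   e.g. from [consensus_scores()].
#' @return data.frame with `from_layer`, `to_layer`, `n`, `mean`, `se`.
#' @export
layer_consensus <- function(net, scores) {
  stopifnot(inherits(net, "crowdnet_network"))
  if (is.null(names(scores))) stop("scores must be named by edge label")
  ends <- split_edge_labels(names(scores))
  lay <- setNames(net$nodes$layer, net$nodes$id)
  missing <- setdiff(unique(c(ends$source, ends$target)), names(lay))
  if (length(missing))
    stop("scored edge endpoints missing from the network: ",
         paste(missing, collapse = ", "))
  cascade <- setdiff(LAYERS, "latent")
  from <- lay[ends$source]
  to <- lay[ends$target]
  consecutive <- !is.na(match(from, cascade)) &
    match(to, cascade) - match(from, cascade) == 1L
  consecutive[is.na(consecutive)] <- FALSE
  group <- ifelse(consecutive, paste0(from, "->", to), "other")
  if (any(group == "other"))
    warning(sum(group == "other"),
            " edge(s) not between consecutive layers assigned to 'other'")
  pairs <- c(paste0(cascade[-length(cascade)], "->", cascade[-1L]), "other")
  out <- lapply(intersect(pairs, unique(group)), function(g) {
    v <- scores[group == g]
    ft <- strsplit(g, "->", fixed = TRUE)[[1L]]
    data.frame(from_layer = ft[1L], to_layer = if (length(ft) > 1) ft[2L] else g,
               n = length(v), mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Mean consensus score of the edges around a node
#'
#' Summarizes how strongly the crowd agreed on the connectivity of one
#' node: `upstream` averages over its incoming edges, `downstream` over
#' its outgoing edges, `adjacent` over both.
#'
#' @param net a [network()] containing the node.
#' @param scores named consensus-score vector (names `"source->target"`).
#' @param node node identifier.
#' @param mode `"adjacent"` (default), `"upstream"` or `"downstream"`.
#' @return List with `mean`, `n` and `defined` (`FALSE` with `mean = NA`
#'   when no edge qualifies).
#' @export
node_consensus <- function(net, scores, node,
                           mode = c("adjacent", "upstream", "downstream")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "crowdnet_network"))
  if (!node %in% net$nodes$id) stop("unknown node: ", node)
  if (is.null(names(scores))) stop("scores must be named by edge label")
  ends <- split_edge_labels(names(scores))
  sel <- switch(mode,
                upstream = ends$target == node,
                downstream = ends$source == node,
                adjacent = ends$source == node | ends$target == node)
  if (!any(sel)) return(list(mean = NA_real_, n = 0L, defined = FALSE))
  list(mean = mean(scores[sel]), n = sum(sel), defined = TRUE)
}

#' Compare consensus scores between two score sets (e.g. species)
#'
#' Compares edge-level consensus scores from two crowds (such as the human
#' and rat networks) over a common edge subset. The default is Welch's
#' unequal-variance two-sample t test; a permutation test (group labels
#' shuffled within the subset) is provided as the distribution-free
#' reference and switches to exhaustive enumeration of all label
#' assignments when that is feasible.
#'
#' @param scores_a,scores_b consensus-score vectors over the same universe.
#' @param subset indices (or edge-label names) of the edges to compare;
#'   `NULL` compares all.
#' @param test `"welch"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed seed for the permutation stream.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` enumerates when there are at most 200000 assignments.
#' @return List with `difference` (mean(a) - mean(b)), `p_value`,
#'   `test`, `n`, `defined` (`FALSE` for the parametric test on subsets
#'   too small to admit it), and `exact` for permutation tests.
#' @export
compare_species <- function(scores_a, scores_b, subset = NULL,
                            test = c("welch", "permutation"),
                            n_perm = 10000, seed = 1, exact = NULL) {
  test <- match.arg(test)
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be over the same universe")
  if (is.null(subset)) subset <- seq_along(scores_a)
  a <- unname(scores_a[subset])
  b <- unname(scores_b[subset])
  if (!length(a)) stop("empty edge subset")
  n <- length(a)
  diff_obs <- mean(a) - mean(b)
  if (test == "welch") {
    if (n < 2 || (var(a) == 0 && var(b) == 0)) {
      return(list(difference = diff_obs, p_value = NA_real_, test = "welch",
                  n = n, defined = FALSE))
    }
    ht <- t.test(a, b)
    return(list(difference = diff_obs, p_value = ht$p.value, test = "welch",
                n = n, defined = TRUE))
  }
  pool <- c(a, b)
  n_tot <- 2L * n
  n_assign <- choose(n_tot, n)
  use_exact <- if (is.null(exact)) n_assign <= 2e5 else isTRUE(exact)
  tol <- 1e-12
  if (use_exact) {
    idx <- combn(n_tot, n)
    diffs <- apply(idx, 2L, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(abs(diffs) >= abs(diff_obs) - tol)
  } else {
    diffs <- with_seed(seed, replicate(n_perm, {
      i <- sample.int(n_tot, n)
      mean(pool[i]) - mean(pool[-i])
    }))
    p <- (1 + sum(abs(diffs) >= abs(diff_obs) - tol)) / (n_perm + 1)
  }
  list(difference = diff_obs, p_value = p, test = "permutation", n = n,
       defined = TRUE, exact = use_exact)
}
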