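#' Default discretization thresholds per data type
#'
#' Symmetric double thresholds on each readout scale: +/-2 on signed
#' fold-changes for expression, +/-3 standard residuals for
#' phosphoproteomics, +/-2 standard residuals for cytokine panels.
#' @export
default_thresholds <- function() {
  c(expression_foldchange = 2, phospho_residual = 3, cytokine_residual = 2)
}

#' Construct a stimulus x readout perturbation panel
#'
#' Continuous measurements of the network's measured nodes under a set of
#' perturbation experiments, each defined by its active stimuli.
#'
#' @param values numeric matrix, experiments x measured nodes (column
#'   names are node ids).
#' @param stimuli list of character vectors: the active stimulus nodes of
#'   each experiment (names become experiment ids).
#' @param data_type named character vector mapping each readout column to
#'   one of `expression_foldchange`, `phospho_residual`,
#'   `cytokine_residual`.
#' @return Object of class `experiment_panel`.
#' @export
experiment_panel <- function(values, stimuli, data_type) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("panel columns must be named by node id")
  if (length(stimuli) != nrow(values))
    stop("one stimuli set is required per experiment (row)")
  if (is.null(names(stimuli)))
    names(stimuli) <- sprintf("exp%02d", seq_along(stimuli))
  rownames(values) <- names(stimuli)
  missing_type <- setdiff(colnames(values), names(data_type))
  if (length(missing_type))
    stop("no data type for readout(s): ", paste(missing_type, collapse = ", "))
  data_type <- data_type[colnames(values)]
  bad <- setdiff(unique(data_type), names(default_thresholds()))
  if (length(bad)) stop("unknown data type(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, stimuli = stimuli, data_type = data_type),
            class = "experiment_panel")
}

#' @export
print.experiment_panel <- function(x, ...) {
  cat(sprintf("Perturbation panel: %d experiments x %d readouts\n",
              nrow(x$values), ncol(x$values)))
  print(table(data_type = x$data_type))
  invisible(x)
}

#' Read / write perturbation panels as CSV
#'
#' The CSV carries `experiment_id`, `stimuli` (semicolon-separated active
#' stimuli) and one column per readout; the readout-to-data-type map
#' travels in a JSON sidecar (default `<path>.types.json`).
#'
#' @param path CSV path.
#' @param data_type named character vector, or path to the JSON map;
#'   `NULL` reads the default sidecar.
#' @export
read_panel <- function(path, data_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("experiment_id", "stimuli") %in% names(tab)[1:2]))
    stop("panel CSV must start with experiment_id and stimuli columns: ", path)
  if (is.null(data_type)) data_type <- paste0(path, ".types.json")
  if (is.character(data_type) && length(data_type) == 1L &&
      is.null(names(data_type)))
    data_type <- unlist(jsonlite::read_json(data_type))
  values <- as.matrix(tab[-(1:2)])
  stimuli <- strsplit(tab$stimuli, ";", fixed = TRUE)
  names(stimuli) <- tab$experiment_id
  experiment_panel(values, stimuli, data_type)
}

#' @rdname read_panel
#' @param panel an [experiment_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "experiment_panel"))
  tab <- data.frame(experiment_id = names(panel$stimuli),
                    stimuli = vapply(panel$stimuli, paste, "", collapse = ";"),
                    panel$values, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(panel$data_type), paste0(path, ".types.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Double-threshold discretization of a perturbation panel
#'
#' Maps each continuous readout to a ternary call using the symmetric
#' double threshold of its data type: +1 if v >= t, -1 if v <= -t, else 0.
#' Values exactly at a threshold are called (inclusive boundary); missing
#' values propagate as `NA`. The map is odd-symmetric:
#' discretize(-v) = -discretize(v).
#'
#' @param panel an [experiment_panel()].
#' @param thresholds named positive thresholds per data type; defaults to
#'   [default_thresholds()].
#' @return Object of class `discretized_panel`: ternary `values` matrix
#'   plus the `thresholds` used, `stimuli` and `data_type`.
#' @export
discretize <- function(panel, thresholds = default_thresholds()) {
  stopifnot(inherits(panel, "experiment_panel"))
  missing_thr <- setdiff(unique(panel$data_type), names(thresholds))
  if (length(missing_thr))
    stop("no threshold for data type(s): ", paste(missing_thr, collapse = ", "))
  if (any(thresholds <= 0)) stop("thresholds must be strictly positive")
  t_col <- thresholds[panel$data_type]
  calls <- panel$values
  for (j in seq_len(ncol(calls))) {
    v <- panel$values[, j]
    calls[, j] <- ifelse(is.na(v), NA_real_,
                         ifelse(v >= t_col[j], 1, ifelse(v <= -t_col[j], -1, 0)))
  }
  structure(list(values = calls, thresholds = thresholds,
                 stimuli = panel$stimuli, data_type = panel$data_type),
            class = "discretized_panel")
}

#' Boolean OR-propagation of stimulus activity over kept edges
#'
#' Computes the least fixed point of the activating-OR semantics: a
#' non-stimulus node is active (1) iff at least one retained incoming edge
#' originates from an active node; the active stimuli are clamped to 1.
#' Acyclic layered maps reach the fixed point in one forward sweep; cycles
#' are handled by iterating to the least fixed point.
#'
#' @param net a [network()].
#' @param stimuli character vector of active stimulus node ids.
#' @param kept edges retained in the model: a logical vector over
#'   `net$edges` rows, a character vector of `"source->target"` labels, or
#'   `NULL` for all edges.
#' @return Named integer 0/1 state vector over all nodes.
#' @export
propagate <- function(net, stimuli, kept = NULL) {
  stopifnot(inherits(net, "crowdnet_network"))
  unknown <- setdiff(stimuli, net$nodes$id)
  if (length(unknown)) stop("unknown stimulus node(s): ",
                            paste(unknown, collapse = ", "))
  ids <- net$nodes$id
  src <- match(net$edges$source, ids)
  dst <- match(net$edges$target, ids)
  ok <- edge_keep_mask(net, kept)
  state <- reach_states(length(ids), src, dst, ok, match(stimuli, ids))
  setNames(as.integer(state), ids)
}

edge_keep_mask <- function(net, kept) {
  m <- nrow(net$edges)
  if (is.null(kept)) return(rep(TRUE, m))
  if (is.logical(kept)) {
    if (length(kept) != m) stop("logical kept mask must cover all edges")
    return(kept)
  }
  labs <- edge_labels(net$edges)
  unknown <- setdiff(kept, labs)
  if (length(unknown)) stop("kept edges not in the network: ",
                            paste(unknown, collapse = ", "))
  labs %in% kept
}

# BFS depth of every node from the set of source nodes (no incoming edge);
# unreachable nodes get the maximum depth + 1
node_depths <- function(n, src, dst) {
  depth <- rep(NA_integer_, n)
  depth[setdiff(seq_len(n), unique(dst))] <- 0L
  current <- 0L
  repeat {
    frontier <- which(depth == current)
    if (!length(frontier)) break
    nxt <- unique(dst[src %in% frontier])
    nxt <- nxt[is.na(depth[nxt])]
    if (length(nxt)) depth[nxt] <- current + 1L
    current <- current + 1L
  }
  depth[is.na(depth)] <- current + 1L
  depth
}

# vectorized least fixed point of OR-propagation
reach_states <- function(n, src, dst, edge_ok, active0) {
  active <- logical(n)
  active[active0] <- TRUE
  repeat {
    firing <- edge_ok & active[src] & !active[dst]
    if (!any(firing)) break
    active[dst[firing]] <- TRUE
  }
  active
}

# mismatches of a kept-edge assignment against expectations; expect is a
# list per experiment of (node index, expected state)
count_mismatches <- function(n, src, dst, edge_ok, stim_idx, expect) {
  total <- 0L
  for (e in seq_along(stim_idx)) {
    st <- reach_states(n, src, dst, edge_ok, stim_idx[[e]])
    exp_e <- expect[[e]]
    if (nrow(exp_e))
      total <- total + sum(st[exp_e$node] != exp_e$state)
  }
  total
}

#' Prune a reference network against discretized data (exact 0/1 program)
#'
#' Finds the subset of reference edges minimizing the number of mismatches
#' between the Boolean model's predictions and the discretized calls, plus
#' a small parsimony penalty per kept edge. The program over binary
#' edge-inclusion and node-state variables (with the OR constraints
#' linearized in the usual way) is solved exactly: because the unsigned
#' activating-OR semantics make node states the reachability closure of
#' the kept edge set, the solver is a specialized branch-and-bound over
#' edge-inclusion variables with reachability-based lower bounds, and
#' returns a provably optimal solution. A +1 call expects the node active;
#' 0 and -1 calls expect it inactive (the reference map is unsigned);
#' `NA` calls are unconstrained.
#'
#' Edges that cannot influence any constrained readout under any
#' assignment are removed up front by the parsimony term. The result is
#' deterministic: search starts from a greedy-refined keep-all incumbent
#' and replaces it only with strictly better solutions, visited in a
#' fixed top-down order (source depth, then lexicographic edge label), so
#' ties between equally optimal edge sets always resolve the same way.
#'
#' @param net the reference [network()].
#' @param data a [discretize()]d panel whose columns are measured nodes of
#'   `net`.
#' @param edge_penalty parsimony penalty per kept edge; the default
#'   1/(10 * |E|) can never trade against a single mismatch.
#' @param max_iter search-node budget; exceeding it raises an error
#'   carrying the best incumbent found.
#' @return Object of class `pruning_result`: `kept` / `removed` edge
#'   data.frames, `mismatches`, `objective`, `states` (fitted 0/1 states,
#'   experiments x nodes), `edge_penalty`, `status`.
#' @export
prune_ilp <- function(net, data, edge_penalty = NULL, max_iter = 5e6) {
  stopifnot(inherits(net, "crowdnet_network"),
            inherits(data, "discretized_panel"))
  if (nrow(data$values) == 0) stop("panel is empty")
  ids <- net$nodes$id
  bad <- setdiff(colnames(data$values), ids[net$nodes$measured])
  if (length(bad))
    stop("panel readout(s) are not measured nodes of the network: ",
         paste(bad, collapse = ", "))
  m <- nrow(net$edges)
  n <- length(ids)
  if (is.null(edge_penalty)) edge_penalty <- 1 / (10 * max(m, 1L))
  eps <- edge_penalty
  src <- match(net$edges$source, ids)
  dst <- match(net$edges$target, ids)
  labs <- edge_labels(net$edges)

  stim_idx <- lapply(data$stimuli, function(s) {
    unknown <- setdiff(s, ids)
    if (length(unknown)) stop("unknown stimulus node(s): ",
                              paste(unknown, collapse = ", "))
    match(s, ids)
  })
  col_idx <- match(colnames(data$values), ids)
  expect <- lapply(seq_len(nrow(data$values)), function(e) {
    calls <- data$values[e, ]
    keep <- !is.na(calls)
    data.frame(node = col_idx[keep], state = as.integer(calls[keep] == 1))
  })

  # edges that can never influence a constrained readout are dropped by
  # the parsimony term without searching over them
  pot_active <- reach_states(n, src, dst, rep(TRUE, m),
                             unique(unlist(stim_idx)))
  constrained <- unique(unlist(lapply(expect, `[[`, "node")))
  can_reach <- reach_states(n, dst, src, rep(TRUE, m), constrained)
  relevant <- which(pot_active[src] & can_reach[dst])
  # branch top-down (upstream edges first) so reachability bounds bind as
  # early as possible; ties within a depth are lexicographic by label
  depth <- node_depths(n, src, dst)
  relevant <- relevant[order(depth[src[relevant]], labs[relevant])]

  status <- rep(NA, m)         # NA undecided, TRUE kept, FALSE removed
  status[-relevant] <- FALSE
  if (!length(relevant)) {
    mis <- count_mismatches(n, src, dst, rep(FALSE, m), stim_idx, expect)
    return(finish_pruning(net, rep(FALSE, m), mis, eps, data, "optimal"))
  }

  # minimum number of undecided edges on any path from the active set to
  # each node (kept edges are free, removed edges unusable); Bellman-Ford
  # style relaxation, cheap at this scale
  undecided_dist <- function(active, usable, w) {
    d <- rep(Inf, n)
    d[active] <- 0
    repeat {
      nd <- d[src] + w
      relax <- usable & nd < d[dst]
      if (!any(relax)) break
      for (i in which(relax)) d[dst[i]] <- min(d[dst[i]], nd[i])
    }
    d
  }

  lower_bound <- function(status) {
    kept_only <- !is.na(status) & status
    possible <- is.na(status) | status
    w <- ifelse(kept_only, 0, 1)
    mism <- 0L
    has_kept_in <- tabulate(dst[kept_only], nbins = n) > 0L
    needy <- logical(n)
    max_dist <- 0
    for (e in seq_along(stim_idx)) {
      exp_e <- expect[[e]]
      if (!nrow(exp_e)) next
      a_min <- reach_states(n, src, dst, kept_only, stim_idx[[e]])
      a_max <- reach_states(n, src, dst, possible, stim_idx[[e]])
      mism <- mism + sum(exp_e$state == 0L & a_min[exp_e$node]) +
        sum(exp_e$state == 1L & !a_max[exp_e$node])
      # nodes that must become active but are not yet kept-reachable and
      # have no kept incoming edge each still need one distinct kept edge
      need <- exp_e$node[exp_e$state == 1L & !a_min[exp_e$node] &
                           a_max[exp_e$node]]
      needy[need[!has_kept_in[need]]] <- TRUE
      if (length(need)) {
        d <- undecided_dist(which(a_min), possible, w)
        max_dist <- max(max_dist, max(d[need]))
      }
    }
    mism + eps * (sum(status, na.rm = TRUE) + max(sum(needy), max_dist))
  }

  objective_of <- function(kept) {
    count_mismatches(n, src, dst, kept, stim_idx, expect) + eps * sum(kept)
  }

  # greedy descent from keep-all: repeatedly drop any edge whose removal
  # lowers the objective, in branch order, until stable; this incumbent is
  # usually optimal or one lattice step away and makes the exact search a
  # tight verification
  greedy <- status | is.na(status)
  repeat {
    improved <- FALSE
    obj_cur <- objective_of(greedy)
    for (e in relevant) {
      if (!greedy[e]) next
      cand <- greedy; cand[e] <- FALSE
      obj_cand <- objective_of(cand)
      if (obj_cand < obj_cur - 1e-12) {
        greedy <- cand
        obj_cur <- obj_cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best <- list(obj = obj_cur, status = greedy,
               mism = count_mismatches(n, src, dst, greedy, stim_idx, expect))

  # objectives live on a lattice spaced by eps (mismatches are integers),
  # so a candidate branch must undercut the incumbent by a full step
  margin <- min(eps, 1) / 2
  iter <- 0L
  truncated <- FALSE
  # iterative DFS; each frame is (depth in `relevant`, status snapshot)
  stack <- list(list(d = 1L, status = status))
  while (length(stack)) {
    frame <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    iter <- iter + 1L
    if (iter > max_iter) { truncated <- TRUE; break }
    st <- frame$status
    lb <- lower_bound(st)
    if (lb > best$obj - margin) next
    d <- frame$d
    if (d > length(relevant)) {
      kept <- !is.na(st) & st
      mis <- count_mismatches(n, src, dst, kept, stim_idx, expect)
      obj <- mis + eps * sum(kept)
      if (obj < best$obj - margin)
        best <- list(obj = obj, status = kept, mism = mis)
      next
    }
    e <- relevant[d]
    st_keep <- st; st_keep[e] <- TRUE
    st_rm <- st; st_rm[e] <- FALSE
    # push keep first so the remove branch is explored first (LIFO):
    # improvements are found along aggressive-removal paths first
    stack[[length(stack) + 1L]] <- list(d = d + 1L, status = st_keep)
    stack[[length(stack) + 1L]] <- list(d = d + 1L, status = st_rm)
  }
  if (truncated) {
    err <- simpleError(sprintf(
      "prune_ilp search budget exceeded after %d nodes", max_iter))
    err$incumbent <- if (is.finite(best$obj))
      finish_pruning(net, best$status, best$mism, eps, data, "incumbent")
    stop(err)
  }
  finish_pruning(net, best$status, best$mism, eps, data, "optimal")
}

finish_pruning <- function(net, kept_mask, mismatches, eps, data, status) {
  ids <- net$nodes$id
  states <- t(vapply(data$stimuli, function(s)
    propagate(net, s, kept = kept_mask), setNames(integer(length(ids)), ids)))
  structure(list(kept = net$edges[kept_mask, , drop = FALSE],
                 removed = net$edges[!kept_mask, , drop = FALSE],
                 mismatches = as.integer(mismatches),
                 objective = mismatches + eps * sum(kept_mask),
                 states = states,
                 edge_penalty = eps,
                 status = status),
            class = "pruning_result")
}

#' @export
print.pruning_result <- function(x, ...) {
  cat(sprintf("Network pruning (%s): kept %d / %d edges, %d mismatch(es)\n",
              x$status, nrow(x$kept), nrow(x$kept) + nrow(x$removed),
              x$mismatches))
  invisible(x)
}

set_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)  # two empty sets are identical
  length(intersect(a, b)) / u
}

#' Threshold sensitivity of the pruned network
#'
#' Re-runs discretization and pruning over a grid of discretization
#' thresholds and reports the Jaccard similarity of each kept-edge set to
#' the result at the base thresholds, quantifying how robust the pruned
#' network is to the discretization choice.
#'
#' @param net the reference [network()].
#' @param panel the continuous [experiment_panel()].
#' @param threshold_grid named list: candidate thresholds per data type
#'   (types absent from the list stay at their base value).
#' @param base_thresholds thresholds defining the reference result.
#' @param ... passed to [prune_ilp()].
#' @return data.frame with one threshold column per data type, `n_kept`,
#'   `mismatches` and `jaccard_to_base`.
#' @export
sensitivity_sweep <- function(net, panel, threshold_grid,
                              base_thresholds = default_thresholds(), ...) {
  stopifnot(inherits(panel, "experiment_panel"))
  if (!length(threshold_grid)) stop("threshold grid is empty")
  base_res <- prune_ilp(net, discretize(panel, base_thresholds), ...)
  base_set <- edge_labels(base_res$kept)
  grid <- expand.grid(threshold_grid, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    thr <- base_thresholds
    thr[names(grid)] <- unlist(grid[i, , drop = FALSE])
    res <- prune_ilp(net, discretize(panel, thr), ...)
    cbind(grid[i, , drop = FALSE],
          data.frame(n_kept = nrow(res$kept), mismatches = res$mismatches,
                     jaccard_to_base = set_jaccard(edge_labels(res$kept),
                                                   base_set)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
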