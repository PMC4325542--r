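#' @importFrom stats sd setNames rbinom rnorm runif rbeta rhyper dhyper t.test
#'   plogis qlogis optim quantile var complete.cases
#' @importFrom utils read.delim write.table combn head modifyList
NULL

# canonical top-down layer order of the signaling map; "latent" sits outside
# the cascade and marks unannotated / unmeasured intermediates
LAYERS <- c("stimulus", "receptor", "adaptor", "signaling", "tf",
            "target", "cytokine", "latent")

#' Construct a directed layered signaling network
#'
#' A network is a set of uniquely identified nodes, each carrying a layer
#' annotation (stimulus, receptor, adaptor, signaling, tf, target, cytokine,
#' or latent) and a measured flag, plus a duplicate-free set of directed
#' edges. Edges are unsigned (activating); self-loops are rejected.
#'
#' @param edges data.frame (or 2-column matrix) with columns `source`,
#'   `target` of node identifiers.
#' @param nodes optional data.frame with columns `id`, `layer`, `measured`.
#'   Nodes appearing in `edges` but not listed here default to
#'   `layer = "latent"`, `measured = FALSE`. Latent nodes must be unmeasured.
#' @return An object of class `crowdnet_network` with elements `nodes`
#'   (data.frame `id`, `layer`, `measured`) and `edges` (data.frame
#'   `source`, `target`).
#' @examples
#' net <- network(data.frame(source = c("S", "A"), target = c("A", "P")),
#'                nodes = data.frame(id = c("S", "A", "P"),
#'                                   layer = c("stimulus", "latent", "signaling"),
#'                                   measured = c(FALSE, FALSE, TRUE)))
#' net
#' @export
network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have columns source and target")
  edges <- data.frame(source = as.character(edges[[1L]]),
                      target = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  if (anyNA(edges) || any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
    stop("edge endpoints must be non-empty identifiers")
  if (any(edges$source == edges$target))
    stop("self-loops are not allowed: ",
         paste(unique(edges$source[edges$source == edges$target]),
               collapse = ", "))
  edges <- unique(edges)
  rownames(edges) <- NULL

  edge_ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- data.frame(id = edge_ids, layer = "latent", measured = FALSE,
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!all(c("id", "layer", "measured") %in% names(nodes)))
      stop("nodes must have columns id, layer, measured")
    nodes <- data.frame(id = as.character(nodes$id),
                        layer = as.character(nodes$layer),
                        measured = as.logical(nodes$measured),
                        stringsAsFactors = FALSE)
    if (anyDuplicated(nodes$id))
      stop("duplicate node ids: ",
           paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
    bad <- setdiff(nodes$layer, LAYERS)
    if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
    missing_nodes <- setdiff(edge_ids, nodes$id)
    if (length(missing_nodes))
      nodes <- rbind(nodes, data.frame(id = missing_nodes, layer = "latent",
                                       measured = FALSE))
  }
  if (any(nodes$layer == "latent" & nodes$measured))
    stop("latent nodes must be unmeasured")
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "crowdnet_network")
}

#' @export
print.crowdnet_network <- function(x, ...) {
  cat(sprintf("Directed network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  tab <- table(factor(x$nodes$layer, levels = LAYERS))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  cat(sprintf("  measured nodes: %d\n", sum(x$nodes$measured)))
  invisible(x)
}

edge_labels <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  paste0(edges$source, "->", edges$target)
}

split_edge_labels <- function(labels) {
  parts <- strsplit(labels, "->", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed edge label(s): ",
                     paste(labels[bad], collapse = ", "))
  data.frame(source = vapply(parts, `[`, "", 1L),
             target = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a network from a SIF or two-column TSV edge list
#'
#' SIF rows are `source<TAB>relation<TAB>target`; the relation column is
#' parsed but collapsed to "activating" (the reference map is unsigned).
#' The `tsv` format is a headered two-column `source`/`target` table.
#' An optional companion node table (TSV with header `id`, `layer`,
#' `measured`) supplies annotations; unannotated nodes default to
#' latent/unmeasured.
#'
#' @param path path to the edge-list file.
#' @param format `"sif"` (default) or `"tsv"`.
#' @param nodes_path optional path to the node-annotation TSV.
#' @param allow_isolated if `TRUE`, node-table ids absent from the edge list
#'   are accepted as isolated nodes; otherwise such dangling annotations are
#'   a validation error.
#' @return A [network()] object.
#' @export
read_network <- function(path, format = c("sif", "tsv"), nodes_path = NULL,
                         allow_isolated = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "sif") {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines)) {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(fields) != 3L)
      if (length(bad))
        stop(sprintf("malformed SIF row at line %d of %s: expected 3 tab-separated fields, got %d",
                     bad[1L], path, lengths(fields)[bad[1L]]))
      edges <- data.frame(source = vapply(fields, `[`, "", 1L),
                          target = vapply(fields, `[`, "", 3L),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(source = character(), target = character())
    }
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(tab)))
      stop("tsv edge list must have columns source and target: ", path)
    edges <- tab[c("source", "target")]
  }

  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- read.delim(nodes_path, stringsAsFactors = FALSE)
    if (!all(c("id", "layer", "measured") %in% names(nodes)))
      stop("node table must have columns id, layer, measured: ", nodes_path)
    dangling <- setdiff(nodes$id, unique(c(edges$source, edges$target)))
    if (length(dangling) && !allow_isolated)
      stop("node annotation(s) not present in any edge and not declared isolated: ",
           paste(dangling, collapse = ", "))
  }
  network(edges, nodes = nodes)
}

#' Write a network as SIF plus a node-annotation table
#'
#' Round-trips with [read_network()]: the node set, edge set and annotations
#' are recovered exactly (pass `allow_isolated = TRUE` when isolated nodes
#' are present).
#'
#' @param net a [network()] object.
#' @param path output SIF path.
#' @param nodes_path output node-table path; defaults to `path` with a
#'   `.nodes.tsv` suffix. `NA` suppresses the node table.
#' @export
write_network <- function(net, path, nodes_path = paste0(path, ".nodes.tsv")) {
  stopifnot(inherits(net, "crowdnet_network"))
  sif <- if (nrow(net$edges))
    paste(net$edges$source, "activates", net$edges$target, sep = "\t")
  else character()
  writeLines(sif, path)
  if (!is.na(nodes_path))
    write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Build the ordered candidate-edge universe
#'
#' The universe is the ordered list of candidate edges over which binary
#' predictions are expressed: the reference edges first (in reference
#' order), then any extra candidate edges deduplicated and sorted
#' lexicographically, so matrix columns are reproducible across runs. Extra
#' edges may only connect nodes already present in the reference (the
#' no-new-nodes rule).
#'
#' @param reference a [network()] object.
#' @param extra_edges optional data.frame/matrix of additional candidate
#'   edges (`source`, `target`).
#' @return An object of class `edge_universe`: list with `edges`
#'   (data.frame), `labels` (`"source->target"`), `n_ref` (number of
#'   reference edges, occupying positions `1:n_ref`), and `network` (the
#'   reference network).
#' @export
build_universe <- function(reference, extra_edges = NULL) {
  stopifnot(inherits(reference, "crowdnet_network"))
  edges <- reference$edges
  n_ref <- nrow(edges)
  if (!is.null(extra_edges) && NROW(extra_edges) > 0) {
    extra <- as.data.frame(extra_edges, stringsAsFactors = FALSE)
    extra <- data.frame(source = as.character(extra[[1L]]),
                        target = as.character(extra[[2L]]),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(extra$source, extra$target)), reference$nodes$id)
    if (length(unknown))
      stop("extra edges may not introduce new nodes: ",
           paste(unknown, collapse = ", "))
    extra <- unique(extra)
    extra <- extra[!(edge_labels(extra) %in% edge_labels(edges)), , drop = FALSE]
    extra <- extra[order(extra$source, extra$target), , drop = FALSE]
    edges <- rbind(edges, extra)
  }
  rownames(edges) <- NULL
  if (nrow(edges) < 1L) stop("universe must contain at least one edge")
  structure(list(edges = edges, labels = edge_labels(edges),
                 n_ref = n_ref, network = reference),
            class = "edge_universe")
}

#' @export
print.edge_universe <- function(x, ...) {
  cat(sprintf("Edge universe: %d candidate edges (%d reference, %d extra)\n",
              nrow(x$edges), x$n_ref, nrow(x$edges) - x$n_ref))
  invisible(x)
}

#' @export
length.edge_universe <- function(x) nrow(x$edges)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes$id)
}

# node ids reachable from `from` (character vector) along directed edges,
# including the sources themselves; implemented with a virtual super-source
reachable_from <- function(net, from, reverse = FALSE) {
  if (!length(from)) return(character())
  edges <- net$edges
  if (reverse) edges <- data.frame(source = edges$target, target = edges$source)
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(source = ".super.", target = from), edges),
    directed = TRUE, vertices = c(".super.", net$nodes$id))
  reached <- igraph::subcomponent(g, ".super.", mode = "out")
  setdiff(names(reached), ".super.")
}

#' Remove latent nodes off all stimulus-to-measured paths
#'
#' Latent (unmeasured, unannotated-layer) nodes are retained only if they
#' lie on some directed path from a stimulus node to a measured node,
#' determined by forward reachability from the stimuli intersected with
#' backward reachability from the measured nodes. All non-latent nodes are
#' kept; edges incident to removed nodes are dropped. The operation is
#' idempotent.
#'
#' @param net a [network()] object with at least one stimulus or measured
#'   node.
#' @return The pruned [network()].
#' @export
prune_unreachable <- function(net) {
  stopifnot(inherits(net, "crowdnet_network"))
  stim <- net$nodes$id[net$nodes$layer == "stimulus"]
  meas <- net$nodes$id[net$nodes$measured]
  if (!length(stim) && !length(meas))
    stop("network has no stimulus or measured node")
  fwd <- reachable_from(net, stim)
  bwd <- reachable_from(net, meas, reverse = TRUE)
  latent <- net$nodes$id[net$nodes$layer == "latent"]
  drop <- latent[!(latent %in% fwd & latent %in% bwd)]
  keep_nodes <- net$nodes[!(net$nodes$id %in% drop), , drop = FALSE]
  keep_edges <- net$edges[!(net$edges$source %in% drop |
                            net$edges$target %in% drop), , drop = FALSE]
  network(keep_edges, nodes = keep_nodes)
}

#' Precision of high-vote edges against a knowledge network
#'
#' For each vote threshold k, the edges with at least k votes are compared
#' with an externally supplied knowledge edge set:
#' precision(k) = |survivors intersect knowledge| / |survivors|. Survivor
#' sets are nested in k, so precision traces how agreement with the
#' knowledge base changes as the required consensus grows. An empty
#' survivor set yields `NA` precision (flagged in the `defined` column).
#'
#' @param votes a [vote_counts()] object (with its universe).
#' @param knowledge knowledge edges: a [network()], a data.frame of
#'   `source`/`target`, or a character vector of `"source->target"` labels.
#' @param thresholds integer vote thresholds, each within `0..M`.
#' @return data.frame with columns `threshold`, `n_edges`, `n_matched`,
#'   `precision`, `defined`.
#' @export
precision_at_threshold <- function(votes, knowledge, thresholds) {
  stopifnot(inherits(votes, "vote_counts"))
  if (is.null(votes$universe))
    stop("votes must carry an edge universe")
  thresholds <- as.integer(thresholds)
  if (any(thresholds < 0L | thresholds > votes$M))
    stop("thresholds must lie within 0..M")
  know <- if (inherits(knowledge, "crowdnet_network")) edge_labels(knowledge$edges)
          else if (is.data.frame(knowledge)) edge_labels(knowledge)
          else as.character(knowledge)
  labs <- votes$universe$labels
  out <- lapply(thresholds, function(k) {
    surv <- labs[votes$k >= k]
    n <- length(surv)
    hit <- sum(surv %in% know)
    data.frame(threshold = k, n_edges = n, n_matched = hit,
               precision = if (n > 0) hit / n else NA_real_,
               defined = n > 0)
  })
  do.call(rbind, out)
}
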