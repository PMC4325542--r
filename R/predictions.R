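#' Construct a matrix of binary network predictions
#'
#' Each submission is a binary vector over the candidate-edge universe:
#' entry (j, i) is 1 when submission j includes candidate edge i.
#'
#' @param values M x N matrix of 0/1 values (rows = submissions).
#' @param universe the [build_universe()] object the columns refer to.
#' @param submissions optional character vector of submission identifiers;
#'   defaults to the rownames of `values` or `sub01`, `sub02`, ...
#' @return Object of class `prediction_matrix`: list with `values`,
#'   `universe`, `submissions`.
#' @export
prediction_matrix <- function(values, universe, submissions = NULL) {
  stopifnot(inherits(universe, "edge_universe"))
  values <- as.matrix(values)
  if (ncol(values) != length(universe))
    stop(sprintf("prediction matrix has %d columns but the universe has %d edges",
                 ncol(values), length(universe)))
  if (!all(values %in% c(0, 1)))
    stop("prediction entries must be 0 or 1")
  storage.mode(values) <- "integer"
  if (is.null(submissions))
    submissions <- rownames(values) %||%
      sprintf("sub%02d", seq_len(nrow(values)))
  if (anyDuplicated(submissions)) stop("duplicate submission identifiers")
  dimnames(values) <- list(submissions, universe$labels)
  structure(list(values = values, universe = universe,
                 submissions = submissions),
            class = "prediction_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("Prediction matrix: %d submissions x %d candidate edges\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  mean edges per submission: %.1f\n", mean(rowSums(x$values))))
  invisible(x)
}

#' Read / write prediction matrices as TSV
#'
#' The on-disk dialect is one header row of edge labels (`source->target`)
#' preceded by a `submission` column, then one row of 0/1 values per
#' submission.
#'
#' @param path file path.
#' @param universe the edge universe the columns must match; if `NULL` a
#'   bare universe is reconstructed from the header labels.
#' @return [prediction_matrix()] for the reader; the path, invisibly, for
#'   the writer.
#' @export
read_predictions <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "submission")
    stop("first column of a predictions TSV must be 'submission': ", path)
  values <- as.matrix(tab[-1L])
  rownames(values) <- tab$submission
  if (is.null(universe)) {
    edges <- split_edge_labels(colnames(values))
    universe <- build_universe(network(edges))
  } else if (!identical(colnames(values), universe$labels)) {
    stop("prediction columns do not match the supplied universe")
  }
  prediction_matrix(values, universe)
}

#' @rdname read_predictions
#' @param predictions a [prediction_matrix()].
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(inherits(predictions, "prediction_matrix"))
  tab <- data.frame(submission = predictions$submissions,
                    predictions$values, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Represent a (gold or silver) standard as a binary vector over a universe
#'
#' @param x a [network()] whose edges are looked up in the universe, a
#'   character vector of edge labels, or a 0/1 vector of length N.
#' @param universe an [build_universe()] object.
#' @return Integer 0/1 vector of length N named by edge label.
#' @export
as_standard_vector <- function(x, universe) {
  stopifnot(inherits(universe, "edge_universe"))
  if (inherits(x, "crowdnet_network")) x <- edge_labels(x$edges)
  if (is.character(x)) {
    y <- as.integer(universe$labels %in% x)
  } else {
    if (length(x) != length(universe))
      stop("standard vector length does not match the universe")
    if (!all(x %in% c(0, 1))) stop("standard entries must be 0 or 1")
    y <- as.integer(x)
  }
  names(y) <- universe$labels
  y
}
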