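#' Generate a random layered signaling network
#'
#' Emulates the top-down cascade architecture of a literature-derived
#' reference map: nodes are organized in layers (stimulus -> receptor ->
#' adaptor -> signaling -> tf -> target -> cytokine) and edges are drawn
#' independently between consecutive layers only, oriented top-down.
#' Every non-stimulus node is guaranteed at least one incoming edge (one
#' is drawn from the upstream layer when sampling leaves it orphaned).
#' The default sizes give a few-dozen-node, ~100-edge scaled-down version
#' of a realistic reference map.
#'
#' @param layer_sizes named integer vector of node counts per layer (in
#'   cascade order; at least a stimulus layer and one measured layer).
#' @param edge_density probability of each possible edge between
#'   consecutive layers, a scalar in (0, 1].
#' @param measured_layers layers whose nodes carry readouts.
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @return A [network()].
#' @export
gen_layered_network <- function(layer_sizes = c(stimulus = 3, receptor = 3,
                                                adaptor = 3, signaling = 4,
                                                tf = 4, target = 4,
                                                cytokine = 3),
                                edge_density = 0.3,
                                measured_layers = c("signaling", "target",
                                                    "cytokine"),
                                seed = 1) {
  layers <- names(layer_sizes)
  if (is.null(layers) || any(!layers %in% setdiff(LAYERS, "latent")))
    stop("layer_sizes must be named by cascade layers")
  if (!"stimulus" %in% layers) stop("a stimulus layer is required")
  if (!any(measured_layers %in% layers))
    stop("at least one measured layer is required")
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must lie in (0, 1]")
  if (any(layer_sizes < 1)) stop("empty layer: every listed layer needs nodes")
  layers <- intersect(setdiff(LAYERS, "latent"), layers)  # cascade order

  prefix <- c(stimulus = "STIM", receptor = "REC", adaptor = "ADA",
              signaling = "SIG", tf = "TF", target = "TGT", cytokine = "CYT")
  node_ids <- lapply(layers, function(l)
    sprintf("%s%02d", prefix[[l]], seq_len(layer_sizes[[l]])))
  names(node_ids) <- layers
  nodes <- data.frame(id = unlist(node_ids, use.names = FALSE),
                      layer = rep(layers, lengths(node_ids)),
                      measured = rep(layers %in% measured_layers,
                                     lengths(node_ids)))

  edges <- with_seed(seed, {
    out <- list()
    for (i in seq_len(length(layers) - 1L)) {
      up <- node_ids[[i]]
      dn <- node_ids[[i + 1L]]
      grid <- expand.grid(source = up, target = dn,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      pick <- runif(nrow(grid)) < edge_density
      sub <- grid[pick, , drop = FALSE]
      # guarantee incoming connectivity for the downstream layer
      orphan <- setdiff(dn, sub$target)
      if (length(orphan))
        sub <- rbind(sub, data.frame(source = sample(up, length(orphan),
                                                     replace = TRUE),
                                     target = orphan))
      out[[i]] <- sub
    }
    do.call(rbind, out)
  })
  rownames(edges) <- NULL
  network(edges, nodes = nodes)
}

#' Sample a connectivity-preserving active sub-network
#'
#' Draws the "biologically active" sub-network that perturbation data are
#' generated from: each reference edge is retained independently with
#' probability `keep_prob`, but every non-stimulus node keeps at least one
#' incoming edge (re-drawn among its reference in-edges), so stimuli can
#' still propagate to readouts. This mirrors a reference map in which many
#' catalogued reactions are inactive in the assayed context while the
#' cascade itself stays wired.
#'
#' @param reference the reference [network()].
#' @param keep_prob probability each edge stays active.
#' @param seed integer seed.
#' @return A [network()] over the same node set.
#' @export
gen_subnetwork <- function(reference, keep_prob = 0.7, seed = 1) {
  stopifnot(inherits(reference, "crowdnet_network"))
  if (keep_prob <= 0 || keep_prob > 1) stop("keep_prob must lie in (0, 1]")
  edges <- reference$edges
  kept <- with_seed(seed, {
    keep <- runif(nrow(edges)) < keep_prob
    for (node in setdiff(unique(edges$target), character())) {
      inc <- which(edges$target == node)
      if (!any(keep[inc])) keep[inc[sample.int(length(inc), 1L)]] <- TRUE
    }
    keep
  })
  network(edges[kept, , drop = FALSE], nodes = reference$nodes)
}

#' Draw a ground-truth edge vector over a universe
#'
#' Marks exactly `round(pi1 * N)` candidate edges as true, uniformly at
#' random without replacement, so the number of true edges E is exact and
#' recovery experiments are sharp. `method = "bernoulli"` instead draws
#' each edge independently with probability `pi1`.
#'
#' @param universe a [build_universe()] object.
#' @param pi1 fraction of true edges, strictly in (0, 1).
#' @param seed integer seed.
#' @param method `"fixed"` (default) or `"bernoulli"`.
#' @return Named 0/1 integer vector of length N.
#' @export
gen_truth <- function(universe, pi1 = 0.16, seed = 1,
                      method = c("fixed", "bernoulli")) {
  method <- match.arg(method)
  stopifnot(inherits(universe, "edge_universe"))
  if (pi1 <= 0 || pi1 >= 1) stop("pi1 must lie strictly in (0, 1)")
  N <- length(universe)
  y <- integer(N)
  if (method == "fixed") {
    E <- round(pi1 * N)
    if (E == 0 || E == N)
      stop("round(pi1 * N) must leave both true and false edges")
    y[with_seed(seed, sample.int(N, E))] <- 1L
  } else {
    y <- with_seed(seed, rbinom(N, 1L, pi1))
    if (sum(y) == 0 || sum(y) == N)
      stop("bernoulli draw left no true (or no false) edges; use a larger N")
  }
  names(y) <- universe$labels
  y
}

#' Simulate a crowd of imperfect network predictors
#'
#' Each predictor j draws a personal true-positive rate P_T^j ~
#' Beta(pt_shape) and false-positive rate P_F^j ~ Beta(pf_shape), then
#' includes each candidate edge independently: a true edge with
#' probability P_T^j, a false edge with probability P_F^j. This is the
#' generative model behind the beta-binomial vote-count mixture, so
#' [count_votes()] + [bbmix()] on the output is a parameter-recovery
#' experiment. Defaults give mean rates 0.8 (true) and 0.3 (false) at
#' concentration 50.
#'
#' @param truth 0/1 truth vector over the universe (e.g. [gen_truth()]).
#' @param universe the [build_universe()] object.
#' @param M number of predictors.
#' @param pt_shape,pf_shape length-2 positive Beta shapes (a, b) for the
#'   per-predictor true/false-positive rates.
#' @param seed integer seed.
#' @return A [prediction_matrix()] with submissions `team01`, `team02`, ...
#' @export
gen_crowd <- function(truth, universe, M = 15,
                      pt_shape = c(40, 10), pf_shape = c(15, 35), seed = 1) {
  stopifnot(inherits(universe, "edge_universe"))
  N <- length(universe)
  if (length(truth) != N) stop("truth vector length does not match universe")
  if (!all(truth %in% c(0, 1))) stop("truth entries must be 0 or 1")
  if (M < 1) stop("M must be at least 1")
  vals <- with_seed(seed, {
    p_t <- rbeta(M, pt_shape[1L], pt_shape[2L])
    p_f <- rbeta(M, pf_shape[1L], pf_shape[2L])
    t(vapply(seq_len(M), function(j) {
      rate <- ifelse(truth == 1, p_t[j], p_f[j])
      rbinom(N, 1L, rate)
    }, integer(N)))
  })
  prediction_matrix(vals, universe, sprintf("team%02d", seq_len(M)))
}

#' Simulate a perturbation panel from a ground-truth Boolean network
#'
#' For each experiment, the active stimuli are propagated through the
#' truth network with Boolean OR semantics; each measured node then emits
#' a continuous readout on its data-type scale: active nodes at
#' `active_level` times the discretization threshold, inactive nodes at 0,
#' both plus Gaussian noise. With probability `flip_rate` a readout is
#' replaced by the opposite-side level (emulating a spurious call). With
#' zero noise and zero flips, [discretize()] recovers the propagated
#' Boolean states exactly.
#'
#' @param truth_network the ground-truth [network()] (stimulus and
#'   measured nodes required).
#' @param experiments list of active-stimulus character vectors; default
#'   is one single-stimulus experiment per stimulus node.
#' @param noise_sd Gaussian noise standard deviation: a scalar or a named
#'   vector per data type.
#' @param flip_rate probability in [0, 1) that a readout flips side.
#' @param thresholds data-type thresholds used to place the activity
#'   levels (the panel is generated on the same scale it will be
#'   discretized on).
#' @param active_level multiple of the threshold at which active nodes
#'   sit.
#' @param seed integer seed.
#' @return An [experiment_panel()].
#' @export
gen_panel <- function(truth_network, experiments = NULL, noise_sd = 0.3,
                      flip_rate = 0, thresholds = default_thresholds(),
                      active_level = 1.5, seed = 1) {
  stopifnot(inherits(truth_network, "crowdnet_network"))
  if (flip_rate < 0 || flip_rate >= 1) stop("flip_rate must lie in [0, 1)")
  nodes <- truth_network$nodes
  stim <- nodes$id[nodes$layer == "stimulus"]
  meas <- nodes$id[nodes$measured]
  if (!length(stim) || !length(meas))
    stop("truth network needs stimulus and measured nodes")
  if (is.null(experiments))
    experiments <- setNames(as.list(stim), paste0("exp_", stim))
  type_of_layer <- c(signaling = "phospho_residual",
                     target = "expression_foldchange",
                     cytokine = "cytokine_residual")
  lay <- setNames(nodes$layer, nodes$id)
  data_type <- ifelse(lay[meas] %in% names(type_of_layer),
                      type_of_layer[lay[meas]], "phospho_residual")
  names(data_type) <- meas
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- setNames(rep(noise_sd, length(default_thresholds())),
                         names(default_thresholds()))
  sd_col <- noise_sd[data_type]
  t_col <- thresholds[data_type]

  values <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = length(experiments), ncol = length(meas),
                  dimnames = list(names(experiments), meas))
    for (e in seq_along(experiments)) {
      st <- propagate(truth_network, experiments[[e]])
      active <- st[meas] == 1L
      flip <- runif(length(meas)) < flip_rate
      shown <- xor(active, flip)
      out[e, ] <- ifelse(shown, active_level * t_col, 0) +
        rnorm(length(meas), 0, sd_col)
    }
    out
  })
  experiment_panel(values, experiments, data_type)
}
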