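# Small in-code fixtures shared across test files.

# stimulus -> latent -> measured chain with an extra dangling latent node
toy_chain <- function() {
  network(data.frame(source = c("S", "L"), target = c("L", "P")),
          nodes = data.frame(id = c("S", "L", "P", "X"),
                             layer = c("stimulus", "latent", "signaling",
                                       "latent"),
                             measured = c(FALSE, FALSE, TRUE, FALSE)))
}

# 5-node layered network used for universe / scoring tests
toy_reference <- function() {
  network(data.frame(source = c("S1", "S1", "R1", "R1", "K1"),
                     target = c("R1", "R2", "K1", "K2", "K2")),
          nodes = data.frame(
            id = c("S1", "S2", "R1", "R2", "K1", "K2"),
            layer = c("stimulus", "stimulus", "receptor", "receptor",
                      "adaptor", "adaptor"),
            measured = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)))
}

random_toy_network <- function(seed) {
  gen_layered_network(layer_sizes = c(stimulus = 2, receptor = 2,
                                      signaling = 3),
                      edge_density = 0.7,
                      measured_layers = "signaling", seed = seed)
}

# tiny random layered instance for ILP oracle checks: <= 12 edges,
# <= 4 experiments, readouts called from a random sub-network plus
# optional call noise
random_ilp_instance <- function(seed, flip_rate = 0) {
  set.seed(seed)
  repeat {
    net <- gen_layered_network(
      layer_sizes = c(stimulus = 2, receptor = sample(2:3, 1),
                      signaling = sample(2:3, 1)),
      edge_density = runif(1, 0.4, 0.8),
      measured_layers = "signaling",
      seed = sample.int(1e6, 1))
    if (nrow(net$edges) <= 12) break
  }
  stim <- net$nodes$id[net$nodes$layer == "stimulus"]
  meas <- net$nodes$id[net$nodes$measured]
  n_exp <- sample(1:4, 1)
  experiments <- lapply(seq_len(n_exp), function(i)
    sample(stim, sample(seq_along(stim), 1)))
  names(experiments) <- paste0("e", seq_len(n_exp))
  keep <- runif(nrow(net$edges)) < 0.7
  calls <- t(vapply(experiments, function(s) {
    st <- propagate(net, s, kept = keep)
    v <- st[meas]
    flip <- runif(length(v)) < flip_rate
    as.numeric(ifelse(flip, 1 - v, v))
  }, numeric(length(meas))))
  colnames(calls) <- meas
  disc <- structure(list(values = calls,
                         thresholds = default_thresholds(),
                         stimuli = experiments,
                         data_type = setNames(rep("phospho_residual",
                                                  length(meas)), meas)),
                    class = "discretized_panel")
  list(net = net, disc = disc)
}

expect_edge_set <- function(net, labels) {
  expect_setequal(paste0(net$edges$source, "->", net$edges$target), labels)
}
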