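test_that("SIF reading transcribes edges with set semantics", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tactivates\tB", "B\tactivates\tC"), f)
  net <- read_network(f)
  expect_equal(nrow(net$nodes), 3)
  expect_edge_set(net, c("A->B", "B->C"))

  writeLines(c("A\tactivates\tB", "A\tactivates\tB"), f)
  expect_equal(nrow(read_network(f)$edges), 1)
})

test_that("malformed SIF rows are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tactivates\tB", "A\tactivates"), f)
  expect_error(read_network(f), "line 2")
})

test_that("self-loops and dangling annotations are validation errors", {
  expect_error(network(data.frame(source = "A", target = "A")), "self-loop")
  f <- withr::local_tempfile(fileext = ".sif")
  nf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tactivates\tB", f)
  write.table(data.frame(id = c("A", "B", "Z"), layer = "latent",
                         measured = FALSE),
              nf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_network(f, nodes_path = nf), "Z")
  expect_silent(read_network(f, nodes_path = nf, allow_isolated = TRUE))
})

test_that("write/read round-trips nodes, edges and annotations", {
  nets <- list(
    toy_reference(),
    network(data.frame(source = character(), target = character()),
            nodes = data.frame(id = c("a", "b", "c"), layer = "stimulus",
                               measured = FALSE)),
    network(data.frame(source = "α", target = "βgene"))
  )
  for (net in nets) {
    f <- withr::local_tempfile(fileext = ".sif")
    write_network(net, f)
    back <- read_network(f, nodes_path = paste0(f, ".nodes.tsv"),
                         allow_isolated = TRUE)
    expect_equal(back$edges[order(edge_labels(back$edges)), ],
                 net$edges[order(edge_labels(net$edges)), ],
                 ignore_attr = TRUE)
    expect_equal(back$nodes[order(back$nodes$id), ],
                 net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)
  }
  # property: random generated networks round-trip
  for (seed in 1:5) {
    net <- random_toy_network(seed)
    f <- withr::local_tempfile(fileext = ".sif")
    write_network(net, f)
    back <- read_network(f, nodes_path = paste0(f, ".nodes.tsv"),
                         allow_isolated = TRUE)
    expect_setequal(edge_labels(back$edges), edge_labels(net$edges))
    expect_setequal(back$nodes$id, net$nodes$id)
  }
})

test_that("universe ordering is reference-first then lexicographic extras", {
  ref <- toy_reference()
  u <- build_universe(ref)
  expect_equal(length(u), 5)
  expect_equal(u$labels, edge_labels(ref$edges))

  extras <- data.frame(source = c("S2", "S1", "S1"),
                       target = c("R2", "R1", "K1"))  # S1->R1 is a ref edge
  u2 <- build_universe(ref, extras)
  expect_equal(length(u2), 7)
  expect_equal(u2$labels[1:5], u$labels)
  expect_equal(u2$labels[6:7], c("S1->K1", "S2->R2"))  # sorted, deduped

  expect_error(build_universe(ref, data.frame(source = "S1", target = "NEW")),
               "new nodes")
})

test_that("latent nodes off every stimulus-to-measured path are pruned", {
  net <- toy_chain()  # S -> L -> P(measured) plus isolated latent X
  pruned <- prune_unreachable(net)
  expect_setequal(pruned$nodes$id, c("S", "L", "P"))
  expect_edge_set(pruned, c("S->L", "L->P"))

  # S -> L1 -> L2 where L2 cannot reach any measured node: enumerating the
  # directed paths S->L1, S->L1->L2 shows neither latent node reaches P
  net2 <- network(data.frame(source = c("S", "L1", "Q"),
                             target = c("L1", "L2", "P")),
                  nodes = data.frame(
                    id = c("S", "L1", "L2", "Q", "P"),
                    layer = c("stimulus", "latent", "latent", "stimulus",
                              "signaling"),
                    measured = c(FALSE, FALSE, FALSE, FALSE, TRUE)))
  pruned2 <- prune_unreachable(net2)
  expect_setequal(pruned2$nodes$id, c("S", "Q", "P"))
  expect_edge_set(pruned2, "Q->P")
})

test_that("pruning is idempotent and spares all non-latent nodes", {
  for (seed in 1:6) {
    net <- gen_layered_network(seed = seed)
    # re-annotate some middle nodes as latent to exercise the rule
    net$nodes$layer[net$nodes$layer %in% c("receptor", "adaptor")] <- "latent"
    once <- prune_unreachable(net)
    twice <- prune_unreachable(once)
    expect_equal(twice$nodes, once$nodes)
    expect_equal(twice$edges, once$edges)
    kept_layers <- net$nodes$id[net$nodes$layer != "latent"]
    expect_true(all(kept_layers %in% once$nodes$id))
  }
})

test_that("precision against a knowledge set follows the survivor sets", {
  ref <- toy_reference()
  u <- build_universe(ref)
  v <- vote_counts(c(3, 1, 0, 2, 1), M = 3, universe = u)
  know <- u$labels[1]

  res <- precision_at_threshold(v, know, thresholds = c(1, 2, 3))
  expect_equal(res$precision[res$threshold == 2],
               1 / 2)   # survivors: edges 1 and 4
  expect_equal(res$precision[res$threshold == 3], 1)  # survivor: edge 1
  expect_equal(res$precision[res$threshold == 1], 1 / 4)

  # all survivors in the knowledge set
  res_all <- precision_at_threshold(v, u$labels, thresholds = 0:3)
  expect_true(all(res_all$precision == 1))

  # empty survivor set is flagged, not an error
  v2 <- vote_counts(c(1, 1, 0, 0, 0), M = 3, universe = u)
  res2 <- precision_at_threshold(v2, know, thresholds = 2)
  expect_false(res2$defined)
  expect_true(is.na(res2$precision))

  expect_error(precision_at_threshold(v, know, thresholds = 4), "0..M")

  # nesting: survivor counts are non-increasing in the threshold
  res3 <- precision_at_threshold(v, know, thresholds = 0:3)
  expect_true(all(diff(res3$n_edges) <= 0))
})
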