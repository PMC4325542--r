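#' Assemble a pipeline configuration
#'
#' A single document of paths, seeds and parameters driving
#' [run_pipeline()]. Input paths left `NULL` are filled by the simulate
#' stage from the synthetic generators, so a fully self-contained toy run
#' needs only an output directory and a seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stage derives its own stream from it.
#' @param network_path,nodes_path optional reference network SIF and node
#'   table.
#' @param predictions_path optional predictions TSV.
#' @param panel_path optional perturbation-panel CSV.
#' @param exclude submissions excluded from vote counting.
#' @param pi_grid mixing-weight grid for [bbmix()].
#' @param n_starts,n_null fitting restarts and null resamples.
#' @param threshold optional vote-threshold override (skips the fitted
#'   threshold).
#' @param thresholds discretization thresholds for the silver stage.
#' @param crowd_M,crowd_pi1 synthetic crowd size and true-edge fraction
#'   (simulate stage only).
#' @return A list of class `crowdnet_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            network_path = NULL, nodes_path = NULL,
                            predictions_path = NULL, panel_path = NULL,
                            exclude = NULL,
                            pi_grid = seq(0.01, 0.5, by = 0.01),
                            n_starts = 4, n_null = 2000,
                            threshold = NULL,
                            thresholds = default_thresholds(),
                            crowd_M = 15, crowd_pi1 = 0.16) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              network_path = network_path, nodes_path = nodes_path,
              predictions_path = predictions_path, panel_path = panel_path,
              exclude = exclude, pi_grid = pi_grid, n_starts = n_starts,
              n_null = n_null, threshold = threshold,
              thresholds = thresholds, crowd_M = crowd_M,
              crowd_pi1 = crowd_pi1)
  class(cfg) <- "crowdnet_config"
  cfg
}

config_hash <- function(cfg) {
  ser <- serialize(unclass(cfg), NULL)
  # small rolling hash; stable across runs for identical configs
  sum(as.numeric(ser) * (seq_along(ser) %% 97 + 1)) %% 1e9
}

#' Run the full aggregation pipeline
#'
#' Executes the stages in order -- simulate (when inputs are not
#' supplied), score, fit, threshold, build, silver -- writing every
#' artifact under `config$out_dir`: the reference network
#' (`network.sif` + node table), predictions (`predictions.tsv`), votes
#' (`votes.tsv`), the score report (`scores.tsv`), the fitted mixture
#' (`fit.json`), the consensus network (`consensus.sif`), the pruned
#' silver network (`silver.sif`, `silver.json`) and a machine-readable
#' run log (`run_log.json` with input checksums, seeds, versions and the
#' config hash). Identical config and seed give identical outputs. A
#' failing stage aborts with the stage named and leaves a `.partial`
#' marker in the output directory.
#'
#' @param config a [pipeline_config()] (or a path to a JSON file of its
#'   fields).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cfg)
  }
  stopifnot(inherits(config, "crowdnet_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(config$out_dir, ".partial")
  file.create(partial)
  stage <- "setup"
  res <- list()
  tryCatch({
    path_of <- function(f) file.path(config$out_dir, f)

    stage <- "simulate"
    if (is.null(config$network_path)) {
      net <- gen_layered_network(seed = derive_seed(config$seed, "network"))
      write_network(net, path_of("network.sif"))
      config$network_path <- path_of("network.sif")
      config$nodes_path <- path_of("network.sif.nodes.tsv")
    } else {
      net <- read_network(config$network_path, nodes_path = config$nodes_path,
                          allow_isolated = TRUE)
    }
    universe <- build_universe(net)
    truth <- NULL
    generate_preds <- is.null(config$predictions_path)
    if (generate_preds) {
      truth <- gen_truth(universe, pi1 = config$crowd_pi1,
                         seed = derive_seed(config$seed, "truth"))
    }
    if (is.null(config$panel_path)) {
      # the perturbation data come from an independent "biologically
      # active" sub-network that keeps the cascade wired
      truth_net <- gen_subnetwork(net,
                                  seed = derive_seed(config$seed, "active"))
      panel <- gen_panel(truth_net, seed = derive_seed(config$seed, "panel"))
      write_panel(panel, path_of("panel.csv"))
      config$panel_path <- path_of("panel.csv")
    } else {
      panel <- read_panel(config$panel_path)
    }

    stage <- "silver"
    silver <- prune_ilp(net, discretize(panel, config$thresholds))
    silver_net <- network(silver$kept, nodes = net$nodes)
    write_network(silver_net, path_of("silver.sif"))
    jsonlite::write_json(
      list(mismatches = silver$mismatches,
           n_kept = nrow(silver$kept), n_removed = nrow(silver$removed),
           removed = edge_labels(silver$removed), status = silver$status,
           thresholds = as.list(config$thresholds)),
      path_of("silver.json"), auto_unbox = TRUE, digits = NA)
    res$silver <- silver

    stage <- "score"
    if (generate_preds) {
      preds <- gen_crowd(truth, universe, M = config$crowd_M,
                         seed = derive_seed(config$seed, "crowd"))
      write_predictions(preds, path_of("predictions.tsv"))
      config$predictions_path <- path_of("predictions.tsv")
    } else {
      preds <- read_predictions(config$predictions_path, universe)
    }
    scores <- score_submissions(preds, silver_net, n_null = config$n_null,
                                seed = derive_seed(config$seed, "score"))
    write.table(scores, path_of("scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$scores <- scores

    stage <- "fit"
    votes <- count_votes(preds, exclude = config$exclude,
                         include_standard = silver_net)
    write.table(data.frame(universe$edges, votes = votes$k),
                path_of("votes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fit <- bbmix(votes, pi_grid = config$pi_grid, n_starts = config$n_starts,
                 seed = derive_seed(config$seed, "fit"))
    res$fit <- fit

    stage <- "threshold"
    th <- optimal_threshold(fit)
    k_star <- config$threshold %||% th$k_star
    if (is.na(k_star))
      stop("no vote threshold satisfies the posterior condition; ",
           "supply config$threshold")
    jsonlite::write_json(
      list(a1 = fit$params$a1, b1 = fit$params$b1, a2 = fit$params$a2,
           b2 = fit$params$b2, pi1 = fit$params$pi1, M = fit$M,
           logLik = fit$logLik, threshold = k_star,
           flags = c(fit$flags, th$flags)),
      path_of("fit.json"), auto_unbox = TRUE, digits = NA)
    res$threshold <- k_star

    stage <- "build"
    consensus <- build_consensus(votes, k_star)
    write_network(consensus, path_of("consensus.sif"))
    res$consensus <- consensus

    stage <- "log"
    inputs <- c(config$network_path, config$predictions_path,
                config$panel_path)
    jsonlite::write_json(
      list(config_hash = config_hash(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("crowdnet")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           inputs = as.list(setNames(as.character(tools::md5sum(inputs)),
                                     basename(inputs)))),
      path_of("run_log.json"), auto_unbox = TRUE)

    file.remove(partial)
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
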