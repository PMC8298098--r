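# Orchestration: run the stages as a configurable pipeline with logging
# and provenance. The per-stage subcommands of the analysis map onto the
# exported stage functions; run_pipeline() wires them together.

#' Default pipeline configuration
#'
#' Collects every stage parameter with its conventional default: traversal
#' cap 0.30 with 10,000 global runs (5,000 per seed type), 480 nm voxels,
#' 20,000 shuffles at family-wise error rate 0.05, cluster floor 0.4,
#' 80 um minimum cable, k = 5 neighbours, 1 um resampling, top 10%
#' distance fraction, 5% pruning and an LHN threshold of 10 synapses.
#' Values can be overridden by a YAML file (see [read_pipeline_config()])
#' or by arguments; unknown keys are rejected.
#'
#' @param ... overrides of top-level keys (partial lists are merged).
#' @return Nested configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    synth = list(),                 # passed to synth_config()
    stages = list(simulate = TRUE, io = TRUE, classify = TRUE,
                  traversal = TRUE, polarity = TRUE, glomstats = TRUE,
                  stereotypy = TRUE),
    inputs = list(),                # external stage inputs (paths)
    traversal = list(cap = 0.30, n_runs = 10000, mode = "aggregate",
                     early_window = c(3, 4)),
    polarity = list(threshold = 0.1),
    glomstats = list(statistic = "min", n_shuffles = 20000, alpha = 0.05,
                     voxel_size = 480, prune_frac = 0.05, min_cable = 80,
                     k = 5, top_frac = 0.10),
    stereotypy = list(resample_step = 1, k = 5, twig_prune = 2, sigma = 3,
                      min_score = 0.4),
    classify = list(frac_single = 0.01, conn_single = 10, frac_sum = 0.10,
                    conn_sum = 100, lhn_threshold = 10)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad2 <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad2) > 0 && !nm %in% c("synth", "inputs"))
        stopf("unknown configuration key(s) under '%s': %s", nm,
              paste(bad2, collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with top-level keys as in [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(name, ...) {
  message(sprintf("[olfconn] %s: %s", name, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: simulate, io (write/read round-trip of
#' the generated tables), classify, traversal, polarity, glomstats,
#' stereotypy. Any stage can be toggled off; a disabled traversal stage
#' can be substituted by an external layer table via
#' `config$inputs$layers`. Outputs are CSV files per stage plus a
#' `provenance.json` recording the configuration, seeds, package version
#' and per-stage row counts, which suffices to reproduce every output.
#'
#' @param config a [pipeline_config()].
#' @param out_dir report directory (created if missing).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  prov <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("olfconn")),
               rows = list())
  results <- list()

  sc <- do.call(synth_config, c(config$synth,
                                list(rng_seed = config$rng_seed)))
  if (isTRUE(st$simulate)) {
    log_stage("simulate", "generating synthetic connectome (seed %d)",
              config$rng_seed)
    conn <- generate_connectome(sc)
    innerv <- generate_innervation_matrix(sc)
    skel <- generate_skeletons(sc)
    results$simulate <- list(connectome = conn, innervation = innerv,
                             skeletons = skel)
    write_table_csv(conn$neurons, file.path(out_dir, "neurons.csv"))
    write_table_csv(conn$edges, file.path(out_dir, "edges.csv"))
    write_table_csv(skel$synapses, file.path(out_dir, "synapses.csv"))
    write_table_csv(data.frame(neuron_id = names(conn$ground_truth$true_layer),
                               true_layer = unname(conn$ground_truth$true_layer)),
                    file.path(out_dir, "ground_truth_layers.csv"))
    prov$rows$neurons <- nrow(conn$neurons)
    prov$rows$edges <- nrow(conn$edges)
  } else {
    conn <- list(neurons = read_neuron_table(config$inputs$neurons),
                 edges = read_edge_list(config$inputs$edges))
    skel <- NULL
    innerv <- NULL
  }

  if (isTRUE(st$io)) {
    # write/read round-trip guards the documented CSV schemas
    neurons <- read_neuron_table(file.path(out_dir, "neurons.csv"))
    edges <- read_edge_list(file.path(out_dir, "edges.csv"))
  } else {
    neurons <- conn$neurons
    edges <- conn$edges
  }
  graph <- build_graph(edges, neurons)
  log_stage("graph", "%d neurons, %d edges after filtering",
            nrow(graph$nodes), nrow(graph$edges))
  results$graph <- graph

  if (isTRUE(st$classify)) {
    cls <- stats::setNames(neurons$class, neurons$neuron_id)
    e <- graph$edges
    alpn_edge <- cls[e$pre_id] == "ALPN"
    is_toon <- vapply(neurons$neuron_id, function(id) {
      inputs <- e$weight[e$post_id == id & alpn_edge]
      classify_toon(inputs, graph$total_in[[id]],
                    config$classify$frac_single, config$classify$conn_single,
                    config$classify$frac_sum, config$classify$conn_sum)
    }, logical(1))
    classes <- data.frame(neuron_id = neurons$neuron_id, is_toon = is_toon,
                          stringsAsFactors = FALSE)
    results$classify <- classes
    write_table_csv(classes, file.path(out_dir, "classes.csv"))
    prov$rows$toons <- sum(is_toon)
  }

  layers <- NULL
  if (isTRUE(st$traversal)) {
    seeds <- neurons$neuron_id[neurons$class == "ALRN"]
    params <- traversal_params(cap = config$traversal$cap,
                               n_runs = config$traversal$n_runs,
                               mode = config$traversal$mode,
                               rng_seed = derive_seed(config$rng_seed,
                                                      "traversal"))
    log_stage("traversal", "%d seeds, %d runs", length(seeds),
              params$n_runs)
    lr <- run_traversal(graph, seeds, params)
    layers <- lr$layers
    results$traversal <- lr
    write_table_csv(layers, file.path(out_dir, "layers.csv"))
    prov$rows$layers <- nrow(layers)
  } else if (!is.null(config$inputs$layers)) {
    layers <- read.csv(config$inputs$layers, stringsAsFactors = FALSE)
    log_stage("traversal", "using external layers from %s",
              config$inputs$layers)
  }
  if (!is.null(layers)) {
    early <- data.frame(
      neuron_id = layers$neuron_id,
      early = classify_early(layers$mean_step,
                             config$traversal$early_window),
      stringsAsFactors = FALSE)
    results$early <- early
    write_table_csv(early, file.path(out_dir, "early_neurons.csv"))
  } else if (isTRUE(st$classify)) {
    stopf("stage 'traversal' is disabled and no 'inputs$layers' was supplied")
  }

  if (isTRUE(st$polarity) && !is.null(skel)) {
    si <- segregation_index(skel$synapses)
    pm <- glomerular_polarity_matrix(skel$synapses,
                                     config$polarity$threshold)
    results$polarity <- list(segregation = si, matrix = pm)
    write_table_csv(si, file.path(out_dir, "segregation_index.csv"))
    prov$rows$polarised <- nrow(pm)
    log_stage("polarity", "%d/%d neurons pass the polarisation threshold",
              nrow(pm), nrow(si))
  }

  if (isTRUE(st$glomstats) && !is.null(innerv)) {
    curves <- cumulative_rank_curves(innerv)
    coin <- coinnervation_test(innerv,
                               statistic = config$glomstats$statistic,
                               n_shuffles = config$glomstats$n_shuffles,
                               alpha = config$glomstats$alpha,
                               rng_seed = derive_seed(config$rng_seed,
                                                      "coinnervation"))
    results$glomstats <- list(curves = curves, coinnervation = coin)
    write_table_csv(coin, file.path(out_dir, "coinnervation.csv"))
    prov$rows$pairs_tested <- nrow(coin)
    log_stage("glomstats", "%d pairs tested, %d significant", nrow(coin),
              sum(coin$significant))
  }

  if (isTRUE(st$stereotypy) && !is.null(skel)) {
    dps <- lapply(skel$skeletons, make_dotprops,
                  resample_step = config$stereotypy$resample_step,
                  k = config$stereotypy$k,
                  twig_prune = config$stereotypy$twig_prune)
    sm <- similarity_matrix(dps, sigma = config$stereotypy$sigma)
    tags <- skel$ground_truth$true_dataset[rownames(sm)]
    cl <- top_match_clusters(sm, tags)
    memb <- refine_clusters(cl, sm, config$stereotypy$min_score)
    clusters <- data.frame(neuron_id = names(memb), cluster = unname(memb),
                           stringsAsFactors = FALSE)
    results$stereotypy <- list(scores = sm, clusters = clusters)
    write_table_csv(clusters, file.path(out_dir, "clusters.csv"))
    prov$rows$clusters <- length(unique(memb))
    log_stage("stereotypy", "%d neurons in %d clusters", nrow(clusters),
              length(unique(memb)))
  }

  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}
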