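#' Configuration for the synthetic connectome generator
#'
#' Bundles every knob of the synthetic-data module: a layered feedforward
#' olfactory graph (receptor neurons to local/projection neurons to
#' third-order neurons to descending neurons) with heavy-tailed edge
#' weights, bilateral sensory populations, glomerulus-structured
#' innervation count matrices, polarised neurons with axon/dendrite
#' synapse labels, and morphological cell types replicated across two
#' datasets with positional jitter.
#'
#' @param n_layers number of feedforward layers (layer 1 = receptor-like
#'   seed neurons).
#' @param neurons_per_layer integer vector of layer sizes. When `NULL` a
#'   default roster of about 500 neurons over five layers is derived, with
#'   the first layer sized `n_glomeruli * n_receptors_per_glomerulus`.
#' @param n_glomeruli number of glomeruli.
#' @param n_receptors_per_glomerulus receptor neurons per glomerulus (used
#'   when `neurons_per_layer` is not given).
#' @param bilateral_fraction proportion of glomeruli whose receptor
#'   population draws from both body sides.
#' @param edge_weight_distribution list with `name` (currently
#'   `"lognormal"`), `meanlog` and `sdlog`: synapse-count edge weights are
#'   drawn from this distribution and discretised to positive integers.
#'   Connectome edge weights are heavy-tailed, which is what makes the
#'   input-fraction cap of the traversal model bite.
#' @param feedforward_fraction minimum proportion of each non-seed
#'   neuron's total input weight that comes from the previous layer.
#' @param n_cell_types,cells_per_type morphological cell-type roster used
#'   by [generate_skeletons()].
#' @param skeleton_jitter_sd per-node Gaussian jitter between members of a
#'   cell type, in micrometres.
#' @param dataset_offset global positional offset applied to dataset "B"
#'   skeletons, in micrometres (a stand-in for residual registration
#'   error between datasets).
#' @param planted_coinnervation_pairs list of glomerulus index pairs
#'   `c(g1, g2)` (optionally `c(g1, g2, factor)`) whose co-innervation is
#'   enriched in the innervation matrix.
#' @param coinnervation_enrichment default enrichment factor (>= 1) for
#'   planted pairs that do not carry their own.
#' @param planted_polarity proportion of skeleton neurons that are fully
#'   axon/dendrite segregated (dendrite carries only inputs, axon only
#'   outputs); the rest mix polarities uniformly.
#' @param innervation_prob background probability that a neuron innervates
#'   any given glomerulus in [generate_innervation_matrix()].
#' @param innervation_lambda Poisson mean of the per-glomerulus synapse
#'   count of an innervating neuron.
#' @param n_neurons_innervation number of neurons (columns) in the
#'   innervation matrix.
#' @param rng_seed integer root seed; every generator derives its own
#'   child stream from it (see [derive_seed()]).
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_layers = 5,
                         neurons_per_layer = NULL,
                         n_glomeruli = 20,
                         n_receptors_per_glomerulus = 8,
                         bilateral_fraction = 0.5,
                         edge_weight_distribution = list(name = "lognormal",
                                                         meanlog = 1.0,
                                                         sdlog = 0.8),
                         feedforward_fraction = 0.9,
                         n_cell_types = 20,
                         cells_per_type = 3,
                         skeleton_jitter_sd = 0.5,
                         dataset_offset = 0.5,
                         planted_coinnervation_pairs = list(),
                         coinnervation_enrichment = 1,
                         planted_polarity = 0.5,
                         innervation_prob = 0.2,
                         innervation_lambda = 15,
                         n_neurons_innervation = 60,
                         rng_seed = 1L) {
  n_layers <- check_count(n_layers, "n_layers", min = 1)
  n_glomeruli <- check_count(n_glomeruli, "n_glomeruli")
  n_receptors_per_glomerulus <-
    check_count(n_receptors_per_glomerulus, "n_receptors_per_glomerulus")
  if (is.null(neurons_per_layer)) {
    base <- c(n_glomeruli * n_receptors_per_glomerulus, 120, 100, 80, 40)
    neurons_per_layer <- if (n_layers <= 5) base[seq_len(n_layers)] else
      c(base, rep(40, n_layers - 5))
  }
  if (length(neurons_per_layer) != n_layers)
    stopf("invalid configuration: 'neurons_per_layer' must have length n_layers (%d)",
          n_layers)
  if (any(neurons_per_layer < 0) || any(neurons_per_layer != floor(neurons_per_layer)))
    stopf("invalid configuration: 'neurons_per_layer' must be non-negative integers")
  check_proportion(bilateral_fraction, "bilateral_fraction")
  check_proportion(feedforward_fraction, "feedforward_fraction")
  check_proportion(planted_polarity, "planted_polarity")
  check_proportion(innervation_prob, "innervation_prob")
  if (!is.list(edge_weight_distribution) ||
      !identical(edge_weight_distribution$name, "lognormal"))
    stopf("invalid configuration: 'edge_weight_distribution' must be list(name = \"lognormal\", meanlog, sdlog)")
  if (!is.numeric(coinnervation_enrichment) || coinnervation_enrichment < 1)
    stopf("invalid configuration: 'coinnervation_enrichment' must be >= 1")
  for (p in planted_coinnervation_pairs) {
    if (!is.numeric(p) || !(length(p) %in% c(2L, 3L)))
      stopf("invalid configuration: 'planted_coinnervation_pairs' elements must be c(g1, g2) or c(g1, g2, factor)")
    if (length(p) == 3L && p[3] < 1)
      stopf("invalid configuration: 'planted_coinnervation_pairs' enrichment factor must be >= 1")
  }
  check_count(n_cell_types, "n_cell_types")
  check_count(cells_per_type, "cells_per_type")
  if (skeleton_jitter_sd < 0)
    stopf("invalid configuration: 'skeleton_jitter_sd' must be >= 0")
  if (dataset_offset < 0)
    stopf("invalid configuration: 'dataset_offset' must be >= 0")
  check_count(n_neurons_innervation, "n_neurons_innervation")
  if (innervation_lambda <= 0)
    stopf("invalid configuration: 'innervation_lambda' must be > 0")
  structure(list(
    n_layers = n_layers,
    neurons_per_layer = as.integer(neurons_per_layer),
    n_glomeruli = n_glomeruli,
    n_receptors_per_glomerulus = n_receptors_per_glomerulus,
    bilateral_fraction = bilateral_fraction,
    edge_weight_distribution = edge_weight_distribution,
    feedforward_fraction = feedforward_fraction,
    n_cell_types = n_cell_types,
    cells_per_type = cells_per_type,
    skeleton_jitter_sd = skeleton_jitter_sd,
    dataset_offset = dataset_offset,
    planted_coinnervation_pairs = planted_coinnervation_pairs,
    coinnervation_enrichment = coinnervation_enrichment,
    planted_polarity = planted_polarity,
    innervation_prob = innervation_prob,
    innervation_lambda = innervation_lambda,
    n_neurons_innervation = n_neurons_innervation,
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

glomerulus_labels <- function(n) sprintf("G%02d", seq_len(n))

# discretised heavy-tailed synapse counts
draw_edge_weights <- function(n, dist) {
  pmax(1L, as.integer(round(rlnorm(n, dist$meanlog, dist$sdlog))))
}

#' Generate a layered synthetic connectome with ground truth
#'
#' Builds a feedforward, weighted, directed neuron-level graph: layer-1
#' neurons are receptor-like seeds assigned to glomeruli (bilateral for a
#' configurable fraction of glomeruli); every neuron in layer k > 1 draws
#' at least `feedforward_fraction` of its total input weight from layer
#' k - 1, with the remainder spread over lateral/recurrent partners.
#' Weights are positive integers from a discretised lognormal. Output is
#' deterministic for a fixed `rng_seed`.
#'
#' @param config a [synth_config()].
#' @return A list with `neurons` (neuron metadata table), `edges`
#'   (`pre_id`, `post_id`, `weight`) and `ground_truth` (list with
#'   `true_layer`, `true_type`, `true_dataset`, `planted_pairs`,
#'   `planted_polarity`, all keyed by neuron id; `true_layer` is 1-based
#'   with seeds at layer 1).
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  npl <- config$neurons_per_layer
  n <- sum(npl)
  empty_neurons <- data.frame(neuron_id = character(), class = character(),
                              cell_type = character(), glomerulus = character(),
                              side = character(), lineage = character(),
                              transmitter = character(),
                              stringsAsFactors = FALSE)
  empty_edges <- data.frame(pre_id = character(), post_id = character(),
                            weight = integer(), stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(neurons = empty_neurons, edges = empty_edges,
                ground_truth = list(true_layer = integer(),
                                    true_type = character(),
                                    true_dataset = character(),
                                    planted_pairs = config$planted_coinnervation_pairs,
                                    planted_polarity = character())))
  }
  with_seed(derive_seed(config$rng_seed, "generate_connectome"), {
    layer <- rep(seq_along(npl), npl)
    ids <- sprintf("n%04d", seq_len(n))
    cls <- character(n)
    for (k in seq_along(npl)) {
      in_k <- which(layer == k)
      m <- length(in_k)
      if (m == 0) next
      cls[in_k] <- if (k == 1) "ALRN"
      else if (k == 2) sample(c("ALPN", "ALLN"), m, TRUE, prob = c(0.7, 0.3))
      else if (k == length(npl) && k > 2) "DN"
      else if (k == 3) sample(c("TOON", "KC", "LHN"), m, TRUE,
                              prob = c(0.5, 0.3, 0.2))
      else sample(c("other", "MBON"), m, TRUE, prob = c(0.8, 0.2))
    }
    glom <- rep(NA_character_, n)
    side <- rep("right", n)
    seeds <- which(layer == 1)
    if (length(seeds) > 0 && config$n_glomeruli > 0) {
      gl <- glomerulus_labels(config$n_glomeruli)
      glom[seeds] <- rep(gl, length.out = length(seeds))
      bilat <- runif(config$n_glomeruli) < config$bilateral_fraction
      names(bilat) <- gl
      for (i in seq_along(seeds)) {
        if (bilat[[glom[seeds[i]]]])
          side[seeds[i]] <- if (i %% 2 == 0) "left" else "right"
      }
    }
    lineage <- sample(paste0("hl", LETTERS[1:6]), n, TRUE)
    transmitter <- ifelse(cls == "ALRN", "acetylcholine",
                          sample(c("acetylcholine", "GABA", "glutamate"),
                                 n, TRUE, prob = c(0.5, 0.3, 0.2)))
    cell_type <- paste0(cls, "_t",
                        1 + (seq_len(n) - 1L) %% max(1L, config$n_cell_types))
    neurons <- data.frame(neuron_id = ids, class = cls, cell_type = cell_type,
                          glomerulus = glom, side = side, lineage = lineage,
                          transmitter = transmitter, stringsAsFactors = FALSE)

    ff <- config$feedforward_fraction
    pre <- character(0); post <- character(0); w <- integer(0)
    for (k in seq_along(npl)[-1]) {
      prev <- which(layer == k - 1)
      if (length(prev) == 0) next
      others <- which(layer != k - 1)
      for (j in which(layer == k)) {
        n_ff <- sample(3:6, 1)
        n_ff <- min(n_ff, length(prev))
        src <- sample(prev, n_ff)
        wf <- draw_edge_weights(n_ff, config$edge_weight_distribution)
        pre <- c(pre, ids[src]); post <- c(post, rep(ids[j], n_ff)); w <- c(w, wf)
        # lateral/recurrent edges, capped so the feedforward share holds
        if (ff < 1) {
          budget <- floor(sum(wf) * (1 - ff) / max(ff, 1e-12))
          cand <- setdiff(others, j)
          n_lat <- min(sample(0:3, 1), length(cand))
          if (n_lat > 0 && budget > 0) {
            lsrc <- sample(cand, n_lat)
            lw <- draw_edge_weights(n_lat, config$edge_weight_distribution)
            keep <- cumsum(lw) <= budget
            if (any(keep)) {
              lsrc <- lsrc[keep]; lw <- lw[keep]
              pre <- c(pre, ids[lsrc])
              post <- c(post, rep(ids[j], length(lsrc)))
              w <- c(w, lw)
            }
          }
        }
      }
    }
    edges <- if (length(w) == 0) empty_edges else {
      e <- aggregate(weight ~ pre_id + post_id,
                     data.frame(pre_id = pre, post_id = post, weight = w,
                                stringsAsFactors = FALSE), sum)
      e <- e[order(e$post_id, e$pre_id), , drop = FALSE]
      rownames(e) <- NULL
      e$weight <- as.integer(e$weight)
      e
    }
    polarised <- runif(n) < config$planted_polarity
    gt <- list(
      true_layer = stats::setNames(layer, ids),
      true_type = stats::setNames(cell_type, ids),
      true_dataset = stats::setNames(rep("A", n), ids),
      planted_pairs = config$planted_coinnervation_pairs,
      planted_polarity = stats::setNames(ifelse(polarised, "polarised", "mixed"),
                                         ids)
    )
    list(neurons = neurons, edges = edges, ground_truth = gt)
  })
}

#' Generate a glomeruli-by-neurons synapse count matrix
#'
#' Background innervation is independent across glomeruli: each neuron
#' innervates each glomerulus with probability `innervation_prob` and then
#' places `Pois(innervation_lambda) + 1` synapses there. For every planted
#' glomerulus pair, additional neurons are drawn to co-innervate both
#' members of the pair so that the joint innervation probability is
#' multiplied by the pair's enrichment factor; a factor of 1 leaves the
#' null model untouched.
#'
#' @param config a [synth_config()].
#' @return Integer matrix, rows = glomeruli, columns = neurons.
#' @export
generate_innervation_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  G <- config$n_glomeruli
  if (G < 2) stopf("invalid configuration: 'n_glomeruli' must be >= 2")
  N <- config$n_neurons_innervation
  for (p in config$planted_coinnervation_pairs) {
    if (any(p[1:2] < 1) || any(p[1:2] > G))
      stopf("planted pair (%d, %d) out of range for %d glomeruli",
            p[1], p[2], G)
  }
  with_seed(derive_seed(config$rng_seed, "generate_innervation_matrix"), {
    p0 <- config$innervation_prob
    lam <- config$innervation_lambda
    M <- matrix(rbinom(G * N, 1, p0) * (rpois(G * N, lam) + 1L), G, N)
    for (p in config$planted_coinnervation_pairs) {
      f <- if (length(p) >= 3) p[3] else config$coinnervation_enrichment
      p_extra <- min(1, (f - 1) * p0^2)
      sel <- which(runif(N) < p_extra)
      for (g in p[1:2]) {
        M[g, sel] <- rpois(length(sel), lam) + 1L
      }
    }
    storage.mode(M) <- "integer"
    dimnames(M) <- list(glomerulus_labels(G), sprintf("ln%03d", seq_len(N)))
    M
  })
}

# A reproducible template tree for one cell type: a soma, a dendritic
# arbor and an axonal arbor, each a short trunk with side branches.
# Coordinates in nm.
make_template_tree <- function(center, step_nm = 2500) {
  unit <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  nodes <- list(c(center, 1))  # x, y, z, swc type (1 = soma)
  parents <- c(-1L)
  grow <- function(from_idx, dir, n, swc_type) {
    pos <- nodes[[from_idx]][1:3]
    parent <- from_idx
    for (i in seq_len(n)) {
      pos <- pos + dir * step_nm + rnorm(3, sd = step_nm * 0.3)
      nodes[[length(nodes) + 1L]] <<- c(pos, swc_type)
      parents[length(parents) + 1L] <<- parent
      parent <- length(nodes)
    }
    parent
  }
  for (swc_type in c(3L, 2L)) {         # 3 = dendrite, 2 = axon
    dir <- unit()
    tip <- grow(1L, dir, 12L, swc_type)
    trunk_idx <- length(nodes) - 11:6    # mid-trunk nodes for side branches
    for (b in 1:2) grow(sample(trunk_idx, 1), unit(), 6L, swc_type)
  }
  m <- do.call(rbind, nodes)
  data.frame(id = seq_len(nrow(m)), type = as.integer(m[, 4]),
             x = m[, 1], y = m[, 2], z = m[, 3],
             radius = 100, parent = parents)
}

#' Generate cell-type replicated skeletons and a synapse table
#'
#' Each cell type has a template tree; every member is the template plus
#' Gaussian node jitter (`skeleton_jitter_sd`), and members of dataset
#' "B" get an additional small global offset (`dataset_offset`). Synapses
#' are placed on nodes; for a `planted_polarity` fraction of neurons the
#' dendrite carries only input (post) synapses and the axon only output
#' (pre) synapses, while the rest mix polarities uniformly across
#' compartments. The dendritic and axonal arbors of a type are each
#' assigned a glomerulus so that polarity profiles over glomeruli have
#' planted structure.
#'
#' @param config a [synth_config()].
#' @param neuron_table optional neuron table with columns `neuron_id`,
#'   `cell_type` and optionally `dataset`; by default a roster of
#'   `n_cell_types * cells_per_type` members per dataset (A and B) is
#'   created.
#' @return List with `skeletons` (named list of SWC data frames,
#'   coordinates in nm, each with a `compartment` node attribute derived
#'   from the SWC type column), `synapses` (a synapse table) and
#'   `ground_truth`.
#' @export
generate_skeletons <- function(config, neuron_table = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$cells_per_type < 1)
    stopf("invalid configuration: 'cells_per_type' must be >= 1")
  with_seed(derive_seed(config$rng_seed, "generate_skeletons"), {
    types <- sprintf("T%02d", seq_len(config$n_cell_types))
    if (is.null(neuron_table)) {
      roster <- expand.grid(member = seq_len(config$cells_per_type),
                            dataset = c("A", "B"), cell_type = types,
                            stringsAsFactors = FALSE)
      roster$neuron_id <- sprintf("%s_%s_c%d", roster$cell_type,
                                  roster$dataset, roster$member)
    } else {
      roster <- neuron_table
      if (is.null(roster$dataset)) roster$dataset <- "A"
      types <- unique(roster$cell_type)
    }
    # well-separated template centres on a coarse 3D grid (100 um spacing)
    side <- ceiling(length(types)^(1 / 3))
    grid <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
    centers <- grid[seq_along(types), , drop = FALSE] * 1e5
    rownames(centers) <- types
    templates <- lapply(types, function(tt) make_template_tree(centers[tt, ]))
    names(templates) <- types
    gl <- glomerulus_labels(max(config$n_glomeruli, 2L))
    arbor_glom <- lapply(types, function(tt) sample(gl, 2))  # dendrite, axon
    names(arbor_glom) <- types

    offset <- { v <- rnorm(3); v / sqrt(sum(v^2)) * config$dataset_offset * 1e3 }
    jitter_nm <- config$skeleton_jitter_sd * 1e3
    polarised <- runif(nrow(roster)) < config$planted_polarity

    skeletons <- vector("list", nrow(roster))
    names(skeletons) <- roster$neuron_id
    syn <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      tpl <- templates[[roster$cell_type[i]]]
      sk <- tpl
      nn <- nrow(sk)
      sk[, c("x", "y", "z")] <- sk[, c("x", "y", "z")] +
        matrix(rnorm(nn * 3, sd = jitter_nm), nn, 3)
      if (roster$dataset[i] == "B")
        sk[, c("x", "y", "z")] <- sweep(sk[, c("x", "y", "z")], 2, -offset)
      skeletons[[i]] <- sk
      comp <- c("soma", "axon", "dendrite")[match(sk$type, c(1L, 2L, 3L))]
      on_node <- which(comp != "soma" & runif(nn) < 0.6)
      if (length(on_node) > 0) {
        pol <- if (polarised[i])
          ifelse(comp[on_node] == "dendrite", "post", "pre")
        else sample(c("pre", "post"), length(on_node), TRUE)
        ag <- arbor_glom[[roster$cell_type[i]]]
        syn[[i]] <- data.frame(
          neuron_id = roster$neuron_id[i],
          polarity = pol,
          x = sk$x[on_node], y = sk$y[on_node], z = sk$z[on_node],
          compartment = comp[on_node],
          roi = ifelse(comp[on_node] == "dendrite", ag[1], ag[2]),
          glomerulus = ifelse(comp[on_node] == "dendrite", ag[1], ag[2]),
          stringsAsFactors = FALSE)
      }
    }
    synapses <- do.call(rbind, syn[!vapply(syn, is.null, logical(1))])
    rownames(synapses) <- NULL
    gt <- list(
      true_layer = stats::setNames(rep(NA_integer_, nrow(roster)),
                                   roster$neuron_id),
      true_type = stats::setNames(roster$cell_type, roster$neuron_id),
      true_dataset = stats::setNames(roster$dataset, roster$neuron_id),
      planted_pairs = config$planted_coinnervation_pairs,
      planted_polarity = stats::setNames(
        ifelse(polarised, "polarised", "mixed"), roster$neuron_id)
    )
    list(skeletons = skeletons, synapses = synapses, ground_truth = gt)
  })
}
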