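# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# build a connectome graph from a bare edge list without any filtering
graph_fixture <- function(edges, classes = NULL) {
  ids <- unique(c(edges$pre_id, edges$post_id))
  if (is.null(classes)) classes <- rep("other", length(ids))
  neurons <- data.frame(neuron_id = ids, class = classes,
                        stringsAsFactors = FALSE)
  build_graph(edges, neurons, min_weight = 1,
              drop_within_class = character())
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(pre_id = m[, 1], post_id = m[, 2],
             weight = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

# small probabilistic graphs (<= 6 nodes) for traversal oracle checks;
# each entry: edges, seeds, cap
tiny_traversal_fixtures <- function() {
  list(
    chain = list(edges = edge_df("s", "a", 10, "a", "b", 10),
                 seeds = "s", cap = 0.3),
    half_edge = list(edges = edge_df("s", "a", 10, "s", "b", 3,
                                     "x", "b", 17),
                     seeds = "s", cap = 0.3),
    diamond = list(edges = edge_df("s", "a", 6, "s", "b", 2, "z", "b", 18,
                                   "a", "t", 5, "b", "t", 5),
                   seeds = "s", cap = 0.3),
    deep = list(edges = edge_df("s", "a", 3, "x", "a", 27, "a", "b", 1,
                                "c", "b", 9, "s", "c", 10, "b", "t", 4),
                seeds = "s", cap = 0.3)
  )
}

# a straight segment along +x, length_um long, nodes every step_um (nm out)
straight_swc <- function(length_um = 10, step_um = 0.5) {
  x <- seq(0, length_um, by = step_um) * 1e3
  n <- length(x)
  data.frame(id = seq_len(n), type = 2L, x = x, y = 0, z = 0, radius = 50,
             parent = c(-1L, seq_len(n - 1)))
}

# densely resampled box-filling arbour used for translation-oracle tests:
# a long winding path in a small volume (coordinates nm)
dense_arbour_swc <- function(n_per_leg = 80, step_nm = 250, legs = 6) {
  pos <- matrix(0, 0, 3)
  cur <- c(0, 0, 0)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, 1, 0))
  for (l in seq_len(legs)) {
    d <- dirs[(l - 1) %% nrow(dirs) + 1, ]
    for (i in seq_len(n_per_leg)) {
      cur <- cur + d * step_nm
      pos <- rbind(pos, cur)
    }
  }
  n <- nrow(pos)
  data.frame(id = seq_len(n), type = 2L, x = pos[, 1], y = pos[, 2],
             z = pos[, 3], radius = 50, parent = c(-1L, seq_len(n - 1)))
}

translate_swc <- function(skel, offset_nm) {
  skel$x <- skel$x + offset_nm[1]
  skel$y <- skel$y + offset_nm[2]
  skel$z <- skel$z + offset_nm[3]
  skel
}

# synapse table for one hand-built neuron
synapse_rows <- function(neuron_id, compartment, polarity, glomerulus,
                         n = 10) {
  data.frame(neuron_id = neuron_id, polarity = polarity,
             x = seq_len(n) * 100, y = 0, z = 0,
             compartment = compartment, roi = glomerulus,
             glomerulus = glomerulus, stringsAsFactors = FALSE)
}
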