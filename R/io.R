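# Readers and writers for the standard formats the pipeline touches, and
# construction of the filtered analysis graph. CSV dialect: comma-separated,
# UTF-8, mandatory header row; all coordinates in nm.

neuron_classes <- c("ALRN", "ALLN", "ALPN", "TOON", "LHN", "KC", "MBON",
                    "DAN", "DN", "other")

check_columns <- function(df, needed, what, path) {
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stopf("%s '%s': missing column(s) %s", what, path,
          paste(sQuote(miss), collapse = ", "))
  invisible(df)
}

#' Read a neuron metadata table
#'
#' Columns: `neuron_id`, `class`, `cell_type`, `glomerulus`, `side`,
#' `lineage`, `transmitter`. `neuron_id` must be unique and `class` must
#' come from the closed vocabulary
#' ALRN/ALLN/ALPN/TOON/LHN/KC/MBON/DAN/DN/other.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_neuron_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("neuron_id", "class"), "neuron table", path)
  dup <- df$neuron_id[duplicated(df$neuron_id)]
  if (length(dup) > 0)
    stopf("neuron table '%s': duplicate neuron_id %s (first at row %d)",
          path, dup[1], which(df$neuron_id == dup[1])[1])
  bad <- which(!df$class %in% neuron_classes)
  if (length(bad) > 0)
    stopf("neuron table '%s': unknown class '%s' at row %d", path,
          df$class[bad[1]], bad[1])
  df$neuron_id <- as.character(df$neuron_id)
  df
}

#' Read a weighted synaptic edge list
#'
#' Columns `pre_id`, `post_id`, `weight`; weights must be positive
#' integers (synapse counts).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_edge_list <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("pre_id", "post_id", "weight"), "edge list", path)
  bad <- which(!is.finite(df$weight) | df$weight < 1 |
                 df$weight != floor(df$weight))
  if (length(bad) > 0)
    stopf("edge list '%s': weight must be a positive integer (row %d)",
          path, bad[1])
  df$pre_id <- as.character(df$pre_id)
  df$post_id <- as.character(df$post_id)
  df$weight <- as.integer(df$weight)
  df
}

#' Read a per-synapse table
#'
#' Columns `neuron_id`, `polarity` (pre/post), `x`, `y`, `z` (nm),
#' `compartment` (axon/dendrite/linker/soma/unknown) and optionally
#' `roi`/`glomerulus`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_synapse_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("neuron_id", "polarity", "x", "y", "z", "compartment"),
                "synapse table", path)
  bad <- which(!df$polarity %in% c("pre", "post"))
  if (length(bad) > 0)
    stopf("synapse table '%s': polarity must be 'pre' or 'post' (row %d)",
          path, bad[1])
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad) > 0)
    stopf("synapse table '%s': non-finite coordinates (row %d)", path, bad[1])
  df
}

#' Read a skeleton in SWC format
#'
#' Standard SWC columns (id, type, x, y, z, radius, parent; coordinates in
#' nm); a parent of -1 marks the root. Parent references must resolve and
#' must not form cycles.
#'
#' @param path SWC file path ('#' comment lines are skipped).
#' @return A data frame with the seven SWC columns.
#' @export
read_swc <- function(path) {
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "radius",
                                 "parent"))
  if (nrow(df) == 0) return(df)
  idx <- match(df$parent, df$id)
  bad <- which(df$parent != -1 & is.na(idx))
  if (length(bad) > 0)
    stopf("SWC '%s': row %d has unknown parent %d", path, bad[1],
          df$parent[bad[1]])
  # walk each parent chain; revisiting a node before reaching a root is a
  # cycle (a node whose parent is itself is the degenerate case)
  n <- nrow(df)
  state <- integer(n)  # 0 unseen, 1 on current path, 2 done
  for (s in seq_len(n)) {
    v <- s
    path_nodes <- integer(0)
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      path_nodes <- c(path_nodes, v)
      v <- if (df$parent[v] == -1) NA_integer_ else idx[v]
    }
    if (!is.na(v) && state[v] == 1L)
      stopf("SWC '%s': cyclic parent chain involving row %d", path, v)
    state[path_nodes] <- 2L
  }
  df
}

#' Write a skeleton in SWC format
#' @param skel SWC data frame (see [read_swc()]).
#' @param path output file path.
#' @export
write_swc <- function(skel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC: id type x y z radius parent (coordinates in nm)", con)
  write.table(skel[, c("id", "type", "x", "y", "z", "radius", "parent")],
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table as CSV with the package's documented schema
#' @param df data frame.
#' @param path output file path.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the filtered analysis graph
#'
#' Duplicate (pre, post) records are summed, then edges below `min_weight`
#' synapses are removed (single-synapse connections are reconstruction
#' noise) and edges whose two endpoints both belong to a class in
#' `drop_within_class` are removed (within-class Kenyon cell connections
#' are considered false positives). Filtering is idempotent.
#'
#' @param edges edge list data frame (`pre_id`, `post_id`, `weight`).
#' @param neurons neuron table; every edge endpoint must appear in it.
#' @param min_weight minimum surviving synapse count (default 2).
#' @param drop_within_class character vector of classes whose within-class
#'   edges are dropped (default `"KC"`).
#' @return An object of class `"connectome_graph"`: list with `edges`,
#'   `nodes`, `total_in` (named per-node total input weight) and `igraph`.
#' @export
build_graph <- function(edges, neurons, min_weight = 2,
                        drop_within_class = "KC") {
  unknown <- setdiff(unique(c(edges$pre_id, edges$post_id)),
                     neurons$neuron_id)
  if (length(unknown) > 0)
    stopf("edge list refers to neuron(s) absent from the neuron table: %s",
          paste(unknown, collapse = ", "))
  if (nrow(edges) > 0) {
    edges <- aggregate(weight ~ pre_id + post_id, edges, sum)
    cls <- stats::setNames(neurons$class, neurons$neuron_id)
    keep <- edges$weight >= min_weight &
      !(cls[edges$pre_id] %in% drop_within_class &
          cls[edges$post_id] %in% drop_within_class &
          cls[edges$pre_id] == cls[edges$post_id])
    edges <- edges[keep, , drop = FALSE]
    edges <- edges[order(edges$post_id, edges$pre_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  total_in <- stats::setNames(numeric(nrow(neurons)), neurons$neuron_id)
  if (nrow(edges) > 0) {
    s <- tapply(edges$weight, edges$post_id, sum)
    total_in[names(s)] <- s
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("pre_id", "post_id", "weight")],
    directed = TRUE, vertices = neurons$neuron_id)
  structure(list(edges = edges, nodes = neurons, total_in = total_in,
                 igraph = g),
            class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf("connectome graph: %d neurons, %d edges, %g synapses\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Extract the edge list of a connectome graph
#' @param graph a `"connectome_graph"`.
#' @return The filtered edge list data frame.
#' @export
as_edge_list <- function(graph) {
  stopifnot(inherits(graph, "connectome_graph"))
  graph$edges
}
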