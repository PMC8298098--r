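# Morphological similarity scoring on dotprops, across-dataset cell-type
# clustering with minimum-cut refinement, and connectivity-similarity
# stereotypy statistics.

# ---- skeleton processing ------------------------------------------------

swc_children <- function(skel) {
  idx <- match(skel$parent, skel$id)
  split(which(!is.na(idx)), factor(idx[!is.na(idx)],
                                   levels = seq_len(nrow(skel))))
}

# remove terminal twigs shorter than threshold_um; iterates because a
# pruned branch may expose a new short twig
prune_twigs <- function(skel, threshold_um, scale_nm = 1e3) {
  repeat {
    ch <- swc_children(skel)
    n_child <- vapply(ch, length, integer(1))
    idx <- match(skel$parent, skel$id)
    leaves <- which(n_child == 0)
    drop <- integer(0)
    for (leaf in leaves) {
      path <- integer(0)
      v <- leaf
      len <- 0
      while (!is.na(idx[v]) && n_child[v] <= 1) {
        p <- idx[v]
        len <- len + sqrt((skel$x[v] - skel$x[p])^2 +
                            (skel$y[v] - skel$y[p])^2 +
                            (skel$z[v] - skel$z[p])^2) / scale_nm
        path <- c(path, v)
        if (n_child[p] > 1 || is.na(idx[p])) break
        v <- p
      }
      if (length(path) > 0 && len < threshold_um)
        drop <- union(drop, path)
    }
    if (length(drop) == 0) return(skel)
    skel <- skel[-drop, , drop = FALSE]
  }
}

# resample every unbranched path at ~step_um spacing; returns a point
# matrix in um
resample_points <- function(skel, step_um, scale_nm = 1e3) {
  xyz <- as.matrix(skel[, c("x", "y", "z")]) / scale_nm
  idx <- match(skel$parent, skel$id)
  ch <- swc_children(skel)
  n_child <- vapply(ch, length, integer(1))
  is_fixed <- is.na(idx) | n_child != 1  # root, branch points, leaves
  # walk up from every leaf/branch node to the previous fixed node
  paths <- list()
  for (v in which(is_fixed & !is.na(idx))) {
    path <- v
    p <- idx[v]
    while (!is_fixed[p]) {
      path <- c(path, p)
      p <- idx[p]
    }
    paths[[length(paths) + 1L]] <- rev(c(path, p))
  }
  if (length(paths) == 0) return(xyz)
  pts <- list()
  for (pp in paths) {
    seg <- xyz[pp, , drop = FALSE]
    d <- sqrt(rowSums(diff(seg)^2))
    s <- c(0, cumsum(d))
    L <- s[length(s)]
    t_new <- if (L <= step_um) c(0, L) else seq(0, L, by = step_um)
    if (t_new[length(t_new)] < L) t_new <- c(t_new, L)
    pts[[length(pts) + 1L]] <- cbind(
      approx(s, seg[, 1], xout = t_new)$y,
      approx(s, seg[, 2], xout = t_new)$y,
      approx(s, seg[, 3], xout = t_new)$y)
  }
  unique(do.call(rbind, pts))
}

#' Convert a skeleton to a tangent-vector point cloud (dotprops)
#'
#' The skeleton is scaled to micrometres, terminal twigs shorter than
#' `twig_prune` are removed, the arbour is resampled to approximately
#' `resample_step` spacing and each point receives a unit tangent: the
#' dominant principal direction of its `k`-point neighbourhood (the point
#' and its nearest neighbours).
#'
#' @param skel SWC data frame (coordinates in nm by default).
#' @param resample_step resampling step, um.
#' @param k neighbourhood size for the local tangent.
#' @param twig_prune twig-pruning threshold, um.
#' @param scale_nm unit scale of the input coordinates (default 1000,
#'   i.e. nm in, um out).
#' @return Object of class `"dotprops"`: list with `points` (n x 3, um),
#'   `tangents` (n x 3 unit vectors) and `k`.
#' @export
make_dotprops <- function(skel, resample_step = 1, k = 5, twig_prune = 2,
                          scale_nm = 1e3) {
  skel <- prune_twigs(skel, twig_prune, scale_nm)
  pts <- resample_points(skel, resample_step, scale_nm)
  n <- nrow(pts)
  if (n < k + 1)
    stopf("fewer than k + 1 = %d points left after processing", k + 1)
  D <- cross_dist(pts, pts)
  tangents <- t(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]  # the point itself plus k - 1 others
    v <- eigen(stats::cov(pts[nb, , drop = FALSE]),
               symmetric = TRUE)$vectors[, 1]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  structure(list(points = pts, tangents = tangents, k = k),
            class = "dotprops")
}

#' Normalised morphological similarity between two dotprops
#'
#' A simplified parametric scorer: the directed raw score is the sum over
#' query points of `sqrt(|u . v|) * exp(-d^2 / (2 sigma^2))` against the
#' nearest target point, self-normalised by the query's raw self-score so
#' a perfect copy scores 1. The pair score is the minimum of the two
#' directed normalised scores, which makes the pair matrix symmetric.
#'
#' @param query,target `"dotprops"` objects.
#' @param sigma distance scale of the Gaussian kernel, um (default 3).
#' @param directed return only the normalised query-to-target score.
#' @return Normalised score (<= 1; 1 for identical clouds).
#' @export
similarity_score <- function(query, target, sigma = 3, directed = FALSE) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  if (nrow(query$points) == 0 || nrow(target$points) == 0)
    stopf("empty dotprops")
  fwd <- dotprops_raw_score(query$points, query$tangents,
                            target$points, target$tangents, sigma) /
    dotprops_raw_score(query$points, query$tangents,
                       query$points, query$tangents, sigma)
  if (directed) return(fwd)
  rev <- dotprops_raw_score(target$points, target$tangents,
                            query$points, query$tangents, sigma) /
    dotprops_raw_score(target$points, target$tangents,
                       target$points, target$tangents, sigma)
  min(fwd, rev)
}

#' Pairwise similarity matrix over a set of dotprops
#'
#' @param dps named list of `"dotprops"`.
#' @param sigma kernel scale, um.
#' @return Symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(dps, sigma = 3) {
  n <- length(dps)
  m <- diag(1, n)
  dimnames(m) <- list(names(dps), names(dps))
  if (n < 2) return(m)
  self <- vapply(dps, function(d)
    dotprops_raw_score(d$points, d$tangents, d$points, d$tangents, sigma),
    numeric(1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fwd <- dotprops_raw_score(dps[[i]]$points, dps[[i]]$tangents,
                              dps[[j]]$points, dps[[j]]$tangents,
                              sigma) / self[i]
    rev <- dotprops_raw_score(dps[[j]]$points, dps[[j]]$tangents,
                              dps[[i]]$points, dps[[i]]$tangents,
                              sigma) / self[j]
    m[i, j] <- m[j, i] <- min(fwd, rev)
  }
  m
}

#' Initial clusters from reciprocal best matches across datasets
#'
#' For every entity and every other dataset, an undirected edge is added
#' to its single best-scoring match in that dataset; clusters are the
#' connected components of the resulting top-match graph. Entities
#' without any cross-dataset candidate become singletons.
#'
#' @param scores symmetric similarity matrix with named rows/columns.
#' @param dataset_tags character vector of dataset tags, one per entity
#'   (>= 2 distinct datasets required).
#' @return List with `membership` (named integer vector) and `graph`
#'   (the igraph top-match graph).
#' @export
top_match_clusters <- function(scores, dataset_tags) {
  ids <- rownames(scores)
  stopifnot(length(dataset_tags) == length(ids))
  if (length(unique(dataset_tags)) < 2)
    stopf("need entities from at least 2 datasets")
  edges <- character(0)
  for (i in seq_along(ids)) {
    for (ds in setdiff(unique(dataset_tags), dataset_tags[i])) {
      cand <- which(dataset_tags == ds)
      if (length(cand) == 0) next
      best <- cand[which.max(scores[i, cand])]
      edges <- c(edges, ids[i], ids[best])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  memb <- igraph::components(g)$membership
  list(membership = stats::setNames(as.integer(memb), ids), graph = g)
}

worst_within <- function(members, scores) {
  if (length(members) < 2) return(Inf)
  sub <- scores[members, members]
  min(sub[upper.tri(sub)])
}

split_by_mincut <- function(members, scores) {
  pairs <- t(combn(members, 2))
  w <- pmax(scores[pairs], 0)  # negative similarities carry no capacity
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  cut <- igraph::min_cut(g, capacity = w, value.only = FALSE)
  list(igraph::V(g)$name[cut$partition1], igraph::V(g)$name[cut$partition2])
}

#' Refine clusters by minimum cuts until a worst-score floor holds
#'
#' While any cluster contains a pair scoring below `min_score`, that
#' cluster is split at the global minimum-weight cut of its
#' similarity-weighted graph (negative scores floored at zero) and the
#' parts are refined recursively. Refinement only splits, never merges,
#' so every output cluster satisfies the floor.
#'
#' @param clusters a [top_match_clusters()] result or a named membership
#'   vector.
#' @param scores symmetric similarity matrix.
#' @param min_score worst tolerated within-cluster pair score
#'   (default 0.4).
#' @return Named integer membership vector.
#' @export
refine_clusters <- function(clusters, scores, min_score = 0.4) {
  memb <- if (is.list(clusters)) clusters$membership else clusters
  out <- list()
  refine <- function(members) {
    if (worst_within(members, scores) >= min_score) {
      out[[length(out) + 1L]] <<- members
    } else {
      parts <- split_by_mincut(members, scores)
      for (p in parts) refine(p)
    }
  }
  for (cl in split(names(memb), memb)) refine(cl)
  res <- integer(0)
  for (i in seq_along(out))
    res[out[[i]]] <- i
  res[names(memb)]
}

# ---- connectivity stereotypy -------------------------------------------

#' Signed, column-normalised connectivity cosine similarity
#'
#' Connection strengths are given a sign per source according to its
#' transmitter (inhibitory transmitters negative), every column (target)
#' is normalised by its maximum absolute strength, and the cosine
#' similarity between source rows is returned. Sources with an all-zero
#' profile get missing similarities.
#'
#' @param conn non-negative matrix, sources x targets.
#' @param transmitters optional named character vector (per source).
#' @param sign_map named numeric vector mapping transmitter to +-1.
#' @param normalize `"column_max"` or `"none"`.
#' @return Symmetric cosine similarity matrix over sources (NA rows for
#'   all-zero sources).
#' @export
connectivity_cosine <- function(conn,
                                transmitters = NULL,
                                sign_map = c(acetylcholine = 1, GABA = -1,
                                             glutamate = -1, unknown = 1),
                                normalize = c("column_max", "none")) {
  normalize <- match.arg(normalize)
  conn <- as.matrix(conn)
  if (any(conn < 0)) stopf("'conn' must be non-negative before signing")
  if (!is.null(transmitters)) {
    sg <- sign_map[transmitters]
    sg[is.na(sg)] <- 1
    conn <- conn * sg
  }
  if (normalize == "column_max") {
    cm <- apply(abs(conn), 2, max)
    cm[cm == 0] <- 1
    conn <- sweep(conn, 2, cm, "/")
  }
  nrm <- sqrt(rowSums(conn^2))
  cs <- tcrossprod(conn) / outer(nrm, nrm)
  cs[nrm == 0, ] <- NA_real_
  cs[, nrm == 0] <- NA_real_
  cs
}

pool_columns <- function(conn, labels) {
  stopifnot(length(labels) == ncol(conn))
  groups <- sort(unique(labels))
  out <- matrix(0, nrow(conn), length(groups),
                dimnames = list(rownames(conn), groups))
  for (g in groups)
    out[, g] <- rowSums(conn[, labels == g, drop = FALSE])
  out
}

#' Sister versus non-sister versus shuffled connectivity similarity
#'
#' Compares downstream-connectivity cosine similarity between "sister"
#' source pairs (same cell type), non-sister pairs (different types) and
#' a shuffled control in which every source's downstream cell-type
#' labels are independently permuted before pooling, producing random
#' small out-of-type groupings. Targets are pooled by cell type
#' (`pool_by = "type"`) or kept as individual cells.
#'
#' @param conn non-negative matrix, sources x target cells.
#' @param source_types character vector, one type label per source row.
#' @param target_types character vector, one type label per target
#'   column.
#' @param pool_by `"type"` or `"cell"`.
#' @param n_label_shuffles shuffle replicates (default 100).
#' @param rng_seed optional seed.
#' @return List of numeric score vectors `sister`, `non_sister`,
#'   `shuffled`.
#' @export
sister_comparison <- function(conn, source_types, target_types,
                              pool_by = c("type", "cell"),
                              n_label_shuffles = 100, rng_seed = NULL) {
  pool_by <- match.arg(pool_by)
  conn <- as.matrix(conn)
  stopifnot(length(source_types) == nrow(conn),
            length(target_types) == ncol(conn))
  pooled <- if (pool_by == "type") pool_columns(conn, target_types) else conn
  cs <- connectivity_cosine(pooled, normalize = "none")
  ut <- which(upper.tri(cs), arr.ind = TRUE)
  same <- source_types[ut[, 1]] == source_types[ut[, 2]]
  sister <- cs[ut][same]
  non_sister <- cs[ut][!same]
  if (length(sister) == 0)
    warnf("no sister pairs (every source type has a single member)")
  groups <- sort(unique(target_types))
  shuffled <- with_seed(rng_seed, {
    unlist(lapply(seq_len(n_label_shuffles), function(rep) {
      if (pool_by == "type") {
        sp <- matrix(0, nrow(conn), length(groups))
        for (i in seq_len(nrow(conn)))
          sp[i, ] <- pool_columns(conn[i, , drop = FALSE],
                                  sample(target_types))[1, ]
      } else {
        sp <- conn
        for (i in seq_len(nrow(conn)))
          sp[i, ] <- conn[i, sample(ncol(conn))]
      }
      cs2 <- connectivity_cosine(sp, normalize = "none")
      cs2[ut][same]
    }))
  })
  list(sister = sister, non_sister = non_sister, shuffled = shuffled)
}
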