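# Glomerular innervation statistics: innervation-breadth curves, the
# co-innervation permutation test with Holm-Sidak correction, input-output
# segregation profiles, intra-glomerular morphology distances and
# KDE-based glomerulus volume reconstruction.

#' Cumulative normalised innervation-breadth curves
#'
#' Per neuron (column): synapse counts are sorted over glomeruli in
#' descending order, the sorted vector is min-max normalised to `[0, 1]`
#' and cumulatively summed. Sparsely innervating neurons plateau within
#' the first few ranks, broadly innervating ones keep rising. Note the
#' degenerate case: a neuron with identical counts in every glomerulus
#' min-max collapses to all zeros and its curve is identically 0.
#'
#' @param mat count matrix, rows = glomeruli, columns = neurons.
#' @return Matrix of cumulative curves, rows = glomerulus rank,
#'   columns = neurons (all-zero columns are dropped with a warning).
#' @export
cumulative_rank_curves <- function(mat) {
  mat <- as.matrix(mat)
  zero <- colSums(mat) == 0
  if (any(zero)) {
    warnf("%d all-zero neuron column(s) excluded", sum(zero))
    mat <- mat[, !zero, drop = FALSE]
  }
  apply(mat, 2, function(x) {
    s <- sort(x, decreasing = TRUE)
    rng <- max(s) - min(s)
    n <- if (rng == 0) rep(0, length(s)) else (s - min(s)) / rng
    cumsum(n)
  })
}

#' Holm-Sidak stepdown multiple-testing correction
#'
#' Stepdown procedure controlling the family-wise error rate: p-values
#' are sorted ascending and the i-th smallest is adjusted to
#' `max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`; hypotheses with adjusted
#' p at or below `alpha` are rejected.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return List with `adjusted` (same order as `p`) and `reject`
#'   (logical).
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("'p' must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(list(adjusted = numeric(0), reject = logical(0)))
  o <- order(p)
  adj_sorted <- cummax(pmin(1, 1 - (1 - p[o])^(m - seq_len(m) + 1)))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Glomerular co-innervation permutation test
#'
#' For every unordered pair of glomeruli and every neuron, a co-occurrence
#' statistic is computed (default: the smaller of the neuron's two
#' synapse counts, i.e. the number of matchable synapses; alternatives:
#' their product, or a binary indicator of joint innervation). The
#' observed statistic of a pair is its sum over neurons. The null
#' distribution permutes, per neuron, that neuron's vector of per-pair
#' statistics across pairs and re-sums per pair; the raw p-value of a
#' pair is the proportion of shuffles whose null sum is at least the
#' observed sum (optionally with an add-one correction for strict
#' Monte-Carlo validity). Raw p-values are corrected by the
#' [holm_sidak()] stepdown at family-wise error rate `alpha`.
#'
#' @param mat count matrix, rows = glomeruli (>= 2), columns = neurons.
#' @param statistic `"min"`, `"product"` or `"indicator"`.
#' @param n_shuffles number of row shuffles (default 20,000).
#' @param alpha family-wise error rate.
#' @param rng_seed optional integer seed.
#' @param correction `"none"` (plain proportion, the conventional choice)
#'   or `"add_one"` (`(b + 1) / (B + 1)`).
#' @return Data frame with one row per pair: `glom1`, `glom2`,
#'   `observed`, `p_raw`, `p_adj`, `significant`.
#' @export
coinnervation_test <- function(mat, statistic = c("min", "product",
                                                  "indicator"),
                               n_shuffles = 20000, alpha = 0.05,
                               rng_seed = NULL,
                               correction = c("none", "add_one")) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  mat <- as.matrix(mat)
  G <- nrow(mat)
  if (G < 2) stopf("need at least 2 glomeruli")
  n_shuffles <- check_count(n_shuffles, "n_shuffles", min = 1)
  pairs <- combn(G, 2)
  a <- mat[pairs[1, ], , drop = FALSE]
  b <- mat[pairs[2, ], , drop = FALSE]
  S <- switch(statistic,
              min = pmin(a, b),
              product = a * b,
              indicator = (a > 0) * (b > 0))
  storage.mode(S) <- "double"
  counts <- with_seed(rng_seed, null_pair_sum_counts(S, n_shuffles))
  p_raw <- if (correction == "none") counts / n_shuffles
  else (counts + 1) / (n_shuffles + 1)
  hs <- holm_sidak(p_raw, alpha)
  gl <- rownames(mat)
  if (is.null(gl)) gl <- as.character(seq_len(G))
  data.frame(glom1 = gl[pairs[1, ]], glom2 = gl[pairs[2, ]],
             observed = rowSums(S), p_raw = p_raw, p_adj = hs$adjusted,
             significant = hs$reject, stringsAsFactors = FALSE)
}

#' Input-output segregation profiles per type
#'
#' Per neuron: glomeruli are ranked by total synapse count (pre + post,
#' descending; ties broken by glomerulus label) and the largest trailing
#' set accounting for at most `prune_frac` of the neuron's synapses is
#' dropped. The per-glomerulus difference postsynapses minus presynapses
#' is computed over the survivors, glomeruli with neither are dropped,
#' glomerular identities are collapsed and the differences sorted in
#' descending order. Profiles are averaged across the neurons of a type
#' by rank position. Positive ranks mark net input, negative ranks net
#' output.
#'
#' @param pre,post count matrices of identical shape (rows = glomeruli,
#'   columns = neurons): presynapse and postsynapse counts.
#' @param prune_frac synapse share of the pruned tail (default 0.05).
#' @param types optional character vector (one per neuron column)
#'   grouping neurons into types; default puts all neurons in one type.
#' @return Named list (one element per type) of mean sorted difference
#'   vectors; element names carry signed ranks.
#' @export
input_output_segregation <- function(pre, post, prune_frac = 0.05,
                                     types = NULL) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post)))
    stopf("'pre' and 'post' must share their shape")
  if (is.null(types)) types <- rep("all", ncol(pre))
  gl <- rownames(pre)
  if (is.null(gl)) gl <- as.character(seq_len(nrow(pre)))
  per_neuron <- lapply(seq_len(ncol(pre)), function(j) {
    tot <- pre[, j] + post[, j]
    if (sum(tot) == 0) return(numeric(0))
    o <- order(-tot, gl)
    tail_share <- rev(cumsum(rev(tot[o]))) / sum(tot)
    drop_from <- which(tail_share <= prune_frac)
    keep <- if (length(drop_from) > 0) o[seq_len(min(drop_from) - 1)] else o
    d <- post[keep, j] - pre[keep, j]
    d <- d[pre[keep, j] != 0 | post[keep, j] != 0]
    sort(d, decreasing = TRUE)
  })
  out <- lapply(split(per_neuron, types), function(group) {
    len <- max(vapply(group, length, integer(1)), 0)
    if (len == 0) return(numeric(0))
    m <- vapply(group, function(v) c(v, rep(NA_real_, len - length(v))),
                numeric(len))
    prof <- rowMeans(as.matrix(m), na.rm = TRUE)
    pos <- sum(prof > 0); neg <- sum(prof < 0)
    nm <- character(len)
    nm[prof > 0] <- paste0("+", seq_len(pos))
    nm[prof < 0] <- paste0("-", seq_len(neg))
    nm[prof == 0] <- "0"
    stats::setNames(prof, nm)
  })
  out
}

# cable length (um) of an SWC fragment: sum of parent-edge lengths whose
# two endpoints are both present
swc_cable_length <- function(skel) {
  if (nrow(skel) == 0) return(0)
  idx <- match(skel$parent, skel$id)
  has <- !is.na(idx)
  if (!any(has)) return(0)
  d <- sqrt((skel$x[has] - skel$x[idx[has]])^2 +
              (skel$y[has] - skel$y[idx[has]])^2 +
              (skel$z[has] - skel$z[idx[has]])^2)
  sum(d) / 1e3
}

cross_dist <- function(a, b) {
  # Euclidean distances between rows of a (n x 3) and b (m x 3)
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}

#' Intra-glomerular morphology distance between two arbours
#'
#' Both skeletons are restricted to a region of interest (when `region`
#' is given as a bounding box) and excluded if the remaining cable is
#' shorter than `min_cable` micrometres. Otherwise, for every node of
#' each neuron the mean Euclidean distance to its `k` nearest nodes in
#' the other neuron is computed; node scores of both neurons are pooled
#' and the mean of the largest `top_frac` fraction is returned. The
#' pooled construction makes the measure symmetric in its arguments.
#'
#' @param a,b SWC data frames (coordinates in nm).
#' @param region optional list with `min` and `max` (length-3, nm)
#'   bounding the glomerulus.
#' @param min_cable minimum cable length inside the region, um.
#' @param k nearest-node count.
#' @param top_frac fraction of largest node scores averaged.
#' @return List with `distance` (um, NA when excluded), `excluded`
#'   (logical) and `cable` (the two cable lengths, um).
#' @export
intraglomerular_distance <- function(a, b, region = NULL, min_cable = 80,
                                     k = 5, top_frac = 0.10) {
  clip <- function(s) {
    if (is.null(region)) return(s)
    inb <- s$x >= region$min[1] & s$x <= region$max[1] &
      s$y >= region$min[2] & s$y <= region$max[2] &
      s$z >= region$min[3] & s$z <= region$max[3]
    s[inb, , drop = FALSE]
  }
  a <- clip(a); b <- clip(b)
  cable <- c(swc_cable_length(a), swc_cable_length(b))
  if (any(cable < min_cable))
    return(list(distance = NA_real_, excluded = TRUE, cable = cable))
  pa <- as.matrix(a[, c("x", "y", "z")]) / 1e3
  pb <- as.matrix(b[, c("x", "y", "z")]) / 1e3
  knn_mean <- function(D, k) {
    k <- min(k, ncol(D))
    apply(D, 1, function(r) mean(sort(r, partial = k)[seq_len(k)]))
  }
  D <- cross_dist(pa, pb)
  scores <- c(knn_mean(D, k), knn_mean(t(D), k))
  m <- ceiling(top_frac * length(scores))
  list(distance = mean(sort(scores, decreasing = TRUE)[seq_len(m)]),
       excluded = FALSE, cable = cable)
}

# Gaussian product-kernel density with Scott's-rule bandwidths, evaluated
# at arbitrary points (all coordinates in nm)
gauss_kde3 <- function(pts, eval, bw = NULL) {
  n <- nrow(pts)
  if (is.null(bw)) {
    scott <- n^(-1 / 7)
    bw <- pmax(apply(pts, 2, sd) * scott, 1e-6)
  }
  E <- matrix(0, nrow(eval), n)
  for (d in 1:3) {
    Z <- outer(eval[, d], pts[, d], "-") / bw[d]
    E <- E - 0.5 * Z^2
  }
  rowSums(exp(E)) / (n * prod(bw) * (2 * pi)^(3 / 2))
}

shift_mask <- function(mask, d, axis) {
  out <- array(FALSE, dim(mask))
  dm <- dim(mask)
  src <- lapply(dm, seq_len)
  dst <- src
  rng <- seq_len(dm[axis] - abs(d))
  if (d > 0) { dst[[axis]] <- rng + d; src[[axis]] <- rng }
  else if (d < 0) { dst[[axis]] <- rng; src[[axis]] <- rng - d }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

erode_mask <- function(mask, iters = 1) {
  for (i in seq_len(iters)) {
    keep <- mask
    for (axis in 1:3) for (d in c(-1, 1))
      keep <- keep & shift_mask(mask, d, axis)
    mask <- keep
  }
  mask
}

fill_holes <- function(mask) {
  dm <- dim(mask)
  # flood the complement from the array border (6-connectivity) by
  # repeated dilation; anything in the complement not reached is a hole
  on_border <- slice.index(mask, 1) %in% c(1, dm[1]) |
    slice.index(mask, 2) %in% c(1, dm[2]) |
    slice.index(mask, 3) %in% c(1, dm[3])
  outside <- !mask & on_border
  repeat {
    grown <- outside
    for (axis in 1:3) for (d in c(-1L, 1L))
      grown <- grown | (shift_mask(outside, d, axis) & !mask)
    if (identical(grown, outside)) break
    outside <- grown
  }
  mask | (!mask & !outside)
}

#' KDE-based glomerulus voxel labelling
#'
#' Fits a Gaussian kernel density estimate (product kernel, Scott's-rule
#' bandwidths) to the synapse cloud of each glomerulus, rasterises space
#' into isotropic voxels (default 480 nm) and assigns every voxel to its
#' most likely glomerulus. Voxels whose best density falls below the
#' threshold are background (the default threshold per glomerulus is the
#' 1st percentile of that glomerulus's density evaluated at its own
#' points). Each label mask is then binary-eroded and hole-filled.
#'
#' @param points_by_glomerulus named list of n-by-3 coordinate matrices
#'   (nm), one per glomerulus; each needs at least 10 points.
#' @param voxel_size isotropic voxel edge, nm.
#' @param pdf_threshold either `NULL` (per-glomerulus 1st percentile), a
#'   single number applied to all glomeruli, or a vector per glomerulus.
#' @param erosion_iters binary erosion iterations (default 1).
#' @return Object of class `"voxel_label_grid"`: list with `origin` (nm),
#'   `voxel_size`, `labels` (3D integer array, 0 = background),
#'   `glomeruli` (label names) and `threshold`.
#' @export
glomerulus_voxel_map <- function(points_by_glomerulus, voxel_size = 480,
                                 pdf_threshold = NULL, erosion_iters = 1) {
  if (length(points_by_glomerulus) == 0) stopf("no glomeruli given")
  for (nm in names(points_by_glomerulus)) {
    p <- points_by_glomerulus[[nm]]
    if (is.null(p) || nrow(p) == 0)
      stopf("glomerulus '%s' has an empty point set", nm)
    if (nrow(p) < 10)
      stopf("glomerulus '%s' has fewer than 10 points; KDE not feasible", nm)
  }
  pts_all <- do.call(rbind, points_by_glomerulus)
  lo <- apply(pts_all, 2, min) - 4 * voxel_size
  hi <- apply(pts_all, 2, max) + 4 * voxel_size
  ax <- lapply(1:3, function(d)
    seq(lo[d] + voxel_size / 2, hi[d], by = voxel_size))
  dm <- vapply(ax, length, integer(1))
  centers <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  G <- length(points_by_glomerulus)
  dens <- matrix(0, nrow(centers), G)
  thr <- numeric(G)
  for (g in seq_len(G)) {
    p <- as.matrix(points_by_glomerulus[[g]])
    dens[, g] <- gauss_kde3(p, centers)
    thr[g] <- if (is.null(pdf_threshold))
      quantile(gauss_kde3(p, p), 0.01)
    else if (length(pdf_threshold) == 1) pdf_threshold
    else pdf_threshold[g]
  }
  best <- max.col(dens, ties.method = "first")
  bestv <- dens[cbind(seq_len(nrow(dens)), best)]
  lab <- ifelse(bestv >= thr[best], best, 0L)
  labels <- array(as.integer(lab), dm)
  if (all(labels == 0L))
    warnf("threshold removed every voxel; the grid is empty")
  for (g in seq_len(G)) {
    mask <- labels == g
    if (!any(mask)) next
    mask2 <- fill_holes(erode_mask(mask, erosion_iters))
    labels[mask & !mask2] <- 0L
    labels[!mask & mask2 & labels == 0L] <- as.integer(g)
  }
  structure(list(origin = lo, voxel_size = voxel_size, labels = labels,
                 glomeruli = names(points_by_glomerulus), threshold = thr),
            class = "voxel_label_grid")
}

#' Export a voxel label as an OBJ surface
#'
#' Writes the boundary faces of one label's voxel mask as a quad mesh in
#' Wavefront OBJ (a blocky isosurface; vertices in nm).
#'
#' @param grid a [glomerulus_voxel_map()] result.
#' @param label glomerulus name or index.
#' @param path output `.obj` path.
#' @export
write_voxel_obj <- function(grid, label, path) {
  stopifnot(inherits(grid, "voxel_label_grid"))
  g <- if (is.character(label)) match(label, grid$glomeruli) else label
  mask <- grid$labels == g
  dm <- dim(mask)
  vs <- grid$voxel_size
  verts <- list(); faces <- list()
  vkey <- new.env(parent = emptyenv())
  get_vert <- function(i, j, k) {
    key <- paste(i, j, k, sep = "_")
    v <- vkey[[key]]
    if (is.null(v)) {
      verts[[length(verts) + 1L]] <<-
        grid$origin + c(i - 1, j - 1, k - 1) * vs
      v <- length(verts)
      vkey[[key]] <- v
    }
    v
  }
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    corners <- list(
      list(c(i - 1, j - 1, k - 1), c(i - 1, j, k - 1), c(i - 1, j, k), c(i - 1, j - 1, k)),
      list(c(i, j - 1, k - 1), c(i, j, k - 1), c(i, j, k), c(i, j - 1, k)),
      list(c(i - 1, j - 1, k - 1), c(i, j - 1, k - 1), c(i, j - 1, k), c(i - 1, j - 1, k)),
      list(c(i - 1, j, k - 1), c(i, j, k - 1), c(i, j, k), c(i - 1, j, k)),
      list(c(i - 1, j - 1, k - 1), c(i, j - 1, k - 1), c(i, j, k - 1), c(i - 1, j, k - 1)),
      list(c(i - 1, j - 1, k), c(i, j - 1, k), c(i, j, k), c(i - 1, j, k)))
    for (f in seq_along(nb)) {
      n <- nb[[f]]
      covered <- all(n >= 1) && n[1] <= dm[1] && n[2] <= dm[2] &&
        n[3] <= dm[3] && mask[n[1], n[2], n[3]]
      if (!covered)
        faces[[length(faces) + 1L]] <- vapply(
          corners[[f]], function(cc) get_vert(cc[1] + 1, cc[2] + 1, cc[3] + 1),
          integer(1))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (v in verts)
    writeLines(sprintf("v %.1f %.1f %.1f", v[1], v[2], v[3]), con)
  for (f in faces)
    writeLines(paste("f", paste(f, collapse = " ")), con)
  invisible(path)
}
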