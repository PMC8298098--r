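# Entropy-based segregation scoring: how completely a neuron separates two
# synapse categories (input vs output, or input-from-class-A vs
# input-from-class-B) between its axon and dendrite.

#' Symmetric binary entropy
#'
#' `-(D log(D) + (1 - D) log(1 - D))` with `0 log 0 = 0`, in the given
#' logarithm base (default 10). Maximal (`log10(2) = 0.30103`) at
#' `D = 0.5`, zero at `D` of 0 or 1.
#'
#' @param D proportion(s) in `[0, 1]`.
#' @param base logarithm base.
#' @return Entropy value(s).
#' @export
binary_entropy <- function(D, base = 10) {
  if (any(!is.finite(D)) || any(D < 0) || any(D > 1))
    stopf("'D' must be in [0, 1]")
  term <- function(p) ifelse(p > 0, p * log(p, base = base), 0)
  -(term(D) + term(1 - D))
}

#' Entropy-based segregation score
#'
#' Given per-compartment counts of two synapse categories, computes
#' `1 - e / c`, where `e` is the synapse-count-weighted mean of the
#' per-compartment binary entropies of the category-1 fraction and `c`
#' is the entropy of the pooled category-1 fraction of the whole neuron.
#' The score is 1 for a totally polarised neuron (each compartment pure,
#' pooled composition mixed) and 0 when every compartment mirrors the
#' pooled composition. When the pooled composition is itself pure
#' (`c = 0`) no separation is measurable and the score is 0, with a
#' warning. The logarithm base cancels in `e / c`.
#'
#' @param counts numeric matrix with one row per compartment (e.g. axon,
#'   dendrite) and two columns, the counts of the two categories (e.g.
#'   inputs and outputs). Compartments with zero synapses are ignored.
#' @param base logarithm base passed to [binary_entropy()].
#' @return Score in `[0, 1]`.
#' @export
segregation_score <- function(counts, base = 10) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stopf("'counts' must have exactly 2 columns")
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- rowSums(counts)
  if (sum(tot) == 0) stopf("all counts are zero")
  use <- tot > 0
  D <- counts[use, 1] / tot[use]
  e <- sum(binary_entropy(D, base) * tot[use]) / sum(tot[use])
  Dp <- sum(counts[, 1]) / sum(counts)
  cc <- binary_entropy(Dp, base)
  if (cc == 0) {
    warnf("pooled composition is single-category; segregation undefined, returning 0")
    return(0)
  }
  min(1, max(0, 1 - e / cc))
}

# per-neuron axon/dendrite input-output counts from a synapse table
axodendritic_counts <- function(syn) {
  syn <- syn[syn$compartment %in% c("axon", "dendrite"), , drop = FALSE]
  lapply(split(syn, syn$neuron_id), function(s) {
    m <- matrix(0, 2, 2, dimnames = list(c("axon", "dendrite"),
                                         c("input", "output")))
    t <- table(factor(s$compartment, c("axon", "dendrite")),
               factor(s$polarity, c("post", "pre")))
    m[, ] <- t
    m
  })
}

#' Axon-dendrite segregation index per neuron
#'
#' Applies [segregation_score()] with categories input (post) vs output
#' (pre) and compartments axon vs dendrite, per neuron of a synapse
#' table. Neurons without any axon/dendrite-labelled synapse are excluded
#' with a warning.
#'
#' @param synapses synapse table (see [read_synapse_table()]).
#' @return Data frame `neuron_id`, `segregation_index`.
#' @export
segregation_index <- function(synapses) {
  counts <- axodendritic_counts(synapses)
  missing <- setdiff(unique(synapses$neuron_id), names(counts))
  if (length(missing) > 0)
    warnf("%d neuron(s) without labelled axon/dendrite synapses excluded",
          length(missing))
  si <- vapply(counts, function(m) {
    if (sum(m) == 0) return(NA_real_)
    if (binary_entropy(sum(m[, 1]) / sum(m)) == 0) return(0)
    segregation_score(m)
  }, numeric(1))
  data.frame(neuron_id = names(si), segregation_index = unname(si),
             stringsAsFactors = FALSE)
}

#' Glomerular axonic-output / dendritic-input bias matrix
#'
#' For every sufficiently polarised neuron (axo-dendritic segregation
#' index above `threshold`, default 0.1) and every glomerulus, computes
#' the fraction of the neuron's total axonic outputs placed in that
#' glomerulus minus the fraction of its total dendritic inputs placed
#' there. +1 means the neuron only outputs axonically in the glomerulus,
#' -1 that it only receives dendritic input there.
#'
#' @param synapses synapse table with `compartment` and `glomerulus`
#'   labels.
#' @param threshold segregation-index cut-off for inclusion.
#' @return Numeric matrix, rows = neurons (passing the threshold),
#'   columns = glomeruli, entries in `[-1, 1]`.
#' @export
glomerular_polarity_matrix <- function(synapses, threshold = 0.1) {
  si <- segregation_index(synapses)
  keep <- si$neuron_id[!is.na(si$segregation_index) &
                         si$segregation_index > threshold]
  syn <- synapses[synapses$neuron_id %in% keep &
                    !is.na(synapses$glomerulus), , drop = FALSE]
  glom <- sort(unique(syn$glomerulus))
  out <- matrix(0, length(keep), length(glom),
                dimnames = list(keep, glom))
  for (id in keep) {
    s <- syn[syn$neuron_id == id, , drop = FALSE]
    ax_out <- s$compartment == "axon" & s$polarity == "pre"
    de_in <- s$compartment == "dendrite" & s$polarity == "post"
    fa <- if (sum(ax_out) > 0)
      table(factor(s$glomerulus[ax_out], glom)) / sum(ax_out) else 0
    fd <- if (sum(de_in) > 0)
      table(factor(s$glomerulus[de_in], glom)) / sum(de_in) else 0
    out[id, ] <- as.numeric(fa) - as.numeric(fd)
  }
  out
}

#' Hierarchical clustering with Ward linkage
#'
#' Agglomerative clustering of the rows of a matrix using Ward's method
#' on Euclidean distances (`hclust` method `"ward.D2"`); deterministic
#' given the input.
#'
#' @param mat numeric matrix (rows = entities).
#' @param k number of clusters to cut at (optional).
#' @param h height to cut at (optional; one of `k`/`h` required).
#' @return List with `labels` (named integer vector) and `tree` (the
#'   `hclust` object).
#' @export
cluster_ward <- function(mat, k = NULL, h = NULL) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stopf("'mat' must be finite")
  if (!is.null(k) && k > nrow(mat))
    stopf("cannot cut %d rows into %d clusters", nrow(mat), k)
  tree <- hclust(dist(mat), method = "ward.D2")
  labels <- if (is.null(k) && is.null(h))
    stats::setNames(rep(1L, nrow(mat)), rownames(mat))
  else cutree(tree, k = k, h = h)
  list(labels = labels, tree = tree)
}
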