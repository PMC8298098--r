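# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation.

# Exact expected traversal step by enumeration over the pool state space
# (aggregate mode). Works on tiny graphs only. Returns a named vector of
# expected mean steps (seeds = 1, unreachable = NA).
enum_mean_steps <- function(edges, ids, seeds, cap) {
  tot_in <- stats::setNames(rep(0, length(ids)), ids)
  for (r in seq_len(nrow(edges)))
    tot_in[edges$post_id[r]] <- tot_in[edges$post_id[r]] + edges$weight[r]
  # reachable closure
  reach <- seeds
  repeat {
    nxt <- unique(edges$post_id[edges$pre_id %in% reach])
    add <- setdiff(nxt, reach)
    if (length(add) == 0) break
    reach <- c(reach, add)
  }
  p_of <- function(S) {
    vapply(ids, function(j) {
      if (j %in% S) return(0)
      w <- sum(edges$weight[edges$post_id == j & edges$pre_id %in% S])
      if (w == 0) return(0)
      min(1, (w / tot_in[[j]]) / cap)
    }, numeric(1))
  }
  memo <- new.env(parent = emptyenv())
  E <- function(S) {
    key <- paste(sort(S), collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    p <- p_of(S)
    cand <- ids[p > 0]
    res <- stats::setNames(rep(NA_real_, length(ids)), ids)
    res[S] <- 0
    if (length(cand) == 0) {
      memo[[key]] <- res
      return(res)
    }
    q <- prod(1 - p[cand])
    num <- stats::setNames(rep(1, length(ids)), ids)
    for (mask in seq_len(2^length(cand) - 1)) {
      Fset <- cand[bitwAnd(2^(seq_along(cand) - 1), mask) > 0]
      PF <- prod(p[Fset]) * prod(1 - p[setdiff(cand, Fset)])
      if (PF == 0) next
      Enext <- E(union(S, Fset))
      rest <- setdiff(ids, union(S, Fset))
      num[rest] <- num[rest] + PF * Enext[rest]
    }
    out <- num / (1 - q)
    out[S] <- 0
    out[setdiff(ids, reach)] <- NA_real_
    memo[[key]] <- out
    out
  }
  e <- E(seeds)
  steps <- 1 + e
  steps[seeds] <- 1
  steps
}

# Literal Holm-Sidak stepdown: walk the sorted p-values and test each
# against its Sidak level; stop at the first acceptance.
oracle_holm_sidak_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    level <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (p[o[i]] <= level) reject[o[i]] <- TRUE else break
  }
  reject
}

oracle_holm_sidak_adjusted <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(seq_len(i), function(j)
      1 - (1 - p[o[j]])^(m - j + 1), numeric(1))
    adj[o[i]] <- min(1, max(vals))
  }
  adj
}

# Plain-R row-shuffle null for one glomerulus pair's min-count
# co-occurrence sum (independent of the compiled kernel).
oracle_pair_shuffle_null <- function(mat, g1, g2, n_shuffles) {
  G <- nrow(mat)
  pairs <- utils::combn(G, 2)
  target <- which(pairs[1, ] == min(g1, g2) & pairs[2, ] == max(g1, g2))
  stat <- matrix(0, ncol(pairs), ncol(mat))
  for (k in seq_len(ncol(pairs)))
    stat[k, ] <- pmin(mat[pairs[1, k], ], mat[pairs[2, k], ])
  list(observed = sum(stat[target, ]),
       null = vapply(seq_len(n_shuffles), function(s) {
         tot <- 0
         for (j in seq_len(ncol(stat)))
           tot <- tot + stat[sample(nrow(stat)), j][target]
         tot
       }, numeric(1)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
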