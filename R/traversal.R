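# Probabilistic graph traversal: layers as the mean step at which a neuron
# is reached from a sensory seed pool, averaged over many stochastic runs.

#' Parameters of the traversal model
#'
#' @param cap input-fraction cap of the linear activation function: a
#'   neuron receiving `cap` (default 30%) or more of its total synaptic
#'   input from the current pool is traversed with probability 1.
#' @param n_runs number of stochastic runs to average (default 10,000 for
#'   global layer models; 5,000 per seed type is conventional for
#'   per-type distance analyses).
#' @param mode `"aggregate"` (one Bernoulli per candidate neuron per
#'   round, with probability driven by its pooled input fraction) or
#'   `"per_edge"` (each in-edge from the pool fires independently and the
#'   neuron joins if any does).
#' @param rng_seed optional integer seed.
#' @return List of class `"traversal_params"`.
#' @export
traversal_params <- function(cap = 0.3, n_runs = 10000,
                             mode = c("aggregate", "per_edge"),
                             rng_seed = NULL) {
  if (!is.numeric(cap) || cap <= 0 || cap > 1)
    stopf("'cap' must be in (0, 1]")
  n_runs <- check_count(n_runs, "n_runs", min = 1)
  structure(list(cap = cap, n_runs = n_runs, mode = match.arg(mode),
                 rng_seed = rng_seed),
            class = "traversal_params")
}

#' Linear activation probability of the traversal model
#'
#' The probability that a candidate neuron is traversed in a round is
#' linear in the fraction of its synaptic input arriving from the current
#' pool, saturating at 1 once that fraction reaches `cap`:
#' `min(1, fraction / cap)`. With the default cap of 0.30, a neuron
#' receiving 30% / 10% of its input from the pool has a 100% / 33.3%
#' chance of being traversed.
#'
#' @param fraction proportion of the neuron's total input weight supplied
#'   by the pool, in `[0, 1]`.
#' @param cap saturation fraction, in `(0, 1]` (default 0.30).
#' @return Probability in `[0, 1]`; vectorised over `fraction`.
#' @export
activation_probability <- function(fraction, cap = 0.3) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stopf("'fraction' must be in [0, 1]")
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0 || cap > 1)
    stopf("'cap' must be in (0, 1]")
  pmin(1, fraction / cap)
}

# internal: adjacency in index form + reachable set
traversal_prep <- function(graph, seeds) {
  stopifnot(inherits(graph, "connectome_graph"))
  ids <- graph$nodes$neuron_id
  if (length(seeds) == 0) stopf("seed set must not be empty")
  sidx <- match(seeds, ids)
  if (anyNA(sidx))
    stopf("seed neuron(s) not in graph: %s",
          paste(seeds[is.na(sidx)], collapse = ", "))
  e <- graph$edges
  pre <- match(e$pre_id, ids)
  post <- match(e$post_id, ids)
  out_t <- split(post, factor(pre, levels = seq_along(ids)))
  out_w <- split(as.numeric(e$weight), factor(pre, levels = seq_along(ids)))
  # BFS for the reachable set
  n <- length(ids)
  reach <- logical(n)
  reach[sidx] <- TRUE
  frontier <- sidx
  while (length(frontier) > 0) {
    nxt <- unique(unlist(out_t[frontier], use.names = FALSE))
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  list(ids = ids, n = n, seeds = sidx, out_t = out_t, out_w = out_w,
       tot_in = as.numeric(graph$total_in[ids]), reachable = reach)
}

traverse_once_prepped <- function(prep, cap, mode) {
  n <- prep$n
  step <- rep(NA_real_, n)
  step[prep$seeds] <- 1
  in_pool <- logical(n)
  in_pool[prep$seeds] <- TRUE
  remaining <- sum(prep$reachable) - length(prep$seeds)
  acc <- numeric(n)  # aggregate: pooled input weight; per_edge: log(1 - p)
  frontier <- prep$seeds
  r <- 1L
  while (remaining > 0) {
    for (v in frontier) {
      tg <- prep$out_t[[v]]
      if (length(tg) == 0) next
      if (mode == "aggregate") {
        acc[tg] <- acc[tg] + prep$out_w[[v]]
      } else {
        p_edge <- pmin(1, (prep$out_w[[v]] / prep$tot_in[tg]) / cap)
        acc[tg] <- acc[tg] + log1p(-pmin(p_edge, 1 - 1e-15)) -
          ifelse(p_edge >= 1, Inf, 0)
      }
    }
    cand <- which(!in_pool & acc != 0)
    p <- if (mode == "aggregate")
      pmin(1, (acc[cand] / prep$tot_in[cand]) / cap)
    else 1 - exp(acc[cand])
    fired <- cand[runif(length(cand)) < p]
    r <- r + 1L
    if (length(fired) > 0) {
      step[fired] <- r
      in_pool[fired] <- TRUE
      remaining <- remaining - length(fired)
      acc[fired] <- 0
    }
    frontier <- fired
  }
  stats::setNames(step, prep$ids)
}

#' One stochastic traversal of the graph
#'
#' Seeds are recorded at step 1. Rounds are synchronous: in round r each
#' not-yet-traversed neuron is tested against the pool as of round r - 1
#' and, if successful, receives step r + 1 and joins the pool. The loop
#' runs until the set of neurons reachable from the seeds is exhausted
#' (every reachable candidate has per-round probability > 0, so the walk
#' terminates with probability one); unreachable neurons keep a missing
#' step.
#'
#' @param graph a [build_graph()] result.
#' @param seeds character vector of seed neuron ids (non-empty).
#' @param params a [traversal_params()].
#' @return Named numeric vector of step indices (NA = unreachable).
#' @export
traverse_once <- function(graph, seeds, params = traversal_params()) {
  prep <- traversal_prep(graph, seeds)
  with_seed(params$rng_seed,
            traverse_once_prepped(prep, params$cap, params$mode))
}

#' Assign layers by repeated probabilistic traversal
#'
#' Runs [traverse_once()] `n_runs` times and reports, per neuron, the mean
#' and standard deviation of the step at which it was reached, counting
#' only runs in which it was reached, together with the reach frequency.
#' Seeds therefore have mean step exactly 1 and every reachable non-seed
#' neuron a mean step > 1.
#'
#' @inheritParams traverse_once
#' @return Object of class `"layer_result"`: list with `layers` (data
#'   frame: `neuron_id`, `mean_step`, `sd_step`, `reach_freq`), `n_runs`,
#'   `seed_ids`, `params`.
#' @export
run_traversal <- function(graph, seeds, params = traversal_params()) {
  prep <- traversal_prep(graph, seeds)
  n <- prep$n
  s1 <- numeric(n); s2 <- numeric(n); cnt <- integer(n)
  with_seed(params$rng_seed, {
    for (run in seq_len(params$n_runs)) {
      st <- traverse_once_prepped(prep, params$cap, params$mode)
      hit <- !is.na(st)
      s1[hit] <- s1[hit] + st[hit]
      s2[hit] <- s2[hit] + st[hit]^2
      cnt[hit] <- cnt[hit] + 1L
    }
  })
  mean_step <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  var_step <- ifelse(cnt > 1, pmax(0, (s2 - s1^2 / cnt) / (cnt - 1)), NA_real_)
  res <- data.frame(neuron_id = prep$ids,
                    mean_step = mean_step,
                    sd_step = sqrt(var_step),
                    reach_freq = cnt / params$n_runs,
                    stringsAsFactors = FALSE)
  structure(list(layers = res, n_runs = params$n_runs,
                 seed_ids = prep$ids[prep$seeds], params = params),
            class = "layer_result")
}

#' @export
print.layer_result <- function(x, ...) {
  cat(sprintf("layer result: %d neurons, %d seeds, %d runs (cap %.2f, %s)\n",
              nrow(x$layers), length(x$seed_ids), x$n_runs, x$params$cap,
              x$params$mode))
  invisible(x)
}

#' Per-seed-type traversal distances
#'
#' Re-runs the traversal model once per seed group (e.g. the receptor
#' neurons of one glomerulus) and collects each neuron's mean step from
#' that group, yielding a neurons-by-seed-types distance matrix. Each
#' group draws an independent child RNG stream so columns do not depend
#' on the order of the groups.
#'
#' @param graph a [build_graph()] result.
#' @param seed_groups named list mapping seed type to a non-empty vector
#'   of seed neuron ids.
#' @param params a [traversal_params()]; 5,000 runs per type is the
#'   conventional setting.
#' @return Numeric matrix, rows = neurons, columns = seed types; entries
#'   are mean steps (>= 1) or NA when unreachable from that group.
#' @export
per_type_distances <- function(graph, seed_groups,
                               params = traversal_params(n_runs = 5000)) {
  if (is.null(names(seed_groups)) || any(names(seed_groups) == ""))
    stopf("'seed_groups' must be a named list")
  for (nm in names(seed_groups))
    if (length(seed_groups[[nm]]) == 0)
      stopf("seed group '%s' is empty", nm)
  cols <- lapply(seq_along(seed_groups), function(i) {
    p <- params
    if (!is.null(params$rng_seed))
      p$rng_seed <- derive_seed(params$rng_seed, names(seed_groups)[i])
    run_traversal(graph, seed_groups[[i]], p)$layers$mean_step
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(graph$nodes$neuron_id, names(seed_groups))
  m
}

#' Lifetime kurtosis (sparseness)
#'
#' Excess kurtosis computed with population moments,
#' `mean(((v - mean) / sd)^4) - 3`; standard-normal data give about 0 and
#' a vector dominated by a single large entry gives a large positive
#' value. Used as a sparseness measure of a neuron's vector of distances
#' to the different receptor-neuron types: high kurtosis means the neuron
#' is close to only a few seed types (sparse tuning).
#'
#' @param values numeric vector, length >= 2 and non-constant.
#' @return Excess kurtosis (scalar).
#' @export
lifetime_kurtosis <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stopf("need at least 2 finite values")
  m <- mean(values)
  v <- mean((values - m)^2)
  if (v == 0) stopf("zero variance: sparseness undefined for a constant vector")
  mean(((values - m) / sqrt(v))^4) - 3
}

#' Early-neuron call from a mean layer
#'
#' A neuron is called "early" when its mean layer, rounded to the nearest
#' integer, falls inside the window (default layers 3-4, the early
#' descending-neuron band). Rounding follows R's `round()` (ties to
#' even, so 4.5 rounds to 4 and is early under the default window);
#' missing layers are never early.
#'
#' @param layer numeric vector of mean layers (NA allowed).
#' @param window inclusive integer window `c(low, high)`.
#' @return Logical vector.
#' @export
classify_early <- function(layer, window = c(3, 4)) {
  r <- round(layer)
  out <- !is.na(r) & r >= window[1] & r <= window[2]
  out
}
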