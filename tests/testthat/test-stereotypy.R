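test_that("dotprops of a straight segment have collinear tangents and contracted spacing", {
  dp <- make_dotprops(straight_swc(10, 0.25), resample_step = 1)
  axis <- c(1, 0, 0)
  expect_true(all(abs(dp$points[, 2:3]) < 1e-9))
  expect_true(all(abs(dp$tangents %*% axis) > 0.999))
  expect_true(all(abs(sqrt(rowSums(dp$tangents^2)) - 1) < 1e-6))
  # consecutive spacing of the resampled chain stays near the step size
  o <- order(dp$points[, 1])
  gaps <- diff(dp$points[o, 1])
  expect_gte(mean(gaps >= 0.5 & gaps <= 1.5), 0.99)
})

test_that("short terminal twigs are pruned before resampling", {
  trunk <- straight_swc(10, 0.5)
  n <- nrow(trunk)
  # a 1 um twig hanging off the middle of the trunk, pointing up
  twig <- data.frame(id = n + 1:2, type = 2L,
                     x = trunk$x[10], y = c(500, 1000), z = 0,
                     radius = 50, parent = c(trunk$id[10], n + 1L))
  skel <- rbind(trunk, twig)
  dp <- make_dotprops(skel, twig_prune = 2)
  expect_true(all(dp$points[, 2] < 0.4))  # twig nodes (y up to 1 um) gone
  dp2 <- make_dotprops(skel, twig_prune = 0.5)
  expect_gt(max(dp2$points[, 2]), 0.9)    # kept when the threshold shrinks
  expect_error(make_dotprops(straight_swc(2, 1), k = 5, twig_prune = 0),
               "k \\+ 1")
})

test_that("similarity scoring is self-normalised, decays with distance and tolerates jitter", {
  set.seed(2)
  sk <- straight_swc(20, 0.5)
  dp <- make_dotprops(sk)
  expect_equal(similarity_score(dp, dp), 1.0)
  far <- make_dotprops(translate_swc(sk, c(0, 1e5, 0)))  # 100 um away
  expect_lt(similarity_score(dp, far), 0.01)
  jit <- sk
  jit[, c("x", "y", "z")] <- jit[, c("x", "y", "z")] +
    matrix(rnorm(nrow(sk) * 3, sd = 500), nrow(sk), 3)  # 0.5 um jitter
  expect_gt(similarity_score(dp, make_dotprops(jit)), 0.8)
  expect_error(similarity_score(dp, structure(list(points = matrix(0, 0, 3),
                                                   tangents = matrix(0, 0, 3)),
                                              class = "dotprops")), "empty")
})

test_that("the pair similarity matrix is symmetric with unit diagonal", {
  sc <- synth_config(n_cell_types = 3, cells_per_type = 2, rng_seed = 12)
  sk <- generate_skeletons(sc)
  sm <- similarity_matrix(lapply(sk$skeletons[1:6], make_dotprops))
  expect_equal(sm, t(sm))
  expect_equal(unname(diag(sm)), rep(1, 6))
})

test_that("reciprocal best matches become pair clusters", {
  ids <- c("a1", "a2", "b1", "b2")
  sm <- diag(1, 4)
  dimnames(sm) <- list(ids, ids)
  sm["a1", "b1"] <- sm["b1", "a1"] <- 0.9
  sm["a2", "b2"] <- sm["b2", "a2"] <- 0.85
  sm["a1", "b2"] <- sm["b2", "a1"] <- 0.1
  sm["a2", "b1"] <- sm["b1", "a2"] <- 0.1
  cl <- top_match_clusters(sm, c("A", "A", "B", "B"))
  expect_equal(cl$membership[["a1"]], cl$membership[["b1"]])
  expect_equal(cl$membership[["a2"]], cl$membership[["b2"]])
  expect_false(cl$membership[["a1"]] == cl$membership[["a2"]])
  expect_error(top_match_clusters(sm, rep("A", 4)), "2 datasets")
})

test_that("a pathological bridge entity merges two types and refinement splits them again", {
  # two types (x*, y*) with high within-type scores, bridged by 'px'
  # whose best matches straddle both
  ids <- c("x1", "x2", "y1", "y2", "px")
  ds <- c("A", "B", "A", "B", "A")
  sm <- diag(1, 5)
  dimnames(sm) <- list(ids, ids)
  set_pair <- function(i, j, v) sm[i, j] <<- sm[j, i] <<- v
  set_pair("x1", "x2", 0.9)
  set_pair("y1", "y2", 0.9)
  set_pair("x1", "y1", 0.05); set_pair("x1", "y2", 0.05)
  set_pair("x2", "y1", 0.05); set_pair("x2", "y2", 0.05)
  set_pair("px", "x1", 0.5)
  # px is x2's best A-side match and px's own best B-side match is y2,
  # so the top-match graph chains both types into one component
  set_pair("px", "x2", 0.95)
  set_pair("px", "y1", 0.3); set_pair("px", "y2", 0.97)
  cl <- top_match_clusters(sm, ds)
  expect_equal(length(unique(cl$membership)), 1)
  memb <- refine_clusters(cl, sm, min_score = 0.4)
  # the worst-pair floor now holds in every refined cluster
  for (grp in split(ids, memb)) {
    if (length(grp) > 1) {
      sub <- sm[grp, grp]
      expect_gte(min(sub[upper.tri(sub)]), 0.4)
    }
  }
  # no refined cluster mixes the two planted types; the x block survives
  # with the bridge attached to its strong side
  for (grp in split(setdiff(ids, "px"), memb[setdiff(ids, "px")]))
    expect_lte(length(unique(substr(grp, 1, 1))), 1)
  expect_equal(memb[["x1"]], memb[["x2"]])
})

test_that("refinement leaves compliant clusters alone and passes singletons through", {
  ids <- c("a", "b", "c")
  sm <- matrix(0.8, 3, 3, dimnames = list(ids, ids))
  diag(sm) <- 1
  memb <- stats::setNames(c(1L, 1L, 1L), ids)
  expect_equal(unname(unique(refine_clusters(memb, sm, 0.4))), 1L)
  single <- stats::setNames(1L, "a")
  expect_length(refine_clusters(single, sm["a", "a", drop = FALSE], 0.4), 1)
})

test_that("connectivity cosine handles signing, scaling and zero profiles", {
  conn <- rbind(src1 = c(1, 2, 0), src2 = c(2, 4, 0))
  cs <- connectivity_cosine(conn)
  expect_equal(cs["src1", "src2"], 1)  # scale invariance
  # identical absolute profiles, opposite transmitters
  cs2 <- connectivity_cosine(conn,
                             transmitters = c(src1 = "acetylcholine",
                                              src2 = "GABA"))
  expect_equal(cs2["src1", "src2"], -1)
  conn0 <- rbind(a = c(1, 1), zero = c(0, 0))
  cs3 <- connectivity_cosine(conn0)
  expect_true(all(is.na(cs3["zero", ])))
  expect_error(connectivity_cosine(rbind(c(-1, 0))), "non-negative")
})

test_that("sister pairs beat shuffled-label pairs on planted type structure", {
  set.seed(21)
  # 4 source types x 3 members; targets belong to 6 types x 4 cells;
  # each source type connects to two preferred target types
  src_types <- rep(paste0("S", 1:4), each = 3)
  tgt_types <- rep(paste0("T", 1:6), each = 4)
  conn <- matrix(rpois(12 * 24, 0.5), 12, 24)
  for (i in seq_along(src_types)) {
    pref <- (as.integer(sub("S", "", src_types[i])) - 1) %% 6 + 1
    cols <- which(tgt_types %in% paste0("T", c(pref, pref %% 6 + 1)))
    conn[i, cols] <- conn[i, cols] + rpois(length(cols), 12)
  }
  res <- sister_comparison(conn, src_types, tgt_types, pool_by = "type",
                           n_label_shuffles = 40, rng_seed = 4)
  expect_gt(median(res$sister), median(res$shuffled))
  expect_gt(median(res$sister), median(res$non_sister))
  # pooling by type does not reduce the sister similarity on this fixture
  res_cell <- sister_comparison(conn, src_types, tgt_types,
                                pool_by = "cell", n_label_shuffles = 2,
                                rng_seed = 4)
  expect_gte(median(res$sister), median(res_cell$sister))
})

test_that("a lone source yields no sister pairs and a warning", {
  conn <- matrix(rpois(8, 3), 2, 4)
  expect_warning(
    res <- sister_comparison(conn, c("S1", "S2"), rep("T1", 4),
                             n_label_shuffles = 2, rng_seed = 1),
    "no sister")
  expect_length(res$sister, 0)
})
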