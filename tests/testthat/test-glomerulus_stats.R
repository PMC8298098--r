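test_that("cumulative rank curves match hand-computed normalisations", {
  # counts (10, 5, 1): sorted, min-max normalised to (1, 4/9, 0)
  m <- matrix(c(5, 10, 1), ncol = 1,
              dimnames = list(paste0("g", 1:3), "n1"))
  expect_equal(unname(cumulative_rank_curves(m)[, 1]),
               c(1, 1 + 4 / 9, 1 + 4 / 9))
  # single innervated glomerulus: plateau from rank 1 on
  m2 <- matrix(c(7, 0, 0, 0), ncol = 1)
  expect_equal(unname(cumulative_rank_curves(m2)[, 1]), c(1, 1, 1, 1))
  # uniform counts collapse to the all-zero curve (documented degeneracy)
  m3 <- matrix(c(4, 4, 4), ncol = 1)
  expect_equal(unname(cumulative_rank_curves(m3)[, 1]), c(0, 0, 0))
  expect_warning(cumulative_rank_curves(cbind(m2, 0)), "all-zero")
  expect_true(all(apply(cumulative_rank_curves(
    matrix(rpois(50, 5), 10, 5) + 1), 2, function(x) all(diff(x) >= 0))))
})

test_that("Holm-Sidak adjustment matches hand-computed and degenerate cases", {
  expect_equal(holm_sidak(rep(1, 5))$reject, rep(FALSE, 5))
  one <- holm_sidak(0.01)
  expect_equal(one$adjusted, 0.01)
  expect_true(one$reject)
  # frozen stepdown example: adj = (1-(1-p1)^3, 1-(1-p2)^2, 1-(1-p3)^1)
  hs <- holm_sidak(c(0.001, 0.02, 0.04))
  expect_equal(hs$adjusted, c(0.002997001, 0.0396, 0.04), tolerance = 1e-9)
  expect_true(all(hs$reject))
})

test_that("Holm-Sidak equals the brute-force stepdown oracle for m <= 4", {
  set.seed(11)
  for (m in 1:4) {
    for (rep in 1:40) {
      p <- round(runif(m), 3)
      got <- holm_sidak(p, alpha = 0.05)
      expect_equal(got$reject, oracle_holm_sidak_reject(p, 0.05))
      expect_equal(got$adjusted, oracle_holm_sidak_adjusted(p),
                   tolerance = 1e-12)
      # corrected rejections are a subset of unadjusted ones
      expect_true(all(p[got$reject] <= 0.05))
      # adjusted p monotone along the sorted order
      expect_true(all(diff(got$adjusted[order(p)]) >= -1e-12))
    }
  }
})

test_that("pair enumeration and degenerate innervation matrices behave", {
  m <- matrix(1L, 39, 5)
  res <- coinnervation_test(m, n_shuffles = 5, rng_seed = 1)
  expect_equal(nrow(res), choose(39, 2))
  expect_equal(nrow(res), 741)
  # two glomeruli: exactly one pair
  expect_equal(nrow(coinnervation_test(matrix(1L, 2, 4), n_shuffles = 5,
                                       rng_seed = 1)), 1)
  # every neuron in exactly one glomerulus: all statistics zero
  one <- matrix(0L, 5, 10)
  one[cbind(rep(1:5, 2), 1:10)] <- 7L
  res1 <- coinnervation_test(one, n_shuffles = 50, rng_seed = 2)
  expect_true(all(res1$observed == 0))
  expect_false(any(res1$significant))
  expect_error(coinnervation_test(matrix(1, 1, 3)), "2 glomeruli")
  expect_error(coinnervation_test(matrix(1, 3, 3), n_shuffles = 0),
               "n_shuffles")
})

test_that("the compiled shuffle null agrees with a plain-R oracle", {
  sc <- synth_config(rng_seed = 17, n_glomeruli = 6,
                     n_neurons_innervation = 15,
                     planted_coinnervation_pairs = list(c(1, 2, 10)))
  m <- generate_innervation_matrix(sc)
  res <- coinnervation_test(m, n_shuffles = 4000, rng_seed = 3)
  set.seed(99)
  orc <- oracle_pair_shuffle_null(m, 1, 2, 4000)
  row <- which(res$glom1 == "G01" & res$glom2 == "G02")
  expect_equal(res$observed[row], orc$observed)
  p_oracle <- mean(orc$null >= orc$observed)
  expect_lt(abs(res$p_raw[row] - p_oracle), 0.02)
})

test_that("null p-values are close to uniform under row shuffling", {
  set.seed(5)
  pooled <- unlist(lapply(1:15, function(r) {
    sc <- synth_config(rng_seed = 7000 + r, n_glomeruli = 8,
                       n_neurons_innervation = 25)
    m <- generate_innervation_matrix(sc)
    coinnervation_test(m, n_shuffles = 400,
                       rng_seed = 7100 + r)$p_raw
  }))
  # one-sided: reject only if p-values are anti-conservative (too small);
  # ties in the discrete null make them super-uniform, which is valid
  ks <- suppressWarnings(stats::ks.test(pooled, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("input-output segregation profiles follow the hand-worked cases", {
  pre <- matrix(c(2, 8), 2, 1, dimnames = list(c("g1", "g2"), "n1"))
  post <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "n1"))
  prof <- input_output_segregation(pre, post)$all
  expect_equal(unname(prof), c(8, -8))
  expect_equal(names(prof), c("+1", "-1"))
  # pre == post: all differences zero
  expect_true(all(input_output_segregation(post, post)$all == 0))
  # post only: all differences positive
  expect_true(all(input_output_segregation(post * 0, post)$all > 0))
  expect_error(input_output_segregation(pre, matrix(0, 3, 1)), "shape")
})

test_that("the bottom-share tail of ranked glomeruli is pruned", {
  pre <- matrix(c(50, 45, 2, 3), 4, 1,
                dimnames = list(paste0("g", 1:4), "n"))
  post <- matrix(0, 4, 1, dimnames = dimnames(pre))
  # total 100; trailing g3+g4 hold 5% <= prune_frac, both dropped
  prof <- input_output_segregation(pre, post, prune_frac = 0.05)$all
  expect_length(prof, 2)
  expect_equal(unname(prof), c(-45, -50))
})

test_that("intra-glomerular distance recovers a pure translation and applies the cable gate", {
  a <- dense_arbour_swc()
  # against an identical copy the k-neighbourhood spans at most a few
  # sampling steps (0.25 um spacing), so the score collapses towards 0
  expect_lt(intraglomerular_distance(a, a)$distance, 0.75)
  b <- translate_swc(a, c(2000, 0, 0))  # 2 um shift
  d <- intraglomerular_distance(a, b)
  expect_false(d$excluded)
  expect_gte(d$distance, 1.8)
  expect_lte(d$distance, 2.2)
  # symmetry of the pooled construction
  expect_equal(intraglomerular_distance(b, a)$distance, d$distance)
  # a 50 um arbour is excluded by the 80 um cable rule
  short <- straight_swc(length_um = 50)
  res <- intraglomerular_distance(short, translate_swc(short, c(0, 2000, 0)))
  expect_true(res$excluded)
  expect_true(is.na(res$distance))
  expect_lt(res$cable[1], 80)
})

test_that("region clipping restricts the cable before the gate", {
  a <- dense_arbour_swc()  # 120 um of cable in total
  region <- list(min = c(-Inf, -Inf, -Inf), max = c(10000, Inf, Inf))
  res <- intraglomerular_distance(a, translate_swc(a, c(500, 0, 0)),
                                  region = region)
  expect_true(res$excluded)  # only a fraction of the arbour is inside
})

test_that("voxel labelling separates two distant clouds and partitions the grid", {
  set.seed(8)
  sd_nm <- 1500
  c1 <- c(0, 0, 0); c2 <- c(30 * sd_nm, 0, 0)  # 30 sd apart
  pts <- list(a = sweep(matrix(rnorm(600, 0, sd_nm), ncol = 3), 2, c1, "+"),
              b = sweep(matrix(rnorm(600, 0, sd_nm), ncol = 3), 2, c2, "+"))
  vm <- glomerulus_voxel_map(pts)
  expect_s3_class(vm, "voxel_label_grid")
  # each voxel carries at most one label by construction of the array;
  # check both labels exist and are disjoint components of the grid
  expect_setequal(setdiff(unique(as.integer(vm$labels)), 0L), c(1L, 2L))
  # voxels within 1 sd of each centroid carry that cloud's label
  near_label <- function(center, want) {
    dims <- dim(vm$labels)
    centers <- lapply(1:3, function(d)
      vm$origin[d] + (seq_len(dims[d]) - 0.5) * vm$voxel_size)
    grid <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
    near <- which(sqrt(colSums((t(grid) - center)^2)) < sd_nm)
    mean(vm$labels[near] == want)
  }
  expect_gte(near_label(c1, 1L), 0.95)
  expect_gte(near_label(c2, 2L), 0.95)
})

test_that("single clouds, degenerate thresholds and bad inputs are handled", {
  set.seed(9)
  one <- list(only = matrix(rnorm(450, 0, 1000), ncol = 3))
  vm <- glomerulus_voxel_map(one)
  expect_setequal(setdiff(unique(as.integer(vm$labels)), 0L), 1L)
  expect_warning(vm2 <- glomerulus_voxel_map(one, pdf_threshold = Inf),
                 "empty")
  expect_true(all(vm2$labels == 0L))
  expect_error(glomerulus_voxel_map(list(g = matrix(0, 0, 3))), "empty point")
  expect_error(glomerulus_voxel_map(list(g = matrix(rnorm(9), 3, 3))),
               "fewer than 10")
})

test_that("erosion never adds voxels and the OBJ export writes a surface", {
  set.seed(10)
  pts <- list(a = matrix(rnorm(600, 0, 1200), ncol = 3))
  vm0 <- glomerulus_voxel_map(pts, erosion_iters = 0)
  vm1 <- glomerulus_voxel_map(pts, erosion_iters = 1)
  expect_lte(sum(vm1$labels == 1), sum(vm0$labels == 1))
  f <- withr::local_tempfile(fileext = ".obj")
  write_voxel_obj(vm1, "a", f)
  lines <- readLines(f)
  expect_gt(sum(startsWith(lines, "v ")), 0)
  expect_gt(sum(startsWith(lines, "f ")), 0)
})
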