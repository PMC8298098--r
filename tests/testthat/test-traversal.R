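test_that("activation probability reproduces the linear-with-cap rule", {
  expect_equal(activation_probability(0.30, 0.30), 1.0)
  expect_equal(activation_probability(0.10, 0.30), 1 / 3)
  expect_equal(activation_probability(0, 0.30), 0)
  expect_equal(activation_probability(0.02, 0.30), 0.02 / 0.30)
  # monotone non-decreasing in the input fraction
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(activation_probability(f, 0.3)) >= 0))
  expect_error(activation_probability(1.2), "fraction")
  expect_error(activation_probability(0.5, 0), "cap")
})

test_that("a fully saturated chain is traversed deterministically", {
  g <- graph_fixture(edge_df("s", "a", 10, "a", "b", 10))
  st <- traverse_once(g, "s", traversal_params(rng_seed = 1))
  expect_equal(st[c("s", "a", "b")], c(s = 1, a = 2, b = 3))
  lr <- run_traversal(g, "s", traversal_params(n_runs = 25, rng_seed = 1))
  expect_equal(lr$layers$mean_step[match(c("s", "a", "b"),
                                         lr$layers$neuron_id)],
               c(1, 2, 3))
  expect_true(all(lr$layers$reach_freq == 1))
})

test_that("unreachable neurons keep a missing step and empty seeds error", {
  g <- graph_fixture(edge_df("s", "a", 10, "x", "b", 10))
  st <- traverse_once(g, "s", traversal_params(rng_seed = 1))
  expect_true(is.na(st[["x"]]))  # no in-edges and not a seed
  expect_true(is.na(st[["b"]]))  # only reachable from x
  expect_error(traverse_once(g, character(0)), "seed")
  expect_error(traverse_once(g, "nope"), "nope")
})

test_that("a single run equals traverse_once under the same stream", {
  fx <- tiny_traversal_fixtures()$deep
  g <- graph_fixture(fx$edges)
  p <- traversal_params(cap = fx$cap, n_runs = 1, rng_seed = 42)
  lr <- run_traversal(g, fx$seeds, p)
  st <- traverse_once(g, fx$seeds, p)
  expect_equal(lr$layers$mean_step, unname(st[lr$layers$neuron_id]))
})

test_that("Monte-Carlo mean steps match the exact enumeration on a small probabilistic graph", {
  fx <- tiny_traversal_fixtures()$half_edge
  g <- graph_fixture(fx$edges)
  exact <- enum_mean_steps(fx$edges, g$nodes$neuron_id, fx$seeds, fx$cap)
  lr <- run_traversal(g, fx$seeds,
                      traversal_params(cap = fx$cap, n_runs = 4000,
                                       rng_seed = 9))
  for (i in seq_len(nrow(lr$layers))) {
    id <- lr$layers$neuron_id[i]
    if (is.na(exact[[id]])) {
      expect_true(is.na(lr$layers$mean_step[i]))
    } else {
      se <- lr$layers$sd_step[i] / sqrt(4000)
      if (is.na(se) || se == 0) {
        expect_equal(lr$layers$mean_step[i], exact[[id]])
      } else {
        expect_lt(abs(lr$layers$mean_step[i] - exact[[id]]), 3 * se)
      }
    }
  }
})

test_that("raising the cap never lowers an expected step (exact expectations)", {
  for (fx in tiny_traversal_fixtures()) {
    ids <- unique(c(fx$edges$pre_id, fx$edges$post_id))
    e1 <- enum_mean_steps(fx$edges, ids, fx$seeds, 0.2)
    e2 <- enum_mean_steps(fx$edges, ids, fx$seeds, 0.35)
    e3 <- enum_mean_steps(fx$edges, ids, fx$seeds, 0.5)
    ok <- !is.na(e1)
    expect_true(all(e2[ok] >= e1[ok] - 1e-12))
    expect_true(all(e3[ok] >= e2[ok] - 1e-12))
  }
})

test_that("per-edge mode agrees with aggregate mode on saturated graphs and differs in general", {
  g <- graph_fixture(edge_df("s", "a", 10, "a", "b", 10))
  st <- traverse_once(g, "s", traversal_params(mode = "per_edge",
                                               rng_seed = 3))
  expect_equal(st[c("s", "a", "b")], c(s = 1, a = 2, b = 3))
  # two weak edges: aggregate pools them, per-edge tests them separately
  fx <- edge_df("s1", "t", 3, "s2", "t", 3, "x", "t", 14)
  g2 <- graph_fixture(fx)
  agg <- run_traversal(g2, c("s1", "s2"),
                       traversal_params(n_runs = 2000, rng_seed = 5))
  pe <- run_traversal(g2, c("s1", "s2"),
                      traversal_params(n_runs = 2000, mode = "per_edge",
                                       rng_seed = 5))
  # aggregate: p = 6/20/0.3 = 1; per edge: 1 - (1 - 0.5)^2 = 0.75 < 1
  expect_equal(agg$layers$mean_step[agg$layers$neuron_id == "t"], 2)
  expect_gt(pe$layers$mean_step[pe$layers$neuron_id == "t"], 2)
})

test_that("per-type distances: one group equals the global result; disjoint lines stay apart", {
  g <- graph_fixture(edge_df("s", "a", 10, "a", "b", 10))
  d <- per_type_distances(g, list(all = "s"),
                          params = traversal_params(n_runs = 10,
                                                    rng_seed = 2))
  lr <- run_traversal(g, "s", traversal_params(n_runs = 10, rng_seed = 2))
  expect_equal(unname(d[, "all"]), lr$layers$mean_step)

  # two disjoint feedforward lines
  g2 <- graph_fixture(edge_df("s1", "a1", 10, "s2", "a2", 10))
  d2 <- per_type_distances(g2, list(L = "s1", R = "s2"),
                           params = traversal_params(n_runs = 10,
                                                     rng_seed = 2))
  expect_true(is.na(d2["a1", "R"]) && is.na(d2["a2", "L"]))
  expect_equal(d2["a1", "L"], 2)
  expect_error(per_type_distances(g2, list(L = character())), "L")
})

test_that("a labelled line is closest to its own seed type", {
  # t's input is dominated by the private line from sx; sy reaches t only
  # through a weak indirect edge
  e <- edge_df("sx", "t", 100, "sy", "a", 100, "a", "t", 10)
  g <- graph_fixture(e)
  d <- per_type_distances(g, list(X = "sx", Y = "sy"),
                          params = traversal_params(n_runs = 400,
                                                    rng_seed = 6))
  expect_lt(d["t", "X"], d["t", "Y"])
})

test_that("lifetime kurtosis follows the population-moment formula", {
  set.seed(1)
  expect_lt(abs(lifetime_kurtosis(rnorm(10000))), 0.15)
  # frozen from an independent evaluation of the moment formula
  expect_equal(lifetime_kurtosis(c(1, rep(0, 49))), 45.0204081632653,
               tolerance = 1e-10)
  expect_error(lifetime_kurtosis(rep(2, 10)), "variance")
  expect_error(lifetime_kurtosis(3), "2 finite values")
})

test_that("early-neuron calls round to the window with documented tie handling", {
  expect_true(classify_early(3.4))
  expect_false(classify_early(5.6))
  expect_true(classify_early(4.5))   # ties round to even: 4.5 -> 4
  expect_false(classify_early(NA))
  expect_equal(classify_early(c(2.4, 3.0, 4.49, 6)),
               c(FALSE, TRUE, TRUE, FALSE))
})
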