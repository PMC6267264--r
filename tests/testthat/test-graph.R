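# Graph metrics, null models, modularity detection, density thresholding.

test_that("clustering coefficient matches hand-enumerated triangle counts", {
  expect_equal(clustering_coefficient(complete_graph(3))$mean, 1)
  star <- named_adj(rbind(c(0, 1, 1, 1, 1),
                          c(1, 0, 0, 0, 0),
                          c(1, 0, 0, 0, 0),
                          c(1, 0, 0, 0, 0),
                          c(1, 0, 0, 0, 0)))
  expect_equal(clustering_coefficient(star)$mean, 0)
  k4e <- complete_graph(4)
  k4e[3, 4] <- k4e[4, 3] <- 0  # K4 minus one edge: per-node c = 2/3,2/3,1,1
  expect_equal(clustering_coefficient(k4e)$mean, 5 / 6)
  expect_error(clustering_coefficient(named_adj(matrix(c(0, -1, -1, 0), 2))),
               "nonnegative")
})

test_that("weighted clustering is scale-invariant and bounded", {
  set.seed(7)
  w <- matrix(0, 6, 6)
  w[upper.tri(w)] <- runif(15) * (runif(15) < 0.7)
  w <- named_adj(w + t(w))
  cw <- clustering_coefficient(w, "weighted")
  expect_true(all(cw$node >= 0 & cw$node <= 1))
  # Onnela normalization by max weight makes the measure scale-invariant
  expect_equal(clustering_coefficient(w * 3.7, "weighted")$mean, cw$mean)
  # on a binary matrix the weighted form reduces to the binary form
  b <- (w > 0.3) + 0
  expect_equal(clustering_coefficient(b, "weighted")$mean,
               clustering_coefficient(b, "binary")$mean)
})

test_that("path length and efficiency match enumerated distances", {
  path3 <- named_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(complete_graph(5))), 1)
  expect_equal(global_efficiency(complete_graph(3)), 1)
  # two disjoint edges: 2 connected pairs at distance 1, 4 pairs excluded
  disj <- matrix(0, 4, 4)
  disj[1, 2] <- disj[2, 1] <- disj[3, 4] <- disj[4, 3] <- 1
  disj <- named_adj(disj)
  expect_warning(l <- characteristic_path_length(disj), "4 disconnected")
  expect_equal(as.numeric(l), 1)
  expect_equal(attr(l, "excluded_pairs"), 4)
  edgeless <- named_adj(matrix(0, 3, 3))
  expect_error(characteristic_path_length(edgeless), "no edges")
  expect_equal(global_efficiency(edgeless), 0)
  # weighted: lengths are 1/weight
  wp <- named_adj(rbind(c(0, 2, 0), c(2, 0, 4), c(0, 4, 0)))
  expect_equal(as.numeric(characteristic_path_length(wp, "weighted")),
               mean(c(1 / 2, 1 / 4, 3 / 4)))
})

test_that("rewired nulls preserve the degree sequence exactly", {
  g <- er_graph(20, 0.3, seed = 101)
  ens <- rewire_null(g, n = 20, seed = 5)
  expect_length(ens$graphs, 20)
  for (m in ens$graphs) {
    expect_identical(rowSums(m), rowSums(g))
    expect_identical(m, t(m))
  }
  expect_false(all(vapply(ens$graphs, identical, TRUE, g)))  # actually rewired
  expect_warning(full <- rewire_null(complete_graph(4), n = 3, seed = 1),
                 "no rewirable")
  expect_true(all(vapply(full$graphs, identical, TRUE, complete_graph(4))))
  expect_identical(rewire_null(g, n = 5, seed = 9), rewire_null(g, n = 5, seed = 9))
})

test_that("rewiring destroys lattice clustering", {
  rl <- ring_lattice(20, 4)
  c_obs <- clustering_coefficient(rl)$mean
  ens <- rewire_null(rl, n = 20, seed = 3)
  c_null <- vapply(ens$graphs, function(m) clustering_coefficient(m)$mean, 0)
  expect_gte(sum(c_null < c_obs), 19)
})

test_that("small-worldness ratios behave at the identity and lattice limits", {
  rl <- ring_lattice(20, 4)
  self <- structure(list(graphs = list(rl), n = 1, seed = 0), class = "null_ensemble")
  sw_self <- small_worldness(rl, self)
  expect_equal(sw_self$gamma, 1)
  expect_equal(sw_self$lambda, 1)
  expect_equal(sw_self$sigma, 1)
  sw <- small_worldness(rl, rewire_null(rl, n = 20, seed = 4))
  expect_gt(sw$gamma, 1)
  expect_gt(sw$sigma, 1)
})

test_that("random graphs are not small-world against their rewired ensembles", {
  sigmas <- vapply(1:50, function(s) {
    g <- er_graph(20, 0.3, seed = 200 + s)
    small_worldness(g, rewire_null(g, n = 5, seed = s))$sigma
  }, 0)
  expect_lt(abs(mean(sigmas) - 1), 0.2)
})

test_that("module detection recovers exact optima on canonical graphs", {
  p <- detect_modules(two_cliques(3), n_iter = 50, seed = 1)
  expect_equal(p$q, 0.5)
  expect_equal(p$n_modules, 2)
  expect_equal(unname(p$assignment[1:3]), rep(p$assignment[[1]], 3))
  expect_equal(unname(p$assignment[4:6]), rep(p$assignment[[4]], 3))

  k5 <- detect_modules(complete_graph(5), n_iter = 20, seed = 1)
  expect_equal(k5$q, 0)
  expect_equal(k5$n_modules, 1)

  bridged <- detect_modules(two_cliques(3, bridge = TRUE), n_iter = 50, seed = 1)
  expect_equal(bridged$n_modules, 2)
  expect_equal(length(unique(bridged$assignment[1:3])), 1)
  expect_equal(length(unique(bridged$assignment[4:6])), 1)
  expect_equal(bridged$q, exhaustive_best_q(two_cliques(3, bridge = TRUE)),
               tolerance = 1e-12)

  expect_warning(z <- detect_modules(named_adj(matrix(0, 4, 4))), "all-zero")
  expect_equal(z$q, 0)
  expect_equal(z$n_modules, 1)
})

test_that("reported Q is reproducible from the assignment and matrix", {
  for (s in 1:5) {
    g <- er_graph(12, 0.25, seed = 300 + s)
    p <- detect_modules(g, n_iter = 30, seed = s)
    expect_equal(p$q, modularity_q(g, p$assignment), tolerance = 1e-12)
    expect_equal(p$q, naive_q(g, unname(p$assignment[rownames(g)])),
                 tolerance = 1e-12)
    expect_true(p$q >= -1 && p$q <= 1)
    expect_identical(sort(unique(unname(p$assignment))), seq_len(p$n_modules))
  }
  expect_identical(detect_modules(er_graph(12, 0.3, seed = 1), n_iter = 20, seed = 2),
                   detect_modules(er_graph(12, 0.3, seed = 1), n_iter = 20, seed = 2))
})

test_that("density thresholding keeps the top positive weights deterministically", {
  labels <- sprintf("r%d", 1:5)
  w <- matrix(0, 5, 5, dimnames = list(labels, labels))
  vals <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  w[1, 2] <- vals[1]; w[1, 3] <- vals[2]; w[2, 3] <- vals[3]
  w[1, 4] <- vals[4]; w[2, 4] <- vals[5]
  w <- w + t(w)
  # density 1 keeps exactly the positive edges
  expect_equal(sum(upper_vec(threshold_at_density(w, 1))), 5)
  # k = 3 of 5 distinct weights: the three largest survive
  b3 <- threshold_at_density(w, 0.3)  # floor(0.3 * 10) = 3
  expect_equal(sum(upper_vec(b3)), 3)
  expect_equal(b3[1, 2] + b3[1, 3] + b3[2, 3], 3)
  # ties at the cut: lexicographically earliest pair kept, runs identical
  wt <- matrix(0, 4, 4, dimnames = list(labels[1:4], labels[1:4]))
  wt[1, 2] <- 0.5; wt[3, 4] <- 0.5; wt[1, 3] <- 0.9
  wt <- wt + t(wt)
  b2 <- threshold_at_density(wt, 2 / 6)  # k = 2, tie between (1,2) and (3,4)
  expect_equal(b2[1, 3], 1)
  expect_equal(b2[1, 2], 1)
  expect_equal(b2[3, 4], 0)
  expect_identical(threshold_at_density(wt, 2 / 6), b2)
})
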