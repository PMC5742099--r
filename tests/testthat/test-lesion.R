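test_that("node attacks implement the three schemes exactly", {
  # node 1 with 4 equal edges
  st <- star_graph(5)
  za <- node_attack(st, 1, "zero_half")
  expect_equal(sum(za[1, ] == 0), 3) # 2 of 4 edges zeroed, plus the diagonal
  expect_equal(sum(za[1, ] > 0), 2)
  expect_valid_network(za)

  dim_a <- node_attack(st, 1, "diminish_half")
  expect_equal(sum(dim_a[1, ]), sum(st[1, ]) / 2)

  # combined on a hand-built 5-node graph: node 3 has edges 4, 3, 2, 1
  W <- edge_matrix(5, list(c(3, 1, 4), c(3, 2, 3), c(3, 4, 2), c(3, 5, 1), c(1, 2, 9)))
  comb <- node_attack(W, 3, "combined")
  expected <- edge_matrix(5, list(c(3, 4, 1), c(3, 5, 0.5), c(1, 2, 9)))
  expect_equal(comb, as_weighted_network(expected), tolerance = 1e-12)

  # deterministic tie-break: equal weights are zeroed at the lowest indices
  z2 <- node_attack(st, 1, "zero_half")
  expect_equal(which(z2[1, ] > 0), c(4, 5), ignore_attr = TRUE)

  iso <- edge_matrix(3, list(c(1, 2, 1)))
  expect_warning(same <- node_attack(iso, 3, "zero_half"), "isolated")
  expect_equal(same, as_weighted_network(iso))
  expect_error(node_attack(st, 9), class = "connectofuse_invalid_parameter")
})

test_that("lesioned networks stay valid and register positive distances", {
  W <- random_network(8, seed = 1)
  for (scheme in c("zero_half", "diminish_half", "combined")) {
    Wl <- node_attack(W, 4, scheme)
    expect_valid_network(Wl)
    expect_gt(gddm_distance(W, Wl, normalization = "none")$d, 0)
  }
})

test_that("node lesion weights are normalised and respect structure", {
  W <- random_network(8, seed = 2)
  v <- node_lesion_weights(W, "diminish_half")
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))

  # hub of a star dominates leaves under the diminish scheme
  st <- star_graph(6)
  vs <- node_lesion_weights(st, "diminish_half")
  expect_gte(vs[1], max(vs[-1]))

  # automorphic nodes get equal weight: 4-cycle with uniform weights
  cyc <- edge_matrix(4, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 1)))
  vc <- node_lesion_weights(cyc, "diminish_half")
  expect_equal(unname(vc), rep(0.25, 4), tolerance = 1e-8)
})

test_that("cluster partitions recover planted structure", {
  cl1 <- complete_graph(5)
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- cl1
  W[6:10, 6:10] <- cl1
  W[5, 6] <- W[6, 5] <- 0.1
  mods <- partition_clusters(W, "modularity")
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[1:5])), 1)
  expect_equal(length(unique(mods[6:10])), 1)

  ring <- edge_matrix(6, lapply(1:6, function(i) c(i, i %% 6 + 1, 1)))
  expect_true(all(partition_clusters(ring, "richclub") == "non_hub"))

  st <- star_graph(8)
  labs <- partition_clusters(st, "richclub")
  expect_true(labs[1] %in% c("hub", "rc_hub"))
  expect_true(all(labs[-1] == "non_hub"))

  expect_error(partition_clusters(complete_graph(3), "modularity"),
    class = "connectofuse_invalid_parameter"
  )
})

test_that("cluster attacks target only the requested edge class", {
  cl1 <- complete_graph(5, weights = 2)
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- cl1
  W[6:10, 6:10] <- cl1
  # two weak bridges, so halving the between class leaves the graph connected
  W[1, 6] <- W[6, 1] <- 0.5
  W[2, 7] <- W[7, 2] <- 0.5
  labels <- c(rep("rc_hub", 5), rep("non_hub", 5))

  att_between <- cluster_attack(W, labels, "zero_half", target = "between")
  expect_equal(att_between[1, 6], 0) # tie-break: lower-index bridge zeroed
  expect_equal(att_between[2, 7], 0.5)
  expect_equal(att_between[1:5, 1:5], W[1:5, 1:5], ignore_attr = TRUE) # untouched

  att_rc <- cluster_attack(W, labels, "diminish_half", target = "within_rc")
  expect_equal(att_rc[1:5, 1:5], W[1:5, 1:5] / 2, ignore_attr = TRUE)
  expect_equal(att_rc[6:10, 6:10], W[6:10, 6:10], ignore_attr = TRUE)

  # empty class: no hubs at all -> within_rc has no edges
  labels2 <- rep("non_hub", 10)
  expect_warning(
    same <- cluster_attack(W, labels2, "zero_half", target = "within_rc"),
    "empty"
  )
  expect_equal(same, as_weighted_network(W))

  wts <- suppressWarnings(cluster_lesion_weights(W, labels, "zero_half"))
  expect_equal(sum(wts), 1, tolerance = 1e-12)
  expect_named(wts, c("within_rc", "within_nonrc", "between"))
  # dense within-clique lesions disturb diffusion more than the weak bridges
  expect_gt(wts["within_rc"], wts["between"])
})

test_that("module-targeted attacks and weights work with integer labels", {
  W <- random_network(8, seed = 3)
  labels <- rep(1:2, each = 4)
  att <- cluster_attack(W, labels, "diminish_half", target = 1)
  expect_equal(att[1:4, 1:4], W[1:4, 1:4] / 2, ignore_attr = TRUE)
  expect_equal(att[5:8, 5:8], W[5:8, 5:8], ignore_attr = TRUE)
  wts <- cluster_lesion_weights(W, labels, "diminish_half")
  expect_equal(sum(wts), 1, tolerance = 1e-12)
  expect_length(wts, 2)
})

test_that("node-weighted stacks remain valid and fuse end to end", {
  co <- small_cohort(seed = 51, n_rois = 12)
  sid <- co$tracts$scan_id[1]
  stack <- build_nws(dplyr::filter(co$tracts, scan_id == sid), co$geometry)
  sub <- stack[c("NSTR", "FA", "ATL")]
  weighted <- node_weighted_stack(sub, "diminish_half")
  for (W in weighted) expect_valid_network(W)
  fit <- integrate_nws(weighted)
  expect_valid_network(fit$W)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})
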