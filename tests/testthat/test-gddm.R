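test_that("graph Laplacian has zero row sums and is positive semidefinite", {
  K2 <- edge_matrix(2, list(c(1, 2, 1)))
  expect_equal(graph_laplacian(K2), matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  expect_equal(graph_laplacian(matrix(0, 3, 3)), matrix(0, 3, 3), ignore_attr = TRUE)

  W <- random_network(5, seed = 1)
  L <- graph_laplacian(W)
  expect_equal(unname(rowSums(L)), rep(0, 5), tolerance = 1e-12)
  expect_true(all(eigen(L, symmetric = TRUE, only.values = TRUE)$values >= -1e-10))

  asym <- W
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(graph_laplacian(asym), class = "connectofuse_invalid_network")
  neg <- W
  neg[1, 2] <- neg[2, 1] <- -1
  expect_error(graph_laplacian(neg), class = "connectofuse_invalid_network")
})

test_that("diffusion kernels match closed forms and conserve mass", {
  L <- graph_laplacian(edge_matrix(2, list(c(1, 2, 1))))
  K <- diffusion_kernel(L, log(2) / 2)$K
  expect_equal(K, matrix(c(0.75, 0.25, 0.25, 0.75), 2), tolerance = 1e-12, ignore_attr = TRUE)

  expect_equal(diffusion_kernel(L, 1e-12)$K, diag(2), tolerance = 1e-9, ignore_attr = TRUE)

  K3 <- diffusion_kernel(graph_laplacian(complete_graph(3)), 100)$K
  expect_equal(K3, matrix(1 / 3, 3, 3), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(diffusion_kernel(L, 0), class = "connectofuse_invalid_parameter")
  expect_error(diffusion_kernel(L, -1), class = "connectofuse_invalid_parameter")

  # mass conservation and range on random graphs, including disconnected ones
  for (seed in 1:5) {
    W <- random_network(7, seed = seed, density = 0.5)
    for (t in c(0.01, 1, 50)) {
      K <- diffusion_kernel(graph_laplacian(W), t)$K
      expect_equal(unname(rowSums(K)), rep(1, 7), tolerance = 1e-8)
      expect_true(all(K >= -1e-10 & K <= 1 + 1e-10))
      expect_equal(K, t(K), tolerance = 1e-10)
    }
  }
})

test_that("diffusion distance matches the two-node closed form", {
  W1 <- edge_matrix(2, list(c(1, 2, 1)))
  W2 <- edge_matrix(2, list(c(1, 2, 2)))
  res <- gddm_distance(W1, W2, normalization = "none")
  # kernels share eigenvectors; d(t) = (e^{-2t} - e^{-4t})^2, peak 1/16 at ln(2)/2
  expect_equal(res$d, 0.0625, tolerance = 1e-8)
  expect_equal(res$t_star, log(2) / 2, tolerance = 1e-6)

  # K3 scaled pair: eigenvalues {0,3,3} vs {0,6,6}, d(t) = 2 (e^{-3t}-e^{-6t})^2
  r3 <- gddm_distance(complete_graph(3), 2 * complete_graph(3), normalization = "none")
  expect_equal(r3$d, 2 / 16, tolerance = 1e-8)
  expect_equal(r3$t_star, log(2) / 3, tolerance = 1e-6)
})

test_that("diffusion distance is symmetric, zero on identical inputs, and maximal over t", {
  W <- random_network(6, seed = 3)
  expect_equal(gddm_distance(W, W)$d, 0, tolerance = 1e-12)

  W2 <- random_network(6, seed = 4)
  d_ab <- gddm_distance(W, W2)$d
  d_ba <- gddm_distance(W2, W)$d
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
  expect_gte(d_ab, 0)

  # brute-force t sampling never beats the searched optimum
  s1 <- connectofuse:::laplacian_spectrum(graph_laplacian(connectofuse:::prescale_network(W, "max")))
  s2 <- connectofuse:::laplacian_spectrum(graph_laplacian(connectofuse:::prescale_network(W2, "max")))
  profile <- connectofuse:::gdd_profile(s1, s2)
  set.seed(99)
  random_t <- exp(runif(50, log(1e-4), log(1e3)))
  expect_true(all(vapply(random_t, profile, numeric(1)) <= d_ab + 1e-9))

  expect_error(
    gddm_distance(W, random_network(5, seed = 1)),
    class = "connectofuse_invalid_parameter"
  )
})

test_that("pairwise dissimilarity is consistent with individual distances", {
  W <- random_network(5, seed = 5)
  dup <- pairwise_dissimilarity(list(a = W, b = W))
  expect_equal(dup$D, matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
    tolerance = 1e-12
  )

  nets <- list(
    a = random_network(5, seed = 6),
    b = random_network(5, seed = 7),
    c = random_network(5, seed = 8)
  )
  ds <- pairwise_dissimilarity(nets)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(
      ds$D[pair[1], pair[2]],
      gddm_distance(nets[[pair[1]]], nets[[pair[2]]])$d,
      tolerance = 1e-9
    )
  }
  expect_equal(ds$D, t(ds$D))
  expect_true(all(diag(ds$D) == 0))
  expect_error(pairwise_dissimilarity(list(W)), class = "connectofuse_invalid_parameter")
})

test_that("a scan's nine weightings give a valid 9 x 9 dissimilarity matrix", {
  co <- small_cohort(seed = 21, n_rois = 20)
  sid <- co$tracts$scan_id[1]
  stack <- build_nws(dplyr::filter(co$tracts, scan_id == sid), co$geometry)
  ds <- pairwise_dissimilarity(stack)
  expect_equal(dim(ds$D), c(9, 9))
  expect_equal(rownames(ds$D), nws_names())
  expect_equal(ds$D, t(ds$D))
  expect_true(all(ds$D >= 0))
  # PSTR is a global rescaling of NSTR, so max-normalised kernels coincide;
  # every other pair of weightings is genuinely apart
  expect_equal(ds$D["NSTR", "PSTR"], 0, tolerance = 1e-10)
  off <- ds$D[upper.tri(ds$D)]
  expect_equal(sum(off <= 1e-10), 1)
})
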