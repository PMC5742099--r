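test_that("ICC matches hand cases and an independent ANOVA oracle", {
  expect_equal(icc(matrix(c(1, 3, 1, 3), 2))$icc, 1) # perfect agreement
  expect_equal(icc(matrix(c(1, 3, 3, 1), 2))$icc, -1) # pure disagreement

  set.seed(10)
  for (rep in 1:5) {
    M <- matrix(rnorm(24, sd = 2), 6, 4) + rnorm(6)
    expect_equal(icc(M)$icc, aov_icc11(M), tolerance = 1e-10)
  }

  # two-way forms against aov mean squares
  M <- matrix(rnorm(24), 6, 4) + rnorm(6) + rep(rnorm(4), each = 6)
  df <- data.frame(
    value = as.vector(M),
    subject = factor(rep(1:6, times = 4)),
    scan = factor(rep(1:4, each = 6))
  )
  ms <- summary(stats::aov(value ~ subject + scan, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  expect_equal(icc(M, form = "3_1")$icc, (msr - mse) / (msr + 3 * mse), tolerance = 1e-10)
  expect_equal(
    icc(M, form = "2_1")$icc,
    (msr - mse) / (msr + 3 * mse + 4 * (msc - mse) / 6),
    tolerance = 1e-10
  )

  expect_error(icc(matrix(2, 3, 3)), class = "connectofuse_degenerate_icc")
  expect_error(icc(matrix(1:3, 1)), class = "connectofuse_invalid_parameter")
})

test_that("ICC accepts long metric tables", {
  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    scan_id = rep(c("s1", "s2"), 2),
    value = c(1, 1, 3, 3)
  )
  expect_equal(icc(tbl)$icc, 1)
})

test_that("ICC recovers the generating intra-class correlation", {
  recover <- function(rho, n = 50, k = 3, reps = 200) {
    sb <- sqrt(rho)
    sw <- sqrt(1 - rho)
    mean(vapply(seq_len(reps), function(r) {
      M <- matrix(rnorm(n, sd = sb), n, k) + matrix(rnorm(n * k, sd = sw), n, k)
      icc(M)$icc
    }, numeric(1)))
  }
  set.seed(2024)
  for (rho in c(0.2, 0.5, 0.9)) {
    expect_lt(abs(recover(rho) - rho), 0.07)
  }
})

test_that("rank-sum test enumerates exactly for small samples", {
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 6)

  same <- wilcoxon_ranksum(c(2, 5, 7), c(2, 5, 7))
  expect_equal(same$p_value, 1)

  # agreement with the standard implementation in tie-free exact cases
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(5)
    y <- rnorm(6)
    expect_equal(
      wilcoxon_ranksum(x, y)$p_value,
      wilcox.test(x, y, exact = TRUE)$p.value,
      tolerance = 1e-12
    )
  }

  # p decreases as the same sample is shifted further (large-sample branch)
  set.seed(4)
  x <- rnorm(30)
  y <- rnorm(30)
  ps <- vapply(c(0.3, 0.8, 1.5), function(sh) {
    wilcoxon_ranksum(x, y + sh)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(wilcoxon_ranksum(numeric(0), 1), class = "connectofuse_invalid_parameter")
})

# block-structured distance matrix for a subjects x scans design
block_distance <- function(n_sub, n_scan, within, between) {
  m <- n_sub * n_scan
  subj <- rep(seq_len(n_sub), each = n_scan)
  D <- matrix(between, m, m)
  D[outer(subj, subj, `==`)] <- within
  diag(D) <- 0
  list(D = D, subjects = paste0("sub", subj))
}

test_that("k-NN recognition is perfect under block separation and at chance under permutation", {
  bd <- block_distance(5, 5, within = 0, between = 1)
  rec <- knn_recognition(bd$D, bd$subjects, k = 4)
  expect_equal(rec$accuracy, 1.0)
  expect_equal(nrow(rec$assignments), 25)

  set.seed(5)
  accs <- vapply(1:100, function(r) {
    knn_recognition(bd$D, sample(bd$subjects), k = 4)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 5), 0.06)

  # k = 1 with a same-subject nearest neighbour is always right
  set.seed(6)
  noisy <- bd$D + matrix(runif(625, 0, 0.05), 25, 25)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  expect_equal(knn_recognition(noisy, bd$subjects, k = 1)$accuracy, 1.0)

  expect_error(knn_recognition(bd$D, bd$subjects, k = 0), class = "connectofuse_invalid_parameter")
  expect_error(knn_recognition(bd$D, bd$subjects, k = 25), class = "connectofuse_invalid_parameter")
})

test_that("the clustering quality index matches its defining arithmetic", {
  const <- block_distance(3, 4, within = 2, between = 2)
  expect_equal(qci(const$D, const$subjects), 1.0)

  bd <- block_distance(2, 2, within = 1, between = 2)
  expect_equal(qci(bd$D, bd$subjects), 2.0)

  sep <- block_distance(4, 3, within = 0.5, between = 3)
  expect_equal(
    qci(10 * sep$D, sep$subjects),
    qci(sep$D, sep$subjects),
    tolerance = 1e-12
  )

  # monotone in between-subject separation
  q1 <- qci(sep$D, sep$subjects)
  sep2 <- block_distance(4, 3, within = 0.5, between = 6)
  expect_gt(qci(sep2$D, sep2$subjects), q1)

  zero_within <- block_distance(2, 2, within = 0, between = 1)
  expect_error(qci(zero_within$D, zero_within$subjects), class = "connectofuse_degenerate_qci")
  expect_error(qci(bd$D, c("a", "a", "a", "b")), class = "connectofuse_invalid_parameter")
})

test_that("classical MDS reproduces realisable distance matrices", {
  D3 <- complete_graph(3) # equilateral triangle, side 1
  emb <- mds_embed(D3, dims = 2)
  rec <- as.matrix(dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_equal(rec, D3, tolerance = 1e-8, ignore_attr = TRUE)

  dup <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3)
  emb_dup <- mds_embed(dup, dims = 2)
  gap <- sqrt(sum((as.numeric(emb_dup[1, -1]) - as.numeric(emb_dup[2, -1]))^2))
  expect_lt(gap, 1e-6)

  set.seed(7)
  X <- matrix(rnorm(15), 5, 3)
  Dx <- as.matrix(dist(X))
  emb_x <- mds_embed(Dx, dims = 4)
  rec_x <- as.matrix(dist(as.matrix(emb_x[, -1])))
  expect_equal(rec_x, Dx, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(mds_embed(Dx, dims = 5), class = "connectofuse_invalid_parameter")
})
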