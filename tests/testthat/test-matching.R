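test_that("identical clusters have zero dissimilarity under every method", {
  cl <- random_cluster(3)
  for (m in c("mahalanobis", "symmetrized_kl", "euclidean_center"))
    expect_equal(cluster_dissimilarity(cl, cl, dissimilarity_config(m)), 0,
                 tolerance = 1e-10)
})

test_that("the 1-D pooled Mahalanobis closed form is reproduced", {
  c1 <- cluster_summary(0, matrix(1, 1, 1), 10)
  c2 <- cluster_summary(2, matrix(1, 1, 1), 10)
  expect_equal(cluster_dissimilarity(c1, c2), sqrt(2), tolerance = 1e-12)
  expect_equal(cluster_dissimilarity(c1, c2,
                                     dissimilarity_config(squared = TRUE)),
               2, tolerance = 1e-12)
})

test_that("dissimilarities match independent direct-formula evaluation", {
  set.seed(21)
  for (trial in 1:25) {
    c1 <- random_cluster(3)
    c2 <- random_cluster(3)
    expect_equal(cluster_dissimilarity(c1, c2, dissimilarity_config()),
                 oracle_mahalanobis(c1$mean, c1$covariance, c1$size,
                                    c2$mean, c2$covariance, c2$size),
                 tolerance = 1e-10)
    expect_equal(cluster_dissimilarity(c1, c2,
                                       dissimilarity_config("symmetrized_kl")),
                 oracle_symmetrized_kl(c1$mean, c1$covariance,
                                       c2$mean, c2$covariance),
                 tolerance = 1e-10)
    expect_equal(cluster_dissimilarity(c1, c2,
                                       dissimilarity_config("euclidean_center")),
                 sqrt(sum((c1$mean - c2$mean)^2)), tolerance = 1e-12)
  }
})

test_that("Mahalanobis and symmetrized KL are affine invariant; Euclidean is not", {
  set.seed(22)
  p <- 3
  c1 <- random_cluster(p)
  c2 <- random_cluster(p)
  A <- matrix(stats::rnorm(p * p), p) + diag(2, p)
  b <- stats::rnorm(p)
  map <- function(cl) cluster_summary(drop(A %*% cl$mean) + b,
                                      A %*% cl$covariance %*% t(A), cl$size)
  for (m in c("mahalanobis", "symmetrized_kl")) {
    cfg <- dissimilarity_config(m)
    expect_equal(cluster_dissimilarity(map(c1), map(c2), cfg),
                 cluster_dissimilarity(c1, c2, cfg), tolerance = 1e-8)
  }
  cfg_e <- dissimilarity_config("euclidean_center")
  expect_gt(abs(cluster_dissimilarity(map(c1), map(c2), cfg_e) -
                  cluster_dissimilarity(c1, c2, cfg_e)), 1e-4)
})

test_that("degenerate covariances are reported, not silently inverted", {
  z <- matrix(0, 2, 2)
  c1 <- cluster_summary(c(0, 0), z, 10)
  c2 <- cluster_summary(c(1, 1), z, 10)
  expect_error(cluster_dissimilarity(c1, c2), "singular")
})

test_that("the mixed edge cover handles the forced small cases", {
  cl <- random_cluster(2)
  mec0 <- mixed_edge_cover(list(cl), list(cl))
  expect_equal(nrow(mec0$edges), 1L)
  expect_equal(mec0$cost, 0, tolerance = 1e-10)

  # a single pair costing more than 2 lambda stays unmatched
  lam <- 1.5
  d_far <- matrix(4, 1, 1)
  mec1 <- mixed_edge_cover(list(cl), list(cl),
                           dissimilarity_config(lambda = lam), d = d_far)
  expect_equal(nrow(mec1$edges), 0L)
  expect_equal(mec1$cost, 2 * lam)

  # spec'd 3 x 2 instance with a shared partner
  d <- matrix(c(0.5, 3, 1, 3, 0.5, 5), 3, 2)
  mec2 <- mixed_edge_cover(random_cluster_list(3, 2), random_cluster_list(2, 2),
                           dissimilarity_config(lambda = 2), d = d)
  expect_equal(mec2$cost, 2)
  got <- mec2$edges[order(mec2$edges[, 1L]), , drop = FALSE]
  expect_equal(unname(got), matrix(c(1L, 1L, 2L, 2L, 3L, 1L), 3, 2,
                                   byrow = TRUE))

  # one empty side: everything unmatched at lambda each
  mec3 <- mixed_edge_cover(random_cluster_list(3, 2), list(),
                           dissimilarity_config(lambda = 2))
  expect_equal(mec3$cost, 6)
  expect_equal(mec3$unmatched_A, 1:3)
})

test_that("exact cover cost equals brute-force enumeration", {
  set.seed(23)
  dummy <- function(k) random_cluster_list(k, 1)
  for (trial in 1:150) {
    ka <- sample(1:4, 1L)
    kb <- sample(1:4, 1L)
    d <- matrix(stats::runif(ka * kb, 0, 6), ka, kb)
    for (lam in c(0.7, 2, 4.5)) {
      mec <- mixed_edge_cover(dummy(ka), dummy(kb),
                              dissimilarity_config(lambda = lam), d = d)
      expect_equal(mec$cost, brute_force_mec_cost(d, lam), tolerance = 1e-9)
    }
  }
})

test_that("every covered cluster averages within 2 lambda of its matches", {
  set.seed(24)
  for (trial in 1:60) {
    ka <- sample(1:5, 1L)
    kb <- sample(1:5, 1L)
    d <- matrix(stats::runif(ka * kb, 0, 8), ka, kb)
    lam <- stats::runif(1L, 0.5, 4)
    mec <- mixed_edge_cover(random_cluster_list(ka, 1),
                            random_cluster_list(kb, 1),
                            dissimilarity_config(lambda = lam), d = d)
    for (i in setdiff(seq_len(ka), mec$unmatched_A)) {
      part <- mec$edges[mec$edges[, 1L] == i, 2L]
      expect_lte(mean(d[i, part]), 2 * lam + 1e-9)
    }
    for (j in setdiff(seq_len(kb), mec$unmatched_B)) {
      part <- mec$edges[mec$edges[, 2L] == j, 1L]
      expect_lte(mean(d[part, j]), 2 * lam + 1e-9)
    }
  }
})

test_that("sample dissimilarity is symmetric and bounded by all-unmatched", {
  set.seed(25)
  for (trial in 1:15) {
    A <- random_cluster_list(sample(1:4, 1L), 2)
    B <- random_cluster_list(sample(1:4, 1L), 2)
    dab <- sample_dissimilarity(A, B)
    dba <- sample_dissimilarity(B, A)
    expect_equal(dab, dba, tolerance = 1e-10)
    lam <- 2  # p = 2 default
    expect_lte(dab, lam * (length(A) + length(B)) + 1e-9)
  }
})

test_that("far-apart samples pay the full penalty and duplicates add little", {
  far_a <- toy_sample("a", matrix(c(0, 0, 40, 0, 0, 40), 3, 2, byrow = TRUE))
  far_b <- toy_sample("b", matrix(c(200, 200), 1, 2))
  lam <- 2
  expect_equal(sample_dissimilarity(far_a, far_b,
                                    dissimilarity_config(lambda = lam)),
               lam * 4)

  # duplicating an A cluster adds at most lambda to the cover cost
  set.seed(26)
  A <- random_cluster_list(3, 2)
  B <- random_cluster_list(3, 2)
  cfg <- dissimilarity_config(lambda = 2)
  base <- sample_dissimilarity(A, B, cfg)
  dup <- sample_dissimilarity(c(A, A[1]), B, cfg)
  expect_lte(dup, base + 2 + 1e-9)
})
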