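# ML-fit oracle: a single Gaussian fitted to pooled raw cells must agree
# with the moment-matched merge of per-subset summaries
ml_summary <- function(x, id = "s", cl = 1L) {
  mu <- colMeans(x)
  cluster_summary(mu, crossprod(sweep(x, 2L, mu)) / nrow(x), nrow(x),
                  members = list(list(sample_id = id, cluster = cl)))
}

test_that("merging identical clusters keeps moments and doubles the count", {
  cl <- random_cluster(3)
  cl$members <- list(list(sample_id = "a", cluster = 1L))
  mec <- mixed_edge_cover(list(cl), list(cl))
  meta <- merge_matched(list(cl), list(cl), mec)
  expect_length(meta, 1L)
  expect_equal(meta[[1L]]$mean, cl$mean, tolerance = 1e-12)
  expect_equal(meta[[1L]]$covariance, cl$covariance, tolerance = 1e-10)
  expect_equal(meta[[1L]]$size, 2L * cl$size)
})

test_that("the 1-D merge matches the pooled maximum-likelihood fit", {
  c1 <- cluster_summary(0, matrix(1, 1, 1), 10)
  c2 <- cluster_summary(2, matrix(1, 1, 1), 10)
  merged <- cytotemplates:::merge_cluster_summaries(list(c1, c2))
  expect_equal(merged$mean, 1)
  expect_equal(drop(merged$covariance), 2)
  expect_equal(merged$size, 20L)
})

test_that("moment-matched merges equal ML fits on pooled raw cells", {
  set.seed(41)
  for (trial in 1:30) {
    p <- sample(2:4, 1L)
    n1 <- sample(20:80, 1L)
    n2 <- sample(20:80, 1L)
    x1 <- MASS::mvrnorm(n1, stats::rnorm(p), diag(stats::runif(p, 0.5, 2)))
    x2 <- MASS::mvrnorm(n2, stats::rnorm(p, 2), diag(stats::runif(p, 0.5, 2)))
    merged <- cytotemplates:::merge_cluster_summaries(list(ml_summary(x1),
                                                    ml_summary(x2)))
    pooled <- ml_summary(rbind(x1, x2))
    expect_equal(merged$mean, pooled$mean, tolerance = 1e-6)
    expect_equal(merged$covariance, pooled$covariance, tolerance = 1e-6)
    expect_equal(merged$size, pooled$size)
  }
})

test_that("unmatched clusters pass through as self-contained meta-clusters", {
  near <- cluster_summary(c(0, 0), diag(2), 50,
                          members = list(list(sample_id = "a", cluster = 1L)))
  far <- cluster_summary(c(100, 100), diag(2), 30,
                         members = list(list(sample_id = "a", cluster = 2L)))
  other <- cluster_summary(c(0.1, 0), diag(2), 40,
                           members = list(list(sample_id = "b", cluster = 1L)))
  mec <- mixed_edge_cover(list(near, far), list(other))
  meta <- merge_matched(list(near, far), list(other), mec)
  expect_length(meta, 2L)
  singleton <- meta[[which(vapply(meta, function(m) m$size, 1L) == 30L)]]
  expect_equal(singleton$mean, far$mean)
  expect_equal(singleton$covariance, far$covariance)
})

test_that("trees over one or two samples have the degenerate shapes", {
  s <- toy_sample("solo", matrix(c(0, 0), 1, 2))
  t1 <- build_template_tree(list(s))
  expect_equal(t1$n_leaves, 1L)
  expect_equal(t1$nodes[[t1$root]]$height, 0)

  s1 <- toy_sample("a", matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE))
  s2 <- toy_sample("b", matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE))
  t2 <- build_template_tree(list(s1, s2))
  root <- t2$nodes[[t2$root]]
  expect_equal(root$height, 0, tolerance = 1e-10)
  expect_equal(sort(unname(vapply(root$clusters, function(cl) cl$size, 1L))),
               c(100L, 100L))
})

test_that("well-separated classes pair within class before across", {
  means_a <- matrix(c(0, 0, 12, 0), 2, 2, byrow = TRUE)
  means_b <- means_a + 60
  samples <- list(toy_sample("A1", means_a), toy_sample("B1", means_b),
                  toy_sample("A2", means_a + 0.3),
                  toy_sample("B2", means_b + 0.3))
  tree <- build_template_tree(samples)
  root <- tree$nodes[[tree$root]]
  kids <- lapply(root$children, function(i) tree$nodes[[i]])
  leaf_sets <- lapply(kids, function(nd) sort(nd$sample_ids))
  expect_setequal(leaf_sets, list(c("A1", "A2"), c("B1", "B2")))
  for (k in kids) expect_lt(k$height, root$height)
})

test_that("cell counts are conserved from leaves to the root", {
  set.seed(42)
  samples <- lapply(1:5, function(i)
    toy_sample(paste0("s", i),
               matrix(stats::rnorm(6, sd = 20), 3, 2), n_per = 30L + i))
  tree <- suppressMessages(build_template_tree(samples))
  total_in <- sum(vapply(samples, function(s)
    sum(vapply(s$clusters, function(cl) cl$size, 1L)), 1L))
  root <- tree$nodes[[tree$root]]
  expect_equal(sum(vapply(root$clusters, function(cl) cl$size, 1L)),
               total_in)
})

test_that("tree construction is deterministic for fixed input", {
  set.seed(43)
  samples <- lapply(1:6, function(i)
    toy_sample(paste0("s", i), matrix(stats::rnorm(8, sd = 15), 4, 2)))
  t1 <- suppressMessages(build_template_tree(samples))
  t2 <- suppressMessages(build_template_tree(samples))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_tree_newick(t1, p1); write_tree_newick(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("template cuts isolate classes and respect trivial limits", {
  means_a <- matrix(c(0, 0, 12, 0), 2, 2, byrow = TRUE)
  means_b <- means_a + 60
  samples <- list(toy_sample("A1", means_a), toy_sample("A2", means_a + 0.3),
                  toy_sample("B1", means_b), toy_sample("B2", means_b + 0.3))
  tree <- build_template_tree(samples)
  md <- cohort_metadata(c("A1", "A2", "B1", "B2"),
                        c("ca", "ca", "cb", "cb"))
  ts <- cut_templates(tree, "by_labels", metadata = md)
  expect_length(ts, 2L)
  expect_setequal(attr(ts, "labels"), c("ca", "cb"))

  one_class <- cut_templates(tree, "by_labels",
                             metadata = cohort_metadata(md$sample_id, "all"))
  expect_length(one_class, 1L)
  expect_equal(one_class[[1L]]$id, tree$nodes[[tree$root]]$id)

  high <- cut_templates(tree, "by_height",
                        h = tree$nodes[[tree$root]]$height + 1)
  expect_length(high, 1L)

  gap <- cut_templates(tree, "by_gap")
  expect_length(gap, 2L)
})

test_that("dynamic insertion merges near samples and spawns new classes", {
  means <- matrix(c(0, 0, 12, 0), 2, 2, byrow = TRUE)
  s1 <- toy_sample("s1", means)
  s2 <- toy_sample("s2", means + 0.2)
  tree <- build_template_tree(list(s1, s2))
  ts <- cut_templates(tree, "by_height", h = tree$nodes[[tree$root]]$height)
  expect_length(ts, 1L)

  same <- toy_sample("s3", means + 0.1)
  ins <- insert_sample(ts, same, threshold = 5)
  expect_false(ins$is_new)
  expect_equal(ins$assigned, 1L)
  sizes <- vapply(ins$templates[[1L]]$clusters, function(cl) cl$size, 1L)
  expect_equal(sum(sizes), 300L)

  alien <- toy_sample("s4", means + 500)
  ins2 <- insert_sample(ins$templates, alien, threshold = 3)
  expect_true(ins2$is_new)
  expect_length(ins2$templates, 2L)
})

test_that("incremental insertion reproduces the batch templates", {
  means_a <- matrix(c(0, 0, 12, 0), 2, 2, byrow = TRUE)
  means_b <- means_a + 80
  mk <- function(id, base, eps) toy_sample(id, base + eps)
  train <- list(mk("a1", means_a, 0), mk("a2", means_a, 0.2),
                mk("b1", means_b, 0), mk("b2", means_b, 0.2),
                mk("a3", means_a, -0.2), mk("b3", means_b, -0.2))
  tree <- build_template_tree(train)
  batch <- cut_templates(tree, "by_gap")

  inc <- cytotemplates:::new_template_set(list())
  for (s in train) inc <- insert_sample(inc, s, threshold = 3)$templates
  expect_length(inc, length(batch))
  k_batch <- sort(vapply(batch, function(t) length(t$clusters), 1L))
  k_inc <- sort(vapply(inc, function(t) length(t$clusters), 1L))
  expect_equal(k_inc, k_batch)
})

test_that("meta-cluster participation reflects planted presence", {
  common <- matrix(c(0, 0, 15, 0, 0, 15), 3, 2, byrow = TRUE)
  extra <- c(40, 40)
  set.seed(44)
  n <- 50L
  carries <- stats::runif(n) < 0.6
  samples <- lapply(seq_len(n), function(i) {
    m <- if (carries[i]) rbind(common, extra) else common
    toy_sample(paste0("s", i), m + stats::rnorm(length(m), sd = 0.05))
  })
  tree <- suppressMessages(build_template_tree(samples))
  root <- tree$nodes[[tree$root]]
  part <- metacluster_participation(root)
  expect_length(part, 4L)
  expect_equal(sum(part == 1), 3L)
  expect_equal(unname(part[part < 1]), mean(carries), tolerance = 0.1 / 0.6)

  # degenerate poles of the participation fraction
  expect_equal(max(part), 1)
  singleton_tpl <- tree$nodes[[tree$root]]
  expect_gte(min(part), 1 / n)
})
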