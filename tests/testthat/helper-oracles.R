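# Brute-force minimum-cost mixed edge cover by enumeration over every edge
# subset of the complete bipartite graph: the independent oracle for the
# exact solver. Feasible for ka * kb <= 16.
brute_force_mec_cost <- function(d, lambda) {
  ka <- nrow(d)
  kb <- ncol(d)
  ne <- ka * kb
  if (ne == 0L) return(lambda * (ka + kb))
  stopifnot(ne <= 16L)
  masks <- 0:(2^ne - 1L)
  bits <- vapply(seq_len(ne) - 1L, function(b)
    bitwAnd(bitwShiftR(masks, b), 1L), integer(length(masks)))
  dsum <- as.vector(bits %*% as.vector(d))   # edge (i,j) -> bit (j-1)*ka+i-1
  n_uncov <- integer(length(masks))
  for (i in seq_len(ka)) {
    rowmask <- sum(2^(( seq_len(kb) - 1L) * ka + i - 1L))
    n_uncov <- n_uncov + (bitwAnd(masks, as.integer(rowmask)) == 0L)
  }
  for (j in seq_len(kb)) {
    colmask <- sum(2^(( j - 1L) * ka + seq_len(ka) - 1L))
    n_uncov <- n_uncov + (bitwAnd(masks, as.integer(colmask)) == 0L)
  }
  min(dsum + lambda * n_uncov)
}

# all costs for several lambdas without re-enumerating
brute_force_mec_costs <- function(d, lambdas) {
  ka <- nrow(d)
  kb <- ncol(d)
  ne <- ka * kb
  if (ne == 0L) return(lambdas * (ka + kb))
  masks <- 0:(2^ne - 1L)
  bits <- vapply(seq_len(ne) - 1L, function(b)
    bitwAnd(bitwShiftR(masks, b), 1L), integer(length(masks)))
  dsum <- as.vector(bits %*% as.vector(d))
  n_uncov <- integer(length(masks))
  for (i in seq_len(ka)) {
    rowmask <- sum(2^(( seq_len(kb) - 1L) * ka + i - 1L))
    n_uncov <- n_uncov + (bitwAnd(masks, as.integer(rowmask)) == 0L)
  }
  for (j in seq_len(kb)) {
    colmask <- sum(2^(( j - 1L) * ka + seq_len(ka) - 1L))
    n_uncov <- n_uncov + (bitwAnd(masks, as.integer(colmask)) == 0L)
  }
  vapply(lambdas, function(l) min(dsum + l * n_uncov), numeric(1L))
}

# direct-formula Gaussian dissimilarities, written independently of the
# package implementation (different algebraic route: explicit inverses)
oracle_mahalanobis <- function(m1, S1, n1, m2, S2, n2, squared = FALSE) {
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  q <- 0.5 * t(m1 - m2) %*% chol2inv(chol(Sp)) %*% (m1 - m2)
  if (squared) drop(q) else sqrt(drop(q))
}

oracle_symmetrized_kl <- function(m1, S1, m2, S2) {
  p <- length(m1)
  kl <- function(ma, Sa, mb, Sb) {
    iSb <- chol2inv(chol(Sb))
    0.5 * (sum(diag(iSb %*% Sa)) +
             drop(t(mb - ma) %*% iSb %*% (mb - ma)) - p +
             as.numeric(determinant(Sb)$modulus) -
             as.numeric(determinant(Sa)$modulus))
  }
  drop(kl(m1, S1, m2, S2) + kl(m2, S2, m1, S1)) / 2
}

# random Gaussian cluster summaries for property tests
random_cluster <- function(p, spread = 1) {
  A <- matrix(rnorm(p * p, sd = spread), p)
  cluster_summary(rnorm(p, sd = 3), crossprod(A) + diag(0.5, p),
                  size = sample(10:200, 1L))
}

random_cluster_list <- function(k, p) lapply(seq_len(k), function(i)
  random_cluster(p))

# a clustered_sample with given population means (identity covariance)
toy_sample <- function(id, means, n_per = 50L, sd = 1) {
  k <- nrow(means)
  clusters <- lapply(seq_len(k), function(i)
    cluster_summary(means[i, ], diag(sd^2, ncol(means)), n_per,
                    members = list(list(sample_id = id, cluster = i))))
  clustered_sample(id, clusters)
}
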