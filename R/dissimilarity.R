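#' Configuration for cluster dissimilarities and the mixed edge cover
#'
#' @param method one of `"mahalanobis"` (pooled-covariance Mahalanobis
#'   distance), `"symmetrized_kl"` (symmetrized Kullback-Leibler divergence
#'   between the two Gaussians) or `"euclidean_center"` (plain distance
#'   between the mean vectors).
#' @param lambda positive penalty for leaving a cluster unmatched in the
#'   mixed edge cover. `NULL` (the default) resolves to the dimensionality
#'   `p` at call time, so that with the squared Mahalanobis reading a pair is
#'   matched only when the average squared deviation per dimension is below
#'   one.
#' @param squared if `TRUE` the Mahalanobis dissimilarity is the squared form
#'   `1/2 * t(d) %*% solve(Sp) %*% d`; the default is its square root.
#' @return Object of class `dissimilarity_config`.
#' @export
dissimilarity_config <- function(method = c("mahalanobis", "symmetrized_kl",
                                            "euclidean_center"),
                                 lambda = NULL, squared = FALSE) {
  method <- match.arg(method)
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be positive")
  structure(list(method = method, lambda = lambda, squared = squared),
            class = "dissimilarity_config")
}

resolve_lambda <- function(cfg, p) {
  if (is.null(cfg$lambda)) p else cfg$lambda
}

#' Dissimilarity between two Gaussian clusters
#'
#' The default is the pooled-covariance Mahalanobis distance
#' \deqn{d(c_1, c_2) = \sqrt{\tfrac12 (\mu_1-\mu_2)^\top \Sigma_p^{-1}
#' (\mu_1-\mu_2)}, \qquad
#' \Sigma_p = \frac{(n_1-1)\Sigma_1 + (n_2-1)\Sigma_2}{n_1+n_2-2},}
#' optionally without the square root (`squared = TRUE` in the config).
#' `symmetrized_kl` uses the closed Gaussian form
#' \eqn{\frac12[KL(N_1\|N_2) + KL(N_2\|N_1)]} and `euclidean_center` the
#' plain distance between means. Mahalanobis and symmetrized KL are invariant
#' under invertible affine maps applied to both clusters; the Euclidean
#' center distance is not, which is why it fails to register populations
#' whose spread differs across channels.
#'
#' @param c1,c2 [cluster_summary()] objects of equal dimension.
#' @param cfg a [dissimilarity_config()].
#' @return Non-negative scalar.
#' @export
cluster_dissimilarity <- function(c1, c2, cfg = dissimilarity_config()) {
  delta <- c1$mean - c2$mean
  switch(cfg$method,
    euclidean_center = sqrt(sum(delta^2)),
    mahalanobis = {
      n1 <- c1$size; n2 <- c2$size
      if (n1 + n2 < 3L)
        stop("pooled Mahalanobis needs n1 + n2 >= 3")
      sp <- ((n1 - 1) * c1$covariance + (n2 - 1) * c2$covariance) /
        (n1 + n2 - 2)
      q <- tryCatch(drop(crossprod(delta, solve(sp, delta))) / 2,
                    error = function(e)
                      stop("singular pooled covariance: ",
                           conditionMessage(e)))
      q <- max(q, 0)
      if (cfg$squared) q else sqrt(q)
    },
    symmetrized_kl = {
      p <- length(delta)
      i1 <- solve(c1$covariance)
      i2 <- solve(c2$covariance)
      (sum(diag(i2 %*% c1$covariance)) + sum(diag(i1 %*% c2$covariance)) -
         2 * p + drop(crossprod(delta, (i1 + i2) %*% delta))) / 4
    })
}

# full dissimilarity matrix between two cluster lists
dissimilarity_matrix <- function(A, B, cfg) {
  d <- matrix(0, length(A), length(B))
  for (i in seq_along(A)) for (j in seq_along(B))
    d[i, j] <- cluster_dissimilarity(A[[i]], B[[j]], cfg)
  d
}
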