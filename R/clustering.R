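#' Gaussian summary of one cell population
#'
#' The unit of all cross-sample matching: a cluster reduced to its mean
#' vector, covariance matrix and cell count. `members` records provenance as
#' a list of `(sample_id, cluster)` pairs and is filled in by the template
#' machinery; a plain cluster owns itself.
#'
#' @param mean numeric mean vector (length p).
#' @param covariance p x p symmetric positive semi-definite matrix.
#' @param size integer cell count, at least 1.
#' @param label optional phenotype annotation.
#' @param members provenance list; default empty.
#' @return Object of class `cluster_summary`.
#' @export
cluster_summary <- function(mean, covariance, size, label = NULL,
                            members = list()) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (!all(is.finite(mean))) stop("cluster mean must be finite")
  if (nrow(covariance) != length(mean) || ncol(covariance) != length(mean))
    stop("covariance dimensions must match the mean")
  if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance))))
    stop("covariance must be symmetric")
  covariance <- (covariance + t(covariance)) / 2
  ev <- min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * (1 + max(abs(covariance))))
    stop("covariance must be positive semi-definite")
  if (size < 1) stop("cluster size must be at least 1")
  structure(list(mean = mean, covariance = covariance,
                 size = as.integer(size), label = label, members = members),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: p = %d, n = %d%s\n", length(x$mean), x$size,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' A clustered sample: Gaussian populations plus assignments
#'
#' @param sample_id sample identifier.
#' @param clusters list of [cluster_summary()] objects.
#' @param assignments optional per-cell cluster index (1-based); its tabulated
#'   sizes must match the cluster sizes.
#' @return Object of class `clustered_sample`.
#' @export
clustered_sample <- function(sample_id, clusters, assignments = NULL) {
  if (!length(clusters)) stop("a clustered sample needs at least one cluster")
  sizes <- vapply(clusters, function(cl) cl$size, integer(1L))
  if (!is.null(assignments)) {
    tab <- tabulate(assignments, nbins = length(clusters))
    if (!identical(as.integer(tab), as.integer(sizes)))
      stop("cluster sizes do not match the assignment vector")
  }
  structure(list(sample_id = as.character(sample_id), clusters = clusters,
                 assignments = assignments),
            class = "clustered_sample")
}

#' @export
print.clustered_sample <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) cl$size, integer(1L))
  cat(sprintf("clustered_sample '%s': %d clusters, %d cells\n",
              x$sample_id, length(x$clusters), sum(sizes)))
  cat("sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# Sigma <- Sigma + eps * I keeps pooled covariances invertible for tiny
# clusters; eps scales with the average variance.
regularize_covariance <- function(sigma, rel = 1e-6, floor = 1e-12) {
  p <- nrow(sigma)
  eps <- max(rel * sum(diag(sigma)) / p, floor)
  sigma + diag(eps, p)
}

# k-means++ seeding: each new center is drawn with probability proportional
# to the squared distance from the nearest center chosen so far; makes the
# restarts reliable when cluster sizes are very unequal
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  chosen <- integer(k)
  chosen[1L] <- sample.int(n, 1L)
  centers[1L, ] <- x[chosen[1L], ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    pick <- if (sum(d2) > 0)
      sample.int(n, 1L, prob = d2)
    else  # duplicated points: fall back to any unused row
      sample(setdiff(seq_len(n), chosen[seq_len(j - 1L)]), 1L)
    chosen[j] <- pick
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Partition a sample with k-means
#'
#' Standard k-means (Hartigan-Wong) restarted `n_restarts` times from
#' k-means++ seedings, keeping the lowest within-cluster sum of squares;
#' deterministic given `seed`. Restarts that converge with an empty cluster
#' are re-initialized (up to 5 extra attempts).
#'
#' @param events an [event_matrix()], ideally variance-stabilized.
#' @param k number of clusters, at most the number of cells.
#' @param seed integer RNG seed.
#' @param n_restarts random restarts, default 10.
#' @return A [clustered_sample()]; cluster parameters are the regularized
#'   per-cluster Gaussian summaries (see [summarize_clusters()]).
#' @export
fit_kmeans <- function(events, k, seed = 1L, n_restarts = 10L) {
  x <- unclass(events)
  if (k > nrow(x)) stop("k cannot exceed the number of cells")
  if (k == nrow(x))  # every cell its own cluster; WCSS is zero
    return(summarize_clusters(events, seq_len(nrow(x))))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- NULL
    for (attempt in seq_len(6L)) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = kmeanspp_centers(x, k),
                                       iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0L)) break
      message("degenerate k-means restart; re-initializing (attempt ",
              attempt, ")")
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce ", k,
                          " non-empty clusters")
  summarize_clusters(events, best$cluster)
}

# internal index helpers --------------------------------------------------

index_asw <- function(d, assignments) {
  sil <- cluster::silhouette(assignments, dist = d)
  # singleton clusters get silhouette 0 by convention (cluster::silhouette
  # already applies this); average over all points
  mean(sil[, "sil_width"])
}

index_ch <- function(x, assignments) {
  n <- nrow(x); k <- length(unique(assignments))
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(assignments)) {
    xi <- x[assignments == g, , drop = FALSE]
    mu <- colMeans(xi)
    w <- w + sum(sweep(xi, 2L, mu)^2)
    b <- b + nrow(xi) * sum((mu - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

index_dunn <- function(dm, assignments) {
  ids <- sort(unique(assignments))
  diam <- 0
  sep <- Inf
  for (i in seq_along(ids)) {
    ai <- assignments == ids[i]
    diam <- max(diam, max(dm[ai, ai]))
    for (j in seq_along(ids)) if (j > i) {
      sep <- min(sep, min(dm[ai, assignments == ids[j]]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

index_db <- function(x, assignments) {
  ids <- sort(unique(assignments))
  k <- length(ids)
  cent <- t(vapply(ids, function(g)
    colMeans(x[assignments == g, , drop = FALSE]), numeric(ncol(x))))
  s <- vapply(seq_along(ids), function(i) {
    xi <- x[assignments == ids[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cent[i, ])^2)))
  }, numeric(1L))
  m <- as.matrix(stats::dist(cent))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) (s[i] + s[j]) / m[i, j],
               numeric(1L)))
  }, numeric(1L))
  mean(r)
}

index_sdbw <- function(x, assignments) {
  ids <- sort(unique(assignments))
  k <- length(ids)
  p <- ncol(x)
  cent <- t(vapply(ids, function(g)
    colMeans(x[assignments == g, , drop = FALSE]), numeric(p)))
  var_all <- apply(x, 2L, stats::var)
  var_cl <- lapply(ids, function(g) {
    xi <- x[assignments == g, , drop = FALSE]
    if (nrow(xi) > 1L) apply(xi, 2L, stats::var) else rep(0, p)
  })
  norm2 <- function(v) sqrt(sum(v^2))
  scat <- mean(vapply(var_cl, norm2, numeric(1L))) / norm2(var_all)
  stdev <- sqrt(sum(vapply(var_cl, norm2, numeric(1L)))) / k
  dens <- function(center, members) {
    xi <- x[members, , drop = FALSE]
    sum(sqrt(rowSums(sweep(xi, 2L, center)^2)) <= stdev)
  }
  total <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    members <- assignments == ids[i] | assignments == ids[j]
    denom <- max(dens(cent[i, ], assignments == ids[i]),
                 dens(cent[j, ], assignments == ids[j]))
    mid <- (cent[i, ] + cent[j, ]) / 2
    total <- total + if (denom == 0) 0 else dens(mid, members) / denom
  }
  scat + total / (k * (k - 1))
}

#' Five cluster-validity indices for one partition
#'
#' Computes average silhouette width, Calinski-Harabasz, Dunn, S_Dbw and
#' Davies-Bouldin for a clustering of an event matrix. The first three are
#' better when larger, the last two when smaller. The quadratic-cost indices
#' (silhouette, Dunn) are evaluated on a seeded subsample of at most
#' `subsample` cells.
#'
#' @param events an [event_matrix()] or plain numeric matrix.
#' @param assignments per-cell cluster index with at least 2 non-empty
#'   clusters.
#' @param subsample cap for the pairwise-distance indices, default 5000.
#' @param seed subsampling seed.
#' @return Named numeric vector
#'   `c(asw, calinski_harabasz, dunn, s_dbw, davies_bouldin)`.
#' @export
validation_indices <- function(events, assignments, subsample = 5000L,
                               seed = 1L) {
  x <- unclass(events)
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(x))
    stop("one assignment per cell required")
  if (length(unique(assignments)) < 2L)
    stop("validity indices need at least 2 clusters")
  if (nrow(x) > subsample) {
    set.seed(seed)
    idx <- sort(sample.int(nrow(x), subsample))
    # keep at least one point per cluster
    for (g in setdiff(unique(assignments), unique(assignments[idx])))
      idx <- sort(c(idx, which(assignments == g)[1L]))
    xs <- x[idx, , drop = FALSE]
    as_s <- assignments[idx]
  } else {
    xs <- x
    as_s <- assignments
  }
  d <- stats::dist(xs)
  dm <- as.matrix(d)
  c(asw = index_asw(d, as_s),
    calinski_harabasz = index_ch(x, assignments),
    dunn = index_dunn(dm, as_s),
    s_dbw = index_sdbw(x, assignments),
    davies_bouldin = index_db(x, assignments))
}

#' Choose the number of clusters by index consensus
#'
#' Fits k-means for every `k` in `k_range`, scores each partition with the
#' five validity indices, lets each index vote for its optimal `k` (argmax
#' for silhouette / Calinski-Harabasz / Dunn, argmin for S_Dbw /
#' Davies-Bouldin) and returns the majority `k`, breaking ties toward the
#' smaller value.
#'
#' @param events an [event_matrix()].
#' @param k_range integer vector of candidate cluster numbers (>= 2).
#' @param seed RNG seed (k-means restarts and index subsampling).
#' @param ... passed to [fit_kmeans()].
#' @return A list of class `validation_report`: `k_values`, `scores` (matrix
#'   k x index), `votes` (named integer per index), `consensus_k`, and
#'   `fits` (the [clustered_sample()] per k).
#' @export
select_k <- function(events, k_range = 2:8, seed = 1L, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("k_range must start at 2 or above")
  scores <- matrix(NA_real_, length(k_range), 5L,
                   dimnames = list(k_range,
                                   c("asw", "calinski_harabasz", "dunn",
                                     "s_dbw", "davies_bouldin")))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- fit_kmeans(events, k_range[i], seed = seed, ...)
    fits[[i]] <- fit
    scores[i, ] <- validation_indices(events, fit$assignments, seed = seed)
  }
  maximize <- c(asw = TRUE, calinski_harabasz = TRUE, dunn = TRUE,
                s_dbw = FALSE, davies_bouldin = FALSE)
  votes <- vapply(colnames(scores), function(ix) {
    v <- scores[, ix]
    k_range[if (maximize[[ix]]) which.max(v) else which.min(v)]
  }, integer(1L))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  consensus_k <- min(winners)
  structure(list(k_values = k_range, scores = scores, votes = votes,
                 consensus_k = consensus_k,
                 fit = fits[[match(consensus_k, k_range)]]),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("cluster-number selection over k =",
      paste(range(x$k_values), collapse = ".."), "\n")
  cat("votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "),
      "\n")
  cat("consensus k =", x$consensus_k, "\n")
  invisible(x)
}

#' Gaussian summaries from a hard partition
#'
#' Reduces each cluster to its sample mean and maximum-likelihood covariance
#' (divisor n), regularized with a small diagonal ridge so downstream
#' Mahalanobis computations never meet a singular matrix.
#'
#' @param events an [event_matrix()].
#' @param assignments per-cell cluster index; every index up to the maximum
#'   must be non-empty.
#' @return A [clustered_sample()].
#' @export
summarize_clusters <- function(events, assignments) {
  x <- unclass(events)
  assignments <- as.integer(assignments)
  k <- max(assignments)
  sizes <- tabulate(assignments, nbins = k)
  if (any(sizes == 0L)) stop("empty cluster index in 'assignments'")
  sid <- sample_id(events)
  clusters <- lapply(seq_len(k), function(g) {
    xi <- x[assignments == g, , drop = FALSE]
    mu <- colMeans(xi)
    n <- nrow(xi)
    sig <- if (n > 1L) crossprod(sweep(xi, 2L, mu)) / n else
      matrix(0, ncol(x), ncol(x))
    cluster_summary(mu, regularize_covariance(sig), n,
                    members = list(list(sample_id = sid, cluster = g)))
  })
  clustered_sample(sid, clusters, assignments)
}
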