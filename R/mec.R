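# Exact O(n^3) Hungarian algorithm (shortest augmenting path / Jonker-
# Volgenant potentials) for square cost matrices. Sizes here are the number
# of clusters per sample (tens), so plain R is fast enough.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                 # columns shifted by 1; column 1 is virtual
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_row <- integer(n)    # match_row[i] = column assigned to row i
  for (j in seq_len(n) + 1L) if (p[j] > 0L) match_row[p[j]] <- j - 1L
  match_row
}

#' Minimum-cost mixed edge cover between two cluster lists
#'
#' Registers cell populations across two samples (or templates). Every
#' cluster is either matched to one or more clusters on the other side or
#' left unmatched at a fixed penalty `lambda`; the cover minimizes the total
#' of all matched-pair dissimilarities plus `lambda` per unmatched cluster.
#' Multi-matching resolves split or merged populations; a cluster with no
#' sufficiently close partner stays unmatched, which is how missing
#' populations are handled.
#'
#' The optimum is computed exactly: an optimal cover can always be arranged
#' as vertex-disjoint stars, so the problem reduces to a square assignment
#' problem in which each cluster may also pay `min(lambda, d_min)` to be
#' covered by a dummy (unmatched, or attached to its nearest partner as an
#' extra satellite). The assignment is solved with the Hungarian algorithm.
#'
#' @param A,B lists of [cluster_summary()] objects (a [clustered_sample()]
#'   or template node is accepted and its cluster list used).
#' @param cfg a [dissimilarity_config()]; `lambda = NULL` resolves to the
#'   dimensionality p.
#' @param d optional precomputed dissimilarity matrix
#'   (`length(A)` x `length(B)`).
#' @return Object of class `mec_result`: `edges` (two-column matrix of
#'   matched index pairs), `unmatched_A`, `unmatched_B`, `cost`, `lambda`,
#'   and the dissimilarity matrix `d`.
#' @export
mixed_edge_cover <- function(A, B, cfg = dissimilarity_config(), d = NULL) {
  A <- as_cluster_list(A)
  B <- as_cluster_list(B)
  ka <- length(A)
  kb <- length(B)
  if (ka < 1L && kb < 1L) stop("both sides are empty")
  p <- if (ka) length(A[[1L]]$mean) else length(B[[1L]]$mean)
  lambda <- resolve_lambda(cfg, p)
  if (is.null(d)) d <- dissimilarity_matrix(A, B, cfg)
  if (ka == 0L || kb == 0L) {
    return(new_mec_result(matrix(integer(0), 0L, 2L), seq_len(ka),
                          seq_len(kb), lambda * (ka + kb), lambda, d))
  }
  # per-vertex price of not taking part in the one-to-one core matching:
  # stay unmatched (lambda) or ride along as a satellite of the nearest
  # partner (d_min)
  pa <- pmin(lambda, apply(d, 1L, min))
  pb <- pmin(lambda, apply(d, 2L, min))
  n <- ka + kb
  big <- (sum(d) + lambda * n + 1) * 2
  cost <- matrix(big, n, n)
  cost[seq_len(ka), seq_len(kb)] <- d
  for (i in seq_len(ka)) cost[i, kb + i] <- pa[i]
  for (j in seq_len(kb)) cost[ka + j, j] <- pb[j]
  cost[ka + seq_len(kb), kb + seq_len(ka)] <- 0
  assign <- solve_assignment(cost)

  edges <- matrix(integer(0), 0L, 2L)
  covered_a <- rep(FALSE, ka)
  covered_b <- rep(FALSE, kb)
  for (i in seq_len(ka)) {
    j <- assign[i]
    if (j <= kb) {
      edges <- rbind(edges, c(i, j))
      covered_a[i] <- TRUE
      covered_b[j] <- TRUE
    }
  }
  # vertices priced out of the core matching: attach to nearest partner when
  # strictly cheaper than the penalty, else leave unmatched
  for (i in which(!covered_a)) {
    dmin <- min(d[i, ])
    if (dmin < lambda) {
      edges <- rbind(edges, c(i, which.min(d[i, ])))
      covered_a[i] <- TRUE
      covered_b[which.min(d[i, ])] <- TRUE
    }
  }
  for (j in which(!covered_b)) {
    dmin <- min(d[, j])
    if (dmin < lambda) {
      edges <- rbind(edges, c(which.min(d[, j]), j))
      covered_b[j] <- TRUE
      covered_a[which.min(d[, j])] <- TRUE
    }
  }
  unmatched_A <- which(!covered_a)
  unmatched_B <- which(!covered_b)
  cost_total <- (if (nrow(edges)) sum(d[edges]) else 0) +
    lambda * (length(unmatched_A) + length(unmatched_B))
  new_mec_result(edges, unmatched_A, unmatched_B, cost_total, lambda, d)
}

new_mec_result <- function(edges, unmatched_A, unmatched_B, cost, lambda, d) {
  colnames(edges) <- c("a", "b")
  structure(list(edges = edges, unmatched_A = as.integer(unmatched_A),
                 unmatched_B = as.integer(unmatched_B), cost = cost,
                 lambda = lambda, d = d),
            class = "mec_result")
}

#' @export
print.mec_result <- function(x, ...) {
  cat(sprintf(
    "mixed edge cover: %d edge(s), %d + %d unmatched, lambda = %.4g\n",
    nrow(x$edges), length(x$unmatched_A), length(x$unmatched_B), x$lambda))
  cat(sprintf("cost D(A,B) = %.6g\n", x$cost))
  invisible(x)
}

as_cluster_list <- function(x) {
  if (inherits(x, "clustered_sample")) return(x$clusters)
  if (inherits(x, "template_node")) return(x$clusters)
  if (inherits(x, "cluster_summary")) return(list(x))
  if (is.list(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a cluster list")
}

# matched partners of cluster i on side A (column indices), per mec edges
mec_partners <- function(mec, i, side = c("A", "B")) {
  side <- match.arg(side)
  if (side == "A") mec$edges[mec$edges[, 1L] == i, 2L]
  else mec$edges[mec$edges[, 2L] == i, 1L]
}

#' Dissimilarity between two samples or templates
#'
#' The minimum cost of the mixed edge cover between the two cluster lists;
#' symmetric by construction of the objective.
#'
#' @inheritParams mixed_edge_cover
#' @return Non-negative scalar `D(A, B)`.
#' @export
sample_dissimilarity <- function(A, B, cfg = dissimilarity_config()) {
  mixed_edge_cover(A, B, cfg)$cost
}
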