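#' Merge matched clusters into meta-clusters
#'
#' Given a mixed edge cover between the cluster lists of two nodes, each
#' connected component of the cover's edge set becomes one meta-cluster
#' (clusters chained through shared partners collapse together); unmatched
#' clusters carry over as self-contained singleton meta-clusters. Parameters
#' are the maximum-likelihood estimates for the pooled cells, computed by
#' moment matching from the component summaries:
#' \deqn{\mu = \sum_i n_i \mu_i / n, \qquad
#' \Sigma = \sum_i n_i (\Sigma_i + \mu_i \mu_i^\top) / n - \mu\mu^\top,
#' \qquad n = \sum_i n_i.}
#' Provenance (`members`) is concatenated, so participation fractions remain
#' computable at any tree level.
#'
#' @param A,B cluster lists (or [clustered_sample()] / template nodes).
#' @param mec the [mixed_edge_cover()] computed between `A` and `B`.
#' @return List of [cluster_summary()] meta-clusters.
#' @export
merge_matched <- function(A, B, mec) {
  A <- as_cluster_list(A)
  B <- as_cluster_list(B)
  ka <- length(A)
  kb <- length(B)
  # union-find over ka + kb vertices
  parent <- seq_len(ka + kb)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(mec$edges)) {
    for (e in seq_len(nrow(mec$edges))) {
      ri <- find(mec$edges[e, 1L])
      rj <- find(ka + mec$edges[e, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(ka + kb), find, integer(1L))
  all_clusters <- c(A, B)
  unname(lapply(split(seq_len(ka + kb), roots), function(idx) {
    merge_cluster_summaries(all_clusters[idx])
  }))
}

# moment-matching ML pooling of Gaussian summaries
merge_cluster_summaries <- function(clusters) {
  if (length(clusters) == 1L) return(clusters[[1L]])
  sizes <- vapply(clusters, function(cl) cl$size, integer(1L))
  n <- sum(sizes)
  p <- length(clusters[[1L]]$mean)
  mu <- rep(0, p)
  for (i in seq_along(clusters)) mu <- mu + sizes[i] * clusters[[i]]$mean
  mu <- mu / n
  second <- matrix(0, p, p)
  for (i in seq_along(clusters)) {
    ci <- clusters[[i]]
    second <- second + sizes[i] * (ci$covariance + tcrossprod(ci$mean))
  }
  sigma <- second / n - tcrossprod(mu)
  sigma <- (sigma + t(sigma)) / 2
  cluster_summary(mu, sigma, n,
                  members = do.call(c, lapply(clusters, `[[`, "members")))
}

new_template_node <- function(id, clusters, sample_ids, height = 0,
                              children = NULL) {
  structure(list(id = id, clusters = clusters,
                 sample_ids = sample_ids, height = height,
                 children = children),
            class = "template_node")
}

#' @export
print.template_node <- function(x, ...) {
  cat(sprintf("template '%s': %d meta-cluster(s) over %d sample(s), height %.4g\n",
              x$id, length(x$clusters), length(x$sample_ids), x$height))
  invisible(x)
}

#' Build a template tree by hierarchical matching and merging
#'
#' Agglomerative construction over clustered samples: every sample starts as
#' an orphan leaf; repeatedly the pair of orphans with the smallest mixed
#' edge cover cost `D` is matched, its clusters merged into meta-clusters,
#' and the merged node (with height `D`) replaces the pair, until one orphan
#' (the root) remains. Ties in the minimum are broken toward the
#' lexicographically smallest pair of node ids, so rebuilding from the same
#' input yields an identical tree.
#'
#' @param samples list of [clustered_sample()] objects (N >= 1) with unique
#'   sample ids.
#' @param cfg a [dissimilarity_config()].
#' @return Object of class `template_tree`: `nodes` (list of
#'   `template_node`s, leaves first), `root` (node index), `heights`,
#'   `cfg`. Supports `print`, `plot` and [ape::as.phylo] conversion.
#' @export
build_template_tree <- function(samples, cfg = dissimilarity_config()) {
  if (inherits(samples, "clustered_sample")) samples <- list(samples)
  n <- length(samples)
  if (n < 1L) stop("at least one sample is required")
  ids <- vapply(samples, function(s) s$sample_id, character(1L))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  nodes <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    cl <- samples[[i]]$clusters
    nodes[[i]] <- new_template_node(ids[i], cl, ids[i], height = 0)
  }
  if (n == 1L)
    return(structure(list(nodes = nodes, root = 1L, n_leaves = 1L,
                          cfg = cfg),
                     class = "template_tree"))
  orphans <- seq_len(n)
  D <- matrix(NA_real_, 2L * n - 1L, 2L * n - 1L)
  for (a in seq_along(orphans)) for (b in seq_along(orphans)) if (a < b)
    D[orphans[a], orphans[b]] <-
      sample_dissimilarity(nodes[[orphans[a]]], nodes[[orphans[b]]], cfg)
  next_id <- n
  while (length(orphans) > 1L) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (a in seq_along(orphans)) for (b in seq_along(orphans)) if (a < b) {
      dv <- D[orphans[a], orphans[b]]
      if (dv < best_d) {        # strict <: first (lexicographic) pair wins
        best_d <- dv
        best <- c(orphans[a], orphans[b])
      }
    }
    vi <- nodes[[best[1L]]]
    vj <- nodes[[best[2L]]]
    mec <- mixed_edge_cover(vi, vj, cfg)
    meta <- merge_matched(vi, vj, mec)
    next_id <- next_id + 1L
    if (best_d > 0 &&
        (vi$height > best_d || vj$height > best_d))
      message("height inversion at node ", next_id,
              " (child higher than parent)")
    nodes[[next_id]] <- new_template_node(
      paste0("T", next_id - n),
      meta, c(vi$sample_ids, vj$sample_ids), height = best_d,
      children = best)
    orphans <- c(setdiff(orphans, best), next_id)
    for (o in setdiff(orphans, next_id)) {
      D[min(o, next_id), max(o, next_id)] <-
        sample_dissimilarity(nodes[[o]], nodes[[next_id]], cfg)
    }
  }
  structure(list(nodes = nodes, root = orphans, n_leaves = n, cfg = cfg),
            class = "template_tree")
}

#' @export
print.template_tree <- function(x, ...) {
  root <- x$nodes[[x$root]]
  cat(sprintf("template tree: %d leaves, root height %.4g, %d root meta-cluster(s)\n",
              x$n_leaves, root$height, length(root$clusters)))
  invisible(x)
}

tree_heights <- function(tree) {
  vapply(tree$nodes[seq.int(tree$n_leaves + 1L, length.out =
                              length(tree$nodes) - tree$n_leaves)],
         function(nd) nd$height, numeric(1L))
}

# leaf sample ids under a node
node_leaves <- function(tree, id) tree$nodes[[id]]$sample_ids

#' Convert a template tree to an ape phylogeny
#'
#' Branch lengths are parent height minus child height; negative spans
#' (height inversions) are emitted as zero-length branches with a warning.
#'
#' @param x a `template_tree` with at least two leaves.
#' @param ... unused.
#' @return An [ape::as.phylo] `phylo` object.
#' @method as.phylo template_tree
#' @export
as.phylo.template_tree <- function(x, ...) {
  if (x$n_leaves < 2L) stop("a phylo object needs at least 2 leaves")
  ape::read.tree(text = newick_string(x))
}

newick_string <- function(tree) {
  clamped <- FALSE
  render <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children)) return(nd$id)
    parts <- vapply(nd$children, function(ch) {
      len <- nd$height - tree$nodes[[ch]]$height
      if (len < 0) {
        clamped <<- TRUE
        len <- 0
      }
      paste0(render(ch), ":", format(len, digits = 12))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(render(tree$root), ";")
  if (clamped)
    warning("height inversion: negative branch length clamped to 0")
  out
}

#' @export
plot.template_tree <- function(x, ...) {
  ape::plot.phylo(as.phylo.template_tree(x), ...)
  invisible(x)
}

#' Write a template tree as Newick
#'
#' Leaf names are sample ids; branch lengths are parent height minus child
#' height (clamped at zero, with a warning, on height inversions). A
#' single-leaf tree is written as `"S1;"`.
#'
#' @param tree a `template_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Cut a template tree into class templates
#'
#' The roots of well-separated branches of the tree act as class templates.
#' Three cut rules are provided: `by_height` takes the maximal subtrees whose
#' merge height stays below `h`; `by_gap` places `h` automatically at the
#' largest relative gap between consecutive sorted merge heights (the
#' standard dendrogram heuristic); `by_labels` takes, for each class in the
#' metadata, the maximal nodes all of whose samples carry that label
#' (returning a per-class forest with a warning when a class is not
#' contiguous in the tree).
#'
#' @param tree a `template_tree`.
#' @param mode `"by_gap"`, `"by_height"` or `"by_labels"`.
#' @param h cut height for `by_height`.
#' @param metadata a [cohort_metadata()] (or data frame with `sample_id`,
#'   `class_label`), required for `by_labels`.
#' @param label_by metadata column used for `by_labels`, default
#'   `"class_label"`.
#' @return A `template_set`: list of `template_node`s with attribute
#'   `root_height`.
#' @export
cut_templates <- function(tree, mode = c("by_gap", "by_height", "by_labels"),
                          h = NULL, metadata = NULL,
                          label_by = "class_label") {
  mode <- match.arg(mode)
  root_h <- tree$nodes[[tree$root]]$height
  if (tree$n_leaves == 1L || length(tree$nodes) == tree$n_leaves)
    return(new_template_set(tree$nodes[tree$root], root_h))
  if (mode == "by_gap") {
    hs <- sort(tree_heights(tree))
    if (length(hs) == 1L) {
      h <- hs / 2
    } else {
      lo <- pmax(hs[-length(hs)], .Machine$double.eps)
      ratios <- hs[-1L] / lo
      g <- which.max(ratios)
      h <- (hs[g] + hs[g + 1L]) / 2
    }
    mode <- "by_height"
  }
  if (mode == "by_height") {
    if (is.null(h)) stop("'h' is required for a by_height cut")
    picked <- integer(0)
    walk <- function(id) {
      nd <- tree$nodes[[id]]
      if (nd$height <= h) {
        picked <<- c(picked, id)
      } else {
        for (ch in nd$children) walk(ch)
      }
    }
    walk(tree$root)
    return(new_template_set(tree$nodes[picked], root_h))
  }
  # by_labels
  if (is.null(metadata)) stop("'metadata' is required for a by_labels cut")
  labels <- stats::setNames(as.character(metadata[[label_by]]),
                            metadata$sample_id)
  leaf_ids <- vapply(tree$nodes[seq_len(tree$n_leaves)], `[[`,
                     character(1L), "id")
  if (!all(leaf_ids %in% names(labels)))
    stop("metadata is missing labels for some samples")
  node_label <- function(id) {
    l <- unique(labels[node_leaves(tree, id)])
    if (length(l) == 1L) l else NA_character_
  }
  picked <- integer(0)
  walk <- function(id) {
    if (!is.na(node_label(id))) {
      picked <<- c(picked, id)
    } else {
      for (ch in tree$nodes[[id]]$children) walk(ch)
    }
  }
  walk(tree$root)
  picked_labels <- vapply(picked, node_label, character(1L))
  if (anyDuplicated(picked_labels))
    warning("class(es) ", paste(unique(picked_labels[duplicated(picked_labels)]),
                                collapse = ", "),
            " are not contiguous in the tree; returning per-class forests")
  out <- new_template_set(tree$nodes[picked], root_h)
  attr(out, "labels") <- picked_labels
  out
}

new_template_set <- function(nodes, root_height = NA_real_) {
  structure(nodes, root_height = root_height, class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template set: %d template(s)\n", length(x)))
  for (t in x)
    cat(sprintf("  '%s': %d meta-cluster(s), %d sample(s)\n", t$id,
                length(t$clusters), length(t$sample_ids)))
  invisible(x)
}

#' Insert a new sample into an existing set of templates
#'
#' Computes the mixed-edge-cover dissimilarity between the sample and every
#' template; if the closest template is within `threshold` the sample is
#' merged into it (meta-cluster parameters updated by the same
#' match-and-merge step used during tree construction), otherwise the sample
#' founds a new singleton template. This is the dynamic-update companion of
#' [build_template_tree()]: inserting samples one at a time into an empty
#' set reproduces the batch templates on well-separated classes.
#'
#' @param templates a `template_set` (possibly empty list).
#' @param S a [clustered_sample()].
#' @param cfg a [dissimilarity_config()].
#' @param threshold merge threshold; default is the originating tree's root
#'   height when the set was produced by [cut_templates()].
#' @return List with `templates` (updated set), `assigned` (template index,
#'   or `NA` for a new class), `is_new` and `D` (per-template
#'   dissimilarities).
#' @export
insert_sample <- function(templates, S, cfg = dissimilarity_config(),
                          threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- attr(templates, "root_height")
    if (is.null(threshold) || is.na(threshold))
      stop("no default threshold available; supply 'threshold'")
  }
  if (threshold <= 0) stop("'threshold' must be positive")
  root_h <- attr(templates, "root_height")
  if (!length(templates)) {
    node <- new_template_node(S$sample_id, S$clusters, S$sample_id)
    return(list(templates = new_template_set(list(node), root_h),
                assigned = NA_integer_, is_new = TRUE, D = numeric(0)))
  }
  D <- vapply(templates, function(t) sample_dissimilarity(t, S, cfg),
              numeric(1L))
  if (min(D) <= threshold) {
    i <- which.min(D)
    t <- templates[[i]]
    mec <- mixed_edge_cover(t, S, cfg)
    merged <- merge_matched(t, S, mec)
    templates[[i]] <- new_template_node(
      t$id, merged, c(t$sample_ids, S$sample_id),
      height = max(t$height, min(D)), children = t$children)
    list(templates = new_template_set(unclass(templates), root_h),
         assigned = i, is_new = FALSE, D = D)
  } else {
    node <- new_template_node(S$sample_id, S$clusters, S$sample_id)
    list(templates = new_template_set(c(unclass(templates), list(node)),
                                      root_h),
         assigned = NA_integer_, is_new = TRUE, D = D)
  }
}

#' Fraction of a template's samples present in each meta-cluster
#'
#' @param template a `template_node` with intact provenance records.
#' @return Numeric vector, one fraction per meta-cluster: the number of
#'   distinct samples contributing clusters to it divided by the number of
#'   samples the template covers.
#' @export
metacluster_participation <- function(template) {
  n_samples <- length(template$sample_ids)
  vapply(template$clusters, function(cl) {
    if (!length(cl$members))
      stop("provenance records missing from meta-cluster")
    length(unique(vapply(cl$members, `[[`, character(1L), "sample_id"))) /
      n_samples
  }, numeric(1L))
}
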