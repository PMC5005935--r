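# JSON serialization of cluster lists, templates and score reports; the
# interchange format used by the command-line wrapper.

cluster_to_list <- function(cl) {
  list(mean = cl$mean, covariance = cl$covariance, size = cl$size,
       label = cl$label, members = cl$members)
}

cluster_from_list <- function(x) {
  cluster_summary(unlist(x$mean), matrix(unlist(x$covariance),
                                         length(unlist(x$mean))),
                  x$size, label = x$label,
                  members = lapply(x$members, function(m)
                    list(sample_id = m$sample_id,
                         cluster = as.integer(m$cluster))))
}

#' Write a set of templates (or one clustered sample) to JSON
#'
#' @param x a `template_set`, `template_node` or [clustered_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_templates_json <- function(x, path) {
  if (inherits(x, "clustered_sample"))
    x <- new_template_set(list(new_template_node(x$sample_id, x$clusters,
                                                 x$sample_id)))
  if (inherits(x, "template_node")) x <- new_template_set(list(x))
  payload <- list(
    root_height = attr(x, "root_height"),
    templates = lapply(x, function(t)
      list(id = t$id, height = t$height, sample_ids = t$sample_ids,
           clusters = lapply(t$clusters, cluster_to_list))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a template set back from JSON
#'
#' @param path file written by [write_templates_json()].
#' @return A `template_set`.
#' @export
read_templates_json <- function(path) {
  payload <- jsonlite::read_json(path)
  nodes <- lapply(payload$templates, function(t)
    new_template_node(t$id, lapply(t$clusters, cluster_from_list),
                      unlist(t$sample_ids),
                      height = if (is.null(t$height)) 0 else t$height))
  rh <- payload$root_height
  new_template_set(nodes, if (is.null(rh)) NA_real_ else rh)
}

#' Write a score report to JSON
#'
#' @param report a `score_report` from [score_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_json <- function(report, path) {
  payload <- list(score = report$score, predicted = report$predicted,
                  lambda = report$lambda, m_plus = report$m_plus,
                  clusters = report$clusters)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
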