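# shared pipeline steps for the cohort-level tests: cluster every sample
# with the index consensus and return clustered_sample objects
cluster_cohort <- function(samples, k_range = 2:6, seed = 3L) {
  lapply(samples, function(em)
    suppressMessages(select_k(em, k_range, seed = seed)$fit))
}

# grouping of leaf sample ids implied by a template set
template_grouping <- function(ts) {
  g <- rep(seq_along(ts), vapply(ts, function(t) length(t$sample_ids), 1L))
  stats::setNames(g, unlist(lapply(ts, function(t) t$sample_ids)))
}
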