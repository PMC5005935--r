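#' Specification of one synthetic cell population
#'
#' Generative counterpart of a meta-cluster: a Gaussian population with an
#' expected mixture fraction and a probability of being present in any given
#' sample. Fractions of the populations actually present in a sample are
#' renormalized to one.
#'
#' @param mean numeric mean vector.
#' @param covariance covariance matrix (default identity).
#' @param fraction expected mixture fraction in (0, 1].
#' @param presence_prob probability that a sample carries the population.
#' @param tag short label (e.g. `"blast"`).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(mean, covariance = diag(length(mean)),
                            fraction, presence_prob = 1, tag = "pop") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (presence_prob <= 0 || presence_prob > 1)
    stop("presence_prob must be in (0, 1]")
  cl <- cluster_summary(mean, covariance, size = 1L)  # validates mean/cov
  structure(list(mean = cl$mean, covariance = cl$covariance,
                 fraction = fraction, presence_prob = presence_prob,
                 tag = tag),
            class = "population_spec")
}

# default lymphocyte-like geometry: four well-separated unit Gaussians in
# five channels, pairwise means >= 8 pooled sd apart
hd_populations <- function() {
  list(
    population_spec(c(8, 8, 8, 0, 0), fraction = 0.35, tag = "helperT"),
    population_spec(c(8, 8, 0, 8, 0), fraction = 0.25, tag = "cytotoxicT"),
    population_spec(c(8, 0, 0, 0, 8), fraction = 0.20, tag = "B"),
    population_spec(c(8, 0, 0, 0, 0), fraction = 0.20, tag = "NK"))
}

hd_channels <- c("CD45", "CD3", "CD4", "CD8", "CD19")

# blast-like population >= 5 sd away from every shared population
blast_population <- function(fraction = 0.4) {
  population_spec(c(4, 4, 4, 4, 4), fraction = fraction, tag = "blast")
}

#' Draw one synthetic sample from a Gaussian mixture
#'
#' Populations are included independently with their `presence_prob`; the
#' mixture weights of the included populations are their renormalized
#' expected fractions perturbed by a Dirichlet draw (concentration
#' `dirichlet_conc` times the fractions), cell counts are multinomial, and
#' cells are Gaussian. Optional per-population mean shifts model batch,
#' subject or day effects. A draw in which no population is present is
#' resampled (with a message).
#'
#' @param populations list of [population_spec()]s.
#' @param n_cells number of cells.
#' @param sample_id sample identifier.
#' @param shifts optional numeric matrix (p x n_populations) of mean shifts.
#' @param channel_names channel names, default `ch1..chp`.
#' @param dirichlet_conc Dirichlet concentration; larger means weights
#'   closer to the expected fractions. The default 5000 keeps weight wiggle
#'   below about one percentage point (sd ~ sqrt(f(1-f)/conc)).
#' @param seed optional RNG seed; omit to draw from the current RNG stream
#'   (used by the cohort generators, which seed once).
#' @return List with `events` (an [event_matrix()]), `assignments` (true
#'   population index per cell, indexing `populations`), and `present`
#'   (logical per population).
#' @export
simulate_sample <- function(populations, n_cells, sample_id = "sim",
                            shifts = NULL, channel_names = NULL,
                            dirichlet_conc = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- length(populations)
  p <- length(populations[[1L]]$mean)
  if (is.null(shifts)) shifts <- matrix(0, p, np)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(p))
  probs <- vapply(populations, `[[`, numeric(1L), "presence_prob")
  repeat {
    present <- stats::runif(np) <= probs
    if (any(present)) break
    message("sample '", sample_id, "' drew no populations; resampling")
  }
  idx <- which(present)
  frac <- vapply(populations[idx], `[[`, numeric(1L), "fraction")
  frac <- frac / sum(frac)
  alpha <- frac * dirichlet_conc
  g <- stats::rgamma(length(alpha), shape = alpha)
  w <- g / sum(g)
  counts <- as.vector(stats::rmultinom(1L, n_cells, w))
  values <- matrix(0, n_cells, p)
  assignments <- integer(n_cells)
  row <- 0L
  for (m in seq_along(idx)) {
    if (counts[m] == 0L) next
    pop <- populations[[idx[m]]]
    cells <- MASS::mvrnorm(counts[m], pop$mean + shifts[, idx[m]],
                           pop$covariance)
    cells <- matrix(cells, ncol = p)
    values[row + seq_len(counts[m]), ] <- cells
    assignments[row + seq_len(counts[m])] <- idx[m]
    row <- row + counts[m]
  }
  list(events = event_matrix(values, channel_names, sample_id),
       assignments = assignments, present = present)
}

#' Simulate a healthy-donor style cohort
#'
#' A nested design of subjects x days x technical replicates, with four
#' well-separated lymphocyte-like Gaussian populations in five channels.
#' Mean shifts are drawn per population at each level of the hierarchy, with
#' `subject_sd >> day_sd >> replicate_sd` by default so that between-subject
#' variation dominates and the subject grouping is recoverable from the
#' template tree.
#'
#' @param n_subjects,n_days,n_replicates design counts (default 5 x 1 x 5 =
#'   25 samples).
#' @param n_cells cells per sample, default 2000.
#' @param subject_sd,day_sd,replicate_sd mean-shift standard deviations per
#'   hierarchy level (defaults 2, 0.5, 0.1).
#' @param seed cohort seed; fixes everything.
#' @return List with `samples` (list of [event_matrix()]), `metadata`
#'   (a [cohort_metadata()] with subject/day/replicate columns;
#'   `class_label` is the subject), `assignments` (true per-cell population
#'   indices per sample) and `populations`.
#' @export
simulate_hd_cohort <- function(n_subjects = 5L, n_days = 1L,
                               n_replicates = 5L, n_cells = 2000L,
                               subject_sd = 2, day_sd = 0.5,
                               replicate_sd = 0.1, seed = 1L) {
  set.seed(seed)
  pops <- hd_populations()
  np <- length(pops)
  p <- length(pops[[1L]]$mean)
  subjects <- LETTERS[seq_len(n_subjects)]
  samples <- list()
  assignments <- list()
  meta <- list()
  for (s in seq_len(n_subjects)) {
    subject_shift <- matrix(stats::rnorm(p * np, sd = subject_sd), p, np)
    for (d in seq_len(n_days)) {
      day_shift <- matrix(stats::rnorm(p * np, sd = day_sd), p, np)
      for (r in seq_len(n_replicates)) {
        rep_shift <- matrix(stats::rnorm(p * np, sd = replicate_sd), p, np)
        sid <- sprintf("%s_d%d_r%d", subjects[s], d, r)
        sim <- simulate_sample(pops, n_cells, sid,
                               shifts = subject_shift + day_shift +
                                 rep_shift,
                               channel_names = hd_channels)
        samples[[sid]] <- sim$events
        assignments[[sid]] <- sim$assignments
        meta[[sid]] <- data.frame(sample_id = sid,
                                  class_label = subjects[s],
                                  subject = subjects[s],
                                  day = as.character(d),
                                  replicate = as.character(r),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  class(md) <- c("cohort_metadata", "data.frame")
  list(samples = samples, metadata = md, assignments = assignments,
       populations = pops)
}

#' Simulate a two-class disease cohort with planted blast populations
#'
#' Both classes share the four lymphocyte-like populations; every positive
#' sample additionally carries a blast-like population, at an abundance
#' drawn uniformly from `blast_range` (default 20-60% of cells), placed at
#' least 5 pooled-sd away from all shared populations. Positive samples are
#' given twice the between-sample mean-shift spread of negatives, mirroring
#' the greater heterogeneity of diseased cohorts. A stratified train/test
#' split is returned.
#'
#' @param n_neg,n_pos class sizes (defaults 200 and 30).
#' @param n_cells cells per sample, default 1000.
#' @param blast_range abundance range of the planted population.
#' @param neg_shift_sd,pos_shift_sd per-population between-sample shift
#'   standard deviations (defaults 0.3 and 0.6).
#' @param blast_presence probability a positive sample carries the blast
#'   population (default 1).
#' @param train_frac fraction of each class assigned to the training split.
#' @param seed cohort seed.
#' @return List with `samples`, `metadata` (columns `sample_id`,
#'   `class_label` in `"positive"`/`"negative"`, `split` in
#'   `"train"`/`"test"`), `assignments`, `populations` (shared then blast;
#'   the blast population index is `length(populations)`).
#' @export
simulate_disease_cohort <- function(n_neg = 200L, n_pos = 30L,
                                    n_cells = 1000L,
                                    blast_range = c(0.2, 0.6),
                                    neg_shift_sd = 0.3, pos_shift_sd = 0.6,
                                    blast_presence = 1, train_frac = 0.5,
                                    seed = 1L) {
  set.seed(seed)
  shared <- hd_populations()
  np_shared <- length(shared)
  p <- length(shared[[1L]]$mean)
  samples <- list()
  assignments <- list()
  meta <- list()
  draw <- function(sid, positive) {
    sd_here <- if (positive) pos_shift_sd else neg_shift_sd
    if (positive) {
      bf <- stats::runif(1L, blast_range[1L], blast_range[2L])
      pops <- lapply(shared, function(sp) {
        sp$fraction <- sp$fraction * (1 - bf)
        sp
      })
      pops <- c(pops, list({
        b <- blast_population(bf)
        b$presence_prob <- blast_presence
        b
      }))
    } else {
      pops <- shared
    }
    shifts <- matrix(stats::rnorm(p * length(pops), sd = sd_here), p,
                     length(pops))
    simulate_sample(pops, n_cells, sid, shifts = shifts,
                    channel_names = hd_channels)
  }
  for (i in seq_len(n_neg)) {
    sid <- sprintf("neg%03d", i)
    sim <- draw(sid, FALSE)
    samples[[sid]] <- sim$events
    assignments[[sid]] <- sim$assignments
    meta[[sid]] <- data.frame(sample_id = sid, class_label = "negative",
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_pos)) {
    sid <- sprintf("pos%03d", i)
    sim <- draw(sid, TRUE)
    samples[[sid]] <- sim$events
    assignments[[sid]] <- sim$assignments
    meta[[sid]] <- data.frame(sample_id = sid, class_label = "positive",
                              stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  md$split <- "test"
  for (lab in c("negative", "positive")) {
    idx <- which(md$class_label == lab)
    n_train <- round(length(idx) * train_frac)
    md$split[sample(idx, n_train)] <- "train"
  }
  class(md) <- c("cohort_metadata", "data.frame")
  list(samples = samples, metadata = md, assignments = assignments,
       populations = c(shared, list(blast_population())))
}
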