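#' Spillover matrix for spectral unmixing
#'
#' Column `j` of the spillover matrix holds the fractional contribution of
#' fluorochrome `j` to each detector; each column must sum to one.
#'
#' @param M square numeric matrix (p x p).
#' @param channel_names channel names; defaults to `colnames(M)`.
#' @return An object of class `spillover_matrix`.
#' @export
spillover_matrix <- function(M, channel_names = colnames(M)) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("spillover matrix must be square")
  if (is.null(channel_names))
    stop("spillover matrix needs channel names")
  if (any(abs(colSums(M) - 1) > 1e-6))
    stop("each spillover column must sum to 1 (tolerance 1e-6)")
  if (!is.finite(kappa(M)) || kappa(M) > 1e8)
    stop("spillover matrix is singular or ill-conditioned; ",
         "repair it before unmixing")
  dimnames(M) <- list(channel_names, channel_names)
  structure(M, class = c("spillover_matrix", "matrix", "array"))
}

#' Compensate spectral spillover
#'
#' Recovers per-cell signals `s` from observations `o = M s` by solving the
#' linear system with the spillover matrix (the additive noise term is
#' ignored, the simplest and most widely used unmixing scheme). Channels not
#' named in the spillover matrix pass through untouched.
#'
#' @param events an [event_matrix()].
#' @param spill a [spillover_matrix()] whose channels are a subset of the
#'   event matrix channels.
#' @return A compensated [event_matrix()].
#' @export
compensate <- function(events, spill) {
  ch <- colnames(spill)
  missing <- setdiff(ch, colnames(events))
  if (length(missing))
    stop("spillover channels absent from sample: ",
         paste(missing, collapse = ", "))
  k <- kappa(unclass(spill))
  if (!is.finite(k) || k > 1e8)
    stop("spillover matrix is ill-conditioned (kappa = ", format(k),
         "); repair it before unmixing")
  out <- unclass(events)
  out[, ch] <- t(solve(unclass(spill), t(out[, ch, drop = FALSE])))
  event_matrix(out, colnames(events), sample_id(events))
}

#' Remove boundary events by total fluorescence
#'
#' Drops cells whose summed signal over the given channels falls outside
#' `[low, high]`; very dim cells are likely debris, very bright ones doublets
#' or instrument noise.
#'
#' @param events an [event_matrix()].
#' @param low,high thresholds on per-cell total signal, `low < high`.
#' @param channels channels summed to form the total; default all.
#' @return Filtered [event_matrix()] with attribute `removed`, an integer
#'   vector `c(low = , high = )` of counts removed at each end.
#' @export
filter_boundary <- function(events, low, high, channels = colnames(events)) {
  if (!(low < high)) stop("'low' must be smaller than 'high'")
  totals <- rowSums(unclass(events)[, channels, drop = FALSE])
  keep <- totals >= low & totals <= high
  if (!any(keep))
    stop("boundary filter removed every cell; widen the thresholds")
  out <- events[keep, , drop = FALSE]
  attr(out, "removed") <- c(low = sum(totals < low), high = sum(totals > high))
  out
}

#' Per-channel asinh transformation
#'
#' Applies `asinh(z / c)` to each channel with channel-specific cofactor `c`.
#' The transform is strictly monotone and invertible (`c * sinh(y)` maps
#' back).
#'
#' @param events an [event_matrix()].
#' @param cofactors positive numeric: a single value used for every channel,
#'   or a named vector giving cofactors for a subset of channels (others are
#'   left untransformed).
#' @return Transformed [event_matrix()].
#' @export
asinh_transform <- function(events, cofactors) {
  if (any(cofactors <= 0) || anyNA(cofactors))
    stop("cofactors must be positive")
  out <- unclass(events)
  if (is.null(names(cofactors))) {
    if (length(cofactors) == 1L)
      cofactors <- stats::setNames(rep(cofactors, ncol(out)), colnames(out))
    else if (length(cofactors) == ncol(out))
      names(cofactors) <- colnames(out)
    else
      stop("unnamed 'cofactors' must have length 1 or ncol(events)")
  }
  missing <- setdiff(names(cofactors), colnames(out))
  if (length(missing))
    stop("unknown channels in 'cofactors': ", paste(missing, collapse = ", "))
  for (ch in names(cofactors))
    out[, ch] <- asinh(out[, ch] / cofactors[[ch]])
  event_matrix(out, colnames(events), sample_id(events))
}

#' One-dimensional density-peak clustering
#'
#' Finds modes of a kernel density estimate (Silverman bandwidth) of a single
#' channel and assigns every value to its nearest enclosing peak, cutting at
#' the density valleys between retained peaks. Peaks must reach at least
#' `floor` of the global density maximum and stand out from their
#' surrounding valleys by at least `prominence` of it; both knobs suppress
#' noise modes.
#'
#' @param values numeric vector of (transformed) intensities. Fewer than 50
#'   values, or a constant vector, yield a single peak spanning everything.
#' @param floor,prominence fractions of the maximum density (defaults 0.05).
#' @return A list of class `peak_clustering_1d` with `peak_locations`
#'   (ascending), `assignments`, per-peak `variances` and `sizes`.
#' @export
find_density_peaks_1d <- function(values, floor = 0.05, prominence = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  one_peak <- function() {
    v <- if (n > 1L) stats::var(values) else 0
    structure(list(peak_locations = mean(values),
                   assignments = rep(1L, n),
                   variances = if (is.finite(v)) v else 0,
                   sizes = n),
              class = "peak_clustering_1d")
  }
  if (n < 50L || stats::sd(values) == 0) return(one_peak())
  d <- stats::density(values, bw = "nrd0", n = 512L)
  y <- d$y
  ymax <- max(y)
  m <- length(y)
  is_max <- c(FALSE, y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
              FALSE)
  peaks <- which(is_max & y >= floor * ymax)
  if (!length(peaks)) return(one_peak())
  # iteratively drop the least prominent peak until all stand out
  repeat {
    if (length(peaks) == 1L) break
    prom <- vapply(seq_along(peaks), function(i) {
      left <- if (i == 1L) min(y[1:peaks[1L]]) else
        min(y[peaks[i - 1L]:peaks[i]])
      right <- if (i == length(peaks)) min(y[peaks[i]:m]) else
        min(y[peaks[i]:peaks[i + 1L]])
      y[peaks[i]] - max(left, right)
    }, numeric(1L))
    worst <- which.min(prom)
    if (prom[worst] >= prominence * ymax) break
    peaks <- peaks[-worst]
  }
  if (length(peaks) == 1L) {
    out <- one_peak()
    out$peak_locations <- d$x[peaks]
    return(out)
  }
  # valley between adjacent peaks = assignment boundary
  cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    d$x[seg[which.min(y[seg])]]
  }, numeric(1L))
  assignments <- findInterval(values, cuts) + 1L
  sizes <- tabulate(assignments, nbins = length(peaks))
  # drop empty peaks (possible when a mode sits outside the data range)
  keep <- sizes > 0L
  if (!all(keep)) {
    relabel <- cumsum(keep)
    assignments <- relabel[assignments]
    peaks <- peaks[keep]
    sizes <- sizes[keep]
  }
  variances <- vapply(seq_along(peaks), function(i) {
    v <- values[assignments == i]
    if (length(v) > 1L) stats::var(v) else 0
  }, numeric(1L))
  structure(list(peak_locations = d$x[peaks], assignments = assignments,
                 variances = variances, sizes = sizes),
            class = "peak_clustering_1d")
}

#' Bartlett's statistic for homogeneity of variances
#'
#' The likelihood-ratio statistic
#' \deqn{\chi^2 = \frac{(N-m)\ln s_p^2 - \sum_i (n_i-1)\ln\sigma_i^2}{C}}
#' with pooled variance \eqn{s_p^2 = \sum_i (n_i-1)\sigma_i^2 / (N-m)} and
#' the usual correction
#' \eqn{C = 1 + \frac{1}{3(m-1)}\left(\sum_i \frac{1}{n_i-1} -
#' \frac{1}{N-m}\right)}. Zero for equal variances; grows with
#' heteroscedasticity.
#'
#' @param variances per-group sample variances (zero-variance groups are
#'   dropped with a warning).
#' @param sizes per-group counts, each at least 2.
#' @return Non-negative scalar; 0 (with a warning) when fewer than two usable
#'   groups remain.
#' @export
bartlett_statistic <- function(variances, sizes) {
  if (length(variances) != length(sizes))
    stop("'variances' and 'sizes' must have equal length")
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  keep <- variances > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance group(s) dropped from Bartlett pool")
    variances <- variances[keep]
    sizes <- sizes[keep]
  }
  m <- length(variances)
  if (m < 2L) {
    warning("fewer than 2 groups; homoscedasticity trivially satisfied")
    return(0)
  }
  nm1 <- sizes - 1
  N <- sum(sizes)
  sp2 <- sum(nm1 * variances) / (N - m)
  C <- 1 + (sum(1 / nm1) - 1 / (N - m)) / (3 * (m - 1))
  stat <- ((N - m) * log(sp2) - sum(nm1 * log(variances))) / C
  max(stat, 0)
}

#' Default log-spaced cofactor grid
#'
#' @param from,to grid range (positive), defaults 1 to 1e5.
#' @param n number of points, default 30.
#' @return Ascending numeric vector.
#' @export
cofactor_grid <- function(from = 1, to = 1e5, n = 30L) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  exp(seq(log(from), log(to), length.out = n))
}

#' Select a variance-stabilizing cofactor for one channel
#'
#' For each candidate cofactor `c` the channel is transformed with
#' `asinh(z/c)` in every sample, one-dimensional density peaks are located
#' per sample, the peak variances and sizes from all samples are pooled into
#' a single list, and Bartlett's statistic of the pool is computed. The
#' returned cofactor minimizes the statistic (ties go to the smallest
#' cofactor); the same cofactor is meant to be applied to this channel in
#' every sample.
#'
#' @param samples list of [event_matrix()] objects sharing `channel`.
#' @param channel channel name.
#' @param grid candidate cofactors, see [cofactor_grid()].
#' @param ... passed to [find_density_peaks_1d()].
#' @return A list of class `cofactor_profile` with `grid`, `bartlett_values`,
#'   `n_peaks` (pooled peak count per candidate, candidates with < 2 pooled
#'   peaks score 0 and are flagged in `degenerate`), and `best_cofactor`.
#' @export
select_cofactor <- function(samples, channel, grid = cofactor_grid(), ...) {
  if (!length(grid)) stop("empty cofactor grid")
  if (!is.list(samples)) samples <- list(samples)
  for (s in samples)
    if (!channel %in% colnames(s))
      stop("channel '", channel, "' missing from sample ", sample_id(s))
  grid <- sort(as.numeric(grid))
  vals <- lapply(samples, function(s) unclass(s)[, channel])
  stats_out <- numeric(length(grid))
  n_peaks <- integer(length(grid))
  for (g in seq_along(grid)) {
    pooled_var <- numeric(0)
    pooled_n <- integer(0)
    for (v in vals) {
      pk <- find_density_peaks_1d(asinh(v / grid[g]), ...)
      usable <- pk$sizes >= 2L
      pooled_var <- c(pooled_var, pk$variances[usable])
      pooled_n <- c(pooled_n, pk$sizes[usable])
    }
    pos <- pooled_var > 0
    n_peaks[g] <- sum(pos)
    stats_out[g] <- if (n_peaks[g] < 2L) 0 else
      suppressWarnings(bartlett_statistic(pooled_var[pos], pooled_n[pos]))
  }
  best <- grid[which.min(stats_out)]
  structure(list(grid = grid, bartlett_values = stats_out,
                 n_peaks = n_peaks, degenerate = n_peaks < 2L,
                 best_cofactor = best),
            class = "cofactor_profile")
}

#' @export
print.cofactor_profile <- function(x, ...) {
  cat(sprintf("cofactor profile over %d candidates in [%.3g, %.3g]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("best cofactor %.4g (Bartlett %.4g)\n", x$best_cofactor,
              x$bartlett_values[which.min(x$bartlett_values)]))
  invisible(x)
}
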