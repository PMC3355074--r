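# Window methylome construction from per-CpG bisulfite observations.
#
# The unit of analysis is the CpG sampling event: one read observation of one
# CpG. A window's methylation level is the ratio of methylated events to total
# events over all CpGs sampled in the window; windows offering too few events
# carry no usable level and are flagged invalid.

#' Build a window methylome from per-CpG bisulfite observations
#'
#' Aggregates per-CpG sampling events into per-window totals and levels.
#' Windows with fewer than `min_events` CpG sampling events are marked invalid
#' (the default 20 guards against low-mappability windows); when per-window
#' read counts are supplied, windows under `min_reads` are also invalidated
#' (set both to 100 for the deep-coverage variant). Windows excluded by the
#' grid (gap windows) are always invalid.
#'
#' @param obs tibble of CpG observations: `chrom`, `pos` (0-based cytosine
#'   position), `n_meth`, `n_total`.
#' @param grid a `window_grid` from [partition_genome()].
#' @param min_events minimum CpG sampling events for a valid window.
#' @param min_reads minimum mapped reads (only enforced when `window_reads`
#'   is given).
#' @param window_reads optional tibble (`window_id`, `reads`) of mapped-read
#'   counts per window.
#' @return a `window_methylome` tibble: the grid columns plus `events`,
#'   `meth_events`, `level`, `reads`, `valid`. Observations falling outside
#'   every window are counted in the `n_outside` attribute.
#' @export
build_window_methylome <- function(obs, grid, min_events = 20, min_reads = 0,
                                   window_reads = NULL) {
  stopifnot(all(c("chrom", "pos", "n_meth", "n_total") %in% names(obs)))
  if (min_events < 1) abort("min_events must be >= 1")
  if (nrow(obs) > 0 && (any(obs$n_meth < 0) || any(obs$n_meth > obs$n_total) ||
                        any(obs$n_total < 1))) {
    abort("observations must satisfy 0 <= n_meth <= n_total, n_total >= 1")
  }
  ws <- grid_window_size(grid)
  wstart <- floor(obs$pos / ws) * ws
  m <- match(paste(obs$chrom, wstart), paste(grid$chrom, grid$start))
  n_outside <- sum(is.na(m))
  if (n_outside > 0) {
    warn(sprintf("%d observation(s) fall outside every window; ignored", n_outside))
  }
  keep <- !is.na(m)
  sums <- tibble(window_id = grid$window_id[m[keep]],
                 n_meth = obs$n_meth[keep], n_total = obs$n_total[keep]) |>
    group_by(.data$window_id) |>
    summarise(events = sum(.data$n_total), meth_events = sum(.data$n_meth))

  out <- grid
  out$events <- 0
  out$meth_events <- 0
  i <- match(sums$window_id, out$window_id)
  out$events[i] <- sums$events
  out$meth_events[i] <- sums$meth_events
  out$reads <- NA_real_
  if (!is.null(window_reads)) {
    out$reads <- 0
    j <- match(window_reads$window_id, out$window_id)
    out$reads[j] <- window_reads$reads
  }
  out$valid <- !out$excluded & out$events >= min_events
  if (!is.null(window_reads)) out$valid <- out$valid & out$reads >= min_reads
  out$level <- ifelse(out$valid, out$meth_events / pmax(out$events, 1), NA_real_)
  attr(out, "n_outside") <- n_outside
  attr(out, "min_events") <- min_events
  class(out) <- unique(c("window_methylome", class(out)))
  out
}

#' Average two replicate window methylomes
#'
#' Produces the consensus methylome as the unweighted mean of the two window
#' levels; a window is valid only where both replicates are valid. Events are
#' summed for bookkeeping (the averaged level is deliberately not re-derived
#' from pooled counts, so each replicate contributes equally regardless of its
#' coverage).
#'
#' @param a,b `window_methylome` objects on the same grid.
#' @return a `window_methylome` tibble.
#' @export
average_methylomes <- function(a, b) {
  if (!identical(paste(a$chrom, a$start, a$end), paste(b$chrom, b$start, b$end))) {
    abort("methylomes are not on the same window grid")
  }
  out <- a
  out$valid <- a$valid & b$valid
  out$level <- ifelse(out$valid, (a$level + b$level) / 2, NA_real_)
  out$events <- a$events + b$events
  out$meth_events <- a$meth_events + b$meth_events
  out$reads <- a$reads + b$reads
  out
}

#' Call methylation deserts
#'
#' Methylation deserts are the windows in the lowest `percentile` of the
#' methylation-level distribution over valid windows (operationally: windows
#' whose level is at or below the empirical percentile cutoff; ties at the
#' cutoff are all included, so the call set can exceed the nominal fraction by
#' the tied windows).
#'
#' @param m a `window_methylome`.
#' @param percentile desert fraction (default 0.01; 0.05 is the relaxed
#'   variant).
#' @return tibble of desert windows (grid columns + `level`), with attributes
#'   `level_cutoff`, `percentile`, and `degenerate` (TRUE when every valid
#'   window is tied at the cutoff).
#' @export
call_deserts <- function(m, percentile = 0.01) {
  if (percentile <= 0 || percentile >= 1) abort("percentile must be in (0, 1)")
  valid <- m[m$valid, ]
  if (nrow(valid) == 0) abort("no valid windows")
  k <- max(1L, floor(percentile * nrow(valid)))
  cutoff <- sort(valid$level)[k]
  deserts <- valid[valid$level <= cutoff, ]
  out <- as_tibble(deserts)
  attr(out, "level_cutoff") <- cutoff
  attr(out, "percentile") <- percentile
  attr(out, "degenerate") <- nrow(deserts) == nrow(valid)
  if (nrow(deserts) == nrow(valid)) {
    warn("all valid windows tied at the desert cutoff (degenerate call set)")
  }
  out
}

#' Per-window accuracy of methylation-level estimates
#'
#' Computes, for every valid window, the two-sided Clopper-Pearson binomial
#' confidence interval for the methylation level given the window's methylated
#' and total CpG sampling events. A window "passes" when the interval
#' half-width relative to the point estimate is at most `error_bound`
#' (absolute half-width when the estimate is 0, where relative error is
#' undefined).
#'
#' @param m a `window_methylome`.
#' @param error_bound maximum tolerated (relative) half-width, e.g. 0.10.
#' @param confidence confidence level for the interval, e.g. 0.95.
#' @return tibble over valid windows: `window_id`, `events`, `meth_events`,
#'   `level`, `ci_lo`, `ci_hi`, `half_width`, `pass`; the fraction of valid
#'   windows passing is the `fraction_passing` attribute.
#' @export
accuracy_profile <- function(m, error_bound = 0.10, confidence = 0.95) {
  valid <- m[m$valid, ]
  if (nrow(valid) == 0) abort("no valid windows")
  x <- valid$meth_events
  n <- valid$events
  alpha <- 1 - confidence
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  half <- (hi - lo) / 2
  level <- x / n
  pass <- ifelse(level > 0, half / level <= error_bound, half <= error_bound)
  out <- tibble(window_id = valid$window_id, events = n, meth_events = x,
                level = level, ci_lo = lo, ci_hi = hi, half_width = half,
                pass = pass)
  attr(out, "fraction_passing") <- mean(pass)
  attr(out, "error_bound") <- error_bound
  attr(out, "confidence") <- confidence
  out
}

#' Write a window methylome as BED4+
#' @param m a `window_methylome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  y <- as_tibble(m)
  y$level <- ifelse(is.na(y$level), ".", format(round(y$level, 6), trim = TRUE))
  y$valid <- as.integer(y$valid)
  write_bed(y, path, extra = c("level", "events", "meth_events", "valid"))
}

#' Read a window methylome written by [write_methylome()]
#' @param path file path.
#' @return tibble with interval, `level`, `events`, `meth_events`, `valid`.
#' @export
read_methylome <- function(path) {
  x <- read_bed(path, extra_names = c("level", "events", "meth_events", "valid"))
  x$level <- suppressWarnings(as.numeric(x$level))
  x$valid <- x$valid == 1
  x
}
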