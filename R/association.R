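# Statistical layer tying methylation, LCR architecture, and structural
# variation together: two-sample KS association on window levels, size-matched
# permutation nulls, distance-decay profiles, enrichment folds, case-control
# contrasts, relative/attributable risk, and a generic permutation enrichment
# for arbitrary feature sets.

new_assoc <- function(kind, statistic, p_value, n_case, n_control,
                      estimate = NA_real_, estimate_name = NA_character_,
                      seed = NULL, n_replicates = NULL, extra = list()) {
  structure(list(kind = kind, statistic = statistic, p_value = p_value,
                 n_case = n_case, n_control = n_control, estimate = estimate,
                 estimate_name = estimate_name, seed = seed,
                 n_replicates = n_replicates, extra = extra),
            class = "nahr_assoc")
}

#' @export
print.nahr_assoc <- function(x, ...) {
  cat(sprintf("<nahr_assoc: %s>\n", x$kind))
  cat(sprintf("  statistic = %.4g, p = %.4g (n_case = %d, n_control = %d)\n",
              x$statistic, x$p_value, x$n_case, x$n_control))
  if (!is.na(x$estimate)) {
    cat(sprintf("  %s = %.4g\n", x$estimate_name, x$estimate))
  }
  if (!is.null(x$n_replicates)) {
    cat(sprintf("  replicates = %d, seed = %s\n", x$n_replicates,
                as.character(x$seed %||% NA)))
  }
  invisible(x)
}

#' Tidy an association result
#' @param x a `nahr_assoc`.
#' @param ... unused.
#' @return one-row tibble with the statistic, p-value, estimate, and sizes.
#' @export
tidy.nahr_assoc <- function(x, ...) {
  tibble(kind = x$kind, statistic = x$statistic, p_value = x$p_value,
         estimate = x$estimate, estimate_name = x$estimate_name,
         n_case = x$n_case, n_control = x$n_control)
}

#' One-row summary of an association result
#' @inheritParams tidy.nahr_assoc
#' @return one-row tibble.
#' @export
glance.nahr_assoc <- function(x, ...) {
  tibble(kind = x$kind, statistic = x$statistic, p_value = x$p_value,
         n = x$n_case + x$n_control,
         n_replicates = x$n_replicates %||% NA_integer_,
         seed = x$seed %||% NA_integer_)
}

# normalise a window label (logical vector, window_id vector, or a tibble
# with window_id / contains) to a logical aligned with the grid rows
as_window_flag <- function(grid, x) {
  if (is.logical(x)) {
    stopifnot(length(x) == nrow(grid))
    return(x)
  }
  if (is.data.frame(x)) {
    if ("contains" %in% names(x)) return(as_window_flag(grid, x$contains))
    if ("window_id" %in% names(x)) return(grid$window_id %in% x$window_id)
  }
  if (is.numeric(x)) return(grid$window_id %in% x)
  abort("cannot interpret window labels")
}

#' KS association of methylation with element-bearing windows
#'
#' Two-sample Kolmogorov-Smirnov test comparing methylation levels of valid
#' windows containing elements against the remaining valid windows.
#'
#' @param m a `window_methylome`.
#' @param element_windows output of [windows_containing()], a logical vector
#'   aligned with the grid, or a vector of window ids.
#' @return a `nahr_assoc` (kind `"KS"`) with D, p, and the direction of the
#'   shift.
#' @export
ks_methylation_association <- function(m, element_windows) {
  flag <- as_window_flag(m, element_windows)
  g1 <- m$level[m$valid & flag]
  g2 <- m$level[m$valid & !flag]
  if (length(g1) == 0 || length(g2) == 0) {
    warn("empty group: KS not computed")
    return(new_assoc("KS", NA_real_, NA_real_, length(g1), length(g2),
                     extra = list(skipped = TRUE)))
  }
  kt <- suppressWarnings(ks.test(g1, g2))
  new_assoc("KS", unname(kt$statistic), unname(kt$p.value),
            length(g1), length(g2),
            extra = list(direction = if (median(g1) <= median(g2))
              "elements_lower" else "elements_higher"))
}

#' Event-weighted methylation level of elements
#'
#' Scores each element as the event-weighted mean level of the valid windows
#' it overlaps; elements overlapping no valid window get NA (they are counted
#' in the `n_excluded` attribute by callers).
#'
#' @param elements interval tibble.
#' @param m a `window_methylome`.
#' @return numeric vector of element levels.
#' @export
element_methylation_levels <- function(elements, m) {
  ws <- grid_window_size(m)
  key <- paste(m$chrom, m$start)
  vapply(seq_len(nrow(elements)), function(i) {
    idx <- seq(floor(elements$start[i] / ws), floor((elements$end[i] - 1) / ws))
    rows <- match(paste(elements$chrom[i], idx * ws), key)
    rows <- rows[!is.na(rows)]
    rows <- rows[m$valid[rows]]
    if (length(rows) == 0) return(NA_real_)
    sum(m$level[rows] * m$events[rows]) / sum(m$events[rows])
  }, numeric(1))
}

#' Size-matched permutation association
#'
#' Compares the methylation levels of elements against levels of
#' length-matched segments drawn uniformly on the same chromosomes
#' (`n_per_element` draws per element), by two-sample KS. D quantifies the
#' fraction of elements associated with the methylation shift.
#'
#' @param elements interval tibble.
#' @param m a `window_methylome`.
#' @param n_per_element random segments per element (default 100).
#' @param seed RNG seed (recorded in the result).
#' @param gaps optional assembly gaps to avoid when sampling.
#' @return a `nahr_assoc` (kind `"KS"`); elements overlapping only invalid
#'   windows are excluded and counted in `extra$n_excluded`.
#' @export
permutation_association <- function(elements, m, n_per_element = 100,
                                    seed = NULL, gaps = NULL) {
  sizes <- attr(m, "chrom_sizes")
  if (is.null(sizes)) abort("methylome carries no chrom_sizes attribute")
  obs <- element_methylation_levels(elements, m)
  null_seg <- sample_matched_segments(elements, sizes,
                                      n_per_element = n_per_element,
                                      gaps = gaps, seed = seed)
  nul <- element_methylation_levels(null_seg, m)
  n_excl <- sum(is.na(obs))
  obs <- obs[!is.na(obs)]; nul <- nul[!is.na(nul)]
  if (length(obs) == 0 || length(nul) == 0) {
    warn("no scoreable elements")
    return(new_assoc("KS", NA_real_, NA_real_, length(obs), length(nul),
                     seed = seed, extra = list(skipped = TRUE)))
  }
  exact <- (length(obs) + length(nul)) < 50
  kt <- suppressWarnings(ks.test(obs, nul, exact = exact))
  new_assoc("KS", unname(kt$statistic), unname(kt$p.value), length(obs),
            length(nul), seed = seed, n_replicates = n_per_element,
            extra = list(n_excluded = n_excl,
                         direction = if (median(obs) <= median(nul))
                           "elements_lower" else "elements_higher"))
}

#' Distance-decay of hypomethylation around elements
#'
#' For each distance, places flanks of `flank_size` bases that far outward
#' from every element edge, scores them on the methylome, and KS-compares
#' them against flanks at the same distance from size-matched random
#' segments. A methylation effect confined to element-proximal sequence
#' yields a D that decays with distance.
#'
#' @inheritParams permutation_association
#' @param distances distances in bases (default 10-100 kb in 10 kb steps).
#' @param flank_size flank width in bases (default 10 kb).
#' @return tibble with one row per distance: `distance`, `d_max`, `p_value`,
#'   `n_case`, `n_control`.
#' @export
distance_decay <- function(elements, m, distances = seq(1e4, 1e5, by = 1e4),
                           flank_size = 1e4, n_per_element = 100,
                           seed = NULL, gaps = NULL) {
  sizes <- attr(m, "chrom_sizes")
  if (is.null(sizes)) abort("methylome carries no chrom_sizes attribute")
  null_seg <- sample_matched_segments(elements, sizes,
                                      n_per_element = n_per_element,
                                      gaps = gaps, seed = seed)
  purrr::map_dfr(distances, function(d) {
    fo <- flank_at_distance(elements, sizes, distance = d,
                            flank_size = flank_size)
    fn <- flank_at_distance(null_seg, sizes, distance = d,
                            flank_size = flank_size)
    lo <- element_methylation_levels(fo, m)
    ln <- element_methylation_levels(fn, m)
    lo <- lo[!is.na(lo)]; ln <- ln[!is.na(ln)]
    if (length(lo) == 0 || length(ln) == 0) {
      return(tibble(distance = d, d_max = NA_real_, p_value = NA_real_,
                    n_case = length(lo), n_control = length(ln)))
    }
    kt <- suppressWarnings(ks.test(lo, ln,
                                   exact = (length(lo) + length(ln)) < 50))
    tibble(distance = d, d_max = unname(kt$statistic),
           p_value = unname(kt$p.value), n_case = length(lo),
           n_control = length(ln))
  })
}

# elements flagged by stratum membership of their overlapping windows
elements_in_stratum <- function(elements, grid, stratum) {
  ws <- grid_window_size(grid)
  key <- paste(grid$chrom, grid$start)
  vapply(seq_len(nrow(elements)), function(i) {
    idx <- seq(floor(elements$start[i] / ws), floor((elements$end[i] - 1) / ws))
    rows <- match(paste(elements$chrom[i], idx * ws), key)
    rows <- rows[!is.na(rows)]
    any(stratum[rows])
  }, logical(1))
}

#' Enrichment fold of elements in a window stratum
#'
#' Fold is the fraction of elements whose windows lie in the stratum divided
#' by the fraction of valid windows in the stratum (a stratum holding 1% of
#' windows but 10% of elements is a tenfold enrichment); significance from a
#' 2x2 chi-square of element counts in/out of the stratum against window
#' counts in/out (exact binomial fallback when an expected cell is 0).
#'
#' @param elements interval tibble.
#' @param stratum_windows window labels (see [ks_methylation_association()]).
#' @param grid a `window_grid` (or `window_methylome`, whose `valid` column
#'   restricts the frame).
#' @return a `nahr_assoc` (kind `"fold"`).
#' @export
enrichment_fold <- function(elements, stratum_windows, grid) {
  stratum <- as_window_flag(grid, stratum_windows)
  valid <- if ("valid" %in% names(grid)) grid$valid else !grid$excluded
  stratum <- stratum & valid
  if (sum(stratum) == 0) abort("empty stratum")
  in_str <- elements_in_stratum(elements, grid, stratum)
  k <- sum(in_str); n_el <- length(in_str)
  s <- sum(stratum); n_w <- sum(valid)
  fold <- (k / n_el) / (s / n_w)
  tab <- matrix(c(k, n_el - k, s, n_w - s), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    p <- stats::binom.test(k, n_el, p = s / n_w)$p.value
    flagged <- TRUE; stat <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    p <- unname(ct$p.value); stat <- unname(ct$statistic); flagged <- FALSE
  }
  new_assoc("fold", statistic = stat, p_value = p, n_case = n_el,
            n_control = n_w, estimate = fold, estimate_name = "fold",
            extra = list(elements_in = k, windows_in = s,
                         exact_fallback = flagged))
}

#' Case-control enrichment in a window stratum
#'
#' 2x2 chi-square of {case, control} x {in stratum, out of stratum} element
#' counts; fold is the ratio of in-stratum proportions (Fisher's exact test
#' when a margin is zero).
#'
#' @param case_elements,control_elements interval tibbles.
#' @inheritParams enrichment_fold
#' @return a `nahr_assoc` (kind `"chisq"`).
#' @export
case_control_enrichment <- function(case_elements, control_elements,
                                    stratum_windows, grid) {
  stratum <- as_window_flag(grid, stratum_windows)
  valid <- if ("valid" %in% names(grid)) grid$valid else !grid$excluded
  stratum <- stratum & valid
  ka <- sum(elements_in_stratum(case_elements, grid, stratum))
  kb <- sum(elements_in_stratum(control_elements, grid, stratum))
  na_ <- nrow(case_elements); nb <- nrow(control_elements)
  if (na_ == 0 || nb == 0) abort("both element sets must be non-empty")
  tab <- matrix(c(ka, na_ - ka, kb, nb - kb), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- fisher.test(tab)$p.value
    stat <- NA_real_; flagged <- TRUE
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    p <- unname(ct$p.value); stat <- unname(ct$statistic); flagged <- FALSE
  }
  fold <- (ka / na_) / (kb / nb)
  new_assoc("chisq", statistic = stat, p_value = p, n_case = na_,
            n_control = nb, estimate = fold, estimate_name = "fold",
            extra = list(case_in = ka, control_in = kb,
                         exact_fallback = flagged))
}

#' Build the three-way window groups for risk analysis
#'
#' Labels every valid window by (a) whether it contains elements, (b)
#' whether it is a methylation desert, (c) whether it contains a DP-LCR
#' region.
#'
#' @param m a `window_methylome` (defines the valid-window universe).
#' @param elements element intervals.
#' @param deserts desert call set from [call_deserts()].
#' @param dp_regions DP-LCR region tibble (optional).
#' @return tibble: `window_id`, `a`, `b`, `c` over valid windows.
#' @export
window_groups <- function(m, elements, deserts, dp_regions = NULL) {
  a <- as_window_flag(m, windows_containing(elements, m))
  b <- as_window_flag(m, deserts)
  cc <- if (!is.null(dp_regions) && nrow(dp_regions) > 0) {
    as_window_flag(m, windows_containing(dp_regions, m))
  } else rep(FALSE, nrow(m))
  tibble(window_id = m$window_id, a = a, b = b, c = cc)[m$valid, ]
}

#' Statistical relative and attributable risk
#'
#' With a = element-bearing windows and e the exposure (desert windows or
#' DP-LCR windows), RR = P(a|e) / P(a|not e) and AR is the population
#' attributable fraction (P(a) - P(a|not e)) / P(a). The excess-risk variant
#' P(a|e) - P(a|not e) is reported in `extra`. P-value from the 2x2
#' chi-square of a by e.
#'
#' @param groups window groups from [window_groups()].
#' @param exposure `"b"` (methylation desert) or `"c"` (DP-LCR region).
#' @return a `nahr_assoc` pair packed in one object: `estimate` = RR,
#'   `extra$ar` = AR.
#' @export
relative_attributable_risk <- function(groups, exposure = c("b", "c")) {
  exposure <- match.arg(exposure)
  a <- groups$a
  e <- groups[[exposure]]
  if (!any(e) || all(e)) abort("exposure group empty or universal")
  p_a <- mean(a)
  p_a_e <- mean(a[e])
  p_a_ne <- mean(a[!e])
  rr <- if (p_a_ne == 0) Inf else p_a_e / p_a_ne
  if (p_a_ne == 0) warn("P(a | not e) = 0: relative risk infinite")
  ar <- if (p_a == 0) NA_real_ else (p_a - p_a_ne) / p_a
  tab <- table(factor(e, c(TRUE, FALSE)), factor(a, c(TRUE, FALSE)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_ else
    unname(suppressWarnings(chisq.test(tab, correct = FALSE))$p.value)
  new_assoc("RR", statistic = rr, p_value = p, n_case = sum(e),
            n_control = sum(!e), estimate = rr, estimate_name = "RR",
            extra = list(ar = ar, excess_risk = p_a_e - p_a_ne,
                         p_a = p_a, p_a_given_e = p_a_e,
                         p_a_given_not_e = p_a_ne, exposure = exposure))
}

#' Permutation enrichment of features in target windows
#'
#' Observed statistic: number of features overlapping any target window.
#' Null: each feature replaced by a length-matched segment placed uniformly
#' on its chromosome, `n_perm` times. Fold = observed / mean(null); p uses
#' the add-one estimator (1 + #null >= obs) / (n_perm + 1), so it is never 0.
#'
#' @param features feature intervals.
#' @param target_windows window labels over `grid`.
#' @param grid a `window_grid`.
#' @param n_perm permutation replicates (>= 100).
#' @param seed RNG seed.
#' @return a `nahr_assoc` (kind `"fold"`), null mean/sd in `extra`.
#' @export
feature_enrichment_permutation <- function(features, target_windows, grid,
                                           n_perm = 1000, seed = NULL) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  sizes <- attr(grid, "chrom_sizes")
  stratum <- as_window_flag(grid, target_windows)
  obs <- sum(elements_in_stratum(features, grid, stratum))
  null_counts <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(r) {
      seg <- sample_matched_segments(features, sizes, n_per_element = 1)
      sum(elements_in_stratum(seg, grid, stratum))
    }, numeric(1))
  })
  fold <- obs / mean(null_counts)
  p <- (1 + sum(null_counts >= obs)) / (n_perm + 1)
  new_assoc("fold", statistic = obs, p_value = p, n_case = nrow(features),
            n_control = n_perm, estimate = fold, estimate_name = "fold",
            seed = seed, n_replicates = n_perm,
            extra = list(null_mean = mean(null_counts),
                         null_sd = sd(null_counts)))
}
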