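# Structural heterozygosity: under the infinite-allele model at
# drift-mutation equilibrium, heterozygosity ratios between loci estimate
# their mutation-rate ratios. Any non-normal copy-number signal at a locus is
# read as presence of a minor structural allele; heterozygosity is 2pq.

#' Merge per-sample CNV calls into loci
#'
#' Calls overlapping across samples (or within `merge_gap` bases of each
#' other) define one locus; each locus records the samples carrying a variant
#' state there.
#'
#' @param calls CNV tibble: `sample_id`, `chrom`, `start`, `end`, `state`.
#' @param merge_gap maximum gap between calls of one locus (default 0:
#'   strict overlap).
#' @return locus tibble: `locus_id`, `chrom`, `start`, `end`, `n_calls`,
#'   `carriers` (list-column of unique carrier sample ids).
#' @export
define_loci <- function(calls, merge_gap = 0) {
  check_intervals(calls, what = "calls")
  if (nrow(calls) == 0) {
    return(tibble(locus_id = integer(), chrom = character(), start = numeric(),
                  end = numeric(), n_calls = integer(), carriers = list()))
  }
  x <- calls |> arrange(.data$chrom, .data$start, .data$end)
  x <- x |>
    group_by(.data$chrom) |>
    mutate(new_locus = c(1, (.data$start[-1] -
                               cummax(.data$end)[-dplyr::n()]) > merge_gap),
           locus_key = cumsum(.data$new_locus)) |>
    ungroup()
  x |>
    group_by(.data$chrom, .data$locus_key) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_calls = dplyr::n(),
              carriers = list(sort(unique(.data$sample_id))),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(locus_id = row_number()) |>
    select("locus_id", "chrom", "start", "end", "n_calls", "carriers")
}

# one family's carriers count once in numerator and denominator when the
# variant is shared by related samples
collapse_family_counts <- function(carriers, samples, pedigree) {
  n_total <- length(samples)
  if (is.null(pedigree)) {
    return(list(k = length(carriers), n = n_total))
  }
  fam <- setNames(pedigree$family, pedigree$sample)
  carrier_fam <- fam[carriers]
  related <- !is.na(carrier_fam)
  shared <- table(carrier_fam[related])
  extra <- sum(pmax(as.integer(shared) - 1L, 0L))
  list(k = length(carriers) - extra, n = n_total - extra)
}

#' Per-locus structural heterozygosity (2pq)
#'
#' q is the frequency of the variant (non-normal) copy-number state, p = 1-q,
#' and heterozygosity is 2pq. When a pedigree is given, a variant shared by
#' related samples (parent and child) is counted once per family — in both
#' the carrier count and the effective sample count. `verbose` adds the
#' numerator-only variant (families collapsed in the carrier count but every
#' sample kept in the denominator).
#'
#' @param loci locus tibble from [define_loci()].
#' @param samples character vector of all cohort sample ids (carriers and
#'   non-carriers).
#' @param pedigree optional tibble (`sample`, `family`, `role`); samples
#'   absent from it are unrelated.
#' @param verbose also report `q_numerator_only` / `het_numerator_only`.
#' @return the locus tibble with `n_eff`, `q`, `het` columns (plus verbose
#'   columns when requested).
#' @export
heterozygosity <- function(loci, samples, pedigree = NULL, verbose = FALSE) {
  samples <- unique(samples)
  if (length(samples) == 0) abort("no samples")
  if (!is.null(pedigree)) {
    stopifnot(all(c("sample", "family") %in% names(pedigree)))
    pedigree <- pedigree[!is.na(pedigree$family), , drop = FALSE]
  }
  counts <- purrr::map(loci$carriers, function(cc) {
    cc <- intersect(cc, samples)
    collapse_family_counts(cc, samples, pedigree)
  })
  out <- as_tibble(loci)
  out$n_eff <- purrr::map_dbl(counts, "n")
  out$q <- purrr::map_dbl(counts, "k") / out$n_eff
  out$het <- 2 * out$q * (1 - out$q)
  if (verbose) {
    out$q_numerator_only <- purrr::map_dbl(counts, "k") / length(samples)
    out$het_numerator_only <- 2 * out$q_numerator_only * (1 - out$q_numerator_only)
  }
  out
}

#' Compare heterozygosity inside vs outside methylation deserts
#'
#' Assigns each locus to the desert stratum when any window it overlaps is a
#' desert, then reports per-stratum mean and SD of heterozygosity and a
#' two-sample Kolmogorov-Smirnov test between the two distributions.
#'
#' @param loci_het output of [heterozygosity()].
#' @param deserts desert call set from [call_deserts()].
#' @param grid the `window_grid` the deserts were called on.
#' @return a `nahr_assoc` result (kind `"KS"`) whose `extra$strata` tibble
#'   holds the per-stratum summaries; an empty stratum skips the comparison
#'   with a warning.
#' @export
het_by_stratum <- function(loci_het, deserts, grid) {
  ws <- grid_window_size(grid)
  desert_key <- paste(deserts$chrom, deserts$start)
  in_desert <- vapply(seq_len(nrow(loci_het)), function(i) {
    idx <- seq(floor(loci_het$start[i] / ws), floor((loci_het$end[i] - 1) / ws))
    any(paste(loci_het$chrom[i], idx * ws) %in% desert_key)
  }, logical(1))
  strata <- tibble(stratum = c("desert", "outside"),
                   n = c(sum(in_desert), sum(!in_desert)),
                   mean_het = c(mean(loci_het$het[in_desert]),
                                mean(loci_het$het[!in_desert])),
                   sd_het = c(sd(loci_het$het[in_desert]),
                              sd(loci_het$het[!in_desert])))
  if (any(strata$n == 0)) {
    warn("empty heterozygosity stratum: KS comparison skipped")
    return(new_assoc("KS", statistic = NA_real_, p_value = NA_real_,
                     n_case = strata$n[1], n_control = strata$n[2],
                     extra = list(strata = strata, skipped = TRUE)))
  }
  kt <- suppressWarnings(ks.test(loci_het$het[in_desert],
                                 loci_het$het[!in_desert]))
  new_assoc("KS", statistic = unname(kt$statistic),
            p_value = unname(kt$p.value), n_case = strata$n[1],
            n_control = strata$n[2],
            extra = list(strata = strata,
                         direction = if (strata$mean_het[1] >= strata$mean_het[2])
                           "desert_higher" else "desert_lower"))
}

#' Read a pedigree from three-column TSV (sample, family, role)
#' @param path file path.
#' @return pedigree tibble.
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, col_names = c("sample", "family", "role"),
                  col_types = "ccc", progress = FALSE)
}
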