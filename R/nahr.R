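# NAHR signature: recurrent CNVs arising by non-allelic homologous
# recombination span essentially the whole interval between two
# directly-oriented paralogous repeats. Classifying each CNV by its geometry
# relative to the LCR architecture and tabulating whole-region vs scattered
# CNVs between paralogous vs non-paralogous flanks exposes that signature.

#' Inter-LCR regions from clustered members
#'
#' For every pair of consecutive LCR members along a chromosome with a
#' positive gap between them, emits the intervening region and records
#' whether the two flanks are paralogous (same cluster).
#'
#' @param members member tibble from [cluster_lcrs()].
#' @return tibble: `region_id`, `chrom`, `start`, `end`, `paralogous`.
#' @export
inter_lcr_regions <- function(members) {
  if (nrow(members) == 0) {
    return(tibble(region_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), paralogous = logical()))
  }
  members |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    reframe(r_start = .data$end[-dplyr::n()], r_end = .data$start[-1],
            paralogous = .data$cluster_id[-dplyr::n()] == .data$cluster_id[-1]) |>
    rename(start = "r_start", end = "r_end") |>
    filter(.data$end > .data$start) |>
    mutate(region_id = row_number()) |>
    select("region_id", "chrom", "start", "end", "paralogous")
}

#' Classify CNVs by their relationship to LCR architecture
#'
#' Precedence: a CNV overlapping two or more inter-LCR regions is `complex`;
#' a CNV overlapping exactly one inter-LCR region is `whole_*` when it covers
#' at least `whole_fraction` of the inter-LCR distance and `scattered_*`
#' otherwise, with the `*_paralogous` / `*_nonparalogous` suffix from the
#' flanks; a CNV overlapping an LCR member but no inter-LCR region is
#' `lcr_overlapping`; anything else is `unassociated`. Every CNV receives
#' exactly one category.
#'
#' @param cnvs CNV tibble: `sample_id`, `chrom`, `start`, `end`, `state`.
#' @param members member tibble from [cluster_lcrs()].
#' @param whole_fraction coverage fraction separating whole-region from
#'   scattered CNVs (default 0.40).
#' @return the CNV tibble with `category` and, for region-assigned CNVs,
#'   `region_id` and `region_coverage` columns.
#' @export
classify_cnv <- function(cnvs, members, whole_fraction = 0.40) {
  check_intervals(cnvs, what = "cnvs")
  regions <- inter_lcr_regions(members)
  n <- nrow(cnvs)
  category <- rep("unassociated", n)
  region_id <- rep(NA_integer_, n)
  region_cov <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hits <- regions[regions$chrom == cnvs$chrom[i] &
                      overlap_width(cnvs$start[i], cnvs$end[i],
                                    regions$start, regions$end) > 0, ]
    if (nrow(hits) >= 2) {
      category[i] <- "complex"
    } else if (nrow(hits) == 1) {
      cov <- overlap_width(cnvs$start[i], cnvs$end[i], hits$start, hits$end) /
        (hits$end - hits$start)
      whole <- cov >= whole_fraction
      category[i] <- paste0(if (whole) "whole_" else "scattered_",
                            if (hits$paralogous) "paralogous" else "nonparalogous")
      region_id[i] <- hits$region_id
      region_cov[i] <- cov
    } else if (nrow(members) > 0 &&
               any(members$chrom == cnvs$chrom[i] &
                   overlap_width(cnvs$start[i], cnvs$end[i],
                                 members$start, members$end) > 0)) {
      category[i] <- "lcr_overlapping"
    }
  }
  out <- as_tibble(cnvs)
  out$category <- category
  out$region_id <- region_id
  out$region_coverage <- region_cov
  out
}

#' NAHR contingency test
#'
#' Tabulates CNV counts as {paralogous, non-paralogous flanks} x
#' {whole-region, scattered} and tests the association with a Pearson
#' chi-square (no continuity correction). The fold is the odds ratio of
#' whole-vs-scattered between paralogous and non-paralogous regions — the
#' strength of the NAHR signature. Also reports the fraction of CNVs
#' attributable to NAHR (whole-region paralogous count over all CNVs and over
#' LCR-associated CNVs).
#'
#' @param classified output of [classify_cnv()] (or any data frame with a
#'   `category` column).
#' @return a `nahr_assoc` result with the 2x2 table, chi-square statistic,
#'   p-value, and odds ratio; a zero margin flags the p-value as undefined.
#' @export
nahr_contingency <- function(classified) {
  cat <- classified$category
  tab <- matrix(c(sum(cat == "whole_paralogous"),
                  sum(cat == "scattered_paralogous"),
                  sum(cat == "whole_nonparalogous"),
                  sum(cat == "scattered_nonparalogous")),
                nrow = 2, byrow = TRUE,
                dimnames = list(flanks = c("paralogous", "nonparalogous"),
                                extent = c("whole", "scattered")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warn("zero margin in NAHR contingency table: p undefined")
    stat <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- unname(ct$p.value)
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  n_lcr_assoc <- sum(cat %in% c("whole_paralogous", "scattered_paralogous",
                                "whole_nonparalogous", "scattered_nonparalogous",
                                "complex", "lcr_overlapping"))
  new_assoc("chisq", statistic = stat, p_value = p,
            n_case = sum(tab[1, ]), n_control = sum(tab[2, ]),
            estimate = or, estimate_name = "odds_ratio",
            extra = list(table = tab, degenerate = degenerate,
                         frac_nahr_all = tab[1, 1] / max(length(cat), 1),
                         frac_nahr_lcr_assoc = tab[1, 1] / max(n_lcr_assoc, 1)))
}
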