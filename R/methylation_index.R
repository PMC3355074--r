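# Germline methylation index (MI): a per-window proxy for long-term germline
# methylation built from CpG-transition SNPs. Methylated cytosines deaminate to
# thymine, so a window's excess of C/T (or G/A) SNPs inside CpG dinucleotides
# with ancestral C (or G) — mSNPs — tracks its historical germline methylation.

genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome must be named by chromosome")
    toupper(genome)
  } else {
    abort("genome must be a named character vector or DNAStringSet")
  }
}

#' Classify SNPs as methylation-associated (mSNPs)
#'
#' An mSNP is a C/T SNP whose ancestral allele is C and whose right neighbour
#' is G, or (the reverse-strand mirror) a G/A SNP whose ancestral allele is G
#' and whose left neighbour is C — i.e. a transition inside a CpG dinucleotide
#' consistent with deamination of methylcytosine. SNPs with unknown ancestral
#' allele, or at a chromosome edge where the required neighbour is missing,
#' are never mSNPs.
#'
#' @param snps tibble with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `ancestral` (one of A/C/G/T or anything else for unknown).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences (used for the flanking-base context).
#' @return logical vector, one element per SNP; the number of SNPs skipped for
#'   missing edge context is in the `n_no_context` attribute.
#' @export
classify_msnp <- function(snps, genome) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "ancestral") %in% names(snps)))
  gen <- genome_as_character(genome)
  unknown <- setdiff(unique(snps$chrom), names(gen))
  if (length(unknown) > 0) {
    abort(paste("SNPs on chromosome(s) absent from genome:",
                paste(unknown, collapse = ", ")))
  }
  chrom_len <- nchar(gen)
  pos1 <- snps$pos + 1 # 1-based for substring
  next_base <- rep(NA_character_, nrow(snps))
  prev_base <- rep(NA_character_, nrow(snps))
  has_next <- pos1 + 1 <= chrom_len[snps$chrom]
  has_prev <- pos1 - 1 >= 1
  if (any(has_next)) {
    next_base[has_next] <- substring(gen[snps$chrom[has_next]],
                                     pos1[has_next] + 1, pos1[has_next] + 1)
  }
  if (any(has_prev)) {
    prev_base[has_prev] <- substring(gen[snps$chrom[has_prev]],
                                     pos1[has_prev] - 1, pos1[has_prev] - 1)
  }
  alleles_ct <- (snps$ref == "C" & snps$alt == "T") | (snps$ref == "T" & snps$alt == "C")
  alleles_ga <- (snps$ref == "G" & snps$alt == "A") | (snps$ref == "A" & snps$alt == "G")
  plus <- alleles_ct & snps$ancestral == "C" & !is.na(next_base) & next_base == "G"
  minus <- alleles_ga & snps$ancestral == "G" & !is.na(prev_base) & prev_base == "C"
  out <- plus | minus
  needs_ctx <- (alleles_ct & snps$ancestral == "C" & !has_next) |
    (alleles_ga & snps$ancestral == "G" & !has_prev)
  attr(out, "n_no_context") <- sum(needs_ctx)
  out
}

#' Count CpG dinucleotides per window
#'
#' Counts occurrences of the CG dinucleotide in each window's reference
#' sequence. A CpG is counted once (as a dinucleotide, not per strand);
#' positions containing N never match, so gap bases are excluded.
#'
#' @param grid a `window_grid`.
#' @param genome named character vector or `DNAStringSet`.
#' @return integer vector of CpG counts aligned with the grid rows. A CpG is
#'   assigned to the window holding its C (first) base.
#' @export
count_cpgs <- function(grid, genome) {
  gen <- genome_as_character(genome)
  ws <- grid_window_size(grid)
  n_cpg <- integer(nrow(grid))
  for (chr in unique(grid$chrom)) {
    if (!chr %in% names(gen)) next
    starts <- gregexpr("CG", gen[[chr]], fixed = TRUE)[[1]]
    if (starts[1] == -1) next
    wstart <- floor((starts - 1) / ws) * ws # starts are 1-based
    tab <- table(wstart)
    m <- match(paste(chr, names(tab)), paste(grid$chrom, grid$start))
    ok <- !is.na(m)
    n_cpg[m[ok]] <- as.integer(tab)[ok]
  }
  n_cpg
}

#' Compute the germline methylation index per window
#'
#' For each window, MI is the mSNP count normalised by the product of the
#' window's CpG count and SNP count (proportional to the expected mSNP count
#' under genome-uniform methylation), rescaled so the genome-wide mean over
#' valid windows is 1. Windows without any SNP have no valid MI; MI is exactly
#' 0 iff the window has SNPs but no mSNP.
#'
#' @param grid a `window_grid`.
#' @param snps SNP tibble (`chrom`, `pos`, `ref`, `alt`, `ancestral`).
#' @param genome named character vector or `DNAStringSet`.
#' @return tibble: grid columns plus `n_snp`, `n_cpg`, `n_msnp`, `mi`,
#'   `valid`. Windows with CpGs absent but mSNPs present (inconsistent input)
#'   are invalidated.
#' @export
compute_mi <- function(grid, snps, genome) {
  ws <- grid_window_size(grid)
  out <- as_tibble(grid)
  out$n_cpg <- count_cpgs(grid, genome)
  out$n_snp <- 0L
  out$n_msnp <- 0L
  if (nrow(snps) == 0) {
    warn("empty SNP set: every window is invalid")
  } else {
    is_m <- classify_msnp(snps, genome)
    wstart <- floor(snps$pos / ws) * ws
    m <- match(paste(snps$chrom, wstart), paste(grid$chrom, grid$start))
    keep <- !is.na(m)
    cnt <- tibble(row = m[keep], msnp = is_m[keep]) |>
      group_by(.data$row) |>
      summarise(n_snp = dplyr::n(), n_msnp = sum(.data$msnp))
    out$n_snp[cnt$row] <- as.integer(cnt$n_snp)
    out$n_msnp[cnt$row] <- as.integer(cnt$n_msnp)
  }
  out$valid <- out$n_snp > 0
  # a window with SNPs but no CpG can still carry MI = 0 when it has no mSNP;
  # mSNPs without CpGs are contradictory and invalidate the window
  bad <- out$valid & out$n_cpg == 0 & out$n_msnp > 0
  out$valid[bad] <- FALSE
  raw <- ifelse(out$valid,
                ifelse(out$n_cpg == 0, 0,
                       out$n_msnp / (out$n_cpg * pmax(out$n_snp, 1))),
                NA_real_)
  mu <- mean(raw[out$valid])
  out$mi <- if (isTRUE(mu > 0)) raw / mu else raw
  class(out) <- unique(c("window_mi", class(out)))
  out
}

#' Read a SNP table from TSV (chrom, pos, ref, alt, ancestral)
#' @param path file path.
#' @return SNP tibble.
#' @export
read_snps <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "pos", "ref", "alt", "ancestral"),
                  col_types = "cdccc", progress = FALSE)
}
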