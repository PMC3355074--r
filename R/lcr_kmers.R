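# Gapped k-mer layer for genome self-comparison. The genome is cut into
# consecutive fragments; every placement of a 21 bp sampling pattern inside a
# fragment yields a 13-letter gapped k-mer. Fragment pairs sharing many k-mers
# are candidate low-copy repeat (LCR) matches. A symmetric (palindromic)
# pattern layout makes the reverse-complement k-mer computable in the same
# pass, so inverted repeats are found exactly.

#' Gapped k-mer sampling scheme
#'
#' The pattern is 21 bases long and samples 13 positions (8 unsampled). The
#' default offsets are a fixed symmetric layout so reverse-complement
#' comparisons use the same pattern; the layout is a configuration constant so
#' runs are reproducible.
#'
#' @param pattern_length pattern span in bases.
#' @param k number of sampled positions.
#' @param sampled_offsets 0-based offsets of the sampled positions within the
#'   pattern; must be symmetric (off sampled iff pattern_length-1-off sampled).
#' @param fragment_length fragment size for the self-comparison (bases).
#' @return a `kmer_scheme` list.
#' @export
kmer_scheme <- function(pattern_length = 21, k = 13,
                        sampled_offsets = c(0, 1, 2, 3, 6, 8, 10, 12, 14, 17, 18, 19, 20),
                        fragment_length = 500) {
  sampled_offsets <- sort(as.integer(sampled_offsets))
  if (length(sampled_offsets) != k) abort("need exactly k sampled offsets")
  if (max(sampled_offsets) >= pattern_length || min(sampled_offsets) < 0) {
    abort("offsets must lie within the pattern")
  }
  if (!setequal(sampled_offsets, pattern_length - 1 - sampled_offsets)) {
    abort("sampled offsets must be symmetric within the pattern")
  }
  if (4^k > .Machine$integer.max) abort("k too large for integer k-mer codes")
  structure(list(pattern_length = as.integer(pattern_length), k = as.integer(k),
                 sampled_offsets = sampled_offsets,
                 fragment_length = as.integer(fragment_length)),
            class = "kmer_scheme")
}

# integer base codes A=0 C=1 G=2 T=3, NA otherwise
.base_codes <- local({
  codes <- rep(NA_integer_, 256)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("a")] <- 0L
  codes[utf8ToInt("C")] <- 1L; codes[utf8ToInt("c")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("g")] <- 2L
  codes[utf8ToInt("T")] <- 3L; codes[utf8ToInt("t")] <- 3L
  codes
})

# forward and reverse-complement gapped k-mer codes for every 0-based pattern
# start 0..L-pattern_length on one chromosome string
kmer_codes <- function(seq_char, scheme) {
  L <- nchar(seq_char)
  np <- L - scheme$pattern_length + 1
  if (np < 1) return(list(fwd = integer(0), rc = integer(0)))
  code <- .base_codes[utf8ToInt(seq_char)]
  offs <- scheme$sampled_offsets
  k <- scheme$k
  w_hi <- as.integer(4^(k - seq_len(k)))   # most-significant-first weights
  w_lo <- as.integer(4^(seq_len(k) - 1))
  fwd <- integer(np)
  rc <- integer(np)
  for (i in seq_len(k)) {
    b <- code[seq_len(np) + offs[i]]
    fwd <- fwd + b * w_hi[i]
    rc <- rc + (3L - b) * w_lo[i] # complement read right-to-left
  }
  list(fwd = fwd, rc = rc)
}

# fragment frame over the genome: one row per fragment with a global id
fragment_frame <- function(genome, scheme) {
  gen <- genome_as_character(genome)
  fl <- scheme$fragment_length
  purrr::map2_dfr(names(gen), nchar(gen), function(chr, len) {
    n <- ceiling(len / fl)
    start <- (seq_len(n) - 1) * fl
    tibble(chrom = chr, start = start, end = pmin(start + fl, len))
  }) |>
    mutate(frag = row_number())
}

# data.table of (kmer fwd code, rc code, fragment id, pos) for every pattern
# placement fully inside a fragment; k-mers touching N are dropped
kmer_fragment_table <- function(genome, scheme) {
  gen <- genome_as_character(genome)
  frags <- fragment_frame(genome, scheme)
  fl <- scheme$fragment_length
  pl <- scheme$pattern_length
  offset <- 0L
  parts <- vector("list", length(gen))
  for (ci in seq_along(gen)) {
    chr <- names(gen)[ci]
    codes <- kmer_codes(gen[[chr]], scheme)
    np <- length(codes$fwd)
    if (np == 0) { parts[[ci]] <- NULL; next }
    pos <- seq_len(np) - 1L # 0-based pattern starts
    in_frag <- (pos %/% fl) == ((pos + pl - 1L) %/% fl)
    ok <- in_frag & !is.na(codes$fwd)
    local_frag <- pos[ok] %/% fl + 1L
    parts[[ci]] <- data.table::data.table(
      kmer = codes$fwd[ok], rck = codes$rc[ok],
      frag = local_frag + offset, pos = pos[ok])
    offset <- offset + ceiling(nchar(gen[[chr]]) / fl)
  }
  kt <- data.table::rbindlist(parts)
  attr(kt, "fragments") <- frags
  kt
}

#' Build a k-mer blacklist from high copy-number repeat annotation
#'
#' Counts every sampled gapped k-mer in the genome and tests, for each k-mer
#' occurring more than `min_freq` times inside the annotated high copy-number
#' repeats (HCRs: LINEs, SINEs, microsatellites), whether it is significantly
#' enriched in HCR sequence (2x2 chi-square of occurrence counts in/out of
#' HCRs against HCR/non-HCR base totals, Benjamini-Hochberg at
#' `fdr_threshold`). Significant, enriched k-mers are excluded from the
#' self-comparison so it does not drown in high-copy repeat hits.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param repeats HCR annotation intervals (`chrom`, `start`, `end`); empty or
#'   NULL yields an empty blacklist.
#' @param scheme a [kmer_scheme()].
#' @param min_freq minimum in-HCR k-mer frequency to be testable (default 10:
#'   a k-mer at or below it is never excluded).
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff (default 0.1).
#' @return a `kmer_blacklist` list: `excluded` (integer k-mer codes), `table`
#'   (tested k-mers with counts, chi-square p, q), `fdr_threshold`,
#'   `min_freq`.
#' @export
build_blacklist <- function(genome, repeats, scheme = kmer_scheme(),
                            min_freq = 10, fdr_threshold = 0.1) {
  empty <- function() structure(list(excluded = integer(0), table = tibble(),
                                     fdr_threshold = fdr_threshold,
                                     min_freq = min_freq),
                                class = "kmer_blacklist")
  if (is.null(repeats) || nrow(repeats) == 0) {
    warn("no repeat annotation: blacklist is empty")
    return(empty())
  }
  gen <- genome_as_character(genome)
  check_intervals(repeats, setNames(nchar(gen), names(gen)), what = "repeats")
  kt <- kmer_fragment_table(genome, scheme)
  frags <- attr(kt, "fragments")
  # absolute genomic position of each placement
  chrom_of_frag <- frags$chrom[kt$frag]
  chrom_offset <- setNames(c(0, cumsum(nchar(gen)))[seq_along(gen)], names(gen))
  abs_pos <- kt$pos
  in_hcr <- rep(FALSE, nrow(kt))
  for (chr in unique(repeats$chrom)) {
    r <- repeats[repeats$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    sel <- which(chrom_of_frag == chr)
    if (length(sel) == 0) next
    idx <- findInterval(abs_pos[sel], r$start)
    in_hcr[sel] <- idx > 0 & abs_pos[sel] < r$end[pmax(idx, 1)]
  }
  hcr_bases <- sum(repeats$end - repeats$start)
  total_bases <- sum(nchar(gen))
  out_bases <- total_bases - hcr_bases
  kt$in_hcr <- in_hcr
  counts <- kt[, list(n_hcr = sum(in_hcr), n_out = sum(!in_hcr)), by = "kmer"]
  tested <- counts[counts$n_hcr > min_freq, ]
  if (nrow(tested) == 0) return(empty())
  a <- tested$n_hcr; b <- tested$n_out
  c_ <- hcr_bases - a; d <- out_bases - b
  n <- a + b + c_ + d
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  enriched <- a / hcr_bases > b / out_bases
  excl <- tested$kmer[q < fdr_threshold & enriched]
  structure(list(excluded = sort(excl),
                 table = tibble(kmer = tested$kmer, n_hcr = a, n_out = b,
                                chisq = stat, p = p, q = q,
                                enriched = enriched,
                                excluded = tested$kmer %in% excl),
                 fdr_threshold = fdr_threshold, min_freq = min_freq),
            class = "kmer_blacklist")
}

#' Genome self-comparison by shared gapped k-mers
#'
#' Scores every fragment pair (in direct and reverse-complement orientation)
#' by the number of shared sampled k-mers, skipping blacklisted k-mers, and
#' emits pairs at or above `min_score`. Self-pairs are suppressed. The result
#' is deterministic for a fixed genome and scheme.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param scheme a [kmer_scheme()].
#' @param blacklist optional `kmer_blacklist` from [build_blacklist()].
#' @param min_score minimum shared k-mers for a pair to be reported.
#' @return tibble of matches: `frag_a`, `frag_b` (global fragment ids,
#'   a < b), `orientation` (`"direct"`/`"inverted"`), `score`; the fragment
#'   frame (id, chrom, start, end) travels in the `fragments` attribute.
#' @export
self_compare <- function(genome, scheme = kmer_scheme(), blacklist = NULL,
                         min_score = 10) {
  kt <- kmer_fragment_table(genome, scheme)
  frags <- attr(kt, "fragments")
  if (!is.null(blacklist) && length(blacklist$excluded) > 0) {
    kt <- kt[!kt$kmer %in% blacklist$excluded &
               !kt$rck %in% blacklist$excluded, ]
  }
  ft <- unique(kt[, c("kmer", "frag")])
  rt <- unique(data.table::data.table(kmer = kt$rck, frag = kt$frag))
  # direct: k-mers present in >= 2 fragments
  nk <- ft[, list(n = .N), by = "kmer"]
  multi <- nk$kmer[nk$n >= 2]
  direct <- NULL
  if (length(multi) > 0) {
    f2 <- ft[ft$kmer %in% multi, ]
    j <- merge(f2, f2, by = "kmer", allow.cartesian = TRUE)
    j <- j[j$frag.x < j$frag.y, ]
    direct <- j[, list(score = .N), by = c("frag.x", "frag.y")]
  }
  # inverted: forward k-mer of one fragment equals RC k-mer of the other
  shared <- intersect(unique(ft$kmer), unique(rt$kmer))
  inverted <- NULL
  if (length(shared) > 0) {
    ji <- merge(ft[ft$kmer %in% shared, ], rt[rt$kmer %in% shared, ],
                by = "kmer", allow.cartesian = TRUE)
    ji <- ji[ji$frag.x < ji$frag.y, ]
    inverted <- ji[, list(score = .N), by = c("frag.x", "frag.y")]
  }
  mk <- function(x, ori) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    tibble(frag_a = x$frag.x, frag_b = x$frag.y, orientation = ori,
           score = as.integer(x$score))
  }
  out <- bind_rows(mk(direct, "direct"), mk(inverted, "inverted"))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(frag_a = integer(), frag_b = integer(),
                  orientation = character(), score = integer())
  }
  out <- out |>
    filter(.data$score >= min_score) |>
    arrange(.data$orientation, .data$frag_a, .data$frag_b)
  attr(out, "fragments") <- frags
  attr(out, "scheme") <- scheme
  out
}
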