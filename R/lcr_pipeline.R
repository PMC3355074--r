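# From fragment matches to pairwise LCRs, paralog clusters, and the
# directly-oriented paralogous LCR (DP-LCR) regions susceptible to NAHR.

#' Reciprocal top-N match filter
#'
#' Keeps a fragment match (a, b) only when b is among a's top `top_n` matches
#' and a is among b's, and neither fragment's match list exceeds `max_list`
#' entries (fragments with huge lists are unresolvable repeat sinks; the list
#' size is tested before ranking). Ties at rank `top_n` are broken by score
#' descending, then partner fragment id ascending.
#'
#' @param matches match tibble from [self_compare()].
#' @param top_n rank cutoff (default 50).
#' @param max_list maximum allowed match-list size (default 1000).
#' @return filtered match tibble (same columns and attributes).
#' @export
reciprocal_filter <- function(matches, top_n = 50, max_list = 1000) {
  if (nrow(matches) == 0) return(matches)
  directed <- bind_rows(
    tibble(frag = matches$frag_a, partner = matches$frag_b,
           score = matches$score, id = seq_len(nrow(matches))),
    tibble(frag = matches$frag_b, partner = matches$frag_a,
           score = matches$score, id = seq_len(nrow(matches))))
  # a fragment's list pools both orientations; size test first, then rank
  list_size <- directed |> count(.data$frag, name = "size")
  too_big <- list_size$frag[list_size$size > max_list]
  ranked <- directed |>
    filter(!.data$frag %in% too_big) |>
    arrange(.data$frag, dplyr::desc(.data$score), .data$partner) |>
    group_by(.data$frag) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    filter(.data$rank <= top_n)
  keep_ids <- ranked |> count(.data$id) |> filter(.data$n == 2) |> pull(.data$id)
  out <- matches[sort(keep_ids), ]
  attr(out, "fragments") <- attr(matches, "fragments")
  attr(out, "scheme") <- attr(matches, "scheme")
  out
}

#' Merge fragment matches into pairwise LCR blocks
#'
#' Chains co-oriented matches whose fragments advance together: consecutive
#' fragments on side A must lie within `max_span` bases of each other and
#' their partners within `max_radius` of the chain's diagonal (direct) or
#' anti-diagonal (inverted) trajectory. A merged block is retained when its
#' summed match score divided by its side-A length exceeds `min_density`.
#'
#' @param matches filtered matches from [reciprocal_filter()] (fragment frame
#'   attached as attribute, or supplied via `fragments`).
#' @param max_span maximum gap between consecutive side-A fragments (bases).
#' @param max_radius maximum diagonal drift (bases).
#' @param min_density minimum score per side-A base.
#' @param fragments fragment frame override.
#' @return pairwise LCR tibble: `pair_id`, `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `orientation`, `score`, `density`.
#' @export
merge_fragments <- function(matches, max_span = 1000, max_radius = 250,
                            min_density = 0.05, fragments = NULL) {
  frags <- fragments %||% attr(matches, "fragments")
  if (is.null(frags)) abort("fragment frame missing")
  empty <- tibble(pair_id = integer(), chrom_a = character(), start_a = numeric(),
                  end_a = numeric(), chrom_b = character(), start_b = numeric(),
                  end_b = numeric(), orientation = character(),
                  score = numeric(), density = numeric())
  if (nrow(matches) == 0) return(empty)
  x <- matches |>
    mutate(chrom_a = frags$chrom[.data$frag_a], a_start = frags$start[.data$frag_a],
           a_end = frags$end[.data$frag_a], chrom_b = frags$chrom[.data$frag_b],
           b_start = frags$start[.data$frag_b], b_end = frags$end[.data$frag_b],
           key = if_else(.data$orientation == "direct",
                         .data$b_start - .data$a_start,
                         .data$b_start + .data$a_start))
  x <- x |>
    group_by(.data$orientation, .data$chrom_a, .data$chrom_b) |>
    arrange(.data$key, .data$a_start, .by_group = TRUE) |>
    # diagonal bands: single-linkage over sorted keys
    mutate(band = cumsum(c(1, diff(.data$key) > max_radius))) |>
    group_by(.data$band, .add = TRUE) |>
    arrange(.data$a_start, .by_group = TRUE) |>
    mutate(chain = cumsum(c(1, (.data$a_start[-1] -
                                  .data$a_end[-dplyr::n()]) >= max_span))) |>
    group_by(.data$chain, .add = TRUE)
  blocks <- x |>
    summarise(start_a = min(.data$a_start), end_a = max(.data$a_end),
              start_b = min(.data$b_start), end_b = max(.data$b_end),
              score = sum(.data$score), n_matches = dplyr::n(),
              .groups = "drop") |>
    mutate(density = .data$score / (.data$end_a - .data$start_a)) |>
    filter(.data$density > min_density) |>
    arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b) |>
    mutate(pair_id = row_number()) |>
    select("pair_id", "chrom_a", "start_a", "end_a", "chrom_b", "start_b",
           "end_b", "orientation", "score", "density")
  blocks
}

#' Alignment identity of two segments
#'
#' Affine-gap alignment identity (matches / alignment columns) over the
#' optimal local alignment of the two segments. Scoring the local alignment
#' rather than a fully global one keeps the estimate unbiased when segment
#' boundaries carry some non-homologous flank (detected LCR blocks are
#' fragment-quantized); a floor on the aligned fraction
#' (`min_aligned_frac` of the shorter segment, with the unaligned remainder
#' counted as mismatch) prevents unrelated segments from scoring high on a
#' short chance match. The second segment is reverse-complemented when
#' `orientation` is `"inverted"`. Segments longer than `max_full` bases are
#' aligned in anchored chunks (each chunk of the first sequence aligned
#' against the corresponding, margin-padded region of the second), exact for
#' substitution-only divergence and a close approximation otherwise.
#' Degenerate pairings (length ratio > 5) score 0.
#'
#' @param seq_a,seq_b character strings (DNA).
#' @param orientation `"direct"` or `"inverted"`.
#' @param max_full maximum length for a single full alignment.
#' @param chunk,margin chunk size and padding for long segments (bases).
#' @param min_aligned_frac minimum fraction of the shorter segment the
#'   alignment must span before the denominator is padded.
#' @return identity fraction in `[0, 1]`.
#' @export
compute_identity <- function(seq_a, seq_b, orientation = "direct",
                             max_full = 5000, chunk = 2000, margin = 200,
                             min_aligned_frac = 0.8) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la == 0 || lb == 0) return(0)
  if (max(la, lb) / min(la, lb) > 5) {
    warn("degenerate pairing (length ratio > 5): identity set to 0")
    return(0)
  }
  if (orientation == "inverted") {
    seq_b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_b)))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln_id <- function(p, s) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(p),
                                         Biostrings::DNAString(s),
                                         type = "local", substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    c(Biostrings::nmatch(aln), Biostrings::nchar(aln))
  }
  if (max(la, lb) <= max_full) {
    tot <- aln_id(seq_a, seq_b)
  } else {
    starts <- seq(1, la, by = chunk)
    tot <- c(0, 0)
    scale <- lb / la
    for (s in starts) {
      e <- min(s + chunk - 1, la)
      bs <- max(1, floor((s - 1) * scale) + 1 - margin)
      be <- min(lb, ceiling(e * scale) + margin)
      tot <- tot + aln_id(substring(seq_a, s, e), substring(seq_b, bs, be))
    }
  }
  tot[1] / max(tot[2], min_aligned_frac * min(la, lb))
}

#' K-mer content similarity between two pairwise LCRs
#'
#' `1 - (kmerDiff + log(1 + sizeDiff)) / kmerInBothSets`, where `kmerDiff` is
#' the size of the symmetric difference of the two k-mer sets, `sizeDiff` the
#' absolute difference of the pairs' summed segment lengths in bases, and
#' `kmerInBothSets` the intersection size (natural log). An empty
#' intersection returns `-Inf`, which never clusters.
#'
#' @param kmers_a,kmers_b k-mer code sets (integer vectors, treated as sets).
#' @param size_a,size_b summed segment lengths of the two pairs (bases).
#' @return similarity score `<= 1`.
#' @export
kmer_similarity <- function(kmers_a, kmers_b, size_a, size_b) {
  kmers_a <- unique(kmers_a); kmers_b <- unique(kmers_b)
  inter <- length(intersect(kmers_a, kmers_b))
  if (inter == 0) return(-Inf)
  kdiff <- length(kmers_a) + length(kmers_b) - 2 * inter
  1 - (kdiff + log1p(abs(size_a - size_b))) / inter
}

# k-mer set of a pairwise LCR: union over its two member segments
pair_kmer_profile <- function(pairs, genome, scheme) {
  gen <- genome_as_character(genome)
  seg_kmers <- function(chr, s, e) {
    sq <- substring(gen[[chr]], s + 1, e)
    v <- kmer_codes(sq, scheme)$fwd
    unique(v[!is.na(v)])
  }
  purrr::pmap(list(pairs$chrom_a, pairs$start_a, pairs$end_a,
                   pairs$chrom_b, pairs$start_b, pairs$end_b),
              function(ca, sa, ea, cb, sb, eb) {
                union(seg_kmers(ca, sa, ea), seg_kmers(cb, sb, eb))
              })
}

#' Cluster pairwise LCRs into paralog families
#'
#' Single-linkage connected components over two criteria: k-mer content
#' similarity at least `min_similarity` ([kmer_similarity()]) or any
#' positional overlap between member segments of different pairs. After
#' clustering, members shorter than `min_len` or with alignment identity
#' (against their own paralog) below `min_identity` are dropped; clusters
#' emptied by the filter disappear.
#'
#' @param pairs pairwise LCR tibble from [merge_fragments()], with an
#'   `identity` column (see [detect_lcrs()]).
#' @param genome named character vector or `DNAStringSet`.
#' @param scheme a [kmer_scheme()].
#' @param min_similarity k-mer similarity threshold (default 0.5).
#' @param min_len minimum member length in bases (default 1000).
#' @param min_identity minimum member identity (default 0.90).
#' @return member tibble: `cluster_id`, `pair_id`, `member` (`"a"`/`"b"`),
#'   `chrom`, `start`, `end`, `orientation`, `identity`.
#' @export
cluster_lcrs <- function(pairs, genome, scheme = kmer_scheme(),
                         min_similarity = 0.5, min_len = 1000,
                         min_identity = 0.90) {
  empty <- tibble(cluster_id = integer(), pair_id = integer(),
                  member = character(), chrom = character(), start = numeric(),
                  end = numeric(), orientation = character(),
                  identity = numeric())
  if (nrow(pairs) == 0) return(empty)
  if (!"identity" %in% names(pairs)) abort("pairs need an identity column")
  n <- nrow(pairs)
  profiles <- pair_kmer_profile(pairs, genome, scheme)
  sizes <- (pairs$end_a - pairs$start_a) + (pairs$end_b - pairs$start_b)
  members_of <- function(i) {
    tibble(chrom = c(pairs$chrom_a[i], pairs$chrom_b[i]),
           start = c(pairs$start_a[i], pairs$start_b[i]),
           end = c(pairs$end_a[i], pairs$end_b[i]))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      sim <- kmer_similarity(profiles[[i]], profiles[[j]], sizes[i], sizes[j])
      linked <- sim >= min_similarity
      if (!linked) {
        mi <- members_of(i); mj <- members_of(j)
        for (u in 1:2) for (v in 1:2) {
          if (mi$chrom[u] == mj$chrom[v] &&
              overlap_width(mi$start[u], mi$end[u], mj$start[v], mj$end[v]) > 0) {
            linked <- TRUE
          }
        }
      }
      if (linked) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster_id <- match(root, sort(unique(root)))
  members <- bind_rows(
    tibble(cluster_id = cluster_id, pair_id = pairs$pair_id, member = "a",
           chrom = pairs$chrom_a, start = pairs$start_a, end = pairs$end_a,
           orientation = pairs$orientation, identity = pairs$identity),
    tibble(cluster_id = cluster_id, pair_id = pairs$pair_id, member = "b",
           chrom = pairs$chrom_b, start = pairs$start_b, end = pairs$end_b,
           orientation = pairs$orientation, identity = pairs$identity))
  members |>
    filter(.data$end - .data$start >= min_len, .data$identity >= min_identity) |>
    arrange(.data$cluster_id, .data$chrom, .data$start)
}

#' Extract DP-LCR regions (NAHR-susceptible intervals)
#'
#' For every same-cluster pair of members on one chromosome in direct
#' orientation, with both members at least `min_size` bases, pairwise identity
#' at least `min_identity`, and separated by more than 0 and less than
#' `max_distance` bases, emits the intervening region (between the inner
#' repeat edges). Overlapping regions emitted by the same cluster are merged;
#' output is sorted.
#'
#' @param members member tibble from [cluster_lcrs()].
#' @param pairs the pairwise LCR tibble (for identities of paired members).
#' @param genome optional genome; when supplied, same-cluster member
#'   combinations that are not an original pairwise LCR are also evaluated
#'   (direct-orientation identity computed on the fly).
#' @param min_size minimum flanking-repeat size (default 10 kb).
#' @param min_identity minimum flank identity (default 0.95).
#' @param max_distance maximum inter-repeat distance (default 10 Mb).
#' @return region tibble: `chrom`, `start`, `end`, `cluster_id`,
#'   `flank_a_start`, `flank_a_end`, `flank_b_start`, `flank_b_end`,
#'   `identity`, `lcr_size`.
#' @export
find_dp_lcr_regions <- function(members, pairs, genome = NULL,
                                min_size = 1e4, min_identity = 0.95,
                                max_distance = 1e7) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  cluster_id = integer(), flank_a_start = numeric(),
                  flank_a_end = numeric(), flank_b_start = numeric(),
                  flank_b_end = numeric(), identity = numeric(),
                  lcr_size = numeric())
  if (nrow(members) == 0) return(empty)
  gen <- if (!is.null(genome)) genome_as_character(genome) else NULL
  cand <- list()
  for (cl in unique(members$cluster_id)) {
    mm <- members[members$cluster_id == cl, ]
    if (nrow(mm) < 2) next
    for (i in seq_len(nrow(mm) - 1)) for (j in seq((i + 1), nrow(mm))) {
      a <- mm[i, ]; b <- mm[j, ]
      if (a$chrom != b$chrom) next
      if (a$end - a$start < min_size || b$end - b$start < min_size) next
      lo <- if (a$start <= b$start) a else b
      hi <- if (a$start <= b$start) b else a
      gap <- hi$start - lo$end
      if (gap <= 0 || gap >= max_distance) next
      if (a$pair_id == b$pair_id) {
        if (a$orientation != "direct") next
        id <- a$identity
      } else if (!is.null(gen)) {
        sa <- substring(gen[[a$chrom]], a$start + 1, a$end)
        sb <- substring(gen[[b$chrom]], b$start + 1, b$end)
        id <- tryCatch(compute_identity(sa, sb, "direct"), warning = function(w) 0)
      } else next
      if (id < min_identity) next
      cand[[length(cand) + 1]] <- tibble(
        chrom = lo$chrom, start = lo$end, end = hi$start, cluster_id = cl,
        flank_a_start = lo$start, flank_a_end = lo$end,
        flank_b_start = hi$start, flank_b_end = hi$end, identity = id,
        lcr_size = min(a$end - a$start, b$end - b$start))
    }
  }
  if (length(cand) == 0) return(empty)
  regions <- bind_rows(cand) |> arrange(.data$cluster_id, .data$chrom, .data$start)
  # merge overlapping emissions within a cluster (redundant member pairings)
  merged <- regions |>
    group_by(.data$cluster_id, .data$chrom) |>
    mutate(grp = cumsum(c(1, .data$start[-1] >= cummax(.data$end)[-dplyr::n()]))) |>
    group_by(.data$grp, .add = TRUE) |>
    summarise(start = min(.data$start), end = max(.data$end),
              flank_a_start = .data$flank_a_start[1],
              flank_a_end = .data$flank_a_end[1],
              flank_b_start = .data$flank_b_start[which.max(.data$end)],
              flank_b_end = .data$flank_b_end[which.max(.data$end)],
              identity = max(.data$identity), lcr_size = max(.data$lcr_size),
              .groups = "drop") |>
    select(-"grp") |>
    arrange(.data$chrom, .data$start, .data$end)
  merged[c("chrom", "start", "end", "cluster_id", "flank_a_start",
           "flank_a_end", "flank_b_start", "flank_b_end", "identity",
           "lcr_size")]
}

#' Run the full LCR detection pipeline
#'
#' Genome self-comparison, reciprocal filtering, block merging, identity
#' scoring, paralog clustering, and DP-LCR region extraction in one call.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param repeats optional HCR annotation for the k-mer blacklist.
#' @param scheme a [kmer_scheme()].
#' @param min_score minimum shared k-mers per fragment pair.
#' @param top_n,max_list reciprocal filter parameters.
#' @param max_span,max_radius,min_density merge parameters.
#' @param min_similarity,min_len,min_identity clustering parameters.
#' @param dp_min_size,dp_min_identity,dp_max_distance DP-LCR criteria.
#' @return an `lcr_result` list: `pairs` (pairwise LCRs with identity),
#'   `members` (clustered, filtered members), `dp_regions`, `blacklist`.
#' @export
detect_lcrs <- function(genome, repeats = NULL, scheme = kmer_scheme(),
                        min_score = 10, top_n = 50, max_list = 1000,
                        max_span = 1000, max_radius = 250, min_density = 0.05,
                        min_similarity = 0.5, min_len = 1000,
                        min_identity = 0.90, dp_min_size = 1e4,
                        dp_min_identity = 0.95, dp_max_distance = 1e7) {
  gen <- genome_as_character(genome)
  blacklist <- if (!is.null(repeats) && nrow(repeats) > 0) {
    build_blacklist(gen, repeats, scheme)
  } else NULL
  matches <- self_compare(gen, scheme, blacklist, min_score = min_score)
  filtered <- reciprocal_filter(matches, top_n = top_n, max_list = max_list)
  pairs <- merge_fragments(filtered, max_span = max_span,
                           max_radius = max_radius, min_density = min_density)
  if (nrow(pairs) > 0) {
    pairs$identity <- purrr::pmap_dbl(
      list(pairs$chrom_a, pairs$start_a, pairs$end_a, pairs$chrom_b,
           pairs$start_b, pairs$end_b, pairs$orientation),
      function(ca, sa, ea, cb, sb, eb, ori) {
        suppressWarnings(compute_identity(
          substring(gen[[ca]], sa + 1, ea), substring(gen[[cb]], sb + 1, eb),
          orientation = ori))
      })
  } else pairs$identity <- numeric(0)
  members <- cluster_lcrs(pairs, gen, scheme, min_similarity = min_similarity,
                          min_len = min_len, min_identity = min_identity)
  dp <- find_dp_lcr_regions(members, pairs, genome = gen,
                            min_size = dp_min_size,
                            min_identity = dp_min_identity,
                            max_distance = dp_max_distance)
  structure(list(pairs = pairs, members = members, dp_regions = dp,
                 blacklist = blacklist, scheme = scheme),
            class = "lcr_result")
}
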