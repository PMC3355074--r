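# k-mer self-comparison, reciprocal filtering, merging, clustering, identity,
# and DP-LCR extraction — small planted genomes throughout.

test_that("kmer scheme validates its layout", {
  s <- kmer_scheme()
  expect_equal(s$pattern_length, 21L)
  expect_equal(length(s$sampled_offsets), 13L)
  expect_error(kmer_scheme(sampled_offsets = 0:12), "symmetric")
  expect_error(kmer_scheme(sampled_offsets = c(0:11, 25)), "within")
})

test_that("identical fragments score all shared sampled k-mers, direct orientation", {
  withr::with_seed(101, {
    frag <- random_dna(500)
    gen <- c(chr1 = paste0(frag, frag))
    m <- self_compare(gen, min_score = 1)
    direct <- m[m$orientation == "direct", ]
    expect_equal(nrow(direct), 1)
    expect_equal(direct$frag_a, 1L)
    expect_equal(direct$frag_b, 2L)
    # oracle: distinct sampled k-mer strings shared by the two copies
    expect_equal(direct$score, length(unique(oracle_sampled_kmers(frag))))
  })
})

test_that("a fragment and its reverse complement score identically, inverted", {
  withr::with_seed(102, {
    frag <- random_dna(500)
    gen_inv <- c(chr1 = paste0(frag, revcomp(frag)))
    m <- self_compare(gen_inv, min_score = 1)
    inv <- m[m$orientation == "inverted", ]
    expect_equal(nrow(inv), 1)
    expect_equal(inv$score, length(unique(oracle_sampled_kmers(frag))))
  })
})

test_that("diverged fragments score what brute-force placement comparison predicts", {
  withr::with_seed(103, {
    frag <- random_dna(500)
    mut <- mutate_dna(frag, 0.10)$seq
    gen <- c(chr1 = paste0(frag, mut))
    m <- self_compare(gen, min_score = 1)
    got <- m$score[m$orientation == "direct"]
    # oracle: count shared distinct sampled strings between the two copies
    want <- length(intersect(unique(oracle_sampled_kmers(frag)),
                             unique(oracle_sampled_kmers(mut))))
    expect_equal(got, want)
    # and the analytic expectation 480 * 0.9^13 is within 3 sigma
    expl <- 480 * 0.9^13
    expect_lt(abs(got - expl), 3 * sqrt(480 * 0.9^13 * (1 - 0.9^13)) + 20)
  })
})

test_that("k-mers containing N are never hashed", {
  withr::with_seed(104, {
    frag <- random_dna(500)
    with_n <- paste0(substring(frag, 1, 250), "N", substring(frag, 252, 500))
    gen <- c(chr1 = paste0(frag, with_n))
    m <- self_compare(gen, min_score = 1)
    full <- length(unique(oracle_sampled_kmers(frag)))
    expect_lt(m$score[m$orientation == "direct"], full)
  })
})

test_that("blacklisted k-mers are skipped; HCR frequency <= 10 is never excluded", {
  withr::with_seed(105, {
    core <- random_dna(600)
    # high-copy tract: same 100-mer repeated 30 times
    unit <- random_dna(100)
    hcr <- strrep(unit, 30)
    gen <- c(chr1 = paste0(core, hcr, core))
    repeats <- tibble::tibble(chrom = "chr1", start = 600, end = 600 + 3000)
    bl <- build_blacklist(gen, repeats)
    expect_gt(length(bl$excluded), 0)
    # every excluded k-mer passed the frequency and enrichment gates
    expect_true(all(bl$table$n_hcr[bl$table$excluded] > 10))
    expect_true(all(bl$table$enriched[bl$table$excluded]))
    # k-mers with HCR frequency <= 10 never excluded (they are never tested)
    expect_true(all(bl$table$n_hcr > 10))
    # genome with no repeats: empty blacklist, warning
    expect_warning(bl0 <- build_blacklist(gen, NULL), "empty")
    expect_length(bl0$excluded, 0)
    m_with <- self_compare(gen, blacklist = bl, min_score = 5)
    m_without <- self_compare(gen, min_score = 5)
    # repeat-unit self matches vanish under the blacklist
    expect_lt(nrow(m_with), nrow(m_without))
  })
})

test_that("reciprocal filter equals a brute-force double-loop oracle", {
  withr::with_seed(106, {
    for (rep in 1:5) {
      n_frag <- 30
      cand <- tibble::tibble(
        frag_a = sample.int(n_frag, 120, replace = TRUE),
        frag_b = sample.int(n_frag, 120, replace = TRUE),
        orientation = "direct",
        score = sample.int(50, 120, replace = TRUE))
      cand <- cand[cand$frag_a < cand$frag_b, ]
      cand <- cand[!duplicated(cand[c("frag_a", "frag_b")]), ]
      top_n <- 3; max_list <- 6
      got <- reciprocal_filter(cand, top_n = top_n, max_list = max_list)
      # oracle
      lists <- lapply(seq_len(n_frag), function(f) {
        rows <- which(cand$frag_a == f | cand$frag_b == f)
        partner <- ifelse(cand$frag_a[rows] == f, cand$frag_b[rows],
                          cand$frag_a[rows])
        ord <- order(-cand$score[rows], partner)
        list(rows = rows[ord], partner = partner[ord])
      })
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        a <- cand$frag_a[i]; b <- cand$frag_b[i]
        la <- lists[[a]]; lb <- lists[[b]]
        if (length(la$rows) > max_list || length(lb$rows) > max_list) return(FALSE)
        (i %in% head(la$rows, top_n)) && (i %in% head(lb$rows, top_n))
      }, logical(1))
      expect_equal(got[c("frag_a", "frag_b", "score")],
                   cand[keep, c("frag_a", "frag_b", "score")],
                   ignore_attr = TRUE)
    }
  })
})

test_that("an overlong match list drops all of a fragment's pairs", {
  cand <- tibble::tibble(frag_a = 1L, frag_b = 2:1003,
                         orientation = "direct", score = 5L)
  got <- reciprocal_filter(cand, top_n = 50, max_list = 1000)
  expect_equal(nrow(got), 0)
})

test_that("merging chains a planted duplication into one block and enforces thresholds", {
  withr::with_seed(107, {
    src <- random_dna(1500)
    gen <- c(chr1 = paste0(random_dna(2000), src, random_dna(3000),
                           mutate_dna(src, 0.03)$seq, random_dna(1500)))
    m <- self_compare(gen, min_score = 10)
    f <- reciprocal_filter(m)
    blocks <- merge_fragments(f)
    expect_equal(nrow(blocks), 1)
    expect_equal(blocks$orientation, "direct")
    expect_lt(abs((blocks$end_a - blocks$start_a) - 1500), 1001)
    expect_lt(abs(blocks$start_a - 2000), 501)
    expect_lt(abs(blocks$start_b - 6500), 501)
    # blocks 5 kb apart on side A must not merge
    far <- tibble::tibble(frag_a = c(1L, 12L), frag_b = c(100L, 111L),
                          orientation = "direct", score = 100L)
    frags <- tibble::tibble(chrom = "chr1", start = (0:119) * 500,
                            end = (1:120) * 500, frag = 1:120)
    b2 <- merge_fragments(far, fragments = frags)
    expect_equal(nrow(b2), 2)
    # density at or below 0.05 is dropped
    weak <- tibble::tibble(frag_a = 1L, frag_b = 100L,
                           orientation = "direct", score = 25L)
    expect_equal(nrow(merge_fragments(weak, fragments = frags)), 0)
    strong <- weak; strong$score <- 26L
    expect_equal(nrow(merge_fragments(strong, fragments = frags)), 1)
  })
})

test_that("k-mer similarity reproduces the printed formula", {
  # identity
  expect_equal(kmer_similarity(1:10, 1:10, 100, 100), 1)
  # 10 shared, 2 + 3 unique, sizeDiff 0 -> 1 - 5/10
  expect_equal(kmer_similarity(1:12, c(1:10, 20, 21, 22), 100, 100), 0.5)
  # hand-computed with log(1+sizeDiff)
  expect_equal(kmer_similarity(1:12, c(1:10, 20, 21, 22), 100, 150),
               1 - (5 + log(51)) / 10)
  # monotone decrease in kmerDiff and sizeDiff at fixed intersection
  s0 <- kmer_similarity(1:10, 1:10, 100, 100)
  s1 <- kmer_similarity(1:11, 1:10, 100, 100)
  s2 <- kmer_similarity(1:11, 1:10, 100, 400)
  expect_true(s0 > s1 && s1 > s2)
  # empty intersection never clusters
  expect_identical(kmer_similarity(1:5, 6:10, 100, 100), -Inf)
})

test_that("identity: exact copies, planted substitutions, RC symmetry, degenerate pairs", {
  withr::with_seed(108, {
    s <- random_dna(1000)
    expect_equal(compute_identity(s, s), 1)
    mut <- mutate_dna(s, 0.05)
    got <- compute_identity(s, mut$seq)
    expect_equal(got, 1 - mut$n_sub / 1000, tolerance = 0.004)
    # inverted orientation equals direct comparison after RC
    expect_equal(compute_identity(s, revcomp(mut$seq), orientation = "inverted"),
                 got, tolerance = 1e-9)
    # long segments take the chunked path and stay accurate
    sl <- random_dna(12000)
    ml <- mutate_dna(sl, 0.04)
    expect_equal(compute_identity(sl, ml$seq), 1 - ml$n_sub / 12000,
                 tolerance = 0.005)
    expect_warning(z <- compute_identity(s, random_dna(10000)), "degenerate")
    expect_equal(z, 0)
    # unrelated same-length sequences do not alias as homologous
    expect_lt(compute_identity(random_dna(2000), random_dna(2000)), 0.6)
  })
})

test_that("clustering joins by overlap or k-mer similarity and equals union-find", {
  withr::with_seed(109, {
    seg <- random_dna(3000)
    gen <- c(chr1 = paste0(seg, random_dna(2000), seg, random_dna(2000),
                           substring(seg, 1, 1500), random_dna(5000)))
    # pairs sharing an overlapping member must cluster together
    pairs <- tibble::tibble(
      pair_id = 1:2,
      chrom_a = "chr1", start_a = c(0, 1000), end_a = c(3000, 3000),
      chrom_b = "chr1", start_b = c(5000, 10000), end_b = c(8000, 11500),
      orientation = "direct", score = 1000, density = 0.5, identity = 0.99)
    members <- cluster_lcrs(pairs, gen, min_len = 1000, min_identity = 0.9)
    expect_equal(length(unique(members$cluster_id)), 1)
    # disjoint, dissimilar pairs stay apart
    g2 <- c(chr1 = random_dna(30000))
    pairs2 <- tibble::tibble(
      pair_id = 1:2,
      chrom_a = "chr1", start_a = c(0, 20000), end_a = c(2000, 22000),
      chrom_b = "chr1", start_b = c(5000, 25000), end_b = c(7000, 27000),
      orientation = "direct", score = 1000, density = 0.5, identity = 0.99)
    members2 <- cluster_lcrs(pairs2, g2, min_len = 1000, min_identity = 0)
    expect_equal(length(unique(members2$cluster_id)), 2)
    # short or low-identity members are filtered out
    pairs3 <- pairs2
    pairs3$identity <- c(0.99, 0.5)
    members3 <- cluster_lcrs(pairs3, g2, min_len = 1000, min_identity = 0.9)
    expect_true(all(members3$pair_id == 1))
  })
})

test_that("clustering equals a brute-force union-find oracle on random pair sets", {
  withr::with_seed(110, {
    gen <- c(chr1 = random_dna(60000))
    for (rep in 1:3) {
      n <- 6
      starts <- sample(seq(0, 50000, by = 2000), 2 * n)
      pairs <- tibble::tibble(
        pair_id = seq_len(n), chrom_a = "chr1",
        start_a = starts[1:n], end_a = starts[1:n] + sample(1000:2500, n, TRUE),
        chrom_b = "chr1", start_b = starts[n + 1:n],
        end_b = starts[n + 1:n] + sample(1000:2500, n, TRUE),
        orientation = "direct", score = 500, density = 0.5, identity = 0.99)
      min_sim <- 0.5
      members <- cluster_lcrs(pairs, gen, min_similarity = min_sim,
                              min_len = 500, min_identity = 0)
      # oracle: explicit predicate + transitive closure
      prof <- lapply(seq_len(n), function(i) {
        ka <- unique(oracle_sampled_kmers(substring(gen, pairs$start_a[i] + 1,
                                                    pairs$end_a[i])))
        kb <- unique(oracle_sampled_kmers(substring(gen, pairs$start_b[i] + 1,
                                                    pairs$end_b[i])))
        union(ka, kb)
      })
      sizes <- (pairs$end_a - pairs$start_a) + (pairs$end_b - pairs$start_b)
      adj <- matrix(FALSE, n, n)
      for (i in 1:n) for (j in 1:n) {
        if (i == j) next
        inter <- length(intersect(prof[[i]], prof[[j]]))
        kdiff <- length(prof[[i]]) + length(prof[[j]]) - 2 * inter
        sim <- if (inter == 0) -Inf else
          1 - (kdiff + log1p(abs(sizes[i] - sizes[j]))) / inter
        ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2)) > 0
        pos <- ov(pairs$start_a[i], pairs$end_a[i], pairs$start_a[j], pairs$end_a[j]) ||
          ov(pairs$start_a[i], pairs$end_a[i], pairs$start_b[j], pairs$end_b[j]) ||
          ov(pairs$start_b[i], pairs$end_b[i], pairs$start_a[j], pairs$end_a[j]) ||
          ov(pairs$start_b[i], pairs$end_b[i], pairs$start_b[j], pairs$end_b[j])
        adj[i, j] <- sim >= min_sim || pos
      }
      reach <- adj | diag(n)
      for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ])
      oracle_comp <- apply(reach, 1, function(r) min(which(r)))
      got <- members |> dplyr::distinct(pair_id, cluster_id)
      mapped <- tapply(oracle_comp, oracle_comp, function(x) x)
      # same partition: pairs share a package cluster iff they share an oracle one
      for (i in 1:n) for (j in 1:n) {
        ci <- got$cluster_id[got$pair_id == i]
        cj <- got$cluster_id[got$pair_id == j]
        expect_equal(ci == cj, oracle_comp[i] == oracle_comp[j])
      }
    }
  })
})

test_that("DP-LCR extraction enforces orientation, size, identity, and distance", {
  mk_members <- function(ori, size = 2e4, gap = 2e6, identity = 0.97) {
    tibble::tibble(cluster_id = 1L, pair_id = 1L, member = c("a", "b"),
                   chrom = "chr1", start = c(0, size + gap),
                   end = c(size, 2 * size + gap), orientation = ori,
                   identity = identity)
  }
  mk_pairs <- function(m) tibble::tibble(pair_id = 1L)
  ok <- mk_members("direct")
  r <- find_dp_lcr_regions(ok, mk_pairs(ok))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 2e4)
  expect_equal(r$end, 2e4 + 2e6)
  # inverted pair meeting every other criterion yields nothing
  expect_equal(nrow(find_dp_lcr_regions(mk_members("inverted"), mk_pairs(ok))), 0)
  # too far apart
  expect_equal(nrow(find_dp_lcr_regions(mk_members("direct", gap = 1.2e7),
                                        mk_pairs(ok))), 0)
  # too small
  expect_equal(nrow(find_dp_lcr_regions(mk_members("direct", size = 5e3),
                                        mk_pairs(ok))), 0)
  # identity below 95%
  expect_equal(nrow(find_dp_lcr_regions(mk_members("direct", identity = 0.93),
                                        mk_pairs(ok))), 0)
})

test_that("the full pipeline is strand-symmetric", {
  cfg <- sim_config(seed = 13, chrom_lengths = c(chr1 = 1.2e6),
                    duplications = tibble::tibble(size = 15000, identity = 0.97,
                                                  separation = 3e5,
                                                  orientation = "direct"))
  g <- simulate_genome(cfg)
  res_fwd <- detect_lcrs(g$genome)
  rc_gen <- setNames(revcomp(g$genome[["chr1"]]), "chr1")
  res_rc <- detect_lcrs(rc_gen)
  expect_equal(nrow(res_fwd$dp_regions), 1)
  expect_equal(nrow(res_rc$dp_regions), 1)
  L <- 1.2e6
  # mirrored coordinates, within fragment quantization
  expect_lt(abs(res_rc$dp_regions$start - (L - res_fwd$dp_regions$end)), 501)
  expect_lt(abs(res_rc$dp_regions$end - (L - res_fwd$dp_regions$start)), 501)
})

test_that("pipeline output is deterministic", {
  cfg <- sim_config(seed = 14, chrom_lengths = c(chr1 = 8e5),
                    duplications = tibble::tibble(size = 12000, identity = 0.96,
                                                  separation = 2e5,
                                                  orientation = "direct"))
  g <- simulate_genome(cfg)
  r1 <- detect_lcrs(g$genome)
  r2 <- detect_lcrs(g$genome)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$dp_regions, r2$dp_regions)
})
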