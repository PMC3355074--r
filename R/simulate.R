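# Synthetic data with planted truth. Every pipeline stage is exercised on
# genomes, methylomes, SNP tables, element sets, and CNV cohorts whose true
# structure is known, so recovery, calibration, and power are measurable.
# The generator emulates the statistical structure the analyses assume (i.i.d.
# background sequence, binomial bisulfite sampling, methylation-proportional
# CpG-transition SNPs, allele-frequency CNV cohorts); it does not attempt a
# realistic repeat landscape or coalescent haplotypes.

#' Default planted-duplication table
#'
#' Twelve direct duplications of 20-50 kb at identities 95-99%, separated by
#' 0.1-8 Mb — the architecture the DP-LCR caller is validated against. Rows
#' can be edited or the table replaced wholesale in [sim_config()].
#' @return tibble with `size`, `identity`, `separation`, `orientation`.
#' @export
default_duplications <- function() {
  tibble(size = rep(c(2e4, 3e4, 5e4), length.out = 12),
         identity = seq(0.95, 0.99, length.out = 12),
         separation = c(1e5, 2e5, 3e5, 5e5, 8e5, 1e6, 1.5e6, 2e6, 3e6, 4e6,
                        6e6, 8e6),
         orientation = "direct")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' study conditions the package is validated under: 100 kb windows, a 1%
#' desert fraction at near-zero methylation against a high-methylation
#' background, a few hundred CpG sampling events per window, direct
#' duplications of 10-50 kb at 95-99% identity separated by 0.1-8 Mb, and a
#' 200-sample CNV cohort.
#'
#' @param seed mandatory integer seed; every stage derives its RNG stream
#'   from it.
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param gc GC content of the background sequence.
#' @param duplications tibble (`size`, `identity`, `separation`,
#'   `orientation`) of duplications to plant.
#' @param window_size analysis window width (bases).
#' @param desert_fraction fraction of windows planted as methylation deserts.
#' @param desert_level_mean mean true methylation of desert windows (0 plants
#'   exactly-zero windows).
#' @param background_level_mean,background_level_conc beta mean and
#'   concentration of background window methylation.
#' @param cpg_per_window CpG sites receiving observations per window.
#' @param events_per_window mean CpG sampling events per window.
#' @param msnp_slope per-CpG probability of a planted mSNP per unit of window
#'   methylation.
#' @param background_snp_rate per-base rate of non-CpG background SNPs.
#' @param n_elements,element_fold,element_size_range element-set model: count,
#'   desert enrichment fold, size range (bases).
#' @param n_samples,n_trios cohort sample count and number of trio families.
#' @param n_loci,locus_q_range,nahr_fraction,cnv_size_range CNV locus model:
#'   locus count, variant-frequency range, fraction of loci that are
#'   NAHR-type (spanning a DP-LCR region), and scattered-CNV size range.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chrA = 1e7, chrB = 1e7),
                       gc = 0.5,
                       duplications = default_duplications(),
                       window_size = 1e5,
                       desert_fraction = 0.01,
                       desert_level_mean = 0.03,
                       background_level_mean = 0.75,
                       background_level_conc = 12,
                       cpg_per_window = 500,
                       events_per_window = 200,
                       msnp_slope = 0.005,
                       background_snp_rate = 1.3e-3,
                       n_elements = 500,
                       element_fold = 10,
                       element_size_range = c(1e3, 2e4),
                       n_samples = 200,
                       n_trios = 0,
                       n_loci = 100,
                       locus_q_range = c(0.05, 0.35),
                       nahr_fraction = 0.2,
                       cnv_size_range = c(5e3, 5e4)) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  stopifnot(cfg$gc > 0, cfg$gc < 1, cfg$desert_fraction > 0,
            cfg$desert_fraction < 1, cfg$desert_level_mean >= 0,
            cfg$element_fold >= 1)
  structure(cfg, class = "sim_config")
}

.ascii_acgt <- c(65L, 67L, 71L, 84L) # A C G T

#' Simulate a genome with planted duplications
#'
#' Background sequence is i.i.d. at the configured GC content. Each planted
#' duplication copies a source segment, applies uniform substitutions at rate
#' 1 - identity, reverse-complements the copy when inverted, and places it
#' `separation` bases downstream. Copies never overlap each other; an
#' arrangement that cannot be placed is rejected with an explanation.
#'
#' @param cfg a [sim_config()].
#' @return list: `genome` (named character vector), `truth` (tibble of both
#'   copies per duplication), `expected_dp_regions` (the inter-copy regions a
#'   correct DP-LCR caller should recover: direct, >= 10 kb, identity >=
#'   0.95, separation < 10 Mb).
#' @export
simulate_genome <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    codes <- lapply(cfg$chrom_lengths, function(L) {
      sample.int(4L, L, replace = TRUE, prob = p) - 1L
    })
    dups <- as_tibble(cfg$duplications)
    placed <- tibble(chrom = character(), start = numeric(), end = numeric())
    truth <- vector("list", nrow(dups))
    for (i in seq_len(nrow(dups))) {
      size <- dups$size[i]; sep <- dups$separation[i]
      span <- 2 * size + sep
      ok_chroms <- names(cfg$chrom_lengths)[cfg$chrom_lengths >= span]
      if (length(ok_chroms) == 0) {
        abort(sprintf("duplication %d (span %g bp) exceeds every chromosome", i, span))
      }
      done <- FALSE
      for (try in seq_len(2000)) {
        chr <- sample(ok_chroms, 1)
        L <- cfg$chrom_lengths[[chr]]
        s1 <- floor(runif(1) * (L - span + 1))
        s2 <- s1 + size + sep
        cand <- tibble(chrom = chr, start = c(s1, s2), end = c(s1, s2) + size)
        prev <- placed[placed$chrom == chr, ]
        clash <- nrow(prev) > 0 &&
          any(outer(cand$start, prev$end, `<`) & outer(cand$end, prev$start, `>`))
        if (!clash) {
          src <- codes[[chr]][(s1 + 1):(s1 + size)]
          n_mut <- rbinom(1, size, 1 - dups$identity[i])
          if (n_mut > 0) {
            at <- sample.int(size, n_mut)
            src[at] <- (src[at] + sample.int(3L, n_mut, replace = TRUE)) %% 4L
          }
          if (dups$orientation[i] == "inverted") src <- rev(3L - src)
          codes[[chr]][(s2 + 1):(s2 + size)] <- src
          placed <- bind_rows(placed, cand)
          truth[[i]] <- tibble(dup_id = i, chrom = chr, start1 = s1,
                               end1 = s1 + size, start2 = s2, end2 = s2 + size,
                               size = size, identity = dups$identity[i],
                               separation = sep,
                               orientation = dups$orientation[i])
          done <- TRUE
          break
        }
      }
      if (!done) {
        abort(sprintf("could not place duplication %d without overlap after 2000 tries", i))
      }
    }
    truth <- if (nrow(dups) == 0) {
      tibble(dup_id = integer(), chrom = character(), start1 = numeric(),
             end1 = numeric(), start2 = numeric(), end2 = numeric(),
             size = numeric(), identity = numeric(), separation = numeric(),
             orientation = character())
    } else bind_rows(truth)
    genome <- vapply(codes, function(cd) intToUtf8(.ascii_acgt[cd + 1L]),
                     character(1))
    expected <- truth |>
      filter(.data$orientation == "direct", .data$size >= 1e4,
             .data$identity >= 0.95, .data$separation > 0,
             .data$separation < 1e7) |>
      mutate(start = .data$end1, end = .data$start2) |>
      select("dup_id", "chrom", "start", "end")
    list(genome = genome, truth = truth, expected_dp_regions = expected)
  })
}

#' Simulate true window methylation and per-CpG bisulfite observations
#'
#' Background window methylation follows the configured beta distribution;
#' a planted fraction of windows are deserts at the (near-)zero desert level.
#' Each window receives `cpg_per_window` CpG sites at random positions; per
#' site, sampling events are Poisson around the per-window mean and methylated
#' events are binomial at the window's true level.
#'
#' @param cfg a [sim_config()].
#' @param grid a `window_grid`.
#' @return list: `truth` (grid with `true_level`, `desert`), `obs`
#'   (CpG observation tibble).
#' @export
simulate_methylome_and_obs <- function(cfg, grid) {
  withr::with_seed(cfg$seed + 202L, {
    n <- nrow(grid)
    usable <- which(!grid$excluded)
    k <- max(1L, round(cfg$desert_fraction * length(usable)))
    desert <- rep(FALSE, n)
    desert[sample(usable, k)] <- TRUE
    a <- cfg$background_level_mean * cfg$background_level_conc
    b <- (1 - cfg$background_level_mean) * cfg$background_level_conc
    level <- rbeta(n, a, b)
    if (cfg$desert_level_mean <= 0) {
      level[desert] <- 0
    } else {
      dc <- 30
      level[desert] <- rbeta(sum(desert), cfg$desert_level_mean * dc,
                             (1 - cfg$desert_level_mean) * dc)
    }
    ws <- grid_window_size(grid)
    per_cpg <- cfg$events_per_window / cfg$cpg_per_window
    obs <- purrr::map_dfr(seq_len(n), function(i) {
      if (grid$excluded[i]) return(NULL)
      pos <- grid$start[i] + sample.int(ws, cfg$cpg_per_window) - 1
      ev <- rpois(cfg$cpg_per_window, per_cpg)
      keep <- ev > 0
      if (!any(keep)) return(NULL)
      tibble(chrom = grid$chrom[i], pos = sort(pos[keep]),
             n_total = ev[keep], n_meth = rbinom(sum(keep), ev[keep], level[i]))
    })
    truth <- as_tibble(grid)
    truth$true_level <- level
    truth$desert <- desert
    list(truth = truth, obs = obs[c("chrom", "pos", "n_meth", "n_total")])
  })
}

#' Simulate SNPs whose CpG-transition rate tracks methylation
#'
#' Every CpG dinucleotide in the genome becomes an mSNP (C/T with ancestral C
#' or, on the other strand, G/A with ancestral G, chosen uniformly) with
#' probability `msnp_slope` times its window's true methylation — the premise
#' behind the methylation index. Background SNPs are added outside CpGs at
#' `background_snp_rate` per base with ancestral = reference.
#'
#' @param cfg a [sim_config()].
#' @param grid a `window_grid`.
#' @param genome named character vector from [simulate_genome()].
#' @param true_meth truth tibble from [simulate_methylome_and_obs()]
#'   (per-window `true_level`).
#' @return SNP tibble (`chrom`, `pos`, `ref`, `alt`, `ancestral`), sorted.
#' @export
simulate_snps <- function(cfg, grid, genome, true_meth) {
  gen <- genome_as_character(genome)
  ws <- grid_window_size(grid)
  key <- paste(grid$chrom, grid$start)
  withr::with_seed(cfg$seed + 303L, {
    out <- list()
    for (chr in names(gen)) {
      cg <- gregexpr("CG", gen[[chr]], fixed = TRUE)[[1]]
      cg <- if (cg[1] == -1) integer(0) else as.integer(cg) - 1L # 0-based C
      if (length(cg) > 0) {
        row <- match(paste(chr, floor(cg / ws) * ws), key)
        lev <- ifelse(is.na(row), 0, true_meth$true_level[row])
        hit <- runif(length(cg)) < cfg$msnp_slope * lev
        if (any(hit)) {
          c_side <- runif(sum(hit)) < 0.5
          pos <- ifelse(c_side, cg[hit], cg[hit] + 1L)
          out[[length(out) + 1]] <- tibble(
            chrom = chr, pos = pos,
            ref = ifelse(c_side, "C", "G"),
            alt = ifelse(c_side, "T", "A"),
            ancestral = ifelse(c_side, "C", "G"))
        }
      }
      L <- nchar(gen[[chr]])
      n_bg <- rbinom(1, L, cfg$background_snp_rate)
      if (n_bg > 0) {
        bp <- sample.int(L, n_bg) - 1L # 0-based
        in_cpg <- bp %in% c(cg, cg + 1L)
        bp <- bp[!in_cpg]
        if (length(bp) > 0) {
          refb <- substring(gen[[chr]], bp + 1, bp + 1)
          known <- refb %in% c("A", "C", "G", "T")
          bp <- bp[known]; refb <- refb[known]
          altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                         character(1))
          out[[length(out) + 1]] <- tibble(chrom = chr, pos = bp, ref = refb,
                                           alt = unname(altb), ancestral = refb)
        }
      }
    }
    bind_rows(out) |> distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      arrange(.data$chrom, .data$pos)
  })
}

#' Simulate an element set with desert enrichment
#'
#' Places each element in a desert window with probability
#' `pi = F f / (1 - f + F f)` (F the configured enrichment fold, f the
#' realized desert window fraction), uniformly otherwise; element sizes are
#' uniform over `element_size_range` and elements stay inside their window.
#'
#' @param cfg a [sim_config()].
#' @param grid a `window_grid`.
#' @param deserts desert windows (call set or truth tibble with `desert`
#'   column).
#' @return element tibble (`chrom`, `start`, `end`, `in_desert`).
#' @export
simulate_elements <- function(cfg, grid, deserts) {
  desert_flag <- if (is.data.frame(deserts) && "desert" %in% names(deserts)) {
    deserts$desert
  } else as_window_flag(grid, deserts)
  usable <- !grid$excluded
  f <- sum(desert_flag & usable) / sum(usable)
  if (f <= 0) abort("no desert windows to enrich into")
  F_ <- cfg$element_fold
  pi_ <- F_ * f / (1 - f + F_ * f)
  ws <- grid_window_size(grid)
  withr::with_seed(cfg$seed + 404L, {
    in_desert <- runif(cfg$n_elements) < pi_
    idx_d <- which(desert_flag & usable)
    idx_o <- which(!desert_flag & usable)
    win <- ifelse(in_desert,
                  idx_d[sample.int(length(idx_d), cfg$n_elements, replace = TRUE)],
                  idx_o[sample.int(length(idx_o), cfg$n_elements, replace = TRUE)])
    size <- pmin(round(runif(cfg$n_elements, cfg$element_size_range[1],
                             cfg$element_size_range[2])), ws)
    start <- grid$start[win] + floor(runif(cfg$n_elements) * (ws - size + 1))
    tibble(chrom = grid$chrom[win], start = start, end = start + size,
           in_desert = in_desert) |>
      arrange(.data$chrom, .data$start)
  })
}

#' Simulate a CNV cohort with known allele frequencies and trios
#'
#' A configured fraction of loci are NAHR-type: their recurrent CNVs span at
#' least the whole-region threshold of a DP-LCR region. Remaining loci are
#' scattered intervals placed uniformly. Each unrelated sample (and each
#' parent) carries the variant with the locus frequency q; trio children
#' inherit a carrier parent's variant with probability 1/2.
#'
#' @param cfg a [sim_config()].
#' @param dp_regions DP-LCR region tibble (may be the simulator's
#'   `expected_dp_regions`); may be empty, in which case all loci are
#'   scattered.
#' @param chrom_lengths named vector (defaults to the config's).
#' @return list: `calls` (CNV call tibble), `pedigree`, `truth` (per-locus
#'   interval, type, true q).
#' @export
simulate_cnv_cohort <- function(cfg, dp_regions = NULL,
                                chrom_lengths = cfg$chrom_lengths) {
  withr::with_seed(cfg$seed + 505L, {
    n_trio_samp <- 3L * cfg$n_trios
    if (n_trio_samp > cfg$n_samples) abort("more trio members than samples")
    ids <- sprintf("S%03d", seq_len(cfg$n_samples))
    pedigree <- tibble(sample = ids, family = NA_character_,
                       role = "unrelated")
    if (cfg$n_trios > 0) {
      fam <- rep(sprintf("F%02d", seq_len(cfg$n_trios)), each = 3)
      pedigree$family[seq_len(n_trio_samp)] <- fam
      pedigree$role[seq_len(n_trio_samp)] <- rep(c("father", "mother", "child"),
                                                 cfg$n_trios)
    }
    n_nahr <- if (is.null(dp_regions) || nrow(dp_regions) == 0) 0L else
      min(round(cfg$nahr_fraction * cfg$n_loci), cfg$n_loci)
    loci <- vector("list", cfg$n_loci)
    for (i in seq_len(cfg$n_loci)) {
      if (i <= n_nahr) {
        r <- dp_regions[1L + (i - 1L) %% nrow(dp_regions), ]
        len <- r$end - r$start
        trim <- floor(runif(2) * 0.08 * len)
        loci[[i]] <- tibble(locus_id = i, chrom = r$chrom,
                            start = r$start + trim[1], end = r$end - trim[2],
                            type = "nahr")
      } else {
        chr <- sample(names(chrom_lengths), 1)
        size <- round(runif(1, cfg$cnv_size_range[1], cfg$cnv_size_range[2]))
        s <- floor(runif(1) * (chrom_lengths[[chr]] - size))
        loci[[i]] <- tibble(locus_id = i, chrom = chr, start = s,
                            end = s + size, type = "scattered")
      }
    }
    truth <- bind_rows(loci)
    truth$q <- runif(cfg$n_loci, cfg$locus_q_range[1], cfg$locus_q_range[2])
    truth$state <- sample(c("gain", "loss"), cfg$n_loci, replace = TRUE)
    parent_roles <- c("father", "mother", "unrelated")
    calls <- purrr::map_dfr(seq_len(cfg$n_loci), function(i) {
      carrier <- rep(FALSE, cfg$n_samples)
      indep <- pedigree$role %in% parent_roles
      carrier[indep] <- runif(sum(indep)) < truth$q[i]
      if (cfg$n_trios > 0) {
        for (fm in unique(pedigree$family[!is.na(pedigree$family)])) {
          rows <- which(pedigree$family == fm)
          child <- rows[pedigree$role[rows] == "child"]
          parents <- rows[pedigree$role[rows] %in% c("father", "mother")]
          inherit <- carrier[parents] & (runif(length(parents)) < 0.5)
          carrier[child] <- any(inherit)
        }
      }
      if (!any(carrier)) return(NULL)
      tibble(sample_id = ids[carrier], chrom = truth$chrom[i],
             start = truth$start[i], end = truth$end[i],
             state = truth$state[i], locus_id = i)
    })
    list(calls = calls, pedigree = pedigree, truth = truth)
  })
}
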