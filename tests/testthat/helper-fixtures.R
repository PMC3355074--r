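# In-code fixtures shared across the suite. Everything is generated, nothing
# is stored on disk.

fake_grid <- function(chrom_lengths, ws = 1e4, gaps = NULL) {
  partition_genome(chrom_lengths, gaps = gaps, window_size = ws)
}

# methylome with prescribed window levels (NA level -> invalid window)
fake_methylome <- function(grid, levels, events = 200) {
  m <- grid
  m$events <- rep_len(events, nrow(grid))
  m$valid <- !grid$excluded & !is.na(levels)
  m$level <- ifelse(m$valid, levels, NA_real_)
  m$meth_events <- ifelse(m$valid, round(m$level * m$events), 0)
  m$reads <- NA_real_
  class(m) <- unique(c("window_methylome", class(m)))
  m
}

# random DNA string of length n
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# copy of a DNA string with substitutions at the given per-base rate;
# returns list(seq, n_sub)
mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  at <- which(runif(length(bases)) < rate)
  if (length(at) > 0) {
    bases[at] <- vapply(bases[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  list(seq = paste(bases, collapse = ""), n_sub = length(at))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# independent sampled-k-mer extraction used as an oracle against the package's
# encoder: returns the multiset of sampled 13-letter strings per pattern start
oracle_sampled_kmers <- function(seq, offsets = c(0, 1, 2, 3, 6, 8, 10, 12, 14, 17, 18, 19, 20),
                                 pattern_length = 21) {
  n <- nchar(seq) - pattern_length + 1
  if (n < 1) return(character(0))
  vapply(seq_len(n), function(p) {
    paste(vapply(offsets, function(o) substring(seq, p + o, p + o), character(1)),
          collapse = "")
  }, character(1))
}
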