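# Genomic coordinate frame shared by every analysis layer. All coordinates are
# 0-based half-open [start, end), emitted as BED.

#' Normalise chromosome sizes to a named numeric vector
#'
#' Accepts a two-column data frame (chrom, length) or a named numeric vector.
#' @param chrom_sizes data frame with columns `chrom`, `length`, or a named
#'   numeric vector of chromosome lengths in bases.
#' @return named numeric vector of lengths.
#' @keywords internal
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
    out <- setNames(as.numeric(chrom_sizes$length), as.character(chrom_sizes$chrom))
  } else {
    if (is.null(names(chrom_sizes))) {
      abort("chrom_sizes must be a named vector or a (chrom, length) data frame")
    }
    out <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  if (any(out <= 0) || anyNA(out)) abort("chromosome lengths must be positive")
  if (anyDuplicated(names(out))) abort("duplicated chromosome names")
  out
}

check_intervals <- function(x, chrom_sizes = NULL, what = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(sprintf("%s must satisfy 0 <= start < end", what))
  }
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(sprintf("%s on undeclared chromosome(s): %s", what,
                    paste(unknown, collapse = ", ")))
    }
    if (any(x$end > sizes[x$chrom])) {
      abort(sprintf("%s extend beyond chromosome ends", what))
    }
  }
  invisible(x)
}

# widths of pairwise intersections, vectorised
overlap_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# seed the RNG only when a seed is supplied; otherwise use the ambient stream
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# union of intervals per chromosome (overlapping/adjacent records merged)
reduce_intervals <- function(x) {
  as_tibble(x)[c("chrom", "start", "end")] |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(c(1, .data$start[-1] > cummax(.data$end)[-dplyr::n()]))) |>
    group_by(.data$grp, .add = TRUE) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("chrom", "start", "end")
}

#' Partition a genome into fixed-width windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_size` bases
#' starting at position 0; the trailing partial window is dropped so every
#' window offers the same sampling opportunity. Windows whose overlap with
#' assembly gaps reaches `max_gap_fraction` of their length are flagged
#' `excluded` (they stay in the frame so window indices are stable).
#'
#' @param chrom_sizes named numeric vector or (chrom, length) data frame.
#' @param gaps optional data frame of assembly-gap intervals
#'   (`chrom`, `start`, `end`).
#' @param window_size window width in bases (default 100 kb).
#' @param max_gap_fraction gap-overlap fraction at which a window is excluded.
#' @return a `window_grid` tibble with columns `chrom`, `start`, `end`,
#'   `window_id`, `gap_frac`, `excluded`, ordered by (chrom, start); the
#'   window size and chromosome sizes travel as attributes.
#' @examples
#' partition_genome(c(chr1 = 350000), window_size = 100000)
#' @export
partition_genome <- function(chrom_sizes, gaps = NULL, window_size = 1e5,
                             max_gap_fraction = 0.5) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (window_size <= 0) abort("window_size must be positive")
  if (!is.null(gaps)) check_intervals(gaps, sizes, what = "gaps")

  grid <- purrr::map2_dfr(names(sizes), unname(sizes), function(chr, len) {
    n <- floor(len / window_size)
    if (n == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
    start <- (seq_len(n) - 1) * window_size
    tibble(chrom = chr, start = start, end = start + window_size)
  })
  grid <- arrange(grid, .data$chrom, .data$start)
  grid$window_id <- seq_len(nrow(grid))

  grid$gap_frac <- 0
  if (!is.null(gaps) && nrow(gaps) > 0) {
    gap_bp <- grid |>
      inner_join(reduce_intervals(gaps), by = "chrom",
                 suffix = c("", ".gap"), relationship = "many-to-many") |>
      mutate(w = overlap_width(.data$start, .data$end, .data$start.gap, .data$end.gap)) |>
      group_by(.data$window_id) |>
      summarise(gap_bp = sum(.data$w))
    grid$gap_frac[match(gap_bp$window_id, grid$window_id)] <-
      gap_bp$gap_bp / window_size
  }
  grid$excluded <- grid$gap_frac >= max_gap_fraction

  out <- as_tibble(grid)
  attr(out, "window_size") <- window_size
  attr(out, "chrom_sizes") <- sizes
  class(out) <- c("window_grid", class(out))
  out
}

grid_window_size <- function(grid) {
  ws <- attr(grid, "window_size")
  ws %||% unique(grid$end - grid$start)[1]
}

#' Label windows containing elements
#'
#' A window is labeled `TRUE` when at least one base of any element overlaps it
#' (half-open overlap).
#'
#' @param elements interval data frame (`chrom`, `start`, `end`).
#' @param grid a `window_grid` from [partition_genome()].
#' @return the grid tibble with a logical `contains` column.
#' @export
windows_containing <- function(elements, grid) {
  check_intervals(elements, attr(grid, "chrom_sizes"), what = "elements")
  ws <- grid_window_size(grid)
  hit <- rep(FALSE, nrow(grid))
  if (nrow(elements) > 0) {
    # windows tile from 0, so overlapped window starts are directly computable
    idx_lo <- floor(elements$start / ws)
    idx_hi <- floor((elements$end - 1) / ws)
    reps <- idx_hi - idx_lo + 1
    key_chrom <- rep(elements$chrom, reps)
    key_start <- (idx_lo[rep(seq_along(reps), reps)] +
                    (sequence(reps) - 1)) * ws
    m <- match(paste(key_chrom, key_start), paste(grid$chrom, grid$start))
    hit[m[!is.na(m)]] <- TRUE
  }
  out <- grid
  out$contains <- hit
  out
}

#' Draw size-matched random segments
#'
#' For each element, draws `n_per_element` segments of identical length
#' uniformly on the same chromosome (the null used by the size-matched
#' association tests). Draws overlapping an assembly gap are redrawn up to
#' `max_retry` times; segments still overlapping a gap are emitted with
#' `gap_overlap = TRUE`.
#'
#' @inheritParams windows_containing
#' @param chrom_sizes named numeric vector or (chrom, length) data frame.
#' @param n_per_element segments per source element (default 100).
#' @param gaps optional gap intervals to avoid.
#' @param max_retry redraw cap per segment.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#' @return tibble of segments with `source_id` (row of the source element),
#'   `chrom`, `start`, `end`, `gap_overlap`.
#' @export
sample_matched_segments <- function(elements, chrom_sizes, n_per_element = 100,
                                    gaps = NULL, max_retry = 100, seed = NULL) {
  sizes <- as_chrom_sizes(chrom_sizes)
  check_intervals(elements, sizes, what = "elements")
  lens <- elements$end - elements$start
  if (any(lens >= sizes[elements$chrom] + 1e-9 & lens > sizes[elements$chrom])) {
    abort("element longer than its chromosome")
  }
  with_seed_opt(seed, {
    src <- rep(seq_len(nrow(elements)), each = n_per_element)
    chrom <- elements$chrom[src]
    len <- lens[src]
    k <- sizes[chrom] - len + 1 # number of admissible starts
    draw <- function(idx) pmin(floor(runif(length(idx)) * k[idx]), k[idx] - 1)
    start <- draw(seq_along(src))
    gap_overlap <- rep(FALSE, length(src))
    if (!is.null(gaps) && nrow(gaps) > 0) {
      overlaps_gap <- function(chr, s, e) {
        seg <- tibble(chrom = chr, start = s, end = e, .row = seq_along(chr))
        hit <- seg |>
          inner_join(as_tibble(gaps)[c("chrom", "start", "end")], by = "chrom",
                     suffix = c("", ".gap"), relationship = "many-to-many") |>
          filter(overlap_width(.data$start, .data$end,
                               .data$start.gap, .data$end.gap) > 0)
        seq_along(chr) %in% hit$.row
      }
      bad <- overlaps_gap(chrom, start, start + len)
      tries <- 0
      while (any(bad) && tries < max_retry) {
        idx <- which(bad)
        start[idx] <- draw(idx)
        bad[idx] <- overlaps_gap(chrom[idx], start[idx], start[idx] + len[idx])
        tries <- tries + 1
      }
      gap_overlap <- bad
    }
    tibble(source_id = src, chrom = chrom, start = start, end = start + len,
           gap_overlap = gap_overlap)
  })
}

#' Flank intervals at a distance from elements
#'
#' Places, for each element, two flanks of `flank_size` bases `distance` bases
#' outward from the element edges, clipped at chromosome bounds; flanks clipped
#' to nothing are dropped.
#'
#' @inheritParams sample_matched_segments
#' @param distance gap between element edge and flank, in bases.
#' @param flank_size flank width in bases.
#' @return tibble with `source_id`, `chrom`, `start`, `end`, `side`
#'   (`"left"`/`"right"`).
#' @export
flank_at_distance <- function(elements, chrom_sizes, distance, flank_size) {
  sizes <- as_chrom_sizes(chrom_sizes)
  check_intervals(elements, sizes, what = "elements")
  if (distance < 0 || flank_size <= 0) abort("need distance >= 0 and flank_size > 0")
  left <- tibble(source_id = seq_len(nrow(elements)), chrom = elements$chrom,
                 start = elements$start - distance - flank_size,
                 end = elements$start - distance, side = "left")
  right <- tibble(source_id = seq_len(nrow(elements)), chrom = elements$chrom,
                  start = elements$end + distance,
                  end = elements$end + distance + flank_size, side = "right")
  out <- bind_rows(left, right)
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, sizes[out$chrom])
  out |>
    filter(.data$end > .data$start) |>
    arrange(.data$source_id, .data$side)
}

# ---- plain-text I/O -------------------------------------------------------

#' Read chromosome sizes from a two-column TSV (name, length)
#' @param path file path.
#' @return tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "cd", progress = FALSE)
}

#' Read a BED3+ file into an interval tibble
#' @param path file path.
#' @param extra_names names for columns beyond chrom/start/end (optional).
#' @return tibble with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE, comment = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names)) {
    names(x)[seq(4, 3 + length(extra_names))] <- extra_names
  }
  x
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any columns named in `extra` as
#' tab-separated BED with no header.
#' @param x interval data frame.
#' @param path output file.
#' @param extra character vector of additional columns to keep, in order.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = character()) {
  cols <- c("chrom", "start", "end", extra)
  y <- as_tibble(x)[cols]
  y$start <- format(y$start, scientific = FALSE, trim = TRUE)
  y$end <- format(y$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(y, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
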