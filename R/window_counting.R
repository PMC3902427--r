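# Sliding-window tiling and read counting. Coordinates are 0-based
# half-open throughout; a window's ordinal index within its chromosome is
# start / window_shift.

#' Tile the genome into overlapping windows
#'
#' Windows start at 0, `window_shift`, 2*`window_shift`, ... and have width
#' `window_size`, clipped at the chromosome end. Truncated terminal windows
#' shorter than the shift are dropped (they would duplicate the previous
#' window's tail).
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param cfg A [ram_config()].
#' @return Data frame `chrom`, `start`, `end`, `index` (0-based ordinal
#'   within chromosome), ordered by (chromosome, start). Chromosome order
#'   follows `chrom_lengths`.
#' @export
tile_windows <- function(chrom_lengths, cfg = ram_config()) {
  stopifnot(all(chrom_lengths >= 1))
  shift <- cfg$window_shift
  size <- cfg$window_size
  out <- lapply(seq_along(chrom_lengths), function(i) {
    L <- as.numeric(chrom_lengths[i])
    n <- .n_windows(L, size, shift)
    if (n == 0L) return(NULL)
    s <- (seq_len(n) - 1) * shift
    data.frame(chrom = names(chrom_lengths)[i], start = s,
               end = pmin(s + size, L), index = seq_len(n) - 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# windows kept: start <= L - shift (width >= shift)
.n_windows <- function(L, size, shift) {
  if (L < shift) return(0L)
  as.integer(floor((L - shift) / shift) + 1)
}

#' Count reads per window per sample
#'
#' Each read contributes at its anchor base: the leftmost aligned base,
#' optionally moved `read_extension` bp toward the read's 3' end (i.e. the
#' anchor of an extended fragment). The anchor increments every window that
#' contains it -- exactly `window_size / window_shift` windows (2 with the
#' defaults) except within the first shift of a chromosome. Library sizes
#' are the per-sample total read counts, fixed before any filtering.
#'
#' @param readsets Named list of `read_set` objects (see
#'   [simulate_reads()] / [read_fixture()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param cfg A [ram_config()].
#' @param windows Optional precomputed [tile_windows()] result.
#' @return An object of class `ram_counts`: list with `windows` (the tiling
#'   data frame), `samples` (data frame `sample`, `group`, `sex`), `counts`
#'   (integer matrix windows x samples) and `library_sizes` (named vector).
#' @export
count_reads <- function(readsets, chrom_lengths, cfg = ram_config(),
                        windows = NULL) {
  if (is.null(windows)) windows <- tile_windows(chrom_lengths, cfg)
  chroms <- names(chrom_lengths)
  n_win_chrom <- vapply(chrom_lengths, .n_windows,
                        integer(1), cfg$window_size, cfg$window_shift)
  offset <- setNames(cumsum(c(0, n_win_chrom[-length(n_win_chrom)])), chroms)
  ratio <- cfg$window_size %/% cfg$window_shift
  total <- nrow(windows)

  counts <- matrix(0L, nrow = total, ncol = length(readsets),
                   dimnames = list(NULL, names(readsets)))
  lib <- integer(length(readsets))
  for (j in seq_along(readsets)) {
    r <- readsets[[j]]$reads
    lib[j] <- nrow(r)
    if (!nrow(r)) next
    bad <- setdiff(unique(r$chrom), chroms)
    if (length(bad))
      stop("reads on unknown chromosome(s): ", paste(bad, collapse = ", "))
    a <- .anchor(r, chrom_lengths, cfg$read_extension)
    k_hi <- a %/% cfg$window_shift
    nw <- n_win_chrom[r$chrom]
    acc <- integer(total)
    for (d in 0:(ratio - 1)) {
      k <- k_hi - d
      ok <- k >= 0 & k < nw
      if (!any(ok)) next
      gidx <- offset[r$chrom[ok]] + k[ok] + 1
      acc <- acc + tabulate(gidx, nbins = total)
    }
    counts[, j] <- acc
  }
  structure(list(windows = windows,
                 samples = data.frame(
                   sample = vapply(readsets, `[[`, "", "sample"),
                   group = vapply(readsets, `[[`, "", "group"),
                   sex = vapply(readsets, `[[`, "", "sex"),
                   stringsAsFactors = FALSE, row.names = NULL),
                 counts = counts,
                 library_sizes = setNames(lib, names(readsets))),
            class = "ram_counts")
}

# anchor base per read: leftmost aligned base, shifted ext bp toward 3'
.anchor <- function(reads, chrom_lengths, ext = 0L) {
  a <- reads$start
  if (ext > 0L) {
    a <- ifelse(reads$strand == "-", pmax(reads$start - ext, 0), reads$start)
  }
  pmin(a, as.numeric(chrom_lengths[reads$chrom]) - 1)
}

#' @export
print.ram_counts <- function(x, ...) {
  cat(sprintf("ram_counts: %d windows x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Remove low-coverage windows
#'
#' Retains windows with at least `min_reads` reads in at least
#' `ceiling(min_sample_fraction * n_samples)` samples (with 12 samples and
#' the default 25%, that is 3 samples with >= 10 reads). Library sizes are
#' left untouched.
#'
#' @param m A `ram_counts` object.
#' @param cfg A [ram_config()].
#' @return `m` restricted to the retained windows.
#' @export
filter_low_coverage <- function(m, cfg = ram_config()) {
  stopifnot(inherits(m, "ram_counts"), nrow(m$counts) > 0)
  need <- ceiling(cfg$min_sample_fraction * ncol(m$counts))
  keep <- rowSums(m$counts >= cfg$min_reads) >= need
  m$windows <- m$windows[keep, , drop = FALSE]
  rownames(m$windows) <- NULL
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}

#' Write a window-count matrix as TSV
#'
#' @param m A `ram_counts` object.
#' @param path Output path (`chrom`, `start`, `end`, one column per sample).
#' @export
write_count_matrix <- function(m, path) {
  tab <- cbind(m$windows[, c("chrom", "start", "end")],
               as.data.frame(m$counts))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
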