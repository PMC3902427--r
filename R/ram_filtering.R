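# From per-window test results to RAM calls: raw-p gate, per-sample
# support, adjacency, and merging of surviving windows into regions.
# Filters only ever remove windows, so the final set is nested in the
# preliminary set.

#' Call preliminary RAMs from a differential-test result
#'
#' Windows with raw p below `alpha` become preliminary RAMs, directed by
#' the sign of the log2 fold change. No multiple-testing correction is
#' applied at this stage: error control comes from the support and
#' adjacency filters plus the sex-contrast empirical FDR bound.
#'
#' @param d A [run_comparison()] result.
#' @param cfg A [ram_config()].
#' @return Data frame of RAM records: the window and test fields plus
#'   logical flags `prelim`, `support_ok`, `adjacency_ok` (the latter two
#'   `NA` until the corresponding filter has run).
#' @export
call_preliminary_rams <- function(d, cfg = ram_config()) {
  keep <- d$p < cfg$alpha & d$direction != "none"
  rams <- d[keep, , drop = FALSE]
  rams$prelim <- rep(TRUE, nrow(rams))
  rams$support_ok <- rep(NA, nrow(rams))
  rams$adjacency_ok <- rep(NA, nrow(rams))
  rownames(rams) <- NULL
  rams
}

#' Per-sample support filter
#'
#' A RAM must reflect a shift shared by the group, not one extreme sample.
#' For each RAM window, per-sample depth-normalized counts are compared to
#' the midpoint between the two group medians; the call is supported when,
#' in each group, at least `max(2, ceiling(support_fraction * group size))`
#' samples lie on their group's side of that midpoint (below for the group
#' the call says is lower, above for the higher one).
#'
#' @param rams RAM records from [call_preliminary_rams()].
#' @param m The `ram_counts` object the test was run on (same window set).
#' @param group_a,group_b The compared groups (B = exposed/higher dose).
#' @param cfg A [ram_config()].
#' @param sizes Optional effective library sizes.
#' @return `rams` with the `support_ok` flag filled in.
#' @export
sample_support_filter <- function(rams, m, group_a, group_b,
                                  cfg = ram_config(), sizes = NULL) {
  if (!nrow(rams)) { rams$support_ok <- logical(0); return(rams) }
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  ia <- which(m$samples$group == group_a)
  ib <- which(m$samples$group == group_b)
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples")
  need_a <- max(2L, ceiling(cfg$support_fraction * length(ia)))
  need_b <- max(2L, ceiling(cfg$support_fraction * length(ib)))

  key <- paste(m$windows$chrom, m$windows$start)
  row <- match(paste(rams$chrom, rams$start), key)
  if (anyNA(row)) stop("RAM references a window absent from the count matrix")

  norm <- sweep(m$counts[row, , drop = FALSE], 2, sizes, "/") * 1e6
  med_a <- apply(norm[, ia, drop = FALSE], 1, median)
  med_b <- apply(norm[, ib, drop = FALSE], 1, median)
  mid <- (med_a + med_b) / 2
  above_a <- rowSums(norm[, ia, drop = FALSE] > mid)
  below_a <- rowSums(norm[, ia, drop = FALSE] < mid)
  above_b <- rowSums(norm[, ib, drop = FALSE] > mid)
  below_b <- rowSums(norm[, ib, drop = FALSE] < mid)

  hyper <- rams$direction == "hyper"  # B elevated
  rams$support_ok <- ifelse(hyper,
                            below_a >= need_a & above_b >= need_b,
                            above_a >= need_a & below_b >= need_b)
  rams
}

#' Adjacency filter
#'
#' An isolated significant window is discarded: a RAM window keeps its call
#' only if another preliminary RAM of the same comparison and direction
#' starts within `adjacency_stretch - window_size` bp (default 400 bp, so
#' the two windows fit inside one 500 bp stretch; directly flanking
#' windows, 50 bp apart, are the tightest case).
#'
#' @param rams RAM records for one comparison.
#' @param cfg A [ram_config()].
#' @return `rams` with the `adjacency_ok` flag filled in.
#' @export
adjacency_filter <- function(rams, cfg = ram_config()) {
  if (!nrow(rams)) { rams$adjacency_ok <- logical(0); return(rams) }
  if (length(unique(rams$comparison)) > 1)
    stop("adjacency_filter expects RAMs from a single comparison")
  max_gap <- cfg$adjacency_stretch - cfg$window_size
  rams$adjacency_ok <- FALSE
  for (grp in split(seq_len(nrow(rams)),
                    list(rams$chrom, rams$direction), drop = TRUE)) {
    s <- sort(rams$start[grp])
    if (length(s) < 2) next
    gap <- diff(s)
    ok_sorted <- c(gap <= max_gap, FALSE) | c(FALSE, gap <= max_gap)
    ok <- ok_sorted[match(rams$start[grp], s)]
    rams$adjacency_ok[grp] <- ok
  }
  rams
}

#' Final RAM windows
#'
#' @param rams RAM records with all flags filled.
#' @return The subset with `prelim`, `support_ok` and `adjacency_ok` all
#'   `TRUE`.
#' @export
final_rams <- function(rams) {
  keep <- rams$prelim & rams$support_ok & rams$adjacency_ok
  out <- rams[!is.na(keep) & keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge final RAM windows into regions
#'
#' Overlapping or book-ended windows of the same direction are merged;
#' each region reports its window count and the minimum window p.
#'
#' @param rams Final RAM records (one comparison).
#' @return Data frame `chrom`, `start`, `end`, `direction`, `n_windows`,
#'   `min_p`, sorted by position.
#' @export
merge_rams <- function(rams) {
  if (!nrow(rams))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_windows = integer(0), min_p = numeric(0),
                      stringsAsFactors = FALSE))
  out <- lapply(split(rams, rams$direction), function(r) {
    gr <- .df0_to_gr(r)
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    reg <- .gr_to_df0(red)
    reg$direction <- r$direction[1]
    reg$n_windows <- as.integer(table(factor(S4Vectors::subjectHits(hit),
                                             levels = seq_along(red))))
    reg$min_p <- vapply(seq_along(red), function(i)
      min(r$p[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == i]]),
      numeric(1))
    reg
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply the full RAM filter chain to one comparison
#'
#' Convenience wrapper: preliminary call, support filter, adjacency filter.
#'
#' @inheritParams sample_support_filter
#' @param d A [run_comparison()] result.
#' @return List `rams` (all records with flags), `final` (surviving
#'   windows), `counts` (named vector of stage counts).
#' @export
call_rams <- function(d, m, group_a, group_b, cfg = ram_config(),
                      sizes = NULL) {
  rams <- call_preliminary_rams(d, cfg)
  rams <- sample_support_filter(rams, m, group_a, group_b, cfg, sizes)
  rams <- adjacency_filter(rams, cfg)
  fin <- final_rams(rams)
  list(rams = rams,
       final = fin,
       counts = c(prelim = nrow(rams), support_ok = sum(rams$support_ok),
                  final = nrow(fin)))
}

#' Write final RAMs as BED6
#'
#' Name = comparison, score = -10 log10 p (capped at 1000), strand `+` for
#' hyper, `-` for hypo.
#'
#' @param rams Final RAM records.
#' @param path Output BED path.
#' @export
write_rams_bed <- function(rams, path) {
  gr <- GenomicRanges::GRanges(
    if (nrow(rams)) rams$chrom else character(0),
    IRanges::IRanges(start = rams$start + 1, end = rams$end),
    strand = ifelse(rams$direction == "hyper", "+", "-"))
  if (nrow(rams)) {
    gr$name <- rams$comparison
    gr$score <- pmin(round(-10 * log10(pmax(rams$p, 1e-100))), 1000)
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
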