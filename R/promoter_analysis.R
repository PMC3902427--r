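# Promoter-level dose-response classification (gain/loss x UG-only /
# both / MG-only) and the promoter heatmap matrix with its inclusion
# filter. Promoters are unique TSS regions (gene ids); window-level counts
# are carried alongside.

#' Classify promoters by methylation response and exposure class
#'
#' Uses the two exposure-versus-control comparisons. Per promoter (gene),
#' the direction of its RAM windows in `Ctr_vs_UG` and in `Ctr_vs_MG`
#' determines:
#'
#' * response: `gain` (hyper in the exposed group), `loss` (hypo), `none`,
#'   or `mixed` (both directions within one comparison, or opposite
#'   directions between the two comparisons -- excluded from class counts);
#' * exposure class: `UG_only` (responsive at the low dose only, the
#'   non-monotonic signature), `MG_only`, `both`, or `none`.
#'
#' @param prom_ug Promoter-assigned RAM records (see [assign_promoters()])
#'   from the `Ctr_vs_UG` comparison.
#' @param prom_mg Same for `Ctr_vs_MG`.
#' @return Data frame of class `promoter_classification`: `gene_id`,
#'   `state_UG`, `state_MG` (per-comparison direction summaries),
#'   `response`, `exposure_class`, `n_windows_UG`, `n_windows_MG`.
#' @export
classify_promoter_dose_response <- function(prom_ug, prom_mg) {
  for (d in list(prom_ug, prom_mg))
    stopifnot(is.data.frame(d),
              all(c("gene_id", "direction") %in% names(d) | !nrow(d)))
  genes <- sort(unique(c(prom_ug$gene_id, prom_mg$gene_id)))
  state <- function(d, g) {
    dir <- unique(d$direction[d$gene_id == g])
    if (length(dir) == 0) "none"
    else if (length(dir) > 1) "mixed"
    else if (dir == "hyper") "hyper" else "hypo"
  }
  s_ug <- vapply(genes, state, "", d = prom_ug)
  s_mg <- vapply(genes, state, "", d = prom_mg)

  resp <- character(length(genes))
  expo <- character(length(genes))
  for (i in seq_along(genes)) {
    u <- s_ug[i]; m <- s_mg[i]
    if (u == "mixed" || m == "mixed" ||
        (u != "none" && m != "none" && u != m)) {
      resp[i] <- "mixed"; expo[i] <- "mixed"
    } else if (u == "none" && m == "none") {
      resp[i] <- "none"; expo[i] <- "none"
    } else {
      dir <- if (u != "none") u else m
      resp[i] <- if (dir == "hyper") "gain" else "loss"
      expo[i] <- if (u != "none" && m != "none") "both"
                 else if (u != "none") "UG_only" else "MG_only"
    }
  }
  out <- data.frame(gene_id = genes, state_UG = unname(s_ug),
                    state_MG = unname(s_mg), response = resp,
                    exposure_class = expo,
                    n_windows_UG = vapply(genes, function(g)
                      sum(prom_ug$gene_id == g), integer(1)),
                    n_windows_MG = vapply(genes, function(g)
                      sum(prom_mg$gene_id == g), integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("promoter_classification", class(out))
  out
}

#' Summarize promoter classes into counts and percentages
#'
#' Reports the six gain/loss x exposure-class counts, the gain and loss
#' subtotals, the grand total, and the integer-rounded percent gained and
#' lost. Mixed promoters are excluded from the six classes and reported
#' separately. `promoter_summary_from_counts()` performs the same
#' arithmetic on externally supplied counts.
#'
#' @param cls A `promoter_classification`.
#' @return List of class `promoter_summary`: `counts` (2 x 3 matrix
#'   gain/loss x UG_only/both/MG_only), `gain_total`, `loss_total`,
#'   `grand_total`, `pct_gain`, `pct_loss`, `n_mixed`.
#' @export
promoter_summary <- function(cls) {
  keep <- cls$response %in% c("gain", "loss")
  counts <- matrix(0L, 2, 3, dimnames = list(c("gain", "loss"),
                                             c("UG_only", "both", "MG_only")))
  for (r in rownames(counts))
    for (k in colnames(counts))
      counts[r, k] <- sum(cls$response[keep] == r &
                            cls$exposure_class[keep] == k)
  out <- promoter_summary_from_counts(counts["gain", ], counts["loss", ])
  out$n_mixed <- sum(cls$response == "mixed")
  out
}

#' @rdname promoter_summary
#' @param gain,loss Numeric vectors of class counts `(UG_only, both,
#'   MG_only)` for promoters gaining and losing methylation.
#' @export
promoter_summary_from_counts <- function(gain, loss) {
  stopifnot(length(gain) == 3, length(loss) == 3)
  counts <- rbind(gain = as.numeric(gain), loss = as.numeric(loss))
  colnames(counts) <- c("UG_only", "both", "MG_only")
  gain_total <- sum(gain)
  loss_total <- sum(loss)
  grand <- gain_total + loss_total
  structure(list(counts = counts, gain_total = gain_total,
                 loss_total = loss_total, grand_total = grand,
                 pct_gain = round(100 * gain_total / grand),
                 pct_loss = round(100 * loss_total / grand),
                 n_mixed = NA_integer_),
            class = "promoter_summary")
}

#' @export
print.promoter_summary <- function(x, ...) {
  cat("Promoter RAM classes (promoters):\n")
  print(x$counts)
  cat(sprintf("gain %d (%d%%) / loss %d (%d%%), total %d",
              x$gain_total, x$pct_gain, x$loss_total, x$pct_loss,
              x$grand_total))
  if (!is.na(x$n_mixed)) cat(sprintf(" (+%d mixed, excluded)", x$n_mixed))
  cat("\n")
  invisible(x)
}

#' Promoter heatmap matrix with inclusion filter
#'
#' Builds the per-sample normalized-coverage matrix over promoter regions
#' that carry at least one RAM window passing the display filter: (a) some
#' exposure group's mean normalized count over the window falls below the
#' low-reads threshold (`min_reads` scaled by the median effective library
#' size), or (b) the ratio between any two group means is at least
#' `heatmap_fold`. Cells are counts per million summed over the promoter
#' span (TSS +/- `promoter_flank`); rows are ordered by response class then
#' exposure class.
#'
#' @param prom_rams Promoter-assigned RAM records (both exposure-vs-control
#'   comparisons row-bound), with `gene_id`.
#' @param m The `ram_counts` object (window set the RAMs refer to).
#' @param ann A `genome_annotation`.
#' @param cls Optional `promoter_classification` used to order rows.
#' @param cfg A [ram_config()].
#' @param sizes Optional effective library sizes.
#' @return List of class `promoter_heatmap`: `matrix` (promoters x
#'   samples, CPM), `included` (logical per input RAM window row),
#'   `row_class` (response/exposure label per matrix row).
#' @export
heatmap_matrix <- function(prom_rams, m, ann, cls = NULL,
                           cfg = ram_config(), sizes = NULL) {
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  included <- heatmap_window_filter(prom_rams, m, cfg, sizes)
  genes <- unique(prom_rams$gene_id[included])
  norm <- sweep(m$counts, 2, sizes, "/") * 1e6

  prom <- ann$promoters[match(genes, ann$promoters$gene_id), , drop = FALSE]
  rows <- matrix(0, nrow = length(genes), ncol = ncol(m$counts),
                 dimnames = list(genes, m$samples$sample))
  if (length(genes)) {
    hit <- .interval_overlaps(m$windows, prom)
    for (k in seq_along(genes)) {
      w <- hit$from[hit$to == k]
      if (length(w)) rows[k, ] <- colSums(norm[w, , drop = FALSE])
    }
  }
  row_class <- rep(NA_character_, length(genes))
  if (!is.null(cls)) {
    j <- match(genes, cls$gene_id)
    row_class <- paste(cls$response[j], cls$exposure_class[j], sep = "/")
    ord <- order(cls$response[j], cls$exposure_class[j], genes)
    rows <- rows[ord, , drop = FALSE]
    row_class <- row_class[ord]
  }
  structure(list(matrix = rows, included = included, row_class = row_class),
            class = "promoter_heatmap")
}

#' Heatmap inclusion filter for RAM windows
#'
#' @inheritParams heatmap_matrix
#' @return Logical vector: window passes via the low-reads or the
#'   fold-change criterion.
#' @export
heatmap_window_filter <- function(prom_rams, m, cfg = ram_config(),
                                  sizes = NULL) {
  if (!nrow(prom_rams)) return(logical(0))
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  key <- paste(m$windows$chrom, m$windows$start)
  row <- match(paste(prom_rams$chrom, prom_rams$start), key)
  if (anyNA(row)) stop("RAM window absent from the count matrix")
  norm <- sweep(m$counts[row, , drop = FALSE], 2, sizes, "/") * 1e6
  gmeans <- vapply(GROUP_LEVELS, function(g) {
    j <- which(m$samples$group == g)
    rowMeans(norm[, j, drop = FALSE])
  }, numeric(nrow(norm)))
  if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = 1,
                                             dimnames = list(NULL,
                                                             GROUP_LEVELS))
  low_thresh <- cfg$min_reads / median(sizes) * 1e6
  low <- apply(gmeans, 1, min) < low_thresh
  ratio <- apply(gmeans, 1, function(v) {
    if (min(v) == 0) return(if (max(v) > 0) Inf else 1)
    max(v) / min(v)
  })
  low | ratio >= cfg$heatmap_fold
}
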