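# CpG-island shore/shelf derivation, window context classification, and
# promoter assignment. Interval algebra is delegated to GenomicRanges;
# coordinates stay 0-based half-open at this module's surface.

#' Build a genome annotation from CGIs and gene models
#'
#' Derives CGI shores and shelves and gene-feature interval sets used by
#' the context classifiers. Shores are the `shore_extent` (default 2 kb)
#' flanks of merged CpG islands, minus any CGI; shelves are the next
#' `shelf_extent` (default 2 kb) band, minus CGIs and shores; both are
#' clipped to chromosome bounds. CGIs, shores and shelves are pairwise
#' disjoint by construction.
#'
#' @param cgis Data frame `chrom`, `start`, `end` of CpG islands (0-based
#'   half-open); overlapping islands are merged first.
#' @param genes Gene-model data frame as produced by [build_toy_genome()]
#'   or [read_fixture()] (BED12 semantics: transcript span, CDS span via
#'   `cds_start`/`cds_end`, exon blocks).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param cfg A [ram_config()].
#' @return Object of class `genome_annotation`: `chrom_sizes`, data frames
#'   `cgis`, `shores`, `shelves`, `promoters` (TSS +/- `promoter_flank`,
#'   with `gene_id`), `tss` (per gene), and `features` (named list of
#'   GRanges: `CDS_exon`, `UTR5`, `UTR3`, `TSS_up_1kb`, `TSS_up_5kb`,
#'   `intron`).
#' @export
build_annotation <- function(cgis, genes, chrom_sizes, cfg = ram_config()) {
  ss <- derive_shores_shelves(cgis, chrom_sizes, cfg)
  tss <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss,
                    stringsAsFactors = FALSE)
  promoters <- data.frame(
    chrom = tss$chrom,
    start = pmax(tss$tss - cfg$promoter_flank, 0),
    end = pmin(tss$tss + cfg$promoter_flank,
               as.numeric(chrom_sizes[tss$chrom])),
    gene_id = tss$gene_id, stringsAsFactors = FALSE)
  structure(list(chrom_sizes = chrom_sizes, cgis = ss$cgis,
                 shores = ss$shores, shelves = ss$shelves,
                 promoters = promoters, tss = tss,
                 features = .gene_features(genes, chrom_sizes)),
            class = "genome_annotation")
}

#' Derive CGI shores and shelves
#'
#' @inheritParams build_annotation
#' @return List of data frames `cgis` (merged), `shores`, `shelves`, each
#'   a disjoint merged interval set, 0-based half-open.
#' @export
derive_shores_shelves <- function(cgis, chrom_sizes, cfg = ram_config()) {
  sl <- chrom_sizes
  gr <- GenomicRanges::reduce(.df0_to_gr(cgis))
  clip <- function(g) {
    s <- pmax(GenomicRanges::start(g), 1)
    e <- pmin(GenomicRanges::end(g), as.numeric(sl[as.character(
      GenomicRanges::seqnames(g))]))
    keep <- s <= e
    GenomicRanges::GRanges(GenomicRanges::seqnames(g)[keep],
                           IRanges::IRanges(s[keep], e[keep]))
  }
  expand <- function(g, by) {
    clip(GenomicRanges::GRanges(
      GenomicRanges::seqnames(g),
      IRanges::IRanges(GenomicRanges::start(g) - by,
                       GenomicRanges::end(g) + by)))
  }
  near <- expand(gr, cfg$shore_extent)
  shores <- GenomicRanges::reduce(GenomicRanges::setdiff(near, gr))
  far <- expand(gr, cfg$shore_extent + cfg$shelf_extent)
  shelves <- GenomicRanges::reduce(
    GenomicRanges::setdiff(GenomicRanges::setdiff(far, near), gr))
  list(cgis = .gr_to_df0(gr), shores = .gr_to_df0(shores),
       shelves = .gr_to_df0(shelves))
}

#' Classify windows by CpG-island context
#'
#' Any >= 1 bp overlap labels the window, at the highest-precedence
#' category: CGI > shore > shelf; windows more than
#' `shore_extent + shelf_extent` from every island are `open_sea`.
#'
#' @param windows Data frame `chrom`, `start`, `end`.
#' @param ann A `genome_annotation` (or the [derive_shores_shelves()] list).
#' @return Character vector of labels, one per window.
#' @export
classify_cgi_context <- function(windows, ann) {
  lab <- rep("open_sea", nrow(windows))
  lab[.overlaps_any(windows, ann$shelves)] <- "shelf"
  lab[.overlaps_any(windows, ann$shores)] <- "shore"
  lab[.overlaps_any(windows, ann$cgis)] <- "CGI"
  lab
}

# strand-aware gene-feature interval sets as GRanges; combining ranges
# from chromosomes with disjoint seqlevels is routine here, so Seqinfo
# merge warnings are muted
.gene_features <- function(genes, chrom_sizes) suppressWarnings({
  g1 <- function(chrom, start0, end0) {
    keep <- end0 > start0
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start0[keep] + 1, end0[keep]))
  }
  ex_chrom <- rep(genes$chrom, lengths(genes$exon_starts))
  ex_start <- unlist(genes$exon_starts)
  ex_end <- ex_start + unlist(genes$exon_sizes)
  ex_cds_start <- rep(genes$cds_start, lengths(genes$exon_starts))
  ex_cds_end <- rep(genes$cds_end, lengths(genes$exon_starts))
  ex_strand <- rep(genes$strand, lengths(genes$exon_starts))

  cds <- g1(ex_chrom, pmax(ex_start, ex_cds_start), pmin(ex_end, ex_cds_end))
  # 5'UTR: exon bases upstream of the CDS (before cds_start on +, after
  # cds_end on -); 3'UTR the converse
  utr5 <- c(g1(ex_chrom[ex_strand == "+"],
               ex_start[ex_strand == "+"],
               pmin(ex_end, ex_cds_start)[ex_strand == "+"]),
            g1(ex_chrom[ex_strand == "-"],
               pmax(ex_start, ex_cds_end)[ex_strand == "-"],
               ex_end[ex_strand == "-"]))
  utr3 <- c(g1(ex_chrom[ex_strand == "-"],
               ex_start[ex_strand == "-"],
               pmin(ex_end, ex_cds_start)[ex_strand == "-"]),
            g1(ex_chrom[ex_strand == "+"],
               pmax(ex_start, ex_cds_end)[ex_strand == "+"],
               ex_end[ex_strand == "+"]))

  up <- function(d1, d2) {
    # upstream band [TSS-d2, TSS-d1) on +, (TSS+d1, TSS+d2] on -
    plus <- genes$strand == "+"
    s0 <- ifelse(plus, genes$tss - d2, genes$tss + d1 + 1)
    e0 <- ifelse(plus, genes$tss - d1, genes$tss + d2 + 1)
    s0 <- pmax(s0, 0)
    e0 <- pmin(e0, as.numeric(chrom_sizes[genes$chrom]))
    g1(genes$chrom, s0, e0)
  }
  tss1 <- up(0, 1000)
  tss5 <- up(1000, 5000)

  exons <- g1(ex_chrom, ex_start, ex_end)
  span <- g1(genes$chrom, genes$start, genes$end)
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(span),
                                   GenomicRanges::reduce(exons))

  lapply(list(CDS_exon = cds, UTR5 = utr5, UTR3 = utr3,
              TSS_up_1kb = tss1, TSS_up_5kb = tss5, intron = intron),
         GenomicRanges::reduce)
})

#' Classify windows by gene-feature context
#'
#' Precedence (any >= 1 bp overlap): CDS exon > 5'UTR > 3'UTR > 1 kb
#' upstream of a TSS > 1-5 kb upstream of a TSS > intron > intergenic.
#' Upstream bands are strand-aware.
#'
#' @inheritParams classify_cgi_context
#' @return Character vector of labels, one per window.
#' @export
classify_gene_context <- function(windows, ann) {
  gr <- .df0_to_gr(windows)
  lab <- rep("intergenic", nrow(windows))
  for (nm in rev(c("CDS_exon", "UTR5", "UTR3", "TSS_up_1kb", "TSS_up_5kb",
                   "intron"))) {
    hit <- suppressWarnings(IRanges::overlapsAny(gr, ann$features[[nm]]))
    lab[hit] <- nm
  }
  lab
}

#' Context distribution of a labeled window set
#'
#' @param labels Character vector of category labels.
#' @param categories Category universe (defaults to the observed labels).
#' @param weights Optional non-negative weight per window (e.g. read
#'   counts, to express the distribution in reads rather than windows).
#' @return Named numeric vector of proportions summing to 1, with the
#'   denominator attached as `attr(, "n")`.
#' @export
context_distribution <- function(labels, categories = NULL, weights = NULL) {
  stopifnot(length(labels) > 0)
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(all(weights >= 0), sum(weights) > 0)
  if (is.null(categories)) categories <- sort(unique(labels))
  tot <- vapply(categories, function(k) sum(weights[labels == k]), numeric(1))
  p <- tot / sum(weights)
  attr(p, "n") <- sum(weights)
  p
}

#' Relative enrichment of a RAM distribution over a background
#'
#' Percent change of each category's share relative to the background
#' (library) share: `100 * (p_ram - p_bg) / p_bg`. Categories absent from
#' the background are reported as `NA` rather than infinite.
#'
#' @param ram_dist,bg_dist Proportion vectors over the same categories
#'   (see [context_distribution()]); `ram_dist` may be expressed in
#'   percent, as printed shares are.
#' @return Named numeric vector of percent changes (not rounded; reports
#'   round to one decimal).
#' @export
enrichment_vs_background <- function(ram_dist, bg_dist) {
  stopifnot(all(names(ram_dist) %in% names(bg_dist)))
  bg <- bg_dist[names(ram_dist)]
  out <- 100 * (as.numeric(ram_dist) - as.numeric(bg)) / as.numeric(bg)
  out[as.numeric(bg) == 0] <- NA_real_
  names(out) <- names(ram_dist)
  out
}

#' Assign RAM windows to promoters
#'
#' A window is assigned to every gene whose TSS lies within
#' `promoter_flank` of any base of the window -- equivalently, the window
#' overlaps `[TSS - flank, TSS + flank)`. Windows near several TSSs keep
#' all assignments (one output row per window-gene pair).
#'
#' @param rams RAM records (or any data frame with `chrom`, `start`,
#'   `end`).
#' @param ann A `genome_annotation`.
#' @return `rams` rows replicated per overlapping promoter, with a
#'   `gene_id` column; windows in no promoter are dropped.
#' @export
assign_promoters <- function(rams, ann) {
  if (!nrow(rams)) {
    rams$gene_id <- character(0)
    return(rams)
  }
  hit <- .interval_overlaps(rams, ann$promoters)
  out <- rams[hit$from, , drop = FALSE]
  out$gene_id <- ann$promoters$gene_id[hit$to]
  rownames(out) <- NULL
  out
}

#' Annotate RAM records with CGI and gene context
#'
#' @param rams RAM records.
#' @param ann A `genome_annotation`.
#' @return `rams` with `cgi_context` and `gene_context` columns.
#' @export
annotate_rams <- function(rams, ann) {
  rams$cgi_context <- if (nrow(rams)) classify_cgi_context(rams, ann)
                      else character(0)
  rams$gene_context <- if (nrow(rams)) classify_gene_context(rams, ann)
                       else character(0)
  rams
}
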