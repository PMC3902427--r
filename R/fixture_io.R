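# On-disk fixture layout: one BED6 per sample (<sample>.bed), chrom.sizes,
# cgi.bed, genes.bed (BED12, thickStart/thickEnd = CDS), samples.tsv
# (sample/group/sex), truth.tsv (planted effects). All coordinates BED
# 0-based half-open.

#' Write a simulated experiment to disk as plain-text fixture files
#'
#' Emits per-sample reads as BED6, chromosome sizes, the CpG-island BED,
#' gene models as BED12 (thickStart/thickEnd delimiting the CDS), the
#' sample sheet, and the planted-effect truth table. Everything round-trips
#' through [read_fixture()].
#'
#' @param genome A `genome_model`.
#' @param landscape A `methylation_landscape` (its truth table is written).
#' @param readsets Named list of `read_set` objects.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(genome, landscape, readsets, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  write.table(genome$chromosomes, file.path(out_dir, "chrom.sizes"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  rtracklayer::export(.df0_to_gr(genome$cgis),
                      file.path(out_dir, "cgi.bed"), format = "bed")

  rtracklayer::export(.genes_to_gr(genome$genes),
                      file.path(out_dir, "genes.bed"), format = "bed")

  samples <- data.frame(sample = vapply(readsets, `[[`, "", "sample"),
                        group = vapply(readsets, `[[`, "", "group"),
                        sex = vapply(readsets, `[[`, "", "sex"),
                        stringsAsFactors = FALSE)
  write.table(samples, file.path(out_dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- landscape$truth[, c("chrom", "start", "end", "direction",
                               "dose_class", "multiplier")]
  write.table(truth, file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (rs in readsets) {
    r <- rs$reads
    gr <- GenomicRanges::GRanges(
      if (nrow(r)) r$chrom else character(0),
      IRanges::IRanges(start = r$start + 1, end = r$end),
      strand = r$strand)
    if (nrow(r)) {
      gr$name <- sprintf("%s_r%06d", rs$sample, seq_len(nrow(r)))
      gr$score <- 0L
    }
    rtracklayer::export(gr, file.path(out_dir, paste0(rs$sample, ".bed")),
                        format = "bed")
  }
  invisible(out_dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()], or any directory with
#'   the same layout (per-sample BED6 named after the sample sheet,
#'   `chrom.sizes`, `cgi.bed`, `genes.bed`, `samples.tsv`, optionally
#'   `truth.tsv`).
#' @return List with `chrom_sizes` (named vector), `cgis` and `genes` data
#'   frames (0-based half-open), `samples` (sample sheet), `readsets`
#'   (named list of `read_set`), and `truth` (or `NULL`).
#' @export
read_fixture <- function(dir) {
  chrom_sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  cgis <- .gr_to_df0(rtracklayer::import(file.path(dir, "cgi.bed"),
                                         format = "bed"))
  genes <- .gr_to_genes(rtracklayer::import(file.path(dir, "genes.bed"),
                                            format = "bed"))
  samples <- read.table(file.path(dir, "samples.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  readsets <- lapply(seq_len(nrow(samples)), function(i) {
    structure(list(reads = read_reads_bed(
                     file.path(dir, paste0(samples$sample[i], ".bed"))),
                   sample = samples$sample[i], group = samples$group[i],
                   sex = samples$sex[i]),
              class = "read_set")
  })
  names(readsets) <- samples$sample
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.table(truth_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  list(chrom_sizes = chrom_sizes, cgis = cgis, genes = genes,
       samples = samples, readsets = readsets, truth = truth)
}

#' Read aligned-read positions from a BED file
#'
#' @param path BED6 (or BED3+) file of aligned reads.
#' @return Data frame `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- .gr_to_df0(gr)
  st <- as.character(GenomicRanges::strand(gr))
  df$strand <- ifelse(st == "*", "+", st)
  df
}

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(as.numeric(tab[[2]]), tab[[1]])
}

# genes data frame <-> BED12 GRanges
.genes_to_gr <- function(genes) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(start = genes$cds_start + 1,
                               end = genes$cds_end)
  gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(genes)), function(i) {
    rel <- genes$exon_starts[[i]] - genes$start[i] + 1
    IRanges::IRanges(start = rel, width = genes$exon_sizes[[i]])
  }))
  gr
}

.gr_to_genes <- function(gr) {
  start0 <- GenomicRanges::start(gr) - 1
  genes <- data.frame(
    gene_id = if (!is.null(gr$name)) gr$name
              else sprintf("gene%04d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = start0,
    end = GenomicRanges::end(gr),
    cds_start = GenomicRanges::start(gr$thick) - 1,
    cds_end = GenomicRanges::end(gr$thick),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  blocks <- gr$blocks
  genes$exon_starts <- lapply(seq_along(gr), function(i)
    start0[i] + GenomicRanges::start(blocks[[i]]) - 1)
  genes$exon_sizes <- lapply(seq_along(gr), function(i)
    GenomicRanges::width(blocks[[i]]))
  genes
}
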