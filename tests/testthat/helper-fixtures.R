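# Shared fixture builders. Everything is generated in code at test time;
# the simulated experiment is cached so several files can reuse it.

# wrap a bare count matrix as a ram_counts object
make_counts <- function(Y, groups = rep(c("A", "B"), each = ncol(Y) / 2),
                        sex = rep(c("M", "F"), length.out = ncol(Y)),
                        sizes = rep(1e6, ncol(Y)), shift = 50L) {
  Y <- as.matrix(Y)
  ids <- paste0("s", seq_len(ncol(Y)))
  colnames(Y) <- ids
  structure(list(
    windows = data.frame(chrom = "chr1",
                         start = (seq_len(nrow(Y)) - 1) * shift,
                         end = (seq_len(nrow(Y)) - 1) * shift + 2 * shift,
                         index = seq_len(nrow(Y)) - 1L),
    samples = data.frame(sample = ids, group = groups, sex = sex,
                         stringsAsFactors = FALSE),
    counts = Y,
    library_sizes = stats::setNames(sizes, ids)),
    class = "ram_counts")
}

# a read_set from bare read coordinates
make_read_set <- function(chrom, start, end, strand = "+",
                          sample = "s1", group = "Ctr", sex = "M") {
  structure(list(reads = data.frame(chrom = chrom, start = start, end = end,
                                    strand = strand,
                                    stringsAsFactors = FALSE),
                 sample = sample, group = group, sex = sex),
            class = "read_set")
}

# small simulated experiment shared across files (12 samples, ~2.6 Mb)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- build_toy_genome(
        c(chr1 = 1.2e6, chr2 = 6e5, chrX = 6e5, chrY = 2e5), seed = 101)
      effects <- default_effects(genome, n = 12, seed = 101)
      landscape <- plant_methylome(genome, effects, seed = 101)
      readsets <- simulate_experiment(
        landscape, genome, sim_config(reads_per_sample = 150000, seed = 101))
      cache <<- list(
        genome = genome, landscape = landscape, readsets = readsets,
        chrom_sizes = stats::setNames(genome$chromosomes$length,
                                      genome$chromosomes$name))
    }
    cache
  }
})

# hand-built two-gene annotation on one 30 kb chromosome, for per-base
# oracle comparisons (one gene per strand, 3 exons each)
toy_genes <- function() {
  g <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(5000, 18000),
    end = c(9000, 23000),
    cds_start = c(5400, 18600),
    cds_end = c(8600, 22500),
    stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  g$exon_starts <- list(c(5000, 6500, 8200), c(18000, 20000, 22000))
  g$exon_sizes <- list(c(800, 700, 800), c(900, 800, 1000))
  g
}

# per-base CGI-context classifier (independent of the interval algebra)
base_cgi_label <- function(b, cgis, shore = 2000, shelf = 2000) {
  d <- Inf
  for (i in seq_len(nrow(cgis))) {
    s <- cgis$start[i]; e <- cgis$end[i]
    if (b >= s && b < e) return("CGI")
    d <- min(d, if (b < s) s - b else b - e + 1)
  }
  if (d <= shore) "shore"
  else if (d <= shore + shelf) "shelf"
  else "open_sea"
}

# per-base gene-feature classifier with the documented precedence
base_gene_label <- function(b, genes) {
  in_exon <- function(g, b) {
    any(b >= g$exon_starts[[1]] & b < g$exon_starts[[1]] + g$exon_sizes[[1]])
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (in_exon(g, b) && b >= g$cds_start && b < g$cds_end) return("CDS_exon")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (in_exon(g, b) &&
        ((g$strand == "+" && b < g$cds_start) ||
         (g$strand == "-" && b >= g$cds_end))) return("UTR5")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (in_exon(g, b) &&
        ((g$strand == "-" && b < g$cds_start) ||
         (g$strand == "+" && b >= g$cds_end))) return("UTR3")
  }
  for (d in list(c(0, 1000, "TSS_up_1kb"), c(1000, 5000, "TSS_up_5kb"))) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      lo <- as.numeric(d[1]); hi <- as.numeric(d[2])
      hit <- if (g$strand == "+") b >= g$tss - hi && b < g$tss - lo
             else b > g$tss + lo && b <= g$tss + hi
      if (hit) return(d[3])
    }
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (b >= g$start && b < g$end) return("intron")
  }
  "intergenic"
}

# closed-form two-group Poisson LRT (group-mean MLEs are closed form)
poisson_lrt_oracle <- function(y, ia, ib, sizes) {
  ll <- function(r, idx) sum(stats::dpois(y[idx], pmax(r * sizes[idx], 1e-12),
                                          log = TRUE))
  ra <- sum(y[ia]) / sum(sizes[ia])
  rb <- sum(y[ib]) / sum(sizes[ib])
  r0 <- sum(y) / sum(sizes)
  2 * (ll(ra, ia) + ll(rb, ib) - ll(r0, c(ia, ib)))
}
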