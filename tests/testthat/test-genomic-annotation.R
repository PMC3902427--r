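test_that("shores and shelves are derived exactly as the flank definition", {
  cfg <- ram_config()
  sizes <- c(chr1 = 30000)

  one <- derive_shores_shelves(
    data.frame(chrom = "chr1", start = 10000, end = 10500), sizes, cfg)
  expect_equal(one$shores,
               data.frame(chrom = "chr1", start = c(8000, 10500),
                          end = c(10000, 12500)))
  expect_equal(one$shelves,
               data.frame(chrom = "chr1", start = c(6000, 12500),
                          end = c(8000, 14500)))

  # clipping at the chromosome start: shore truncated, left shelf empty
  edge <- derive_shores_shelves(
    data.frame(chrom = "chr1", start = 500, end = 900), sizes, cfg)
  expect_equal(edge$shores$start, c(0, 900))
  expect_equal(edge$shores$end, c(500, 2900))
  expect_equal(edge$shelves, data.frame(chrom = "chr1", start = 2900,
                                        end = 4900))

  # two islands 1 kb apart: the gap is entirely shore, no shelf between
  two <- derive_shores_shelves(
    data.frame(chrom = "chr1", start = c(10000, 11500),
               end = c(11000, 12000)), sizes, cfg)
  expect_true(any(two$shores$start == 11000 & two$shores$end == 11500))
  expect_false(any(two$shelves$start >= 11000 & two$shelves$end <= 11500))
})

test_that("interval-derived shores/shelves match the per-base oracle", {
  cfg <- ram_config()
  sizes <- c(chr1 = 30000)
  cgis <- data.frame(chrom = "chr1", start = c(500, 10000, 11500, 22000),
                     end = c(900, 11000, 12000, 22800))
  ss <- derive_shores_shelves(cgis, sizes, cfg)

  in_set <- function(b, set) any(set$start <= b & b < set$end)
  bases <- seq(0, 29999, by = 37)  # dense systematic sample of positions
  for (b in bases) {
    want <- base_cgi_label(b, cgis)
    got <- if (in_set(b, ss$cgis)) "CGI"
           else if (in_set(b, ss$shores)) "shore"
           else if (in_set(b, ss$shelves)) "shelf"
           else "open_sea"
    expect_identical(got, want)
  }

  # disjointness and idempotence
  ovl <- function(a, b) {
    h <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end)),
      GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end)))
    length(h)
  }
  expect_equal(ovl(ss$cgis, ss$shores), 0)
  expect_equal(ovl(ss$cgis, ss$shelves), 0)
  expect_equal(ovl(ss$shores, ss$shelves), 0)
  expect_equal(derive_shores_shelves(ss$cgis, sizes, cfg), ss)
})

test_that("window CGI context uses overlap with CGI > shore > shelf", {
  cfg <- ram_config()
  sizes <- c(chr1 = 30000)
  cgis <- data.frame(chrom = "chr1", start = 10000, end = 10500)
  ann <- derive_shores_shelves(cgis, sizes, cfg)

  w <- data.frame(chrom = "chr1",
                  start = c(9950, 20000, 7950, 5950),
                  end = c(10050, 20100, 8050, 6050))
  expect_equal(classify_cgi_context(w, ann),
               c("CGI", "open_sea", "shore", "shelf"))

  # random windows against the per-base oracle at max precedence
  set.seed(61)
  wr <- data.frame(chrom = "chr1", start = sample(0:298, 80) * 100)
  wr$end <- wr$start + 100
  got <- classify_cgi_context(wr, ann)
  prec <- c(CGI = 1, shore = 2, shelf = 3, open_sea = 4)
  want <- vapply(seq_len(nrow(wr)), function(i) {
    labs <- vapply(wr$start[i]:(wr$end[i] - 1), base_cgi_label, "",
                   cgis = cgis)
    names(which.min(prec[unique(labs)]))
  }, "")
  expect_equal(got, unname(want))
})

test_that("gene-feature context follows the documented precedence", {
  cfg <- ram_config()
  sizes <- c(chr1 = 30000)
  genes <- toy_genes()
  ann <- build_annotation(data.frame(chrom = "chr1", start = 1, end = 2),
                          genes, sizes, cfg)

  # forced single-category windows on the + strand gene
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 5500, end = 5600), ann), "CDS_exon")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 5000, end = 5100), ann), "UTR5")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 8800, end = 8900), ann), "UTR3")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 4500, end = 4600), ann), "TSS_up_1kb")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 1000, end = 1100), ann), "TSS_up_5kb")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 6000, end = 6100), ann), "intron")
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 29000, end = 29100), ann),
    "intergenic")
  # strand awareness: upstream of the - strand gene is to its right
  expect_equal(classify_gene_context(
    data.frame(chrom = "chr1", start = 23500, end = 23600), ann),
    "TSS_up_1kb")

  # per-base oracle over the whole toy chromosome
  w <- data.frame(chrom = "chr1", start = seq(0, 29900, by = 100))
  w$end <- w$start + 100
  got <- classify_gene_context(w, ann)
  prec <- c(CDS_exon = 1, UTR5 = 2, UTR3 = 3, TSS_up_1kb = 4,
            TSS_up_5kb = 5, intron = 6, intergenic = 7)
  want <- vapply(seq_len(nrow(w)), function(i) {
    labs <- vapply(seq(w$start[i], w$end[i] - 1, by = 7), base_gene_label,
                   "", genes = genes)
    names(which.min(prec[unique(labs)]))
  }, "")
  expect_equal(got, unname(want))
})

test_that("context distributions are proportions that hand-tally", {
  labs <- c(rep("CGI", 5), rep("shore", 10), rep("shelf", 3),
            rep("open_sea", 2))
  d <- context_distribution(labs, c("CGI", "shore", "shelf", "open_sea"))
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(as.numeric(d), c(5, 10, 3, 2) / 20)
  expect_equal(attr(d, "n"), 20)

  dw <- context_distribution(c("a", "b"), weights = c(30, 10))
  expect_equal(as.numeric(dw), c(0.75, 0.25))
  expect_equal(as.numeric(context_distribution(rep("CGI", 4))), 1)
})

test_that("enrichment versus background reproduces the worked shares", {
  bg <- c(shore = 43, CGI = 27, shelf = 16, open_sea = 14)
  expect_equal(round(enrichment_vs_background(c(shore = 51), bg)[["shore"]],
                     1), 18.6)
  expect_equal(round(enrichment_vs_background(c(shore = 50), bg)[["shore"]],
                     1), 16.3)
  expect_equal(round(enrichment_vs_background(c(shore = 38), bg)[["shore"]],
                     1), -11.6)
  expect_equal(enrichment_vs_background(bg, bg),
               setNames(rep(0, 4), names(bg)))
  expect_true(is.na(enrichment_vs_background(
    c(shore = 10), c(shore = 0))[["shore"]]))
})

test_that("promoter assignment uses TSS +/- flank, half-open", {
  cfg <- ram_config()
  sizes <- c(chr1 = 30000)
  genes <- toy_genes()  # gplus TSS = 5000, gminus TSS = 22999
  ann <- build_annotation(data.frame(chrom = "chr1", start = 1, end = 2),
                          genes, sizes, cfg)

  inside <- data.frame(chrom = "chr1", start = 5000 + 1400,
                       end = 5000 + 1500)
  expect_equal(assign_promoters(inside, ann)$gene_id, "gplus")
  outside <- data.frame(chrom = "chr1", start = 5000 + 1500,
                        end = 5000 + 1600)
  expect_equal(nrow(assign_promoters(outside, ann)), 0)

  # brute-force TSS distance scan on random windows
  set.seed(62)
  w <- data.frame(chrom = "chr1", start = sample(0:290, 120) * 100)
  w$end <- w$start + 100
  got <- assign_promoters(w, ann)
  want <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    hits <- genes$gene_id[w$start[i] < genes$tss + cfg$promoter_flank &
                            w$end[i] > genes$tss - cfg$promoter_flank]
    if (length(hits)) data.frame(start = w$start[i], gene_id = hits)
  }))
  expect_equal(nrow(got), nrow(want))
  expect_equal(sort(paste(got$start, got$gene_id)),
               sort(paste(want$start, want$gene_id)))
})
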