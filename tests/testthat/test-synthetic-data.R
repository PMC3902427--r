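# The simulator is first-class code: its determinism, placement process,
# dose-class semantics and sampling weights are tested against independent
# expectations, because every downstream benchmark leans on it.

test_that("toy genome construction validates input and is reproducible", {
  expect_error(build_toy_genome(c(chr1 = 0, chrX = 1e5, chrY = 1e5)),
               "10 kb")
  expect_error(build_toy_genome(c(chr1 = 1e5, chr2 = 1e5)), "chrX")
  expect_error(build_toy_genome(c(chrX = 1e5, chrY = 1e5)), "autosome")

  g1 <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 4)
  g2 <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 4)
  g3 <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1$cgis, g3$cgis))
})

test_that("CGI placement follows the renewal-process rate", {
  # 2 Mb autosome, mean spacing 50 kb -> ~40 islands expected
  lambda <- 2e6 / 5e4
  counts <- vapply(1:40, function(s) {
    g <- build_toy_genome(c(chr1 = 2e6, chrX = 1e4, chrY = 1e4),
                          cgi_spacing = 5e4, seed = s)
    sum(g$cgis$chrom == "chr1")
  }, numeric(1))
  expect_true(all(abs(counts - lambda) <= 3 * sqrt(lambda)))
  expect_lt(abs(mean(counts) - lambda), 3)
})

test_that("planting respects dose-class semantics and records truth", {
  genome <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 4)

  null_lsc <- plant_methylome(genome, NULL, seed = 2)
  expect_identical(null_lsc$tiles$m_Ctr, null_lsc$tiles$m_UG)
  expect_identical(null_lsc$tiles$m_Ctr, null_lsc$tiles$m_MG)
  expect_equal(nrow(null_lsc$truth), 0)

  # forced by the dose-class definition: UG-only doubling of base 0.2
  eff <- data.frame(chrom = "chr1", start = 10000, end = 10500,
                    direction = "hyper", dose_class = "UG_only",
                    multiplier = 2)
  lsc <- plant_methylome(genome, eff, base_level = 0.2, jitter_sd = 0,
                         seed = 2)
  expect_equal(lsc$truth$m_Ctr, 0.2)
  expect_equal(lsc$truth$m_UG, 0.4)
  expect_equal(lsc$truth$m_MG, 0.2)

  expect_error(plant_methylome(genome, transform(eff, chrom = "chr9")),
               "unknown chromosome")
  expect_error(plant_methylome(genome, transform(eff, end = 9e5)), "bounds")
  expect_error(plant_methylome(genome, transform(eff, multiplier = 9),
                               base_level = 0.2, jitter_sd = 0),
               "outside \\[0,1\\]")

  # mixed classes: realized group levels must order as declared, per region
  set.seed(31)
  combos <- expand.grid(direction = c("hyper", "hypo"),
                        dose_class = c("monotonic", "UG_only", "MG_only"),
                        stringsAsFactors = FALSE)
  eff2 <- data.frame(chrom = "chr1", start = seq(0, 29) * 4000,
                     end = seq(0, 29) * 4000 + 500,
                     direction = combos$direction[rep(1:6, 5)],
                     dose_class = combos$dose_class[rep(1:6, 5)],
                     multiplier = runif(30, 2, 3))
  lsc2 <- plant_methylome(genome, eff2, seed = 3)
  tr <- lsc2$truth
  up <- tr$direction == "hyper"
  mono <- tr$dose_class == "monotonic"
  expect_true(all(tr$m_Ctr[mono & up] <= tr$m_UG[mono & up] &
                    tr$m_UG[mono & up] <= tr$m_MG[mono & up]))
  expect_true(all(tr$m_Ctr[mono & !up] >= tr$m_UG[mono & !up] &
                    tr$m_UG[mono & !up] >= tr$m_MG[mono & !up]))
  ug <- tr$dose_class == "UG_only"
  expect_equal(tr$m_MG[ug], tr$m_Ctr[ug])
  expect_true(all(tr$m_UG[ug & up] > tr$m_Ctr[ug & up]))
  mg <- tr$dose_class == "MG_only"
  expect_equal(tr$m_UG[mg], tr$m_Ctr[mg])
  # group-mean level inside every planted region differs from background
  # in the planted direction
  bg <- lsc2$base_level
  shifted <- ifelse(up, pmax(tr$m_UG, tr$m_MG), pmin(tr$m_UG, tr$m_MG))
  expect_true(all(ifelse(up, shifted > bg, shifted < bg)))
})

test_that("read sampling matches its binomial expectation and zero cases", {
  genome <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 4)
  lsc <- plant_methylome(genome, NULL, jitter_sd = 0, seed = 2)
  smp <- list(sample = "a", group = "Ctr", sex = "M")

  rs0 <- simulate_reads(lsc, genome, sim_config(reads_per_sample = 0),
                        smp)
  expect_equal(nrow(rs0$reads), 0)

  # a zeroed-out tile draws no reads
  lsc_zero <- lsc
  lsc_zero$tiles[3, c("m_Ctr", "m_UG", "m_MG")] <- 0
  rs <- simulate_reads(lsc_zero, genome,
                       sim_config(reads_per_sample = 20000,
                                  depth_sd_log10 = 0), smp)
  z <- lsc_zero$tiles[3, ]
  expect_equal(sum(rs$reads$chrom == z$chrom & rs$reads$start >= z$start &
                     rs$reads$start < z$end), 0)

  # binomial oracle: a region holding weight share p of the genome should
  # draw ~ n*p read starts
  cfg <- sim_config(reads_per_sample = 100000, depth_sd_log10 = 0)
  w <- lsc$tiles$m_Ctr *
    (lsc$tiles$end - lsc$tiles$start) / lsc$tile_size
  nb <- genome$cgis
  nb$start <- pmax(nb$start - 4000, 0)
  nb$end <- pmin(nb$end + 4000, 2e5)
  enr <- rep(1, nrow(lsc$tiles))
  for (i in seq_len(nrow(nb))) {
    hit <- lsc$tiles$chrom == nb$chrom[i] & lsc$tiles$start < nb$end[i] &
      lsc$tiles$end > nb$start[i]
    enr[hit] <- cfg$enrichment_fold
  }
  w <- w * enr
  sexcol <- lsc$sex_effects$male_factor
  for (i in seq_len(nrow(lsc$sex_effects))) {
    se <- lsc$sex_effects[i, ]
    hit <- lsc$tiles$chrom == se$chrom
    w[hit] <- w[hit] * se$male_factor
  }
  region <- lsc$tiles$chrom == "chr1" & lsc$tiles$start < 20000
  p <- sum(w[region]) / sum(w)
  n <- cfg$reads_per_sample
  obs <- vapply(1:5, function(s) {
    cfg$seed <- s
    r <- simulate_reads(lsc, genome, cfg, smp)$reads
    sum(r$chrom == "chr1" & r$start < 20000)
  }, numeric(1))
  expect_lt(abs(mean(obs) - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("realized CpG-territory enrichment tracks the configured fold", {
  fx <- small_fixture()
  folds <- vapply(fx$readsets[c("Ctr1", "MG3")], function(rs)
    measure_enrichment(rs$reads, fx$genome), numeric(1))
  expect_true(all(abs(folds - 2.3) / 2.3 < 0.15))
})

test_that("simulation is seed-deterministic and fixtures round-trip", {
  genome <- build_toy_genome(c(chr1 = 2e5, chrX = 1e5, chrY = 1e5), seed = 4)
  eff <- data.frame(chrom = "chr1", start = 10000, end = 10500,
                    direction = "hyper", dose_class = "monotonic",
                    multiplier = 2)
  lsc <- plant_methylome(genome, eff, seed = 2)
  cfg <- sim_config(reads_per_sample = 5000, seed = 9)
  smp <- list(sample = "Ctr1", group = "Ctr", sex = "F")
  r1 <- simulate_reads(lsc, genome, cfg, smp, sample_index = 2)
  r2 <- simulate_reads(lsc, genome, cfg, smp, sample_index = 2)
  expect_identical(r1, r2)

  dir <- withr::local_tempdir()
  readsets <- list(Ctr1 = r1,
                   UG1 = simulate_reads(lsc, genome, cfg,
                                        list(sample = "UG1", group = "UG",
                                             sex = "M"), 3))
  write_fixture(genome, lsc, readsets, dir)
  back <- read_fixture(dir)

  expect_equal(back$chrom_sizes,
               setNames(genome$chromosomes$length, genome$chromosomes$name))
  expect_equal(back$cgis, genome$cgis)
  expect_equal(back$genes$gene_id, genome$genes$gene_id)
  expect_equal(back$genes$tss, genome$genes$tss)
  expect_equal(back$genes$cds_start, genome$genes$cds_start)
  expect_equal(back$genes$exon_starts, genome$genes$exon_starts,
               ignore_attr = TRUE)
  expect_equal(nrow(back$truth), nrow(lsc$truth))
  for (nm in names(readsets))
    expect_equal(back$readsets[[nm]]$reads, readsets[[nm]]$reads,
                 ignore_attr = TRUE)

  # empty read set still writes a valid (zero-line) BED
  empty <- make_read_set(character(0), numeric(0), numeric(0), character(0),
                         sample = "E1", group = "Ctr", sex = "M")
  write_fixture(genome, lsc, list(E1 = empty), dir)
  expect_equal(nrow(read_reads_bed(file.path(dir, "E1.bed"))), 0)
})
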