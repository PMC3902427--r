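#' @title Synthetic enrichment-sequencing data
#' @description Tools to build a toy genome, plant a methylation landscape
#'   with known dose-response truth, and simulate methylation-enrichment
#'   sequencing reads, so the whole RAM pipeline runs at desk scale against
#'   a known answer.
#' @name synthetic_data
NULL

# ---- toy genome ------------------------------------------------------------

#' Build a toy genome with CpG islands and gene models
#'
#' Chromosome names and lengths are taken as given; CpG islands are placed
#' along each chromosome by a renewal process whose mean start-to-start
#' spacing is `cgi_spacing`, and gene models (transcript span, exon/intron
#' structure, CDS) are laid down with their TSS biased toward CpG islands,
#' as in real mammalian genomes. The genome must contain at least one
#' autosome plus chromosomes named `chrX` and `chrY`, which the sex-contrast
#' QC relies on.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp;
#'   must include `chrX` and `chrY` and at least one other chromosome, all
#'   lengths >= 10 kb.
#' @param cgi_spacing Mean start-to-start spacing of CpG islands in bp.
#' @param cgi_length_range Range (min, max) of CpG-island lengths in bp.
#' @param gene_density Mean genes per bp (default one gene per 100 kb).
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#'
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data frame `name`, `length`), `cgis` (data frame `chrom`, `start`,
#'   `end`; 0-based half-open, non-overlapping), and `genes` (data frame
#'   with `gene_id`, `chrom`, `strand`, `start`, `end`, `cds_start`,
#'   `cds_end`, `tss`, and list columns `exon_starts`, `exon_sizes`).
#' @export
build_toy_genome <- function(chrom_lengths = c(chr1 = 2.5e6, chr2 = 1.5e6,
                                               chrX = 1.5e6, chrY = 5e5),
                             cgi_spacing = 5e4,
                             cgi_length_range = c(300, 1500),
                             gene_density = 1e-5,
                             seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (!all(c("chrX", "chrY") %in% names(chrom_lengths)))
    stop("genome must include chromosomes named 'chrX' and 'chrY'")
  if (sum(!names(chrom_lengths) %in% c("chrX", "chrY")) < 1L)
    stop("genome must include at least one autosome")
  if (any(chrom_lengths < 1e4))
    stop("all chromosome lengths must be >= 10 kb")
  if (cgi_spacing <= diff(range(cgi_length_range)) + cgi_length_range[2])
    stop("cgi_spacing too small for the requested CGI lengths")

  set.seed(as.integer(seed))
  chroms <- data.frame(name = names(chrom_lengths),
                       length = as.numeric(chrom_lengths),
                       stringsAsFactors = FALSE)

  mean_len <- mean(cgi_length_range)
  cgi <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    starts <- numeric(0)
    lens <- numeric(0)
    pos <- stats::rexp(1, 1 / cgi_spacing)
    while (pos + cgi_length_range[2] < L) {
      len <- round(runif(1, cgi_length_range[1], cgi_length_range[2]))
      starts <- c(starts, round(pos))
      lens <- c(lens, len)
      # start-to-start gap averages cgi_spacing; islands never overlap
      pos <- pos + len + 200 +
        stats::rexp(1, 1 / max(cgi_spacing - mean_len - 200, 1))
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = chroms$name[i], start = starts, end = starts + lens,
               stringsAsFactors = FALSE)
  }))
  rownames(cgi) <- NULL

  genes <- .place_genes(chroms, cgi, gene_density)

  structure(list(chromosomes = chroms, cgis = cgi, genes = genes),
            class = "genome_model")
}

# gene models: TSS biased to CGI edges, alternating exon/intron structure,
# CDS spanning from inside the first exon to inside the last
.place_genes <- function(chroms, cgi, gene_density) {
  out <- list()
  gid <- 0L
  for (i in seq_len(nrow(chroms))) {
    chrom <- chroms$name[i]
    L <- chroms$length[i]
    n_genes <- max(1L, round(L * gene_density))
    chrom_cgis <- cgi[cgi$chrom == chrom, , drop = FALSE]
    for (g in seq_len(n_genes)) {
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:6, 1L)
      ex_len <- round(runif(n_ex, 150, 400))
      in_len <- if (n_ex > 1) round(runif(n_ex - 1, 500, 3000)) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      # ~70% of TSSs sit at a CpG island; the rest are placed uniformly
      if (nrow(chrom_cgis) > 0 && runif(1) < 0.7) {
        k <- sample.int(nrow(chrom_cgis), 1L)
        tss <- if (strand == "+") chrom_cgis$start[k] + round(runif(1, 0, 200))
               else chrom_cgis$end[k] - round(runif(1, 0, 200))
      } else {
        if (L < 15000) next  # too short to place a free-standing gene
        tss <- round(runif(1, 6000, L - 6000))
      }
      start <- if (strand == "+") tss else tss - span + 1L
      if (start < 0 || start + span > L) next
      bounds <- cumsum(c(0, as.vector(rbind(ex_len,
                                            c(in_len, 0))))[seq_len(2 * n_ex)])
      ex_start <- start + bounds[seq(1, 2 * n_ex - 1, by = 2)]
      cds_start <- ex_start[1] + round(ex_len[1] / 2)
      cds_end <- ex_start[n_ex] + round(ex_len[n_ex] / 2)
      out[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid), chrom = chrom, strand = strand,
        start = start, end = start + span,
        cds_start = cds_start, cds_end = cds_end,
        tss = if (strand == "+") start else start + span - 1L,
        stringsAsFactors = FALSE)
      out[[gid]]$exon_starts <- list(as.numeric(ex_start))
      out[[gid]]$exon_sizes <- list(as.numeric(ex_len))
    }
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  genes
}

# ---- planted methylome -----------------------------------------------------

#' Plant a methylation landscape with known differential regions
#'
#' Lays a piecewise-constant methylation level over fixed-size tiles of the
#' genome (background level `base_level` with small per-tile jitter), then
#' overwrites the tiles inside each planted region with group-specific
#' levels that realize the requested direction and dose-response class:
#'
#' * `monotonic`: levels ordered Ctr <= UG <= MG (hyper) or the reverse
#'   (hypo), with the low dose at the geometric midpoint;
#' * `UG_only`: only the low-dose group shifted, MG identical to Ctr
#'   (the non-monotonic case);
#' * `MG_only`: only the high-dose group shifted.
#'
#' A `multiplier` of k means the affected group's level is k-fold the
#' background (hyper) or background/k (hypo).
#'
#' @param genome A `genome_model` from [build_toy_genome()].
#' @param effects Data frame of planted regions with columns `chrom`,
#'   `start`, `end`, `direction` (`"hyper"`/`"hypo"`), `dose_class`
#'   (`"monotonic"`/`"UG_only"`/`"MG_only"`), `multiplier` (> 1). `NULL`
#'   plants nothing.
#' @param base_level Background methylation level in `[0,1]`.
#' @param jitter_sd SD of the per-tile jitter on the background level.
#' @param tile_size Tile width in bp (sub-window resolution is not needed:
#'   the analysis operates at 100 bp windows).
#' @param seed Integer seed.
#'
#' @return An object of class `methylation_landscape`: list with `tiles`
#'   (data frame `chrom`, `start`, `end`, `m_Ctr`, `m_UG`, `m_MG`), `truth`
#'   (the effects table plus realized per-group levels), `sex_effects`
#'   (chrX/chrY sampling-weight factors by sex), `tile_size`, `base_level`.
#' @export
plant_methylome <- function(genome, effects = NULL, base_level = 0.25,
                            jitter_sd = 0.015, tile_size = 500L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  set.seed(as.integer(seed))
  tiles <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)),
    function(i) {
      L <- genome$chromosomes$length[i]
      s <- seq(0, L - 1, by = tile_size)
      data.frame(chrom = genome$chromosomes$name[i], start = s,
                 end = pmin(s + tile_size, L), stringsAsFactors = FALSE)
    }))
  m <- pmin(pmax(base_level + rnorm(nrow(tiles), 0, jitter_sd), 0.01), 1)
  tiles$m_Ctr <- tiles$m_UG <- tiles$m_MG <- m

  truth <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      dose_class = character(0), multiplier = numeric(0),
                      m_Ctr = numeric(0), m_UG = numeric(0),
                      m_MG = numeric(0), stringsAsFactors = FALSE)

  if (!is.null(effects) && nrow(effects)) {
    stopifnot(all(c("chrom", "start", "end", "direction", "dose_class",
                    "multiplier") %in% names(effects)))
    lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
    if (any(!effects$chrom %in% names(lens)))
      stop("planted interval on unknown chromosome")
    if (any(effects$start < 0 | effects$end > lens[effects$chrom] |
            effects$start >= effects$end))
      stop("planted interval outside chromosome bounds")
    eg <- .interval_overlaps(effects, effects)
    if (any(eg$from != eg$to)) stop("planted regions must not overlap")

    rows <- vector("list", nrow(effects))
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      fac <- .dose_factors(e$direction, e$dose_class, e$multiplier)
      hit <- tiles$chrom == e$chrom & tiles$start < e$end & tiles$end > e$start
      base <- tiles$m_Ctr[hit]
      lv <- outer(base, fac)
      if (any(lv > 1 | lv < 0))
        stop(sprintf("effect %d: multiplier pushes level outside [0,1]", k))
      tiles$m_Ctr[hit] <- lv[, 1]
      tiles$m_UG[hit] <- lv[, 2]
      tiles$m_MG[hit] <- lv[, 3]
      # truth records the realized extent: the hull of affected tiles
      # (levels are piecewise-constant per tile)
      rows[[k]] <- cbind(data.frame(chrom = e$chrom,
                                    start = min(tiles$start[hit]),
                                    end = max(tiles$end[hit]),
                                    direction = e$direction,
                                    dose_class = e$dose_class,
                                    multiplier = e$multiplier,
                                    stringsAsFactors = FALSE),
                         m_Ctr = mean(lv[, 1]), m_UG = mean(lv[, 2]),
                         m_MG = mean(lv[, 3]))
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
  }

  sex_effects <- .default_sex_effects(genome)

  structure(list(tiles = tiles, truth = truth, sex_effects = sex_effects,
                 tile_size = as.integer(tile_size), base_level = base_level),
            class = "methylation_landscape")
}

# per-group level factors (Ctr, UG, MG) for one planted effect
.dose_factors <- function(direction, dose_class, multiplier) {
  stopifnot(direction %in% c("hyper", "hypo"),
            dose_class %in% c("monotonic", "UG_only", "MG_only"),
            multiplier > 1)
  k <- if (direction == "hyper") multiplier else 1 / multiplier
  switch(dose_class,
         monotonic = c(1, sqrt(k), k),
         UG_only = c(1, k, 1),
         MG_only = c(1, 1, k))
}

# chrX dosage (female two X copies) and male-specific chrY with a small
# female background leak, emulating the sex signal used for the FDR check
.default_sex_effects <- function(genome, female_chry_leak = 0.005) {
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  data.frame(
    chrom = c("chrX", "chrY"),
    start = c(0, 0),
    end = as.numeric(lens[c("chrX", "chrY")]),
    male_factor = c(1, 1),
    female_factor = c(2, female_chry_leak),
    stringsAsFactors = FALSE)
}

# ---- read simulation -------------------------------------------------------

#' Simulation settings for enrichment-sequencing reads
#'
#' @param reads_per_sample Target reads per sample before the per-sample
#'   depth scatter.
#' @param read_length Single-end read length in bp (default 80).
#' @param enrichment_fold Target fold enrichment of read depth in CpG-rich
#'   territory (CpG islands +/- 4 kb) relative to the rest of the genome;
#'   default 2.3, the enrichment level typical of methylation-dependent
#'   restriction-enzyme libraries.
#' @param depth_sd_log10 SD (log10 scale) of the per-sample library-size
#'   scatter; 0 gives exactly `reads_per_sample` reads.
#' @param seed Master seed; sample `i` (0-based index) uses stream
#'   `seed + i`, so single samples can be regenerated in isolation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(reads_per_sample = 500000L, read_length = 80L,
                       enrichment_fold = 2.3, depth_sd_log10 = 0.1,
                       seed = 1L) {
  stopifnot(reads_per_sample >= 0, read_length >= 1, enrichment_fold >= 1,
            depth_sd_log10 >= 0)
  structure(list(reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 enrichment_fold = enrichment_fold,
                 depth_sd_log10 = depth_sd_log10,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The 12-sample, three-dose study design
#'
#' Four animals per exposure group (control, low dose `UG`, high dose `MG`);
#' the control and low-dose groups each have two males and two females, the
#' high-dose group one male and three females (5 males, 7 females overall).
#'
#' @return Data frame with columns `sample`, `group`, `sex`.
#' @export
default_sample_sheet <- function() {
  data.frame(
    sample = c(paste0("Ctr", 1:4), paste0("UG", 1:4), paste0("MG", 1:4)),
    group = rep(c("Ctr", "UG", "MG"), each = 4L),
    sex = c("M", "M", "F", "F", "M", "M", "F", "F", "M", "F", "F", "F"),
    stringsAsFactors = FALSE)
}

#' Simulate enrichment-sequencing reads for one sample
#'
#' Reads are drawn tile by tile with sampling weight proportional to the
#' tile's methylation level for the sample's group, times a CpG-density
#' enrichment factor (`enrichment_fold` inside CpG islands +/- 4 kb, 1
#' elsewhere), times the sex factor on chrX/chrY (female X dosage; chrY
#' reads essentially male-only). Read starts are uniform within the tile;
#' the read end is start + read length, clipped at the chromosome end.
#'
#' @param landscape A `methylation_landscape`.
#' @param genome The matching `genome_model`.
#' @param simcfg A [sim_config()].
#' @param sample A list or one-row data frame with `sample`, `group`
#'   (`"Ctr"`, `"UG"` or `"MG"`), `sex` (`"M"`/`"F"`).
#' @param sample_index 0-based index of the sample in the experiment; the
#'   RNG stream is `simcfg$seed + sample_index`.
#'
#' @return An object of class `read_set`: list with `reads` (data frame
#'   `chrom`, `start`, `end`, `strand`, sorted by position; 0-based
#'   half-open), and the sample metadata.
#' @export
simulate_reads <- function(landscape, genome, simcfg, sample,
                           sample_index = 0L) {
  stopifnot(inherits(landscape, "methylation_landscape"),
            inherits(genome, "genome_model"),
            inherits(simcfg, "sim_config"))
  sample <- as.list(sample)
  stopifnot(sample$group %in% GROUP_LEVELS, sample$sex %in% c("M", "F"))
  set.seed(as.integer(simcfg$seed) + as.integer(sample_index))

  tiles <- landscape$tiles
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  mk <- function(reads) structure(list(reads = reads,
                                       sample = sample$sample,
                                       group = sample$group, sex = sample$sex),
                                  class = "read_set")
  if (nrow(tiles) == 0) {
    warning("empty landscape: returning an empty read set")
    return(mk(empty))
  }

  w <- tiles[[paste0("m_", sample$group)]] * (tiles$end - tiles$start) /
    landscape$tile_size
  w <- w * .enrichment_weight(tiles, genome, simcfg$enrichment_fold)
  sexcol <- if (sample$sex == "M") "male_factor" else "female_factor"
  for (i in seq_len(nrow(landscape$sex_effects))) {
    se <- landscape$sex_effects[i, ]
    hit <- tiles$chrom == se$chrom & tiles$start < se$end & tiles$end > se$start
    w[hit] <- w[hit] * se[[sexcol]]
  }

  n <- simcfg$reads_per_sample
  if (simcfg$depth_sd_log10 > 0 && n > 0)
    n <- max(1L, round(n * 10^rnorm(1, 0, simcfg$depth_sd_log10)))
  if (n == 0 || sum(w) <= 0) return(mk(empty))

  per_tile <- as.vector(stats::rmultinom(1, n, w))
  idx <- rep.int(seq_len(nrow(tiles)), per_tile)
  width <- tiles$end[idx] - tiles$start[idx]
  start <- tiles$start[idx] + floor(runif(length(idx)) * width)
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  reads <- data.frame(chrom = tiles$chrom[idx], start = start,
                      end = pmin(start + simcfg$read_length,
                                 lens[tiles$chrom[idx]]),
                      strand = base::sample(c("+", "-"), length(idx),
                                            replace = TRUE),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  reads <- reads[order(match(reads$chrom, genome$chromosomes$name),
                       reads$start), , drop = FALSE]
  rownames(reads) <- NULL
  mk(reads)
}

# fold weight for tiles overlapping CGI +/- flank
.enrichment_weight <- function(tiles, genome, fold, flank = 4000L) {
  nb <- genome$cgis
  nb$start <- pmax(nb$start - flank, 0)
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  nb$end <- pmin(nb$end + flank, lens[nb$chrom])
  hit <- .overlaps_any(tiles, nb)
  ifelse(hit, fold, 1)
}

#' Simulate the full multi-sample experiment
#'
#' @inheritParams simulate_reads
#' @param samples Sample sheet (see [default_sample_sheet()]).
#' @return Named list of `read_set` objects, one per sample sheet row.
#' @export
simulate_experiment <- function(landscape, genome, simcfg,
                                samples = default_sample_sheet()) {
  out <- lapply(seq_len(nrow(samples)), function(i) {
    simulate_reads(landscape, genome, simcfg, samples[i, ],
                   sample_index = i - 1L)
  })
  names(out) <- samples$sample
  out
}

#' Measure the realized CpG-territory enrichment of a read set
#'
#' Ratio of mean read-anchor density (reads per bp) inside CpG islands
#' +/- `flank` to the density outside; compares the simulator's output to
#' its configured fold, and can equally be applied to real alignments.
#'
#' @param reads Data frame of reads (`chrom`, `start`, `end`).
#' @param genome A `genome_model` (or list with `cgis` and `chromosomes`).
#' @param flank Neighborhood half-width in bp.
#' @return The observed fold enrichment (a single number).
#' @export
measure_enrichment <- function(reads, genome, flank = 4000L) {
  nb <- genome$cgis
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  nb$start <- pmax(nb$start - flank, 0)
  nb$end <- pmin(nb$end + flank, lens[nb$chrom])
  gr <- GenomicRanges::reduce(.df0_to_gr(nb))
  bp_in <- sum(GenomicRanges::width(gr))
  bp_out <- sum(lens) - bp_in
  anchors <- data.frame(chrom = reads$chrom, start = reads$start,
                        end = reads$start + 1)
  n_in <- sum(.overlaps_any(anchors, nb))
  (n_in / bp_in) / ((nrow(reads) - n_in) / bp_out)
}

# ---- data-frame interval helpers (0-based half-open) -----------------------

.df0_to_gr <- function(df, strand = NULL) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end),
                         strand = if (is.null(strand)) "*" else strand)
}

.gr_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

.overlaps_any <- function(query, subject) {
  # seqlevel mismatches between query and subject are expected, not a worry
  suppressWarnings(IRanges::overlapsAny(.df0_to_gr(query),
                                        .df0_to_gr(subject)))
}

.interval_overlaps <- function(query, subject) {
  h <- suppressWarnings(GenomicRanges::findOverlaps(.df0_to_gr(query),
                                                    .df0_to_gr(subject)))
  data.frame(from = S4Vectors::queryHits(h), to = S4Vectors::subjectHits(h))
}
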