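# End-to-end orchestration: simulate a fixture to disk, run the complete
# analysis from fixture files to annotated RAM tables, and score calls
# against planted truth. The pipeline itself is deterministic (no RNG), so
# re-running on the same inputs reproduces byte-identical outputs.

#' Default planted differential regions for the toy experiment
#'
#' Plants `n` regions of `width` bp on autosomal CpG-island shores (where
#' enrichment-seq coverage is high enough to test), cycling through all
#' direction x dose-class combinations. chrX/chrY are left untouched so the
#' sex-contrast QC sees only the built-in sex effects.
#'
#' @param genome A `genome_model`.
#' @param n Number of planted regions.
#' @param width Region width in bp.
#' @param multiplier Effect multiplier (k-fold up for hyper, down for
#'   hypo).
#' @param seed Integer seed for site selection.
#' @return Effects data frame for [plant_methylome()] (columns `chrom`,
#'   `start`, `end`, `direction`, `dose_class`, `multiplier`).
#' @export
default_effects <- function(genome, n = 36L, width = 500L, multiplier = 3,
                            seed = 1L) {
  set.seed(as.integer(seed))
  auto <- genome$cgis[!genome$cgis$chrom %in% c("chrX", "chrY"), ,
                      drop = FALSE]
  if (nrow(auto) < n)
    stop("not enough autosomal CpG islands to plant ", n, " regions")
  pick <- sort(base::sample(seq_len(nrow(auto)), n))
  combos <- expand.grid(direction = c("hyper", "hypo"),
                        dose_class = c("monotonic", "UG_only", "MG_only"),
                        stringsAsFactors = FALSE)
  k <- rep(seq_len(nrow(combos)), length.out = n)
  # right shore of the chosen island, snapped to the landscape tile grid
  # (still well inside the CpG-enriched sampling zone)
  start <- round(auto$end[pick] / 500) * 500
  data.frame(chrom = auto$chrom[pick],
             start = start,
             end = start + width,
             direction = combos$direction[k],
             dose_class = combos$dose_class[k],
             multiplier = multiplier,
             stringsAsFactors = FALSE)
}

#' Simulate a complete fixture experiment to disk
#'
#' Builds the toy genome, plants the methylation landscape, simulates
#' enrichment-seq reads for the 12-sample three-dose design, and writes
#' everything as plain-text fixture files.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for all stages.
#' @param chrom_lengths,cgi_spacing Passed to [build_toy_genome()].
#' @param effects Planted effects; `NULL` uses [default_effects()].
#' @param simcfg A [sim_config()]; its seed is overridden by `seed`.
#' @param samples Sample sheet (default [default_sample_sheet()]).
#' @return List with `genome`, `landscape`, `readsets`, `dir`, invisibly.
#' @export
simulate_fixture <- function(out_dir, seed = 1L,
                             chrom_lengths = c(chr1 = 2.5e6, chr2 = 1.5e6,
                                               chrX = 1.5e6, chrY = 5e5),
                             cgi_spacing = 5e4,
                             effects = NULL,
                             simcfg = sim_config(),
                             samples = default_sample_sheet()) {
  genome <- build_toy_genome(chrom_lengths, cgi_spacing = cgi_spacing,
                             seed = seed)
  if (is.null(effects)) effects <- default_effects(genome, seed = seed)
  landscape <- plant_methylome(genome, effects, seed = seed)
  simcfg$seed <- as.integer(seed)
  readsets <- simulate_experiment(landscape, genome, simcfg, samples)
  write_fixture(genome, landscape, readsets, out_dir)
  invisible(list(genome = genome, landscape = landscape,
                 readsets = readsets, dir = out_dir))
}

#' Run the complete RAM pipeline on a fixture directory
#'
#' Stages: read inputs, tile and count windows, coverage filter, effective
#' library sizes, common-dispersion estimate, the three pairwise NB
#' comparisons, RAM filter chain, merging, CGI/gene-context annotation and
#' distributions, enrichment versus the library background, promoter
#' assignment and dose-response classification, promoter heatmap, sex-based
#' FDR QC, cross-comparison overlap. All tables are written to `out_dir`
#' (TSV/BED, 0-based half-open) along with a JSON manifest of configuration,
#' input digests and per-stage counts.
#'
#' @param input_dir Fixture directory (see [read_fixture()] for layout).
#' @param out_dir Output directory; `NULL` writes nothing.
#' @param cfg A [ram_config()].
#' @param normalization `"raw"` or `"trimmed"` (see
#'   [effective_library_sizes()]).
#' @param verbose Log stage counts via `message()`.
#' @return List of class `ram_run`: `counts` (filtered `ram_counts`),
#'   `sizes`, `dispersion`, `diff` (per-comparison test tables), `rams`
#'   (per-comparison filter results), `regions` (merged), `annotation`,
#'   `context` (RAM and library context distributions and enrichment),
#'   `promoter` (classification, summary, heatmap), `qc` (sex FDR report,
#'   overlap), `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, cfg = ram_config(),
                         normalization = c("trimmed", "raw"),
                         verbose = TRUE) {
  normalization <- match.arg(normalization)
  say <- function(...) if (verbose) message(sprintf(...))
  fx <- read_fixture(input_dir)

  say("tiling + counting %d samples over %d bp", nrow(fx$samples),
      sum(fx$chrom_sizes))
  counts_all <- count_reads(fx$readsets, fx$chrom_sizes, cfg)
  n_tiled <- nrow(counts_all$counts)
  m <- filter_low_coverage(counts_all, cfg)
  say("windows: %d tiled, %d retained after coverage filter", n_tiled,
      nrow(m$counts))

  sizes <- effective_library_sizes(m, method = normalization)
  disp <- estimate_common_dispersion(m, sizes = sizes)
  say("common dispersion phi = %.4f (%d windows)", disp$phi,
      disp$n_windows_used)

  diff <- run_all_comparisons(m, disp, sizes = sizes)
  rams <- lapply(names(COMPARISONS), function(nm) {
    cmp <- COMPARISONS[[nm]]
    r <- call_rams(diff[[nm]], m, cmp[["A"]], cmp[["B"]], cfg, sizes)
    say("%s: %d prelim -> %d supported -> %d final", nm,
        r$counts["prelim"], r$counts["support_ok"], r$counts["final"])
    r
  })
  names(rams) <- names(COMPARISONS)
  regions <- lapply(rams, function(r) merge_rams(r$final))

  ann <- build_annotation(fx$cgis, fx$genes, fx$chrom_sizes, cfg)
  cgi_cats <- c("CGI", "shore", "shelf", "open_sea")
  lib_labels <- classify_cgi_context(m$windows, ann)
  # library background in reads: retained windows weighted by total counts
  lib_dist <- context_distribution(lib_labels, cgi_cats,
                                   weights = rowSums(m$counts))
  context <- list(library = lib_dist)
  for (nm in names(rams)) {
    fin <- annotate_rams(rams[[nm]]$final, ann)
    rams[[nm]]$final <- fin
    if (nrow(fin)) {
      d <- context_distribution(fin$cgi_context, cgi_cats)
      context[[nm]] <- list(
        distribution = d,
        enrichment = enrichment_vs_background(d, lib_dist),
        gene_distribution = context_distribution(
          fin$gene_context, c("CDS_exon", "UTR5", "UTR3", "TSS_up_1kb",
                              "TSS_up_5kb", "intron", "intergenic")))
    }
  }

  prom <- lapply(rams, function(r) assign_promoters(r$final, ann))
  cls <- classify_promoter_dose_response(prom$Ctr_vs_UG, prom$Ctr_vs_MG)
  summ <- promoter_summary(cls)
  say("promoters: %d gain / %d loss (grand total %d)", summ$gain_total,
      summ$loss_total, summ$grand_total)
  heat <- heatmap_matrix(rbind(prom$Ctr_vs_UG, prom$Ctr_vs_MG), m, ann,
                         cls = cls, cfg = cfg, sizes = sizes)

  qc <- sex_based_fdr(m, disp, cfg, sizes)
  say("sex contrast: X=%d Y=%d autosomes=%d -> max FDR %.1f%%",
      qc$x_count, qc$y_count, qc$autosome_count, qc$max_fdr_percent)
  overlap <- comparison_overlap(lapply(rams, `[[`, "final"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ramscan")),
    config = unclass(cfg),
    normalization = normalization,
    input_digests = as.list(tools::md5sum(Filter(
      function(f) !dir.exists(f),
      sort(list.files(input_dir, full.names = TRUE))))),
    stage_counts = list(
      windows_tiled = n_tiled,
      windows_retained = nrow(m$counts),
      per_comparison = lapply(rams, function(r) as.list(r$counts))),
    dispersion = disp$phi,
    coordinates = "0-based half-open (BED)")

  run <- structure(list(counts = m, sizes = sizes, dispersion = disp,
                        diff = diff, rams = rams, regions = regions,
                        annotation = ann, context = context,
                        promoter = list(assignments = prom,
                                        classification = cls,
                                        summary = summ, heatmap = heat),
                        qc = list(sex_fdr = qc, overlap = overlap),
                        manifest = manifest),
                   class = "ram_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  for (nm in names(run$diff)) {
    wt(run$diff[[nm]][, c("chrom", "start", "end", "comparison", "log2FC",
                          "lrt", "p", "direction", "fdr")],
       paste0("diff_", nm, ".tsv"))
    wt(run$rams[[nm]]$rams, paste0("rams_", nm, ".tsv"))
    if (nrow(run$rams[[nm]]$final))
      write_rams_bed(run$rams[[nm]]$final,
                     file.path(out_dir, paste0("rams_", nm, ".bed")))
    wt(run$regions[[nm]], paste0("regions_", nm, ".tsv"))
  }
  ctx <- do.call(rbind, lapply(names(run$context), function(nm) {
    d <- if (nm == "library") run$context[[nm]]
         else run$context[[nm]]$distribution
    data.frame(set = nm, category = names(d), proportion = as.numeric(d))
  }))
  wt(ctx, "context_distributions.tsv")
  wt(run$promoter$classification, "promoter_classes.tsv")
  hm <- run$promoter$heatmap$matrix
  wt(cbind(promoter = rownames(hm), class = run$promoter$heatmap$row_class,
           as.data.frame(hm)), "promoter_heatmap.tsv")
  qc <- run$qc$sex_fdr
  wt(data.frame(metric = c("chrX", "chrY", "autosomes", "total",
                           "max_fdr_percent", "female_chrY_hyper"),
                value = c(qc$x_count, qc$y_count, qc$autosome_count,
                          qc$total, qc$max_fdr_percent,
                          qc$female_chry_hyper)),
     "qc_sex_fdr.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Score final RAM calls against planted truth
#'
#' A planted region counts as recovered when, in at least one comparison
#' where its group levels predict a difference, a final RAM window of the
#' predicted direction overlaps it. The false-call fraction is the share of
#' final RAM windows (all three comparisons pooled) lying outside every
#' planted region and outside the sex-effect chromosomes (whose dosage
#' differences between unbalanced groups are real simulated signal, not
#' noise).
#'
#' @param rams Named list of final RAM data frames (the three exposure
#'   comparisons, as in `run_pipeline()$rams[[i]]$final`).
#' @param truth Truth table with realized per-group levels (`m_Ctr`,
#'   `m_UG`, `m_MG`), from `plant_methylome()$truth` or `truth.tsv` plus
#'   re-derivation.
#' @param sex_chroms Chromosomes carrying built-in sex effects.
#' @return List: `sensitivity` (fraction of planted regions recovered),
#'   `false_window_percent`, `per_region` (logical vector), `n_false`,
#'   `n_windows`.
#' @export
evaluate_recovery <- function(rams, truth, sex_chroms = c("chrX", "chrY")) {
  if (!all(c("m_Ctr", "m_UG", "m_MG") %in% names(truth)))
    truth <- .truth_levels(truth)
  eps <- 1e-9
  recovered <- rep(FALSE, nrow(truth))
  for (nm in names(rams)) {
    cmp <- COMPARISONS[[nm]]
    ma <- truth[[paste0("m_", cmp[["A"]])]]
    mb <- truth[[paste0("m_", cmp[["B"]])]]
    expected <- ifelse(mb > ma + eps, "hyper",
                       ifelse(mb < ma - eps, "hypo", "none"))
    fin <- rams[[nm]]
    if (!nrow(fin)) next
    for (dir in c("hyper", "hypo")) {
      idx <- which(expected == dir)
      if (!length(idx)) next
      sub <- fin[fin$direction == dir, , drop = FALSE]
      if (!nrow(sub)) next
      hit <- .interval_overlaps(truth[idx, , drop = FALSE], sub)
      recovered[idx[unique(hit$from)]] <- TRUE
    }
  }
  all_windows <- do.call(rbind, lapply(rams, function(f)
    f[, c("chrom", "start", "end")]))
  n_windows <- nrow(all_windows)
  outside <- !all_windows$chrom %in% sex_chroms &
    !.overlaps_any(all_windows, truth)
  list(sensitivity = mean(recovered),
       false_window_percent = if (n_windows > 0)
         100 * sum(outside) / n_windows else 0,
       per_region = recovered,
       n_false = sum(outside), n_windows = n_windows)
}

# reconstruct per-group expected levels from a bare truth table
.truth_levels <- function(truth, base = 1) {
  fac <- t(vapply(seq_len(nrow(truth)), function(i)
    .dose_factors(truth$direction[i], truth$dose_class[i],
                  truth$multiplier[i]), numeric(3)))
  truth$m_Ctr <- base * fac[, 1]
  truth$m_UG <- base * fac[, 2]
  truth$m_MG <- base * fac[, 3]
  truth
}
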