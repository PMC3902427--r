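# Sex-contrast quality control: running the identical RAM pipeline on a
# male-versus-female relabeling of the samples gives an empirical upper
# bound on the false discovery rate -- autosomal calls in that contrast are
# treated as false positives, X/Y calls as true sex differences. Also the
# cross-comparison overlap (distinct-RAM) statistics.

#' Sex-based maximum-FDR report from chromosome-class counts
#'
#' Pure arithmetic on final significant-window counts from the
#' male-versus-female contrast: `max_fdr_percent = 100 * autosomal /
#' (X + Y + autosomal)`, rounded to one decimal. This is an upper bound on
#' the FDR of the exposure comparisons run with the same thresholds --
#' genuinely sex-different autosomal regions would inflate it.
#'
#' @param x_count,y_count,autosome_count Final window counts on chrX, chrY
#'   and the autosomes.
#' @return List of class `sex_fdr_report`: the three counts, `total`,
#'   `max_fdr_percent`, and `female_chry_hyper` (`NA` here; filled by
#'   [sex_based_fdr()]).
#' @export
sex_fdr_report <- function(x_count, y_count, autosome_count) {
  total <- x_count + y_count + autosome_count
  structure(list(x_count = x_count, y_count = y_count,
                 autosome_count = autosome_count, total = total,
                 max_fdr_percent = if (total > 0)
                   round(100 * autosome_count / total, 1) else 0.0,
                 female_chry_hyper = NA_integer_),
            class = "sex_fdr_report")
}

#' @export
print.sex_fdr_report <- function(x, ...) {
  cat(sprintf(
    "sex-contrast windows: chrX %d, chrY %d, autosomes %d (total %d)\n",
    x$x_count, x$y_count, x$autosome_count, x$total))
  cat(sprintf("maximum FDR estimate: %.1f%%\n", x$max_fdr_percent))
  if (!is.na(x$female_chry_hyper))
    cat(sprintf("female-hypermethylated chrY windows: %d (QC %s)\n",
                x$female_chry_hyper,
                if (x$female_chry_hyper == 0) "pass" else "FAIL"))
  invisible(x)
}

#' Sex-based empirical maximum-FDR estimate
#'
#' Runs the full RAM pipeline -- the same test, support and adjacency
#' filters as the exposure comparisons -- on a male-versus-female grouping
#' of the samples, then tallies final windows by chromosome class. Calls
#' `run_comparison()` and `call_rams()` directly, so the code path is
#' identical to the exposure analysis by construction.
#'
#' @param m A `ram_counts` object after [filter_low_coverage()].
#' @param phi Common dispersion for the sex contrast (a
#'   `dispersion_estimate` or number).
#' @param cfg A [ram_config()].
#' @param sizes Optional effective library sizes.
#' @return A `sex_fdr_report` with `female_chry_hyper` filled in, plus the
#'   final sex-contrast RAM records attached as `$rams`.
#' @export
sex_based_fdr <- function(m, phi, cfg = ram_config(), sizes = NULL) {
  sex <- m$samples$sex
  if (is.null(sex) || anyNA(sex) || any(!nzchar(sex)))
    stop("missing sex labels in the sample sheet")
  if (sum(sex == "M") < 2 || sum(sex == "F") < 2)
    stop("need >= 2 samples of each sex")
  m_sex <- m
  m_sex$samples$group <- sex  # relabeled design; nothing else changes
  d <- run_comparison(m_sex, "M", "F", phi, sizes = sizes,
                      comparison = "M_vs_F")
  res <- call_rams(d, m_sex, "M", "F", cfg, sizes)
  fin <- res$final
  cls <- .chrom_class(fin$chrom)
  rep <- sex_fdr_report(sum(cls == "chrX"), sum(cls == "chrY"),
                        sum(cls == "autosome"))
  rep$female_chry_hyper <- female_chry_qc(fin)
  rep$rams <- fin
  rep
}

.chrom_class <- function(chrom) {
  ifelse(chrom == "chrX", "chrX", ifelse(chrom == "chrY", "chrY", "autosome"))
}

#' Count female-hypermethylated chrY windows
#'
#' In the male-versus-female contrast (female as the elevated-direction
#' group), chrY coverage should be male-only up to background leakage, so
#' any final chrY window called hyper in females is a red flag. QC passes
#' at 0.
#'
#' @param sex_rams Final RAM records from the M-vs-F comparison (hyper =
#'   elevated in females).
#' @return Integer count.
#' @export
female_chry_qc <- function(sex_rams) {
  if (!nrow(sex_rams)) return(0L)
  sum(sex_rams$chrom == "chrY" & sex_rams$direction == "hyper")
}

#' Cross-comparison overlap of RAM window sets
#'
#' Windows are identified by (chrom, start). Reports per-comparison sizes,
#' the union, the 7-cell Venn partition, the number of windows distinct to
#' a single comparison, and the integer-rounded distinct percentage.
#'
#' @param sets Named list of three RAM data frames (or character vectors of
#'   window ids).
#' @return List of class `ram_overlap`: `sizes`, `union_size`, `venn`
#'   (named 7-vector; names like `"A"`, `"AB"`, `"ABC"` refer to the list
#'   order), `distinct`, `distinct_percent`.
#' @export
comparison_overlap <- function(sets) {
  stopifnot(length(sets) == 3)
  ids <- lapply(sets, function(s) {
    if (is.character(s)) unique(s) else unique(paste(s$chrom, s$start))
  })
  u <- unique(unlist(ids))
  inA <- u %in% ids[[1]]; inB <- u %in% ids[[2]]; inC <- u %in% ids[[3]]
  venn <- c(A = sum(inA & !inB & !inC), B = sum(!inA & inB & !inC),
            C = sum(!inA & !inB & inC), AB = sum(inA & inB & !inC),
            AC = sum(inA & !inB & inC), BC = sum(!inA & inB & inC),
            ABC = sum(inA & inB & inC))
  distinct <- venn[["A"]] + venn[["B"]] + venn[["C"]]
  structure(list(
    sizes = setNames(lengths(ids), names(sets)),
    union_size = length(u), venn = venn, distinct = distinct,
    distinct_percent = if (length(u) > 0)
      round(100 * distinct / length(u)) else 0L),
    class = "ram_overlap")
}

#' Distinct-RAM percentage from printed counts
#'
#' The same rounding used in reports, applied to externally supplied
#' distinct and union counts.
#'
#' @param distinct,union_size Window counts.
#' @return Integer percent.
#' @export
distinct_percent <- function(distinct, union_size) {
  round(100 * distinct / union_size)
}

#' @export
print.ram_overlap <- function(x, ...) {
  cat("RAM overlap across comparisons\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                        collapse = ", "), "\n")
  cat(sprintf("  union %d; distinct %d (%d%%)\n", x$union_size, x$distinct,
              x$distinct_percent))
  invisible(x)
}
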