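#' Pipeline configuration
#'
#' Collects every tuning constant of the RAM-calling pipeline in one
#' validated list. The defaults are the published operating point of the
#' tiered analysis: 100 bp windows shifted by 50 bp, a coverage floor of 10
#' reads in 25% of samples, a raw p-value gate at 0.05, support from at
#' least half (minimum 2) of the samples per group, a 500 bp adjacency
#' stretch, promoters at TSS +/- 1.5 kb, shores and shelves extending 2 kb
#' each beyond CpG islands, and a 5-fold change gate for the promoter
#' heatmap.
#'
#' @param window_size Window width in bp.
#' @param window_shift Moving shift in bp; must divide `window_size`.
#' @param min_reads Coverage floor: minimum reads in a window for a sample
#'   to count toward retention.
#' @param min_sample_fraction Fraction of samples that must reach
#'   `min_reads` for a window to be retained (ceiling is applied).
#' @param alpha Raw p-value threshold for preliminary RAM calls.
#' @param support_fraction Fraction of samples per group (minimum 2) that
#'   must lie on their group's side of the between-group midpoint.
#' @param adjacency_stretch Span in bp within which two same-direction
#'   significant windows support each other (both windows must fit inside
#'   one stretch, so starts may differ by at most
#'   `adjacency_stretch - window_size`).
#' @param promoter_flank Promoter half-width around the TSS in bp.
#' @param shore_extent Width of the CpG-island shore band in bp.
#' @param shelf_extent Width of the CpG-island shelf band beyond the shore
#'   in bp.
#' @param heatmap_fold Fold-change gate for inclusion in the promoter
#'   heatmap.
#' @param read_extension Optional extension of each read toward its 3' end
#'   in bp before anchoring (0 = anchor at the leftmost aligned base).
#'
#' @return A named list of class `ram_config`.
#' @examples
#' cfg <- ram_config()
#' cfg$window_size
#' @export
ram_config <- function(window_size = 100L,
                       window_shift = 50L,
                       min_reads = 10L,
                       min_sample_fraction = 0.25,
                       alpha = 0.05,
                       support_fraction = 0.5,
                       adjacency_stretch = 500L,
                       promoter_flank = 1500L,
                       shore_extent = 2000L,
                       shelf_extent = 2000L,
                       heatmap_fold = 5,
                       read_extension = 0L) {
  cfg <- list(
    window_size = as.integer(window_size),
    window_shift = as.integer(window_shift),
    min_reads = as.integer(min_reads),
    min_sample_fraction = min_sample_fraction,
    alpha = alpha,
    support_fraction = support_fraction,
    adjacency_stretch = as.integer(adjacency_stretch),
    promoter_flank = as.integer(promoter_flank),
    shore_extent = as.integer(shore_extent),
    shelf_extent = as.integer(shelf_extent),
    heatmap_fold = heatmap_fold,
    read_extension = as.integer(read_extension)
  )
  validate_ram_config(cfg)
  class(cfg) <- "ram_config"
  cfg
}

validate_ram_config <- function(cfg) {
  stopifnot(
    cfg$window_size >= 1L,
    cfg$window_shift >= 1L,
    cfg$window_size %% cfg$window_shift == 0L,
    cfg$min_reads >= 0L,
    cfg$min_sample_fraction > 0, cfg$min_sample_fraction <= 1,
    cfg$alpha > 0, cfg$alpha < 1 || cfg$alpha == 1,
    cfg$support_fraction > 0, cfg$support_fraction <= 1,
    cfg$adjacency_stretch >= cfg$window_size,
    cfg$promoter_flank > 0L,
    cfg$shore_extent > 0L,
    cfg$shelf_extent > 0L,
    cfg$heatmap_fold >= 1,
    cfg$read_extension >= 0L
  )
  invisible(cfg)
}

#' @export
print.ram_config <- function(x, ...) {
  cat("RAM pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# exposure groups in dose order; used wherever ordering matters
GROUP_LEVELS <- c("Ctr", "UG", "MG")

# the three pairwise comparisons, B = exposed / higher-dose group
COMPARISONS <- list(
  Ctr_vs_UG = c(A = "Ctr", B = "UG"),
  Ctr_vs_MG = c(A = "Ctr", B = "MG"),
  UG_vs_MG  = c(A = "UG",  B = "MG")
)
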