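# Negative-binomial differential test per window, from first principles.
#
# Model: counts y_ij ~ NB(mu_ij, phi) with variance mu + phi*mu^2, where
# mu_ij = r_{g(j)} * s_j: a per-group mean rate r times the sample's
# effective library size s. The dispersion phi is common to all windows
# (n = 4 per group cannot support stable per-window dispersions). The test
# is a likelihood-ratio of the two-rate model against a single shared rate,
# referred to chi-square with 1 df.

MU_FLOOR <- 1e-8

#' Effective library sizes
#'
#' The default effective size is simply the per-sample total read count.
#' `method = "trimmed"` additionally applies a trimmed-mean-of-log-ratios
#' adjustment computed on the retained windows: for each sample, log2
#' ratios of depth-normalized counts against a reference sample (the one
#' whose library size is closest to the median) are trimmed (30% on the
#' log-ratio tails, 5% on the magnitude tails) and the mean of the survivors
#' scales the raw size, so that compositional differences between libraries
#' do not masquerade as methylation differences.
#'
#' In designs mixing males and females, sex-chromosome territory is a
#' strong compositional confounder: females spend a visibly larger share
#' of their library on chrX (dosage) and none on chrY, deflating their
#' autosomal rates under raw-total normalization. The trimmed factors are
#' therefore computed on autosomal windows by default
#' (`exclude_chroms`), so between-sample scaling is anchored where groups
#' are comparable.
#'
#' @param m A `ram_counts` object (post coverage filter for `"trimmed"`).
#' @param method `"raw"` or `"trimmed"`.
#' @param exclude_chroms Chromosomes excluded from the trimmed-factor
#'   computation (ignored for `"raw"`).
#' @return Named numeric vector of strictly positive effective sizes.
#' @export
effective_library_sizes <- function(m, method = c("raw", "trimmed"),
                                    exclude_chroms = c("chrX", "chrY")) {
  method <- match.arg(method)
  stopifnot(all(m$library_sizes > 0))
  sizes <- as.numeric(m$library_sizes)
  names(sizes) <- names(m$library_sizes)
  if (method == "raw") return(sizes)
  use <- !m$windows$chrom %in% exclude_chroms
  if (!any(use)) use <- rep(TRUE, nrow(m$counts))
  Y <- m$counts[use, , drop = FALSE]
  ref <- which.min(abs(sizes - median(sizes)))
  f <- vapply(seq_along(sizes), function(j)
    trimmed_ratio_factor(Y[, j], Y[, ref], sizes[j], sizes[ref]),
    numeric(1))
  # factors are relative; normalize so they multiply to 1
  f <- f / exp(mean(log(f)))
  sizes * f
}

#' Trimmed-mean-of-ratios factor between two samples
#'
#' @param y,y_ref Count vectors over the same windows.
#' @param n,n_ref Raw library sizes.
#' @param logratio_trim,magnitude_trim Two-sided trim fractions on the
#'   log2-ratio and on the average-abundance scale.
#' @return The scaling factor (1 for identical depth-normalized profiles).
#' @export
trimmed_ratio_factor <- function(y, y_ref, n, n_ref,
                                 logratio_trim = 0.3, magnitude_trim = 0.05) {
  keep <- y > 0 & y_ref > 0
  if (!any(keep)) return(1)
  M <- log2((y[keep] / n) / (y_ref[keep] / n_ref))
  A <- 0.5 * log2((y[keep] / n) * (y_ref[keep] / n_ref))
  lo_m <- quantile(M, logratio_trim)
  hi_m <- quantile(M, 1 - logratio_trim)
  lo_a <- quantile(A, magnitude_trim)
  hi_a <- quantile(A, 1 - magnitude_trim)
  use <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
  if (!any(use)) return(1)
  2^mean(M[use])
}

# ---- NB fitting core -------------------------------------------------------

# Profile MLE of the per-window rate r given phi, vectorized over windows.
# Y: windows x samples matrix, sizes: per-sample effective sizes.
# The score in t = log r is strictly decreasing, so safeguarded Newton
# (clamped steps) converges to the unique root; all-zero rows sit at the
# mu floor.
.nb_fit_rate <- function(Y, sizes, phi, tol = 1e-8, max_iter = 50L) {
  Y <- as.matrix(Y)
  S <- sum(sizes)
  rate0 <- pmax(rowSums(Y), MU_FLOOR) / S  # Poisson MLE start
  if (phi <= 0) return(pmax(rowSums(Y) / S, MU_FLOOR / max(sizes)))
  t <- log(rate0)
  for (it in seq_len(max_iter)) {
    M <- outer(exp(t), sizes)
    score <- rowSums((Y - M) / (1 + phi * M))
    info <- rowSums(M * (1 + phi * Y) / (1 + phi * M)^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -4), 4)
    t <- t + step
    if (max(abs(step)) < tol) break
  }
  pmax(exp(t), MU_FLOOR / max(sizes))
}

# per-window NB log-likelihood given rates (vector over windows)
.nb_ll <- function(Y, sizes, rate, phi) {
  Y <- as.matrix(Y)
  M <- pmax(outer(rate, sizes), MU_FLOOR)
  if (phi <= 1e-10) {
    rowSums(dpois(Y, lambda = M, log = TRUE))
  } else {
    rowSums(dnbinom(Y, size = 1 / phi, mu = M, log = TRUE))
  }
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes, over a log-spaced grid on `[1e-6, 10]` refined by
#' golden-section search to relative tolerance 1e-4, the sum over windows
#' of the NB profile log-likelihood, with the per-group mean rates profiled
#' out at each candidate dispersion. By default the profile likelihood is
#' Cox-Reid adjusted (minus half the log-determinant of the observed
#' information of the profiled means), which removes the downward bias that
#' plain profiling incurs when every window carries `n_groups` nuisance
#' means; `adjust = FALSE` gives the unadjusted profile likelihood.
#'
#' @param m A `ram_counts` object (ideally after [filter_low_coverage()]).
#' @param groups Optional sample-to-group assignment (defaults to
#'   `m$samples$group`); at least 2 groups with >= 2 samples each.
#' @param sizes Optional effective library sizes.
#' @param max_windows Windows are subsampled (deterministically,
#'   evenly-spaced) beyond this count to bound run time.
#' @param adjust Use the Cox-Reid adjusted profile likelihood (default).
#' @return List of class `dispersion_estimate`: `phi`, `n_windows_used`,
#'   `method`.
#' @export
estimate_common_dispersion <- function(m, groups = NULL, sizes = NULL,
                                       max_windows = 20000L, adjust = TRUE) {
  if (is.null(groups)) groups <- m$samples$group
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  Y <- m$counts[rowSums(m$counts) > 0, , drop = FALSE]
  if (nrow(Y) == 0) stop("all windows have zero counts")
  if (nrow(Y) > max_windows) {
    idx <- unique(round(seq(1, nrow(Y), length.out = max_windows)))
    Y <- Y[idx, , drop = FALSE]
  }
  glev <- names(tab)
  cols <- lapply(glev, function(g) which(groups == g))

  obj <- function(phi) {
    tot <- 0
    for (k in seq_along(cols)) {
      Yg <- Y[, cols[[k]], drop = FALSE]
      sg <- sizes[cols[[k]]]
      r <- .nb_fit_rate(Yg, sg, phi)
      tot <- tot + sum(.nb_ll(Yg, sg, r, phi))
      if (adjust) {
        M <- pmax(outer(r, sg), MU_FLOOR)
        info <- rowSums(M * (1 + phi * Yg) / (1 + phi * M)^2)
        tot <- tot - 0.5 * sum(log(pmax(info, 1e-12)))
      }
    }
    tot
  }

  grid <- 10^seq(-6, 1, length.out = 22)
  ll <- vapply(grid, obj, numeric(1))
  i <- which.max(ll)
  lo <- if (i == 1) log(grid[1]) else log(grid[i - 1])
  hi <- if (i == length(grid)) log(grid[length(grid)]) else log(grid[i + 1])
  phi <- exp(.golden_max(function(t) obj(exp(t)), lo, hi, tol = 1e-4))
  structure(list(phi = phi, n_windows_used = nrow(Y),
                 method = if (adjust) "adjusted_profile_ml" else "profile_ml"),
            class = "dispersion_estimate")
}

# golden-section maximization on [lo, hi] to absolute tolerance tol
# (applied on the log scale, so tol is a relative tolerance on phi)
.golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc >= fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.4g (%s, %d windows)\n",
              x$phi, x$method, x$n_windows_used))
  invisible(x)
}

#' Negative-binomial likelihood-ratio test for one window
#'
#' Fits per-group mean rates by Newton iteration on the log rate (full
#' model) and a single shared rate (null model), and refers twice the
#' log-likelihood difference (clipped at zero) to chi-square with 1 df.
#' `log2FC` is `log2(r_B / r_A)`.
#'
#' @param y Integer count vector for one window.
#' @param groups Two-level group label per sample; `group_b` is the
#'   exposed / higher-dose group.
#' @param sizes Effective library sizes.
#' @param phi Common NB dispersion (>= 0; 0 is the Poisson limit).
#' @param group_a,group_b Labels of the reference and exposed group.
#' @return List `log2FC`, `lrt_stat`, `p_value`.
#' @export
nb_lrt_window <- function(y, groups, sizes, phi,
                          group_a = sort(unique(groups))[1],
                          group_b = sort(unique(groups))[2]) {
  if (any(y < 0)) stop("negative counts")
  res <- .nb_lrt_matrix(matrix(as.numeric(y), nrow = 1), groups, sizes, phi,
                        group_a, group_b)
  list(log2FC = res$log2FC, lrt_stat = res$lrt, p_value = res$p)
}

# vectorized two-group NB LRT over a windows x samples matrix
.nb_lrt_matrix <- function(Y, groups, sizes, phi, group_a, group_b) {
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 samples per group (", group_a, " vs ", group_b, ")")
  Ya <- Y[, ia, drop = FALSE]; sa <- sizes[ia]
  Yb <- Y[, ib, drop = FALSE]; sb <- sizes[ib]
  ra <- .nb_fit_rate(Ya, sa, phi)
  rb <- .nb_fit_rate(Yb, sb, phi)
  r0 <- .nb_fit_rate(cbind(Ya, Yb), c(sa, sb), phi)
  ll_full <- .nb_ll(Ya, sa, ra, phi) + .nb_ll(Yb, sb, rb, phi)
  ll_null <- .nb_ll(cbind(Ya, Yb), c(sa, sb), r0, phi)
  lrt <- pmax(2 * (ll_full - ll_null), 0)
  data.frame(log2FC = log2(rb / ra), lrt = lrt,
             p = pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Run one pairwise differential comparison over all retained windows
#'
#' @param m A `ram_counts` object (after [filter_low_coverage()]).
#' @param group_a Reference group label (e.g. `"Ctr"`).
#' @param group_b Exposed / higher-dose group label; positive `log2FC`
#'   (direction `"hyper"`) means elevated coverage in this group.
#' @param phi Common dispersion (a `dispersion_estimate` or a number).
#' @param sizes Optional effective library sizes.
#' @param comparison Label stored in the result (default
#'   `"<group_a>_vs_<group_b>"`).
#' @return Data frame (one row per retained window): `chrom`, `start`,
#'   `end`, `comparison`, `log2FC`, `lrt`, `p`, `direction`
#'   (`hyper`/`hypo`/`none`), and a Benjamini-Hochberg `fdr` column
#'   (reporting only; RAM calling gates on raw p).
#' @export
run_comparison <- function(m, group_a, group_b, phi, sizes = NULL,
                           comparison = paste0(group_a, "_vs_", group_b)) {
  if (inherits(phi, "dispersion_estimate")) phi <- phi$phi
  groups <- m$samples$group
  for (g in c(group_a, group_b))
    if (!g %in% groups) stop("group not present in sample sheet: ", g)
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  res <- .nb_lrt_matrix(m$counts, groups, sizes, phi, group_a, group_b)
  out <- cbind(m$windows[, c("chrom", "start", "end")],
               comparison = comparison, res,
               direction = ifelse(res$log2FC > 0, "hyper",
                                  ifelse(res$log2FC < 0, "hypo", "none")),
               stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Run the three pairwise dose comparisons
#'
#' @inheritParams run_comparison
#' @return Named list of [run_comparison()] results for `Ctr_vs_UG`,
#'   `Ctr_vs_MG` and `UG_vs_MG`.
#' @export
run_all_comparisons <- function(m, phi, sizes = NULL) {
  if (is.null(sizes)) sizes <- effective_library_sizes(m)
  lapply(COMPARISONS, function(cmp)
    run_comparison(m, cmp[["A"]], cmp[["B"]], phi, sizes = sizes))
}
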