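# The NB machinery is checked two ways: against small independent oracles
# (closed-form Poisson LRT, grid-search MLE, direct trimmed-mean
# recomputation) and against edgeR's GLM fit as an external reference
# implementation at a fixed dispersion.

test_that("effective library sizes: symmetry, scale invariance, oracle", {
  set.seed(21)
  Y <- matrix(rnbinom(500 * 6, size = 10, mu = 40), 500, 6)
  m <- make_counts(Y, groups = rep(c("A", "B"), 3))

  expect_equal(effective_library_sizes(m), m$library_sizes,
               ignore_attr = TRUE)

  same <- make_counts(matrix(rep(Y[, 1], 6), ncol = 6),
                      groups = rep(c("A", "B"), 3))
  f_same <- effective_library_sizes(same, "trimmed") / same$library_sizes
  expect_equal(unname(f_same), rep(1, 6), tolerance = 1e-12)

  # doubling one sample's counts and size leaves normalized means intact
  m2 <- m
  m2$counts[, 3] <- 2L * m2$counts[, 3]
  m2$library_sizes[3] <- 2 * m2$library_sizes[3]
  s1 <- effective_library_sizes(m, "trimmed")
  s2 <- effective_library_sizes(m2, "trimmed")
  expect_equal(sweep(m$counts, 2, s1, "/"), sweep(m2$counts, 2, s2, "/"),
               tolerance = 1e-12)

  # brute-force trimmed-mean recomputation (30% log-ratio, 5% magnitude)
  sizes <- as.numeric(m$library_sizes)
  ref <- which.min(abs(sizes - median(sizes)))
  brute <- vapply(1:6, function(j) {
    keep <- Y[, j] > 0 & Y[, ref] > 0
    M <- log2((Y[keep, j] / sizes[j]) / (Y[keep, ref] / sizes[ref]))
    A <- 0.5 * log2((Y[keep, j] / sizes[j]) * (Y[keep, ref] / sizes[ref]))
    use <- M >= quantile(M, .3) & M <= quantile(M, .7) &
      A >= quantile(A, .05) & A <= quantile(A, .95)
    2^mean(M[use])
  }, numeric(1))
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(effective_library_sizes(m, "trimmed") /
                        m$library_sizes), brute, tolerance = 1e-10)
})

test_that("common dispersion: Poisson limit, recovery, degenerate input", {
  mkm <- function(Y) make_counts(Y, groups = rep(c("A", "B", "C"), each = 4),
                                 sizes = rep(1e6, 12))
  # Poisson counts: dispersion collapses to (near) zero
  phis <- vapply(1:3, function(s) {
    set.seed(s)
    estimate_common_dispersion(mkm(matrix(rpois(2000 * 12, 50), 2000)))$phi
  }, numeric(1))
  expect_lte(median(phis), 0.01)

  # parameter recovery at phi = 0.2
  phis2 <- vapply(1:3, function(s) {
    set.seed(100 + s)
    Y <- matrix(rnbinom(5000 * 12, size = 5, mu = 50), 5000)
    estimate_common_dispersion(mkm(Y))$phi
  }, numeric(1))
  expect_gte(median(phis2), 0.15)
  expect_lte(median(phis2), 0.25)

  # identical constant columns: no overdispersion, lower grid bound
  const <- mkm(matrix(50L, 200, 12))
  expect_lt(estimate_common_dispersion(const)$phi, 2e-6)

  expect_error(estimate_common_dispersion(
    make_counts(matrix(rpois(40, 5), 20, 2), groups = c("A", "B"))),
    ">= 2 samples")
  expect_error(estimate_common_dispersion(mkm(matrix(0L, 50, 12))),
               "zero counts")
})

test_that("window LRT: null identity, Poisson-limit and grid-search oracles", {
  grp <- rep(c("A", "B"), each = 4)
  eq <- nb_lrt_window(rep(7, 8), grp, rep(1e6, 8), phi = 0.1)
  expect_equal(eq$log2FC, 0, tolerance = 1e-10)
  expect_equal(eq$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(eq$p_value, 1, tolerance = 1e-6)

  expect_error(nb_lrt_window(c(-1, rep(2, 7)), grp, rep(1e6, 8), 0.1),
               "negative")

  set.seed(14)
  for (i in 1:30) {
    y <- rpois(8, runif(1, 2, 40))
    sizes <- runif(8, 8e5, 1.2e6)
    fit <- nb_lrt_window(y, grp, sizes, phi = 0)
    expect_lt(abs(fit$lrt_stat - poisson_lrt_oracle(y, 1:4, 5:8, sizes)),
              1e-6)
  }

  # grid-search MLE oracle at phi = 0.2 (coarse grid then refinement)
  grid_mle <- function(y, idx, sizes, phi) {
    naive <- max(sum(y[idx]) / sum(sizes[idx]), 1e-9)
    ll <- function(r) sum(dnbinom(y[idx], size = 1 / phi,
                                  mu = pmax(r * sizes[idx], 1e-8),
                                  log = TRUE))
    g <- naive * exp(seq(log(0.2), log(5), length.out = 200))
    best <- g[which.max(vapply(g, ll, numeric(1)))]
    g2 <- best * exp(seq(-0.04, 0.04, length.out = 200))
    g2[which.max(vapply(g2, ll, numeric(1)))]
  }
  set.seed(15)
  for (i in 1:10) {
    y <- rpois(8, runif(1, 3, 30))
    sizes <- runif(8, 8e5, 1.2e6)
    fit <- nb_lrt_window(y, grp, sizes, phi = 0.2)
    ra <- grid_mle(y, 1:4, sizes, 0.2)
    rb <- grid_mle(y, 5:8, sizes, 0.2)
    expect_lt(abs(fit$log2FC - log2(rb / ra)), 1e-3)
  }
})

test_that("comparisons are antisymmetric, scale invariant, calibrated", {
  set.seed(22)
  Y <- matrix(rnbinom(800 * 8, size = 8, mu = 30), 800, 8)
  m <- make_counts(Y, groups = rep(c("Ctr", "UG"), each = 4))
  d1 <- run_comparison(m, "Ctr", "UG", 0.125)
  d2 <- run_comparison(m, "UG", "Ctr", 0.125)
  expect_equal(d1$log2FC, -d2$log2FC, tolerance = 1e-8)
  expect_equal(d1$p, d2$p, tolerance = 1e-8)
  expect_true(all(d1$direction[d1$log2FC > 0] == "hyper"))
  expect_true(all(d1$p >= pchisq(d1$lrt, 1, lower.tail = FALSE) - 1e-12))

  # the test depends on library sizes only through the normalized rates:
  # rescaling all sizes by any constant changes nothing (counts are data
  # and cannot be rescaled without changing their information content)
  m2 <- m
  m2$library_sizes <- 5 * m2$library_sizes
  d3 <- run_comparison(m2, "Ctr", "UG", 0.125)
  expect_equal(d1$p, d3$p, tolerance = 1e-8)
  expect_equal(d1$log2FC, d3$log2FC, tolerance = 1e-8)
  expect_equal(d1$lrt, d3$lrt, tolerance = 1e-8)

  expect_error(run_comparison(m, "Ctr", "MG", 0.125), "MG")

  # null calibration at the 5% gate
  set.seed(23)
  phi_true <- 0.15
  Yn <- matrix(rnbinom(5000 * 8, size = 1 / phi_true, mu = 50), 5000, 8)
  mn <- make_counts(Yn, groups = rep(c("Ctr", "UG"), each = 4))
  ph <- estimate_common_dispersion(mn)$phi
  dn <- run_comparison(mn, "Ctr", "UG", ph)
  expect_gt(mean(dn$p < 0.05), 0.03)
  expect_lt(mean(dn$p < 0.05), 0.07)
})

test_that("LRT agrees with edgeR's GLM fit at a fixed common dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  nw <- 300
  phi <- 0.12
  Y <- matrix(rnbinom(nw * 8, size = 1 / phi, mu = 40), nw, 8)
  Y[1:30, 5:8] <- matrix(rnbinom(30 * 4, size = 1 / phi, mu = 120), 30, 4)
  sizes <- runif(8, 8e5, 1.2e6)
  grp <- rep(c("A", "B"), each = 4)
  m <- make_counts(Y, groups = grp, sizes = sizes)
  d <- run_comparison(m, "A", "B", phi)

  design <- stats::model.matrix(~factor(grp))
  fit <- edgeR::glmFit(Y, design, dispersion = phi, offset = log(sizes),
                       prior.count = 0)
  ref <- edgeR::glmLRT(fit)$table
  expect_equal(d$lrt, ref$LR, tolerance = 1e-6)
  expect_equal(d$log2FC, ref$logFC, tolerance = 1e-6)
})
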