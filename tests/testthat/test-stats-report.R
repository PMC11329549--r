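# Nonparametric statistics against hand values, brute-force enumeration
# and the base-R reference implementations.

test_that("Spearman correlation matches hand values and the reference", {
  expect_equal(spearmanCorrelation(1:6, (1:6)^3)$spearman_r, 1)
  expect_equal(spearmanCorrelation(1:6, -(1:6))$spearman_r, -1)
  sc <- spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sc$spearman_r, 0.8)
  expect_equal(sc$method, "exact permutation")
  ## cross-check r and the exact p against the base implementation
  ref <- suppressWarnings(cor.test(1:5, c(2, 1, 4, 3, 5),
                                   method = "spearman", exact = TRUE))
  expect_equal(sc$spearman_r, unname(ref$estimate))
  expect_equal(sc$p_value, ref$p.value, tolerance = 1e-12)
  ## larger n: t-approximation against cor.test's estimate
  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40)
  sc2 <- spearmanCorrelation(x, y)
  ref2 <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(sc2$spearman_r, unname(ref2$estimate), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rnorm(25); y <- x + rnorm(25)
  r0 <- spearmanCorrelation(x, y)$spearman_r
  expect_equal(spearmanCorrelation(exp(x), y)$spearman_r, r0)
  expect_equal(spearmanCorrelation(x, y^3 + 5 * y)$spearman_r, r0)
  expect_equal(spearmanCorrelation(1 / (1 + exp(-x)), y)$spearman_r, r0)
})

test_that("Spearman handles degenerate input", {
  sc <- spearmanCorrelation(rep(1, 5), 1:5)
  expect_true(is.na(sc$spearman_r))
  expect_match(sc$method, "undefined")
  expect_error(spearmanCorrelation(1:2, 1:2), "n >= 3")
})

test_that("Mann-Whitney U matches enumeration and the reference", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 labelings at least as extreme
  expect_equal(mw$p_value, bruteForceMannWhitneyP(c(1, 2, 3), c(4, 5, 6)))
  expect_true(mw$exact)

  set.seed(4)
  a <- rnorm(8); b <- rnorm(9, mean = 0.8)
  mine <- mannWhitneyU(a, b)
  expect_equal(mine$p_value, bruteForceMannWhitneyP(a, b), tolerance = 1e-12)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("U statistic identities hold across random draws", {
  set.seed(5)
  for (i in 1:10) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    ua <- mannWhitneyU(a, b)$U
    ub <- mannWhitneyU(b, a)$U
    expect_equal(ua + ub, n1 * n2)  # complementarity
    expect_gte(ua, 0); expect_lte(ua, n1 * n2)
  }
  x <- c(1, 2, 2, 7)
  expect_equal(mannWhitneyU(x, x)$U, length(x)^2 / 2)  # identical multisets
})

test_that("tied data fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6); b <- c(2, 3, 3, 4, 5, 8, 9)
  mine <- mannWhitneyU(a, b)
  expect_false(mine$exact)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("mean and 95% CI match the t construction", {
  ci <- meanCI95(1:5)
  expect_equal(unname(ci["mean"]), 3)
  expect_equal(unname(ci["hi"] - ci["mean"]), 2.776445 * sd(1:5) / sqrt(5),
               tolerance = 1e-6)
  expect_equal(unname(ci["hi"] - ci["mean"]), 1.963, tolerance = 1e-3)
  expect_equal(unname(ci["mean"] - ci["lo"]), unname(ci["hi"] - ci["mean"]))
  cst <- meanCI95(rep(4, 6))
  expect_equal(unname(cst), c(4, 4, 4))
  expect_error(meanCI95(3), "at least 2")
})

test_that("significance markers follow the reporting thresholds", {
  expect_equal(significanceMarker(0.2), "")
  expect_equal(significanceMarker(0.04), "*")
  expect_equal(significanceMarker(0.005), "**")
  expect_equal(significanceMarker(0.0005), "***")
  expect_equal(significanceMarker(0.0005, "▲"), "▲▲▲")
})

test_that("summary tables carry grouped means, markers and correlations", {
  co <- generateCohort(cohortSpec(nPerLocation = 30, seed = 2))
  tabs <- buildSummaryTables(co)
  expect_equal(nrow(tabs$parameters), 4)  # 2 methods x 2 locations
  expect_equal(nrow(tabs$partitions), 4)
  ## the configured strong location effect in E_nf is flagged
  expect_true(all(grepl("\\*", tabs$parameters$E_nf_fmt)))
  ## combined partition is reported at one decimal
  dualRows <- tabs$partitions[tabs$partitions$method == "dual", ]
  expect_true(all(grepl("^\\d+\\.\\d \\(", dualRows$partition_combined_fmt)))
  ## correlation table covers all parameter-partition pairs per method
  expect_setequal(unique(tabs$correlations$parameter),
                  c("E_f0", "E_feps", "E_nf", "k0", "M"))
  expect_equal(sum(tabs$correlations$method == "single"), 5)
  expect_equal(sum(tabs$correlations$method == "dual"), 15)
  ## Holm adjustment is opt-in
  expect_false("p_holm" %in% names(tabs$correlations))
  expect_true("p_holm" %in%
                names(buildSummaryTables(co, holm = TRUE)$correlations))
})

test_that("single-location cohorts emit no between-location markers", {
  co <- generateCohort(cohortSpec(nPerLocation = 10, seed = 2))
  co <- co[co$location == "distal_groove", ]
  tabs <- buildSummaryTables(co)
  expect_false(any(grepl("▲", tabs$partitions$partition_Ta_fmt)))
  expect_false(any(grepl("\\*", tabs$parameters$E_nf_fmt)))
})
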