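# Test-plan selection, rank tests against enumeration oracles and base R
# cross-checks, normality diagnostics, per-region orchestration.

test_that("test plan follows the n < 30 nonparametric rule", {
  p1 <- selectTest(6, TRUE, 3)
  expect_equal(p1$family, "nonparametric")
  expect_equal(p1$omnibus_test, "friedman")
  expect_equal(p1$posthoc_test, "wilcoxon_signed_rank")
  expect_equal(selectTest(6, TRUE, 2)$omnibus_test, "wilcoxon_signed_rank")
  expect_equal(selectTest(50, FALSE, 2)$omnibus_test, "two_sample_t")
  expect_equal(selectTest(8, FALSE, 2)$omnibus_test, "wilcoxon_rank_sum")
  expect_equal(selectTest(8, FALSE, 4)$omnibus_test, "kruskal_wallis")
  expect_equal(selectTest(40, TRUE, 3)$omnibus_test,
               "repeated_measures_anova")
  expect_error(selectTest(6, TRUE, 1), "two groups")
  expect_error(selectTest(1, TRUE, 2), "two observations")
  # pure function
  expect_identical(selectTest(6, TRUE, 3), selectTest(6, TRUE, 3))
})

test_that("Friedman statistic matches the closed form and base R", {
  # strict ordering g1 < g2 < g3 in every subject: rank sums (6, 12, 18),
  # statistic 12 on 2 degrees of freedom
  set.seed(8)
  m <- t(apply(matrix(rnorm(18), 6), 1, sort))
  f <- friedmanTest(m)
  expect_equal(f$statistic, 12)
  expect_equal(f$df, 2)
  expect_equal(f$p_value, pchisq(12, 2, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  m0 <- matrix(rep(c(1, 1, 1), each = 4), 4)
  f0 <- friedmanTest(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)
  # base R cross-check on random matrices (with and without ties)
  for (i in 1:5) {
    mm <- matrix(sample(1:4, 15, replace = TRUE) + rnorm(15, 0, 0.01), 5)
    expect_equal(friedmanTest(mm)$statistic,
                 unname(friedman.test(mm)$statistic), tolerance = 1e-9)
  }
  # the chi-square approximation tracks the exact permutation p in the
  # decision-relevant tail (exact p <= 0.2); in the bulk of a 6-subject
  # permutation distribution the discreteness alone exceeds 0.05
  hits <- 0L
  for (i in 1:60) {
    mm <- matrix(rnorm(18), 6) +
      matrix(rep(c(0, 0.6, 1.2), each = 6), 6)  # push toward the tail
    f <- friedmanTest(mm)
    expect_false(is.na(f$p_exact))
    if (f$p_exact <= 0.2) {
      hits <- hits + 1L
      expect_lt(abs(f$p_value - f$p_exact), 0.05)
    }
    if (hits >= 10L) break
  }
  expect_gte(hits, 5L)
  expect_error(friedmanTest(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("signed-rank test matches full sign enumeration", {
  # all six differences positive: two-sided exact p = 2/64
  w <- wilcoxonSignedRank(2:7, 1:6)
  expect_equal(w$p_value, 2 / 64)
  expect_true(w$exact)
  # y = x: degenerate path
  wd <- wilcoxonSignedRank(1:5, 1:5)
  expect_equal(wd$p_value, 1)
  expect_true(wd$degenerate)
  # brute-force enumeration oracle for n <= 10 (distinct |d|, no ties)
  set.seed(9)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    w <- wilcoxonSignedRank(x, y)
    d <- (x - y)[(x - y) != 0]
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    Vs <- as.vector(signs %*% r)
    V <- sum(r[d > 0])
    pOracle <- min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
    expect_equal(w$p_value, pOracle)
    # base R agreement when ties absent
    expect_equal(w$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample branch returns a sane two-sided p
  set.seed(10)
  xl <- rnorm(40); yl <- xl + rnorm(40, 0.3)
  wl <- wilcoxonSignedRank(xl, yl)
  expect_false(wl$exact)
  expect_true(wl$p_value > 0 && wl$p_value < 1)
})

test_that("rank-sum test matches the label-permutation oracle", {
  # complete separation at n = m = 4: two-sided exact p = 2/70
  r <- wilcoxonRankSum(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(r$p_value, 2 / 70)
  # identical samples: p near 1
  expect_gt(wilcoxonRankSum(c(1, 2, 3), c(1.01, 2.01, 2.99))$p_value, 0.5)
  # permutation oracle + base R on random small samples
  set.seed(11)
  for (i in 1:5) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    r <- wilcoxonRankSum(x, y)
    all <- c(x, y); rk <- rank(all)
    combos <- combn(nx + ny, nx)
    Ws <- colSums(matrix(rk[combos], nrow = nx))
    W <- sum(rk[seq_len(nx)])
    pOracle <- min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
    expect_equal(r$p_value, pOracle)
    expect_equal(r$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normality diagnostics are calibrated and powered", {
  set.seed(12)
  # under H0 the p-values should rarely be tiny
  ps <- replicate(40, normalityDiagnostics(rnorm(80))$shapiro_p)
  expect_gt(mean(ps > 0.01), 0.9)
  # power against a clearly skewed alternative
  pe <- replicate(40, normalityDiagnostics(rexp(100))$shapiro_p)
  expect_gt(mean(pe < 0.01), 0.9)
  pa <- replicate(20, normalityDiagnostics(rexp(100))$anderson_p)
  expect_gt(mean(pa < 0.01), 0.9)
  nd <- normalityDiagnostics(rnorm(30))
  expect_equal(nrow(nd$qq_points), 30)
  expect_error(normalityDiagnostics(c(1, 2)), "at least 3")
  expect_error(normalityDiagnostics(rep(5, 10)), "constant")
})

test_that("per-region orchestration recovers an injected group effect", {
  set.seed(13)
  q <- simulateQuantCohort(nAnimals = 8,
                           groupEffects = list(pts = list(cortex = 0.5)),
                           cvAnimal = 0.05, cvNoise = 0.04)
  res <- runRegionStats(q, paired = TRUE, parameters = "UR")
  expect_true(all(res$test == "friedman"))
  expect_lt(res$p_value[res$region == "cortex"], 0.05)
  # post hoc present for three groups
  expect_true(all(!is.na(res$posthoc)))
  # two-group design: no post hoc
  q2tab <- quantTable(q)
  q2 <- new("QuantResult",
            table = q2tab[q2tab$state %in% c("sham", "pts"), ],
            referenceRegion = "cerebellum")
  res2 <- runRegionStats(q2, paired = TRUE, parameters = "UR")
  expect_true(all(is.na(res2$posthoc)))
  expect_true(all(res2$test == "wilcoxon_signed_rank"))
})

test_that("plots are written for each region when a plot dir is given", {
  set.seed(14)
  q <- simulateQuantCohort(nAnimals = 5)
  pd <- file.path(tempdir(), "statplots")
  res <- runRegionStats(q, paired = TRUE, parameters = "UR", plotDir = pd)
  files <- list.files(pd)
  if (capabilities("png")) {
    expect_true(any(grepl("boxplot", files)))
    expect_true(any(grepl("qq", files)))
  } else {
    succeed("no png device available; plot emission skipped gracefully")
  }
})
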