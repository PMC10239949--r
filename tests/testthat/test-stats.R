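test_that("normality gate distinguishes normal from heavy-tailed samples", {
  set.seed(51)
  normChoice <- vapply(1:100, function(i)
    normalityGate(rnorm(50))$choice == "parametric", logical(1))
  expect_gte(mean(normChoice), 0.9)
  expChoice <- vapply(1:100, function(i)
    normalityGate(rexp(50))$choice == "rank", logical(1))
  expect_gte(mean(expChoice), 0.9)
  expect_equal(normalityGate(rep(1, 10))$choice, "rank")
  expect_equal(normalityGate(c(1, 2))$choice, "rank")
})

test_that("per-timepoint Mann-Whitney tests with Bonferroni adjustment", {
  set.seed(52)
  d <- expand.grid(id = 1:8, group = c("a", "b"), time = 1:5)
  d$value <- rnorm(nrow(d))
  res <- timepointGroupTests(d)
  expect_equal(nrow(res), 5)
  expect_true(all(res$p_adjusted >= res$p))
  expect_equal(res$p_adjusted, pmin(1, 5 * res$p))
  # identical distributions: adjusted p-values saturate near 1
  d2 <- d; d2$value <- rep(1:8, 10)
  res2 <- timepointGroupTests(d2)
  expect_true(all(res2$p_adjusted > 0.9))
})

test_that("Mann-Whitney U equals brute-force pair counting on small samples", {
  set.seed(53)
  for (i in 1:50) {
    x <- sample(0:10, sample(3:8, 1), replace = TRUE) / 2
    y <- sample(0:10, sample(3:8, 1), replace = TRUE) / 2
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    expect_equal(unname(wt$statistic), oracleU(x, y))
  }
})

test_that("mixed model finds a true group effect and is invariant to duplication", {
  cfg <- cohortConfig(seed = 54)
  tr <- simulateTrajectories(cfg)
  d <- data.frame(lamb = tr$lamb_id, group = tr$group, time = tr$time_min,
                  epa = tr$epa_true)
  m <- repeatedMeasuresGroupModel(d)
  expect_lt(m$pGroup, 0.05)
  expect_lt(m$pTime, 1e-10)
  expect_lt(m$groupEstimate, 0)  # elevated group aerates more slowly
  m2 <- suppressWarnings(repeatedMeasuresGroupModel(rbind(d, d)))
  expect_equal(m2$groupEstimate, m$groupEstimate, tolerance = 1e-6)
  expect_error(repeatedMeasuresGroupModel(d[d$group == "control", ]),
               "two groups")
})

test_that("lamb-adjusted regression: exact fit, permutation null, slope recovery", {
  set.seed(55)
  lamb <- rep(c("A", "B", "C"), each = 10)
  x <- runif(30)
  y <- 100 - 50 * x + rep(c(0, 10, 20), each = 10)
  fit <- lambAdjustedRegression(y, x, lamb)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -50, tolerance = 1e-8)
  # permuting the predictor within lamb destroys the association
  yn <- y + rnorm(30, 0, 5)
  pvals <- vapply(1:60, function(i) {
    xp <- ave(x, lamb, FUN = sample)
    lambAdjustedRegression(yn, xp, lamb)$p
  }, numeric(1))
  expect_gt(mean(pvals), 0.3)  # roughly uniform, not concentrated at 0
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_error(lambAdjustedRegression(y, rep(1, 30), lamb), "constant")
  expect_error(lambAdjustedRegression(y[1:10], x[1:10], lamb[1:10]),
               "two lambs")
})

test_that("paired comparison gates on normality and handles degeneracy", {
  set.seed(56)
  x <- rnorm(20)
  res0 <- pairedCompare(x, x)
  expect_equal(res0$p, 1)
  expect_match(res0$note, "all differences zero")
  resC <- pairedCompare(x, x + 1)
  expect_match(resC$note, "degenerate")
  # normal differences -> paired t; heavy-tailed -> Wilcoxon
  resN <- pairedCompare(x, x + rnorm(20, 0.5, 0.3))
  expect_equal(resN$test, "paired t")
  y <- x + rexp(20)^3
  resW <- pairedCompare(x, y)
  expect_equal(resW$test, "Wilcoxon signed-rank")
  # power: shift 1, SD 1, n = 17 detected in most replicates
  hits <- vapply(1:200, function(i) {
    b <- rnorm(17)
    pairedCompare(b, b + rnorm(17, 1, 1))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("block comparisons control the family and reduce to a paired test", {
  set.seed(57)
  # stationary null: rarely any significant block
  anySig <- vapply(1:60, function(i) {
    d <- expand.grid(lamb = paste0("L", 1:10),
                     block = c("pre", paste0("post", 1:6)))
    d$value <- rnorm(nrow(d)) + rep(rnorm(10), 7)
    any(suppressWarnings(blocksVsBaseline(d))$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(anySig), 0.1)
  # a real block-2 effect is found
  d <- expand.grid(lamb = paste0("L", 1:12),
                   block = c("pre", paste0("post", 1:6)))
  d$value <- rnorm(nrow(d), 0, 0.5) + ifelse(d$block == "post2", 3, 0)
  res <- suppressWarnings(blocksVsBaseline(d))
  expect_lt(res$p_adjusted[res$block == "post2"], 0.01)
  expect_true(all(res$p_adjusted[res$block != "post2"] > 0.05))
  # two blocks only: paired reduction
  d2 <- d[d$block %in% c("pre", "post1"), ]
  d2$block <- droplevels(factor(d2$block))
  r2 <- blocksVsBaseline(d2)
  wide <- reshape(d2, idvar = "lamb", timevar = "block", direction = "wide")
  pc <- pairedCompare(wide$value.pre, wide$value.post1)
  expect_equal(r2$p_adjusted, pc$p, tolerance = 1e-10)
  expect_error(blocksVsBaseline(d[d$block != "pre", ]), "baseline")
})

test_that("paired MDD inverts the exact noncentral-t power function", {
  mdd <- pairedMDD(17, 0.1, 0.80, 0.05)
  # independent oracle: base R's own exact paired power solver
  expect_equal(mdd, power.t.test(n = 17, sd = 0.1, power = 0.80,
                                 type = "paired")$delta, tolerance = 1e-3)
  # achieved power at the MDD is the target, by exact evaluation
  df <- 16; tc <- qt(0.975, df); ncp <- mdd * sqrt(17) / 0.1
  achieved <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  expect_equal(achieved, 0.80, tolerance = 0.005)
  # scale equivariance
  expect_equal(pairedMDD(17, 0.2), 2 * pairedMDD(17, 0.1), tolerance = 1e-8)
  expect_error(pairedMDD(1, 0.1), "at least 2")
  expect_error(pairedMDD(17, 0.1, power = 0.04, alpha = 0.05), "infeasible")
})

test_that("Monte-Carlo power at the MDD matches the target", {
  set.seed(58)
  mdd <- pairedMDD(17, 0.1, 0.80, 0.05)
  diffs <- matrix(rnorm(17 * 10000, mdd, 0.1), nrow = 17)
  tstat <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(17))
  power <- mean(abs(tstat) > qt(0.975, 16))
  expect_equal(power, 0.80, tolerance = 0.02)
})
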