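#' Normality-gated choice between parametric and rank tests
#'
#' Shapiro-Wilk at the 5\% level: a parametric test (and mean +/- SEM
#' summaries) when normality is not rejected, otherwise a rank test (and
#' median (IQR) summaries). Samples too small or degenerate for the test
#' (n < 3, constant values) force the rank choice.
#'
#' @param x numeric sample (for paired designs, the differences).
#' @param alpha test level (default 0.05).
#' @return list: \code{choice} ("parametric" or "rank"), \code{p}
#'   (Shapiro-Wilk p, NA when not testable), \code{summaryStyle}.
#' @export
normalityGate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) {
    return(list(choice = "rank", p = NA_real_,
                summaryStyle = "median (IQR)"))
  }
  p <- stats::shapiro.test(x)$p.value
  if (p >= alpha)
    list(choice = "parametric", p = p, summaryStyle = "mean +/- SEM")
  else
    list(choice = "rank", p = p, summaryStyle = "median (IQR)")
}

#' Per-timepoint group comparison of ordinal grades
#'
#' Mann-Whitney U test between groups at each timepoint, Bonferroni
#' adjusted across the timepoints tested
#' (\code{p_adjusted = min(1, m * p)}). Ties are handled by mid-ranks with
#' the normal approximation (tie-corrected) for larger samples, exact
#' p-values otherwise, as \code{\link[stats]{wilcox.test}} does.
#'
#' @param data data.frame with columns \code{value}, \code{group} (two
#'   levels) and \code{time}.
#' @return data.frame per timepoint: \code{time, n1, n2, U, p, p_adjusted}.
#'   Timepoints with an empty group are skipped.
#' @export
timepointGroupTests <- function(data) {
  stopIfNot(all(c("value", "group", "time") %in% names(data)),
            "data needs columns value, group, time")
  groups <- unique(data$group)
  stopIfNot(length(groups) == 2L, "exactly two groups are required")
  rows <- list()
  for (tt in sort(unique(data$time))) {
    d <- data[data$time == tt & is.finite(data$value), ]
    x <- d$value[d$group == groups[1]]
    y <- d$value[d$group == groups[2]]
    if (length(x) == 0L || length(y) == 0L) next
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    rows[[length(rows) + 1L]] <- data.frame(
      time = tt, n1 = length(x), n2 = length(y),
      U = unname(wt$statistic), p = wt$p.value)
  }
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_adjusted <- pmin(1, m * res$p)
  res
}

#' Repeated-measures mixed-effects comparison of EPA between groups
#'
#' Linear mixed model with fixed effects of time (categorical) and group
#' and a random intercept per lamb, fitted by REML; main-effect p-values
#' use Satterthwaite denominator degrees of freedom. A mixed model rather
#' than classical repeated-measures ANOVA tolerates missing cells.
#' Singular fits (a boundary variance estimate) are reported with a
#' warning, not an error; genuine convergence failures still stop.
#'
#' @param data data.frame with columns \code{lamb, group, time, epa}.
#' @return list: \code{model} (the merMod fit), \code{anova} (type III
#'   table), \code{pTime}, \code{pGroup}, \code{groupEstimate} (fixed
#'   effect of the second group level), \code{singular}.
#' @export
repeatedMeasuresGroupModel <- function(data) {
  stopIfNot(all(c("lamb", "group", "time", "epa") %in% names(data)),
            "data needs columns lamb, group, time, epa")
  stopIfNot(length(unique(data$group)) == 2L, "exactly two groups required")
  byGroup <- tapply(data$lamb, data$group, function(l) length(unique(l)))
  stopIfNot(all(byGroup >= 2L), "need at least 2 lambs per group")
  stopIfNot(length(unique(data$time)) >= 2L, "need at least 2 timepoints")
  d <- data
  d$time <- factor(d$time)
  d$group <- factor(d$group)
  d$lamb <- factor(d$lamb)
  fit <- lmerTest::lmer(epa ~ time + group + (1 | lamb), data = d,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit: lamb variance estimated at zero",
            call. = FALSE)
  an <- stats::anova(fit)
  co <- summary(fit)$coefficients
  gRow <- grep("^group", rownames(co))
  list(model = fit, anova = an,
       pTime = an["time", "Pr(>F)"], pGroup = an["group", "Pr(>F)"],
       groupEstimate = unname(co[gRow, "Estimate"]), singular = singular)
}

#' Lamb-adjusted regression of AaDO2 on an aeration measure
#'
#' Linear model \code{aado2 ~ predictor + lamb} with fixed per-lamb
#' intercepts and a common slope, describing the within-lamb relationship
#' between gas exchange and aeration (grade or EPA); reports the overall
#' R-squared and the predictor's slope and p-value. Set
#' \code{perLambSlope = TRUE} for a per-lamb-slope variant (the reported
#' slope is then the average of the per-lamb slopes).
#'
#' @param aado2 numeric response, mmHg.
#' @param predictor numeric aeration measure (LUS grade or EPA).
#' @param lamb lamb identifiers (>= 2 lambs, >= 3 points per lamb).
#' @param perLambSlope fit lamb-specific slopes (default FALSE).
#' @return list: \code{r2, p, slope, model}.
#' @export
lambAdjustedRegression <- function(aado2, predictor, lamb,
                                   perLambSlope = FALSE) {
  stopIfNot(length(aado2) == length(predictor) &&
              length(aado2) == length(lamb), "inputs must have equal length")
  lamb <- factor(lamb)
  stopIfNot(nlevels(lamb) >= 2L, "at least two lambs are required")
  stopIfNot(all(table(lamb) >= 3L), "at least 3 points per lamb are required")
  if (stats::sd(predictor) == 0)
    stop("rank-deficient design: predictor is constant", call. = FALSE)
  d <- data.frame(y = aado2, x = predictor, lamb = lamb)
  if (perLambSlope) {
    fit <- stats::lm(y ~ lamb + lamb:x, data = d)
    sm <- summary(fit)
    slopes <- stats::coef(fit)[grep(":x$", names(stats::coef(fit)))]
    return(list(r2 = sm$r.squared, p = NA_real_, slope = mean(slopes),
                model = fit))
  }
  fit <- stats::lm(y ~ x + lamb, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design in lamb-adjusted regression", call. = FALSE)
  sm <- summary(fit)
  list(r2 = sm$r.squared, p = sm$coefficients["x", "Pr(>|t|)"],
       slope = sm$coefficients["x", "Estimate"], model = fit)
}

summariseDiffs <- function(d, style) {
  if (style == "parametric")
    list(estimate = mean(d), spread = stats::sd(d) / sqrt(length(d)),
         label = "mean +/- SEM of differences")
  else {
    q <- unname(stats::quantile(d, c(0.25, 0.75), type = 7))
    list(estimate = stats::median(d), spread = q,
         label = "median (IQR) of differences")
  }
}

#' Paired before/after comparison with normality gating
#'
#' Tests the paired differences for normality (Shapiro-Wilk, 5\%) and runs
#' a paired t-test when normal, a Wilcoxon signed-rank test otherwise.
#' All-zero differences return p = 1 with a note instead of a test.
#'
#' @param before,after equal-length paired measurements (n >= 3).
#' @param forceRank always use the Wilcoxon test (as done for ordinal
#'   grades).
#' @return list: \code{test, statistic, p, n, estimate, spread, note}.
#' @export
pairedCompare <- function(before, after, forceRank = FALSE) {
  stopIfNot(length(before) == length(after), "unpaired input lengths")
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  stopIfNot(n >= 3L, "at least 3 pairs are required")
  d <- after - before
  if (all(d == 0)) {
    return(list(test = "none", statistic = NA_real_, p = 1, n = n,
                estimate = 0, spread = 0,
                note = "all differences zero: no test performed"))
  }
  gate <- normalityGate(d)
  note <- NULL
  if (stats::sd(d) <= 1e-10 * max(abs(d)))
    note <- "constant non-zero differences (degenerate)"
  if (!forceRank && gate$choice == "parametric") {
    tt <- stats::t.test(after, before, paired = TRUE)
    s <- summariseDiffs(d, "parametric")
    list(test = "paired t", statistic = unname(tt$statistic),
         p = tt$p.value, n = n, estimate = s$estimate, spread = s$spread,
         note = note)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
    s <- summariseDiffs(d, "rank")
    list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
         p = wt$p.value, n = n, estimate = s$estimate, spread = s$spread,
         note = note)
  }
}

#' Compare post-event blocks to the pre-event baseline
#'
#' Random-intercept-per-lamb model of the block metric with each
#' post-event block compared to the baseline block under Dunnett
#' familywise control (multivariate-t via \pkg{multcomp}); Bonferroni is
#' available as a fallback. A single post block reduces to a paired
#' comparison.
#'
#' @param data data.frame with columns \code{lamb, block, value}; the
#'   baseline block must be the first factor level (or named "pre").
#' @param method \code{"dunnett"} (default) or \code{"bonferroni"}.
#' @return data.frame per post block: \code{block, estimate, se, p_adjusted}.
#' @export
blocksVsBaseline <- function(data, method = c("dunnett", "bonferroni")) {
  method <- match.arg(method)
  stopIfNot(all(c("lamb", "block", "value") %in% names(data)),
            "data needs columns lamb, block, value")
  d <- data[is.finite(data$value), ]
  present <- unique(as.character(d$block))
  baseLevel <- if (is.factor(data$block)) levels(data$block)[1]
  else if ("pre" %in% present) "pre" else sort(present)[1]
  stopIfNot(baseLevel %in% present, "baseline block missing from the data")
  ord <- if (is.factor(data$block)) intersect(levels(data$block), present)
  else sort(present)
  d$block <- factor(as.character(d$block),
                    levels = c(baseLevel, setdiff(ord, baseLevel)))
  stopIfNot(length(unique(d$lamb)) >= 2L, "at least two lambs are required")
  d$lamb <- factor(d$lamb)
  nBlocks <- nlevels(d$block)
  stopIfNot(nBlocks >= 2L, "need a baseline and at least one post block")
  if (nBlocks == 2L) {
    wide <- stats::reshape(d[, c("lamb", "block", "value")],
                           idvar = "lamb", timevar = "block",
                           direction = "wide")
    res <- pairedCompare(wide[[2]], wide[[3]])
    return(data.frame(block = levels(d$block)[2], estimate = res$estimate,
                      se = if (length(res$spread) == 1) res$spread else NA,
                      p_adjusted = res$p, stringsAsFactors = FALSE))
  }
  fit <- lmerTest::lmer(value ~ block + (1 | lamb), data = d,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  if (method == "dunnett") {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(block = "Dunnett"))
    sm <- summary(gl)
    data.frame(block = levels(d$block)[-1],
               estimate = unname(sm$test$coefficients),
               se = unname(sm$test$sigma),
               p_adjusted = unname(sm$test$pvalues),
               stringsAsFactors = FALSE)
  } else {
    co <- summary(fit)$coefficients
    idx <- grep("^block", rownames(co))
    data.frame(block = levels(d$block)[-1],
               estimate = unname(co[idx, "Estimate"]),
               se = unname(co[idx, "Std. Error"]),
               p_adjusted = pmin(1, length(idx) * co[idx, "Pr(>|t|)"]),
               stringsAsFactors = FALSE)
  }
}

pairedPower <- function(delta, n, sd, alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- delta * sqrt(n) / sd
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Minimal detectable difference of a paired t-test
#'
#' The smallest true mean paired difference that a two-sided paired
#' t-test at level \code{alpha} with \code{n} pairs and difference SD
#' \code{sd} detects with the target power, obtained by exact inversion of
#' the noncentral-t power function. Scale-equivariant in \code{sd}.
#'
#' @param n number of pairs (>= 2).
#' @param sd standard deviation of the paired differences (> 0).
#' @param power target power in (0, 1) (default 0.80).
#' @param alpha two-sided level in (0, 1) (default 0.05).
#' @return the minimal detectable difference, same units as \code{sd}.
#' @export
pairedMDD <- function(n, sd, power = 0.80, alpha = 0.05) {
  stopIfNot(n >= 2, "n must be at least 2")
  stopIfNot(sd > 0, "sd must be positive")
  stopIfNot(power > 0 && power < 1 && alpha > 0 && alpha < 1,
            "power and alpha must lie strictly in (0, 1)")
  stopIfNot(power > alpha,
            "infeasible: target power must exceed the test level")
  upper <- sd
  while (pairedPower(upper, n, sd, alpha) < power) upper <- upper * 2
  stats::uniroot(function(d) pairedPower(d, n, sd, alpha) - power,
                 c(1e-12, upper), tol = 1e-12)$root
}
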