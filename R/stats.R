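# Round half away from zero, matching the usual clinical-report convention
# (base round() uses banker's rounding).
roundHalfUp <- function(x, digits = 1L) {
    m <- 10^digits
    floor(x * m + 0.5) / m
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,n non-negative integers with `successes <= n`, `n > 0`.
#' @param level confidence level (default 0.95).
#' @param method `"wilson"` (score interval, default), `"wilson_cc"`
#'   (continuity-corrected), or `"clopper_pearson"` (exact beta).
#' @return Named numeric `c(lo, hi)` in [0, 1].
#' @examples
#' wilsonCi(176, 177)  # c(0.969, 0.999) to 3 dp
#' @export
wilsonCi <- function(successes, n, level = 0.95,
                     method = c("wilson", "wilson_cc", "clopper_pearson")) {
    method <- match.arg(method)
    if (n <= 0) stop("n must be positive")
    if (successes < 0 || successes > n)
        stop("successes must lie in [0, n]")
    p <- successes / n
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- switch(method,
        wilson = {
            den <- 1 + z^2 / n
            ctr <- (p + z^2 / (2 * n)) / den
            half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
            c(ctr - half, ctr + half)
        },
        wilson_cc = {
            den <- 2 * (n + z^2)
            lo <- (2 * n * p + z^2 - 1 -
                   z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
                  den
            hi <- (2 * n * p + z^2 + 1 +
                   z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
                  den
            if (p == 0) lo <- 0
            if (p == 1) hi <- 1
            c(lo, hi)
        },
        clopper_pearson = {
            a <- 1 - level
            lo <- if (successes == 0) 0
                  else stats::qbeta(a / 2, successes, n - successes + 1)
            hi <- if (successes == n) 1
                  else stats::qbeta(1 - a / 2, successes + 1, n - successes)
            c(lo, hi)
        })
    ci <- pmin(1, pmax(0, ci))
    names(ci) <- c("lo", "hi")
    ci
}

#' Multi-scenario positive predictive value
#'
#' PPV among screen positives depends on how cases without complete
#' diagnostic testing are counted. Five scenarios are computed:
#' \describe{
#'   \item{complete}{TP/(TP+FP) among cases with complete testing.}
#'   \item{fetal_only}{the same, restricted to suspected-fetal cases with
#'     fetal testing.}
#'   \item{conservative}{TP/(TP+FP+incomplete): incomplete testing counted
#'     as hypothetical false positives.}
#'   \item{upper_bound}{(TP+incomplete+untested)/total: everything
#'     unverified counted as true positive.}
#'   \item{lower_bound}{TP/total: everything unverified counted as false
#'     positive.}
#' }
#' On any cohort `lower_bound <= conservative <= complete <= upper_bound`.
#'
#' @param cohort a cohort table with columns `suspectedOrigin`, `testing`,
#'   `completeness`, `confirmed` (as from [cohortFixture()] or
#'   [readCohortTable()]).
#' @param level confidence level for the Wilson intervals.
#' @param ciMethod interval method; see [wilsonCi()].
#' @return A `data.frame` with one row per scenario: `scenario`,
#'   `numerator`, `denominator`, `ppv` (proportion), `percent` (rounded
#'   half-up to 1 decimal), `lo`, `hi`. Scenarios with an empty denominator
#'   are flagged with `NA` values.
#' @examples
#' ppvScenarios(cohortFixture())
#' @export
ppvScenarios <- function(cohort, level = 0.95, ciMethod = "wilson") {
    cohort <- as.data.frame(cohort)
    comp <- cohort$completeness == "complete"
    tp <- sum(comp & cohort$confirmed == "true_positive")
    fp <- sum(comp & cohort$confirmed == "false_positive")
    inc <- sum(cohort$completeness == "incomplete")
    tot <- nrow(cohort)
    fet <- cohort$suspectedOrigin == "fetal" &
        cohort$testing %in% c("fetal_only", "both") & comp
    ftp <- sum(fet & cohort$confirmed == "true_positive")
    ffp <- sum(fet & cohort$confirmed == "false_positive")
    rows <- list(
        complete     = c(tp, tp + fp),
        fetal_only   = c(ftp, ftp + ffp),
        conservative = c(tp, tp + fp + inc),
        upper_bound  = c(tp + (tot - (tp + fp)), tot),
        lower_bound  = c(tp, tot))
    out <- do.call(rbind, lapply(names(rows), function(sc) {
        num <- rows[[sc]][1L]
        den <- rows[[sc]][2L]
        if (den == 0) {
            warning("empty denominator for scenario ", sc)
            return(data.frame(scenario = sc, numerator = num,
                              denominator = den, ppv = NA_real_,
                              percent = NA_real_, lo = NA_real_,
                              hi = NA_real_))
        }
        ci <- wilsonCi(num, den, level, ciMethod)
        data.frame(scenario = sc, numerator = num, denominator = den,
                   ppv = num / den,
                   percent = roundHalfUp(100 * num / den, 1L),
                   lo = ci[["lo"]], hi = ci[["hi"]])
    }))
    rownames(out) <- out$scenario
    out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples. For pooled size up to
#' `exactLimit` (default 20) the p-value is exact, by enumeration of all
#' group labelings of the pooled values (ties handled through midranks);
#' the two-sided p doubles the smaller exact tail, capped at 1. For larger
#' samples the normal approximation with tie and continuity corrections is
#' used (via [stats::wilcox.test()]).
#'
#' @param x,y non-empty numeric samples.
#' @param exactLimit pooled-size limit for exact enumeration.
#' @return List with `statistic` (rank-sum W of `x`), `p.value`, and
#'   `method`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 20L) {
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be non-empty")
    nx <- length(x)
    pooled <- c(x, y)
    n <- length(pooled)
    rk <- rank(pooled)
    wObs <- sum(rk[seq_len(nx)])
    if (n <= exactLimit) {
        sel <- utils::combn(n, nx)
        ws <- colSums(matrix(rk[sel], nrow = nx))
        tol <- 1e-8
        pLess <- mean(ws <= wObs + tol)
        pMore <- mean(ws >= wObs - tol)
        p <- min(1, 2 * min(pLess, pMore))
        list(statistic = wObs, p.value = p, method = "exact enumeration")
    } else {
        wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
        list(statistic = wObs, p.value = wt$p.value,
             method = "normal approximation")
    }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities at or below the
#' observed table's (via [stats::fisher.test()]), with the sample odds
#' ratio `ad/bc` reported by default (Haldane--Anscombe 0.5 correction
#' applied to every cell when any cell is zero). The conditional
#' maximum-likelihood odds ratio is available as an alternative.
#'
#' @param a,b,c,d non-negative integer cells, row-wise: `a b / c d`. Both
#'   margins must be positive.
#' @param orMethod `"sample"` (default) or `"conditional_mle"`.
#' @return List with `odds.ratio`, `p.value`, and `table`.
#' @examples
#' fisherExact(5, 0, 0, 5)$p.value  # 2/252
#' fisherExact(20, 10, 5, 15)$odds.ratio  # 6
#' @export
fisherExact <- function(a, b, c, d,
                        orMethod = c("sample", "conditional_mle")) {
    orMethod <- match.arg(orMethod)
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    tab <- matrix(cells, nrow = 2L, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate margins: every row and column total must be positive")
    ft <- stats::fisher.test(tab)
    orv <- if (orMethod == "sample") {
        if (any(cells == 0)) ((a + 0.5) * (d + 0.5)) /
                             ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
    } else unname(ft$estimate)
    list(odds.ratio = orv, p.value = ft$p.value, table = tab)
}

#' Concordance between estimated and confirmed deletion sizes
#'
#' Ordinary least-squares regression of confirmed (microarray) size on
#' cfDNA-estimated size.
#'
#' @param estimatedMb,confirmedMb paired numeric sizes in megabases; at
#'   least 3 pairs with non-constant `estimatedMb`.
#' @return List with `slope`, `intercept`, `r.squared`, `n`.
#' @export
sizeConcordance <- function(estimatedMb, confirmedMb) {
    if (length(estimatedMb) != length(confirmedMb))
        stop("size vectors must be paired")
    keep <- !is.na(estimatedMb) & !is.na(confirmedMb)
    estimatedMb <- estimatedMb[keep]
    confirmedMb <- confirmedMb[keep]
    if (length(estimatedMb) < 3L) stop("at least 3 pairs are required")
    if (stats::var(estimatedMb) == 0)
        stop("estimated sizes are constant; regression undefined")
    fit <- stats::lm(confirmedMb ~ estimatedMb)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r.squared = summary(fit)$r.squared,
         n = length(estimatedMb))
}

#' Summarise a screen-positive cohort
#'
#' Reports the headline cohort percentages, each rounded half-up to one
#' decimal: suspected-maternal share, ultrasound-finding share, diagnostic
#' testing availability, postnatally deferred share of fetal-tested cases,
#' cardiac share of ultrasound-flagged cases, and fetal-inheritance share
#' among suspected-maternal cases with fetal testing. Categories with an
#' empty denominator are omitted with a message.
#'
#' @param cohort a cohort table; see [cohortFixture()] for the schema.
#' @return `data.frame` with columns `metric`, `numerator`, `denominator`,
#'   `percent`.
#' @examples
#' summarizeCohort(cohortFixture())
#' @export
summarizeCohort <- function(cohort) {
    cohort <- as.data.frame(cohort)
    n <- nrow(cohort)
    fetalTested <- cohort$testing %in% c("fetal_only", "both")
    matFetal <- cohort$suspectedOrigin == "maternal" & fetalTested
    metrics <- list(
        suspected_maternal = c(sum(cohort$suspectedOrigin == "maternal"), n),
        ultrasound = c(sum(cohort$ultrasound), n),
        diagnostic_testing = c(sum(cohort$testing != "none"), n),
        deferred_postnatal = c(sum(cohort$deferredPostnatal & fetalTested),
                               sum(fetalTested)),
        cardiac_of_ultrasound = c(sum(cohort$cardiac & cohort$ultrasound),
                                  sum(cohort$ultrasound)),
        fetal_inheritance = c(sum(cohort$fetalInherited[matFetal],
                                  na.rm = TRUE),
                              sum(matFetal)))
    out <- do.call(rbind, lapply(names(metrics), function(m) {
        num <- metrics[[m]][1L]
        den <- metrics[[m]][2L]
        if (den == 0) {
            message("omitting '", m, "': empty denominator")
            return(NULL)
        }
        data.frame(metric = m, numerator = num, denominator = den,
                   percent = roundHalfUp(100 * num / den, 1L))
    }))
    rownames(out) <- out$metric
    out
}

#' Read and write cohort tables
#'
#' TSV I/O for cohort tables with the [cohortFixture()] schema. Comment
#' lines starting with `#` are ignored on read and may carry metadata on
#' write.
#'
#' @param path file path.
#' @return `readCohortTable` returns a `DataFrame`.
#' @export
readCohortTable <- function(path) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("caseId", "suspectedOrigin", "testing", "completeness",
              "confirmed")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("cohort table lacks required column(s): ",
             paste(missing, collapse = ", "))
    DataFrame(df)
}

#' @rdname readCohortTable
#' @param cohort cohort table to write.
#' @param header optional named character vector of `# key: value` lines.
#' @export
writeCohortTable <- function(cohort, path, header = NULL) {
    writeTruthTable(cohort, path, header)
}
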