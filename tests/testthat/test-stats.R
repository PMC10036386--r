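test_that("Wilson intervals match closed-form evaluations", {
    expect_equal(unname(round(wilsonCi(176, 177), 3)), c(0.969, 0.999))
    expect_equal(unname(round(wilsonCi(5, 10), 3)), c(0.237, 0.763))
    expect_equal(wilsonCi(0, 10)[["lo"]], 0)
    expect_equal(wilsonCi(10, 10)[["hi"]], 1)
    expect_error(wilsonCi(5, 0), "positive")
    expect_error(wilsonCi(11, 10), "\\[0, n\\]")

    # widening n at the same proportion narrows the interval
    w1 <- wilsonCi(8, 10)
    w2 <- wilsonCi(80, 100)
    expect_lt(diff(w2), diff(w1))

    # alternative methods bracket the point estimate
    for (m in c("wilson_cc", "clopper_pearson")) {
        ci <- wilsonCi(17, 30, method = m)
        expect_lt(ci[["lo"]], 17 / 30)
        expect_gt(ci[["hi"]], 17 / 30)
    }
})

test_that("PPV scenarios reproduce the published values from the fixture", {
    ppv <- ppvScenarios(cohortFixture())
    expect_equal(ppv["complete", "percent"], 99.4)
    expect_equal(ppv["fetal_only", "percent"], 98.7)
    expect_equal(ppv["conservative", "percent"], 90.7)
    expect_equal(ppv["upper_bound", "percent"], 99.7)
    expect_equal(ppv["lower_bound", "percent"], 57.3)
    expect_identical(ppv["complete", "numerator"], 176L)
    expect_identical(ppv["complete", "denominator"], 177L)
    expect_identical(ppv["conservative", "denominator"], 194L)
})

test_that("scenario ordering holds on any cohort", {
    # all-true-positive toy cohort: every scenario is 100%
    toy <- data.frame(suspectedOrigin = rep("fetal", 10),
                      testing = "fetal_only", completeness = "complete",
                      confirmed = "true_positive")
    expect_true(all(ppvScenarios(toy)$ppv == 1))

    for (seed in c(3, 17, 91)) {
        truth <- simulateCohort(.model, 300, seed = seed, profiles = FALSE)
        ppv <- ppvScenarios(truth)$ppv
        names(ppv) <- rownames(ppvScenarios(truth))
        expect_lte(ppv[["lower_bound"]], ppv[["conservative"]])
        expect_lte(ppv[["conservative"]], ppv[["complete"]])
        expect_lte(ppv[["complete"]], ppv[["upper_bound"]])
    }
})

test_that("Wilcoxon rank-sum matches enumeration and the normal branch", {
    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")

    # tied data agree with the independent enumeration oracle
    set.seed(41)
    for (i in 1:10) {
        x <- sample(1:4, 5, replace = TRUE)
        y <- sample(1:4, 4, replace = TRUE)
        expect_equal(wilcoxonRankSum(x, y)$p.value, oracleWilcoxonP(x, y))
    }
    # untied data agree with wilcox.test's exact path
    for (i in 1:10) {
        v <- sample(100, 10)
        x <- v[1:5]; y <- v[6:10]
        expect_equal(wilcoxonRankSum(x, y)$p.value,
                     stats::wilcox.test(x, y, exact = TRUE)$p.value)
    }
    # the normal approximation is close to enumeration at n = 10 + 10
    set.seed(42)
    x <- rnorm(10); y <- rnorm(10, 0.5)
    pExact <- wilcoxonRankSum(x, y)$p.value
    pApprox <- stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value
    expect_lt(abs(pExact - pApprox), 0.01)
    # above the exact limit the implementation switches to the
    # approximation
    res <- wilcoxonRankSum(rnorm(15), rnorm(15))
    expect_identical(res$method, "normal approximation")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
    sym <- fisherExact(1, 1, 1, 1)
    expect_equal(sym$odds.ratio, 1)
    expect_equal(sym$p.value, 1)
    expect_equal(fisherExact(5, 0, 0, 5)$p.value, 2 / 252)
    expect_equal(fisherExact(20, 10, 5, 15)$odds.ratio, 6)
    expect_error(fisherExact(0, 0, 3, 4), "degenerate margins")
    expect_error(fisherExact(1.5, 1, 1, 1), "integers")

    set.seed(43)
    for (i in 1:20) {
        cells <- as.integer(sample(0:8, 4, replace = TRUE))
        tab <- matrix(cells, 2)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        expect_equal(fisherExact(cells[1], cells[3], cells[2],
                                 cells[4])$p.value,
                     oracleFisherP(cells[1], cells[3], cells[2], cells[4]),
                     tolerance = 1e-10)
    }
    # conditional-MLE odds ratio comes from the exact conditional fit
    orCond <- fisherExact(20, 10, 5, 15,
                          orMethod = "conditional_mle")$odds.ratio
    expect_equal(orCond,
                 unname(stats::fisher.test(
                     matrix(c(20, 5, 10, 15), 2))$estimate))
})

test_that("size concordance is an OLS fit with guarded input", {
    onLine <- suppressWarnings(sizeConcordance(c(1, 2, 3, 4),
                                               c(1, 2, 3, 4)))
    expect_equal(onLine$slope, 1)
    expect_equal(onLine$intercept, 0)
    expect_equal(onLine$r.squared, 1)
    expect_error(sizeConcordance(c(1, 2), c(1, 2)), "at least 3")
    expect_error(sizeConcordance(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("cohort summary reproduces the published percentages", {
    sm <- summarizeCohort(cohortFixture())
    expect_equal(sm["suspected_maternal", "percent"], 57.7)
    expect_equal(sm["ultrasound", "percent"], 51.1)
    expect_equal(sm["diagnostic_testing", "percent"], 63.2)
    expect_equal(sm["deferred_postnatal", "percent"], 45.8)
    expect_equal(sm["cardiac_of_ultrasound", "percent"], 60.5)
    expect_equal(sm["fetal_inheritance", "percent"], 58.1)
    # percentages use half-up rounding (57.654... -> 57.7)
    expect_equal(sm["suspected_maternal", "numerator"], 177)
    expect_equal(sm["suspected_maternal", "denominator"], 307)

    # an empty category is omitted with a note
    tiny <- data.frame(suspectedOrigin = "fetal", testing = "none",
                       completeness = "none", confirmed = "unknown",
                       ultrasound = FALSE, cardiac = FALSE,
                       deferredPostnatal = FALSE, fetalInherited = NA)
    expect_message(smTiny <- summarizeCohort(tiny), "empty denominator")
    expect_false("cardiac_of_ultrasound" %in% smTiny$metric)
})

test_that("cohort tables survive a TSV round trip with metadata header", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCohortTable(cohortFixture(), path, header = c(source = "fixture"))
    expect_identical(readLines(path, n = 1L), "# source: fixture")
    back <- readCohortTable(path)
    expect_identical(nrow(back), 307L)
    expect_equal(ppvScenarios(back)["complete", "percent"], 99.4)
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines("a\tb\n1\t2", bad)
    expect_error(readCohortTable(bad), "required column")
})
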