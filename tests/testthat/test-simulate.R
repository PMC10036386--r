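test_that("expected depth ratio follows the plasma mixture model", {
    expect_equal(expectedDepthRatio("fetal_de_novo", 0.10), 0.95)
    expect_equal(expectedDepthRatio("paternal_fetal", 0.10), 0.95)
    expect_equal(expectedDepthRatio("maternal_not_transmitted", 0.10), 0.55)
    expect_equal(expectedDepthRatio("maternal_transmitted", 0.10), 0.50)
    expect_equal(expectedDepthRatio("maternal_transmitted", 0.37), 0.50)
    expect_equal(expectedDepthRatio("none", 0.10), 1)
    expect_error(expectedDepthRatio("fetal_de_novo", 0), "in \\(0,1\\)")
    expect_error(expectedDepthRatio("fetal_de_novo", 1.2), "in \\(0,1\\)")

    # monotone: ratio decreases as the carrier fraction grows, and for a
    # non-transmitted maternal deletion it increases with ff
    ffs <- seq(0.05, 0.45, by = 0.05)
    mnt <- vapply(ffs, function(f)
        expectedDepthRatio("maternal_not_transmitted", f), numeric(1))
    expect_true(all(diff(mnt) > 0))
    fet <- vapply(ffs, function(f)
        expectedDepthRatio("fetal_de_novo", f), numeric(1))
    expect_true(all(diff(fet) < 0))
})

test_that("simulated counts match their analytic expectations", {
    nb <- length(binGrid(.model))
    # null sample: mean within 3 SE of the diploid depth, and total reads
    # conserved within 4 SE
    p0 <- simulateSample(.model, "none", ff = 0.10, meanDepth = 1000,
                         seed = 21)
    se <- sqrt(1000 / nb)
    expect_lt(abs(mean(counts(p0)) - 1000), 3 * se)
    expect_lt(abs(sum(counts(p0)) - 1000 * nb), 4 * sqrt(1000 * nb))

    # non-transmitted maternal deletion at ff 0.10: fully deleted bins
    # average 55% of depth
    iv <- canonicalDeletion(.model, "AD")
    p1 <- simulateSample(.model, "maternal_not_transmitted", iv, ff = 0.10,
                         meanDepth = 1000, seed = 22)
    hits <- IRanges::overlapsAny(binGrid(.model), iv, type = "within")
    expect_lt(abs(mean(counts(p1)[hits]) - 550),
              3 * sqrt(550 / sum(hits)))
})

test_that("identical seed gives identical profiles", {
    iv <- canonicalDeletion(.model, "AB")
    a <- simulateSample(.model, "fetal_de_novo", iv, ff = 0.12, seed = 5)
    b <- simulateSample(.model, "fetal_de_novo", iv, ff = 0.12, seed = 5)
    expect_identical(counts(a), counts(b))
})

test_that("a half-covered boundary bin is depressed proportionally", {
    # deletion covering bins 10..20 plus exactly half of bin 21
    bins <- binGrid(.model)
    iv <- grInterval(GenomicRanges::start(bins)[10L],
                     GenomicRanges::start(bins)[21L] + 24999L)
    reps <- 300
    set.seed(33)
    half <- vapply(seq_len(reps), function(i) {
        counts(simulateSample(.model, "maternal_transmitted", iv,
                              ff = 0.10, meanDepth = 400))[21L]
    }, numeric(1))
    # carrier fraction 1, half-covered: expected ratio midway between
    # 0.5 (inside) and 1 (outside) = 0.75
    expect_lt(abs(mean(half) - 300), 3 * sqrt(300 / reps))
})

test_that("negative-binomial dispersion widens counts beyond Poisson", {
    set.seed(14)
    pois <- counts(simulateSample(.model, "none", ff = 0.1,
                                  meanDepth = 2000))
    nb <- counts(simulateSample(.model, "none", ff = 0.1, meanDepth = 2000,
                                dispersion = 0.02))
    expect_lt(stats::var(pois), 2000 + 0.02 * 2000^2 / 2)
    expect_gt(stats::var(nb), 2 * stats::var(pois))
})

test_that("cohort generation hits its composition targets", {
    n <- 8000
    truth <- simulateCohort(.model, n, seed = 91, profiles = FALSE)
    pm <- 0.577
    se <- sqrt(pm * (1 - pm) / n)
    matShare <- mean(truth$suspectedOrigin == "maternal")
    expect_lt(abs(matShare - pm), 3 * se)

    # transmission among maternal carriers is one half
    mat <- truth$origin %in% c("maternal_transmitted",
                               "maternal_not_transmitted")
    tr <- mean(truth$origin[mat] == "maternal_transmitted")
    expect_lt(abs(tr - 0.5), 3 * sqrt(0.25 / sum(mat)))

    # fetal fractions respect the truncation bounds and target median
    expect_true(all(truth$ff >= 0.02 & truth$ff <= 0.45))
    expect_lt(abs(stats::median(truth$ff) - 0.1048), 0.01)

    expect_error(simulateCohort(.model, 0), "positive")
})

test_that("cohort truth tables are byte-identical under a repeated seed", {
    t1 <- simulateCohort(.model, 40, seed = 7, profiles = FALSE)
    t2 <- simulateCohort(.model, 40, seed = 7, profiles = FALSE)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeTruthTable(t1, f1)
    writeTruthTable(t2, f2)
    expect_identical(readLines(f1), readLines(f2))

    se1 <- simulateCohort(.model, 15, seed = 8)
    se2 <- simulateCohort(.model, 15, seed = 8)
    expect_identical(SummarizedExperiment::assay(se1, "counts"),
                     SummarizedExperiment::assay(se2, "counts"))
})
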