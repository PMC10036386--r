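test_that("reference building validates its panel and floors variance", {
    expect_error(buildReference(.panel[, 1:5]), "at least 10")
    # a panel of identical profiles hits the sd floor on every bin
    flat <- matrix(rep(counts(simulateSample(.model, "none", ff = 0.1,
                                             seed = 2)), 12), ncol = 12)
    expect_warning(refFlat <- buildReference(flat), "floored")
    expect_true(all(binSds(refFlat) == refFlat@sdFloor))
    # simulated null panel: per-bin mean of unit-scaled counts near 1
    se <- (1 / sqrt(1000)) / sqrt(panelSize(.ref))
    expect_true(all(abs(binMeans(.ref) - 1) < 4 * se))
    expect_identical(panelSize(.ref), 50L)
})

test_that("normalisation is exact on reference-identical input and rejects degenerate input", {
    flat <- matrix(rep(1000L, 71 * 12), ncol = 12)
    refFlat <- suppressWarnings(buildReference(flat))
    expect_equal(normalizeProfile(rep(1000L, 71), refFlat), rep(1, 71))
    expect_error(normalizeProfile(rep(0L, 71), .ref), "degenerate")
    expect_error(normalizeProfile(rep(1000L, 10), .ref), "different bin grids")
    # null sample: mean ratio near 1
    r <- normalizeProfile(simulateSample(.model, "none", ff = .1, seed = 3),
                          .ref)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    # anchored scaling leaves the baseline to the external depth estimate
    ra <- normalizeProfile(simulateSample(.model, "none", ff = .1, seed = 3),
                           .ref, depthAnchor = 1000)
    expect_lt(abs(mean(ra) - 1), 3 * sqrt(1 / 1000 / 71))
})

test_that("a single outlier bin is not called a deletion", {
    ratios <- rep(1, 71)
    ratios[30] <- 1 - 3 * binSds(.ref)[30]  # one bin at z = -3
    res <- scanRegion(ratios, .ref)
    expect_false(res$detected)
})

test_that("event fraction inverts the depth-ratio model with clipping", {
    expect_equal(estimateEventFraction(0.95), 0.10)
    expect_equal(estimateEventFraction(0.50), 1.0)
    expect_equal(estimateEventFraction(1.0), 0.0)
    expect_equal(estimateEventFraction(0.3), 1.0)   # clipped above
    expect_equal(estimateEventFraction(1.2), 0.0)   # clipped below
})

test_that("a maternal A-D deletion is recovered nearly exactly", {
    iv <- canonicalDeletion(.model, "AD")
    trueBins <- sum(IRanges::overlapsAny(binGrid(.model), iv,
                                         type = "within"))
    for (seed in 1:5) {
        p <- simulateSample(.model, "maternal_not_transmitted", iv,
                            ff = 0.10, meanDepth = 1000, seed = seed)
        call <- callDeletion(p, .ref, .model)
        expect_true(isDetected(call))
        covered <- overlapBp(callInterval(call), iv)
        expect_gte(covered / GenomicRanges::width(iv), 0.95)
        expect_lt(abs(eventFraction(call) - 0.90), 0.05)
        # sizes are quantised to the bin grid
        expect_lt(abs(sizeMb(call) / 0.05 - round(sizeMb(call) / 0.05)),
                  1e-9)
        expect_equal(sizeMb(call), call@nBins * 0.05, tolerance = 1e-9)
    }
})

test_that("anchored mode recovers a weak fetal event at typical depth", {
    iv <- canonicalDeletion(.model, "AD")
    hits <- 0
    for (seed in 11:16) {
        p <- simulateSample(.model, "fetal_de_novo", iv, ff = 0.12,
                            meanDepth = 1000, seed = seed)
        call <- callDeletion(p, .ref, .model, depthAnchor = 1000)
        if (isDetected(call) && abs(eventFraction(call) - 0.12) < 0.05)
            hits <- hits + 1
    }
    expect_gte(hits, 5)
})

test_that("null samples are rarely called", {
    set.seed(99)
    det <- vapply(1:25, function(i) {
        isDetected(callDeletion(simulateSample(.model, "none", ff = 0.1),
                                .ref, .model))
    }, logical(1))
    expect_lte(sum(det), 1)
})

test_that("an undetected call carries no interval and prints as such", {
    call <- methods::new("DeletionCall", detected = FALSE,
        interval = GenomicRanges::GRanges(), sizeMb = numeric(0),
        z = numeric(0), eventFraction = numeric(0), nBins = integer(0))
    expect_false(isDetected(call))
    expect_length(callInterval(call), 0L)
    expect_output(show(call), "no deletion detected")
})
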