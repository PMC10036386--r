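test_that("default model satisfies the LCR22/probe/bin-grid invariants", {
    bins <- binGrid(.model)
    expect_length(bins, 71L)
    expect_true(all(GenomicRanges::width(bins) == 50000L))
    # conservation: bin lengths sum to the (padded) region length
    expect_identical(sum(GenomicRanges::width(bins)),
                     GenomicRanges::width(analysisRegion(.model)))
    # contiguous, sorted, non-overlapping
    st <- GenomicRanges::start(bins)
    expect_true(all(diff(st) == 50000L))

    lcr <- lcrBlocks(.model)
    expect_identical(names(lcr), c("A", "B", "C", "D"))
    expect_true(all(GenomicRanges::start(lcr)[-1] >
                    GenomicRanges::end(lcr)[-4]))

    # the canonical A-D deletion spans ~2.54 Mb, within one bin
    adMb <- GenomicRanges::width(canonicalDeletion(.model, "AD")) / 1e6
    expect_lte(abs(adMb - 2.54), 0.05)

    # every probe lies strictly between blocks A and B
    gap <- grInterval(GenomicRanges::end(lcr["A"]) + 1L,
                      GenomicRanges::start(lcr["B"]) - 1L)
    for (i in seq_along(probes(.model)))
        expect_identical(overlapBp(probes(.model)[i], gap),
                         GenomicRanges::width(probes(.model)[i]))
})

test_that("makeBins tiles exactly and pads to a whole number of bins", {
    expect_length(makeBins(grInterval(1L, 3550000L), 50000L), 71L)
    expect_length(makeBins(grInterval(1L, 50000L), 50000L), 1L)
    expect_error(makeBins(grInterval(1L, 100L), 0L), "positive")
    # non-multiple region is padded upward
    b <- makeBins(grInterval(1L, 120000L), 50000L)
    expect_length(b, 3L)
    expect_identical(GenomicRanges::end(b)[3L], 150000L)
    # padding recorded in the model
    m <- loadRegionModel(binWidth = 50000L)
    expect_identical(m@padding, 0L)
})

test_that("overlapBp follows half-open overlap semantics and is symmetric", {
    # [0,100) vs [50,150) in BED terms -> 50 bp
    expect_identical(overlapBp(grInterval(1L, 100L), grInterval(51L, 150L)),
                     50L)
    # abutting intervals do not overlap
    expect_identical(overlapBp(grInterval(1L, 100L), grInterval(101L, 200L)),
                     0L)
    # identity
    a <- grInterval(5L, 250L)
    expect_identical(overlapBp(a, a), GenomicRanges::width(a))
    # different chromosomes -> 0 with a warning
    expect_warning(
        ov <- overlapBp(grInterval(1L, 100L),
                        grInterval(1L, 100L, chrom = "chr21")),
        "different chromosomes")
    expect_identical(ov, 0L)
    # symmetry over random interval pairs
    set.seed(11)
    for (i in 1:50) {
        s <- sample.int(1000L, 4L, replace = TRUE)
        a <- grInterval(s[1L], s[1L] + s[2L])
        b <- grInterval(s[3L], s[3L] + s[4L])
        expect_identical(overlapBp(a, b), overlapBp(b, a))
    }
})

test_that("BED round-trip preserves coordinates and names bit-exactly", {
    path <- withr::local_tempfile(fileext = ".bed")
    writeBedTrack(lcrBlocks(.model), path)
    back <- readBedTrack(path)
    expect_identical(GenomicRanges::start(back),
                     GenomicRanges::start(lcrBlocks(.model)))
    expect_identical(GenomicRanges::end(back),
                     GenomicRanges::end(lcrBlocks(.model)))
    expect_identical(names(back), names(lcrBlocks(.model)))
    # on-disk starts are 0-based half-open
    onDisk <- read.table(path, sep = "\t")
    expect_identical(as.integer(onDisk[[2L]]),
                     GenomicRanges::start(lcrBlocks(.model)) - 1L)
    expect_identical(as.integer(onDisk[[3L]]),
                     GenomicRanges::end(lcrBlocks(.model)))
})

test_that("malformed BED and invalid models are rejected with clear errors", {
    bad <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr22\t100\t200\tok", "chr22\t500\t400\tbad"), bad)
    expect_error(readBedTrack(bad), "line 2.*start >= end")
    short <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr22\t100", short)
    expect_error(readBedTrack(short), "fewer than 3 columns")
    expect_error(readBedTrack("no/such/file.bed"), "not found")

    # a probe outside the A-B interblock gap violates model validity
    prbBed <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr22\t20400000\t20450000\tN25", prbBed)  # beyond block B
    expect_error(loadRegionModel(probesBed = prbBed),
                 "between LCR blocks A and B")
})
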