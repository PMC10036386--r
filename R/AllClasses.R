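#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata mcols mcols<-
NULL

#' RegionModel: coordinate system for 22q11.2 bin-depth analysis
#'
#' Holds the 22q11.2 analysis window, the LCR22 A--D low-copy-repeat blocks,
#' the FISH probe targets (N25, TUPLE1/HIRA, TBX1), and the fixed-width bin
#' grid tiling the window. All coordinates are \linkS4class{GRanges}
#' (1-based, closed); BED input/output preserves the BED 0-based half-open
#' convention via \pkg{rtracklayer}.
#'
#' @slot region `GRanges` of length 1, the analysis window.
#' @slot lcrBlocks `GRanges` named `A`..`D`, ordered, non-overlapping.
#' @slot probes `GRanges` of FISH probe targets, all strictly between
#'   blocks A and B.
#' @slot bins `GRanges` bin grid tiling the (padded) window exactly.
#' @slot binWidth integer, bin width in bases (default 50000).
#' @slot genomeBuild character label of the coordinate set.
#' @slot padding integer, bases appended to the window end so that it is a
#'   whole number of bins.
#'
#' @seealso [defaultRegionModel()], [loadRegionModel()], [makeBins()]
#' @exportClass RegionModel
setClass("RegionModel",
    slots = c(
        region      = "GRanges",
        lcrBlocks   = "GRanges",
        probes      = "GRanges",
        bins        = "GRanges",
        binWidth    = "integer",
        genomeBuild = "character",
        padding     = "integer"
    )
)

setValidity("RegionModel", function(object) {
    msg <- character()
    reg <- object@region
    lcr <- object@lcrBlocks
    prb <- object@probes
    if (length(reg) != 1L)
        msg <- c(msg, "region must be a single interval")
    if (!identical(names(lcr), c("A", "B", "C", "D")))
        msg <- c(msg, "lcrBlocks must be named A, B, C, D in order")
    if (length(lcr) == 4L) {
        if (is.unsorted(GenomicRanges::start(lcr)) ||
            any(GenomicRanges::start(lcr)[-1L] <=
                GenomicRanges::end(lcr)[-4L]))
            msg <- c(msg, "LCR blocks must be ordered A<B<C<D and non-overlapping")
        gapAB <- GRanges(GenomicRanges::seqnames(reg),
            IRanges(GenomicRanges::end(lcr["A"]) + 1L,
                    GenomicRanges::start(lcr["B"]) - 1L))
        if (length(prb) > 0L) {
            within <- IRanges::overlapsAny(prb, gapAB, type = "within")
            if (!all(within))
                msg <- c(msg,
                    "every probe must lie strictly between LCR blocks A and B")
        }
    }
    if (length(object@bins) > 0L) {
        b <- object@bins
        if (any(GenomicRanges::width(b) != object@binWidth))
            msg <- c(msg, "all bins must have width binWidth")
        if (sum(GenomicRanges::width(b)) !=
            GenomicRanges::width(reg) + object@padding)
            msg <- c(msg, "bin grid must tile the padded region exactly")
        st <- GenomicRanges::start(b)
        if (is.unsorted(st, strictly = TRUE) ||
            any(diff(st) != object@binWidth))
            msg <- c(msg, "bins must be contiguous, sorted and non-overlapping")
    }
    if (object@binWidth <= 0L) msg <- c(msg, "binWidth must be positive")
    if (length(msg)) msg else TRUE
})

#' BinProfile: per-bin read counts for one plasma sample
#'
#' @slot sampleId character sample label.
#' @slot counts integer vector, one non-negative count per bin of the grid.
#' @slot ff numeric fetal fraction in (0,1), as reported to the caller.
#'
#' @exportClass BinProfile
setClass("BinProfile",
    slots = c(sampleId = "character", counts = "integer", ff = "numeric")
)

setValidity("BinProfile", function(object) {
    msg <- character()
    if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
    if (length(object@ff) != 1L || object@ff <= 0 || object@ff >= 1)
        msg <- c(msg, "ff must be a single value in (0,1)")
    if (length(msg)) msg else TRUE
})

#' ReferenceStats: per-bin baseline from a panel of unaffected samples
#'
#' Per-bin mean and standard deviation of depth-normalised counts (each
#' panel profile scaled to unit mean over the region first).
#'
#' @slot binMean numeric per-bin mean of normalised counts.
#' @slot binSd numeric per-bin standard deviation, floored at `sdFloor`.
#' @slot panelSize integer number of panel samples (>= 10).
#' @slot sdFloor numeric epsilon used to floor zero-variance bins.
#'
#' @exportClass ReferenceStats
setClass("ReferenceStats",
    slots = c(binMean = "numeric", binSd = "numeric",
              panelSize = "integer", sdFloor = "numeric")
)

setValidity("ReferenceStats", function(object) {
    msg <- character()
    if (length(object@binMean) != length(object@binSd))
        msg <- c(msg, "binMean and binSd must have equal length")
    if (any(object@binSd <= 0)) msg <- c(msg, "binSd must be positive")
    if (object@panelSize < 10L) msg <- c(msg, "panelSize must be >= 10")
    if (length(msg)) msg else TRUE
})

#' DeletionCall: result of scanning one bin profile
#'
#' @slot detected logical; when `FALSE` the remaining slots are empty.
#' @slot interval `GRanges` bin-aligned detected interval.
#' @slot sizeMb numeric deletion size in megabases (a multiple of
#'   binWidth/1e6).
#' @slot z numeric aggregate region z-score of the call.
#' @slot eventFraction numeric event-specific fraction in [0,1].
#' @slot nBins integer number of bins in the call.
#'
#' @exportClass DeletionCall
setClass("DeletionCall",
    slots = c(detected = "logical", interval = "GRanges", sizeMb = "numeric",
              z = "numeric", eventFraction = "numeric", nBins = "integer")
)

setValidity("DeletionCall", function(object) {
    msg <- character()
    if (!object@detected) {
        if (length(object@interval) != 0L || length(object@sizeMb) != 0L)
            msg <- c(msg, "an undetected call must carry no interval or size")
    } else {
        if (length(object@interval) != 1L)
            msg <- c(msg, "a detected call must carry a single interval")
        if (length(object@eventFraction) == 1L &&
            (object@eventFraction < 0 || object@eventFraction > 1))
            msg <- c(msg, "eventFraction must lie in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' MosaicismAssessment: mosaicism ratio and origin call
#'
#' @slot mr numeric mosaicism ratio (event fraction / fetal fraction).
#' @slot originCall `"suspected_fetal"` or `"likely_maternal"`.
#' @slot cutoff numeric MR threshold used (default 3).
#' @slot eventFraction,ff numeric inputs the assessment was derived from.
#'
#' @exportClass MosaicismAssessment
setClass("MosaicismAssessment",
    slots = c(mr = "numeric", originCall = "character", cutoff = "numeric",
              eventFraction = "numeric", ff = "numeric")
)

#' TestingRecommendation: confirmatory-testing advice for one call
#'
#' @slot probeDetectable named logical, one flag per FISH probe.
#' @slot fishSufficient logical, `TRUE` iff every probe overlaps the call.
#' @slot recommendedAssays ordered character; microarray is always first.
#' @slot maternalTestingAdvised logical.
#'
#' @exportClass TestingRecommendation
setClass("TestingRecommendation",
    slots = c(probeDetectable = "logical", fishSufficient = "logical",
              recommendedAssays = "character",
              maternalTestingAdvised = "logical")
)

setValidity("TestingRecommendation", function(object) {
    msg <- character()
    if (!"microarray" %in% object@recommendedAssays)
        msg <- c(msg, "microarray must always be recommended")
    if (object@fishSufficient && !all(object@probeDetectable))
        msg <- c(msg, "fishSufficient requires every probe to be detectable")
    if (length(msg)) msg else TRUE
})
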