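#' Default 22q11.2 region model
#'
#' Builds the default coordinate model of the 22q11.2 region: a 3.55-Mb
#' analysis window tiled by 50-kb bins, the four low-copy-repeat blocks
#' LCR22 A--D whose non-allelic homologous recombination mediates the
#' recurrent deletions, and the three FISH probe targets (N25, TUPLE1/HIRA,
#' TBX1) that hybridise between blocks A and B.
#'
#' The default coordinates are representative GRCh37-derived values rounded
#' to the 50-kb bin grid so that the canonical A--D deletion spans exactly
#' 51 bins (2.55 Mb, within one bin of the commonly quoted 2.54 Mb). They
#' are intended for simulation and method evaluation, not clinical
#' annotation, and can be overridden from BED files with
#' [loadRegionModel()].
#'
#' @param binWidth integer bin width in bases; default 50000.
#' @return A [RegionModel-class] object.
#' @examples
#' model <- defaultRegionModel()
#' length(binGrid(model))   # 71 bins of 50 kb
#' @export
defaultRegionModel <- function(binWidth = 50000L) {
    chrom <- "chr22"
    region <- GRanges(chrom, IRanges(18900001L, 22450000L))
    lcr <- GRanges(chrom, IRanges(
        start = c(18900001L, 20150001L, 20700001L, 21450001L),
        end   = c(19050000L, 20300000L, 20850000L, 21600000L)))
    names(lcr) <- c("A", "B", "C", "D")
    prb <- GRanges(chrom, IRanges(
        start = c(19100001L, 19330001L, 19740001L),
        end   = c(19150000L, 19380000L, 19790000L)))
    names(prb) <- c("N25", "TUPLE1_HIRA", "TBX1")
    newRegionModel(region, lcr, prb, binWidth,
                   genomeBuild = "GRCh37-like (representative, bin-aligned)")
}

# Assemble and validate a RegionModel, padding the window to whole bins.
newRegionModel <- function(region, lcrBlocks, probes, binWidth,
                           genomeBuild = "unspecified") {
    binWidth <- as.integer(binWidth)
    if (length(binWidth) != 1L || is.na(binWidth) || binWidth <= 0L)
        stop("binWidth must be a single positive integer")
    gb <- makeBins(region, binWidth)
    padding <- sum(GenomicRanges::width(gb)) - GenomicRanges::width(region)
    padded <- region
    GenomicRanges::end(padded) <- GenomicRanges::end(padded) + padding
    methods::new("RegionModel", region = padded, lcrBlocks = lcrBlocks,
        probes = probes, bins = gb, binWidth = binWidth,
        genomeBuild = genomeBuild, padding = as.integer(padding))
}

#' Load a region model from BED files or defaults
#'
#' @param regionBed,lcrBed,probesBed optional paths to BED files (3+
#'   columns, tab separated, 0-based half-open) giving the analysis window,
#'   the LCR22 A--D blocks (names in column 4), and the probe targets
#'   (names in column 4). Components left `NULL` fall back to the defaults
#'   of [defaultRegionModel()].
#' @param binWidth integer bin width in bases.
#' @param genomeBuild character build label recorded in the model.
#' @return A [RegionModel-class] object; probes outside the A--B interblock
#'   gap or malformed BED records raise errors.
#' @export
loadRegionModel <- function(regionBed = NULL, lcrBed = NULL,
                            probesBed = NULL, binWidth = 50000L,
                            genomeBuild = NULL) {
    def <- defaultRegionModel(binWidth)
    region <- if (is.null(regionBed)) analysisRegion(def) else {
        g <- readBedTrack(regionBed)
        if (length(g) != 1L)
            stop("region BED must contain exactly one interval")
        granges(g)
    }
    lcr <- if (is.null(lcrBed)) lcrBlocks(def) else {
        g <- readBedTrack(lcrBed)
        if (is.null(names(g)) || !setequal(names(g), c("A", "B", "C", "D")))
            stop("LCR BED must name four blocks A, B, C, D in column 4")
        g[order(GenomicRanges::start(g))]
    }
    prb <- if (is.null(probesBed)) probes(def) else {
        g <- readBedTrack(probesBed)
        if (is.null(names(g))) stop("probe BED must carry names in column 4")
        g
    }
    if (is.null(genomeBuild))
        genomeBuild <- if (is.null(regionBed) && is.null(lcrBed) &&
                           is.null(probesBed)) genomeBuild(def) else "user"
    newRegionModel(region, lcr, prb, binWidth, genomeBuild)
}

#' Tile a region with fixed-width bins
#'
#' Produces the contiguous, non-overlapping, sorted bin grid covering the
#' region. When the region length is not an integer multiple of `width` the
#' region end is padded upward so that the last bin is full-width; the
#' amount of padding is recorded in the model when called through
#' [loadRegionModel()].
#'
#' @param region `GRanges` of length 1.
#' @param width positive integer bin width in bases.
#' @return `GRanges` of bins, each of width `width`.
#' @examples
#' g <- GenomicRanges::GRanges("chr22", IRanges::IRanges(1, 3550000))
#' length(makeBins(g, 50000))  # 71
#' @export
makeBins <- function(region, width) {
    width <- as.integer(width)
    if (length(width) != 1L || is.na(width) || width <= 0L)
        stop("bin width must be a single positive integer")
    if (!is(region, "GRanges") || length(region) != 1L)
        stop("region must be a GRanges of length 1")
    n <- ceiling(GenomicRanges::width(region) / width)
    starts <- GenomicRanges::start(region) + width * (seq_len(n) - 1L)
    GRanges(GenomicRanges::seqnames(region),
            IRanges(starts, width = width))
}

#' Overlap between two genomic intervals, in bases
#'
#' Symmetric base-pair overlap of two single intervals. Abutting intervals
#' overlap by 0. Intervals on different chromosomes overlap by 0, with a
#' warning.
#'
#' @param a,b `GRanges` of length 1.
#' @return Integer number of overlapping bases.
#' @export
overlapBp <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"),
              length(a) == 1L, length(b) == 1L)
    if (as.character(GenomicRanges::seqnames(a)) !=
        as.character(GenomicRanges::seqnames(b))) {
        warning("intervals on different chromosomes; overlap is 0")
        return(0L)
    }
    ov <- min(GenomicRanges::end(a), GenomicRanges::end(b)) -
          max(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
    max(0L, as.integer(ov))
}

#' Canonical LCR-mediated deletion intervals
#'
#' Returns the recurrent deletion interval spanning two LCR22 blocks:
#' from the proximal edge of the first block to the proximal edge of the
#' second, the usual convention for NAHR-mediated events whose breakpoints
#' fall inside the repeats. `"subAB"` is a smaller atypical interval nested
#' within the A--B region.
#'
#' @param model a [RegionModel-class].
#' @param class one of `"AD"`, `"AB"`, `"BD"`, `"CD"`, `"subAB"`.
#' @return `GRanges` of length 1.
#' @examples
#' GenomicRanges::width(canonicalDeletion(defaultRegionModel(), "AD")) / 1e6
#' @export
canonicalDeletion <- function(model,
                              class = c("AD", "AB", "BD", "CD", "subAB")) {
    class <- match.arg(class)
    lcr <- lcrBlocks(model)
    chrom <- GenomicRanges::seqnames(analysisRegion(model))
    s <- stats::setNames(GenomicRanges::start(lcr), names(lcr))
    endA <- GenomicRanges::end(lcr["A"])
    iv <- switch(class,
        AD = IRanges(s[["A"]], s[["D"]] - 1L),
        AB = IRanges(s[["A"]], s[["B"]] - 1L),
        BD = IRanges(s[["B"]], s[["D"]] - 1L),
        CD = IRanges(s[["C"]], s[["D"]] - 1L),
        subAB = IRanges(endA + 150001L, endA + 650000L))
    GRanges(chrom, iv)
}

#' Read and write BED tracks
#'
#' Thin wrappers around \pkg{rtracklayer} BED import/export that validate
#' records up front and report the offending line on failure. BED files are
#' 0-based half-open on disk; the returned `GRanges` follow the usual
#' 1-based closed convention.
#'
#' @param path file path.
#' @return `readBedTrack` returns a `GRanges`, named from BED column 4 when
#'   present.
#' @export
readBedTrack <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    for (i in which(keep)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed BED line ", i, " (fewer than 3 columns): ",
                 lines[[i]])
        s <- suppressWarnings(as.numeric(f[2L]))
        e <- suppressWarnings(as.numeric(f[3L]))
        if (is.na(s) || is.na(e))
            stop("malformed BED line ", i, " (non-numeric coordinates)")
        if (s >= e)
            stop("malformed BED line ", i, " (start >= end): ", lines[[i]])
    }
    g <- rtracklayer::import(path, format = "BED")
    if (!is.null(mcols(g)$name)) names(g) <- mcols(g)$name
    granges(g, use.mcols = FALSE)
}

#' @rdname readBedTrack
#' @param gr `GRanges` to write; `names(gr)` populate BED column 4.
#' @export
writeBedTrack <- function(gr, path) {
    out <- granges(gr, use.mcols = FALSE)
    if (!is.null(names(out))) mcols(out)$name <- names(out)
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

## Accessors -----------------------------------------------------------

#' @rdname RegionModel-class
#' @export
setMethod("analysisRegion", "RegionModel", function(x) x@region)

#' @rdname RegionModel-class
#' @export
setMethod("lcrBlocks", "RegionModel", function(x) x@lcrBlocks)

#' @rdname RegionModel-class
#' @export
setMethod("probes", "RegionModel", function(x) x@probes)

#' @rdname RegionModel-class
#' @export
setMethod("binGrid", "RegionModel", function(x) x@bins)

#' @rdname RegionModel-class
#' @export
setMethod("binWidth", "RegionModel", function(x) x@binWidth)

#' @rdname RegionModel-class
#' @export
setMethod("genomeBuild", "RegionModel", function(x) x@genomeBuild)

setMethod("show", "RegionModel", function(object) {
    reg <- object@region
    cat("RegionModel on", as.character(GenomicRanges::seqnames(reg)),
        sprintf("[%d, %d]", GenomicRanges::start(reg),
                GenomicRanges::end(reg)),
        sprintf("(%.2f Mb, build: %s)\n",
                GenomicRanges::width(reg) / 1e6, object@genomeBuild))
    cat(" ", length(object@bins), "bins of", object@binWidth, "bp")
    if (object@padding > 0L)
        cat(" (window padded by", object@padding, "bp)")
    cat("\n  LCR22 blocks:", paste(names(object@lcrBlocks), collapse = ", "),
        "\n  FISH probes:", paste(names(object@probes), collapse = ", "),
        "\n")
})
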