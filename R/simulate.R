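#' Deletion origins modelled by the simulator
#'
#' A heterozygous 22q11.2 deletion present in a fraction `c` of the plasma
#' cfDNA depresses binned read depth inside the deleted interval to
#' `1 - c/2` of the diploid baseline. The carrier fraction `c` depends on
#' who carries the deletion: the fetus only (`c = ff`, de novo or
#' paternally inherited), the mother only (`c = 1 - ff`, maternal deletion
#' not transmitted to the fetus), or both (`c = 1`, maternal deletion
#' transmitted).
#'
#' @format Character vector of the recognised origin labels.
#' @export
DELETION_ORIGINS <- c("none", "fetal_de_novo", "maternal_not_transmitted",
                      "maternal_transmitted", "paternal_fetal")

# Fraction of plasma cfDNA molecules that carry the deletion.
carrierFraction <- function(origin, ff) {
    switch(origin,
        none                     = 0,
        fetal_de_novo            = ff,
        paternal_fetal           = ff,
        maternal_not_transmitted = 1 - ff,
        maternal_transmitted     = 1,
        stop("unknown deletion origin: ", origin))
}

#' Expected depth ratio inside a deleted interval
#'
#' Relative to the diploid baseline, the expected binned depth inside a
#' heterozygous deletion carried by a fraction `c` of the cfDNA is
#' `1 - c/2`; outside the deletion it is 1.
#'
#' @param origin one of [DELETION_ORIGINS].
#' @param ff fetal fraction, in (0,1).
#' @return Expected depth ratio (a single number in (0,1]).
#' @examples
#' expectedDepthRatio("fetal_de_novo", 0.10)             # 0.95
#' expectedDepthRatio("maternal_not_transmitted", 0.10)  # 0.55
#' expectedDepthRatio("maternal_transmitted", 0.10)      # 0.50
#' @export
expectedDepthRatio <- function(origin, ff) {
    origin <- match.arg(origin, DELETION_ORIGINS)
    if (!is.numeric(ff) || length(ff) != 1L || ff <= 0 || ff >= 1)
        stop("ff must be a single value in (0,1)")
    1 - carrierFraction(origin, ff) / 2
}

#' Simulate one plasma bin profile
#'
#' Draws per-bin read counts for a maternal plasma sample. Each bin count
#' is drawn independently with mean
#' `meanDepth * (1 - fracOverlap * c/2) * bias`, where `fracOverlap` is the
#' fraction of the bin covered by the deletion interval (boundary bins are
#' depressed proportionally) and `c` the carrier fraction for `origin` at
#' fetal fraction `ff`. Counts are Poisson when `dispersion = 0` and
#' negative binomial (variance `mu + dispersion * mu^2`) otherwise.
#'
#' @param model a [RegionModel-class].
#' @param origin one of [DELETION_ORIGINS].
#' @param interval `GRanges` deleted interval (required unless
#'   `origin = "none"`); must lie within the analysis window.
#' @param ff fetal fraction in (0,1).
#' @param meanDepth expected reads per bin at diploid dosage (default 1000).
#' @param dispersion negative-binomial overdispersion (default 0 = Poisson).
#' @param bias optional per-bin multiplicative bias vector (default all 1);
#'   hook for GC/mappability-style effects, which are not otherwise
#'   modelled.
#' @param sampleId sample label.
#' @param seed optional integer; identical seed and inputs give identical
#'   profiles.
#' @return A [BinProfile-class].
#' @examples
#' model <- defaultRegionModel()
#' p <- simulateSample(model, "maternal_not_transmitted",
#'                     canonicalDeletion(model, "AD"), ff = 0.10, seed = 1)
#' @export
simulateSample <- function(model, origin = "none", interval = NULL,
                           ff = 0.10, meanDepth = 1000, dispersion = 0,
                           bias = NULL, sampleId = "sample", seed = NULL) {
    origin <- match.arg(origin, DELETION_ORIGINS)
    if (meanDepth <= 0) stop("meanDepth must be positive")
    if (dispersion < 0) stop("dispersion must be non-negative")
    bins <- binGrid(model)
    nb <- length(bins)
    if (is.null(bias)) bias <- rep(1, nb)
    if (length(bias) != nb) stop("bias must have one value per bin")
    mu <- rep(meanDepth, nb) * bias
    if (origin != "none") {
        if (is.null(interval))
            stop("a deletion interval is required when origin != 'none'")
        if (overlapBp(interval, analysisRegion(model)) !=
            GenomicRanges::width(interval))
            stop("deletion interval falls outside the analysis window")
        frac <- binOverlapFraction(bins, interval)
        mu <- mu * (1 - frac * carrierFraction(origin, ff) / 2)
    }
    if (!is.null(seed)) set.seed(seed)
    counts <- if (dispersion == 0) stats::rpois(nb, mu)
              else stats::rnbinom(nb, size = 1 / dispersion, mu = mu)
    methods::new("BinProfile", sampleId = sampleId,
                 counts = as.integer(counts), ff = ff)
}

# Fraction of each bin covered by an interval.
binOverlapFraction <- function(bins, interval) {
    w <- pmin(GenomicRanges::end(bins), GenomicRanges::end(interval)) -
         pmax(GenomicRanges::start(bins), GenomicRanges::start(interval)) + 1L
    pmax(w, 0L) / GenomicRanges::width(bins)
}

#' Simulate a reference panel of unaffected samples
#'
#' @param model a [RegionModel-class].
#' @param n number of panel samples (default 50).
#' @param meanDepth,dispersion as in [simulateSample()].
#' @param seed optional integer seed.
#' @return Integer matrix of counts, bins in rows, samples in columns.
#' @export
simulatePanel <- function(model, n = 50, meanDepth = 1000, dispersion = 0,
                          seed = NULL) {
    if (n < 1) stop("n must be positive")
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n), function(i) {
        counts(simulateSample(model, "none", ff = 0.10,
                              meanDepth = meanDepth,
                              dispersion = dispersion,
                              sampleId = sprintf("panel%03d", i)))
    }, integer(length(binGrid(model))))
}

#' Cohort-level simulation parameters
#'
#' Defaults emulate the composition of a screen-positive 22q11.2 NIPS
#' cohort: 57.7% of events maternal in origin, a 50% transmission risk for
#' maternal carriers, 85% of deletions the common A--D event with the
#' remainder nested/atypical, and fetal fractions lognormal with median
#' 10.48% truncated to [0.02, 0.45].
#'
#' @param pMaternal probability an event is carried by the mother.
#' @param pTransmit probability a maternal deletion is transmitted.
#' @param pPaternal probability a fetal event is paternally inherited.
#' @param sizeMix named weights over deletion classes
#'   (`AD`, `AB`, `BD`, `CD`, `subAB`); must sum to 1.
#' @param ffMeanlog,ffSdlog lognormal parameters of the fetal fraction.
#' @param ffRange truncation bounds for the fetal fraction.
#' @param pUltrasound probability of a reported ultrasound finding.
#' @param testingProbs named probabilities over diagnostic-testing
#'   dispositions (`fetal_only`, `maternal_only`, `both`, `none`).
#' @return A named list of validated parameters.
#' @export
cohortParams <- function(pMaternal = 0.577, pTransmit = 0.5,
                         pPaternal = 0.01,
                         sizeMix = c(AD = 0.85, AB = 0.06, BD = 0.02,
                                     CD = 0.05, subAB = 0.02),
                         ffMeanlog = log(0.1048), ffSdlog = 0.45,
                         ffRange = c(0.02, 0.45),
                         pUltrasound = 0.511,
                         testingProbs = c(fetal_only = 0.270,
                                          maternal_only = 0.248,
                                          both = 0.114, none = 0.368)) {
    p <- c(pMaternal, pTransmit, pPaternal, pUltrasound, testingProbs)
    if (any(p < 0 | p > 1)) stop("all probabilities must lie in [0,1]")
    if (abs(sum(sizeMix) - 1) > 1e-8) stop("sizeMix weights must sum to 1")
    if (abs(sum(testingProbs) - 1) > 1e-8)
        stop("testingProbs must sum to 1")
    list(pMaternal = pMaternal, pTransmit = pTransmit,
         pPaternal = pPaternal, sizeMix = sizeMix, ffMeanlog = ffMeanlog,
         ffSdlog = ffSdlog, ffRange = ffRange, pUltrasound = pUltrasound,
         testingProbs = testingProbs)
}

# Truncated-lognormal fetal fractions (resampling rejection).
drawFF <- function(n, params) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- stats::rlnorm(n, params$ffMeanlog, params$ffSdlog)
        out <- c(out, x[x >= params$ffRange[1] & x <= params$ffRange[2]])
    }
    out[seq_len(n)]
}

#' Simulate a screen-positive cohort
#'
#' Draws latent truth (origin, deletion class and interval, fetal fraction,
#' ultrasound flag, diagnostic-testing disposition) for `n` screen-positive
#' cases and, optionally, a bin-count profile for each. Reproducible under
#' `seed`.
#'
#' @param model a [RegionModel-class].
#' @param n number of cases.
#' @param params a [cohortParams()] list.
#' @param meanDepth,dispersion count model, as in [simulateSample()].
#' @param seed integer seed.
#' @param profiles when `FALSE`, only the truth table is generated.
#' @param ffRange optional length-2 override restricting fetal fractions to
#'   a fixed interval (uniform draw), as used in evaluation experiments.
#' @return When `profiles = TRUE`, a
#'   \linkS4class{RangedSummarizedExperiment} with a `counts` assay (bins
#'   by samples), `rowRanges` the bin grid, and the truth table as
#'   `colData`; otherwise the truth table as a `DataFrame`.
#' @export
simulateCohort <- function(model, n = 100, params = cohortParams(),
                           meanDepth = 1000, dispersion = 0, seed = NULL,
                           profiles = TRUE, ffRange = NULL) {
    if (n <= 0) stop("n must be positive")
    if (!is.null(seed)) set.seed(seed)
    maternal <- stats::runif(n) < params$pMaternal
    origin <- ifelse(maternal,
        ifelse(stats::runif(n) < params$pTransmit,
               "maternal_transmitted", "maternal_not_transmitted"),
        ifelse(stats::runif(n) < params$pPaternal,
               "paternal_fetal", "fetal_de_novo"))
    delClass <- sample(names(params$sizeMix), n, replace = TRUE,
                       prob = params$sizeMix)
    ffs <- if (is.null(ffRange)) drawFF(n, params)
           else stats::runif(n, ffRange[1], ffRange[2])
    ultrasound <- stats::runif(n) < params$pUltrasound
    testing <- sample(names(params$testingProbs), n, replace = TRUE,
                      prob = params$testingProbs)
    ivs <- lapply(delClass, function(cl) canonicalDeletion(model, cl))

    # Diagnostic dispositions implied by the latent truth. Every simulated
    # screen positive carries a real deletion, so completed testing always
    # confirms it: testing of the individual the event sits in (or a
    # positive fetal result for a transmitted maternal deletion) is
    # complete; testing only the other individual with a normal result is
    # incomplete and cannot rule the deletion out.
    suspectedOrigin <- ifelse(maternal, "maternal", "fetal")
    transmitted <- origin == "maternal_transmitted"
    fetalTested <- testing %in% c("fetal_only", "both")
    completeness <- rep("none", n)
    completeness[testing == "maternal_only"] <-
        ifelse(maternal[testing == "maternal_only"], "complete",
               "incomplete")
    completeness[testing == "both"] <- "complete"
    completeness[testing == "fetal_only"] <-
        ifelse(!maternal[testing == "fetal_only"] |
               transmitted[testing == "fetal_only"], "complete",
               "incomplete")
    confirmed <- ifelse(completeness == "complete", "true_positive",
                        "unknown")
    fetalInherited <- ifelse(maternal & fetalTested, transmitted, NA)
    cardiac <- ultrasound & stats::runif(n) < 0.605
    deferredPostnatal <- fetalTested & stats::runif(n) < 0.458

    truth <- DataFrame(
        sampleId = sprintf("case%05d", seq_len(n)),
        origin = origin, suspectedOrigin = suspectedOrigin,
        delClass = delClass,
        delStart = vapply(ivs, GenomicRanges::start, integer(1)),
        delEnd = vapply(ivs, GenomicRanges::end, integer(1)),
        trueSizeMb = vapply(ivs, GenomicRanges::width, integer(1)) / 1e6,
        ff = ffs, ultrasound = ultrasound, testing = testing,
        completeness = completeness, confirmed = confirmed,
        cardiac = cardiac, deferredPostnatal = deferredPostnatal,
        fetalInherited = fetalInherited)
    rownames(truth) <- truth$sampleId
    if (!profiles) return(truth)
    mat <- vapply(seq_len(n), function(i) {
        counts(simulateSample(model, origin[i], ivs[[i]], ff = ffs[i],
                              meanDepth = meanDepth,
                              dispersion = dispersion,
                              sampleId = truth$sampleId[i]))
    }, integer(length(binGrid(model))))
    colnames(mat) <- truth$sampleId
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat), rowRanges = binGrid(model),
        colData = truth)
    S4Vectors::metadata(se) <- list(seed = seed, meanDepth = meanDepth,
                                    dispersion = dispersion,
                                    params = params)
    se
}

#' Write a cohort truth table as TSV
#'
#' @param truth a `DataFrame` (or the `colData` of a simulated cohort).
#' @param path output file.
#' @param header optional named character vector written as `# key: value`
#'   comment lines before the table.
#' @export
writeTruthTable <- function(truth, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(sprintf("# %s: %s", names(header), header), con)
    utils::write.table(as.data.frame(truth), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

## Accessors -----------------------------------------------------------

#' @rdname BinProfile-class
#' @export
setMethod("sampleId", "BinProfile", function(x) x@sampleId)

#' @rdname BinProfile-class
#' @export
setMethod("ff", "BinProfile", function(x) x@ff)

#' @rdname BinProfile-class
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "BinProfile", function(object, ...) object@counts)

setMethod("show", "BinProfile", function(object) {
    cat("BinProfile", object@sampleId, "-", length(object@counts),
        sprintf("bins, ff = %.3f, mean depth = %.1f\n",
                object@ff, mean(object@counts)))
})
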