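#' Mosaicism ratio
#'
#' The mosaicism ratio (MR) divides the fraction of cfDNA carrying the
#' abnormal event by the overall fetal fraction of the specimen. A purely
#' fetal heterozygous deletion gives MR near 1; a maternal carrier, whose
#' deletion rides on the dominant maternal share of the cfDNA, gives MR
#' well above 1 at typical fetal fractions.
#'
#' @param eventFraction event-specific fraction in [0, 1].
#' @param ff fetal fraction, > 0.
#' @return The ratio `eventFraction / ff`.
#' @examples
#' mosaicismRatio(0.10, 0.10)   # 1: fetal-looking
#' mosaicismRatio(0.90, 0.10)   # 9: maternal-looking
#' @export
mosaicismRatio <- function(eventFraction, ff) {
    if (any(ff <= 0)) stop("ff must be positive")
    if (any(eventFraction < 0 | eventFraction > 1))
        stop("eventFraction must lie in [0,1]")
    eventFraction / ff
}

#' Classify the origin of a called deletion from its MR
#'
#' Labels a call `"likely_maternal"` when the mosaicism ratio exceeds the
#' cutoff (default 3) and `"suspected_fetal"` otherwise; a tie at exactly
#' the cutoff resolves to `"suspected_fetal"`, conservative with respect to
#' fetal follow-up. An optional secondary rule flags `"likely_maternal"`
#' whenever the event fraction exceeds 0.5 regardless of MR, since more
#' than half the cfDNA can only carry the event if the mother does.
#'
#' @param mr mosaicism ratio, >= 0.
#' @param cutoff MR threshold (default 3).
#' @param eventFraction optional event fraction enabling the secondary
#'   rule.
#' @param secondaryRule apply the event-fraction rule (default `FALSE`).
#' @return `"likely_maternal"` or `"suspected_fetal"`.
#' @examples
#' classifyOrigin(8.354)  # likely_maternal
#' classifyOrigin(1.023)  # suspected_fetal
#' @export
classifyOrigin <- function(mr, cutoff = 3, eventFraction = NULL,
                           secondaryRule = FALSE) {
    if (any(mr < 0)) stop("mr must be non-negative")
    lab <- ifelse(mr > cutoff, "likely_maternal", "suspected_fetal")
    if (secondaryRule && !is.null(eventFraction))
        lab[eventFraction > 0.5] <- "likely_maternal"
    lab
}

#' Assess origin of a call
#'
#' Convenience wrapper combining [mosaicismRatio()] and [classifyOrigin()]
#' into a [MosaicismAssessment-class].
#'
#' @param eventFraction event-specific fraction in [0, 1] (or a detected
#'   [DeletionCall-class]).
#' @param ff fetal fraction, > 0.
#' @param cutoff MR threshold (default 3).
#' @param secondaryRule see [classifyOrigin()].
#' @return A [MosaicismAssessment-class].
#' @export
assessOrigin <- function(eventFraction, ff, cutoff = 3,
                         secondaryRule = FALSE) {
    if (is(eventFraction, "DeletionCall")) {
        if (!isDetected(eventFraction))
            stop("cannot assess origin of an undetected call")
        eventFraction <- eventFraction(eventFraction)
    }
    mr <- mosaicismRatio(eventFraction, ff)
    methods::new("MosaicismAssessment", mr = mr,
        originCall = classifyOrigin(mr, cutoff, eventFraction,
                                    secondaryRule),
        cutoff = cutoff, eventFraction = eventFraction, ff = ff)
}

#' Expected mosaicism ratio under each deletion origin
#'
#' Closed-form MR implied by the plasma mixture model: a fetal event (de
#' novo or paternally inherited) has event fraction `ff` and MR 1 at any
#' fetal fraction; a maternal deletion not transmitted to the fetus has
#' event fraction `1 - ff`, hence MR `(1 - ff)/ff`, strictly decreasing in
#' `ff` and dropping below the classification cutoff of 3 once `ff` exceeds
#' 0.25; a transmitted maternal deletion has event fraction 1 and MR
#' `1/ff`.
#'
#' @param origin one of [DELETION_ORIGINS].
#' @param ff fetal fraction in (0, 1).
#' @return Expected mosaicism ratio.
#' @examples
#' analyticMr("maternal_not_transmitted", 0.1048)  # 8.54
#' analyticMr("maternal_not_transmitted", 0.2783)  # 2.59 (< 3)
#' @export
analyticMr <- function(origin, ff) {
    origin <- match.arg(origin, DELETION_ORIGINS)
    if (!is.numeric(ff) || any(ff <= 0) || any(ff >= 1))
        stop("ff must lie in (0,1)")
    switch(origin,
        none                     = 0 * ff,
        fetal_de_novo            = rep(1, length(ff)),
        paternal_fetal           = rep(1, length(ff)),
        maternal_not_transmitted = (1 - ff) / ff,
        maternal_transmitted     = 1 / ff)
}

# True origin -> fetal/maternal side, for recovery scoring.
originSide <- function(origin) {
    ifelse(origin %in% c("maternal_not_transmitted", "maternal_transmitted"),
           "likely_maternal", "suspected_fetal")
}

## Accessors -----------------------------------------------------------

#' @rdname MosaicismAssessment-class
#' @export
setMethod("mosaicismRatioOf", "MosaicismAssessment", function(x) x@mr)

#' @rdname MosaicismAssessment-class
#' @export
setMethod("originCall", "MosaicismAssessment", function(x) x@originCall)

#' @rdname MosaicismAssessment-class
#' @export
setMethod("ff", "MosaicismAssessment", function(x) x@ff)

#' @rdname MosaicismAssessment-class
#' @export
setMethod("eventFraction", "MosaicismAssessment",
          function(x) x@eventFraction)

setMethod("show", "MosaicismAssessment", function(object) {
    cat(sprintf(
        "MosaicismAssessment: MR = %.3f (eps = %.3f / ff = %.3f) -> %s (cutoff %.1f)\n",
        object@mr, object@eventFraction, object@ff, object@originCall,
        object@cutoff))
})
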