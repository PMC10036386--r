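#' Would standard FISH probes detect the called deletion?
#'
#' The common commercial FISH probes for 22q11.2 (N25, TUPLE1/HIRA, TBX1)
#' hybridise between LCR22 blocks A and B, so nested or atypical deletions
#' that do not span the A--B interblock region escape them. A probe is
#' flagged detectable iff the predicted interval overlaps its target by at
#' least one base.
#'
#' @param call a detected [DeletionCall-class].
#' @param model a [RegionModel-class].
#' @return Named logical vector, one flag per configured probe.
#' @examples
#' # an A-D call overlaps all three probes; a C-D call none
#' @export
probeDetectability <- function(call, model) {
    if (!isDetected(call))
        stop("probe detectability is undefined for an undetected call")
    prb <- probes(model)
    iv <- callInterval(call)
    out <- vapply(seq_along(prb),
                  function(i) overlapBp(iv, prb[i]) > 0L, logical(1))
    names(out) <- names(prb)
    out
}

#' Recommend confirmatory testing for a screen-positive call
#'
#' Microarray is always recommended first: it confirms the deletion,
#' resolves its true size and gene content, and cannot be escaped by
#' atypical breakpoints. FISH is listed only when every configured probe
#' overlaps the predicted interval. Maternal testing is advised when the
#' origin assessment is `"likely_maternal"`, since a confirmed maternal
#' deletion carries a 50% transmission risk to the fetus.
#'
#' @param call a detected [DeletionCall-class].
#' @param assessment a [MosaicismAssessment-class] for the same call.
#' @param model a [RegionModel-class].
#' @return A [TestingRecommendation-class].
#' @export
recommendTesting <- function(call, assessment, model) {
    det <- probeDetectability(call, model)
    fishOk <- all(det)
    assays <- c("microarray", if (fishOk) "FISH")
    methods::new("TestingRecommendation", probeDetectable = det,
        fishSufficient = fishOk, recommendedAssays = assays,
        maternalTestingAdvised =
            originCall(assessment) == "likely_maternal")
}

## Accessors -----------------------------------------------------------

#' @rdname TestingRecommendation-class
#' @export
setMethod("probeDetectable", "TestingRecommendation",
          function(x) x@probeDetectable)

#' @rdname TestingRecommendation-class
#' @export
setMethod("fishSufficient", "TestingRecommendation",
          function(x) x@fishSufficient)

#' @rdname TestingRecommendation-class
#' @export
setMethod("recommendedAssays", "TestingRecommendation",
          function(x) x@recommendedAssays)

#' @rdname TestingRecommendation-class
#' @export
setMethod("maternalTestingAdvised", "TestingRecommendation",
          function(x) x@maternalTestingAdvised)

setMethod("show", "TestingRecommendation", function(object) {
    cat("TestingRecommendation:",
        paste(object@recommendedAssays, collapse = " > "), "\n")
    cat("  probes:",
        paste(sprintf("%s=%s", names(object@probeDetectable),
                      ifelse(object@probeDetectable, "yes", "no")),
              collapse = ", "), "\n")
    cat("  maternal testing advised:",
        ifelse(object@maternalTestingAdvised, "yes", "no"), "\n")
})
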