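# Accessor generics. Slot access from user code goes through these.

#' @rdname RegionModel-class
#' @param x a package object.
#' @export
setGeneric("analysisRegion", function(x) standardGeneric("analysisRegion"))

#' @rdname RegionModel-class
#' @export
setGeneric("lcrBlocks", function(x) standardGeneric("lcrBlocks"))

#' @rdname RegionModel-class
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname RegionModel-class
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

#' @rdname RegionModel-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname RegionModel-class
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname BinProfile-class
#' @param x a package object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname BinProfile-class
#' @export
setGeneric("ff", function(x) standardGeneric("ff"))

#' @rdname ReferenceStats-class
#' @param x a package object.
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))

#' @rdname DeletionCall-class
#' @param x a package object.
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname DeletionCall-class
#' @export
setGeneric("callInterval", function(x) standardGeneric("callInterval"))

#' @rdname DeletionCall-class
#' @export
setGeneric("sizeMb", function(x) standardGeneric("sizeMb"))

#' @rdname DeletionCall-class
#' @export
setGeneric("eventFraction", function(x) standardGeneric("eventFraction"))

#' @rdname DeletionCall-class
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname MosaicismAssessment-class
#' @param x a package object.
#' @export
setGeneric("mosaicismRatioOf", function(x) standardGeneric("mosaicismRatioOf"))

#' @rdname MosaicismAssessment-class
#' @export
setGeneric("originCall", function(x) standardGeneric("originCall"))

#' @rdname TestingRecommendation-class
#' @param x a package object.
#' @export
setGeneric("probeDetectable", function(x) standardGeneric("probeDetectable"))

#' @rdname TestingRecommendation-class
#' @export
setGeneric("fishSufficient", function(x) standardGeneric("fishSufficient"))

#' @rdname TestingRecommendation-class
#' @export
setGeneric("recommendedAssays",
    function(x) standardGeneric("recommendedAssays"))

#' @rdname TestingRecommendation-class
#' @export
setGeneric("maternalTestingAdvised",
    function(x) standardGeneric("maternalTestingAdvised"))
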