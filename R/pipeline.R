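#' Run the full simulate -> call -> classify -> advise -> stats pipeline
#'
#' Simulates a reference panel and a screen-positive cohort, calls each
#' sample, classifies the origin of every detected deletion, derives a
#' testing recommendation, and summarises the run (detection rate, origin
#' recovery, size concordance). All tabular outputs are written as TSV and
#' structured outputs as JSON under `outDir`; every file carries the seed
#' and a config hash in a metadata header, so that identical seed and
#' config give byte-identical bundles.
#'
#' @param outDir output directory (created if needed).
#' @param nCases cohort size.
#' @param seed integer seed driving every random draw.
#' @param model a [RegionModel-class].
#' @param regionBed,lcrBed,probesBed optional BED paths; when any is given
#'   the model is loaded from them via [loadRegionModel()] and a missing
#'   file raises a config error naming the path.
#' @param params a [cohortParams()] list.
#' @param meanDepth,dispersion count model; see [simulateSample()].
#' @param panelSize reference-panel size.
#' @param zThreshold scan acceptance threshold; see [scanRegion()].
#' @param mrCutoff MR classification cutoff.
#' @param ciMethod Wilson-interval variant for any PPV output.
#' @param verbose log per-stage progress with counts.
#' @return Invisibly, a list with the truth table, the per-sample results
#'   `data.frame`, and the run summary.
#' @export
runPipeline <- function(outDir, nCases = 200, seed = 1,
                        model = NULL, regionBed = NULL, lcrBed = NULL,
                        probesBed = NULL,
                        params = cohortParams(), meanDepth = 1000,
                        dispersion = 0, panelSize = 50, zThreshold = NULL,
                        mrCutoff = 3, ciMethod = "wilson",
                        verbose = TRUE) {
    say <- function(...) if (verbose) message(...)
    if (nCases <= 0) stop("config error in field 'nCases': must be positive")
    if (is.null(model)) {
        model <- if (is.null(regionBed) && is.null(lcrBed) &&
                     is.null(probesBed)) defaultRegionModel()
        else tryCatch(
            loadRegionModel(regionBed, lcrBed, probesBed),
            error = function(e) stop("config error in region model paths: ",
                                     conditionMessage(e)))
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    config <- list(nCases = nCases, seed = seed, meanDepth = meanDepth,
                   dispersion = dispersion, panelSize = panelSize,
                   zThreshold = zThreshold, mrCutoff = mrCutoff,
                   ciMethod = ciMethod, params = params,
                   binWidth = binWidth(model),
                   genomeBuild = genomeBuild(model))
    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    cfgHash <- unname(tools::md5sum(cfgPath))
    hdr <- c(seed = as.character(seed), config_md5 = cfgHash)

    say("stage simulate: panel of ", panelSize, " + cohort of ", nCases)
    set.seed(seed)
    panel <- simulatePanel(model, n = panelSize, meanDepth = meanDepth,
                           dispersion = dispersion)
    ref <- buildReference(panel)
    se <- simulateCohort(model, n = nCases, params = params,
                         meanDepth = meanDepth, dispersion = dispersion)
    truth <- SummarizedExperiment::colData(se)
    writeTruthTable(truth, file.path(outDir, "truth.tsv"), hdr)

    say("stage call: ", nCases, " samples in")
    cnt <- SummarizedExperiment::assay(se, "counts")
    res <- lapply(seq_len(nCases), function(i) {
        call <- callDeletion(cnt[, i], ref, model, zThreshold = zThreshold,
                             depthAnchor = meanDepth)
        if (!isDetected(call))
            return(data.frame(sampleId = truth$sampleId[i],
                              detected = FALSE, sizeMb = NA_real_,
                              eventFraction = NA_real_, z = NA_real_,
                              mr = NA_real_, originCall = NA_character_,
                              fishSufficient = NA,
                              maternalTestingAdvised = NA))
        ass <- assessOrigin(call, ff = truth$ff[i], cutoff = mrCutoff)
        rec <- recommendTesting(call, ass, model)
        data.frame(sampleId = truth$sampleId[i], detected = TRUE,
                   sizeMb = sizeMb(call),
                   eventFraction = eventFraction(call), z = zScore(call),
                   mr = mosaicismRatioOf(ass), originCall = originCall(ass),
                   fishSufficient = fishSufficient(rec),
                   maternalTestingAdvised = maternalTestingAdvised(rec))
    })
    res <- do.call(rbind, res)
    say("stage call: ", sum(res$detected), " detected out")
    writeTruthTable(DataFrame(res), file.path(outDir, "calls.tsv"), hdr)

    say("stage stats")
    ppv <- ppvScenarios(truth, ciMethod = ciMethod)
    writeTruthTable(DataFrame(ppv), file.path(outDir, "ppv.tsv"), hdr)
    det <- res$detected
    recovered <- det &
        res$originCall == originSide(truth$origin)
    conc <- if (sum(det) >= 3 &&
                stats::var(res$sizeMb[det]) > 0)
        sizeConcordance(res$sizeMb[det], truth$trueSizeMb[det])
    else NULL
    summary <- list(
        seed = seed, config_md5 = cfgHash, n = nCases,
        detection_rate = mean(det),
        origin_recovery_rate = mean(recovered),
        size_within_2bins_rate = mean(
            abs(res$sizeMb[det] - truth$trueSizeMb[det]) <=
                2 * binWidth(model) / 1e6),
        concordance = conc,
        ppv = stats::setNames(as.list(ppv$ppv), ppv$scenario))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("done: ", outDir)
    invisible(list(truth = truth, results = res, summary = summary,
                   reference = ref))
}

# Printed cohort statistics the fixture reconstructs, used by
# fixtureReport() as its comparison column.
fixtureReferenceValues <- function() {
    c(ppv_complete = 99.4, ppv_fetal_only = 98.7, ppv_conservative = 90.7,
      ppv_upper_bound = 99.7, ppv_lower_bound = 57.3,
      pct_suspected_maternal = 57.7, pct_ultrasound = 51.1,
      pct_diagnostic_testing = 63.2, pct_deferred_postnatal = 45.8,
      pct_cardiac_of_ultrasound = 60.5, pct_fetal_inheritance = 58.1)
}

#' Recompute the headline cohort numbers from the fixture
#'
#' Runs the statistics layer over the deterministic 307-case fixture and
#' tabulates each computed value against the published cohort statistic
#' the fixture reconstructs.
#'
#' @param ciMethod Wilson-interval variant; see [wilsonCi()].
#' @return `data.frame` with columns `metric`, `computed`, `reference`,
#'   `pass` (exact agreement after half-up rounding to 1 decimal).
#' @examples
#' fixtureReport()
#' @export
fixtureReport <- function(ciMethod = "wilson") {
    fx <- cohortFixture()
    ppv <- ppvScenarios(fx, ciMethod = ciMethod)
    sm <- summarizeCohort(fx)
    computed <- c(
        ppv_complete = ppv["complete", "percent"],
        ppv_fetal_only = ppv["fetal_only", "percent"],
        ppv_conservative = ppv["conservative", "percent"],
        ppv_upper_bound = ppv["upper_bound", "percent"],
        ppv_lower_bound = ppv["lower_bound", "percent"],
        pct_suspected_maternal = sm["suspected_maternal", "percent"],
        pct_ultrasound = sm["ultrasound", "percent"],
        pct_diagnostic_testing = sm["diagnostic_testing", "percent"],
        pct_deferred_postnatal = sm["deferred_postnatal", "percent"],
        pct_cardiac_of_ultrasound = sm["cardiac_of_ultrasound", "percent"],
        pct_fetal_inheritance = sm["fetal_inheritance", "percent"])
    ref <- fixtureReferenceValues()
    data.frame(metric = names(ref), computed = unname(computed[names(ref)]),
               reference = unname(ref),
               pass = unname(computed[names(ref)] == ref))
}
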