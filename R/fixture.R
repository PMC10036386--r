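#' Deterministic 307-case screen-positive cohort fixture
#'
#' Reconstructs, case by case, the dispositions of a published
#' screen-positive 22q11.2 NIPS cohort of 307 pregnancies: 177 suspected
#' maternal and 130 suspected fetal events; 194 cases with a diagnostic
#' result (83 fetal-only, 76 maternal-only, 35 both), of which 17 were
#' incomplete, leaving 177 complete (176 true positives, 1 false positive);
#' 157 cases with ultrasound findings (95 cardiac); 118 with fetal or
#' neonatal testing, 54 of them deferred to the postnatal period; and, of
#' the 43 suspected-maternal cases with fetal testing, 25 with fetal
#' inheritance confirmed. Individual-level covariate joints beyond these
#' published marginals are an arbitrary deterministic allocation; cases
#' without complete testing carry confirmation status `"unknown"` and are
#' never imputed.
#'
#' Classification rules: a case is a true positive when the deletion was
#' confirmed by FISH and/or microarray in the individual the screen
#' implicated (for suspected maternal events, a positive fetal result also
#' confirms the deletion); testing of the wrong individual with a normal
#' result, or karyotype-only testing, is "incomplete" and cannot rule the
#' deletion out.
#'
#' @return A `DataFrame` of 307 rows with columns `caseId`,
#'   `suspectedOrigin` (maternal/fetal), `testing`
#'   (fetal_only/maternal_only/both/none), `completeness`
#'   (complete/incomplete/none), `confirmed`
#'   (true_positive/false_positive/unknown), and logical `ultrasound`,
#'   `cardiac`, `deferredPostnatal`, `fetalInherited` (NA where
#'   undefined).
#' @examples
#' fx <- cohortFixture()
#' table(fx$suspectedOrigin)
#' @export
cohortFixture <- function() {
    block <- function(n, suspectedOrigin, testing, completeness, confirmed,
                      nUltrasound, nCardiac, nDeferred, inherited = NULL) {
        stopifnot(nUltrasound <= n, nCardiac <= nUltrasound)
        data.frame(
            suspectedOrigin = rep(suspectedOrigin, n),
            testing = rep(testing, n),
            completeness = rep(completeness, n),
            confirmed = rep(confirmed, n),
            ultrasound = rep(c(TRUE, FALSE), c(nUltrasound, n - nUltrasound)),
            cardiac = rep(c(TRUE, FALSE),
                          c(nCardiac, n - nCardiac)),
            deferredPostnatal = rep(c(TRUE, FALSE), c(nDeferred, n - nDeferred)),
            fetalInherited = if (is.null(inherited)) rep(NA, n)
                             else rep(c(TRUE, FALSE),
                                      c(inherited, n - inherited)))
    }
    fx <- rbind(
        # suspected maternal, both tested: maternal deletion confirmed in
        # all 31; fetal inheritance in 20 of 31
        block(31, "maternal", "both", "complete", "true_positive",
              nUltrasound = 20, nCardiac = 12, nDeferred = 14,
              inherited = 20),
        # suspected maternal, fetal-only testing, fetus positive:
        # deletion confirmed via the fetus
        block(5, "maternal", "fetal_only", "complete", "true_positive",
              nUltrasound = 4, nCardiac = 3, nDeferred = 2, inherited = 5),
        # suspected maternal, fetal-only testing, fetus negative: a
        # non-transmitted maternal deletion cannot be excluded
        block(7, "maternal", "fetal_only", "incomplete", "unknown",
              nUltrasound = 4, nCardiac = 2, nDeferred = 3, inherited = 0),
        # suspected maternal, maternal testing complete
        block(66, "maternal", "maternal_only", "complete", "true_positive",
              nUltrasound = 20, nCardiac = 12, nDeferred = 0),
        # suspected maternal, maternal testing inadequate (e.g. karyotype)
        block(8, "maternal", "maternal_only", "incomplete", "unknown",
              nUltrasound = 3, nCardiac = 2, nDeferred = 0),
        block(60, "maternal", "none", "none", "unknown",
              nUltrasound = 30, nCardiac = 18, nDeferred = 0),
        # suspected fetal, fetal-only testing
        block(70, "fetal", "fetal_only", "complete", "true_positive",
              nUltrasound = 45, nCardiac = 27, nDeferred = 33),
        # the cohort's single false positive (normal amniocentesis FISH
        # and microarray, no maternal testing)
        block(1, "fetal", "fetal_only", "complete", "false_positive",
              nUltrasound = 0, nCardiac = 0, nDeferred = 0),
        block(4, "fetal", "both", "complete", "true_positive",
              nUltrasound = 3, nCardiac = 2, nDeferred = 2),
        # suspected fetal with maternal-only testing: wrong individual,
        # incomplete
        block(2, "fetal", "maternal_only", "incomplete", "unknown",
              nUltrasound = 1, nCardiac = 1, nDeferred = 0),
        block(53, "fetal", "none", "none", "unknown",
              nUltrasound = 27, nCardiac = 16, nDeferred = 0))
    fx <- DataFrame(caseId = sprintf("case%03d", seq_len(nrow(fx))), fx)
    rownames(fx) <- fx$caseId

    # internal consistency against the published marginals
    stopifnot(
        nrow(fx) == 307L,
        sum(fx$suspectedOrigin == "maternal") == 177L,
        sum(fx$testing != "none") == 194L,
        sum(fx$testing == "fetal_only") == 83L,
        sum(fx$testing == "maternal_only") == 76L,
        sum(fx$testing == "both") == 35L,
        sum(fx$completeness == "complete") == 177L,
        sum(fx$completeness == "incomplete") == 17L,
        sum(fx$completeness == "complete" &
            fx$suspectedOrigin == "maternal") == 102L,
        sum(fx$confirmed == "true_positive") == 176L,
        sum(fx$confirmed == "false_positive") == 1L,
        sum(fx$ultrasound) == 157L,
        sum(fx$cardiac) == 95L,
        sum(fx$testing %in% c("fetal_only", "both")) == 118L,
        sum(fx$deferredPostnatal) == 54L,
        sum(!is.na(fx$fetalInherited)) == 43L,
        sum(fx$fetalInherited, na.rm = TRUE) == 25L,
        # 177 complete + 17 incomplete + 113 untested = 307
        177L + 17L + sum(fx$testing == "none") == 307L,
        83L + 76L + 35L == 194L)
    fx
}
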