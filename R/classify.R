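## Rule-based sagittal gait-pattern classification (the classic Types I-IV
## of spastic diplegia) plus deviation flags for mild patterns.
##
## The source classification is an expert reading of sagittal curves;
## the numeric cutoffs here (heel-up toe-walking threshold, the 1-SD
## normative band, the midstance evaluation window) are configuration
## values with documented defaults, and every comparison is recorded in an
## auditable rule trace.

#' Classifier configuration
#'
#' @param toeWalkThreshold heel-up foot orientation (deg) above which the
#'   10-30% average indicates toe-walking.
#' @param bandK band half-width in SD units.
#' @param midstanceWindow percent range of the cycle over which stance
#'   posture is judged.
#' @param coupleAnkleBound upper bound (deg) on midstance ankle
#'   dorsiflexion for the plantarflexion-knee-extension couple flag.
#' @param heelDownThreshold orientation (deg) below which the foot counts
#'   as heel-down during the first rocker.
#' @param terminalSwingWindow percent range for terminal-swing knee
#'   extension.
#' @return A named list of thresholds.
#' @export
classifierConfig <- function(toeWalkThreshold = 10, bandK = 1,
                             midstanceWindow = c(10, 40),
                             coupleAnkleBound = 5,
                             heelDownThreshold = -2,
                             terminalSwingWindow = c(90, 100)) {
    list(toeWalkThreshold = toeWalkThreshold, bandK = bandK,
         midstanceWindow = midstanceWindow,
         coupleAnkleBound = coupleAnkleBound,
         heelDownThreshold = heelDownThreshold,
         terminalSwingWindow = terminalSwingWindow)
}

## mean of a curve over a percent window (inclusive samples)
.windowMean <- function(curve, win) {
    mean(curve[(win[1]:win[2]) + 1L])
}

## subject's mean normalized curve for one side
.sideMeanCurve <- function(kin, side) {
    cv <- kin@cycles[[side]]$curves
    if (dim(cv)[1] == 0) stop("no complete cycle for side ", side)
    apply(cv, c(2, 3), mean)
}

#' Classify the sagittal gait pattern of one side
#'
#' Ordered rule evaluation against a normative band: (1) toe-walking if the
#' 10-30% foot orientation average exceeds the heel-up threshold or the
#' first rocker is absent; (2) ankle regime in stance: plantarflexion
#' throughout (stance maximum below zero), normal, or excessive
#' dorsiflexion (midstance average above the band); (3) knee and hip
#' posture in midstance: extended (within or below the band) versus
#' increased flexion (above the band). The combination maps to: type I
#' (true equinus: toe-walking, plantarflexion throughout, knee and hip
#' extended), II (jump: as I but with flexed knee and hip), III (apparent
#' equinus: toe-walking with normal ankle range and increased knee and hip
#' flexion), IV (crouch: excessive dorsiflexion with increased knee and
#' hip flexion). Anything else is `unclassified_mild`.
#'
#' @param feat one side's row of [extractGaitFeatures()] (data.frame row or
#'   named vector).
#' @param kin the [JointKinematics-class] of the trial (normalized).
#' @param band a [NormativeBand-class].
#' @param side `"left"` or `"right"`.
#' @param config a [classifierConfig()].
#' @return A [RoddaResult-class].
#' @export
classifyRodda <- function(feat, kin, band, side = "right",
                          config = classifierConfig()) {
    stopifnot(is(band, "NormativeBand"))
    feat <- unlist(feat)
    subj <- .sideMeanCurve(kin, side)
    hi <- band@mean + config$bandK * band@sd
    w <- config$midstanceWindow
    trace <- NULL
    note <- function(criterion, observed, threshold, verdict) {
        trace <<- rbind(trace, data.frame(
            criterion = criterion, observed = round(observed, 2),
            threshold = round(threshold, 2), verdict = verdict))
        verdict
    }
    flags <- deviationFlags(feat, kin, band, side, config)
    footAvg <- feat[["foot_orientation_avg_10_30"]]
    toeWalkOrient <- note("toe_walking_foot_orientation", footAvg,
                          config$toeWalkThreshold,
                          footAvg > config$toeWalkThreshold)
    absentRocker <- note("absent_first_rocker",
                         min(subj[1:11, "foot"]),
                         config$heelDownThreshold,
                         "absent_first_rocker" %in% flags)
    toeWalking <- toeWalkOrient || absentRocker
    ankleStanceMax <- feat[["ankle_max_dorsiflexion_stance"]]
    plantarThroughout <- note("ankle_plantarflexion_throughout_stance",
                              ankleStanceMax, 0, ankleStanceMax < 0)
    ankleMid <- .windowMean(subj[, "ankle"], w)
    ankleBandHi <- .windowMean(hi[, "ankle"], w)
    excessiveDorsi <- note("ankle_excessive_dorsiflexion_midstance",
                           ankleMid, ankleBandHi, ankleMid > ankleBandHi)
    kneeMid <- .windowMean(subj[, "knee"], w)
    kneeBandHi <- .windowMean(hi[, "knee"], w)
    kneeFlexed <- note("knee_increased_flexion_midstance", kneeMid,
                       kneeBandHi, kneeMid > kneeBandHi)
    hipMid <- .windowMean(subj[, "hip"], w)
    hipBandHi <- .windowMean(hi[, "hip"], w)
    hipFlexed <- note("hip_increased_flexion_midstance", hipMid,
                      hipBandHi, hipMid > hipBandHi)
    type <- if (toeWalking && plantarThroughout && !kneeFlexed)
        "I_true_equinus"
    else if (toeWalking && plantarThroughout && kneeFlexed)
        "II_jump"
    else if (toeWalking && !plantarThroughout && !excessiveDorsi &&
             kneeFlexed && hipFlexed)
        "III_apparent_equinus"
    else if (excessiveDorsi && kneeFlexed && hipFlexed)
        "IV_crouch"
    else "unclassified_mild"
    new("RoddaResult", side = side, type = type, ruleTrace = trace,
        deviationFlags = flags)
}

#' Deviation flags for mild gait patterns
#'
#' Flags raised relative to the normative band: increased knee flexion at
#' initial contact (0% sample above band mean + 1 SD); decreased terminal
#' swing extension (90-100% knee minimum above the band); knee
#' hyperextension in stance (peak stance extension below 0); absent first
#' rocker (the foot orientation never passes through a heel-down phase in
#' 0-10%); and the plantarflexion-knee-extension couple (stance knee
#' hyperextension combined with limited midstance ankle dorsiflexion).
#'
#' @inheritParams classifyRodda
#' @return Character vector (possibly empty) of flag names.
#' @export
deviationFlags <- function(feat, kin, band, side = "right",
                           config = classifierConfig()) {
    feat <- unlist(feat)
    subj <- .sideMeanCurve(kin, side)
    hi <- band@mean + config$bandK * band@sd
    flags <- character(0)
    if (feat[["knee_at_ic"]] > hi[1, "knee"])
        flags <- c(flags, "increased_knee_flexion_at_ic")
    tw <- config$terminalSwingWindow
    idx <- (tw[1]:tw[2]) + 1L
    if (min(subj[idx, "knee"]) > min(hi[idx, "knee"]))
        flags <- c(flags, "decreased_terminal_swing_extension")
    hyper <- feat[["knee_peak_extension_in_stance"]] < 0
    if (hyper) flags <- c(flags, "knee_hyperextension_in_stance")
    if (min(subj[1:11, "foot"]) > config$heelDownThreshold)
        flags <- c(flags, "absent_first_rocker")
    if (hyper && feat[["ankle_max_dorsiflexion_midstance"]] <=
        config$coupleAnkleBound)
        flags <- c(flags, "plantarflexion_knee_extension_couple")
    flags
}

#' Participant-level label from both sides
#'
#' The participant label is the more affected side's type (severity order
#' crouch > apparent equinus > jump > true equinus > unclassified mild);
#' both side results are kept alongside.
#'
#' @param results list of [RoddaResult-class], one per side.
#' @return List with `label` and the per-side `results`.
#' @export
classifyParticipant <- function(results) {
    sev <- c(unclassified_mild = 0, I_true_equinus = 1, II_jump = 2,
             III_apparent_equinus = 3, IV_crouch = 4)
    types <- vapply(results, function(r) r@type, "")
    list(label = unname(types[which.max(sev[types])]), results = results)
}

setMethod("show", "RoddaResult", function(object) {
    cat(sprintf("RoddaResult (%s): %s\n", object@side, object@type))
    if (length(object@deviationFlags))
        cat("  flags:", paste(object@deviationFlags, collapse = ", "), "\n")
    cat(sprintf("  rule trace: %d comparisons\n", nrow(object@ruleTrace)))
})
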