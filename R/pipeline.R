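## End-to-end analysis orchestration and structured trial rejection.

#' Analyze a tracked or simulated trial
#'
#' Runs the analysis stages downstream of tracking: joint kinematics, gait
#' events, cycle normalization and spatio-temporal parameters. The input
#' may be a [TrackedLandmarks-class] (from [trackSequence()]) or a
#' [WalkerTrajectory-class], which is passed through
#' [asTrackedLandmarks()] first (applying the same gap filling, smoothing
#' and quality gate as video tracking).
#'
#' @param x a [TrackedLandmarks-class] or [WalkerTrajectory-class].
#' @param vThresh,dwell event-detection parameters (m/s, frames).
#' @param smoothCutoffHz smoothing cutoff used when `x` is a trajectory.
#' @param foregroundSide camera-near side for step-length pairing.
#' @return List of class `GaitAnalysis`: `tracked`, `kinematics`, `events`,
#'   `spatioTemporal`.
#' @examples
#' res <- analyzeTrial(simulateTrial("normal", seed = 5))
#' res$spatioTemporal$gaitSpeed
#' @export
analyzeTrial <- function(x, vThresh = 0.05, dwell = 3L,
                         smoothCutoffHz = 6, foregroundSide = "right") {
    tracked <- if (is(x, "WalkerTrajectory"))
        asTrackedLandmarks(x, smoothCutoffHz = smoothCutoffHz)
    else x
    kin <- computeJointKinematics(tracked)
    ev <- detectGaitEvents(tracked, vThresh = vThresh, dwell = dwell)
    kin <- normalizeCycles(kin, ev, missing = tracked@missing)
    st <- spatioTemporal(tracked, ev, foregroundSide)
    structure(list(tracked = tracked, kinematics = kin, events = ev,
                   spatioTemporal = st),
              class = "GaitAnalysis")
}

#' Run a pipeline step, converting trial rejections into a status record
#'
#' Evaluates an expression that may signal a `gaitTrialRejection`
#' condition; rejections are caught and returned as a structured record,
#' never as an unhandled error.
#'
#' @param expr expression to evaluate.
#' @return On success `list(status = "processed", value = <result>)`; on
#'   rejection `list(status = "rejected", reasonCode = <code>,
#'   message = <text>)`.
#' @examples
#' bad <- simulateTrial(gaitPattern("normal", dropout = 0.3, seed = 1))
#' withTrialRejection(analyzeTrial(bad))$status
#' @export
withTrialRejection <- function(expr) {
    tryCatch(
        list(status = "processed", value = expr),
        gaitTrialRejection = function(cond) {
            message("trial rejected [", cond$reasonCode, "]: ",
                    conditionMessage(cond))
            list(status = "rejected", reasonCode = cond$reasonCode,
                 message = conditionMessage(cond))
        })
}

#' Classify a trial end to end
#'
#' Extracts features and classifies both sides of an analyzed trial.
#'
#' @param analysis a `GaitAnalysis` from [analyzeTrial()].
#' @param band a [NormativeBand-class].
#' @param config a [classifierConfig()].
#' @return List with `features` (data.frame), per-side `results`
#'   ([RoddaResult-class]) and the participant-level `label`.
#' @export
classifyTrial <- function(analysis, band, config = classifierConfig()) {
    feat <- extractGaitFeatures(analysis$kinematics,
                                analysis$spatioTemporal)
    results <- lapply(.SIDES, function(side)
        classifyRodda(feat[side, ], analysis$kinematics, band, side,
                      config))
    names(results) <- .SIDES
    c(list(features = feat), classifyParticipant(results))
}
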