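## Kinematic feature set per side, computed per cycle on the normalized
## curves and averaged across the cycles of a side.
##
## The knee "peak extension in stance" is the minimum knee flexion between
## the loading-response peak and toe-off: clinical tables print negative
## values here for hyperextending knees, which a maximum-flexion reading
## could not produce. The midstance ankle maximum (10-40% window) is kept
## separately from the whole-stance maximum: in a walker without double
## support the pre-swing roll-over dorsiflexion dominates the whole-stance
## maximum, while sagittal ankle posture under load lives in midstance.

.FEATURE_NAMES <- c("hip_max_extension", "hip_rom", "knee_at_ic",
                    "knee_loading_response", "knee_peak_extension_in_stance",
                    "knee_max_in_swing", "knee_rom",
                    "ankle_max_dorsiflexion_stance",
                    "ankle_max_dorsiflexion_swing",
                    "ankle_max_dorsiflexion_midstance",
                    "foot_orientation_avg_10_30")

.cycleFeatures <- function(curve, toPct) {
    hip <- curve[, "hip"]; knee <- curve[, "knee"]
    ankle <- curve[, "ankle"]; foot <- curve[, "foot"]
    toIdx <- max(2L, min(100L, round(toPct) + 1L))
    lrIdx <- which.max(knee[1:16])
    c(hip_max_extension = min(hip),
      hip_rom = max(hip) - min(hip),
      knee_at_ic = knee[1],
      knee_loading_response = max(knee[1:16]),
      knee_peak_extension_in_stance = min(knee[lrIdx:toIdx]),
      knee_max_in_swing = max(knee[toIdx:101]),
      knee_rom = max(knee) - min(knee),
      ankle_max_dorsiflexion_stance = max(ankle[1:toIdx]),
      ankle_max_dorsiflexion_swing = max(ankle[toIdx:101]),
      ankle_max_dorsiflexion_midstance = max(ankle[11:41]),
      foot_orientation_avg_10_30 = mean(foot[11:31]))
}

#' Extract the per-side kinematic feature set
#'
#' Computes, per gait cycle and then averaged across the cycles of each
#' side: maximum hip extension (signed; negative = beyond neutral) and hip
#' ROM; knee flexion at initial contact (0%), loading-response peak (max in
#' 0-15%), peak extension in stance (minimum between the loading-response
#' peak and toe-off; negative = hyperextension), maximum in swing, and ROM;
#' maximum ankle dorsiflexion in stance and in swing (plus the midstance
#' 10-40% maximum); and the foot orientation averaged over 10-30% of the
#' cycle. Gait speed and mean step length are appended when a
#' spatio-temporal summary is supplied.
#'
#' @param kin a [JointKinematics-class] with normalized cycles
#'   (see [normalizeCycles()]).
#' @param st optional result of [spatioTemporal()].
#' @return data.frame with one row per side (rownames `left`, `right`),
#'   features in degrees, plus `nCycles`, and `gaitSpeed`/`stepLength` if
#'   `st` is given.
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' kin <- computeJointKinematics(traj)
#' ev <- detectGaitEvents(traj)
#' kin <- normalizeCycles(kin, ev)
#' extractGaitFeatures(kin)
#' @export
extractGaitFeatures <- function(kin, st = NULL) {
    if (!length(kin@cycles)) stop("run normalizeCycles() first")
    rows <- lapply(.SIDES, function(side) {
        cyc <- kin@cycles[[side]]
        nc <- dim(cyc$curves)[1]
        if (nc == 0)
            stop("no complete normalized cycle for side ", side)
        feats <- vapply(seq_len(nc), function(k)
            .cycleFeatures(cyc$curves[k, , ], cyc$toeoffPct[k]),
            numeric(length(.FEATURE_NAMES)))
        out <- rowMeans(feats)
        c(out, nCycles = nc)
    })
    out <- as.data.frame(do.call(rbind, rows))
    rownames(out) <- .SIDES
    if (!is.null(st)) {
        out$gaitSpeed <- st$gaitSpeed
        out$stepLength <- st$meanStepLength
    }
    out
}

#' Build a normative kinematic band from an ensemble of normal trials
#'
#' Each trial contributes its mean normalized curve (averaged over its
#' cycles and sides); the band is the pointwise mean and sample SD over
#' trials, with a half-width of 1 SD by default when used by the
#' classifier.
#'
#' @param kinList list of at least 5 [JointKinematics-class] objects with
#'   normalized cycles.
#' @return A [NormativeBand-class].
#' @export
buildNormativeBand <- function(kinList) {
    if (length(kinList) < 5)
        stop("need at least 5 trials to build a normative band")
    curves <- lapply(kinList, function(kin) {
        stopifnot(is(kin, "JointKinematics"))
        if (!length(kin@cycles)) stop("run normalizeCycles() first")
        acc <- NULL
        for (side in .SIDES) {
            cv <- kin@cycles[[side]]$curves
            if (dim(cv)[1]) acc <- abind2(acc, cv)
        }
        if (is.null(acc)) stop("trial without complete cycles")
        apply(acc, c(2, 3), mean)
    })
    arr <- array(unlist(curves), dim = c(101, 4, length(curves)))
    m <- apply(arr, c(1, 2), mean)
    s <- apply(arr, c(1, 2), stats::sd)
    colnames(m) <- colnames(s) <- .ANGLES
    new("NormativeBand", mean = m, sd = s, n = length(curves))
}

## bind cycle arrays [cycle, 101, 4] along the first dimension
abind2 <- function(a, b) {
    if (is.null(a)) return(b)
    out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], 101, 4))
    out[seq_len(dim(a)[1]), , ] <- a
    out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    dimnames(out) <- list(NULL, NULL, .ANGLES)
    out
}

#' Normative band from simulated normal walkers
#'
#' Convenience constructor for the classifier's default reference: a batch
#' of normal-pattern trials with the default landmark noise, analyzed at
#' trajectory level (no rendering), under fixed seeds.
#'
#' @param nTrials number of trials (>= 5).
#' @param seed base seed; trial k uses `seed + k`.
#' @param noiseSd landmark noise SD in m.
#' @return A [NormativeBand-class].
#' @examples
#' band <- defaultNormativeBand(nTrials = 5)
#' @export
defaultNormativeBand <- function(nTrials = 8L, seed = 100L,
                                 noiseSd = 0.005) {
    kins <- lapply(seq_len(nTrials), function(k) {
        pat <- gaitPattern("normal", noiseSd = noiseSd, seed = seed + k)
        traj <- simulateTrial(pat, nCycles = 3L)
        tl <- asTrackedLandmarks(traj)
        kin <- computeJointKinematics(tl)
        ev <- detectGaitEvents(tl)
        suppressMessages(normalizeCycles(kin, ev, missing = tl@missing))
    })
    buildNormativeBand(kins)
}

#' @describeIn buildNormativeBand Accessors for the band mean and SD
#'   matrices (101 x 4).
#' @param band a `NormativeBand`.
#' @param what `"mean"` or `"sd"`.
#' @export
bandCurves <- function(band, what = c("mean", "sd")) {
    what <- match.arg(what)
    slot(band, what)
}

setMethod("show", "NormativeBand", function(object) {
    cat(sprintf(
        "NormativeBand from %d trials | median SD: hip %.2f, knee %.2f, ankle %.2f deg\n",
        object@n, stats::median(object@sd[, "hip"]),
        stats::median(object@sd[, "knee"]),
        stats::median(object@sd[, "ankle"])))
})
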