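## Sagittal joint angles from 2D landmark positions.
##
## The hip is approximated by the femur inclination: because raw inclination
## from the horizontal would put typical values near 90 degrees while
## clinical hip curves span roughly -25..+40, the angle is reported as the
## deviation of the femur from the downward vertical (i.e. 90 degrees minus
## the horizontal inclination), positive in flexion. Note the reference is
## the room, not the pelvis; curves carry a known offset against
## pelvis-referenced hip kinematics.

.angleFromVertical <- function(v) {
    ## angle of a (downward-pointing) segment vector from the downward
    ## vertical, positive toward +x (forward), degrees
    atan2(v[, 1], -v[, 2]) / .deg2rad
}

.asPointMatrix <- function(p) {
    if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
}

.checkDistinct <- function(a, b, what) {
    d <- rowSums((a - b)^2)
    if (any(d < 1e-20, na.rm = TRUE))
        stop(sprintf("degenerate input: %s are coincident", what))
}

#' Hip flexion from trochanter and epicondyle
#'
#' Angle of the femur vector (trochanter to epicondyle) from the downward
#' vertical, positive when the epicondyle is forward of the trochanter
#' (flexion). A vertical femur reads 0 degrees.
#'
#' @param trochanter,epicondyle 2-column matrices (or length-2 vectors) of
#'   (x forward, y up) positions in m.
#' @return Hip flexion in degrees.
#' @examples
#' hipFlexionAngle(c(0, 1), c(0.2, 0.6))  # +26.57
#' @export
hipFlexionAngle <- function(trochanter, epicondyle) {
    trochanter <- .asPointMatrix(trochanter)
    epicondyle <- .asPointMatrix(epicondyle)
    .checkDistinct(trochanter, epicondyle, "trochanter and epicondyle")
    .angleFromVertical(epicondyle - trochanter)
}

#' Knee flexion from trochanter, epicondyle and malleolus
#'
#' Signed angle between the femur vector and the tibia vector (epicondyle to
#' malleolus): 0 when collinear (full extension), positive in flexion,
#' negative in hyperextension.
#'
#' @param trochanter,epicondyle,malleolus positions as in
#'   [hipFlexionAngle()].
#' @return Knee flexion in degrees.
#' @examples
#' kneeFlexionAngle(c(0, 1), c(0, 0.6), c(-0.15, 0.25))  # +23.20
#' @export
kneeFlexionAngle <- function(trochanter, epicondyle, malleolus) {
    trochanter <- .asPointMatrix(trochanter)
    epicondyle <- .asPointMatrix(epicondyle)
    malleolus <- .asPointMatrix(malleolus)
    .checkDistinct(trochanter, epicondyle, "femur endpoints")
    .checkDistinct(epicondyle, malleolus, "tibia endpoints")
    .wrapDeg(.angleFromVertical(epicondyle - trochanter) -
             .angleFromVertical(malleolus - epicondyle))
}

#' Ankle dorsiflexion from tibia and foot landmarks
#'
#' Signed angle between the foot axis (heel to toe) and the perpendicular to
#' the tibia: 0 when the foot is perpendicular to the tibia, dorsiflexion
#' positive, plantarflexion negative.
#'
#' @param epicondyle,malleolus,heel,toe positions as in [hipFlexionAngle()].
#' @return Ankle dorsiflexion in degrees.
#' @examples
#' ankleDorsiflexionAngle(c(0, 0.6), c(0, 0.2), c(-0.05, 0), c(0.15, 0))  # 0
#' @export
ankleDorsiflexionAngle <- function(epicondyle, malleolus, heel, toe) {
    epicondyle <- .asPointMatrix(epicondyle)
    malleolus <- .asPointMatrix(malleolus)
    heel <- .asPointMatrix(heel)
    toe <- .asPointMatrix(toe)
    .checkDistinct(epicondyle, malleolus, "tibia endpoints")
    .checkDistinct(heel, toe, "heel and toe")
    f <- toe - heel
    phi <- atan2(f[, 2], f[, 1]) / .deg2rad
    .wrapDeg(phi - .angleFromVertical(malleolus - epicondyle))
}

#' Foot orientation relative to the room
#'
#' Angle of the heel-to-toe line from the horizontal, positive when the heel
#' is higher than the toe (heel up).
#'
#' @param heel,toe positions as in [hipFlexionAngle()].
#' @return Foot orientation in degrees (heel-up positive).
#' @examples
#' footOrientationAngle(c(0, 0.10), c(0.15, 0.05))  # +18.43
#' @export
footOrientationAngle <- function(heel, toe) {
    heel <- .asPointMatrix(heel)
    toe <- .asPointMatrix(toe)
    .checkDistinct(heel, toe, "heel and toe")
    f <- toe - heel
    -atan2(f[, 2], f[, 1]) / .deg2rad
}

## positions from either container as [frame, landmark, coord, side]
.positionArray <- function(x) {
    if (is(x, "WalkerTrajectory")) x@positions
    else if (is(x, "TrackedLandmarks")) x@positionsM
    else stop("expected a WalkerTrajectory or TrackedLandmarks")
}

.missingArray <- function(x) {
    if (is(x, "WalkerTrajectory")) x@missing
    else if (is(x, "TrackedLandmarks")) x@missing
    else stop("expected a WalkerTrajectory or TrackedLandmarks")
}

.timestampsOf <- function(x) x@timestamps

#' Compute sagittal joint-angle time series
#'
#' Applies the four angle operations frame-by-frame to tracked or simulated
#' landmark positions, per side.
#'
#' @param x a [TrackedLandmarks-class] or [WalkerTrajectory-class].
#' @return A [JointKinematics-class] with raw angle series; cycle-normalized
#'   curves are added by [normalizeCycles()].
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' kin <- computeJointKinematics(traj)
#' head(kinematicAngles(kin, "right"))
#' @export
computeJointKinematics <- function(x) {
    pos <- .positionArray(x)
    angles <- lapply(.SIDES, function(side) {
        p <- pos[, , , side, drop = FALSE]
        dim(p) <- dim(p)[1:3]
        dimnames(p) <- dimnames(pos)[1:3]
        troch <- p[, "trochanter", , drop = FALSE]; dim(troch) <- c(dim(p)[1], 2)
        epi <- p[, "epicondyle", , drop = FALSE]; dim(epi) <- c(dim(p)[1], 2)
        mall <- p[, "malleolus", , drop = FALSE]; dim(mall) <- c(dim(p)[1], 2)
        heel <- p[, "heel", , drop = FALSE]; dim(heel) <- c(dim(p)[1], 2)
        toe <- p[, "toe", , drop = FALSE]; dim(toe) <- c(dim(p)[1], 2)
        femur <- epi - troch
        tibia <- mall - epi
        foot <- toe - heel
        hip <- atan2(femur[, 1], -femur[, 2]) / .deg2rad
        thetaT <- atan2(tibia[, 1], -tibia[, 2]) / .deg2rad
        phi <- atan2(foot[, 2], foot[, 1]) / .deg2rad
        cbind(hip = hip, knee = .wrapDeg(hip - thetaT),
              ankle = .wrapDeg(phi - thetaT), foot = -phi)
    })
    names(angles) <- .SIDES
    new("JointKinematics", timestamps = .timestampsOf(x), angles = angles,
        cycles = list(), fps = .FPS)
}

#' @describeIn computeJointKinematics Accessor for the raw angle matrix of
#'   one side (columns hip, knee, ankle, foot; degrees).
#' @param kin a `JointKinematics` object.
#' @param side `"left"` or `"right"`.
#' @export
kinematicAngles <- function(kin, side = c("right", "left")) {
    side <- match.arg(side)
    kin@angles[[side]]
}

#' @describeIn computeJointKinematics Accessor for the normalized cycles of
#'   one side: list with `curves` (`[cycle, 101, 4]`), `toeoffPct`, `ic`.
#' @export
normalizedCycles <- function(kin, side = c("right", "left")) {
    side <- match.arg(side)
    if (!length(kin@cycles)) stop("run normalizeCycles() first")
    kin@cycles[[side]]
}

#' Time-normalize angle curves to the gait cycle
#'
#' Resamples each complete cycle (initial contact to next same-side initial
#' contact, half-open) onto 101 points (0-100% in 1% steps) by linear
#' interpolation, and expresses toe-off as a percentage of the cycle.
#' Cycles containing missing-flagged frames are excluded with a message.
#'
#' @param kin a [JointKinematics-class].
#' @param events a [GaitEvents-class] for the same trial.
#' @param missing optional logical array `[frame, landmark, side]` of
#'   missing flags (taken from the tracked object the kinematics were
#'   computed from).
#' @return `kin` with the `cycles` slot filled.
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' kin <- computeJointKinematics(traj)
#' ev <- detectGaitEvents(traj)
#' kin <- normalizeCycles(kin, ev)
#' dim(normalizedCycles(kin, "right")$curves)
#' @export
normalizeCycles <- function(kin, events, missing = NULL) {
    stopifnot(is(kin, "JointKinematics"), is(events, "GaitEvents"))
    if (nrow(events@cycles) == 0)
        stop("no complete gait cycle (need an IC, a toe-off and the next IC)")
    n <- length(kin@timestamps)
    cyc <- lapply(.SIDES, function(side) {
        rows <- events@cycles[events@cycles$side == side, , drop = FALSE]
        curves <- array(NA_real_, dim = c(0, 101, 4))
        toeoff <- numeric(0)
        ics <- integer(0)
        excluded <- 0L
        for (r in seq_len(nrow(rows))) {
            ic <- rows$ic[r]; nic <- rows$nextIc[r]; to <- rows$to[r]
            if (nic > n) next
            if (!is.null(missing) &&
                any(missing[ic:(nic - 1L), , side])) {
                excluded <- excluded + 1L
                next
            }
            ang <- kin@angles[[side]]
            if (anyNA(ang[ic:nic, ])) { excluded <- excluded + 1L; next }
            xout <- ic + (0:100) / 100 * (nic - ic)
            res <- vapply(1:4, function(j)
                stats::approx(ic:nic, ang[ic:nic, j], xout = xout)$y,
                numeric(101))
            curves <- array(c(aperm(curves, c(2, 3, 1)), res),
                            dim = c(101, 4, dim(curves)[1] + 1L))
            curves <- aperm(curves, c(3, 1, 2))
            toeoff <- c(toeoff, (to - ic) / (nic - ic) * 100)
            ics <- c(ics, ic)
        }
        if (excluded > 0)
            message(sprintf("%s: excluded %d cycle(s) with missing frames",
                            side, excluded))
        dimnames(curves) <- list(NULL, NULL, .ANGLES)
        list(curves = curves, toeoffPct = toeoff, ic = ics,
             excluded = excluded)
    })
    names(cyc) <- .SIDES
    kin@cycles <- cyc
    kin
}

setMethod("show", "JointKinematics", function(object) {
    n <- length(object@timestamps)
    nc <- if (length(object@cycles))
        vapply(object@cycles, function(s) dim(s$curves)[1], 0L)
    else c(left = NA_integer_, right = NA_integer_)
    cat(sprintf(
        "JointKinematics: %d frames | normalized cycles: left %s, right %s\n",
        n, nc[["left"]], nc[["right"]]))
})
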