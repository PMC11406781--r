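## Gait-curve templates and per-pattern offsets.
##
## The normal template is built from editable keyframes: hip and knee are
## periodic splines; the ankle is derived during stance from a foot-rollover
## (orientation) target -- heel-down contact over 0-10% (first rocker), foot
## flat 10-40% (second rocker), heel rise 40% to toe-off (third rocker) --
## and from a near-neutral ankle target during swing. Patterns are additive
## offset curves on top of the normal template.

.HIP_KEYS <- cbind(p = c(0, 12, 30, 50, 57, 70, 82, 92, 100),
                   v = c(25, 19, 1, -14, -15, 2, 23, 27, 25))
.KNEE_KEYS <- cbind(p = c(0, 7, 14, 28, 40, 48, 55, 62, 73, 84, 93, 100),
                    v = c(5, 13, 17, 8, 4, 10, 22, 40, 62, 35, 10, 5))
## stance foot-orientation target (heel-up positive), 0-60% only
.ORIENT_STANCE_KEYS <- cbind(p = c(0, 4, 10, 15, 25, 35, 40, 45, 50, 55, 60),
                             v = c(-20, -13, 0, 0, 0, 0, 0, 3, 12, 30, 52))
## swing ankle target, 62-100%
.ANKLE_SWING_KEYS <- cbind(p = c(65, 72, 80, 90, 96),
                           v = c(-8, 0, 2, 0, -4))

## per-pattern defaults: cycle length in frames (even), step-length target (m)
## and offset keyframes per joint (deg). Conditions are desk-scale analogs of
## a slow, short-stepping school-age cohort (cohort means: speed 0.69 m/s,
## step 0.37 m).
.PATTERN_DEFAULTS <- list(
    normal = list(cf = 32L, step = 0.42, hip = NULL, knee = NULL,
                  ankle = NULL),
    true_equinus = list(
        cf = 30L, step = 0.33,
        hip = cbind(p = c(0, 50, 100), v = c(-2, -2, -2)),
        knee = cbind(p = c(0, 50, 100), v = c(-2, -2, -2)),
        ankle = cbind(p = c(0, 20, 45, 60, 75, 90, 100),
                      v = c(-30, -22, -20, -24, -16, -22, -30))),
    jump = list(
        cf = 34L, step = 0.32,
        hip = cbind(p = c(0, 40, 70, 100), v = c(12, 12, 10, 12)),
        knee = cbind(p = c(0, 30, 50, 60, 80, 100),
                     v = c(12, 15, 12, 8, 4, 12)),
        ankle = cbind(p = c(0, 25, 45, 60, 80, 100),
                      v = c(-28, -18, -16, -18, -12, -28))),
    apparent_equinus = list(
        cf = 34L, step = 0.30,
        hip = cbind(p = c(0, 50, 100), v = c(3, 5, 3)),
        knee = cbind(p = c(0, 20, 40, 55, 70, 85, 100),
                     v = c(30, 32, 30, 20, 8, 12, 30)),
        ## terminal-swing toe clearance arc: the forefoot descends into
        ## contact rather than parking early
        ankle = cbind(p = c(0, 50, 75, 85, 93, 97, 100),
                      v = c(0, 0, 2, 8, 14, 9, 0))),
    crouch = list(
        cf = 36L, step = 0.27,
        hip = cbind(p = c(0, 40, 70, 100), v = c(15, 15, 13, 15)),
        knee = cbind(p = c(0, 40, 60, 80, 100), v = c(30, 32, 25, 18, 30)),
        ankle = cbind(p = c(0, 40, 60, 80, 100), v = c(15, 17, 10, 3, 15))),
    hyperextension = list(
        cf = 32L, step = 0.36,
        hip = cbind(p = c(0, 50, 100), v = c(-2, -2, -2)),
        knee = cbind(p = c(0, 10, 25, 40, 48, 56, 70, 90, 100),
                     v = c(-4, -10, -14, -10, -4, 2, 0, -2, -4)),
        ankle = cbind(p = c(0, 10, 25, 40, 50, 60, 72, 85, 100),
                      v = c(-12, -13, -14, -9, -6, -4, -2, -6, -12))),
    short_hamstring = list(
        cf = 32L, step = 0.39,
        hip = NULL,
        knee = cbind(p = c(0, 8, 15, 30, 60, 75, 85, 92, 100),
                     v = c(10, 5, 1, 0, 0, 0, 3, 8, 10)),
        ankle = NULL))

## periodic interpolation of keyframes onto the 0..100% grid
.periodicCurve <- function(keys) {
    p <- keys[, 1]; v <- keys[, 2]
    if (p[1] != 0) { p <- c(0, p); v <- c(v[length(v)], v) }
    if (p[length(p)] != 100) { p <- c(p, 100); v <- c(v, v[1]) }
    v[length(v)] <- v[1]  # enforce exact wrap for the periodic spline
    stats::spline(p, v, method = "periodic", xout = 0:100)$y
}

## band-limited periodic smoothing: keep the first `k` harmonics of the
## 100-sample period. Guarantees value and derivative continuity at the wrap.
.resmooth <- function(x, k = 12L) {
    z <- stats::fft(x[1:100])
    keep <- c(1:(k + 1L), (100 - k + 1L):100)
    z[setdiff(1:100, keep)] <- 0
    y <- Re(stats::fft(z, inverse = TRUE)) / 100
    c(y, y[1])
}

## evaluate a 101-point curve at arbitrary phase (percent, wrapped)
.curveAt <- function(curve, pct) {
    pct <- pct %% 100
    i0 <- floor(pct)
    f <- pct - i0
    curve[i0 + 1L] * (1 - f) + curve[i0 + 2L] * f
}

.wrapDeg <- function(x) ((x + 180) %% 360) - 180

## normal template before smoothing: hip, knee, ankle (deg) on 0..100%
.normalBase <- function() {
    hip <- .periodicCurve(.HIP_KEYS)
    knee <- .periodicCurve(.KNEE_KEYS)
    p <- 0:100
    orientSt <- stats::spline(.ORIENT_STANCE_KEYS[, 1],
                              .ORIENT_STANCE_KEYS[, 2],
                              xout = 0:60)$y
    ankleSt <- -orientSt - (hip[1:61] - knee[1:61])
    kp <- seq(0, 60, by = 5)
    keys <- rbind(cbind(p = kp, v = ankleSt[kp + 1L]), .ANKLE_SWING_KEYS)
    ankle <- .periodicCurve(keys)
    cbind(hip = hip, knee = knee, ankle = ankle)
}

.offsetCurve <- function(keys) {
    if (is.null(keys)) rep(0, 101) else .periodicCurve(keys)
}

#' Construct a gait-pattern specification
#'
#' Builds a [GaitPattern-class] with pattern-specific defaults for cycle
#' duration, step-length target and the additive joint-angle offset curves.
#' The cycle duration is quantized to an even number of frames at 30
#' frames/s so that left and right initial contacts fall on frame boundaries.
#'
#' @param patternName one of `"normal"`, `"true_equinus"`, `"jump"`,
#'   `"apparent_equinus"`, `"crouch"`, `"hyperextension"`,
#'   `"short_hamstring"`.
#' @param cycleDuration cycle duration in s (default: pattern-specific,
#'   about 1.0-1.2 s).
#' @param stepLengthTarget target step length in m (default:
#'   pattern-specific, 0.27-0.42 m).
#' @param angleOffsets optional list with 101-point numeric offset curves
#'   `hip`, `knee`, `ankle` (deg) overriding the pattern defaults.
#' @param noiseSd landmark jitter SD in m (default 0.005).
#' @param dropout per-frame dropout probability (default 0).
#' @param seed integer seed for all stochastic elements of a trial.
#' @return A [GaitPattern-class] object.
#' @examples
#' gaitPattern("crouch", seed = 7)
#' @export
gaitPattern <- function(patternName = .PATTERNS, cycleDuration = NULL,
                        stepLengthTarget = NULL, angleOffsets = NULL,
                        noiseSd = 0.005, dropout = 0, seed = 1L) {
    patternName <- match.arg(patternName)
    def <- .PATTERN_DEFAULTS[[patternName]]
    if (is.null(cycleDuration)) cycleDuration <- def$cf / .FPS
    cf <- max(16L, 2L * as.integer(round(cycleDuration * .FPS / 2)))
    if (is.null(stepLengthTarget)) stepLengthTarget <- def$step
    if (is.null(angleOffsets))
        angleOffsets <- list(hip = .offsetCurve(def$hip),
                             knee = .offsetCurve(def$knee),
                             ankle = .offsetCurve(def$ankle))
    new("GaitPattern", patternName = patternName,
        cycleDuration = cf / .FPS, stepLengthTarget = stepLengthTarget,
        angleOffsets = angleOffsets, noiseSd = noiseSd, dropout = dropout,
        seed = as.integer(seed))
}

setMethod("show", "GaitPattern", function(object) {
    cat("GaitPattern:", object@patternName,
        sprintf("| cycle %.3f s (%d frames) | step target %.2f m",
                object@cycleDuration, round(object@cycleDuration * .FPS),
                object@stepLengthTarget),
        sprintf("| noise SD %.3f m, dropout %.2f, seed %d\n",
                object@noiseSd, object@dropout, object@seed))
})

#' Generate per-joint angle curves for one gait cycle
#'
#' Produces the hip, knee and ankle angle curves (degrees, sampled at 0-100%
#' of the gait cycle in 1% steps) plus the implied foot orientation, for the
#' requested pattern. Pattern offsets are added to the normal template and
#' the sum is re-smoothed with a band-limited periodic filter, so the curves
#' and their first derivative are continuous across the 100% -> 0% wrap.
#'
#' Two calibrations make the curves consistent with level-ground walking:
#' (i) the hip-curve excursion is scaled so the forward kinematics realizes
#' the pattern's step-length target, and (ii) a smooth late-stance knee (and,
#' for toe-walkers, contact-side ankle) correction zeroes the per-cycle
#' vertical drift of the footfalls. The returned curves are exactly the
#' curves the simulated trajectory realizes.
#'
#' @param pattern a [GaitPattern-class].
#' @param anthro an [Anthropometry-class]; the default matches the default
#'   simulated walker.
#' @param calibrate logical; disable the step-length and ground-level
#'   calibrations (mainly for testing).
#' @return A `101 x 4` matrix with columns `hip`, `knee`, `ankle`, `foot`
#'   (degrees) and attribute `toeoffPct` (50, the simulator's stance
#'   fraction).
#' @examples
#' curves <- generateJointCurves(gaitPattern("normal"))
#' range(curves[, "knee"])
#' @export
generateJointCurves <- function(pattern, anthro = anthropometryFromStature(),
                                calibrate = TRUE) {
    stopifnot(is(pattern, "GaitPattern"), is(anthro, "Anthropometry"))
    base <- .normalBase()
    off <- pattern@angleOffsets
    hip <- .resmooth(base[, "hip"] + off$hip)
    knee <- .resmooth(base[, "knee"] + off$knee)
    ankle <- .resmooth(base[, "ankle"] + off$ankle)
    curves <- cbind(hip = hip, knee = knee, ankle = ankle)
    toeContact <- .contactIsToe(pattern, curves)
    if (calibrate) {
        curves <- .calibrateWalk(curves, anthro, pattern, toeContact)
        curves <- .calibrateLandingSpeed(curves, anthro, pattern,
                                         toeContact)
    }
    foot <- -(curves[, "hip"] - curves[, "knee"] + curves[, "ankle"])
    out <- cbind(curves, foot = foot)
    rownames(out) <- NULL
    attr(out, "toeoffPct") <- 50
    out
}
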