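#' @import methods
NULL

## Landmark and angle naming used throughout the package.
## Landmarks are ordered proximal -> distal; angles are the four sagittal
## curves reported per side.
.LANDMARKS <- c("trochanter", "epicondyle", "malleolus", "heel", "toe")
.ANGLES <- c("hip", "knee", "ankle", "foot")
.SIDES <- c("left", "right")
.PATTERNS <- c("normal", "true_equinus", "jump", "apparent_equinus",
               "crouch", "hyperextension", "short_hamstring")
.FPS <- 30

#' Lower-limb segment lengths of the simulated walker
#'
#' Holds the sagittal-plane segment lengths (in meters) used by the walker
#' simulator: thigh (greater trochanter to lateral femoral epicondyle), shank
#' (epicondyle to lateral malleolus), foot (heel to toe) and the heel offset
#' (malleolus to heel measured along the foot axis).
#'
#' @slot stature body height in m.
#' @slot thighLength,shankLength,footLength,heelOffset segment lengths in m.
#' @seealso [anthropometryFromStature()]
#' @export
setClass("Anthropometry",
         slots = c(stature = "numeric", thighLength = "numeric",
                   shankLength = "numeric", footLength = "numeric",
                   heelOffset = "numeric"))

setValidity("Anthropometry", function(object) {
    v <- c(object@stature, object@thighLength, object@shankLength,
           object@footLength, object@heelOffset)
    if (any(!is.finite(v)) || any(v <= 0))
        return("all segment lengths must be finite and > 0")
    if (object@thighLength + object@shankLength >= object@stature)
        return("thighLength + shankLength must be smaller than stature")
    if (object@heelOffset >= object@footLength)
        return("heelOffset must be smaller than footLength")
    TRUE
})

#' Specification of a simulated gait pattern
#'
#' Describes one simulated walking condition: the named sagittal gait pattern,
#' its cycle duration (quantized to an even number of frames at 30 frames/s),
#' the step-length target, additive joint-angle offset curves relative to the
#' normal template, and the landmark noise model.
#'
#' @slot patternName one of `"normal"`, `"true_equinus"`, `"jump"`,
#'   `"apparent_equinus"`, `"crouch"`, `"hyperextension"`,
#'   `"short_hamstring"`.
#' @slot cycleDuration gait-cycle duration in s.
#' @slot stepLengthTarget target step length in m.
#' @slot angleOffsets list with numeric 101-point offset curves (`hip`,
#'   `knee`, `ankle`) in degrees, added to the normal template.
#' @slot noiseSd landmark jitter standard deviation in m.
#' @slot dropout per-frame probability that all landmarks of a frame are
#'   flagged missing.
#' @slot seed integer seed governing all stochastic elements of a trial.
#' @seealso [gaitPattern()]
#' @export
setClass("GaitPattern",
         slots = c(patternName = "character", cycleDuration = "numeric",
                   stepLengthTarget = "numeric", angleOffsets = "list",
                   noiseSd = "numeric", dropout = "numeric",
                   seed = "integer"))

setValidity("GaitPattern", function(object) {
    if (!object@patternName %in% .PATTERNS)
        return(sprintf("unknown pattern '%s'; valid patterns are: %s",
                       object@patternName, paste(.PATTERNS, collapse = ", ")))
    if (object@cycleDuration <= 0) return("cycleDuration must be > 0")
    if (object@dropout < 0 || object@dropout > 1)
        return("dropout must be in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (!all(c("hip", "knee", "ankle") %in% names(object@angleOffsets)))
        return("angleOffsets must contain hip, knee and ankle")
    if (!all(vapply(object@angleOffsets[c("hip", "knee", "ankle")],
                    length, 0L) == 101L))
        return("angle offset curves must have 101 samples (0..100%)")
    TRUE
})

#' Ground-truthed landmark trajectory of a simulated walker
#'
#' Per-frame 2D metric positions (x forward, y up, in m) of the five landmarks
#' per side, together with the ground-truth gait events, foot-flat intervals
#' and the joint-angle curves the trajectory realizes.
#'
#' @slot timestamps frame times in s (1/30 s apart).
#' @slot positions numeric array `[frame, landmark, coord, side]` with
#'   landmarks trochanter/epicondyle/malleolus/heel/toe and coords x/y.
#' @slot missing logical array `[frame, landmark, side]`; `TRUE` marks a
#'   dropped (missing) observation, whose positions are `NA`.
#' @slot trueEvents data.frame with columns `side`, `ic`, `to` (1-based frame
#'   indices) for every complete simulated cycle.
#' @slot footFlat data.frame with columns `side`, `start`, `end`: frame
#'   intervals during which the stance foot is flat and its heel is anchored
#'   to the ground (absent for toe-walking patterns).
#' @slot trueCurves list with one `101 x 4` matrix per side (columns hip,
#'   knee, ankle, foot) of the realized cycle-normalized angle curves, plus
#'   attribute-free helper entries `toeoffPct` and `stepLength`.
#' @slot pattern the [GaitPattern-class] used.
#' @slot anthropometry the [Anthropometry-class] used.
#' @slot fps frames per second (30).
#' @export
setClass("WalkerTrajectory",
         slots = c(timestamps = "numeric", positions = "array",
                   missing = "array", trueEvents = "data.frame",
                   footFlat = "data.frame", trueCurves = "list",
                   pattern = "GaitPattern", anthropometry = "Anthropometry",
                   fps = "numeric"))

setValidity("WalkerTrajectory", function(object) {
    d <- dim(object@positions)
    if (length(d) != 4 || d[2] != 5 || d[3] != 2 || d[4] != 2)
        return("positions must be a [frame, 5, 2, 2] array")
    if (d[1] != length(object@timestamps))
        return("timestamps length must match frame count")
    if (any(diff(object@timestamps) <= 0))
        return("timestamps must be strictly increasing")
    TRUE
})

#' Rendered scene configuration
#'
#' Geometry and palette of the rendered lateral-view scene: a walker against a
#' uniform green background, red right sock, blue left sock and near-black pen
#' marks on the leg landmarks.
#'
#' @slot width,height image size in px.
#' @slot pixelsPerMeter scale in px/m.
#' @slot originM world coordinates (m) mapped to the bottom-left image corner.
#' @slot colors named list of RGB triplets in \[0,1\]: `background`,
#'   `sockRight`, `sockLeft`, `mark`, `skin`, `shirt`.
#' @slot markRadiusM radius of the rendered pen marks in m.
#' @slot thighWidthM,shankWidthM limb stroke widths in m.
#' @slot sockHeightM height of the sock body above the sole in m.
#' @slot lightJitterSd per-frame multiplicative brightness jitter SD (0
#'   disables); deterministic given `jitterSeed`.
#' @slot jitterSeed integer seed for the brightness jitter.
#' @slot foregroundSide which leg is camera-near and drawn last
#'   (`"right"` or `"left"`).
#' @seealso [sceneConfig()]
#' @export
setClass("SceneConfig",
         slots = c(width = "integer", height = "integer",
                   pixelsPerMeter = "numeric", originM = "numeric",
                   colors = "list", markRadiusM = "numeric",
                   thighWidthM = "numeric", shankWidthM = "numeric",
                   sockHeightM = "numeric", lightJitterSd = "numeric",
                   jitterSeed = "integer", foregroundSide = "character"))

setValidity("SceneConfig", function(object) {
    if (object@pixelsPerMeter <= 0) return("pixelsPerMeter must be > 0")
    if (object@width < 16L || object@height < 16L)
        return("image must be at least 16 x 16 px")
    need <- c("background", "sockRight", "sockLeft", "mark", "skin", "shirt")
    if (!all(need %in% names(object@colors)))
        return(paste("colors must contain", paste(need, collapse = ", ")))
    if (!object@foregroundSide %in% .SIDES)
        return("foregroundSide must be 'left' or 'right'")
    TRUE
})

#' A lazily rendered RGB frame sequence
#'
#' Binds a [WalkerTrajectory-class] to a [SceneConfig-class]. Frames are
#' rendered deterministically on demand with [getFrame()], so long sequences
#' never have to be held in memory at once.
#'
#' @slot trajectory the trajectory being rendered.
#' @slot scene the scene configuration.
#' @slot timestamps frame times in s.
#' @export
setClass("FrameSequence",
         slots = c(trajectory = "WalkerTrajectory", scene = "SceneConfig",
                   timestamps = "numeric"))

#' Landmark positions extracted from frames
#'
#' Per-frame landmark detections in px and in m (y up), with missing and
#' interpolated flags and a per-trial quality report.
#'
#' @slot timestamps frame times in s.
#' @slot positionsM numeric array `[frame, landmark, coord, side]` in m.
#' @slot positionsPx same layout, image coordinates (origin top-left, y
#'   down); `NA` where the sequence was built directly from a trajectory.
#' @slot rawM same layout as `positionsM`, before smoothing (gap-filled
#'   only); used for plateau-based event refinement.
#' @slot missing logical array `[frame, landmark, side]`: landmark not
#'   observed and not recoverable by interpolation.
#' @slot interpolated logical array `[frame, landmark, side]`: gap filled by
#'   linear interpolation.
#' @slot quality list with at least `validFeetFraction`.
#' @slot walkDirection +1 for walking toward increasing x.
#' @slot smoothed logical; `TRUE` once the zero-lag low-pass filter has been
#'   applied.
#' @slot fps frames per second.
#' @export
setClass("TrackedLandmarks",
         slots = c(timestamps = "numeric", positionsM = "array",
                   rawM = "array",
                   positionsPx = "array", missing = "array",
                   interpolated = "array", quality = "list",
                   walkDirection = "numeric", smoothed = "logical",
                   fps = "numeric"))

#' Sagittal joint-angle time series
#'
#' Raw per-frame hip flexion, knee flexion, ankle dorsiflexion and foot
#' orientation (degrees) per side, and after [normalizeCycles()] the per-cycle
#' 101-point normalized curves with the toe-off percentage.
#'
#' @slot timestamps frame times in s.
#' @slot angles list with one `[frame, 4]` matrix per side (columns hip,
#'   knee, ankle, foot).
#' @slot cycles list per side: `curves` (array `[cycle, 101, 4]`),
#'   `toeoffPct`, `ic` (cycle start frames) and `excluded` (count of cycles
#'   dropped because of missing frames). Empty until [normalizeCycles()] is
#'   called.
#' @slot fps frames per second.
#' @export
setClass("JointKinematics",
         slots = c(timestamps = "numeric", angles = "list", cycles = "list",
                   fps = "numeric"))

#' Detected gait events
#'
#' Initial-contact and toe-off frame indices per side and the derived cycle
#' triples, together with the detection parameters used.
#'
#' @slot ic,to named lists (`left`, `right`) of sorted 1-based frame indices.
#' @slot cycles data.frame with columns `side`, `ic`, `to`, `nextIc`, one row
#'   per complete cycle.
#' @slot params list: `vThresh` (m/s), `dwell` (frames), `refine`.
#' @export
setClass("GaitEvents",
         slots = c(ic = "list", to = "list", cycles = "data.frame",
                   params = "list"))

setValidity("GaitEvents", function(object) {
    if (nrow(object@cycles)) {
        bad <- with(object@cycles, ic >= to | to >= nextIc)
        if (any(bad)) return("cycles must satisfy ic < to < nextIc")
    }
    TRUE
})

#' Normative kinematic band
#'
#' Pointwise mean and sample standard deviation of the four normalized angle
#' curves, built from an ensemble of normal-pattern trials (or user-supplied
#' reference curves). The default band half-width is 1 SD.
#'
#' @slot mean,sd `101 x 4` matrices (columns hip, knee, ankle, foot), degrees.
#' @slot n number of trials in the ensemble.
#' @seealso [buildNormativeBand()]
#' @export
setClass("NormativeBand",
         slots = c(mean = "matrix", sd = "matrix", n = "integer"))

setValidity("NormativeBand", function(object) {
    if (!all(dim(object@mean) == c(101L, 4L)) ||
        !all(dim(object@sd) == c(101L, 4L)))
        return("mean and sd must be 101 x 4 matrices")
    if (any(object@sd < 0, na.rm = TRUE)) return("sd must be >= 0")
    TRUE
})

#' Result of the sagittal gait-pattern classification
#'
#' The per-side verdict of the rule-based classifier: one of the four
#' classic sagittal patterns of spastic diplegia or `unclassified_mild`,
#' an ordered rule trace for auditability, and the deviation flags raised for
#' mild patterns.
#'
#' @slot side `"left"` or `"right"`.
#' @slot type one of `"I_true_equinus"`, `"II_jump"`,
#'   `"III_apparent_equinus"`, `"IV_crouch"`, `"unclassified_mild"`.
#' @slot ruleTrace data.frame with columns `criterion`, `observed`,
#'   `threshold`, `verdict`, in evaluation order.
#' @slot deviationFlags character vector, subset of
#'   `increased_knee_flexion_at_ic`, `decreased_terminal_swing_extension`,
#'   `knee_hyperextension_in_stance`, `absent_first_rocker`,
#'   `plantarflexion_knee_extension_couple`.
#' @export
setClass("RoddaResult",
         slots = c(side = "character", type = "character",
                   ruleTrace = "data.frame", deviationFlags = "character"))

setValidity("RoddaResult", function(object) {
    ok <- c("I_true_equinus", "II_jump", "III_apparent_equinus", "IV_crouch",
            "unclassified_mild")
    if (!object@type %in% ok)
        return(paste("type must be one of", paste(ok, collapse = ", ")))
    if (nrow(object@ruleTrace) == 0) return("ruleTrace must be non-empty")
    TRUE
})
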