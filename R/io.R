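## Readers and writers for the package's plain-text interchange formats.
## All file coordinates are metric (x forward, y up); frame indices in
## files are 0-based; floats are written with 6 significant digits.

.fmt6 <- function(x) signif(x, 8)

#' Write landmark trajectories as CSV
#'
#' Long format, one row per landmark-frame: `frame` (0-based), `time_s`,
#' `side`, `landmark`, `x_m`, `y_m`, `missing_flag`.
#'
#' @param x a [WalkerTrajectory-class] or [TrackedLandmarks-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCsv <- function(x, path) {
    pos <- .positionArray(x)
    miss <- .missingArray(x)
    t <- .timestampsOf(x)
    n <- dim(pos)[1]
    rows <- expand.grid(frame = seq_len(n) - 1L, landmark = .LANDMARKS,
                        side = .SIDES, stringsAsFactors = FALSE)
    rows$time_s <- .fmt6(t[rows$frame + 1L])
    idx <- cbind(rows$frame + 1L,
                 match(rows$landmark, .LANDMARKS), 1L,
                 match(rows$side, .SIDES))
    rows$x_m <- .fmt6(pos[idx])
    idx[, 3] <- 2L
    rows$y_m <- .fmt6(pos[idx])
    rows$missing_flag <- miss[cbind(rows$frame + 1L,
                                    match(rows$landmark, .LANDMARKS),
                                    match(rows$side, .SIDES))]
    rows <- rows[order(rows$frame, rows$side, match(rows$landmark,
                                                    .LANDMARKS)), ]
    utils::write.csv(rows[c("frame", "time_s", "side", "landmark",
                            "x_m", "y_m", "missing_flag")],
                     path, row.names = FALSE)
    invisible(path)
}

#' Read landmark trajectories from CSV
#'
#' Inverse of [writeTrajectoryCsv()]; schema violations are reported with
#' the offending row.
#'
#' @param path CSV file.
#' @param smoothCutoffHz,maxGap,minValidFraction passed to the tracking
#'   finalization (set `smoothCutoffHz = NA` to keep the stored positions
#'   untouched).
#' @return A [TrackedLandmarks-class].
#' @export
readTrajectoryCsv <- function(path, smoothCutoffHz = NA, maxGap = 5L,
                              minValidFraction = 0) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty trajectory file: ", path)
    need <- c("frame", "time_s", "side", "landmark", "x_m", "y_m",
              "missing_flag")
    if (!all(need %in% names(df)))
        stop("trajectory CSV must have columns: ",
             paste(need, collapse = ", "))
    badSide <- which(!df$side %in% .SIDES)
    if (length(badSide))
        stop(sprintf("invalid side '%s' at row %d", df$side[badSide[1]],
                     badSide[1]))
    badLm <- which(!df$landmark %in% .LANDMARKS)
    if (length(badLm))
        stop(sprintf("invalid landmark '%s' at row %d",
                     df$landmark[badLm[1]], badLm[1]))
    n <- max(df$frame) + 1L
    pos <- .emptyPosArray(n)
    pos[cbind(df$frame + 1L, match(df$landmark, .LANDMARKS), 1L,
              match(df$side, .SIDES))] <- df$x_m
    pos[cbind(df$frame + 1L, match(df$landmark, .LANDMARKS), 2L,
              match(df$side, .SIDES))] <- df$y_m
    drop <- df[df$missing_flag %in% c(TRUE, "TRUE", "True", 1), ]
    if (nrow(drop)) {
        for (cc in 1:2)
            pos[cbind(drop$frame + 1L, match(drop$landmark, .LANDMARKS),
                      cc, match(drop$side, .SIDES))] <- NA_real_
    }
    ts <- tapply(df$time_s, df$frame, function(x) x[1])
    .finalizeTracking(NULL, as.numeric(ts), NULL, smoothCutoffHz, maxGap,
                      minValidFraction, 1, posM = pos)
}

#' Write / read gait events as JSON
#'
#' Events are serialized per side with 0-based frame indices:
#' `{"left": {"ic_frames": [...], "to_frames": [...]}, "right": ...,
#' "params": ...}`.
#'
#' @param events a [GaitEvents-class] or a ground-truth event data.frame
#'   (columns `side`, `ic`, `to`).
#' @param path JSON file.
#' @return `path` / a [GaitEvents-class].
#' @export
writeEventsJson <- function(events, path) {
    if (is.data.frame(events)) events <- .asReferenceEvents(events)
    out <- list()
    for (side in .SIDES)
        out[[side]] <- list(ic_frames = as.integer(events@ic[[side]]) - 1L,
                            to_frames = as.integer(events@to[[side]]) - 1L)
    out$params <- events@params
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeEventsJson
#' @export
readEventsJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    ic <- list(); to <- list(); cycles <- NULL
    for (side in .SIDES) {
        ic[[side]] <- sort(as.integer(unlist(x[[side]]$ic_frames))) + 1L
        to[[side]] <- sort(as.integer(unlist(x[[side]]$to_frames))) + 1L
        cyc <- suppressMessages(segmentCycles(ic[[side]], to[[side]]))
        if (nrow(cyc)) cycles <- rbind(cycles, cbind(side = side, cyc))
    }
    if (is.null(cycles))
        cycles <- data.frame(side = character(), ic = integer(),
                             to = integer(), nextIc = integer())
    new("GaitEvents", ic = ic, to = to, cycles = cycles,
        params = if (is.null(x$params)) list() else x$params)
}

#' Write / read raw kinematic angle series as CSV
#'
#' Long format: `side`, `frame` (0-based), `time_s`, then one column per
#' angle (degrees).
#'
#' @param kin a [JointKinematics-class].
#' @param path CSV file.
#' @return `path` / a [JointKinematics-class] (without normalized cycles).
#' @export
writeKinematicsCsv <- function(kin, path) {
    rows <- do.call(rbind, lapply(.SIDES, function(side) {
        a <- kin@angles[[side]]
        data.frame(side = side, frame = seq_len(nrow(a)) - 1L,
                   time_s = .fmt6(kin@timestamps),
                   hip = .fmt6(a[, "hip"]), knee = .fmt6(a[, "knee"]),
                   ankle = .fmt6(a[, "ankle"]), foot = .fmt6(a[, "foot"]))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeKinematicsCsv
#' @export
readKinematicsCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty kinematics file: ", path)
    angles <- lapply(.SIDES, function(side) {
        d <- df[df$side == side, ]
        d <- d[order(d$frame), ]
        as.matrix(d[c("hip", "knee", "ankle", "foot")])
    })
    names(angles) <- .SIDES
    ts <- df$time_s[df$side == .SIDES[1]][order(df$frame[df$side ==
                                                         .SIDES[1]])]
    new("JointKinematics", timestamps = as.numeric(ts), angles = angles,
        cycles = list(), fps = .FPS)
}

#' Write / read a feature table (with optional classification) as JSON
#'
#' @param features data.frame from [extractGaitFeatures()].
#' @param path JSON file.
#' @param classification optional result of [classifyTrial()].
#' @return `path` / list with `features` (data.frame) and, if present,
#'   `classification`.
#' @export
writeFeaturesJson <- function(features, path, classification = NULL) {
    out <- list(features = cbind(side = rownames(features), features))
    if (!is.null(classification)) {
        out$classification <- list(
            label = classification$label,
            sides = lapply(classification$results, function(r)
                list(type = r@type, deviation_flags = r@deviationFlags,
                     rule_trace = r@ruleTrace)))
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeFeaturesJson
#' @export
readFeaturesJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    feats <- as.data.frame(x$features)
    rownames(feats) <- feats$side
    feats$side <- NULL
    x$features <- feats
    x
}

#' Write / read a scene configuration as YAML
#'
#' @param scene a [SceneConfig-class].
#' @param path YAML file.
#' @return `path` / a [SceneConfig-class].
#' @export
writeSceneYaml <- function(scene, path) {
    out <- list(width = scene@width, height = scene@height,
                pixels_per_meter = scene@pixelsPerMeter,
                origin_m = scene@originM,
                colors = scene@colors,
                mark_radius_m = scene@markRadiusM,
                thigh_width_m = scene@thighWidthM,
                shank_width_m = scene@shankWidthM,
                sock_height_m = scene@sockHeightM,
                light_jitter_sd = scene@lightJitterSd,
                jitter_seed = scene@jitterSeed,
                foreground_side = scene@foregroundSide)
    yaml::write_yaml(out, path)
    invisible(path)
}

#' @rdname writeSceneYaml
#' @export
readSceneYaml <- function(path) {
    x <- yaml::read_yaml(path)
    sceneConfig(width = x$width, height = x$height,
                pixelsPerMeter = x$pixels_per_meter,
                originM = unlist(x$origin_m),
                colors = lapply(x$colors, unlist),
                markRadiusM = x$mark_radius_m,
                thighWidthM = x$thigh_width_m,
                shankWidthM = x$shank_width_m,
                sockHeightM = x$sock_height_m,
                lightJitterSd = x$light_jitter_sd,
                jitterSeed = x$jitter_seed,
                foregroundSide = x$foreground_side)
}

#' Run configuration: defaults, (de)serialization and validation
#'
#' One serializable document holding the tunable parameters of every
#' pipeline stage. Unknown keys are rejected.
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
    list(vThresh = 0.05, dwell = 3L, smoothCutoffHz = 6,
         eventCutoffHz = 3.5, maxGap = 5L, minValidFraction = 0.8,
         areaFraction = 0.75, toeWalkThreshold = 10, bandK = 1,
         midstanceWindow = c(10, 40), coupleAnkleBound = 5,
         heelDownThreshold = -2, pixelsPerMeter = 480,
         foregroundSide = "right", seed = 1L)
}

#' @rdname defaultRunConfig
#' @param config named list of overrides for [defaultRunConfig()] values.
#' @param path YAML file.
#' @export
writeRunConfig <- function(config, path) {
    config <- validateRunConfig(config)
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
    validateRunConfig(yaml::read_yaml(path))
}

#' @rdname defaultRunConfig
#' @export
validateRunConfig <- function(config) {
    def <- defaultRunConfig()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    utils::modifyList(def, config)
}

#' Cohort report: per-side feature rows with summary and curve exports
#'
#' Assembles one row per participant-side with the clinical feature
#' columns, appends mean/SD/range summary rows via [cohortTable()], and
#' exports the per-cycle normalized curves (101 samples each) for
#' plotting.
#'
#' @param trialFeatures named list: per participant, a data.frame from
#'   [extractGaitFeatures()] (rows `left`/`right`).
#' @param kinList optional named list of [JointKinematics-class] for the
#'   curve export.
#' @param dir optional output directory; when given, `cohort_summary.csv`
#'   and `curves.csv` are written deterministically.
#' @return List with `table` (side rows), `summary` (from [cohortTable()])
#'   and `curves` (long data.frame or NULL).
#' @export
cohortReport <- function(trialFeatures, kinList = NULL, dir = NULL) {
    stopifnot(length(trialFeatures) >= 1)
    rows <- do.call(rbind, lapply(names(trialFeatures), function(id) {
        f <- trialFeatures[[id]]
        cbind(participant = id, side = rownames(f), f, row.names = NULL)
    }))
    summary <- cohortTable(rows)
    curves <- NULL
    if (!is.null(kinList)) {
        curves <- do.call(rbind, lapply(names(kinList), function(id) {
            kin <- kinList[[id]]
            do.call(rbind, lapply(.SIDES, function(side) {
                cv <- kin@cycles[[side]]$curves
                if (!dim(cv)[1]) return(NULL)
                do.call(rbind, lapply(seq_len(dim(cv)[1]), function(k)
                    data.frame(participant = id, side = side, cycle = k,
                               pct = 0:100,
                               toeoffPct = kin@cycles[[side]]$toeoffPct[k],
                               hip = .fmt6(cv[k, , "hip"]),
                               knee = .fmt6(cv[k, , "knee"]),
                               ankle = .fmt6(cv[k, , "ankle"]),
                               foot = .fmt6(cv[k, , "foot"]))))
            }))
        }))
    }
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(rows, file.path(dir, "cohort_rows.csv"),
                         row.names = FALSE)
        utils::write.csv(cbind(stat = rownames(summary), summary),
                         file.path(dir, "cohort_summary.csv"),
                         row.names = FALSE)
        if (!is.null(curves))
            utils::write.csv(curves, file.path(dir, "curves.csv"),
                             row.names = FALSE)
    }
    list(table = rows, summary = summary, curves = curves)
}

#' Reference cohort spatio-temporal values
#'
#' Per-participant-side mean gait speed and step length of an example
#' clinical cohort (20 children with bilateral cerebral palsy, GMFCS
#' levels I-III; two side-rows per participant; one participant walked
#' with aids and lacks speed and step values), shipped as plain CSV.
#'
#' @return data.frame with columns `participant`, `side`, `trials`,
#'   `gaitSpeed` (m/s), `stepLength` (m), `support`.
#' @examples
#' head(referenceCohort())
#' @export
referenceCohort <- function() {
    path <- system.file("extdata", "cohort_reference.csv",
                        package = "MLGait", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}
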