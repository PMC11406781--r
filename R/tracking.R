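## Landmark tracking over a frame sequence.
##
## Feet are tracked through their sock colors; the two legs are
## disambiguated purely by color (red = right, blue = left). Pen marks are
## dark blobs associated to sides frame by frame: the malleolus anchors to
## its side's sock, the (shared) trochanter to the highest blob, and the
## epicondyles to per-side predictions carried over from the previous
## frame. When the swing leg passes the stance leg, far-side marks are
## briefly occluded; those frames are flagged missing and short gaps are
## filled by linear interpolation.

.emptyPosArray <- function(n) {
    array(NA_real_, dim = c(n, 5L, 2L, 2L),
          dimnames = list(NULL, .LANDMARKS, c("x", "y"), .SIDES))
}

## zero-lag low-pass: 2nd-order Butterworth applied forward and backward
## (effective 4th order), 6 Hz cutoff at 30 frames/s by default
.zeroLagLowpass <- function(x, cutoffHz, fps) {
    ok <- is.finite(x)
    if (sum(ok) < 10 || cutoffHz <= 0 || cutoffHz >= fps / 2) return(x)
    idx <- seq_along(x)
    filled <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
    ## reflective padding suppresses the filter's edge transients
    np <- min(length(filled) - 1L, 20L)
    padded <- c(2 * filled[1] - filled[(np + 1):2],
                filled,
                2 * filled[length(filled)] -
                    filled[(length(filled) - 1):(length(filled) - np)])
    bf <- signal::butter(2, cutoffHz / (fps / 2), type = "low")
    sm <- signal::filtfilt(bf, padded)[(np + 1):(np + length(filled))]
    sm[!ok] <- NA_real_
    sm
}

## fill NA runs of length <= maxGap by linear interpolation;
## returns list(x, filled) where filled marks interpolated entries
.fillShortGaps <- function(x, maxGap = 5L) {
    ok <- is.finite(x)
    filled <- rep(FALSE, length(x))
    if (all(ok) || sum(ok) < 2) return(list(x = x, filled = filled))
    r <- rle(!ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    interp <- stats::approx(which(ok), x[ok], xout = seq_along(x))$y
    for (k in which(r$values)) {
        if (r$lengths[k] <= maxGap && starts[k] > 1 &&
            ends[k] < length(x)) {
            x[starts[k]:ends[k]] <- interp[starts[k]:ends[k]]
            filled[starts[k]:ends[k]] <- TRUE
        }
    }
    list(x = x, filled = filled)
}

## signal a structured trial rejection (criterion: unusable input is
## reported with a machine-readable reason, never an unhandled error)
rejectTrial <- function(reasonCode, message) {
    cond <- structure(class = c("gaitTrialRejection", "error", "condition"),
                      list(message = message, call = sys.call(-1),
                           reasonCode = reasonCode))
    stop(cond)
}

#' Track landmarks across a rendered or recorded frame sequence
#'
#' Runs color segmentation on every frame, extracts heel and toe from the
#' sock masks and the three pen marks per leg from dark blobs, associates
#' them to body sides, converts to metric (y-up) coordinates, fills short
#' gaps by linear interpolation (flagging them), and smooths the
#' trajectories with a zero-lag low-pass filter before any differentiation.
#'
#' Occlusion handling: a sock detection whose blob area falls below
#' `areaFraction` of that side's trial median is treated as partially
#' occluded and flagged missing, as are pen marks that cannot be assigned.
#'
#' Trials in which fewer than `minValidFraction` of frames have both feet
#' visible are rejected with a structured condition of class
#' `gaitTrialRejection` (reason code `feet_identification`), mirroring the
#' exclusion of recordings whose images do not allow reliable foot
#' identification.
#'
#' @param fs a [FrameSequence-class] (or a directory of
#'   `frame_*.png` files with a `scene.yaml`).
#' @param spec a [colorSpec()].
#' @param smoothCutoffHz low-pass cutoff in Hz (`NA` disables smoothing).
#' @param maxGap longest gap (frames) filled by interpolation.
#' @param minValidFraction rejection threshold on the fraction of frames
#'   with both feet valid.
#' @param areaFraction occlusion threshold on sock blob area relative to
#'   the trial median.
#' @param walkDirection +1 for walking toward increasing x.
#' @return A [TrackedLandmarks-class].
#' @export
trackSequence <- function(fs, spec = colorSpec(), smoothCutoffHz = 6,
                          maxGap = 5L, minValidFraction = 0.8,
                          areaFraction = 0.75, walkDirection = 1) {
    if (is.character(fs)) fs <- .frameSequenceFromDir(fs)
    scene <- if (inherits(fs, "DiskFrameSequence")) fs$scene else fs@scene
    n <- nFrames(fs)
    timestamps <- if (inherits(fs, "DiskFrameSequence"))
        (seq_len(n) - 1L) / .FPS else fs@timestamps
    if (n < 2) stop("need at least 2 frames to track")
    posPx <- .emptyPosArray(n)
    areas <- matrix(NA_real_, n, 2, dimnames = list(NULL, .SIDES))
    markAreas <- array(NA_real_, dim = c(n, 3L, 2L),
                       dimnames = list(NULL, .LANDMARKS[1:3], .SIDES))
    prevTroch <- NULL
    shankSamples <- numeric(0)                    # |epicondyle - malleolus| px
    ppm <- scene@pixelsPerMeter
    roi <- NULL                                   # c(r0, r1, c0, c1)
    for (i in seq_len(n)) {
        frame <- getFrame(fs, i)
        ## crop to a region of interest around the previous detections
        if (!is.null(roi)) {
            sub <- frame[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
            off <- c(roi[3] - 1L, roi[1] - 1L)    # (x, y) pixel offset
        } else {
            sub <- frame
            off <- c(0L, 0L)
        }
        hsv <- .frameHsv(sub)
        shift <- function(p) if (is.null(p)) NULL else p + off
        feet <- list(
            right = extractFootPoints(
                segmentColor(sub, spec, "right_sock_red", hsv = hsv),
                walkDirection),
            left = extractFootPoints(
                segmentColor(sub, spec, "left_sock_blue", hsv = hsv),
                walkDirection))
        cents <- .darkBlobCentroids(
            segmentColor(sub, spec, "landmark_dark", hsv = hsv))
        if (nrow(cents)) {
            cents[, "x"] <- cents[, "x"] + off[1]
            cents[, "y"] <- cents[, "y"] + off[2]
        }
        for (side in .SIDES) {
            ft <- feet[[side]]
            if (!is.null(ft)) {
                posPx[i, "heel", , side] <- shift(ft$heel)
                posPx[i, "toe", , side] <- shift(ft$toe)
                areas[i, side] <- ft$area
            }
        }
        if (nrow(cents)) {
            used <- rep(FALSE, nrow(cents))
            ## trochanter: shared by both sides in the sagittal projection;
            ## nearest to the previous position, else the topmost blob
            trIdx <- if (!is.null(prevTroch)) {
                d <- sqrt((cents[, "x"] - prevTroch[1])^2 +
                          (cents[, "y"] - prevTroch[2])^2)
                which.min(d)
            } else which.min(cents[, "y"])
            tr <- cents[trIdx, c("x", "y")]
            if (is.null(prevTroch) ||
                sqrt(sum((tr - prevTroch)^2)) < 0.12 * ppm) {
                posPx[i, "trochanter", , "left"] <- tr
                posPx[i, "trochanter", , "right"] <- tr
                markAreas[i, "trochanter", ] <- cents[trIdx, "area"]
                prevTroch <- tr
                used[trIdx] <- TRUE
            }
            ## malleoli: anchored to the sock of their side
            for (side in .SIDES) {
                ft <- feet[[side]]
                if (is.null(ft)) next
                heelPx <- shift(ft$heel); toePx <- shift(ft$toe)
                pred <- heelPx + 0.28 * (toePx - heelPx)
                cand <- which(!used)
                if (!length(cand)) next
                d <- sqrt((cents[cand, "x"] - pred[1])^2 +
                          (cents[cand, "y"] - pred[2])^2)
                j <- cand[which.min(d)]
                if (min(d) < 0.12 * ppm) {
                    posPx[i, "malleolus", , side] <- cents[j, c("x", "y")]
                    markAreas[i, "malleolus", side] <- cents[j, "area"]
                    used[j] <- TRUE
                }
            }
            ## epicondyles: the epicondyle of a side lies one rigid shank
            ## length from that side's malleolus, and the malleoli are
            ## unambiguous (anchored to the colored socks). Assignment is
            ## stateless: per frame, the pairing must beat the swapped
            ## pairing by a clear margin, otherwise (legs superposed) the
            ## marks are reported missing and interpolation bridges the
            ## crossing. The shank length is estimated online.
            shankEst <- if (length(shankSamples) >= 5)
                stats::median(shankSamples) else NULL
            cand <- which(!used)
            if (length(cand)) {
                epiCost <- function(j, side) {
                    ml <- posPx[i, "malleolus", , side]
                    pt <- cents[cand[j], c("x", "y")]
                    if (anyNA(ml)) {
                        ## fall back to the mid-leg prediction
                        tr2 <- posPx[i, "trochanter", , side]
                        if (anyNA(tr2)) return(Inf)
                        ref <- shankEst
                        if (is.null(ref)) ref <- 0.34 * ppm
                        pred <- tr2 + c(0, 0.95 * ref)
                        return(sqrt(sum((pt - pred)^2)))
                    }
                    dM <- sqrt(sum((pt - ml)^2))
                    ref <- if (is.null(shankEst)) 0.34 * ppm else shankEst
                    abs(dM - ref)
                }
                cost <- matrix(Inf, length(cand), 2)
                for (j in seq_along(cand)) for (s2 in 1:2)
                    cost[j, s2] <- epiCost(j, .SIDES[s2])
                gate <- 0.06 * ppm
                margin <- 0.015 * ppm
                takeSample <- function(side, j) {
                    pt <- cents[cand[j], c("x", "y")]
                    posPx[i, "epicondyle", , side] <<- pt
                    markAreas[i, "epicondyle", side] <<-
                        cents[cand[j], "area"]
                    used[cand[j]] <<- TRUE
                    ml <- posPx[i, "malleolus", , side]
                    if (!anyNA(ml))
                        shankSamples <<- c(utils::tail(shankSamples, 24),
                                           sqrt(sum((pt - ml)^2)))
                }
                if (length(cand) >= 2) {
                    best <- NULL; bestCost <- Inf
                    for (jl in seq_along(cand)) for (jr in seq_along(cand)) {
                        if (jl == jr) next
                        cc <- cost[jl, 1] + cost[jr, 2]
                        if (cc < bestCost) { bestCost <- cc; best <- c(jl, jr) }
                    }
                    swapped <- cost[best[2], 1] + cost[best[1], 2]
                    if (is.finite(bestCost) && swapped - bestCost > margin) {
                        if (cost[best[1], 1] < gate) takeSample("left", best[1])
                        if (cost[best[2], 2] < gate) takeSample("right", best[2])
                    }
                } else {
                    diffC <- abs(cost[1, 1] - cost[1, 2])
                    s2 <- which.min(cost[1, ])
                    if (is.finite(cost[1, s2]) && cost[1, s2] < gate &&
                        (diffC > margin || !is.finite(cost[1, 3 - s2])))
                        takeSample(.SIDES[s2], 1L)
                }
            }
        }
        ## next region of interest from everything seen in this frame
        pts <- matrix(posPx[i, , , ], ncol = 2)
        pts <- pts[stats::complete.cases(pts), , drop = FALSE]
        roi <- if (nrow(pts) >= 4) {
            m <- 0.35 * ppm
            c(max(1L, floor(min(pts[, 2]) - m)),
              min(scene@height, ceiling(max(pts[, 2]) + m)),
              max(1L, floor(min(pts[, 1]) - m)),
              min(scene@width, ceiling(max(pts[, 1]) + m)))
        } else NULL
    }
    ## quality gate on raw detectability: fraction of frames in which
    ## both feet were found in the image at all (before the finer
    ## occlusion guards below, which only refine localization)
    rawValid <- mean(vapply(seq_len(n), function(i)
        !anyNA(posPx[i, c("heel", "toe"), , ]), logical(1)))
    ## occlusion guards: partially occluded socks and pen marks have
    ## shrunken blobs, and a clipped sock yields a foot whose apparent
    ## (rigid) length deviates from the trial median; flag such frames
    ## missing and let interpolation bridge them
    for (side in .SIDES) {
        med <- stats::median(areas[, side], na.rm = TRUE)
        if (is.finite(med)) {
            bad <- which(!is.na(areas[, side]) &
                         areas[, side] < areaFraction * med)
            if (length(bad)) posPx[bad, c("heel", "toe"), , side] <- NA
        }
        fl <- sqrt((posPx[, "toe", "x", side] - posPx[, "heel", "x", side])^2 +
                   (posPx[, "toe", "y", side] - posPx[, "heel", "y", side])^2)
        medL <- stats::median(fl, na.rm = TRUE)
        if (is.finite(medL)) {
            bad <- which(!is.na(fl) & abs(fl - medL) > 0.12 * medL)
            if (length(bad)) posPx[bad, c("heel", "toe"), , side] <- NA
        }
        for (lm in .LANDMARKS[1:3]) {
            medM <- stats::median(markAreas[, lm, side], na.rm = TRUE)
            if (!is.finite(medM)) next
            bad <- which(!is.na(markAreas[, lm, side]) &
                         markAreas[, lm, side] < 0.55 * medM)
            if (length(bad)) posPx[bad, lm, , side] <- NA
        }
    }
    .finalizeTracking(posPx, timestamps, scene, smoothCutoffHz, maxGap,
                      minValidFraction, walkDirection,
                      validFeetFraction = rawValid)
}

## shared tail of the tracking pipeline: quality gate, gap filling,
## smoothing, metric conversion
.finalizeTracking <- function(posPx, timestamps, scene, smoothCutoffHz,
                              maxGap, minValidFraction, walkDirection,
                              posM = NULL, validFeetFraction = NULL) {
    n <- dim(if (is.null(posM)) posPx else posM)[1]
    src <- if (is.null(posM)) posPx else posM
    if (is.null(validFeetFraction))
        validFeetFraction <- mean(vapply(seq_len(n), function(i) {
            !anyNA(src[i, c("heel", "toe"), , ])
        }, logical(1)))
    quality <- list(validFeetFraction = validFeetFraction,
                    nFrames = n)
    if (quality$validFeetFraction < minValidFraction)
        rejectTrial("feet_identification", sprintf(
            "only %.0f%% of frames have both feet identified (need %.0f%%): images not clear enough for correct identification of the feet",
            100 * quality$validFeetFraction, 100 * minValidFraction))
    if (is.null(posM)) {
        posM <- .emptyPosArray(n)
        for (lm in .LANDMARKS) for (side in .SIDES) {
            xy <- posPx[, lm, , side]
            posM[, lm, , side] <- .pxToWorld(scene, xy)
        }
    }
    missing <- array(FALSE, dim = c(n, 5L, 2L),
                     dimnames = list(NULL, .LANDMARKS, .SIDES))
    interpolated <- missing
    rawM <- posM
    for (lm in .LANDMARKS) for (side in .SIDES) {
        bad <- !stats::complete.cases(posM[, lm, , side])
        for (cc in 1:2) {
            v <- posM[, lm, cc, side]
            v[bad] <- NA_real_
            g <- .fillShortGaps(v, maxGap)
            rawM[, lm, cc, side] <- g$x
            v <- g$x
            if (!is.na(smoothCutoffHz))
                v <- .zeroLagLowpass(v, smoothCutoffHz, .FPS)
            posM[, lm, cc, side] <- v
        }
        interpolated[, lm, side] <- bad &
            stats::complete.cases(posM[, lm, , side])
        missing[, lm, side] <- !stats::complete.cases(posM[, lm, , side])
    }
    new("TrackedLandmarks", timestamps = timestamps, positionsM = posM,
        rawM = rawM,
        positionsPx = if (is.null(posPx)) .emptyPosArray(n) else posPx,
        missing = missing, interpolated = interpolated, quality = quality,
        walkDirection = walkDirection, smoothed = !is.na(smoothCutoffHz),
        fps = .FPS)
}

#' Convert a walker trajectory directly into tracked landmarks
#'
#' Bypasses rendering and segmentation: the (typically noisy) trajectory
#' positions are taken as the measured landmarks and passed through the
#' same gap-filling, smoothing and quality-gate steps as video tracking.
#' Dropout frames count as frames without valid feet, so heavily dropped
#' trials are rejected exactly like unclear video.
#'
#' @param traj a [WalkerTrajectory-class].
#' @inheritParams trackSequence
#' @return A [TrackedLandmarks-class].
#' @examples
#' tl <- asTrackedLandmarks(simulateTrial("normal", seed = 2))
#' trackingQuality(tl)$validFeetFraction
#' @export
asTrackedLandmarks <- function(traj, smoothCutoffHz = 6, maxGap = 5L,
                               minValidFraction = 0.8,
                               walkDirection = 1) {
    stopifnot(is(traj, "WalkerTrajectory"))
    pos <- traj@positions
    for (lm in .LANDMARKS) for (side in .SIDES) {
        bad <- traj@missing[, lm, side]
        if (any(bad)) pos[bad, lm, , side] <- NA_real_
    }
    .finalizeTracking(NULL, traj@timestamps, NULL, smoothCutoffHz, maxGap,
                      minValidFraction, walkDirection, posM = pos)
}

#' @describeIn trackSequence Accessor for the per-trial quality report.
#' @param tracked a `TrackedLandmarks` object.
#' @export
trackingQuality <- function(tracked) tracked@quality

#' @describeIn trackSequence Accessor for metric landmark positions
#'   (`[frame, landmark, coord, side]`, m).
#' @export
trackedPositions <- function(tracked) tracked@positionsM

setMethod("show", "TrackedLandmarks", function(object) {
    cat(sprintf(
        "TrackedLandmarks: %d frames | valid feet %.1f%% | smoothed: %s\n",
        length(object@timestamps),
        100 * object@quality$validFeetFraction,
        object@smoothed))
})

## frame sequence backed by PNG files on disk
.frameSequenceFromDir <- function(dir) {
    files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (!length(files)) stop("no frame_*.png files in ", dir)
    scene <- readSceneYaml(file.path(dir, "scene.yaml"))
    structure(list(files = files, scene = scene),
              class = "DiskFrameSequence")
}
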