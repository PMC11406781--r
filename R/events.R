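## Gait-event detection by the zero-velocity rule.
##
## Initial contact is the first instant at which either the heel or the toe
## becomes (near-)stationary: true zero velocity is unattainable on sampled,
## noisy derivatives, so "zero" is a planar-speed threshold (default
## 0.05 m/s) that must hold for a minimum dwell (default 3 frames at 30
## frames/s). Taking the earlier of heel and toe matters for toe-walkers,
## whose forefoot lands first. Toe-off is the first sustained rise of the
## toe speed after its stationary episode.

## planar marker speed by central differences (one-sided at the ends).
## Both coordinates matter: at contact and lift-off of toe-walkers the
## marker moves almost vertically, so a horizontal-only speed is blind to
## the instants the zero-velocity rule is after.
.markerSpeed <- function(xy, fps = .FPS) {
    n <- nrow(xy)
    v <- matrix(NA_real_, n, 2)
    if (n >= 3) v[2:(n - 1), ] <- (xy[3:n, ] - xy[1:(n - 2), ]) * fps / 2
    if (n >= 2) {
        v[1, ] <- (xy[2, ] - xy[1, ]) * fps
        v[n, ] <- (xy[n, ] - xy[n - 1, ]) * fps
    }
    sqrt(v[, 1]^2 + v[, 2]^2)
}

## runs of TRUE with length >= dwell: matrix with columns start, end
.lowSpeedRuns <- function(below, dwell) {
    below[is.na(below)] <- FALSE
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= dwell
    cbind(start = starts[keep], end = ends[keep])
}

#' Detect initial contacts from heel and toe trajectories
#'
#' For each contact episode, the initial contact is the earliest frame at
#' which the heel or the toe horizontal speed falls below `vThresh` and
#' stays below for at least `dwell` frames. Overlapping heel and toe
#' episodes are merged; the earlier onset wins.
#'
#' With `refine = TRUE` the detected frame is additionally snapped to the
#' first frame whose position lies within `posTol` of the episode's
#' stationary plateau, which removes the one-frame bias that a velocity
#' threshold introduces on noisy data.
#'
#' @param heel,toe `n x 2` matrices of (x, y) positions in m.
#' @param vThresh zero-velocity threshold in m/s.
#' @param dwell minimum number of consecutive frames below threshold.
#' @param fps frames per second.
#' @param refine logical; snap to the position plateau.
#' @param posTol plateau distance tolerance in m.
#' @param rawHeel,rawToe optional unsmoothed position matrices used for the
#'   plateau refinement (default: the inputs themselves).
#' @param minIcGap minimum frame separation between successive initial
#'   contacts of the same foot (same-foot contacts are at least a stride
#'   apart); closer detections keep only the earliest.
#' @return Sorted integer vector of initial-contact frames (possibly empty,
#'   with a warning).
#' @export
detectInitialContacts <- function(heel, toe, vThresh = 0.05, dwell = 3L,
                                  fps = .FPS, refine = TRUE,
                                  posTol = 0.0025, rawHeel = heel,
                                  rawToe = toe, minIcGap = 12L) {
    stopifnot(vThresh > 0, dwell >= 1)
    vh <- .markerSpeed(heel, fps)
    vt <- .markerSpeed(toe, fps)
    withMarker <- function(r, m)
        cbind(r, marker = rep(m, nrow(r)))
    runs <- rbind(withMarker(.lowSpeedRuns(vh < vThresh, dwell), 1L),
                  withMarker(.lowSpeedRuns(vt < vThresh, dwell), 2L))
    if (nrow(runs) == 0) {
        warning("no zero-velocity episode found; no initial contact detected")
        return(integer(0))
    }
    runs <- runs[order(runs[, "start"]), , drop = FALSE]
    ## merge overlapping (or nearly adjacent) heel/toe runs into contact
    ## episodes: a foot pivoting slowly about its anchored heel can split
    ## one stance into separate heel and toe runs a frame or two apart
    ics <- integer(0)
    epStart <- runs[1, "start"]; epEnd <- runs[1, "end"]
    epMarker <- runs[1, "marker"]
    flush <- function(s, e, m) {
        if (refine) {
            ## refine on the unsmoothed positions: a zero-lag filter smears
            ## the stop instant symmetrically, the raw plateau does not
            mk <- if (m == 1L) rawHeel else rawToe
            plateau <- c(stats::median(mk[s:e, 1]),
                         stats::median(mk[s:e, 2]))
            win <- max(1L, s - 8L):min(nrow(mk), s + 5L)
            d <- sqrt((mk[win, 1] - plateau[1])^2 +
                      (mk[win, 2] - plateau[2])^2)
            ## noise-adaptive tolerance: the larger of the within-run
            ## scatter and the marker's global frame-to-frame jitter (short
            ## fragmented runs underestimate the former), capped below the
            ## typical one-frame approach step
            dRun <- sqrt((mk[s:e, 1] - plateau[1])^2 +
                         (mk[s:e, 2] - plateau[2])^2)
            jit <- sqrt(sum(apply(mk, 2, function(x) {
                d2 <- diff(x, differences = 2)
                (stats::mad(d2[is.finite(d2)], center = 0) / sqrt(6))^2
            })))
            tolEff <- min(max(posTol, 3 * stats::mad(dRun, center = 0),
                              3 * jit), 0.02)
            ## sustained proximity: the marker must stay on the plateau,
            ## not merely graze it on the way in
            for (k in seq_along(d)) {
                k2 <- min(k + 1L, length(d))
                if (all(d[k:k2] < tolEff)) return(win[k])
            }
        }
        s
    }
    if (nrow(runs) > 1) {
        for (k in 2:nrow(runs)) {
            if (runs[k, "start"] <= epEnd + dwell) {
                epEnd <- max(epEnd, runs[k, "end"])
            } else {
                ics <- c(ics, flush(epStart, epEnd, epMarker))
                epStart <- runs[k, "start"]; epEnd <- runs[k, "end"]
                epMarker <- runs[k, "marker"]
            }
        }
    }
    ics <- c(ics, flush(epStart, epEnd, epMarker))
    ics <- sort(unique(as.integer(ics)))
    ## one initial contact per stance: noise can split a stationary episode
    ## into fragments; contacts of the same foot are at least a stride
    ## apart, so near-duplicates keep only the earliest instant
    if (length(ics) > 1) {
        keep <- ics[1]
        for (k in 2:length(ics))
            if (ics[k] - keep[length(keep)] >= minIcGap)
                keep <- c(keep, ics[k])
        ics <- keep
    }
    ics
}

#' Detect toe-offs following each initial contact
#'
#' Toe-off is the first frame after an initial contact at which the toe
#' speed rises above `vThresh` (after first having settled below it), stays
#' above for at least `dwell` frames, and accelerates to at least
#' `escapeFactor * vThresh` shortly after. The escape condition separates a
#' true lift-off, which accelerates into swing, from the slow pitching of a
#' foot rolling over its anchored heel.
#'
#' @param toe `n x 2` matrix of toe positions in m.
#' @param icFrames sorted initial-contact frames.
#' @param escapeFactor multiple of `vThresh` the speed must reach within
#'   `dwell + 2` frames of the candidate toe-off.
#' @inheritParams detectInitialContacts
#' @return Integer vector parallel to `icFrames`; `NA` marks an incomplete
#'   cycle in which the rule never fired.
#' @export
detectToeOffs <- function(toe, icFrames, vThresh = 0.05, dwell = 3L,
                          fps = .FPS, escapeFactor = 6) {
    stopifnot(length(icFrames) >= 1)
    v <- .markerSpeed(toe, fps)
    n <- length(v)
    vapply(seq_along(icFrames), function(k) {
        ic <- icFrames[k]
        lim <- if (k < length(icFrames)) icFrames[k + 1] - 1L else n
        settle <- ic
        while (settle <= lim && !(!is.na(v[settle]) && v[settle] < vThresh))
            settle <- settle + 1L
        if (settle > lim) return(NA_integer_)
        j <- settle
        while (j <= lim) {
            hi <- j:min(j + dwell - 1L, n)
            esc <- j:min(j + dwell + 1L, n)
            if (length(hi) == dwell &&
                all(!is.na(v[hi]) & v[hi] >= vThresh) &&
                max(v[esc], na.rm = TRUE) >= escapeFactor * vThresh)
                return(as.integer(j))
            j <- j + 1L
        }
        NA_integer_
    }, integer(1))
}

#' Assemble complete gait cycles from events
#'
#' Consecutive same-side initial-contact pairs with an interior toe-off form
#' complete cycles; pairs without one are dropped with a message.
#'
#' @param icFrames sorted initial-contact frames of one side.
#' @param toFrames sorted toe-off frames of the same side.
#' @return data.frame with columns `ic`, `to`, `nextIc`.
#' @examples
#' segmentCycles(c(10, 40, 70), c(28, 58))
#' @export
segmentCycles <- function(icFrames, toFrames) {
    icFrames <- sort(icFrames); toFrames <- sort(toFrames)
    out <- data.frame(ic = integer(), to = integer(), nextIc = integer())
    if (length(icFrames) < 2) return(out)
    dropped <- 0L
    for (k in seq_len(length(icFrames) - 1L)) {
        ic <- icFrames[k]; nic <- icFrames[k + 1L]
        inside <- toFrames[toFrames > ic & toFrames < nic]
        if (length(inside)) {
            out <- rbind(out, data.frame(ic = ic, to = inside[1],
                                         nextIc = nic))
        } else dropped <- dropped + 1L
    }
    if (dropped > 0)
        message(sprintf("dropped %d incomplete cycle(s) without toe-off",
                        dropped))
    out
}

#' Detect gait events for both sides of a trial
#'
#' Runs [detectInitialContacts()] and [detectToeOffs()] on the heel and toe
#' trajectories of each side and assembles complete cycles.
#'
#' @param x a [TrackedLandmarks-class] or [WalkerTrajectory-class].
#' @inheritParams detectInitialContacts
#' @return A [GaitEvents-class].
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' detectGaitEvents(traj)
#' @export
detectGaitEvents <- function(x, vThresh = 0.05, dwell = 3L, refine = TRUE,
                             posTol = 0.0025, eventCutoffHz = 3.5) {
    pos <- .positionArray(x)
    fps <- if (is(x, "TrackedLandmarks")) x@fps else x@fps
    ## adaptive event channel: if the stance-speed floor sits near the
    ## zero-velocity threshold (residual measurement noise), low-pass the
    ## heel/toe series harder before differentiation; clean trajectories
    ## (floor ~0) pass through untouched
    needFilter <- function(xy) {
        ## frame-to-frame jitter estimated from a low quantile of the
        ## second differences: clean motion has quiet stance stretches
        ## where the second difference is essentially zero, while white
        ## measurement noise lifts every frame
        lvl <- max(apply(xy, 2, function(x) {
            d2 <- abs(diff(x, differences = 2))
            stats::quantile(d2[is.finite(d2)], 0.2, names = FALSE)
        }))
        is.finite(lvl) && lvl > 0.0025
    }
    eventChannel <- function(xy) {
        if (is.na(eventCutoffHz) || !needFilter(xy)) return(xy)
        apply(xy, 2, .zeroLagLowpass, cutoffHz = eventCutoffHz, fps = fps)
    }
    ## the event channel starts from the unsmoothed positions: the zero-lag
    ## trajectory filter blurs short stationary episodes; residual noise is
    ## handled by the adaptive filter and threshold below
    raw <- if (is(x, "TrackedLandmarks") && length(dim(x@rawM)) == 4)
        x@rawM else pos
    ic <- list(); to <- list(); cycles <- NULL
    for (side in .SIDES) {
        heel <- eventChannel(raw[, "heel", , side])
        toe <- eventChannel(raw[, "toe", , side])
        ## adaptive threshold: stay clear of the residual noise floor
        floorV <- stats::quantile(c(.markerSpeed(heel, fps),
                                    .markerSpeed(toe, fps)),
                                  0.1, na.rm = TRUE, names = FALSE)
        vEff <- if (is.finite(floorV) && floorV > 0.5 * vThresh)
            max(vThresh, 2.2 * floorV) else vThresh
        ics <- detectInitialContacts(heel, toe, vEff, dwell, fps,
                                     refine, posTol,
                                     rawHeel = raw[, "heel", , side],
                                     rawToe = raw[, "toe", , side])
        tos <- if (length(ics))
            detectToeOffs(toe, ics, vEff, dwell, fps,
                          escapeFactor = 6 * vThresh / vEff)
        else integer(0)
        ic[[side]] <- ics
        to[[side]] <- sort(tos[!is.na(tos)])
        cyc <- segmentCycles(ics, to[[side]])
        if (nrow(cyc))
            cycles <- rbind(cycles, cbind(side = side, cyc))
    }
    if (is.null(cycles))
        cycles <- data.frame(side = character(), ic = integer(),
                             to = integer(), nextIc = integer())
    ## plausibility: within a steady-state trial, cycle durations cluster
    ## tightly; a cycle whose length is far from the trial median points to
    ## a missed or misplaced contact and is dropped
    if (nrow(cycles) >= 3) {
        len <- cycles$nextIc - cycles$ic
        med <- stats::median(len)
        bad <- len < 0.8 * med | len > 1.2 * med
        if (any(bad)) {
            message(sprintf("dropped %d cycle(s) with implausible duration",
                            sum(bad)))
            cycles <- cycles[!bad, , drop = FALSE]
        }
    }
    new("GaitEvents", ic = ic, to = to, cycles = cycles,
        params = list(vThresh = vThresh, dwell = dwell, refine = refine,
                      posTol = posTol))
}

#' @describeIn detectGaitEvents Accessor for event frames of one side.
#' @param events a `GaitEvents` object.
#' @param side `"left"` or `"right"`.
#' @param type `"ic"` or `"to"`.
#' @export
eventFrames <- function(events, side = c("right", "left"),
                        type = c("ic", "to")) {
    side <- match.arg(side); type <- match.arg(type)
    slot(events, type)[[side]]
}

#' @describeIn detectGaitEvents Accessor for the complete-cycle table.
#' @export
gaitCycles <- function(events) events@cycles

setMethod("show", "GaitEvents", function(object) {
    cat(sprintf(
        "GaitEvents: %d IC / %d TO (left), %d IC / %d TO (right), %d complete cycles\n",
        length(object@ic$left), length(object@to$left),
        length(object@ic$right), length(object@to$right),
        nrow(object@cycles)))
})
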