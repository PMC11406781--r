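## Forward kinematics of the sagittal walker.
##
## Angle conventions (degrees):
##   hip   : femur (trochanter -> epicondyle) measured from the downward
##           vertical, positive when the knee is forward of the hip.
##   knee  : hip angle minus tibia angle (tibia = epicondyle -> malleolus,
##           same convention); 0 = full extension, flexion positive.
##   ankle : foot axis angle (heel -> toe, from the horizontal, CCW
##           positive) minus tibia angle; 0 = foot perpendicular to tibia,
##           dorsiflexion positive.
##   foot orientation: heel-up positive = minus the foot-axis angle.
##
## The trochanter path is obtained by anchoring the stance-foot contact
## point to the ground: for heel-strike patterns the heel is anchored from
## initial contact to heel rise (0-40% of the cycle) and the toe during the
## third rocker (40-50%); for toe-walking patterns the toe is anchored over
## 0-50%. At 50% the contralateral initial contact takes over. Anchor
## constants are chained so the trochanter path is continuous.

.deg2rad <- pi / 180

## relative (trochanter-at-origin) landmark positions for given curve phases
## pct: vector of phases in percent. Returns list of 2-col matrices.
.relPositions <- function(curves, anthro, pct) {
    hip <- .curveAt(curves[, "hip"], pct) * .deg2rad
    knee <- .curveAt(curves[, "knee"], pct) * .deg2rad
    ankle <- .curveAt(curves[, "ankle"], pct) * .deg2rad
    thetaT <- hip - knee
    phi <- thetaT + ankle            # foot axis angle from +x
    epi <- cbind(anthro@thighLength * sin(hip),
                 -anthro@thighLength * cos(hip))
    mall <- epi + cbind(anthro@shankLength * sin(thetaT),
                        -anthro@shankLength * cos(thetaT))
    fdir <- cbind(cos(phi), sin(phi))
    heel <- mall - anthro@heelOffset * fdir
    toe <- heel + anthro@footLength * fdir
    list(trochanter = cbind(0 * hip, 0 * hip), epicondyle = epi,
         malleolus = mall, heel = heel, toe = toe)
}

## phase (percent) of a side at time t (frames); right starts its cycle at
## t = 0, left half a cycle later
.phaseAt <- function(t, side, cf) {
    off <- if (side == "left") cf / 2 else 0
    ((t - off) %% cf) / cf * 100
}

## anchor interval table for a trial of nCycles cycles per side
.anchorTable <- function(cf, nCycles, toeContact) {
    ics <- data.frame(
        side = rep(c("right", "left"), each = nCycles + 1L),
        start = c((0:nCycles) * cf, (0:nCycles) * cf + cf / 2))
    ics <- ics[order(ics$start), ]
    rows <- lapply(seq_len(nrow(ics)), function(i) {
        s <- ics$start[i]; side <- ics$side[i]
        if (toeContact)
            data.frame(side = side, point = "toe", start = s,
                       end = s + 0.5 * cf, primary = TRUE)
        else
            rbind(data.frame(side = side, point = "heel", start = s,
                             end = s + 0.4 * cf, primary = TRUE),
                  data.frame(side = side, point = "toe",
                             start = s + 0.4 * cf, end = s + 0.5 * cf,
                             primary = FALSE))
    })
    do.call(rbind, rows)
}

## x of one landmark of one side, relative to trochanter, at real times t
.relXAt <- function(curves, anthro, t, side, point, cf) {
    pct <- .phaseAt(t, side, cf)
    .relPositions(curves, anthro, pct)[[point]][, 1]
}
.relYAt <- function(curves, anthro, t, side, point, cf) {
    pct <- .phaseAt(t, side, cf)
    .relPositions(curves, anthro, pct)[[point]][, 2]
}

## chain anchor constants so the trochanter path is continuous in x and y;
## first contact sits at (0, 0)
.anchorConstants <- function(curves, anthro, anchors, cf) {
    nr <- nrow(anchors)
    ax <- ay <- numeric(nr)
    for (k in seq_len(nr)[-1]) {
        s <- anchors$start[k]
        prevX <- ax[k - 1] -
            .relXAt(curves, anthro, s, anchors$side[k - 1],
                    anchors$point[k - 1], cf)
        prevY <- ay[k - 1] -
            .relYAt(curves, anthro, s, anchors$side[k - 1],
                    anchors$point[k - 1], cf)
        ax[k] <- prevX +
            .relXAt(curves, anthro, s, anchors$side[k], anchors$point[k], cf)
        ay[k] <- prevY +
            .relYAt(curves, anthro, s, anchors$side[k], anchors$point[k], cf)
    }
    anchors$ax <- ax
    anchors$ay <- ay
    anchors
}

## core simulator: positions of all landmarks at the frame grid
.fkCore <- function(curves, anthro, cf, nCycles, toeContact) {
    n <- as.integer(nCycles * cf + cf / 2 + 1L)
    tFrames <- 0:(n - 1L)
    anchors <- .anchorConstants(curves, anthro,
                                .anchorTable(cf, nCycles, toeContact), cf)
    TT <- .trochAt(curves, anthro, anchors, tFrames, cf)
    Tx <- TT[, 1]; Ty <- TT[, 2]
    pos <- array(NA_real_, dim = c(n, 5L, 2L, 2L),
                 dimnames = list(NULL, .LANDMARKS, c("x", "y"), .SIDES))
    for (side in .SIDES) {
        rel <- .relPositions(curves, anthro, .phaseAt(tFrames, side, cf))
        for (lm in .LANDMARKS) {
            pos[, lm, "x", side] <- rel[[lm]][, 1] + Tx
            pos[, lm, "y", side] <- rel[[lm]][, 2] + Ty
        }
    }
    ## ground-truth events (1-based frames)
    ev <- do.call(rbind, lapply(.SIDES, function(side) {
        off <- if (side == "left") cf / 2 else 0
        ics <- off + (0:nCycles) * cf
        ics <- ics[ics <= n - 1L]
        complete <- ics[ics + cf <= n - 1L]
        data.frame(side = side, ic = as.integer(complete) + 1L,
                   to = as.integer(complete + cf %/% 2L) + 1L,
                   nextIc = as.integer(complete + cf) + 1L)
    }))
    flat <- data.frame(side = character(), start = integer(),
                       end = integer())
    if (!toeContact) {
        prim <- anchors[anchors$primary, ]
        flat <- data.frame(
            side = prim$side,
            start = as.integer(ceiling(prim$start + 0.1 * cf)) + 1L,
            end = as.integer(ceiling(prim$start + 0.4 * cf)) + 1L - 1L)
        flat <- flat[flat$end <= n, ]
    }
    prim <- anchors[anchors$primary, ]
    steps <- diff(prim$ax)
    list(n = n, timestamps = tFrames / .FPS, positions = pos, events = ev,
         footFlat = flat, steps = steps, anchors = anchors)
}

.isToeContact <- function(curves) {
    ## heel-up orientation at initial contact implies forefoot contact
    orient0 <- -(curves[1, "hip"] - curves[1, "knee"] + curves[1, "ankle"])
    orient0 > 0
}

## toe-walking patterns land on the forefoot; the anchor schedule follows
## the pattern rather than the (calibration-shifted) curve sign
.TOE_CONTACT <- c(normal = FALSE, true_equinus = TRUE, jump = TRUE,
                  apparent_equinus = TRUE, crouch = FALSE,
                  hyperextension = FALSE, short_hamstring = FALSE)

.contactIsToe <- function(pattern, curves = NULL) {
    if (is(pattern, "GaitPattern") &&
        pattern@patternName %in% names(.TOE_CONTACT))
        return(unname(.TOE_CONTACT[pattern@patternName]))
    if (!is.null(curves)) return(.isToeContact(curves))
    FALSE
}

## Joint calibration of the walking curves: a hip-excursion scale factor m
## drives the realized step length to the pattern target, while a smooth
## late-stance knee bump (plus, for toe-walkers, a contact-side ankle bump)
## zeroes the per-cycle vertical drift of the chained footfall anchors.
## Both residuals are solved together with a damped 2x2 Newton iteration.
.walkBumps <- function() {
    p <- 0:100
    ## wide late-stance bump (38-62%), used for toe-walkers
    bumpLate <- ifelse(p >= 38 & p <= 62,
                       0.5 * (1 - cos(2 * pi * (p - 38) / 24)), 0)
    ## narrow pre-swing bump (44-58%), peak at the contact handoff; only
    ## touches the trailing limb right at toe-off
    bumpMid <- ifelse(p >= 44 & p <= 58,
                      0.5 * (1 - cos(2 * pi * (p - 44) / 14)), 0)
    ## contact-side bump (periodic, peak at 0%)
    dWrap <- pmin(p, 100 - p)
    bumpIC <- ifelse(dWrap <= 12, 0.5 * (1 + cos(pi * dWrap / 12)), 0)
    list(late = bumpLate, mid = bumpMid, ic = bumpIC)
}

.applyWalkParams <- function(curves, m, cc, toeContact, bumps) {
    mh <- mean(curves[1:100, "hip"])
    curves[, "hip"] <- mh + m * (curves[, "hip"] - mh)
    if (toeContact) {
        curves[, "knee"] <- curves[, "knee"] + 0.5 * cc * bumps$late
        curves[, "ankle"] <- curves[, "ankle"] - 0.5 * cc * bumps$ic
    } else {
        ## pre-swing knee flexion and ankle dorsiflexion together: raises
        ## the trailing ankle without pitching the toe into the ground
        curves[, "knee"] <- curves[, "knee"] + cc * bumps$mid
        curves[, "ankle"] <- curves[, "ankle"] + cc * bumps$mid
    }
    curves
}

.calibrateWalk <- function(curves, anthro, pattern, toeContact,
                           stepTol = 0.005, driftTol = 7e-4,
                           maxIter = 12L) {
    cf <- as.integer(round(pattern@cycleDuration * .FPS))
    target <- pattern@stepLengthTarget
    bumps <- .walkBumps()
    rpc <- if (toeContact) 2L else 4L
    resid <- function(par) {
        cv <- .applyWalkParams(curves, par[1], par[2], toeContact, bumps)
        fk <- .fkCore(cv, anthro, cf, 2L, toeContact)
        an <- fk$anchors
        c(step = mean(fk$steps) - target,
          drift = an$ay[1L + rpc] - an$ay[1L])
    }
    par <- c(1, 0)
    r <- resid(par)
    for (it in seq_len(maxIter)) {
        if (abs(r[1]) < stepTol * target && abs(r[2]) < driftTol) break
        ## finite-difference Jacobian
        dm <- 0.05; dc <- 1
        rm <- resid(par + c(dm, 0))
        rc <- resid(par + c(0, dc))
        J <- cbind((rm - r) / dm, (rc - r) / dc)
        step <- tryCatch(solve(J, -r), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        ## damp and clamp the update
        step <- pmax(pmin(step, c(0.4, 8)), c(-0.4, -8))
        par <- par + 0.8 * step
        par[1] <- max(0.3, min(2.5, par[1]))
        par[2] <- max(-35, min(35, par[2]))
        r <- resid(par)
    }
    .applyWalkParams(curves, par[1], par[2], toeContact, bumps)
}

## landing crispness: the zero-velocity rule needs a distinct stop, so the
## contact marker must arrive with a clear approach speed. Patterns whose
## terminal swing "parks" the foot early (soft landing) get a small
## late-swing ankle adjustment, zero at the wrap and at every anchor
## handoff phase, until the last pre-contact step is fast enough.
.landingSpeed <- function(curves, anthro, cf, toeContact) {
    fk <- .fkCore(curves, anthro, cf, 2L, toeContact)
    lm <- if (toeContact) "toe" else "heel"
    p <- fk$positions[, lm, , "right"]
    i <- 2L * cf + 1L                 # third right IC, 1-based
    sqrt(sum((p[i, ] - p[i - 1L, ])^2)) * .FPS
}

.calibrateLandingSpeed <- function(curves, anthro, pattern, toeContact,
                                   vFloor = 0.6, vTarget = 0.9) {
    cf <- as.integer(round(pattern@cycleDuration * .FPS))
    if (.landingSpeed(curves, anthro, cf, toeContact) >= vFloor)
        return(curves)
    p <- 0:100
    bump <- ifelse(p >= 86 & p <= 99.5,
                   0.5 * (1 - cos(2 * pi * (p - 86) / 13.5)), 0)
    vFor <- function(a) {
        cv <- curves
        cv[, "ankle"] <- cv[, "ankle"] + a * bump
        .landingSpeed(cv, anthro, cf, toeContact)
    }
    a1 <- 0; v1 <- vFor(a1)
    a2 <- 5; best <- a2
    for (it in 1:8) {
        v2 <- vFor(a2)
        best <- a2
        if (abs(v2 - vTarget) < 0.1) break
        slope <- (v2 - v1) / (a2 - a1)
        if (!is.finite(slope) || abs(slope) < 1e-6) break
        aNew <- max(-15, min(15, a2 + (vTarget - v2) / slope))
        a1 <- a2; v1 <- v2; a2 <- aNew
        if (abs(a2 - a1) < 1e-3) { best <- a2; break }
    }
    curves[, "ankle"] <- curves[, "ankle"] + best * bump
    curves
}

## evaluate the trochanter position at arbitrary real times given an
## anchor table with chained constants
.trochAt <- function(curves, anthro, anchors, t, cf) {
    k <- findInterval(t, anchors$start)
    k[k < 1L] <- 1L
    Tx <- Ty <- numeric(length(t))
    for (kk in unique(k)) {
        sel <- k == kk
        Tx[sel] <- anchors$ax[kk] -
            .relXAt(curves, anthro, t[sel], anchors$side[kk],
                    anchors$point[kk], cf)
        Ty[sel] <- anchors$ay[kk] -
            .relYAt(curves, anthro, t[sel], anchors$side[kk],
                    anchors$point[kk], cf)
    }
    cbind(Tx, Ty)
}

## vertical footfall consistency: the chained anchor constants must not
## drift up- or downhill cycle over cycle. The per-cycle drift is removed

#' Simulate a walker trajectory from joint-angle curves
#'
#' Runs the forward kinematics of the sagittal walker: landmark positions are
#' built from the angle curves under the package's angle conventions, with
#' the stance-foot contact point anchored to the ground (the heel is exactly
#' stationary during every labelled foot-flat interval). Ground-truth initial
#' contacts and toe-offs are taken from the construction schedule.
#'
#' @param curves a `101 x 3+` matrix of hip/knee/ankle curves as returned by
#'   [generateJointCurves()].
#' @param anthro an [Anthropometry-class].
#' @param pattern the [GaitPattern-class] the curves realize (supplies the
#'   cycle duration and noise model).
#' @param nCycles number of gait cycles per side (>= 1).
#' @param walkwayLength usable walkway length in m; if the requested walk
#'   would overrun it, the trial is truncated with a warning.
#' @return A noise-free [WalkerTrajectory-class].
#' @examples
#' pat <- gaitPattern("normal")
#' traj <- forwardKinematics(generateJointCurves(pat), pattern = pat)
#' dim(trajectoryPositions(traj))
#' @export
forwardKinematics <- function(curves, anthro = anthropometryFromStature(),
                              pattern, nCycles = 3L, walkwayLength = 7) {
    stopifnot(nCycles >= 1L, is(pattern, "GaitPattern"))
    cf <- as.integer(round(pattern@cycleDuration * .FPS))
    toeContact <- .contactIsToe(pattern, curves)
    fk <- .fkCore(curves, anthro, cf, as.integer(nCycles), toeContact)
    span <- max(fk$anchors$ax) - min(fk$anchors$ax) +
        anthro@footLength
    if (span > walkwayLength) {
        fit <- floor((walkwayLength - anthro@footLength -
                      mean(fk$steps)) / (2 * mean(fk$steps)))
        newCycles <- max(1L, as.integer(fit))
        warning(sprintf(
            "requested walk of %.2f m exceeds the %.1f m walkway; truncating from %d to %d cycles",
            span, walkwayLength, nCycles, newCycles))
        nCycles <- newCycles
        fk <- .fkCore(curves, anthro, cf, nCycles, toeContact)
    }
    foot <- -(curves[, "hip"] - curves[, "knee"] + curves[, "ankle"])
    tc <- cbind(curves[, c("hip", "knee", "ankle")], foot = foot)
    trueCurves <- list(left = tc, right = tc,
                       toeoffPct = 50,
                       stepLength = mean(fk$steps))
    miss <- array(FALSE, dim = c(fk$n, 5L, 2L),
                  dimnames = list(NULL, .LANDMARKS, .SIDES))
    new("WalkerTrajectory", timestamps = fk$timestamps,
        positions = fk$positions, missing = miss,
        trueEvents = fk$events, footFlat = fk$footFlat,
        trueCurves = trueCurves, pattern = pattern, anthropometry = anthro,
        fps = .FPS)
}

#' Add measurement noise to a trajectory
#'
#' Adds i.i.d. Gaussian jitter to every landmark coordinate of every frame
#' and flags whole frames as missing with the given dropout probability.
#' The RNG state of the session is left untouched; the result is a
#' deterministic function of `seed`.
#'
#' @param traj a [WalkerTrajectory-class].
#' @param sd jitter standard deviation in m (default: the trajectory
#'   pattern's `noiseSd`).
#' @param dropout per-frame dropout probability (default: the pattern's).
#' @param seed integer seed (default: the pattern's).
#' @return A [WalkerTrajectory-class] with perturbed positions.
#' @examples
#' pat <- gaitPattern("normal", seed = 3)
#' noisy <- addNoise(forwardKinematics(generateJointCurves(pat),
#'                                     pattern = pat))
#' @export
addNoise <- function(traj, sd = traj@pattern@noiseSd,
                     dropout = traj@pattern@dropout,
                     seed = traj@pattern@seed) {
    stopifnot(is(traj, "WalkerTrajectory"))
    if (sd < 0) stop("noise SD must be >= 0")
    if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
    pos <- traj@positions
    miss <- traj@missing
    n <- dim(pos)[1]
    runWithSeed(seed, {
        if (sd > 0)
            pos <- pos + array(stats::rnorm(length(pos), 0, sd), dim(pos))
        if (dropout > 0) {
            drop <- stats::runif(n) < dropout
            if (any(drop)) {
                pos[drop, , , ] <- NA_real_
                miss[drop, , ] <- TRUE
            }
        }
    })
    out <- traj
    out@positions <- pos
    out@missing <- miss
    out
}

#' Evaluate code with a fixed RNG seed, restoring the RNG state afterwards
#'
#' @param seed integer seed.
#' @param expr expression to evaluate in the caller's environment.
#' @return The value of `expr`, invisibly.
#' @keywords internal
#' @export
runWithSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    invisible(eval(substitute(expr), envir = parent.frame()))
}

#' Simulate a complete trial for a pattern
#'
#' Convenience wrapper: generates the pattern's joint curves, runs the
#' forward kinematics and applies the pattern's noise model.
#'
#' @param pattern a [GaitPattern-class] or a pattern name.
#' @param nCycles gait cycles per side.
#' @param anthro an [Anthropometry-class].
#' @param noise logical; apply the pattern's noise model.
#' @param seed optional seed overriding the pattern's.
#' @return A [WalkerTrajectory-class].
#' @examples
#' traj <- simulateTrial("normal", seed = 11)
#' @export
simulateTrial <- function(pattern, nCycles = 3L,
                          anthro = anthropometryFromStature(),
                          noise = TRUE, seed = NULL) {
    if (is.character(pattern)) pattern <- gaitPattern(pattern)
    if (!is.null(seed)) pattern@seed <- as.integer(seed)
    curves <- generateJointCurves(pattern, anthro)
    traj <- forwardKinematics(curves, anthro, pattern, nCycles)
    if (noise && (pattern@noiseSd > 0 || pattern@dropout > 0))
        traj <- addNoise(traj)
    traj
}

#' @describeIn forwardKinematics Accessor for the landmark position array
#'   (`[frame, landmark, coord, side]`, m).
#' @param traj a `WalkerTrajectory`.
#' @export
trajectoryPositions <- function(traj) traj@positions

#' @describeIn forwardKinematics Accessor for the ground-truth event table
#'   (columns `side`, `ic`, `to`, `nextIc`; 1-based frames).
#' @export
trueEvents <- function(traj) traj@trueEvents

#' @describeIn forwardKinematics Accessor for the realized per-cycle angle
#'   curves (list with `left`/`right` 101 x 4 matrices).
#' @export
trueCurves <- function(traj) traj@trueCurves

setMethod("show", "WalkerTrajectory", function(object) {
    n <- dim(object@positions)[1]
    cat(sprintf(
        "WalkerTrajectory: %d frames (%.2f s) | pattern %s | %d true cycles\n",
        n, n / object@fps, object@pattern@patternName,
        nrow(object@trueEvents)))
})
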