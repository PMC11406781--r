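## A hand-built tracked object: two markers stepping forward at known
## positions, for arithmetic-level checks.
syntheticTracked <- function(n = 160, speed = 0.7) {
    pos <- MLGait:::.emptyPosArray(n)
    t <- (0:(n - 1)) / 30
    for (side in c("left", "right")) {
        pos[, "trochanter", "x", side] <- speed * t
        pos[, "trochanter", "y", side] <- 0.6
        pos[, "heel", "x", side] <- speed * t
        pos[, "heel", "y", side] <- 0.05
        pos[, "toe", "x", side] <- speed * t + 0.2
        pos[, "toe", "y", side] <- 0.05
        pos[, "epicondyle", , side] <- cbind(speed * t, 0.35)
        pos[, "malleolus", , side] <- cbind(speed * t, 0.1)
    }
    MLGait:::.finalizeTracking(NULL, t, NULL, NA, 5L, 0, 1, posM = pos)
}

refEventsFor <- function(ic, side) {
    ref <- list(left = integer(0), right = integer(0))
    for (k in seq_along(ic)) ref[[side[k]]] <- c(ref[[side[k]]], ic[k])
    MLGait:::.asReferenceEvents(ref)
}

test_that("step length is the heel-to-heel distance at the two contacts", {
    tl <- syntheticTracked()
    ## foreground (right) IC at frame 31 (x = 0.7 m), background at frame 47
    ev <- refEventsFor(c(31L, 47L), c("right", "left"))
    sl <- stepLengths(tl, ev, foregroundSide = "right")
    expect_equal(sl, 0.7 * (46 / 30) - 0.7 * (30 / 30), tolerance = 1e-9)
    ## reversed order (background first) yields no pair
    ev2 <- refEventsFor(c(31L, 20L), c("right", "left"))
    expect_warning(out <- stepLengths(tl, ev2), "no qualifying")
    expect_length(out, 0)
})

test_that("gait speed is displacement over time between bounding contacts", {
    tl <- syntheticTracked(speed = 0.7)
    ev <- refEventsFor(c(1L, 151L), c("right", "right"))
    expect_equal(gaitSpeed(tl, ev), 0.7, tolerance = 1e-9)
    expect_error(gaitSpeed(tl, refEventsFor(10L, "right")), "two initial")
    ## stationary walker: zero speed with a warning
    still <- syntheticTracked(speed = 0)
    expect_warning(v <- gaitSpeed(still, ev), "degenerate")
    expect_equal(v, 0)
})

test_that("identical event sets give exactly zero reference error", {
    traj <- fixtureTrajectory("normal")
    tl <- asTrackedLandmarks(traj)
    ev <- suppressMessages(detectGaitEvents(tl))
    err <- manualReferenceCompare(tl, ev, ev)
    expect_equal(err$speedAbsErr, 0)
    expect_equal(err$stepAbsErr, 0)
})

test_that("one-frame IC shifts stay within the one-frame travel bound", {
    traj <- fixtureTrajectory("normal")
    tl <- asTrackedLandmarks(traj)
    ev <- suppressMessages(detectGaitEvents(tl))
    shifted <- ev
    for (side in c("left", "right"))
        shifted@ic[[side]] <- pmin(ev@ic[[side]] + 1L,
                                   length(traj@timestamps))
    err <- manualReferenceCompare(tl, ev, shifted)
    v <- gaitSpeed(tl, ev)
    expect_gt(err$speedAbsErr + err$stepAbsErr, 0)
    expect_lt(err$stepAbsErr, v / 30 + 1e-9)
})

test_that("step lengths ignore time shifts and speed ignores translation", {
    tl <- syntheticTracked()
    ev <- refEventsFor(c(31L, 47L, 61L), c("right", "left", "right"))
    sl0 <- stepLengths(tl, ev)
    tlShift <- tl
    tlShift@timestamps <- tl@timestamps + 100
    expect_equal(stepLengths(tlShift, ev), sl0)
    tlTrans <- tl
    tlTrans@positionsM <- tl@positionsM + 3.2
    expect_equal(gaitSpeed(tlTrans, ev), gaitSpeed(tl, ev))
})

test_that("speed scales with the playback rate", {
    tl <- syntheticTracked()
    ev <- refEventsFor(c(1L, 151L), c("right", "right"))
    fast <- tl
    fast@timestamps <- tl@timestamps / 2   # played twice as fast
    expect_equal(gaitSpeed(fast, ev), 2 * gaitSpeed(tl, ev),
                 tolerance = 1e-9)
})

test_that("automatic spatio-temporal errors stay small on simulated trials", {
    errs <- NULL
    pats <- rep(allPatterns(), 2)[1:8]
    for (k in seq_along(pats)) {
        traj <- simulateTrial(pats[k], seed = 200 + k)
        tl <- asTrackedLandmarks(traj)
        ev <- suppressMessages(detectGaitEvents(tl))
        errs <- rbind(errs, manualReferenceCompare(tl, ev, trueEvents(traj)))
    }
    agg <- aggregateErrors(errs)
    expect_lt(agg$mean[agg$metric == "speedAbsErr"], 0.005)
    expect_lt(agg$mean[agg$metric == "stepAbsErr"], 0.015)
})

test_that("cohort aggregation reproduces the reference cohort summaries", {
    tab <- cohortTable(referenceCohort()[c("gaitSpeed", "stepLength")])
    expect_equal(round(tab["mean", "gaitSpeed"], 2), 0.69)
    expect_equal(round(tab["mean", "stepLength"], 2), 0.37)
    expect_equal(tab["max", "gaitSpeed"], 0.91)
    expect_equal(tab["min", "gaitSpeed"], 0.12)
    expect_equal(round(tab["sd", "gaitSpeed"], 2), 0.22)
})

test_that("degenerate cohort aggregates are flagged", {
    one <- cohortTable(data.frame(gaitSpeed = 0.7))
    expect_true(is.na(one["sd", "gaitSpeed"]))
    expect_equal(one["min", "gaitSpeed"], one["max", "gaitSpeed"])
    expect_true(attr(one, "sdUndefined"))
    expect_error(cohortTable(data.frame()), "empty")
})
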