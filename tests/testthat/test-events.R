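test_that("the zero-velocity rule never fires on a constantly moving marker", {
    n <- 60
    heel <- cbind(seq(0, 2, length.out = n), 0.05)
    toe <- cbind(seq(0.2, 2.2, length.out = n), 0.05)
    expect_warning(ics <- detectInitialContacts(heel, toe), "no zero-velocity")
    expect_length(ics, 0)
})

test_that("a marker stationary for the whole trial gives one IC at frame 1", {
    n <- 60
    heel <- cbind(rep(1, n), 0.05)
    toe <- cbind(rep(1.2, n), 0.05)
    ics <- detectInitialContacts(heel, toe)
    expect_identical(ics, 1L)
})

test_that("noise-free detection recovers every IC within one frame", {
    for (pattern in allPatterns()) {
        traj <- fixtureTrajectory(pattern)
        ev <- suppressMessages(detectGaitEvents(traj))
        te <- trueEvents(traj)
        for (side in c("left", "right")) {
            det <- eventFrames(ev, side, "ic")
            for (ic in te$ic[te$side == side])
                expect_lte(min(abs(det - ic)), 1)
        }
    }
})

test_that("noise-free toe-offs land within two frames of the schedule", {
    for (pattern in allPatterns()) {
        traj <- fixtureTrajectory(pattern)
        ev <- suppressMessages(detectGaitEvents(traj))
        te <- trueEvents(traj)
        for (side in c("left", "right")) {
            det <- eventFrames(ev, side, "to")
            expect_gt(length(det), 0)
            for (to in te$to[te$side == side])
                expect_lte(min(abs(det - to)), 2)
        }
    }
})

test_that("detected toe-off sits at about half the cycle", {
    ## the simulated walker has no double-support phase, so its stance
    ## fraction is 50% rather than the physiological ~60%
    res <- fixtureAnalysis("normal")
    cyc <- normalizedCycles(res$kinematics, "right")
    expect_true(all(abs(cyc$toeoffPct - 50) <= 5))
})

test_that("a permanently stationary toe marks the cycle incomplete", {
    n <- 80
    toe <- cbind(rep(1, n), 0)
    tos <- detectToeOffs(toe, icFrames = c(10L, 40L))
    expect_true(all(is.na(tos)))
})

test_that("raising the threshold never loses initial contacts", {
    traj <- fixtureTrajectory("normal")
    pos <- trajectoryPositions(traj)
    heel <- pos[, "heel", , "right"]
    toe <- pos[, "toe", , "right"]
    counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5), function(v)
        length(suppressWarnings(
            detectInitialContacts(heel, toe, vThresh = v, refine = FALSE))),
        0L)
    expect_true(all(diff(counts) >= 0))
})

test_that("event detection is deterministic", {
    traj <- fixtureTrajectory("crouch")
    e1 <- suppressMessages(detectGaitEvents(traj))
    e2 <- suppressMessages(detectGaitEvents(traj))
    expect_identical(e1@ic, e2@ic)
    expect_identical(e1@to, e2@to)
})

test_that("cycle segmentation follows the definition", {
    cyc <- segmentCycles(c(10, 40, 70), c(28, 58))
    expect_equal(cyc$ic, c(10, 40))
    expect_equal(cyc$to, c(28, 58))
    expect_equal(cyc$nextIc, c(40, 70))
    expect_equal(nrow(suppressMessages(segmentCycles(c(10, 40), numeric(0)))),
                 0L)
})

test_that("a four-cycle trial yields at least two cycles per side", {
    pat <- gaitPattern("normal", noiseSd = 0)
    traj <- simulateTrial(pat, nCycles = 4L, noise = FALSE)
    ev <- suppressMessages(detectGaitEvents(traj))
    cyc <- gaitCycles(ev)
    for (side in c("left", "right"))
        expect_gte(sum(cyc$side == side), 2)
    ## every complete cycle is ordered
    expect_true(all(cyc$ic < cyc$to & cyc$to < cyc$nextIc))
})
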