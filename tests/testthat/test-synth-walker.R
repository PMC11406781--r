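test_that("curve templates have the expected clinical shape", {
    normal <- fixtureCurves("normal")
    expect_equal(dim(normal), c(101L, 4L))
    ## knee range of motion around 60 degrees
    expect_gt(diff(range(normal[, "knee"])), 55)
    expect_lt(diff(range(normal[, "knee"])), 65)
    ## near-zero ankle angle in midstance
    expect_lt(abs(normal[26, "ankle"]), 6)
    ## first derivative continuous across the wrap
    for (j in c("hip", "knee", "ankle"))
        expect_lt(abs((normal[2, j] - normal[1, j]) -
                      (normal[101, j] - normal[100, j])), 0.75)
})

test_that("true equinus keeps the ankle in plantarflexion throughout", {
    eq <- fixtureCurves("true_equinus")
    expect_lt(max(eq[, "ankle"]), 0)
    ## heel-up foot orientation during stance (toe-walking)
    expect_gt(mean(eq[11:31, "foot"]), 10)
})

test_that("zero offsets reproduce the normal template exactly", {
    pat <- gaitPattern("normal")
    zero <- gaitPattern("crouch")   # any pattern name
    zero@angleOffsets <- list(hip = rep(0, 101), knee = rep(0, 101),
                              ankle = rep(0, 101))
    zero@cycleDuration <- pat@cycleDuration
    zero@stepLengthTarget <- pat@stepLengthTarget
    ## the contact schedule is part of the pattern, so compare through the
    ## same heel-contact geometry
    zero@patternName <- "normal"
    expect_equal(generateJointCurves(zero), generateJointCurves(pat))
})

test_that("unknown pattern names are rejected with the valid choices", {
    expect_error(gaitPattern("moonwalk"), "normal")
})

test_that("forward kinematics closes the loop with the angle module", {
    for (pattern in allPatterns()) {
        traj <- fixtureTrajectory(pattern)
        curves <- trueCurves(traj)$right
        kin <- computeJointKinematics(traj)
        cf <- round(traj@pattern@cycleDuration * 30)
        n <- length(traj@timestamps)
        ph <- ((0:(n - 1)) %% cf) / cf * 100
        for (j in c("hip", "knee", "ankle", "foot")) {
            truth <- MLGait:::.curveAt(curves[, j], ph)
            err <- max(abs(kinematicAngles(kin, "right")[, j] - truth))
            expect_lt(err, 0.5)
        }
    }
})

test_that("the heel is exactly stationary during labelled foot-flat", {
    traj <- fixtureTrajectory("normal")
    pos <- trajectoryPositions(traj)
    ff <- traj@footFlat
    for (r in seq_len(nrow(ff))) {
        fr <- ff$start[r]:ff$end[r]
        hx <- pos[fr, "heel", "x", ff$side[r]]
        expect_lt(max(abs(diff(hx))) * 30, 1e-6)
    }
})

test_that("realized step length matches the pattern target within 5%", {
    for (pattern in allPatterns()) {
        traj <- fixtureTrajectory(pattern)
        target <- traj@pattern@stepLengthTarget
        ## read the steps from the generated heel positions at true ICs
        te <- trueEvents(traj)
        pos <- trajectoryPositions(traj)
        ics <- te[order(te$ic), ]
        hx <- vapply(seq_len(nrow(ics)), function(k)
            pos[ics$ic[k], "heel", "x", ics$side[k]], 0)
        steps <- diff(hx)
        expect_lt(abs(mean(steps) - target) / target, 0.05)
    }
})

test_that("the trochanter progresses monotonically", {
    traj <- fixtureTrajectory("normal")
    x <- trajectoryPositions(traj)[, "trochanter", "x", "right"]
    expect_true(all(diff(x) > -1e-9))
})

test_that("exactly one IC and one toe-off per side per cycle, in order", {
    for (pattern in c("normal", "true_equinus", "crouch")) {
        te <- trueEvents(fixtureTrajectory(pattern))
        for (side in c("left", "right")) {
            e <- te[te$side == side, ]
            expect_true(all(e$ic < e$to & e$to < e$nextIc))
            expect_equal(anyDuplicated(e$ic), 0L)
        }
        ## events alternate sides over time
        ord <- te[order(te$ic), "side"]
        expect_true(all(ord[-1] != ord[-length(ord)]))
    }
})

test_that("a symmetric walker yields equal left and right features", {
    res <- fixtureAnalysis("normal")
    feat <- extractGaitFeatures(res$kinematics)
    for (col in setdiff(names(feat), "nCycles"))
        expect_lt(abs(feat["left", col] - feat["right", col]), 1)
})

test_that("noise injection is seeded, calibrated and optional", {
    traj <- fixtureTrajectory("normal")
    ## identity case
    same <- addNoise(traj, sd = 0, dropout = 0, seed = 1)
    expect_identical(same@positions, traj@positions)
    ## empirical SD of the jitter
    noisy <- addNoise(traj, sd = 0.005, dropout = 0, seed = 42)
    delta <- noisy@positions - traj@positions
    expect_gt(length(delta), 300)
    expect_lt(abs(stats::sd(delta) - 0.005) / 0.005, 0.10)
    ## determinism
    again <- addNoise(traj, sd = 0.005, dropout = 0, seed = 42)
    expect_identical(noisy@positions, again@positions)
    ## negative SD rejected
    expect_error(addNoise(traj, sd = -1), "SD")
    ## dropout flags whole frames
    dropped <- addNoise(traj, sd = 0, dropout = 0.3, seed = 7)
    expect_true(any(dropped@missing))
    expect_true(all(is.na(dropped@positions[dropped@missing[, 1, 1], 1, 1, 1])))
})

test_that("walks longer than the walkway are truncated with a warning", {
    pat <- gaitPattern("normal", noiseSd = 0)
    curves <- generateJointCurves(pat)
    expect_warning(
        traj <- forwardKinematics(curves, pattern = pat, nCycles = 12L),
        "walkway")
    expect_lt(diff(range(trajectoryPositions(traj)[, "heel", "x", ])), 7)
})
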