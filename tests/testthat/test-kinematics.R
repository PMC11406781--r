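test_that("angle operations reproduce worked examples", {
    ## hip: vertical femur, forward lean, backward lean
    expect_equal(hipFlexionAngle(c(0, 1), c(0, 0.6)), 0)
    expect_equal(hipFlexionAngle(c(0, 1), c(0.20, 0.60)),
                 atan2(0.2, 0.4) * 180 / pi, tolerance = 1e-10)
    expect_lt(hipFlexionAngle(c(0, 1), c(-0.10, 0.60)), 0)
    ## knee: collinear extension, flexion, hyperextension
    expect_equal(kneeFlexionAngle(c(0, 1), c(0, 0.6), c(0, 0.2)), 0)
    expect_equal(kneeFlexionAngle(c(0, 1), c(0, 0.6), c(-0.15, 0.25)),
                 23.1986, tolerance = 1e-4)
    expect_lt(kneeFlexionAngle(c(0, 1), c(0, 0.6), c(0.05, 0.21)), 0)
    ## ankle: neutral, toe lowered 10 degrees
    expect_equal(
        ankleDorsiflexionAngle(c(0, 0.6), c(0, 0.2), c(-0.05, 0), c(0.15, 0)),
        0)
    r <- 10 * pi / 180
    toe <- c(0.20 * cos(-r), 0.20 * sin(-r))
    expect_equal(
        ankleDorsiflexionAngle(c(0, 0.6), c(0, 0.2), c(0, 0), toe),
        -10, tolerance = 1e-10)
    ## foot orientation: flat, heel up, heel down
    expect_equal(footOrientationAngle(c(0, 0.05), c(0.15, 0.05)), 0)
    expect_equal(footOrientationAngle(c(0, 0.10), c(0.15, 0.05)),
                 atan2(0.05, 0.15) * 180 / pi, tolerance = 1e-10)
    expect_lt(footOrientationAngle(c(0, 0.05), c(0.15, 0.10)), 0)
})

test_that("degenerate point configurations raise errors", {
    expect_error(hipFlexionAngle(c(0, 1), c(0, 1)), "coincident")
    expect_error(kneeFlexionAngle(c(0, 1), c(0, 1), c(0, 0.2)))
    expect_error(footOrientationAngle(c(0.1, 0.1), c(0.1, 0.1)))
})

test_that("angles agree with an independent vector oracle", {
    set.seed(11)
    for (k in 1:1000) {
        troch <- stats::runif(2, -1, 1)
        epi <- troch + stats::runif(2, 0.05, 0.5) *
            c(cos(a1 <- stats::runif(1, -pi, pi)), sin(a1))
        mall <- epi + stats::runif(2, 0.05, 0.5) *
            c(cos(a2 <- stats::runif(1, -pi, pi)), sin(a2))
        heel <- mall + stats::runif(2, -0.1, 0.1)
        toe <- heel + stats::runif(2, 0.05, 0.3) *
            c(cos(a3 <- stats::runif(1, -pi, pi)), sin(a3))
        femur <- epi - troch; tibia <- mall - epi; foot <- toe - heel
        expect_equal(hipFlexionAngle(troch, epi),
                     oracleSignedAngle(c(0, -1), femur), tolerance = 1e-9)
        expect_equal(kneeFlexionAngle(troch, epi, mall),
                     oracleSignedAngle(tibia, femur), tolerance = 1e-9)
        perp <- c(tibia[2], -tibia[1]) * -1   # tibia rotated +90 degrees
        expect_equal(ankleDorsiflexionAngle(epi, mall, heel, toe),
                     oracleSignedAngle(perp, foot), tolerance = 1e-9)
        expect_equal(footOrientationAngle(heel, toe),
                     oracleSignedAngle(foot, c(1, 0)), tolerance = 1e-9)
    }
})

test_that("translation leaves all angles unchanged; rotation only the room-referenced ones", {
    traj <- fixtureTrajectory("normal")
    kin <- computeJointKinematics(traj)
    shifted <- traj
    shifted@positions <- traj@positions + 1.23
    kinS <- computeJointKinematics(shifted)
    for (j in c("hip", "knee", "ankle", "foot"))
        expect_equal(kinematicAngles(kinS, "right")[, j],
                     kinematicAngles(kin, "right")[, j], tolerance = 1e-9)
    ## rotate the whole scene by 5 degrees
    th <- 5 * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- traj
    for (lm in 1:5) for (side in 1:2)
        rot@positions[, lm, , side] <- traj@positions[, lm, , side] %*% t(R)
    kinR <- computeJointKinematics(rot)
    expect_equal(kinematicAngles(kinR, "right")[, "knee"],
                 kinematicAngles(kin, "right")[, "knee"], tolerance = 1e-9)
    expect_equal(kinematicAngles(kinR, "right")[, "ankle"],
                 kinematicAngles(kin, "right")[, "ankle"], tolerance = 1e-9)
    expect_equal(kinematicAngles(kinR, "right")[, "hip"],
                 kinematicAngles(kin, "right")[, "hip"] + 5,
                 tolerance = 1e-9)
    expect_equal(kinematicAngles(kinR, "right")[, "foot"],
                 kinematicAngles(kin, "right")[, "foot"] - 5,
                 tolerance = 1e-9)
})

test_that("cycle normalization resamples onto 101 points correctly", {
    res <- fixtureAnalysis("normal")
    cyc <- normalizedCycles(res$kinematics, "right")
    expect_equal(dim(cyc$curves)[2:3], c(101L, 4L))
    expect_true(all(cyc$toeoffPct > 0 & cyc$toeoffPct < 100))
    ## value at 0% equals the value at the IC frame
    ang <- kinematicAngles(res$kinematics, "right")
    for (k in seq_along(cyc$ic))
        expect_equal(cyc$curves[k, 1, "knee"], ang[cyc$ic[k], "knee"],
                     tolerance = 1e-9)
    ## normalized knee curve matches the input template closely
    truth <- trueCurves(fixtureTrajectory("normal"))$right
    for (k in seq_len(dim(cyc$curves)[1]))
        expect_lt(sqrt(mean((cyc$curves[k, , "knee"] -
                             truth[, "knee"])^2)), 1)
    ## resampling conserves extrema within one sample's interpolation error
    expect_lt(abs(max(cyc$curves[1, , "knee"]) - max(truth[, "knee"])), 1.5)
})

test_that("constant signals survive normalization unchanged", {
    res <- fixtureAnalysis("normal")
    kin <- res$kinematics
    for (side in c("left", "right")) kin@angles[[side]][] <- 10
    kin@cycles <- list()
    kin <- normalizeCycles(kin, res$events)
    expect_true(all(abs(normalizedCycles(kin, "right")$curves - 10) < 1e-9))
})

test_that("a cycle of exactly 101 frames resamples to its own samples", {
    ## synthetic single-landmark series: 102 frames, cycle = [1, 102)
    n <- 102L
    ang <- matrix(stats::runif(n * 4, -20, 60), n, 4,
                  dimnames = list(NULL, c("hip", "knee", "ankle", "foot")))
    kin <- new("JointKinematics", timestamps = (0:(n - 1)) / 30,
               angles = list(left = ang, right = ang),
               cycles = list(), fps = 30)
    ev <- MLGait:::.asReferenceEvents(
        data.frame(side = c("right", "right"), ic = c(1L, 102L),
                   to = c(52L, NA)))
    ev@cycles <- data.frame(side = "right", ic = 1L, to = 52L,
                            nextIc = 102L)
    kin <- normalizeCycles(kin, ev)
    cyc <- normalizedCycles(kin, "right")
    ## 101 resampled points fall on frames 1, 2.01, ... only the endpoints
    ## and midpoint are exactly on the grid
    expect_equal(cyc$curves[1, 1, ], ang[1, ], tolerance = 1e-12)
    expect_equal(cyc$curves[1, 101, ], ang[102, ], tolerance = 1e-12)
})

test_that("normalization without a complete cycle is an error", {
    res <- fixtureAnalysis("normal")
    empty <- new("GaitEvents", ic = list(left = integer(0), right = integer(0)),
                 to = list(left = integer(0), right = integer(0)),
                 cycles = data.frame(side = character(), ic = integer(),
                                     to = integer(), nextIc = integer()),
                 params = list())
    expect_error(normalizeCycles(res$kinematics, empty), "complete")
})
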