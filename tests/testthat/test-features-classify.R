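## Feature extraction and the rule-based pattern classifier.

constantKin <- function(value = 10) {
    n <- 102L
    ang <- matrix(value, n, 4,
                  dimnames = list(NULL, c("hip", "knee", "ankle", "foot")))
    kin <- new("JointKinematics", timestamps = (0:(n - 1)) / 30,
               angles = list(left = ang, right = ang),
               cycles = list(), fps = 30)
    ev <- MLGait:::.asReferenceEvents(
        data.frame(side = c("right", "left"), ic = c(1L, 1L),
                   to = c(52L, 52L)))
    ev@ic <- list(left = c(1L, 102L), right = c(1L, 102L))
    ev@to <- list(left = 52L, right = 52L)
    ev@cycles <- data.frame(side = c("left", "right"), ic = 1L, to = 52L,
                            nextIc = 102L)
    normalizeCycles(kin, ev)
}

test_that("a constant knee curve yields the trivial features", {
    kin <- constantKin(10)
    feat <- extractGaitFeatures(kin)
    expect_equal(feat["right", "knee_at_ic"], 10)
    expect_equal(feat["right", "knee_rom"], 0)
    expect_equal(feat["right", "knee_loading_response"], 10)
    expect_equal(feat["right", "hip_rom"], 0)
})

test_that("simulated normal and hyperextension trials show the expected features", {
    featN <- extractGaitFeatures(fixtureAnalysis("normal")$kinematics)
    expect_gt(featN["right", "knee_rom"], 55)
    expect_lt(featN["right", "knee_rom"], 65)
    featH <- extractGaitFeatures(fixtureAnalysis("hyperextension")$kinematics)
    expect_lt(featH["right", "knee_peak_extension_in_stance"], 0)
})

test_that("the normative band degenerates and recovers as expected", {
    kin <- fixtureAnalysis("normal")$kinematics
    ## identical trials: SD exactly zero
    band0 <- buildNormativeBand(rep(list(kin), 5))
    expect_true(all(bandCurves(band0, "sd") == 0))
    expect_error(buildNormativeBand(rep(list(kin), 4)), "at least 5")
    ## injected inter-trial SD of 2 degrees is recovered within 20%
    set.seed(31)
    nT <- 24
    kins <- lapply(1:nT, function(k) {
        k2 <- kin
        off <- stats::rnorm(1, 0, 2)
        for (side in c("left", "right"))
            k2@cycles[[side]]$curves <- k2@cycles[[side]]$curves + off
        k2
    })
    band <- buildNormativeBand(kins)
    got <- mean(bandCurves(band, "sd"))
    expect_lt(abs(got - 2) / 2, 0.20)
    ## band mean of the ensemble stays on the template at midstance
    truth <- trueCurves(fixtureTrajectory("normal"))$right
    expect_lt(abs(bandCurves(band0, "mean")[26, "ankle"] -
                  truth[26, "ankle"]), 1)
})

test_that("each simulator template is classified as its own type", {
    band <- fixtureBand()
    expected <- c(normal = "unclassified_mild",
                  true_equinus = "I_true_equinus",
                  jump = "II_jump",
                  apparent_equinus = "III_apparent_equinus",
                  crouch = "IV_crouch",
                  hyperextension = "unclassified_mild",
                  short_hamstring = "unclassified_mild")
    for (pattern in names(expected)) {
        res <- fixtureAnalysis(pattern)
        cl <- classifyTrial(res, band)
        for (side in c("left", "right"))
            expect_equal(cl$results[[side]]@type, expected[[pattern]],
                         label = paste(pattern, side))
        expect_gt(nrow(cl$results$right@ruleTrace), 0)
    }
})

test_that("true vs apparent equinus are separated on the stated criteria", {
    band <- fixtureBand()
    ## true equinus: toe-walking with plantarflexion throughout stance and
    ## knee/hip extended
    te <- classifyTrial(fixtureAnalysis("true_equinus"), band)
    tr <- te$results$right@ruleTrace
    expect_true(tr$verdict[tr$criterion ==
                           "ankle_plantarflexion_throughout_stance"])
    expect_false(tr$verdict[tr$criterion ==
                            "knee_increased_flexion_midstance"])
    ## apparent equinus: toe-walking with normal ankle range and increased
    ## knee and hip flexion in stance
    ae <- classifyTrial(fixtureAnalysis("apparent_equinus"), band)
    tr <- ae$results$right@ruleTrace
    expect_false(tr$verdict[tr$criterion ==
                            "ankle_plantarflexion_throughout_stance"])
    expect_false(tr$verdict[tr$criterion ==
                            "ankle_excessive_dorsiflexion_midstance"])
    expect_true(tr$verdict[tr$criterion ==
                           "knee_increased_flexion_midstance"])
    expect_true(tr$verdict[tr$criterion ==
                           "hip_increased_flexion_midstance"])
})

test_that("deviation flags fire for the mild-deviation templates", {
    band <- fixtureBand()
    shFlags <- classifyTrial(fixtureAnalysis("short_hamstring"),
                             band)$results$right@deviationFlags
    expect_true(all(c("increased_knee_flexion_at_ic",
                      "decreased_terminal_swing_extension") %in% shFlags))
    hyFlags <- classifyTrial(fixtureAnalysis("hyperextension"),
                             band)$results$right@deviationFlags
    expect_true("knee_hyperextension_in_stance" %in% hyFlags)
    expect_true("absent_first_rocker" %in% hyFlags)
    expect_true("plantarflexion_knee_extension_couple" %in% hyFlags)
    ## the normal template raises nothing
    noFlags <- classifyTrial(fixtureAnalysis("normal"),
                             band)$results$right@deviationFlags
    expect_length(noFlags, 0)
})

test_that("every trial maps to exactly one type, deterministically", {
    band <- fixtureBand()
    valid <- c("I_true_equinus", "II_jump", "III_apparent_equinus",
               "IV_crouch", "unclassified_mild")
    for (pattern in allPatterns()) {
        res <- fixtureAnalysis(pattern)
        c1 <- classifyTrial(res, band)
        c2 <- classifyTrial(res, band)
        expect_true(c1$results$right@type %in% valid)
        expect_identical(c1$results$right@type, c2$results$right@type)
    }
})

test_that("raising the ankle uniformly never moves the verdict backwards", {
    band <- fixtureBand()
    res <- fixtureAnalysis("true_equinus")
    regime <- function(shift) {
        kin <- res$kinematics
        for (side in c("left", "right"))
            kin@cycles[[side]]$curves[, , "ankle"] <-
                kin@cycles[[side]]$curves[, , "ankle"] + shift
        shifted <- res
        shifted$kinematics <- kin
        feat <- extractGaitFeatures(kin, res$spatioTemporal)
        r <- classifyRodda(feat["right", ], kin, band, "right")
        tr <- r@ruleTrace
        if (tr$verdict[tr$criterion == "ankle_plantarflexion_throughout_stance"])
            1L
        else if (tr$verdict[tr$criterion ==
                            "ankle_excessive_dorsiflexion_midstance"]) 3L
        else 2L
    }
    regimes <- vapply(c(0, 10, 20, 30, 45), regime, 0L)
    expect_true(all(diff(regimes) >= 0))
})

test_that("the participant label follows the more affected side", {
    band <- fixtureBand()
    mild <- classifyTrial(fixtureAnalysis("normal"), band)$results$right
    crouch <- classifyTrial(fixtureAnalysis("crouch"), band)$results$left
    out <- classifyParticipant(list(right = mild, left = crouch))
    expect_equal(out$label, "IV_crouch")
})
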