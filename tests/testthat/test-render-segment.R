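## Rendering and color segmentation on small frames.

renderedFixture <- function() {
    memo("rendered_fs", {
        traj <- fixtureTrajectory("normal")
        renderFrames(traj, smallScene())
    })
}

test_that("rendering is deterministic and the background is scene green", {
    fs <- renderedFixture()
    f1 <- getFrame(fs, 10)
    f2 <- getFrame(fs, 10)
    expect_identical(f1, f2)
    expect_equal(as.numeric(f1[5, 5, ]), smallScene()@colors$background)
    expect_equal(dim(f1), c(540L, 960L, 3L))
})

test_that("a uniform green frame contains no sock pixels", {
    bg <- smallScene()@colors$background
    frame <- array(rep(bg, each = 64 * 64), c(64, 64, 3))
    expect_equal(sum(segmentColor(frame, colorSpec(), "right_sock_red")), 0)
    expect_gt(sum(segmentColor(frame, colorSpec(), "background_green")), 0)
})

test_that("the red mask matches the rendered right-sock polygon", {
    fs <- renderedFixture()
    scene <- smallScene()
    traj <- fs@trajectory
    i <- 15L
    frame <- getFrame(fs, i)
    mask <- segmentColor(frame, colorSpec(), "right_sock_red")
    ## oracle: rasterize the ground-truth sock polygon directly
    verts <- MLGait:::.sockVertices(traj@positions[i, "heel", , "right"],
                                    traj@positions[i, "toe", , "right"],
                                    scene@sockHeightM)
    idx <- MLGait:::.polygonIdx(scene@height, scene@width,
                                MLGait:::.worldToPx(scene, verts))
    expect_lt(abs(sum(mask) - length(idx)) / length(idx), 0.15)
    ## centroid within 3 px of the polygon centroid
    my <- row(mask)[mask]; mx <- col(mask)[mask]
    ry <- (idx - 1L) %% scene@height + 1L
    rx <- (idx - 1L) %/% scene@height + 1L
    expect_lt(sqrt((mean(mx) - mean(rx))^2 + (mean(my) - mean(ry))^2), 3)
})

test_that("foot extraction finds the extremes of a rectangle", {
    m <- matrix(FALSE, 60, 220)
    m[25:35, 100:160] <- TRUE
    ft <- extractFootPoints(m, walkDirection = 1)
    expect_lt(abs(ft$heel[1] - 100), 1.5)
    expect_lt(abs(ft$toe[1] - 160), 1.5)
    expect_equal(ft$nBlobs, 1L)
})

test_that("with two blobs the larger is used and reported", {
    m <- matrix(FALSE, 60, 220)
    m[25:35, 100:160] <- TRUE       # large
    m[10:13, 10:16] <- TRUE         # small
    ft <- extractFootPoints(m)
    expect_equal(ft$nBlobs, 2L)
    expect_gt(ft$heel[1], 90)        # the large blob was used
})

test_that("pen marks are assigned by vertical order", {
    scene <- smallScene()
    bg <- scene@colors$background
    frame <- array(rep(bg, each = 540 * 960), c(540, 960, 3))
    for (y in c(400, 300, 200)) {
        idx <- MLGait:::.discIdx(540, 960, c(300, y), 4)
        for (k in 1:3) {
            ch <- frame[, , k]
            ch[idx] <- scene@colors$mark[k]
            frame[, , k] <- ch
        }
    }
    marks <- detectPenMarks(frame, colorSpec())
    expect_equal(unname(marks["trochanter", "y"]), 200, tolerance = 1)
    expect_equal(unname(marks["epicondyle", "y"]), 300, tolerance = 1)
    expect_equal(unname(marks["malleolus", "y"]), 400, tolerance = 1)
})

test_that("occluded pen marks give missing flags, not errors", {
    scene <- smallScene()
    bg <- scene@colors$background
    frame <- array(rep(bg, each = 128 * 128), c(128, 128, 3))
    marks <- detectPenMarks(frame, colorSpec())
    expect_true(all(is.na(marks)))
})

test_that("detections land within 3 px of the projected ground truth", {
    fs <- renderedFixture()
    scene <- smallScene()
    traj <- fs@trajectory
    i <- 15L
    frame <- getFrame(fs, i)
    hsv <- MLGait:::.frameHsv(frame)
    ft <- extractFootPoints(
        segmentColor(frame, colorSpec(), "right_sock_red", hsv = hsv), 1)
    truthHeel <- MLGait:::.worldToPx(scene, traj@positions[i, "heel", , "right"])
    truthToe <- MLGait:::.worldToPx(scene, traj@positions[i, "toe", , "right"])
    expect_lt(sqrt(sum((ft$heel - truthHeel)^2)), 3)
    expect_lt(sqrt(sum((ft$toe - truthToe)^2)), 3)
    ## pen marks: the frame contains up to 6 dark blobs; each true mark
    ## position must have a detection within 3 px
    cents <- MLGait:::.darkBlobCentroids(
        segmentColor(frame, colorSpec(), "landmark_dark", hsv = hsv))
    for (lm in c("trochanter", "epicondyle", "malleolus")) {
        truth <- MLGait:::.worldToPx(scene, traj@positions[i, lm, , "right"])
        d <- sqrt((cents[, "x"] - truth[1])^2 + (cents[, "y"] - truth[2])^2)
        expect_lt(min(d), 3)
    }
})

test_that("landmarks outside the frame abort rendering with the frame index", {
    traj <- fixtureTrajectory("normal")
    tiny <- sceneConfig(width = 200L, height = 150L, pixelsPerMeter = 240,
                        originM = c(-0.6, -0.3))
    expect_error(renderFrames(traj, tiny), "frame [0-9]+")
})

test_that("metric outputs are invariant to the pixel scale", {
    traj <- fixtureTrajectory("normal")
    i <- 15L
    out <- lapply(c(240, 480), function(ppm) {
        scene <- sceneConfig(width = as.integer(960 * ppm / 240),
                             height = as.integer(540 * ppm / 240),
                             pixelsPerMeter = ppm, originM = c(-0.6, -0.3))
        fs <- renderFrames(traj, scene)
        frame <- getFrame(fs, i)
        ft <- extractFootPoints(
            segmentColor(frame, colorSpec(), "right_sock_red"), 1)
        MLGait:::.pxToWorld(scene, rbind(ft$heel, ft$toe))
    })
    ## sub-pixel tolerance at the coarser scale (1 px = 1/240 m)
    expect_lt(max(abs(out[[1]] - out[[2]])), 1.5 / 240)
})

test_that("red-channel processing cannot alter blue-channel output", {
    scene <- smallScene()
    bg <- scene@colors$background
    mk <- function(withRed) {
        frame <- array(rep(bg, each = 200 * 200), c(200, 200, 3))
        blue <- MLGait:::.capsuleIdx(200, 200, c(60, 150), c(100, 150), 8)
        red <- MLGait:::.capsuleIdx(200, 200, c(130, 150), c(170, 150), 8)
        for (k in 1:3) {
            ch <- frame[, , k]
            ch[blue] <- scene@colors$sockLeft[k]
            if (withRed) ch[red] <- scene@colors$sockRight[k]
            frame[, , k] <- ch
        }
        frame
    }
    b1 <- segmentColor(mk(TRUE), colorSpec(), "left_sock_blue")
    b2 <- segmentColor(mk(FALSE), colorSpec(), "left_sock_blue")
    expect_identical(b1, b2)
})

test_that("zero-lag smoothing keeps a stationary landmark's mean exactly", {
    x <- rep(2.5, 120) + c(stats::rnorm(120, 0, 0.004))
    sm <- MLGait:::.zeroLagLowpass(x, 6, 30)
    expect_equal(mean(sm), mean(x), tolerance = 1e-6)
    ## a strictly constant series passes through unchanged
    const <- rep(1.25, 120)
    expect_equal(MLGait:::.zeroLagLowpass(const, 6, 30), const,
                 tolerance = 1e-6)
})

test_that("segmenting an already highlighted region is idempotent", {
    scene <- smallScene()
    bg <- scene@colors$background
    frame <- array(rep(bg, each = 100 * 100), c(100, 100, 3))
    idx <- MLGait:::.capsuleIdx(100, 100, c(30, 50), c(70, 50), 6)
    for (k in 1:3) {
        ch <- frame[, , k]
        ch[idx] <- scene@colors$sockRight[k]
        frame[, , k] <- ch
    }
    m1 <- segmentColor(frame, colorSpec(), "right_sock_red")
    ## repaint exactly the masked pixels and segment again
    frame2 <- frame
    for (k in 1:3) {
        ch <- frame2[, , k]
        ch[m1] <- scene@colors$sockRight[k]
        frame2[, , k] <- ch
    }
    expect_identical(segmentColor(frame2, colorSpec(), "right_sock_red"), m1)
})

test_that("30% frame dropout rejects the trial with a reason code", {
    pat <- gaitPattern("normal", dropout = 0.3, seed = 3)
    traj <- simulateTrial(pat, nCycles = 3L)
    res <- withTrialRejection(analyzeTrial(traj))
    expect_equal(res$status, "rejected")
    expect_equal(res$reasonCode, "feet_identification")
})
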