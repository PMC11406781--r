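## Scene rendering: a lateral-view stick walker against a uniform green
## background, with a red right sock, a blue left sock and near-black pen
## marks at the greater trochanter, lateral femoral epicondyle and lateral
## malleolus of each leg. The camera-near (foreground) leg is drawn last and
## occludes the far leg, mimicking the single-camera viewpoint.

#' Construct a scene configuration
#'
#' Defaults emulate a single camera 1920 x 1080 view of about 4 m of
#' walkway at 30 frames/s. The palette is chosen so that the sock, mark and
#' background classes are separable by the default HSV color filter.
#'
#' @param width,height image size in px.
#' @param pixelsPerMeter scale in px/m.
#' @param originM world coordinates (m) of the bottom-left image corner;
#'   ground level is y = 0.
#' @param colors named list of RGB triplets in \[0,1\] with entries
#'   `background`, `sockRight`, `sockLeft`, `mark`, `skin`, `shirt`.
#' @param markRadiusM pen-mark radius in m.
#' @param thighWidthM,shankWidthM limb stroke widths in m.
#' @param sockHeightM sock body height above the sole in m.
#' @param lightJitterSd SD of the per-frame multiplicative brightness
#'   jitter; 0 disables.
#' @param jitterSeed integer seed for the brightness jitter.
#' @param foregroundSide camera-near leg (`"right"` or `"left"`).
#' @return A [SceneConfig-class].
#' @examples
#' sceneConfig(width = 960L, height = 540L, pixelsPerMeter = 240)
#' @export
sceneConfig <- function(width = 1920L, height = 1080L,
                        pixelsPerMeter = 480,
                        originM = c(-0.5, -0.3),
                        colors = list(
                            background = c(0.13, 0.55, 0.22),
                            sockRight = c(0.80, 0.08, 0.10),
                            sockLeft = c(0.08, 0.15, 0.78),
                            mark = c(0.06, 0.06, 0.07),
                            skin = c(0.93, 0.78, 0.67),
                            shirt = c(0.75, 0.75, 0.78)),
                        markRadiusM = 0.013, thighWidthM = 0.095,
                        shankWidthM = 0.06, sockHeightM = 0.055,
                        lightJitterSd = 0, jitterSeed = 1L,
                        foregroundSide = "right") {
    new("SceneConfig", width = as.integer(width),
        height = as.integer(height), pixelsPerMeter = pixelsPerMeter,
        originM = originM, colors = colors, markRadiusM = markRadiusM,
        thighWidthM = thighWidthM, shankWidthM = shankWidthM,
        sockHeightM = sockHeightM, lightJitterSd = lightJitterSd,
        jitterSeed = as.integer(jitterSeed),
        foregroundSide = foregroundSide)
}

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf(
        "SceneConfig: %d x %d px | %.0f px/m | foreground %s leg\n",
        object@width, object@height, object@pixelsPerMeter,
        object@foregroundSide))
})

## world (m, y up) -> image px (x right, y down), 1-based pixel centers
.worldToPx <- function(scene, xy) {
    xy <- .asPointMatrix(xy)
    cbind(x = (xy[, 1] - scene@originM[1]) * scene@pixelsPerMeter + 0.5,
          y = scene@height -
              (xy[, 2] - scene@originM[2]) * scene@pixelsPerMeter + 0.5)
}

## image px -> world m
.pxToWorld <- function(scene, xy) {
    xy <- .asPointMatrix(xy)
    cbind(x = (xy[, 1] - 0.5) / scene@pixelsPerMeter + scene@originM[1],
          y = (scene@height - xy[, 2] + 0.5) / scene@pixelsPerMeter +
              scene@originM[2])
}

## shape rasterizers: return linear pixel indices into an h x w matrix.
## getFrame() collects indices per shape in draw order and assigns them in
## one pass per channel, so later shapes overwrite earlier ones (occlusion)
## without copying the frame once per shape.
.capsuleIdx <- function(h, w, p1, p2, halfWidthPx) {
    r0 <- max(1L, floor(min(p1[2], p2[2]) - halfWidthPx))
    r1 <- min(h, ceiling(max(p1[2], p2[2]) + halfWidthPx))
    c0 <- max(1L, floor(min(p1[1], p2[1]) - halfWidthPx))
    c1 <- min(w, ceiling(max(p1[1], p2[1]) + halfWidthPx))
    if (r0 > r1 || c0 > c1) return(integer(0))
    cols <- c0:c1; rows <- r0:r1
    px <- rep(cols, each = length(rows))
    py <- rep.int(rows, length(cols))
    d <- p2 - p1
    len2 <- sum(d^2)
    t <- if (len2 < 1e-12) 0 else
        pmin(1, pmax(0, ((px - p1[1]) * d[1] + (py - p1[2]) * d[2]) / len2))
    dist2 <- (px - (p1[1] + t * d[1]))^2 + (py - (p1[2] + t * d[2]))^2
    sel <- dist2 <= halfWidthPx^2
    py[sel] + (px[sel] - 1L) * h
}

.discIdx <- function(h, w, p, radiusPx) .capsuleIdx(h, w, p, p, radiusPx)

## (possibly non-convex) polygon by even-odd crossing test
.polygonIdx <- function(h, w, vertsPx) {
    r0 <- max(1L, floor(min(vertsPx[, 2])))
    r1 <- min(h, ceiling(max(vertsPx[, 2])))
    c0 <- max(1L, floor(min(vertsPx[, 1])))
    c1 <- min(w, ceiling(max(vertsPx[, 1])))
    if (r0 > r1 || c0 > c1) return(integer(0))
    cols <- c0:c1; rows <- r0:r1
    px <- rep(cols, each = length(rows))
    py <- rep.int(rows, length(cols))
    inside <- rep(FALSE, length(px))
    nv <- nrow(vertsPx)
    j <- nv
    for (i in seq_len(nv)) {
        xi <- vertsPx[i, 1]; yi <- vertsPx[i, 2]
        xj <- vertsPx[j, 1]; yj <- vertsPx[j, 2]
        crosses <- ((yi > py) != (yj > py)) &
            (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- xor(inside, crosses)
        j <- i
    }
    py[inside] + (px[inside] - 1L) * h
}

## sock outline in the foot frame (x along sole heel->toe, y up), meters
.sockVertices <- function(heel, toe, sockHeight) {
    f <- toe - heel
    L <- sqrt(sum(f^2))
    fh <- f / L
    nh <- c(-fh[2], fh[1])        # +90 deg, 'up' for a left-to-right foot
    up <- sockHeight; lo <- -0.2 * sockHeight
    shape <- rbind(c(0, 0),
                   c(0.16 * L, up), c(0.72 * L, 0.9 * up),
                   c(L, 0.02 * L),
                   c(0.80 * L, lo), c(0.15 * L, lo))
    t(apply(shape, 1, function(v) heel + v[1] * fh + v[2] * nh))
}

#' Bind a trajectory to a scene as a lazily rendered frame sequence
#'
#' Frames are rendered on demand by [getFrame()]; nothing is rasterized
#' here beyond checking that every (non-missing) landmark projects inside
#' the image.
#'
#' @param traj a [WalkerTrajectory-class].
#' @param scene a [SceneConfig-class].
#' @return A [FrameSequence-class].
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' fs <- renderFrames(traj, sceneConfig(width = 960L, height = 540L,
#'                                      pixelsPerMeter = 240))
#' dim(getFrame(fs, 1))
#' @export
renderFrames <- function(traj, scene = sceneConfig()) {
    stopifnot(is(traj, "WalkerTrajectory"), is(scene, "SceneConfig"))
    pos <- traj@positions
    n <- dim(pos)[1]
    margin <- 2  # px: drawn shapes extend beyond the landmark points
    for (i in seq_len(n)) {
        pts <- rbind(pos[i, , , "left"], pos[i, , , "right"])
        pts <- pts[stats::complete.cases(pts), , drop = FALSE]
        if (!nrow(pts)) next
        px <- .worldToPx(scene, pts)
        if (any(px[, 1] < 1 + margin | px[, 1] > scene@width - margin |
                px[, 2] < 1 + margin | px[, 2] > scene@height - margin))
            stop(sprintf(
                "landmark outside the image at frame %d; enlarge the scene or shift originM",
                i))
    }
    new("FrameSequence", trajectory = traj, scene = scene,
        timestamps = traj@timestamps)
}

#' @describeIn renderFrames Number of frames in a sequence.
#' @param fs a `FrameSequence`.
#' @export
nFrames <- function(fs) {
    if (inherits(fs, "DiskFrameSequence")) return(length(fs$files))
    length(fs@timestamps)
}

#' Render one frame of a sequence
#'
#' Deterministically rasterizes frame `i`: background, shirt, far leg, near
#' leg (occluding), sock polygons with pointed heel/toe tips at the true
#' landmark positions, and dark pen marks. Frames whose trajectory row is
#' missing (dropout) show the background only.
#'
#' @param fs a [FrameSequence-class].
#' @param i frame index (1-based).
#' @return An `height x width x 3` numeric array with values in \[0,1\].
#' @export
getFrame <- function(fs, i) {
    if (inherits(fs, "DiskFrameSequence")) {
        stopifnot(i >= 1, i <= length(fs$files))
        img <- png::readPNG(fs$files[i])
        if (length(dim(img)) == 3 && dim(img)[3] > 3)
            img <- img[, , 1:3]
        return(img)
    }
    scene <- fs@scene
    traj <- fs@trajectory
    stopifnot(i >= 1, i <= length(fs@timestamps))
    h <- scene@height; w <- scene@width
    cl <- scene@colors
    pos <- traj@positions[i, , , , drop = TRUE]  # [landmark, coord, side]
    shapes <- list()   # list of list(idx, col), in draw order
    addShape <- function(idx, col) {
        if (length(idx))
            shapes[[length(shapes) + 1L]] <<- list(idx = idx, col = col)
    }
    legShapes <- function(side) {
        p <- pos[, , side]
        if (anyNA(p)) return(invisible())
        ppm <- scene@pixelsPerMeter
        troch <- .worldToPx(scene, p["trochanter", ])[1, ]
        epi <- .worldToPx(scene, p["epicondyle", ])[1, ]
        mall <- .worldToPx(scene, p["malleolus", ])[1, ]
        addShape(.capsuleIdx(h, w, troch, epi,
                             scene@thighWidthM / 2 * ppm), cl$skin)
        addShape(.capsuleIdx(h, w, epi, mall,
                             scene@shankWidthM / 2 * ppm), cl$skin)
        sockCol <- if (side == "right") cl$sockRight else cl$sockLeft
        verts <- .sockVertices(p["heel", ], p["toe", ], scene@sockHeightM)
        addShape(.polygonIdx(h, w, .worldToPx(scene, verts)), sockCol)
        for (lm in c("trochanter", "epicondyle", "malleolus"))
            addShape(.discIdx(h, w, .worldToPx(scene, p[lm, ])[1, ],
                              scene@markRadiusM * ppm), cl$mark)
        invisible()
    }
    if (!all(is.na(pos))) {
        troch <- pos["trochanter", , scene@foregroundSide]
        if (!anyNA(troch)) {
            top <- troch + c(0.02, 0.3 * traj@anthropometry@stature)
            addShape(.capsuleIdx(h, w, .worldToPx(scene, troch)[1, ],
                                 .worldToPx(scene, top)[1, ],
                                 0.07 * scene@pixelsPerMeter), cl$shirt)
        }
        legShapes(setdiff(.SIDES, scene@foregroundSide))
        legShapes(scene@foregroundSide)
    }
    img <- array(0, dim = c(h, w, 3))
    allIdx <- unlist(lapply(shapes, `[[`, "idx"))
    for (k in 1:3) {
        ch <- matrix(cl$background[k], h, w)
        if (length(allIdx))
            ch[allIdx] <- unlist(lapply(shapes, function(s)
                rep.int(s$col[k], length(s$idx))))
        img[, , k] <- ch
    }
    if (scene@lightJitterSd > 0) {
        fac <- runWithSeed(scene@jitterSeed + i, {
            1 + stats::rnorm(1, 0, scene@lightJitterSd)
        })
        img <- pmin(1, pmax(0, img * fac))
    }
    img
}

#' Write a frame sequence to disk as PNG files plus scene metadata
#'
#' Frames are written as zero-padded `frame_000001.png` files together with
#' a `scene.yaml` serialization of the [SceneConfig-class].
#'
#' @param fs a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeFrames <- function(fs, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nFrames(fs)))
        png::writePNG(getFrame(fs, i),
                      file.path(dir, sprintf("frame_%06d.png", i)))
    writeSceneYaml(fs@scene, file.path(dir, "scene.yaml"))
    invisible(dir)
}

setMethod("show", "FrameSequence", function(object) {
    cat(sprintf(
        "FrameSequence: %d frames, %d x %d px (lazy render)\n",
        length(object@timestamps), object@scene@width,
        object@scene@height))
})
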