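## Color-filter segmentation in HSV space.
##
## The experimental scenario makes the color classes easy to separate: a
## green background, a red right sock, a blue left sock, and near-black pen
## marks. Classes are defined as hue/saturation/value ranges; the red hue
## range wraps around 0/360. Defaults match the renderer's palette; real
## video requires re-tuning via the configuration.

#' Construct a color-filter specification
#'
#' @param ranges named list of class definitions, each a list with `hMin`,
#'   `hMax` (degrees, `hMin > hMax` means the range wraps through 0),
#'   `sMin`, `vMin`, `vMax`. Classes: `right_sock_red`, `left_sock_blue`,
#'   `landmark_dark`, `background_green`.
#' @param minBlobArea minimum connected-component area in px for sock
#'   masks; smaller blobs are removed.
#' @param minMarkArea minimum area for dark pen-mark blobs.
#' @return A list of class `ColorSpec`.
#' @examples
#' spec <- colorSpec()
#' names(spec$ranges)
#' @export
colorSpec <- function(ranges = list(
                          right_sock_red = list(hMin = 335, hMax = 25,
                                                sMin = 0.45, vMin = 0.25,
                                                vMax = 1),
                          left_sock_blue = list(hMin = 195, hMax = 275,
                                                sMin = 0.45, vMin = 0.25,
                                                vMax = 1),
                          landmark_dark = list(hMin = 0, hMax = 360,
                                               sMin = 0, vMin = 0,
                                               vMax = 0.22),
                          background_green = list(hMin = 80, hMax = 170,
                                                  sMin = 0.25, vMin = 0.1,
                                                  vMax = 1)),
                      minBlobArea = 12L, minMarkArea = 4L) {
    need <- c("right_sock_red", "left_sock_blue", "landmark_dark",
              "background_green")
    if (!all(need %in% names(ranges)))
        stop("ranges must define: ", paste(need, collapse = ", "))
    structure(list(ranges = ranges, minBlobArea = as.integer(minBlobArea),
                   minMarkArea = as.integer(minMarkArea)),
              class = "ColorSpec")
}

## HSV conversion of an h x w x 3 frame: list of h x w matrices
.frameHsv <- function(frame) {
    d <- dim(frame)
    m <- matrix(frame, nrow = d[1] * d[2], ncol = 3)
    hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
    list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
         s = matrix(hsv[2, ], d[1], d[2]),
         v = matrix(hsv[3, ], d[1], d[2]))
}

## remove connected components smaller than minArea from a binary mask
.filterSmallBlobs <- function(mask, minArea) {
    if (!any(mask) || minArea <= 1) return(mask)
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < minArea)
    if (length(small)) mask[lab %in% small] <- FALSE
    mask
}

#' Segment one color class of a frame
#'
#' Converts the frame to HSV, thresholds the requested class range and
#' removes connected components below the minimum blob area. An empty mask
#' is a valid result.
#'
#' @param frame an `h x w x 3` RGB array in \[0,1\].
#' @param spec a [colorSpec()].
#' @param which class name: `"right_sock_red"`, `"left_sock_blue"`,
#'   `"landmark_dark"` or `"background_green"`.
#' @param hsv optional precomputed HSV list (internal reuse).
#' @return A logical `h x w` matrix.
#' @examples
#' frame <- array(rep(c(0.13, 0.55, 0.22), each = 16), c(4, 4, 3))
#' sum(segmentColor(frame, colorSpec(), "right_sock_red"))  # 0
#' @export
segmentColor <- function(frame, spec = colorSpec(),
                         which = "right_sock_red", hsv = NULL) {
    stopifnot(inherits(spec, "ColorSpec"),
              which %in% names(spec$ranges))
    if (is.null(hsv)) hsv <- .frameHsv(frame)
    r <- spec$ranges[[which]]
    hueOk <- if (r$hMin <= r$hMax) hsv$h >= r$hMin & hsv$h <= r$hMax
             else hsv$h >= r$hMin | hsv$h <= r$hMax
    mask <- hueOk & hsv$s >= r$sMin & hsv$v >= r$vMin & hsv$v <= r$vMax
    minA <- if (which == "landmark_dark") spec$minMarkArea
            else spec$minBlobArea
    .filterSmallBlobs(mask, minA)
}

## largest blob of a mask (area ties broken by leftmost centroid);
## returns list(mask, area, nBlobs) or NULL if empty
.largestBlob <- function(mask) {
    if (!any(mask)) return(NULL)
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
        ## tie: leftmost centroid (smallest mean column)
        cols <- col(mask)
        mcol <- vapply(best, function(b) mean(cols[lab == b]), 0)
        best <- best[which.min(mcol)]
    }
    list(mask = lab == best, area = max(sizes),
         nBlobs = length(sizes))
}

#' Extract heel and toe points from a sock mask
#'
#' The sock blob's principal axis is computed from the pixel covariance and
#' oriented along the walking direction; the toe is the blob extreme along
#' that axis, the heel the opposite extreme (for an upright, axis-aligned
#' blob this reduces to the extremes along the walking direction). Both
#' points are refined to sub-pixel precision as the centroid of the pixels
#' within a 5-px band of the extreme. If the mask holds several blobs the
#' largest is used (area ties broken by the leftmost) and the event is
#' reported via the `nBlobs` attribute.
#'
#' @param mask logical matrix from [segmentColor()].
#' @param walkDirection +1 for walking toward increasing image x.
#' @return A list with `heel` and `toe` (px, c(x, y)), `area`, `nBlobs`;
#'   or `NULL` for an empty mask (missing landmark).
#' @examples
#' m <- matrix(FALSE, 50, 200); m[20:30, 100:160] <- TRUE
#' extractFootPoints(m)$heel[1]  # ~100
#' @export
extractFootPoints <- function(mask, walkDirection = 1) {
    blob <- .largestBlob(mask)
    if (is.null(blob)) return(NULL)
    ys <- row(mask)[blob$mask]
    xs <- col(mask)[blob$mask]
    cx <- mean(xs); cy <- mean(ys)
    cv <- stats::cov(cbind(xs - cx, ys - cy))
    ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    if (sign(ax[1]) != sign(walkDirection)) ax <- -ax
    pp <- c(-ax[2], ax[1])
    proj <- (xs - cx) * ax[1] + (ys - cy) * ax[2]
    perp <- (xs - cx) * pp[1] + (ys - cy) * pp[2]
    ## tip = axis extreme (plus half-pixel extrapolation beyond the last
    ## pixel center) at the transverse centroid of the extreme 5-px band
    tip <- function(extreme, sel, dir) {
        c(cx, cy) + ax * (extreme + dir * 0.5) + pp * mean(perp[sel])
    }
    toe <- tip(max(proj), proj >= max(proj) - 2.5, +1)
    heel <- tip(min(proj), proj <= min(proj) + 2.5, -1)
    list(heel = heel, toe = toe, area = blob$area, nBlobs = blob$nBlobs)
}

## centroids and areas of all dark blobs: matrix [blob, (x, y, area)]
.darkBlobCentroids <- function(mask) {
    if (!any(mask)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("x", "y", "area"))))
    lab <- EBImage::bwlabel(mask)
    ids <- sort(unique(lab[lab > 0]))
    out <- t(vapply(ids, function(b) {
        sel <- lab == b
        c(mean(col(mask)[sel]), mean(row(mask)[sel]), sum(sel))
    }, numeric(3)))
    colnames(out) <- c("x", "y", "area")
    out
}

#' Detect pen-mark landmarks in a frame
#'
#' Finds dark blobs (optionally restricted to a region of interest) and
#' assigns them to landmark identities by vertical order: the greater
#' trochanter is the highest, then the lateral epicondyle, then the lateral
#' malleolus. Fewer than three blobs yield `NA` rows flagged missing, never
#' an error.
#'
#' @param frame an RGB array.
#' @param spec a [colorSpec()].
#' @param region optional logical mask restricting the search (the leg
#'   region of interest).
#' @param hsv optional precomputed HSV list.
#' @return A `3 x 2` matrix (rows trochanter, epicondyle, malleolus;
#'   columns x, y in px) with `NA` for missing marks.
#' @export
detectPenMarks <- function(frame, spec = colorSpec(), region = NULL,
                           hsv = NULL) {
    mask <- segmentColor(frame, spec, "landmark_dark", hsv = hsv)
    if (!is.null(region)) mask <- mask & region
    cents <- .darkBlobCentroids(mask)
    out <- matrix(NA_real_, 3, 2,
                  dimnames = list(c("trochanter", "epicondyle",
                                    "malleolus"), c("x", "y")))
    if (nrow(cents)) {
        cents <- cents[order(cents[, "y"]), , drop = FALSE]  # top first
        k <- min(3, nrow(cents))
        out[seq_len(k), ] <- cents[seq_len(k), c("x", "y")]
    }
    out
}
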