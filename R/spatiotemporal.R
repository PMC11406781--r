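## Spatio-temporal gait parameters.
##
## Step length is the horizontal distance between the heel of the
## foreground foot at its initial contact and the heel of the background
## foot at the subsequent contralateral initial contact. Gait speed is the
## forward displacement of the trochanter between the first and the last
## detected initial contact of the trial divided by the elapsed time.

#' Step lengths of a trial
#'
#' For each foreground-side initial contact followed by a contralateral
#' initial contact, the horizontal heel-to-heel distance between the two
#' contact instants.
#'
#' @param tracked a [TrackedLandmarks-class] (or [WalkerTrajectory-class]).
#' @param events a [GaitEvents-class] for the same trial.
#' @param foregroundSide the camera-near foot whose contact starts each
#'   step pair.
#' @return Numeric vector of step lengths in m (empty, with a warning, if
#'   no qualifying pair of contacts exists).
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' ev <- detectGaitEvents(traj)
#' stepLengths(traj, ev)
#' @export
stepLengths <- function(tracked, events, foregroundSide = "right") {
    pos <- .positionArray(tracked)
    bg <- setdiff(.SIDES, foregroundSide)
    icF <- events@ic[[foregroundSide]]
    icB <- events@ic[[bg]]
    out <- numeric(0)
    for (ic in icF) {
        nxt <- icB[icB > ic]
        if (!length(nxt)) next
        x1 <- pos[ic, "heel", "x", foregroundSide]
        x2 <- pos[nxt[1], "heel", "x", bg]
        if (is.na(x1) || is.na(x2)) next
        out <- c(out, x2 - x1)
    }
    if (!length(out))
        warning("no qualifying pair of initial contacts; no step length")
    out
}

#' Gait speed of a trial
#'
#' Forward displacement of the trochanter between the first and last
#' detected initial contact (either side), divided by the elapsed time.
#'
#' @inheritParams stepLengths
#' @param side which side's trochanter series to use (both carry the same
#'   hip point in the sagittal projection).
#' @return Speed in m/s.
#' @examples
#' traj <- simulateTrial("normal", noise = FALSE)
#' gaitSpeed(traj, detectGaitEvents(traj))
#' @export
gaitSpeed <- function(tracked, events, side = "right") {
    pos <- .positionArray(tracked)
    ics <- sort(c(events@ic$left, events@ic$right))
    if (length(ics) < 2)
        stop("need at least two initial contacts to compute gait speed")
    t <- .timestampsOf(tracked)
    i0 <- ics[1]; i1 <- ics[length(ics)]
    dx <- pos[i1, "trochanter", "x", side] - pos[i0, "trochanter", "x", side]
    dt <- t[i1] - t[i0]
    v <- dx / dt
    if (abs(v) < 1e-6)
        warning("degenerate trial: walker did not progress between contacts")
    v
}

#' Spatio-temporal summary of one trial
#'
#' @inheritParams stepLengths
#' @return List with `gaitSpeed` (m/s), `stepLengths` (m) and
#'   `meanStepLength`.
#' @export
spatioTemporal <- function(tracked, events, foregroundSide = "right") {
    sl <- stepLengths(tracked, events, foregroundSide)
    list(gaitSpeed = gaitSpeed(tracked, events),
         stepLengths = sl,
         meanStepLength = if (length(sl)) mean(sl) else NA_real_)
}

#' Compare automatic events against a reference for one trial
#'
#' Recomputes gait speed and mean step length from a reference set of
#' initial contacts (for instance manually identified frames, or the
#' simulator's ground truth) and reports the absolute differences from the
#' automatic results.
#'
#' @inheritParams stepLengths
#' @param autoEvents the automatically detected [GaitEvents-class].
#' @param referenceIc named list (`left`, `right`) of reference
#'   initial-contact frames, or a [GaitEvents-class], or the trajectory's
#'   ground-truth event table.
#' @return One-row data.frame with columns `speedAbsErr` (m/s) and
#'   `stepAbsErr` (m).
#' @export
manualReferenceCompare <- function(tracked, autoEvents, referenceIc,
                                   foregroundSide = "right") {
    refEv <- .asReferenceEvents(referenceIc)
    auto <- spatioTemporal(tracked, autoEvents, foregroundSide)
    ref <- spatioTemporal(tracked, refEv, foregroundSide)
    data.frame(speedAbsErr = abs(auto$gaitSpeed - ref$gaitSpeed),
               stepAbsErr = abs(auto$meanStepLength - ref$meanStepLength))
}

.asReferenceEvents <- function(ref) {
    if (is(ref, "GaitEvents")) return(ref)
    if (is.data.frame(ref)) {
        ic <- lapply(.SIDES, function(s) sort(ref$ic[ref$side == s]))
        to <- lapply(.SIDES, function(s) sort(ref$to[ref$side == s]))
        names(ic) <- names(to) <- .SIDES
    } else if (is.list(ref)) {
        ic <- lapply(.SIDES, function(s) sort(as.integer(ref[[s]])))
        names(ic) <- .SIDES
        to <- list(left = integer(0), right = integer(0))
    } else stop("unsupported reference event format")
    cycles <- NULL
    for (side in .SIDES) {
        cyc <- suppressMessages(segmentCycles(ic[[side]], to[[side]]))
        if (nrow(cyc)) cycles <- rbind(cycles, cbind(side = side, cyc))
    }
    if (is.null(cycles))
        cycles <- data.frame(side = character(), ic = integer(),
                             to = integer(), nextIc = integer())
    new("GaitEvents", ic = ic, to = to, cycles = cycles,
        params = list(vThresh = NA_real_, dwell = NA_integer_,
                      refine = FALSE, source = "reference"))
}

#' Summarize absolute errors across trials
#'
#' @param errors data.frame of per-trial rows as returned by
#'   [manualReferenceCompare()].
#' @return data.frame with the mean and SD of each error column.
#' @export
aggregateErrors <- function(errors) {
    stopifnot(nrow(errors) >= 1)
    data.frame(metric = names(errors),
               mean = vapply(errors, mean, 0, na.rm = TRUE),
               sd = vapply(errors, stats::sd, 0, na.rm = TRUE),
               row.names = NULL)
}

#' Cohort summary table
#'
#' Column-wise mean, sample SD (n - 1) and range over the non-missing
#' entries of a per-side cohort table, in the layout of a clinical summary
#' (one row per participant-side, summary rows at the bottom).
#'
#' @param sideRows data.frame with one row per participant-side; all
#'   numeric columns are aggregated, other columns are ignored.
#' @return data.frame with rows `mean`, `sd`, `min`, `max`. With a single
#'   input row the SD is `NA` (flagged by attribute `sdUndefined`).
#' @examples
#' cohortTable(data.frame(gaitSpeed = c(0.86, 0.85), stepLength = c(0.46, 0.48)))
#' @export
cohortTable <- function(sideRows) {
    if (nrow(sideRows) == 0) stop("empty cohort: no side rows")
    num <- sideRows[vapply(sideRows, is.numeric, TRUE)]
    if (!ncol(num)) stop("no numeric columns to aggregate")
    agg <- rbind(
        mean = vapply(num, function(x) mean(x, na.rm = TRUE), 0),
        sd = vapply(num, function(x) {
            x <- x[!is.na(x)]
            if (length(x) < 2) NA_real_ else stats::sd(x)
        }, 0),
        min = vapply(num, function(x) suppressWarnings(min(x, na.rm = TRUE)), 0),
        max = vapply(num, function(x) suppressWarnings(max(x, na.rm = TRUE)), 0))
    out <- as.data.frame(agg)
    attr(out, "sdUndefined") <- nrow(sideRows) < 2
    out
}
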