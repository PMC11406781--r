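#' Derive walker segment lengths from stature
#'
#' Segment lengths default to fixed published body-segment fractions of
#' stature (thigh 0.245 H, shank 0.246 H, foot length 0.152 H) with the heel
#' placed a quarter of the foot length behind the ankle along the foot axis.
#' The default stature of 1.36 m matches the mean height of a school-age
#' cohort of ambulatory children with bilateral cerebral palsy.
#'
#' @param stature body height in m.
#' @param thighLength,shankLength,footLength,heelOffset optional overrides
#'   in m.
#' @return An [Anthropometry-class] object.
#' @examples
#' anthropometryFromStature(1.36)
#' @export
anthropometryFromStature <- function(stature = 1.36,
                                     thighLength = 0.245 * stature,
                                     shankLength = 0.246 * stature,
                                     footLength = 0.152 * stature,
                                     heelOffset = 0.25 * footLength) {
    new("Anthropometry", stature = stature, thighLength = thighLength,
        shankLength = shankLength, footLength = footLength,
        heelOffset = heelOffset)
}

#' @describeIn anthropometryFromStature Accessor for segment lengths as a
#'   named numeric vector (m).
#' @param object an `Anthropometry` object.
#' @export
segmentLengths <- function(object) {
    stopifnot(is(object, "Anthropometry"))
    c(stature = object@stature, thigh = object@thighLength,
      shank = object@shankLength, foot = object@footLength,
      heelOffset = object@heelOffset)
}

setMethod("show", "Anthropometry", function(object) {
    s <- segmentLengths(object)
    cat("Anthropometry (m): stature", format(s["stature"]),
        "| thigh", format(s["thigh"]), "| shank", format(s["shank"]),
        "| foot", format(s["foot"]), "| heel offset",
        format(s["heelOffset"]), "\n")
})
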