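## Shared fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

allPatterns <- function() c("normal", "true_equinus", "jump",
                            "apparent_equinus", "crouch",
                            "hyperextension", "short_hamstring")

## clean (noise-free) trajectory per pattern
fixtureTrajectory <- function(pattern, nCycles = 3L) {
    memo(paste0("traj_", pattern, "_", nCycles), {
        pat <- gaitPattern(pattern, noiseSd = 0)
        simulateTrial(pat, nCycles = nCycles, noise = FALSE)
    })
}

fixtureCurves <- function(pattern) {
    memo(paste0("curves_", pattern),
         generateJointCurves(gaitPattern(pattern)))
}

smallScene <- function() {
    sceneConfig(width = 960L, height = 540L, pixelsPerMeter = 240,
                originM = c(-0.6, -0.3))
}

fixtureBand <- function() memo("band", defaultNormativeBand(nTrials = 6))

## noise-free end-to-end analysis per pattern (trajectory level)
fixtureAnalysis <- function(pattern) {
    memo(paste0("analysis_", pattern),
         suppressMessages(analyzeTrial(fixtureTrajectory(pattern))))
}

## independent angle oracle: |angle| from normalized dot product, sign from
## the z component of the cross product
oracleSignedAngle <- function(u, v) {
    cosA <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ang <- acos(pmin(1, pmax(-1, cosA))) * 180 / pi
    s <- sign(u[1] * v[2] - u[2] * v[1])
    if (s == 0) s <- 1
    s * ang
}
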