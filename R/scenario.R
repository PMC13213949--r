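#' Construct a TissueScenario
#'
#' @param groupLabel "F", "CTRL" or "OA".
#' @param markerProbs Named list region -> named numeric marker probabilities.
#' @param colocProbs Named list region -> named numeric `"A:B"` conditional
#'   probabilities P(B | A positive).
#' @param cellDensity Named numeric, cells/mm^2 per region (ICL > 0).
#' @param vesselDensity Named numeric, vessels/mm^2 per region.
#' @param pixelSizeUm Micrometers per pixel; 0.5 is typical of 20x slide scans
#'   and makes the 15 px cell radius equal 7.5 um.
#' @param noiseLevel Shot-noise scale (sd = noiseLevel * sqrt(intensity)).
#' @param illumGradientAmplitude Multiplicative illumination-gradient
#'   amplitude in `[0, 1)`.
#' @return A [TissueScenario-class].
#' @export
tissueScenario <- function(groupLabel, markerProbs, colocProbs = list(),
                           cellDensity, vesselDensity = c(ICL = 0),
                           pixelSizeUm = 0.5, noiseLevel = 0.2,
                           illumGradientAmplitude = 0.3) {
    new("TissueScenario", groupLabel = groupLabel, markerProbs = markerProbs,
        colocProbs = colocProbs, cellDensity = cellDensity,
        vesselDensity = vesselDensity, pixelSizeUm = pixelSizeUm,
        noiseLevel = noiseLevel,
        illumGradientAmplitude = illumGradientAmplitude)
}

# Packaged per-group parameter tables. The qualitative contrasts they encode:
# CD14 highest in CTRL (ICL, SI-V), CD206 highest in F, CD16 identical across
# groups, ICL cell density elevated in F and OA relative to CTRL, vessels
# denser in SI-V than SI-N with the OA SI-N elevated. Exact values are
# package defaults documented in the methods vignette, not claims about real
# tissue.
.presetTables <- function() {
    list(
        CTRL = list(
            marker = list(ICL  = c(CD14 = 0.30, CD16 = 0.45, CD206 = 0.35),
                          SI_V = c(CD14 = 0.28, CD16 = 0.40, CD206 = 0.28),
                          SI_N = c(CD14 = 0.06, CD16 = 0.12, CD206 = 0.10)),
            coloc = c("CD14:CD16" = 0.55, "CD14:CD206" = 0.60),
            cells = c(ICL = 4300, SI_V = 3000, SI_N = 2000),
            vessels = c(SI_V = 90, SI_N = 25)),
        F = list(
            marker = list(ICL  = c(CD14 = 0.12, CD16 = 0.345, CD206 = 0.70),
                          SI_V = c(CD14 = 0.10, CD16 = 0.39, CD206 = 0.65),
                          SI_N = c(CD14 = 0.04, CD16 = 0.12, CD206 = 0.15)),
            coloc = c("CD14:CD16" = 0.45, "CD14:CD206" = 0.85),
            cells = c(ICL = 5550, SI_V = 3000, SI_N = 2000),
            vessels = c(SI_V = 100, SI_N = 20)),
        OA = list(
            marker = list(ICL  = c(CD14 = 0.10, CD16 = 0.345, CD206 = 0.30),
                          SI_V = c(CD14 = 0.06, CD16 = 0.39, CD206 = 0.22),
                          SI_N = c(CD14 = 0.03, CD16 = 0.12, CD206 = 0.08)),
            coloc = c("CD14:CD16" = 0.75, "CD14:CD206" = 0.30),
            cells = c(ICL = 5650, SI_V = 3000, SI_N = 2000),
            vessels = c(SI_V = 95, SI_N = 45))
    )
}

#' Packaged group scenario presets
#'
#' Returns the default [TissueScenario-class] for one study group. The
#' presets qualitatively encode the group contrasts of the modelled study
#' (CD14 highest in controls, CD206 highest in foals, CD16 flat, intimal
#' density elevated in foals and OA); the exact probabilities are package
#' calibration choices.
#'
#' @param group "F", "CTRL" or "OA".
#' @param ... Overrides forwarded to [tissueScenario()] (e.g. `noiseLevel`).
#' @return A [TissueScenario-class].
#' @examples
#' scenarioPreset("CTRL")
#' @export
scenarioPreset <- function(group = c("CTRL", "F", "OA"), ...) {
    group <- match.arg(group)
    tab <- .presetTables()[[group]]
    args <- list(groupLabel = group,
                 markerProbs = tab$marker,
                 colocProbs = lapply(tab$marker, function(x) tab$coloc),
                 cellDensity = tab$cells,
                 vesselDensity = tab$vessels)
    override <- list(...)
    args[names(override)] <- override
    do.call(tissueScenario, args)
}

#' All three packaged group presets
#'
#' @param ... Overrides forwarded to every [scenarioPreset()] call.
#' @return Named list of [TissueScenario-class] objects (F, CTRL, OA).
#' @export
cohortScenarios <- function(...) {
    stats::setNames(lapply(.GROUPS, scenarioPreset, ...), .GROUPS)
}
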