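# Fixed optics of the renderer: compact super-Gaussian cell blobs
# (order 4, scale 2.25 um = 4.5 px at the default 0.5 um/px, truncated where
# the profile falls below 1e-4); fixed amplitudes so the ideal render is a
# pure function of the ground truth. The plateau-with-shoulder profile models
# a surface-stained cell; its bounded footprint keeps zero-offset local-mean
# thresholding from being dominated by profile tails.
.BLOB_SIGMA_UM <- 2.25
.DAPI_AMP <- 0.85
.MARKER_AMP <- 0.90

# Ideal (noise-free, gradient-free) channel stack for a section: one DAPI
# blob per nucleus, marker blobs only at marker-positive cells. Deterministic.
cleanChannels <- function(gt) {
    stopifnot(is(gt, "GroundTruthSection"))
    nr <- gt@imageShape[1L]; nc <- gt@imageShape[2L]
    sigma <- .BLOB_SIGMA_UM / gt@pixelSizeUm
    cells <- gt@cells
    ch <- list(DAPI = render_blobs_cpp(nr, nc, cells$x, cells$y,
                                       rep(.DAPI_AMP, nrow(cells)), sigma))
    for (mk in markerNames(gt)) {
        pos <- cells[[mk]]
        ch[[mk]] <- render_blobs_cpp(nr, nc, cells$x[pos], cells$y[pos],
                                     rep(.MARKER_AMP, sum(pos)), sigma)
    }
    lapply(ch, function(m) if (max(m) > 1) pmin(m, 1) else m)
}

#' Render the fluorescence channels of a synthetic section
#'
#' Produces one DAPI channel with a Gaussian blob per nucleus and one channel
#' per marker with blobs only at marker-positive cells, modulated by a smooth
#' multiplicative illumination gradient of the scenario's amplitude (linear
#' ramp along a random direction) and degraded by shot noise
#' (sd = noiseLevel * sqrt(intensity); zero-intensity background stays
#' exactly zero). Intensities are clamped to `[0, 1]`.
#'
#' @param gt A [GroundTruthSection-class].
#' @param scenario The generating [TissueScenario-class] (pixel size must
#'   match).
#' @param seed Integer RNG seed for gradient direction and noise.
#' @param quantize16 If TRUE, round intensities to the 16-bit grid (the grid
#'   used when channels are written to TIFF).
#' @return A [CalibratedImage-class] with channels DAPI + markers.
#' @export
renderChannels <- function(gt, scenario, seed = 1L, quantize16 = FALSE) {
    stopifnot(is(gt, "GroundTruthSection"), is(scenario, "TissueScenario"))
    if (abs(gt@pixelSizeUm - scenario@pixelSizeUm) > 1e-9)
        stop("section and scenario pixel sizes differ")
    ch <- cleanChannels(gt)
    nr <- gt@imageShape[1L]; nc <- gt@imageShape[2L]
    withSeed(seed, {
        amp <- scenario@illumGradientAmplitude
        if (amp > 0) {
            phi <- stats::runif(1L, 0, 2 * pi)
            t <- outer(sin(phi) * (0:(nr - 1L)), cos(phi) * (0:(nc - 1L)), "+")
            t <- (t - min(t)) / (max(t) - min(t))
            gain <- 1 - amp * t
            ch <- lapply(ch, function(m) m * gain)
        }
        nl <- scenario@noiseLevel
        if (nl > 0) {
            ch <- lapply(ch, function(m) {
                nz <- which(m > 0)
                v <- m[nz]
                m[nz] <- pmin(pmax(v + nl * sqrt(v) * stats::rnorm(length(nz)), 0), 1)
                m
            })
        }
        if (quantize16) ch <- lapply(ch, function(m) round(m * 65535) / 65535)
        calibratedImage(ch, gt@pixelSizeUm, sampleID(gt))
    })
}

#' Ground-truth signal mask of a marker channel
#'
#' The truth against which segmentation recovery is judged: the strict
#' local-mean binarization of the ideal render (no shot noise, no
#' illumination gradient). Because the measured mask applies the same rule to
#' the degraded render, the difference between the two isolates the effect of
#' the modelled optics nuisances.
#'
#' @param gt A [GroundTruthSection-class].
#' @param marker Marker channel name.
#' @param windowPx Adaptive-threshold half-width, as in
#'   [localAdaptiveBinarize()].
#' @return A [BinaryMask-class].
#' @export
trueSignalMask <- function(gt, marker, windowPx = 50L) {
    ch <- cleanChannels(gt)
    if (!marker %in% names(ch))
        stop(sprintf("unknown marker '%s'", marker))
    localAdaptiveBinarize(ch[[marker]], windowPx = windowPx,
                          channelName = marker)
}
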