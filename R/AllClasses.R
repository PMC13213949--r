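# Region coding shared by the whole package. Label maps store the integer
# codes; user-facing functions use the names.
.REGION_CODES <- c(BACKGROUND = 0L, ICL = 1L, SI_V = 2L, SI_N = 3L, EXCLUDED = 4L)
.TISSUE_REGIONS <- c("ICL", "SI_V", "SI_N")
.GROUPS <- c("F", "CTRL", "OA")

#' Region name/code helpers
#'
#' The package partitions a section into `BACKGROUND`, the intimal cell layer
#' (`ICL`), the subintimal villous layer (`SI_V`), the subintimal non-villous
#' layer (`SI_N`) and `EXCLUDED` artefact zones, coded 0--4 in label maps.
#'
#' @return `regionCodes()` returns the named integer code vector;
#'   `tissueRegions()` the three analysable tissue region names.
#' @examples
#' regionCodes()
#' @export
regionCodes <- function() .REGION_CODES

#' @rdname regionCodes
#' @export
tissueRegions <- function() .TISSUE_REGIONS

#' CalibratedImage: named grayscale channels with a physical pixel size
#'
#' The raw substrate of all segmentation: one non-negative intensity matrix
#' per fluorescence channel (row-major, origin top-left, pixel centers at
#' 0-based integer coordinates, x = column, y = row) plus the isotropic pixel
#' size in micrometers, which carries the mm^2 denominators of all densities.
#'
#' @slot channels Named list of equal-sized numeric matrices in `[0, Inf)`.
#' @slot pixelSizeUm Positive scalar, micrometers per pixel.
#' @slot sampleID Sample identifier string.
#' @export
setClass("CalibratedImage",
    representation(channels = "list", pixelSizeUm = "numeric",
                   sampleID = "character"))

setValidity("CalibratedImage", function(object) {
    ch <- object@channels
    if (length(ch) == 0L) return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
        return("channels must have unique non-empty names")
    if (!all(vapply(ch, is.matrix, logical(1))))
        return("all channels must be matrices")
    d <- dim(ch[[1L]])
    for (m in ch) {
        if (!identical(dim(m), d)) return("all channels must share one shape")
        if (anyNA(m)) return("channel intensities must be finite")
        rng <- range(m)
        if (!all(is.finite(rng))) return("channel intensities must be finite")
        if (rng[1L] < 0) return("channel intensities must be non-negative")
    }
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
        return("pixelSizeUm must be a positive scalar")
    TRUE
})

#' Construct a CalibratedImage
#'
#' @param channels Named list of equal-sized non-negative matrices.
#' @param pixelSizeUm Micrometers per pixel (isotropic, positive).
#' @param sampleID Sample identifier.
#' @return A [CalibratedImage-class] object.
#' @examples
#' img <- calibratedImage(list(DAPI = matrix(0, 8, 8)), 0.5, "s1")
#' channelNames(img)
#' @export
calibratedImage <- function(channels, pixelSizeUm, sampleID = "") {
    new("CalibratedImage", channels = channels,
        pixelSizeUm = as.numeric(pixelSizeUm), sampleID = as.character(sampleID))
}

#' RegionLabelMap: rasterized tissue-region partition
#'
#' One region code per pixel (see [regionCodes()]); region areas in mm^2
#' follow from the pixel size.
#'
#' @slot labels Integer matrix with values in 0--4.
#' @slot pixelSizeUm Positive scalar, micrometers per pixel.
#' @export
setClass("RegionLabelMap",
    representation(labels = "matrix", pixelSizeUm = "numeric"))

setValidity("RegionLabelMap", function(object) {
    l <- object@labels
    if (!is.integer(l)) return("labels must be an integer matrix")
    if (anyNA(l) || any(l < 0L) || any(l > 4L))
        return("labels must be region codes 0..4")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
        return("pixelSizeUm must be a positive scalar")
    TRUE
})

#' BinaryMask: one thresholded fluorescence channel
#'
#' @slot mask Logical matrix, same shape as the source channel.
#' @slot channelName Name of the channel (or channel product) it came from.
#' @slot windowPx Neighborhood half-width used by the adaptive threshold.
#' @export
setClass("BinaryMask",
    representation(mask = "matrix", channelName = "character",
                   windowPx = "integer"))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (anyNA(object@mask)) return("mask must not contain NA")
    if (length(object@windowPx) != 1L || object@windowPx < 1L)
        return("windowPx must be a positive integer")
    TRUE
})

#' CellLabelMap: per-cell pixel masks from seeded watershed
#'
#' Pixel value k > 0 means the pixel belongs to cell k (the k-th seed);
#' 0 means unassigned (farther than `radiusPx` from every seed).
#'
#' @slot labels Integer matrix of cell indices (0 = none).
#' @slot seeds Numeric n x 2 matrix of seed centers, columns x, y (0-based).
#' @slot radiusPx Maximum cell radius in pixels.
#' @export
setClass("CellLabelMap",
    representation(labels = "matrix", seeds = "matrix", radiusPx = "integer"))

setValidity("CellLabelMap", function(object) {
    if (!is.integer(object@labels)) return("labels must be integer")
    if (ncol(object@seeds) != 2L) return("seeds must be an n x 2 matrix")
    if (max(object@labels) > nrow(object@seeds))
        return("label exceeds number of seeds")
    if (length(object@radiusPx) != 1L || object@radiusPx < 1L)
        return("radiusPx must be a positive integer")
    TRUE
})

#' TissueScenario: parameters of one synthetic study condition
#'
#' Encodes a group's study condition: per-region per-marker expression
#' probabilities, conditional co-expression probabilities for marker pairs
#' (P(B|A), applied to cells already positive for A; A-negative cells receive
#' the complementary probability that preserves the configured marginal),
#' cell and vessel densities per region, and the optics nuisances (shot-noise
#' level, multiplicative illumination-gradient amplitude).
#'
#' @slot groupLabel One of "F", "CTRL", "OA".
#' @slot markerProbs Named list: region -> named numeric of marker
#'   probabilities in `[0, 1]`.
#' @slot colocProbs Named list: region -> named numeric of conditional
#'   probabilities, names of the form `"A:B"` meaning P(B positive | A positive).
#' @slot cellDensity Named numeric, cells per mm^2 per region (ICL > 0).
#' @slot vesselDensity Named numeric, vessels per mm^2 per region.
#' @slot pixelSizeUm Micrometers per pixel.
#' @slot noiseLevel Shot-noise scale (0 = noise-free).
#' @slot illumGradientAmplitude Multiplicative gradient amplitude in `[0, 1)`.
#' @export
setClass("TissueScenario",
    representation(groupLabel = "character", markerProbs = "list",
                   colocProbs = "list", cellDensity = "numeric",
                   vesselDensity = "numeric", pixelSizeUm = "numeric",
                   noiseLevel = "numeric", illumGradientAmplitude = "numeric"))

setValidity("TissueScenario", function(object) {
    if (!object@groupLabel %in% .GROUPS)
        return(sprintf("groupLabel must be one of %s", paste(.GROUPS, collapse = ", ")))
    for (rg in names(object@markerProbs)) {
        p <- object@markerProbs[[rg]]
        if (is.null(names(p)) || any(p < 0) || any(p > 1))
            return("markerProbs must be named probabilities in [0, 1]")
    }
    for (rg in names(object@colocProbs)) {
        p <- object@colocProbs[[rg]]
        if (length(p) && (is.null(names(p)) || any(p < 0) || any(p > 1) ||
            any(!grepl(":", names(p)))))
            return("colocProbs must be named 'A:B' probabilities in [0, 1]")
    }
    if (any(object@cellDensity < 0)) return("cell densities must be non-negative")
    if (!"ICL" %in% names(object@cellDensity) || object@cellDensity[["ICL"]] <= 0)
        return("ICL cell density must be strictly positive")
    if (any(object@vesselDensity < 0)) return("vessel densities must be non-negative")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    if (object@noiseLevel < 0) return("noiseLevel must be non-negative")
    if (object@illumGradientAmplitude < 0 || object@illumGradientAmplitude >= 1)
        return("illumGradientAmplitude must be in [0, 1)")
    TRUE
})

#' GroundTruthSection: one synthetic section with known per-cell truth
#'
#' @slot regionPolygons List of `list(class = <region name>, coords = <n x 2
#'   matrix>)` polygons in 0-based pixel coordinates (x = column, y = row).
#' @slot cells data.frame with columns `x`, `y`, `region` and one logical
#'   column per marker.
#' @slot vessels List of `list(coords = <n x 2 matrix>, region = <name>)`.
#' @slot imageShape Integer c(rows, cols).
#' @slot pixelSizeUm Micrometers per pixel.
#' @slot groupLabel Group the generating scenario belonged to.
#' @slot sampleID Sample identifier.
#' @export
setClass("GroundTruthSection",
    representation(regionPolygons = "list", cells = "data.frame",
                   vessels = "list", imageShape = "integer",
                   pixelSizeUm = "numeric", groupLabel = "character",
                   sampleID = "character"))

setValidity("GroundTruthSection", function(object) {
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
        return("imageShape must be c(rows, cols)")
    need <- c("x", "y", "region")
    if (!all(need %in% names(object@cells)))
        return("cells must have columns x, y, region")
    cls <- vapply(object@regionPolygons, function(p) p$class, character(1))
    if (!all(cls %in% names(.REGION_CODES)))
        return("unknown region class in regionPolygons")
    TRUE
})

#' SampleMeasurements: one sample's region x variable metric table
#'
#' Long-format per-sample output of [measureSample()]: one row per
#' (region, variable) with value, units and a flag ("ok", or a reason the
#' value is missing, e.g. "undefined_parent" for a co-localization ratio
#' whose parent marker area is empty).
#'
#' @slot sampleID Sample identifier.
#' @slot group Group label.
#' @slot rows data.frame with columns region, variable, value, units, flag.
#' @export
setClass("SampleMeasurements",
    representation(sampleID = "character", group = "character",
                   rows = "data.frame"))

setValidity("SampleMeasurements", function(object) {
    need <- c("region", "variable", "value", "units", "flag")
    if (!all(need %in% names(object@rows)))
        return("rows must have columns region, variable, value, units, flag")
    r <- object@rows
    ok <- r$flag == "ok" & !is.na(r$value)
    pct <- grepl("_pct$", r$variable)
    if (any(ok & pct & (r$value < 0 | r$value > 100)))
        return("percent variables must lie in [0, 100]")
    if (any(ok & !pct & r$value < 0))
        return("density variables must be non-negative")
    TRUE
})

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "RegionLabelMap", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "GroundTruthSection", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("sampleID", "CalibratedImage", function(x) x@sampleID)
#' @rdname accessors
#' @export
setMethod("sampleID", "GroundTruthSection", function(x) x@sampleID)
#' @rdname accessors
#' @export
setMethod("sampleID", "SampleMeasurements", function(x) x@sampleID)
#' @rdname accessors
#' @export
setMethod("channelNames", "CalibratedImage", function(x) names(x@channels))
#' @rdname accessors
#' @export
setMethod("getChannel", "CalibratedImage", function(x, name) {
    if (!name %in% names(x@channels))
        stop(sprintf("no channel '%s' (have: %s)", name,
                     paste(names(x@channels), collapse = ", ")))
    x@channels[[name]]
})
#' @rdname accessors
#' @export
setMethod("imageShape", "CalibratedImage", function(x) dim(x@channels[[1L]]))
#' @rdname accessors
#' @export
setMethod("imageShape", "RegionLabelMap", function(x) dim(x@labels))
#' @rdname accessors
#' @export
setMethod("imageShape", "GroundTruthSection", function(x) x@imageShape)
#' @rdname accessors
#' @export
setMethod("labelMatrix", "RegionLabelMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelMatrix", "CellLabelMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("windowPx", "BinaryMask", function(x) x@windowPx)
#' @rdname accessors
#' @export
setMethod("radiusPx", "CellLabelMap", function(x) x@radiusPx)
#' @rdname accessors
#' @export
setMethod("seedCoords", "CellLabelMap", function(x) x@seeds)
#' @rdname accessors
#' @export
setMethod("groupLabel", "TissueScenario", function(x) x@groupLabel)
#' @rdname accessors
#' @export
setMethod("groupLabel", "GroundTruthSection", function(x) x@groupLabel)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SampleMeasurements", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("markerNames", "TissueScenario", function(x) {
    names(x@markerProbs[[1L]])
})
#' @rdname accessors
#' @export
setMethod("markerNames", "GroundTruthSection", function(x) {
    setdiff(names(x@cells), c("x", "y", "region"))
})
#' @rdname accessors
#' @export
setMethod("cellTable", "GroundTruthSection", function(x) x@cells)
#' @rdname accessors
#' @export
setMethod("regionPolygons", "GroundTruthSection", function(x) x@regionPolygons)
#' @rdname accessors
#' @export
setMethod("vesselPolygons", "GroundTruthSection", function(x) x@vessels)
#' @rdname accessors
#' @export
setMethod("measurementRows", "SampleMeasurements", function(x) x@rows)

#' @rdname accessors
#' @export
setMethod("regionAreas", "RegionLabelMap", function(x) {
    pxArea <- (x@pixelSizeUm / 1000)^2
    counts <- tabulate(x@labels + 1L, nbins = 5L)
    stats::setNames(counts * pxArea, names(.REGION_CODES))
})

## ---- show methods ----

setMethod("show", "CalibratedImage", function(object) {
    d <- imageShape(object)
    cat(sprintf("CalibratedImage '%s': %d x %d px, %.3g um/px, channels: %s\n",
        object@sampleID, d[1L], d[2L], object@pixelSizeUm,
        paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "RegionLabelMap", function(object) {
    a <- regionAreas(object)
    d <- dim(object@labels)
    cat(sprintf("RegionLabelMap: %d x %d px, %.3g um/px\n", d[1L], d[2L],
                object@pixelSizeUm))
    for (nm in names(a))
        cat(sprintf("  %-10s %8.5f mm^2\n", nm, a[[nm]]))
})

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask '%s': %d x %d px, %d positive (%.2f%%), window %d px\n",
        object@channelName, nrow(object@mask), ncol(object@mask),
        sum(object@mask), 100 * mean(object@mask), object@windowPx))
})

setMethod("show", "CellLabelMap", function(object) {
    cat(sprintf("CellLabelMap: %d seeds, radius %d px, %d labelled px\n",
        nrow(object@seeds), object@radiusPx, sum(object@labels > 0L)))
})

setMethod("show", "TissueScenario", function(object) {
    cat(sprintf("TissueScenario group %s: markers %s; %.3g um/px, noise %.3g, gradient %.3g\n",
        object@groupLabel, paste(markerNames(object), collapse = "/"),
        object@pixelSizeUm, object@noiseLevel, object@illumGradientAmplitude))
})

setMethod("show", "GroundTruthSection", function(object) {
    cat(sprintf("GroundTruthSection '%s' (group %s): %d x %d px, %d cells, %d vessels, %d region polygons\n",
        object@sampleID, object@groupLabel, object@imageShape[1L],
        object@imageShape[2L], nrow(object@cells), length(object@vessels),
        length(object@regionPolygons)))
})

setMethod("show", "SampleMeasurements", function(object) {
    cat(sprintf("SampleMeasurements '%s' (group %s): %d rows\n",
        object@sampleID, object@group, nrow(object@rows)))
    print(utils::head(object@rows, 8L))
    if (nrow(object@rows) > 8L) cat("  ...\n")
})
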