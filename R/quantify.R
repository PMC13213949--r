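#' Marker-positive area fraction within a tissue region
#'
#' Percentage of a region's pixels that are positive in a binary marker mask.
#' EXCLUDED and BACKGROUND pixels enter neither numerator nor denominator.
#'
#' @param mask A [BinaryMask-class].
#' @param labels A [RegionLabelMap-class] of the same shape.
#' @param region One of "ICL", "SI_V", "SI_N".
#' @return Percent in `[0, 100]`.
#' @export
positiveAreaFraction <- function(mask, labels, region) {
    stopifnot(is(mask, "BinaryMask"), is(labels, "RegionLabelMap"))
    if (!identical(dim(mask@mask), dim(labels@labels)))
        stop("mask and label map shapes differ")
    if (!region %in% .TISSUE_REGIONS)
        stop(sprintf("region must be one of %s", paste(.TISSUE_REGIONS, collapse = ", ")))
    inReg <- labels@labels == .REGION_CODES[[region]]
    denom <- sum(inReg)
    if (denom == 0L) stop(sprintf("region %s is empty", region))
    100 * sum(mask@mask & inReg) / denom
}

#' Co-localization ratio within a tissue region
#'
#' Double-positive area as a percentage of the parent single-marker area in
#' the region: if the parent area is 10 units and the double-positive area is
#' 8 units, the ratio is 80 %. An empty parent leaves the ratio undefined:
#' NA is returned with attribute `flag = "undefined_parent"` so downstream
#' statistics can exclude it rather than treat it as 0 or 100.
#'
#' @param parentMask Parent marker [BinaryMask-class] (e.g. CD14).
#' @param colocMask Double-positive [BinaryMask-class], a subset of the
#'   parent by construction via [colocalize()].
#' @param labels A [RegionLabelMap-class].
#' @param region One of "ICL", "SI_V", "SI_N".
#' @return Percent in `[0, 100]`, or NA when the parent area is empty.
#' @export
colocRatio <- function(parentMask, colocMask, labels, region) {
    stopifnot(is(parentMask, "BinaryMask"), is(colocMask, "BinaryMask"),
              is(labels, "RegionLabelMap"))
    if (!region %in% .TISSUE_REGIONS)
        stop(sprintf("region must be one of %s", paste(.TISSUE_REGIONS, collapse = ", ")))
    inReg <- labels@labels == .REGION_CODES[[region]]
    if (any(colocMask@mask & !parentMask@mask & inReg))
        stop("co-localization mask is not a subset of the parent mask in the region")
    parent <- sum(parentMask@mask & inReg)
    if (parent == 0L) {
        out <- NA_real_
        attr(out, "flag") <- "undefined_parent"
        return(out)
    }
    100 * sum(colocMask@mask & inReg) / parent
}

#' Vessel density and perimeter per tissue region
#'
#' Each vessel outline is assigned to the region containing its polygon
#' centroid; per region the count per mm^2 and the mean outline perimeter in
#' micrometers are reported. Vessels whose centroid falls on BACKGROUND or
#' EXCLUDED are counted as unassigned.
#'
#' @param vessels List of vessel outlines: either bare n x 2 coordinate
#'   matrices or `list(coords = ..., ...)` entries (as stored in a
#'   [GroundTruthSection-class]).
#' @param labels A [RegionLabelMap-class].
#' @return data.frame with one row per tissue region: region, count,
#'   countPerMm2, meanPerimeterUm (NA when no vessels); attribute
#'   `nUnassigned` carries the unassigned vessel count.
#' @export
vesselMetrics <- function(vessels, labels) {
    stopifnot(is(labels, "RegionLabelMap"))
    coords <- lapply(vessels, function(v) if (is.list(v)) v$coords else v)
    areas <- regionAreas(labels)
    if (length(coords)) {
        cent <- t(vapply(coords, polygonCentroid, numeric(2)))
        asg <- assignPoints(cent, labels)
        per <- vapply(coords, polygonPerimeter, numeric(1)) * labels@pixelSizeUm
    } else {
        asg <- data.frame(region = character(0), assigned = logical(0))
        per <- numeric(0)
    }
    out <- do.call(rbind, lapply(.TISSUE_REGIONS, function(rg) {
        sel <- which(asg$assigned & asg$region == rg)
        data.frame(region = rg, count = length(sel),
                   countPerMm2 = if (areas[[rg]] > 0) length(sel) / areas[[rg]] else NA_real_,
                   meanPerimeterUm = if (length(sel)) mean(per[sel]) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    attr(out, "nUnassigned") <- if (nrow(asg)) sum(!asg$assigned) else 0L
    out
}

#' Assemble one sample's full measurement table
#'
#' Computes all per-sample metrics in one long-format table: for every
#' marker and region the positive area fraction (`<marker>_area_pct`), for
#' every configured marker pair the co-localization ratio
#' (`<A>_<B>_ratio_pct`), the intimal cell density (`cell_density`, ICL
#' only), and the vessel density (`vessel_density`) per region. Undefined
#' ratios are flagged, never silently zero.
#'
#' @param image A [CalibratedImage-class] (geometry and identity reference).
#' @param masks Named list of marker [BinaryMask-class] objects.
#' @param cellLabels Optional [CellLabelMap-class] (not used by the area
#'   metrics; carried for per-cell secondary outputs).
#' @param seeds n x 2 matrix of manually marked cell centers.
#' @param labels A [RegionLabelMap-class].
#' @param vessels List of vessel outlines (see [vesselMetrics()]).
#' @param group Group label ("F", "CTRL", "OA").
#' @param colocPairs List of length-2 character vectors `c(parent, child)`;
#'   defaults to CD14:CD16 and CD14:CD206 when those markers are present.
#' @return A [SampleMeasurements-class].
#' @export
measureSample <- function(image, masks, cellLabels = NULL, seeds, labels,
                          vessels = list(), group = "CTRL",
                          colocPairs = NULL) {
    stopifnot(is(image, "CalibratedImage"), is(labels, "RegionLabelMap"))
    if (!identical(imageShape(image), dim(labels@labels)))
        stop("image and label map shapes differ")
    if (abs(pixelSize(image) - pixelSize(labels)) > 1e-9)
        stop(sprintf("pixel size mismatch for sample '%s'", sampleID(image)))
    if (is.null(colocPairs)) {
        colocPairs <- Filter(function(p) all(p %in% names(masks)),
                             list(c("CD14", "CD16"), c("CD14", "CD206")))
    }
    rows <- list()
    addRow <- function(region, variable, value, units, flag = "ok") {
        rows[[length(rows) + 1L]] <<- data.frame(
            region = region, variable = variable, value = value,
            units = units, flag = flag, stringsAsFactors = FALSE)
    }
    for (mk in names(masks)) {
        for (rg in .TISSUE_REGIONS)
            addRow(rg, paste0(mk, "_area_pct"),
                   positiveAreaFraction(masks[[mk]], labels, rg), "%")
    }
    for (pair in colocPairs) {
        cm <- colocalize(masks[[pair[1L]]], masks[[pair[2L]]])
        for (rg in .TISSUE_REGIONS) {
            v <- colocRatio(masks[[pair[1L]]], cm, labels, rg)
            addRow(rg, paste0(pair[1L], "_", pair[2L], "_ratio_pct"),
                   as.numeric(v), "%",
                   flag = if (is.na(v)) attr(v, "flag") else "ok")
        }
    }
    addRow("ICL", "cell_density", countSeedDensity(seeds, "ICL", labels),
           "cells/mm2")
    vm <- vesselMetrics(vessels, labels)
    for (i in seq_len(nrow(vm))) {
        addRow(vm$region[i], "vessel_density", vm$countPerMm2[i], "BV/mm2",
               flag = if (is.na(vm$countPerMm2[i])) "empty_region" else "ok")
    }
    new("SampleMeasurements", sampleID = sampleID(image),
        group = as.character(group), rows = do.call(rbind, rows))
}

#' Per-cell marker positivity (secondary output)
#'
#' For each cell mask in a [CellLabelMap-class], the fraction of its pixels
#' positive in a marker mask and a positivity call at a pixel-fraction
#' cutoff. This is the cell-count-based view of marker expression, kept
#' separate from the area-based fractions and ratios.
#'
#' @param cellLabels A [CellLabelMap-class].
#' @param mask A [BinaryMask-class].
#' @param minFraction Fraction of a cell's pixels that must be positive for
#'   the cell to be called positive.
#' @return data.frame: cell, nPixels, positiveFraction, positive.
#' @export
cellPositivity <- function(cellLabels, mask, minFraction = 0.1) {
    stopifnot(is(cellLabels, "CellLabelMap"), is(mask, "BinaryMask"))
    n <- nrow(cellLabels@seeds)
    lab <- cellLabels@labels
    sizes <- tabulate(lab, nbins = n)
    pos <- tabulate(lab[mask@mask], nbins = n)
    frac <- ifelse(sizes > 0L, pos / sizes, NA_real_)
    data.frame(cell = seq_len(n), nPixels = sizes, positiveFraction = frac,
               positive = !is.na(frac) & frac >= minFraction)
}
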