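#' Locally adaptive mean binarization of a fluorescence channel
#'
#' A pixel is positive iff its intensity strictly exceeds the unweighted mean
#' of the square neighborhood of half-width `windowPx` centered on it (window
#' side `2 * windowPx + 1`), with symmetric reflect padding at the borders.
#' This is the local-mean reading of adaptive thresholding with the filter
#' width expressed as the neighborhood radius; the default of 50 px is the
#' standard setting for slide-scanned fluorescence channels.
#'
#' The local mean is computed with an integral image on data centered at one
#' pixel's value, so a constant channel yields an all-false mask exactly.
#'
#' @param channel Numeric matrix of non-negative finite intensities, or a
#'   [CalibratedImage-class] together with `channelName`.
#' @param windowPx Neighborhood half-width in pixels (>= 1). A window larger
#'   than the image degenerates to a global-mean threshold, with a warning.
#' @param channelName Channel to take when `channel` is a CalibratedImage,
#'   and the name recorded on the mask.
#' @return A [BinaryMask-class].
#' @examples
#' x <- matrix(0, 16, 16); x[8, 8] <- 1
#' m <- localAdaptiveBinarize(x, windowPx = 5)
#' sum(maskMatrix(m))  # 1
#' @export
localAdaptiveBinarize <- function(channel, windowPx = 50L, channelName = "") {
    if (is(channel, "CalibratedImage")) {
        if (!nzchar(channelName)) stop("channelName required for a CalibratedImage")
        channel <- getChannel(channel, channelName)
    }
    stopifnot(is.matrix(channel))
    if (anyNA(channel) || any(!is.finite(channel)))
        stop("channel contains non-finite pixels")
    w <- as.integer(windowPx)
    if (length(w) != 1L || is.na(w) || w < 1L) stop("windowPx must be >= 1")
    nr <- nrow(channel); nc <- ncol(channel)
    if (w > min(nr, nc)) {
        warning(sprintf("window half-width %d exceeds image size %dx%d; using global mean",
                        w, nr, nc))
        mask <- channel > mean(channel)
    } else {
        # center on one pixel's value: keeps a constant image exactly at zero
        y <- channel - channel[1L, 1L]
        ri <- c(w:1, 1:nr, nr:(nr - w + 1L))
        ci <- c(w:1, 1:nc, nc:(nc - w + 1L))
        mask <- y > box_mean_cpp(y[ri, ci, drop = FALSE], w, nr, nc)
        # a pixel at the image minimum cannot strictly exceed a mean of
        # values >= that minimum; enforcing this exactly protects flat
        # (e.g. zero-background) areas from integral-image rounding
        mask[y == min(y)] <- FALSE
    }
    new("BinaryMask", mask = mask, channelName = as.character(channelName),
        windowPx = w)
}

#' Co-localization of two binary masks
#'
#' Pixel-level co-localization by multiplication of binary masks, i.e. the
#' elementwise logical AND. Commutative; the result never exceeds either
#' operand.
#'
#' @param maskA,maskB [BinaryMask-class] objects of equal shape.
#' @return A [BinaryMask-class] named `"A:B"`.
#' @export
colocalize <- function(maskA, maskB) {
    stopifnot(is(maskA, "BinaryMask"), is(maskB, "BinaryMask"))
    if (!identical(dim(maskA@mask), dim(maskB@mask)))
        stop("colocalize: mask shapes differ")
    new("BinaryMask", mask = maskA@mask & maskB@mask,
        channelName = paste(maskA@channelName, maskB@channelName, sep = ":"),
        windowPx = maskA@windowPx)
}

#' Per-cell masks from manually marked centers
#'
#' Seeded watershed of the seed distance transform, restricted to disks of
#' radius `radiusPx`: each pixel within `radiusPx` of at least one seed is
#' assigned to its nearest seed (Euclidean distance between pixel center and
#' seed), ties broken toward the lower seed index; pixels farther than
#' `radiusPx` from every seed stay unlabelled. The 15 px default is the
#' empirically determined average synovial lining cell radius.
#'
#' @param seeds n x 2 matrix (or data.frame) of seed centers, columns x, y in
#'   0-based pixel coordinates. Seeds outside the image yield empty masks.
#' @param imageShape Integer c(rows, cols).
#' @param radiusPx Maximum cell radius in pixels.
#' @return A [CellLabelMap-class].
#' @export
cellMasksFromSeeds <- function(seeds, imageShape, radiusPx = 15L) {
    pts <- as.matrix(as.data.frame(seeds)[, 1:2])
    if (nrow(pts)) {
        dup <- duplicated(pts)
        if (any(dup))
            stop(sprintf("duplicate seeds at indices: %s",
                         paste(which(dup), collapse = ", ")))
    }
    r <- as.integer(radiusPx)
    stopifnot(length(imageShape) == 2L, r >= 1L)
    lab <- nearest_seed_cpp(pts[, 1L], pts[, 2L],
                            as.integer(imageShape[1L]),
                            as.integer(imageShape[2L]), as.numeric(r))
    new("CellLabelMap", labels = lab, seeds = pts, radiusPx = r)
}

#' Seed density within a tissue region
#'
#' Number of manually marked cell centers assigned to a region, divided by
#' the region's area in mm^2.
#'
#' @param seeds n x 2 matrix of cell centers (x, y).
#' @param region Region name, usually "ICL".
#' @param labels A [RegionLabelMap-class].
#' @return Cells per mm^2 (scalar).
#' @export
countSeedDensity <- function(seeds, region = "ICL", labels) {
    stopifnot(is(labels, "RegionLabelMap"))
    if (!region %in% .TISSUE_REGIONS)
        stop(sprintf("region must be one of %s", paste(.TISSUE_REGIONS, collapse = ", ")))
    area <- regionAreas(labels)[[region]]
    if (area <= 0)
        stop(sprintf("region %s has zero area", region))
    asg <- assignPoints(seeds, labels)
    sum(asg$assigned & asg$region == region, na.rm = TRUE) / area
}
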