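#' Rasterize tissue-region polygons into a label map
#'
#' Converts manually delineated region polygons into a per-pixel region
#' partition. A pixel belongs to a region iff its center (0-based integer
#' coordinates, x = column, y = row) lies inside the polygon by the even-odd
#' rule; overlaps are resolved by the fixed precedence
#' EXCLUDED > ICL > SI_V > SI_N, and remaining pixels are BACKGROUND.
#'
#' @param polygons List of `list(class = <"ICL"|"SI_V"|"SI_N"|"EXCLUDED">,
#'   coords = <n x 2 matrix of x, y>)`; closed rings may repeat the first
#'   vertex. Coordinates outside the image are clipped.
#' @param imageShape Integer c(rows, cols).
#' @param pixelSizeUm Micrometers per pixel.
#' @return A [RegionLabelMap-class].
#' @examples
#' sq <- list(class = "SI_V", coords = cbind(c(1.5, 5.5, 5.5, 1.5),
#'                                           c(1.5, 1.5, 5.5, 5.5)))
#' m <- rasterizeRegions(list(sq), c(8, 8), 0.5)
#' sum(labelMatrix(m) == regionCodes()[["SI_V"]])  # 16 pixels
#' @export
rasterizeRegions <- function(polygons, imageShape, pixelSizeUm) {
    stopifnot(length(imageShape) == 2L, pixelSizeUm > 0)
    nr <- as.integer(imageShape[1L]); nc <- as.integer(imageShape[2L])
    labels <- matrix(.REGION_CODES[["BACKGROUND"]], nr, nc)
    for (i in seq_along(polygons)) {
        cls <- polygons[[i]]$class
        if (!cls %in% names(.REGION_CODES) || cls == "BACKGROUND")
            stop(sprintf("polygon %d: unknown region class '%s'", i, cls))
        coords <- openRing(polygons[[i]]$coords)
        if (nrow(coords) < 3L)
            stop(sprintf("polygon %d: fewer than 3 vertices", i))
        if (polygonSelfIntersects(coords))
            stop(sprintf("polygon %d (%s): self-intersecting", i, cls))
    }
    # paint in increasing precedence so higher-precedence classes overwrite
    order <- c("SI_N", "SI_V", "ICL", "EXCLUDED")
    for (cls in order) {
        for (p in polygons) {
            if (p$class != cls) next
            coords <- openRing(p$coords)
            x0 <- max(0L, as.integer(ceiling(min(coords[, 1L]))))
            x1 <- min(nc - 1L, as.integer(floor(max(coords[, 1L]))))
            y0 <- max(0L, as.integer(ceiling(min(coords[, 2L]))))
            y1 <- min(nr - 1L, as.integer(floor(max(coords[, 2L]))))
            if (x0 > x1 || y0 > y1) next
            inside <- pip_grid_cpp(coords[, 1L], coords[, 2L],
                                   x0, y0, x1 - x0 + 1L, y1 - y0 + 1L)
            sub <- labels[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
            sub[inside] <- .REGION_CODES[[cls]]
            labels[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- sub
        }
    }
    new("RegionLabelMap", labels = labels, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Assign points to tissue regions
#'
#' Maps each point to the region label of the pixel containing it (floor of
#' both coordinates). Points on EXCLUDED or BACKGROUND pixels, and points
#' outside the image, are flagged unassigned rather than dropped.
#'
#' @param points n x 2 matrix or data.frame with columns x, y (0-based pixel
#'   coordinates).
#' @param labels A [RegionLabelMap-class].
#' @return data.frame with columns x, y, region (NA when unassignable),
#'   assigned (logical) and flag ("ok", "unassigned", "out_of_bounds"); the
#'   out-of-bounds count is attached as attribute `nOutOfBounds`.
#' @export
assignPoints <- function(points, labels) {
    stopifnot(is(labels, "RegionLabelMap"))
    pts <- as.matrix(as.data.frame(points)[, 1:2])
    lm <- labels@labels
    nr <- nrow(lm); nc <- ncol(lm)
    col <- floor(pts[, 1L]); row <- floor(pts[, 2L])
    oob <- col < 0 | col >= nc | row < 0 | row >= nr
    code <- rep(NA_integer_, nrow(pts))
    code[!oob] <- lm[cbind(row[!oob] + 1L, col[!oob] + 1L)]
    nm <- names(.REGION_CODES)
    region <- nm[code + 1L]
    assigned <- !oob & region %in% .TISSUE_REGIONS
    region[!assigned] <- NA_character_
    flag <- ifelse(oob, "out_of_bounds", ifelse(assigned, "ok", "unassigned"))
    out <- data.frame(x = pts[, 1L], y = pts[, 2L], region = region,
                      assigned = assigned, flag = flag,
                      stringsAsFactors = FALSE)
    attr(out, "nOutOfBounds") <- sum(oob)
    out
}

#' Check the villus morphology criterion on a polygon
#'
#' A synovial villus is identified by being taller than wide; this tests the
#' polygon bounding box for strict height > width.
#'
#' @param coords n x 2 matrix of polygon vertices (x, y).
#' @return TRUE iff bounding-box height strictly exceeds width.
#' @examples
#' villusShapeCheck(cbind(c(0, 60, 30), c(0, 0, 100)))  # TRUE
#' @export
villusShapeCheck <- function(coords) {
    coords <- openRing(coords)
    if (nrow(coords) < 3L || nrow(unique(coords)) < 3L)
        stop("degenerate polygon: fewer than 3 distinct vertices")
    h <- diff(range(coords[, 2L]))
    w <- diff(range(coords[, 1L]))
    h > w
}

#' Write / read a region label map as plain files
#'
#' The label map is stored as an 8-bit single-channel TIFF holding the region
#' codes 0--4, next to a JSON summary of region areas in mm^2.
#'
#' @param labels A [RegionLabelMap-class].
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>_areas.json`.
#' @return `writeLabelMapTIFF` the prefix, invisibly; `readLabelMapTIFF` a
#'   [RegionLabelMap-class].
#' @export
writeLabelMapTIFF <- function(labels, prefix) {
    stopifnot(is(labels, "RegionLabelMap"))
    tiff::writeTIFF(labels@labels / 255, paste0(prefix, ".tif"),
                    bits.per.sample = 8L)
    jsonlite::write_json(
        list(pixel_size_um = labels@pixelSizeUm,
             areas_mm2 = as.list(regionAreas(labels))),
        paste0(prefix, "_areas.json"), auto_unbox = TRUE, digits = NA)
    invisible(prefix)
}

#' @rdname writeLabelMapTIFF
#' @export
readLabelMapTIFF <- function(prefix) {
    m <- tiff::readTIFF(paste0(prefix, ".tif"))
    meta <- jsonlite::read_json(paste0(prefix, "_areas.json"))
    lab <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    new("RegionLabelMap", labels = lab,
        pixelSizeUm = as.numeric(meta$pixel_size_um))
}
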