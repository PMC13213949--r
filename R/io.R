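# Plain-text / TIFF interchange formats: single-channel 16-bit TIFFs per
# fluorescence channel, GeoJSON FeatureCollections for region and vessel
# polygons (pixel coordinates, x = column, y = row), CSV for seeds and
# analytes.

.closeRing <- function(coords) {
    coords <- openRing(coords)
    rbind(coords, coords[1L, , drop = FALSE])
}

.featureCollection <- function(features) {
    list(type = "FeatureCollection", features = features)
}

.polygonFeature <- function(coords, properties) {
    list(type = "Feature", properties = properties,
         geometry = list(type = "Polygon",
                         coordinates = list(.closeRing(coords))))
}

#' Write / read a multi-channel image as single-channel 16-bit TIFFs
#'
#' One file `<sampleID>_<channel>.tif` per channel plus a JSON sidecar
#' `<sampleID>_image.json` recording the pixel size and channel names.
#'
#' @param image A [CalibratedImage-class] with intensities in `[0, 1]`.
#' @param dir Output directory.
#' @param sampleID Sample to read back.
#' @return `writeImageTIFF`: the sidecar path, invisibly. `readImageTIFF`:
#'   a [CalibratedImage-class].
#' @export
writeImageTIFF <- function(image, dir) {
    stopifnot(is(image, "CalibratedImage"))
    id <- sampleID(image)
    if (!nzchar(id)) stop("image needs a sampleID to be written")
    for (ch in channelNames(image)) {
        m <- getChannel(image, ch)
        tiff::writeTIFF(pmin(pmax(m, 0), 1),
                        file.path(dir, sprintf("%s_%s.tif", id, ch)),
                        bits.per.sample = 16L)
    }
    side <- file.path(dir, sprintf("%s_image.json", id))
    jsonlite::write_json(list(sample_id = id,
                              pixel_size_um = pixelSize(image),
                              channels = channelNames(image)),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(side)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(dir, sampleID) {
    meta <- jsonlite::read_json(file.path(dir, sprintf("%s_image.json", sampleID)))
    chn <- unlist(meta$channels)
    channels <- lapply(chn, function(ch) {
        f <- file.path(dir, sprintf("%s_%s.tif", sampleID, ch))
        if (!file.exists(f)) stop(sprintf("missing channel file '%s'", f))
        m <- tiff::readTIFF(f)
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        m
    })
    calibratedImage(stats::setNames(channels, chn),
                    as.numeric(meta$pixel_size_um), sampleID)
}

#' Write / read region polygons as GeoJSON
#'
#' One Feature per region polygon with property `region_class` in
#' ICL / SI_V / SI_N / EXCLUDED; coordinates in 0-based pixel units.
#'
#' @param polygons List of `list(class = ..., coords = ...)` polygons.
#' @param path GeoJSON file path.
#' @return `writeRegionsGeoJSON`: `path`, invisibly; `readRegionsGeoJSON`:
#'   the polygon list.
#' @export
writeRegionsGeoJSON <- function(polygons, path) {
    feats <- lapply(polygons, function(p)
        .polygonFeature(p$coords, list(region_class = p$class)))
    jsonlite::write_json(.featureCollection(feats), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeRegionsGeoJSON
#' @export
readRegionsGeoJSON <- function(path) {
    g <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(g$features, function(f) {
        ring <- f$geometry$coordinates[[1L]]
        coords <- do.call(rbind, lapply(ring, function(xy)
            c(as.numeric(xy[[1L]]), as.numeric(xy[[2L]]))))
        list(class = f$properties$region_class, coords = openRing(coords))
    })
}

#' Write / read vessel outlines as GeoJSON
#'
#' One Feature per vessel with properties `kind = "vessel"` and the region
#' class the vessel was generated in (when known).
#'
#' @param vessels List of `list(coords = ..., region = ...)` outlines.
#' @param path GeoJSON file path.
#' @return `writeVesselsGeoJSON`: `path`, invisibly; `readVesselsGeoJSON`:
#'   the vessel list.
#' @export
writeVesselsGeoJSON <- function(vessels, path) {
    feats <- lapply(vessels, function(v)
        .polygonFeature(v$coords, list(kind = "vessel",
                                       region_class = v$region)))
    jsonlite::write_json(.featureCollection(feats), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeVesselsGeoJSON
#' @export
readVesselsGeoJSON <- function(path) {
    g <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(g$features, function(f) {
        ring <- f$geometry$coordinates[[1L]]
        coords <- do.call(rbind, lapply(ring, function(xy)
            c(as.numeric(xy[[1L]]), as.numeric(xy[[2L]]))))
        list(coords = openRing(coords),
             region = f$properties$region_class %||% NA_character_)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read manually punctuated cell centers as CSV
#'
#' Header `sample_id,x,y`, coordinates in 0-based pixel units.
#'
#' @param seeds n x 2 matrix or data.frame of centers (x, y).
#' @param sampleID Sample identifier written on every row.
#' @param path CSV path.
#' @return `writeSeedsCSV`: `path`, invisibly; `readSeedsCSV`: data.frame
#'   with columns sample_id, x, y.
#' @export
writeSeedsCSV <- function(seeds, sampleID, path) {
    pts <- as.data.frame(as.matrix(as.data.frame(seeds)[, 1:2]))
    names(pts) <- c("x", "y")
    utils::write.csv(cbind(sample_id = sampleID, pts), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSeedsCSV
#' @export
readSeedsCSV <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the analyte concentration table as CSV
#'
#' Header `sample_id,group,analyte,value,lod` (concentrations and detection
#' limits in the assay's units, pg/ml unless noted).
#'
#' @param analytes data.frame with those columns.
#' @param path CSV path.
#' @return `writeAnalytesCSV`: `path`, invisibly; `readAnalytesCSV`: the
#'   data.frame.
#' @export
writeAnalytesCSV <- function(analytes, path) {
    need <- c("sample_id", "group", "analyte", "value", "lod")
    stopifnot(all(need %in% names(analytes)))
    utils::write.csv(analytes[, need], path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAnalytesCSV
#' @export
readAnalytesCSV <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
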