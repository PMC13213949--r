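#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate -> segment -> quantify -> stats
#' pipeline. The defaults are the modelled analysis settings: adaptive
#' threshold half-width 50 px, cell radius 15 px, alpha 0.050, and the
#' study's group sizes.
#'
#' @param markers Marker channel names to quantify.
#' @param colocPairs List of `c(parent, child)` marker pairs.
#' @param pixelSizeUm Micrometers per pixel.
#' @param windowPx Adaptive-threshold neighborhood half-width (pixels).
#' @param cellRadiusPx Watershed cell radius (pixels).
#' @param alpha Significance level.
#' @param seed Integer RNG seed.
#' @param nPerGroup Named integer vector of group sizes.
#' @param imageShape Per-sample image shape c(rows, cols).
#' @param scenarioArgs List of overrides forwarded to [cohortScenarios()]
#'   (e.g. `list(noiseLevel = 0)`).
#' @return List of class `synoRunConfig`.
#' @export
runConfig <- function(markers = c("CD14", "CD16", "CD206"),
                      colocPairs = list(c("CD14", "CD16"), c("CD14", "CD206")),
                      pixelSizeUm = 0.5, windowPx = 50L, cellRadiusPx = 15L,
                      alpha = 0.05, seed = 1L,
                      nPerGroup = c(F = 10L, CTRL = 11L, OA = 9L),
                      imageShape = c(512L, 512L), scenarioArgs = list()) {
    cfg <- list(markers = markers, colocPairs = colocPairs,
                pixelSizeUm = pixelSizeUm, windowPx = as.integer(windowPx),
                cellRadiusPx = as.integer(cellRadiusPx), alpha = alpha,
                seed = as.integer(seed), nPerGroup = nPerGroup,
                imageShape = as.integer(imageShape),
                scenarioArgs = scenarioArgs)
    class(cfg) <- "synoRunConfig"
    cfg
}

#' MD5 hash of a run configuration
#'
#' Stamped into every pipeline output header so outputs from different
#' configurations cannot be mixed silently.
#'
#' @param config A `synoRunConfig`.
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f))
    writeLines(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                             digits = NA)), f)
    unname(tools::md5sum(f))
}

.writeCSVWithHash <- function(df, path, hash) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash=%s", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

.readCSVWithHash <- function(path, expectHash = NULL) {
    first <- readLines(path, n = 1L)
    hash <- sub("^# config_hash=", "", first)
    if (!is.null(expectHash) && !identical(hash, expectHash))
        stop(sprintf("config hash mismatch for '%s' (%s vs %s)", path,
                     hash, expectHash))
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    attr(df, "configHash") <- hash
    df
}

#' Simulate a cohort and write it to disk
#'
#' Writes per-sample channel TIFFs, region and vessel GeoJSON, seed CSVs,
#' the analyte table, and a manifest JSON recording seed, config hash and
#' per-file MD5 checksums.
#'
#' @param config A `synoRunConfig`.
#' @param outDir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The cohort (as from [makeCohort()]), invisibly.
#' @export
runSimulate <- function(config = runConfig(), outDir, force = FALSE) {
    if (dir.exists(outDir) && length(list.files(outDir)) && !force)
        stop(sprintf("output dir '%s' is not empty (use force = TRUE)", outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    scen <- do.call(cohortScenarios,
                    c(list(pixelSizeUm = config$pixelSizeUm),
                      config$scenarioArgs))
    cohort <- makeCohort(scen, nPerGroup = config$nPerGroup,
                         seed = config$seed, imageShape = config$imageShape)
    files <- character(0)
    for (s in cohort$samples) {
        id <- s$sampleID
        writeImageTIFF(s$image, outDir)
        writeRegionsGeoJSON(regionPolygons(s$gt),
                            file.path(outDir, sprintf("%s_regions.geojson", id)))
        writeVesselsGeoJSON(vesselPolygons(s$gt),
                            file.path(outDir, sprintf("%s_vessels.geojson", id)))
        cells <- cellTable(s$gt)
        writeSeedsCSV(cells[, c("x", "y")], id,
                      file.path(outDir, sprintf("%s_seeds.csv", id)))
    }
    writeAnalytesCSV(cohort$analytes, file.path(outDir, "analytes.csv"))
    files <- setdiff(list.files(outDir), "manifest.json")
    sums <- tools::md5sum(file.path(outDir, files))
    jsonlite::write_json(list(
        seed = cohort$seed,
        config_hash = configHash(config),
        groups = names(config$nPerGroup),
        n_per_group = as.list(config$nPerGroup),
        samples = names(cohort$samples),
        files = as.list(stats::setNames(unname(sums), files))),
        file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    invisible(cohort)
}

# One sample's quantification: binarize markers, cell masks, measurement rows.
.quantifyOne <- function(image, polygons, seeds, vessels, group, config) {
    labels <- rasterizeRegions(polygons, imageShape(image), pixelSize(image))
    masks <- stats::setNames(lapply(config$markers, function(mk)
        localAdaptiveBinarize(image, windowPx = config$windowPx,
                              channelName = mk)), config$markers)
    cellLabels <- cellMasksFromSeeds(seeds, imageShape(image),
                                     radiusPx = config$cellRadiusPx)
    sm <- measureSample(image, masks, cellLabels, seeds, labels,
                        vessels = vessels, group = group,
                        colocPairs = config$colocPairs)
    asg <- assignPoints(seeds, labels)
    qc <- data.frame(sample_id = sampleID(image), group = group,
                     n_seeds = nrow(as.data.frame(seeds)),
                     n_seeds_unassigned = sum(!asg$assigned),
                     window_px = windowPx(masks[[1L]]),
                     cell_radius_px = radiusPx(cellLabels),
                     isotype_positive_pct = if ("ISO" %in% channelNames(image))
                         100 * mean(maskMatrix(localAdaptiveBinarize(image,
                             windowPx = config$windowPx, channelName = "ISO")))
                     else NA_real_,
                     stringsAsFactors = FALSE)
    list(measurements = sm, qc = qc)
}

#' Quantify a cohort (in memory or from disk)
#'
#' Runs segmentation and per-sample measurement for every sample of a
#' cohort. Accepts the in-memory bundle from [makeCohort()] /
#' [runSimulate()] or a directory written by [runSimulate()]. A failure in
#' any stage aborts with the stage and sample named.
#'
#' @param x Cohort list or directory path.
#' @param config A `synoRunConfig`.
#' @return List: `measurements` (long data.frame with sample_id, group,
#'   region, variable, value, units, flag), `qc` (per-sample QC
#'   data.frame), `perSample` (list of [SampleMeasurements-class]).
#' @export
runQuantify <- function(x, config = runConfig()) {
    inputs <- list()
    if (is.character(x)) {
        man <- jsonlite::read_json(file.path(x, "manifest.json"))
        for (id in unlist(man$samples)) {
            grp <- sub("[0-9]+$", "", id)
            inputs[[id]] <- list(
                id = id, group = grp,
                load = local({
                    id0 <- id; dir0 <- x
                    function() list(
                        image = readImageTIFF(dir0, id0),
                        polygons = readRegionsGeoJSON(file.path(dir0,
                            sprintf("%s_regions.geojson", id0))),
                        vessels = readVesselsGeoJSON(file.path(dir0,
                            sprintf("%s_vessels.geojson", id0))),
                        seeds = as.matrix(readSeedsCSV(file.path(dir0,
                            sprintf("%s_seeds.csv", id0)))[, c("x", "y")]))
                }))
        }
    } else {
        for (s in x$samples) {
            inputs[[s$sampleID]] <- list(
                id = s$sampleID, group = s$group,
                load = local({
                    s0 <- s
                    function() list(
                        image = s0$image,
                        polygons = regionPolygons(s0$gt),
                        vessels = vesselPolygons(s0$gt),
                        seeds = as.matrix(cellTable(s0$gt)[, c("x", "y")]))
                }))
        }
    }
    per <- list(); qc <- list(); rows <- list()
    for (inp in inputs) {
        out <- tryCatch({
            d <- inp$load()
            .quantifyOne(d$image, d$polygons, d$seeds, d$vessels, inp$group,
                         config)
        }, error = function(e)
            stop(sprintf("quantify failed for sample %s: %s", inp$id,
                         conditionMessage(e)), call. = FALSE))
        per[[inp$id]] <- out$measurements
        qc[[inp$id]] <- out$qc
        r <- measurementRows(out$measurements)
        rows[[inp$id]] <- cbind(sample_id = inp$id, group = inp$group, r)
    }
    meas <- do.call(rbind, rows)
    rownames(meas) <- NULL
    list(measurements = meas, qc = do.call(rbind, c(qc, make.row.names = FALSE)),
         perSample = per)
}

#' Group statistics over a cohort measurement table
#'
#' Runs the normality-gated comparison for every (variable, region) pair of
#' the measurement table, and the analyte panel with below-LOD handling when
#' an analyte table is given. Rows flagged as missing are excluded.
#'
#' @param measurements Long measurement data.frame from [runQuantify()].
#' @param analytes Optional analyte data.frame (sample_id, group, analyte,
#'   value, lod).
#' @param config A `synoRunConfig`.
#' @return List: `report` (one row per variable x region x pair with
#'   omnibus and pairwise p-values), `results` (named `synoStatResult`
#'   list), `analytes` (from [analyteCompare()], or NULL), `belowLOD`.
#' @export
runStats <- function(measurements, analytes = NULL, config = runConfig()) {
    df <- measurements[measurements$flag == "ok" & !is.na(measurements$value), ]
    combos <- unique(df[, c("variable", "region")])
    results <- list(); rows <- list()
    for (i in seq_len(nrow(combos))) {
        vb <- combos$variable[i]; rg <- combos$region[i]
        res <- compareGroups(df, variable = vb, region = rg,
                             alpha = config$alpha)
        results[[paste(vb, rg, sep = "|")]] <- res
        if (res$skipped) {
            rows[[length(rows) + 1L]] <- data.frame(
                variable = vb, region = rg, gate = NA, method = NA,
                omnibus_p = NA_real_, group1 = NA, group2 = NA,
                p = NA_real_, p_adj = NA_real_, significant = NA,
                note = res$reason, stringsAsFactors = FALSE)
            next
        }
        for (j in seq_len(nrow(res$pairwise))) {
            pw <- res$pairwise[j, ]
            rows[[length(rows) + 1L]] <- data.frame(
                variable = vb, region = rg, gate = res$gate,
                method = res$omnibus$method, omnibus_p = res$omnibus$p.value,
                group1 = pw$group1, group2 = pw$group2, p = pw$p.value,
                p_adj = pw$p.adj, significant = pw$significant, note = "",
                stringsAsFactors = FALSE)
        }
    }
    an <- NULL
    if (!is.null(analytes)) an <- analyteCompare(analytes, alpha = config$alpha)
    list(report = do.call(rbind, rows), results = results, analytes = an,
         belowLOD = if (is.null(an)) character(0) else an$belowLOD)
}

#' Run the full pipeline: simulate, quantify, compare
#'
#' End-to-end run on a synthetic cohort. With `outDir` set, writes
#' `measurements.csv`, `stats_report.csv`, `qc.csv` and `analytes.csv`
#' (each headed by the config hash) plus `run.json` with per-stage timings.
#'
#' @param config A `synoRunConfig`.
#' @param outDir Optional output directory.
#' @return List: cohort, measurements, qc, stats, timings (seconds per
#'   stage), configHash.
#' @export
runFull <- function(config = runConfig(), outDir = NULL) {
    hash <- configHash(config)
    timings <- c()
    tic <- function() Sys.time()
    scen <- do.call(cohortScenarios,
                    c(list(pixelSizeUm = config$pixelSizeUm),
                      config$scenarioArgs))
    t0 <- tic()
    cohort <- makeCohort(scen, nPerGroup = config$nPerGroup,
                         seed = config$seed, imageShape = config$imageShape)
    timings["simulate"] <- as.numeric(difftime(tic(), t0, units = "secs"))
    t0 <- tic()
    q <- runQuantify(cohort, config)
    timings["quantify"] <- as.numeric(difftime(tic(), t0, units = "secs"))
    t0 <- tic()
    s <- runStats(q$measurements, cohort$analytes, config)
    timings["stats"] <- as.numeric(difftime(tic(), t0, units = "secs"))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        .writeCSVWithHash(q$measurements, file.path(outDir, "measurements.csv"), hash)
        .writeCSVWithHash(s$report, file.path(outDir, "stats_report.csv"), hash)
        .writeCSVWithHash(q$qc, file.path(outDir, "qc.csv"), hash)
        .writeCSVWithHash(cohort$analytes, file.path(outDir, "analytes.csv"), hash)
        jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                                  timings_sec = as.list(timings),
                                  below_lod = s$belowLOD),
                             file.path(outDir, "run.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(cohort = cohort, measurements = q$measurements, qc = q$qc,
         stats = s, timings = timings, configHash = hash)
}

#' Boxplot-ready summary of a measurement table
#'
#' Quartiles and 1.5 IQR whiskers per (group, variable, region).
#'
#' @param measurements Long measurement data.frame.
#' @return data.frame: group, variable, region, n, q1, median, q3, whiskerLo,
#'   whiskerHi.
#' @export
boxplotData <- function(measurements) {
    df <- measurements[measurements$flag == "ok" & !is.na(measurements$value), ]
    sp <- split(df, list(df$group, df$variable, df$region), drop = TRUE)
    out <- lapply(sp, function(d) {
        q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), type = 7)
        iqr <- q[3L] - q[1L]
        lo <- min(d$value[d$value >= q[1L] - 1.5 * iqr])
        hi <- max(d$value[d$value <= q[3L] + 1.5 * iqr])
        data.frame(group = d$group[1L], variable = d$variable[1L],
                   region = d$region[1L], n = nrow(d), q1 = unname(q[1L]),
                   median = unname(q[2L]), q3 = unname(q[3L]),
                   whiskerLo = lo, whiskerHi = hi, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
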