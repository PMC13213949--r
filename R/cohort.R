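#' Default analyte panel for the synthetic cohort
#'
#' Synovial-fluid analyte generator settings: per-group log-normal medians
#' (pg/ml or U/ml), a common log-scale spread, the assay's lower limit of
#' detection, and a flag forcing an analyte to be generated entirely below
#' its LOD (emulating analytes that remain undetectable in every sample:
#' IL-1b, IFN-a, IL-4 and CCL3, with LODs 61, 12, 40 and 5 pg/ml).
#'
#' @return data.frame with columns analyte, lod, F, CTRL, OA (medians),
#'   sdlog, forceBelowLOD.
#' @export
analytePreset <- function() {
    data.frame(
        analyte = c("TNF-a", "IFN-g", "IL-17A", "IL-10", "CCL2", "CCL5",
                    "CCL11", "IL-1b", "IFN-a", "IL-4", "CCL3"),
        lod     = c(1, 0.5, 0.5, 1, 1, 1, 1, 61, 12, 40, 5),
        F       = c(2510, 11, 6.5, 103.5, 734.6, 236, 1636, NA, NA, NA, NA),
        CTRL    = c(6104, 5, 4, 58, 1282, 90, 2586, NA, NA, NA, NA),
        OA      = c(13979, 4, 4, 40, 992, 111, 3840, NA, NA, NA, NA),
        sdlog   = c(1.2, 0.8, 0.6, 0.8, 0.8, 0.8, 0.8, NA, NA, NA, NA),
        forceBelowLOD = c(rep(FALSE, 7L), rep(TRUE, 4L)),
        stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Generates `nPerGroup` samples per group from the given scenarios: a
#' ground-truth section and rendered multi-channel image per sample, plus a
#' per-sample analyte concentration table drawn log-normally per group with
#' configurable detection limits. Deterministic for a fixed seed.
#'
#' @param scenarios Named list of [TissueScenario-class] objects, one per
#'   group (default: the packaged presets).
#' @param nPerGroup Integer, or named integer vector aligned with
#'   `names(scenarios)`; the default is the modelled study's group sizes
#'   (F 10, CTRL 11, OA 9).
#' @param seed Integer RNG seed.
#' @param imageShape Per-sample image shape, c(rows, cols).
#' @param analytes Analyte generator settings, see [analytePreset()]; NULL
#'   skips the analyte table.
#' @param render If FALSE, skip channel rendering (ground truth only).
#' @return List with `samples` (each `list(sampleID, group, gt, image)`),
#'   `analytes` (data.frame or NULL), `scenarios`, `seed`.
#' @export
makeCohort <- function(scenarios = cohortScenarios(),
                       nPerGroup = c(F = 10L, CTRL = 11L, OA = 9L),
                       seed = 1L, imageShape = c(512L, 512L),
                       analytes = analytePreset(), render = TRUE) {
    if (length(nPerGroup) == 1L && is.null(names(nPerGroup)))
        nPerGroup <- stats::setNames(rep(as.integer(nPerGroup),
                                         length(scenarios)), names(scenarios))
    stopifnot(all(names(scenarios) %in% names(nPerGroup)),
              all(nPerGroup[names(scenarios)] >= 1L))
    groups <- names(scenarios)
    ids <- unlist(lapply(groups, function(g)
        sprintf("%s%02d", g, seq_len(nPerGroup[[g]]))))
    if (anyDuplicated(ids))
        stop("duplicate sample identifiers in cohort")
    nTot <- length(ids)
    seeds <- withSeed(seed, matrix(sample.int(2147483646L, 2L * nTot), ncol = 2L))
    samples <- vector("list", nTot)
    k <- 0L
    for (g in groups) {
        for (i in seq_len(nPerGroup[[g]])) {
            k <- k + 1L
            gt <- generateSection(scenarios[[g]], imageShape,
                                  seed = seeds[k, 1L], sampleID = ids[k])
            img <- if (render)
                renderChannels(gt, scenarios[[g]], seed = seeds[k, 2L]) else NULL
            samples[[k]] <- list(sampleID = ids[k], group = g, gt = gt,
                                 image = img)
        }
    }
    atab <- NULL
    if (!is.null(analytes)) {
        atab <- withSeed(seed + 1L, .drawAnalytes(analytes, ids,
            rep(groups, nPerGroup[groups])))
    }
    list(samples = stats::setNames(samples, ids), analytes = atab,
         scenarios = scenarios, seed = as.integer(seed))
}

.drawAnalytes <- function(config, ids, groups) {
    out <- list()
    for (j in seq_len(nrow(config))) {
        a <- config[j, ]
        if (isTRUE(a$forceBelowLOD)) {
            vals <- a$lod * stats::runif(length(ids), 0.05, 0.95)
        } else {
            med <- c(F = a$F, CTRL = a$CTRL, OA = a$OA)
            vals <- stats::rlnorm(length(ids),
                                  meanlog = log(med[paste0(groups)]),
                                  sdlog = a$sdlog)
        }
        out[[j]] <- data.frame(sample_id = ids, group = groups,
                               analyte = a$analyte, value = as.numeric(vals),
                               lod = a$lod, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
}
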