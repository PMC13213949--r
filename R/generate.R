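# Superellipse lobe: |x/a|^p + |y/b|^p = 1, sampled at nv angles.
.superellipse <- function(cx, cy, a, b, p, nv = 96L, phiFrom = 0, phiTo = 2 * pi) {
    th <- seq(phiFrom, phiTo, length.out = nv)
    sgnpow <- function(u, q) sign(u) * abs(u)^q
    cbind(cx + a * sgnpow(cos(th), 2 / p),
          cy + b * sgnpow(sin(th), 2 / p))
}

# Villus + base-layer geometry for one section. The villus is a superellipse
# lobe rooted in a basal SI_N band, taller than wide; the ICL is an apical
# band of configurable thickness along the villus tip.
.sectionGeometry <- function(nr, nc, pixelSizeUm) {
    ratio <- stats::runif(1L, 1.3, 2.2)     # bounding-box height/width
    p <- stats::runif(1L, 2, 3)             # superellipse exponent
    yBase <- round(0.72 * nr)
    top <- 0.05 * nr
    bottom <- yBase - 0.5                   # villus sits exactly on the base band
    b <- (bottom - top) / 2
    cy <- (bottom + top) / 2
    a <- min(b / ratio, 0.40 * nc)
    cx <- nc / 2 + stats::runif(1L, -0.05, 0.05) * nc
    cellDiamPx <- 15 / pixelSizeUm          # 2 x 7.5 um lining-cell radius
    t <- stats::runif(1L, 2, 3) * cellDiamPx
    t <- min(t, 0.7 * a)
    if (a < cellDiamPx)
        stop("villus cannot fit the image at this pixel size")
    # apical band: outer arc around the tip (theta = -pi/2), inner arc shrunk by t
    phiMax <- 1.9
    outer <- .superellipse(cx, cy, a, b, p, 64L, -pi / 2 - phiMax, -pi / 2 + phiMax)
    inner <- .superellipse(cx, cy, a - t, b - t, p, 64L, -pi / 2 + phiMax, -pi / 2 - phiMax)
    villus <- .superellipse(cx, cy, a, b, p, 96L)
    siN <- cbind(c(-0.5, nc - 0.5, nc - 0.5, -0.5),
                 c(yBase - 0.5, yBase - 0.5, nr - 0.5, nr - 0.5))
    exw <- 0.10 * nc
    excl <- cbind(c(0.05 * nc, 0.05 * nc + exw, 0.05 * nc + exw, 0.05 * nc),
                  c(yBase + 0.06 * nr, yBase + 0.06 * nr,
                    min(nr - 2, yBase + 0.20 * nr), min(nr - 2, yBase + 0.20 * nr)))
    list(
        polygons = list(
            list(class = "SI_N", coords = siN),
            list(class = "SI_V", coords = villus),
            list(class = "ICL", coords = rbind(outer, inner)),
            list(class = "EXCLUDED", coords = excl)),
        villus = villus, icl = rbind(outer, inner))
}

# Draw marker flags for n cells of one region. Independent marginals first;
# for each configured pair "A:B" the child B is redrawn as Bernoulli(P(B|A))
# on A-positive cells and with the marginal-preserving complement
# (pB - pA P(B|A)) / (1 - pA), clipped to [0,1], on A-negative cells.
.drawMarkerFlags <- function(n, probs, coloc) {
    flags <- lapply(probs, function(p) stats::runif(n) < p)
    for (pair in names(coloc)) {
        ab <- strsplit(pair, ":", fixed = TRUE)[[1L]]
        if (!all(ab %in% names(probs))) next
        pA <- probs[[ab[1L]]]; pB <- probs[[ab[2L]]]; pBgA <- coloc[[pair]]
        apos <- flags[[ab[1L]]]
        child <- logical(n)
        child[apos] <- stats::runif(sum(apos)) < pBgA
        if (pA < 1) {
            pComp <- min(1, max(0, (pB - pA * pBgA) / (1 - pA)))
            child[!apos] <- stats::runif(sum(!apos)) < pComp
        }
        flags[[ab[2L]]] <- child
    }
    flags
}

#' Generate one synthetic synovial section with known ground truth
#'
#' Builds a villus-shaped tissue geometry (superellipse lobe with
#' bounding-box height/width ratio in 1.3--2.2, rooted in a basal SI_N band,
#' with an apical ICL band 2--3 cell diameters thick and a small EXCLUDED
#' artefact zone in the base), then samples cell centers per region as a
#' Poisson process at the scenario's densities, per-cell marker flags at the
#' region-specific probabilities, and vessel outline polygons. All output is
#' a pure function of `(scenario, imageShape, seed)`.
#'
#' @param scenario A [TissueScenario-class].
#' @param imageShape Integer c(rows, cols); at least 256 px on each side so
#'   a villus fits (default 512 x 512).
#' @param seed Integer RNG seed.
#' @param sampleID Identifier stored on the section.
#' @return A [GroundTruthSection-class].
#' @examples
#' gt <- generateSection(scenarioPreset("CTRL"), seed = 1)
#' gt
#' @export
generateSection <- function(scenario, imageShape = c(512L, 512L), seed = 1L,
                            sampleID = "") {
    stopifnot(is(scenario, "TissueScenario"))
    validObject(scenario)
    nr <- as.integer(imageShape[1L]); nc <- as.integer(imageShape[2L])
    if (min(nr, nc) < 256L)
        stop("imageShape too small: a villus cannot fit below 256 x 256 px")
    psz <- scenario@pixelSizeUm
    withSeed(seed, {
        geom <- .sectionGeometry(nr, nc, psz)
        labels <- rasterizeRegions(geom$polygons, c(nr, nc), psz)
        lm <- labelMatrix(labels)
        pxArea <- pixelAreaMm2(psz)
        markers <- markerNames(scenario)
        cells <- list()
        for (rg in .TISSUE_REGIONS) {
            idx <- which(lm == .REGION_CODES[[rg]])
            dens <- scenario@cellDensity
            d <- if (rg %in% names(dens)) dens[[rg]] else 0
            if (d <= 0 || !length(idx)) next
            n <- stats::rpois(1L, d * length(idx) * pxArea)
            n <- min(n, length(idx))
            if (n == 0L) next
            pick <- sample(idx, n)
            row0 <- (pick - 1L) %% nrow(lm)       # 0-based row
            col0 <- (pick - 1L) %/% nrow(lm)      # 0-based col
            x <- col0 + stats::runif(n)
            y <- row0 + stats::runif(n)
            probs <- scenario@markerProbs[[rg]]
            if (is.null(probs)) probs <- stats::setNames(rep(0, length(markers)), markers)
            coloc <- scenario@colocProbs[[rg]]
            if (is.null(coloc)) coloc <- numeric(0)
            flags <- .drawMarkerFlags(n, as.list(probs[markers]), as.list(coloc))
            df <- data.frame(x = x, y = y, region = rg, stringsAsFactors = FALSE)
            for (mk in markers) df[[mk]] <- flags[[mk]]
            cells[[rg]] <- df
        }
        cells <- if (length(cells)) do.call(rbind, cells) else {
            df <- data.frame(x = numeric(0), y = numeric(0), region = character(0))
            for (mk in markers) df[[mk]] <- logical(0)
            df
        }
        rownames(cells) <- NULL
        vessels <- list()
        for (rg in names(scenario@vesselDensity)) {
            d <- scenario@vesselDensity[[rg]]
            idx <- which(lm == .REGION_CODES[[rg]])
            if (d <= 0 || !length(idx)) next
            n <- stats::rpois(1L, d * length(idx) * pxArea)
            if (n == 0L) next
            pick <- sample(idx, min(n, length(idx)))
            for (k in seq_along(pick)) {
                row0 <- (pick[k] - 1L) %% nrow(lm)
                col0 <- (pick[k] - 1L) %/% nrow(lm)
                r <- stats::runif(1L, 4, 8) / psz      # 4-8 um lumen radius
                th <- seq(0, 2 * pi, length.out = 17L)[-17L]
                rj <- r * (1 + 0.08 * stats::rnorm(16L))
                coords <- cbind(col0 + rj * cos(th), row0 + rj * sin(th))
                # record the region the measurement rule will see: the label
                # of the pixel containing the outline centroid
                cent <- polygonCentroid(coords)
                ccol <- floor(cent[1L]); crow <- floor(cent[2L])
                cls <- if (ccol >= 0 && ccol < ncol(lm) && crow >= 0 &&
                           crow < nrow(lm))
                    names(.REGION_CODES)[lm[crow + 1L, ccol + 1L] + 1L]
                else "BACKGROUND"
                vessels[[length(vessels) + 1L]] <- list(coords = coords,
                                                        region = cls)
            }
        }
        new("GroundTruthSection", regionPolygons = geom$polygons,
            cells = cells, vessels = vessels, imageShape = c(nr, nc),
            pixelSizeUm = psz, groupLabel = scenario@groupLabel,
            sampleID = as.character(sampleID))
    })
}

#' Ground-truth region areas and cell densities of a section
#'
#' Analytic (shoelace) polygon areas per region class in mm^2 and the
#' realized cell density per region (cell count over analytic area). The
#' analytic area is independent of rasterization, so comparing these
#' densities with [countSeedDensity()] on the rasterized map isolates
#' discretization error.
#'
#' @param gt A [GroundTruthSection-class].
#' @return List with `areasMm2` (named by region class) and `cellDensity`
#'   (cells per mm^2, named by region).
#' @export
groundTruthDensities <- function(gt) {
    stopifnot(is(gt, "GroundTruthSection"))
    pxArea <- pixelAreaMm2(gt@pixelSizeUm)
    areas <- c(ICL = 0, SI_V = 0, SI_N = 0, EXCLUDED = 0)
    for (p in gt@regionPolygons)
        areas[[p$class]] <- areas[[p$class]] + polygonArea(p$coords) * pxArea
    # precedence: ICL is carved out of SI_V, EXCLUDED out of SI_N (the
    # packaged geometry nests them that way)
    areas[["SI_V"]] <- areas[["SI_V"]] - areas[["ICL"]]
    areas[["SI_N"]] <- areas[["SI_N"]] - areas[["EXCLUDED"]]
    counts <- table(factor(gt@cells$region, levels = .TISSUE_REGIONS))
    dens <- as.numeric(counts) / areas[.TISSUE_REGIONS]
    list(areasMm2 = areas, cellDensity = stats::setNames(dens, .TISSUE_REGIONS))
}
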