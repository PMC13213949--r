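test_that("scenario validity rejects out-of-range parameters", {
    ok <- scenarioPreset("CTRL")
    expect_s4_class(ok, "TissueScenario")
    expect_error(scenarioPreset("CTRL", pixelSizeUm = 0), "pixelSizeUm")
    expect_error(scenarioPreset("CTRL", illumGradientAmplitude = 1), "illumGradient")
    expect_error(scenarioPreset("CTRL", cellDensity = c(ICL = 0)), "ICL cell density")
    expect_error(scenarioPreset("CTRL",
        markerProbs = list(ICL = c(CD14 = 1.2))), "in \\[0, 1\\]")
})

test_that("section generation is deterministic for a fixed seed", {
    sc <- scenarioPreset("F")
    g1 <- generateSection(sc, seed = 33L, sampleID = "a")
    g2 <- generateSection(sc, seed = 33L, sampleID = "a")
    expect_identical(cellTable(g1), cellTable(g2))
    expect_identical(regionPolygons(g1), regionPolygons(g2))
    expect_identical(vesselPolygons(g1), vesselPolygons(g2))
    g3 <- generateSection(sc, seed = 34L)
    expect_false(identical(cellTable(g1)$x, cellTable(g3)$x))
    expect_error(generateSection(sc, c(128L, 128L), 1L), "too small")
})

test_that("cell counts follow the configured Poisson intensity", {
    sc <- scenarioPreset("CTRL", cellDensity = c(ICL = 5000, SI_V = 0.001, SI_N = 0.001))
    for (k in 1:100) {
        gt <- generateSection(sc, c(256L, 256L), seed = 6000L + k)
        lambda <- 5000 * groundTruthDensities(gt)$areasMm2[["ICL"]]
        n <- sum(cellTable(gt)$region == "ICL")
        expect_lt(abs(n - lambda), 4 * sqrt(lambda) + 1)
    }
})

test_that("zero marker probabilities give all-negative cells", {
    probs <- list(ICL = c(CD14 = 0, CD16 = 0, CD206 = 0),
                  SI_V = c(CD14 = 0, CD16 = 0, CD206 = 0),
                  SI_N = c(CD14 = 0, CD16 = 0, CD206 = 0))
    sc <- scenarioPreset("OA", markerProbs = probs, colocProbs = list())
    gt <- generateSection(sc, seed = 9L)
    cells <- cellTable(gt)
    expect_false(any(cells$CD14) || any(cells$CD16) || any(cells$CD206))
})

test_that("stored cell regions agree with the rasterized region map for every cell", {
    for (g in c("F", "CTRL", "OA")) {
        sc <- scenarioPreset(g)
        gt <- generateSection(sc, seed = 17L + match(g, c("F", "CTRL", "OA")))
        labels <- rasterizeRegions(regionPolygons(gt), imageShape(gt), pixelSize(gt))
        cells <- cellTable(gt)
        res <- assignPoints(cells[, c("x", "y")], labels)
        expect_identical(res$region, cells$region)
    }
})

test_that("the villus polygon is taller than wide and the ICL band hugs its tip", {
    gt <- generateSection(scenarioPreset("CTRL"), seed = 21L)
    polys <- regionPolygons(gt)
    villus <- Filter(function(p) p$class == "SI_V", polys)[[1L]]
    icl <- Filter(function(p) p$class == "ICL", polys)[[1L]]
    expect_true(villusShapeCheck(villus$coords))
    # the ICL band's topmost point coincides with the villus tip region
    expect_lt(abs(min(icl$coords[, 2L]) - min(villus$coords[, 2L])), 2)
})

test_that("empirical marker fractions per region match configured probabilities", {
    sc <- scenarioPreset("CTRL")
    tot <- list(); pos <- list()
    for (k in 1:100) {
        cells <- cellTable(generateSection(sc, c(256L, 256L), seed = 8000L + k))
        for (rg in unique(cells$region)) {
            sub <- cells[cells$region == rg, ]
            for (mk in c("CD14", "CD16", "CD206")) {
                key <- paste(rg, mk)
                tot[[key]] <- (tot[[key]] %||% 0) + nrow(sub)
                pos[[key]] <- (pos[[key]] %||% 0) + sum(sub[[mk]])
            }
        }
    }
    for (key in names(tot)) {
        parts <- strsplit(key, " ")[[1L]]
        p <- scenarioPreset("CTRL")@markerProbs[[parts[1L]]][[parts[2L]]]
        se <- sqrt(p * (1 - p) / tot[[key]])
        expect_lt(abs(pos[[key]] / tot[[key]] - p), 3 * se + 1e-9)
    }
})

test_that("conditional co-expression applies to parent-positive cells", {
    probs <- list(ICL = c(CD14 = 0.5, CD16 = 0.5),
                  SI_V = c(CD14 = 0.5, CD16 = 0.5),
                  SI_N = c(CD14 = 0.5, CD16 = 0.5))
    coloc <- lapply(probs, function(x) c("CD14:CD16" = 0.9))
    sc <- scenarioPreset("CTRL", markerProbs = probs, colocProbs = coloc)
    pos <- tot <- 0
    for (k in 1:40) {
        cells <- cellTable(generateSection(sc, c(256L, 256L), seed = 8500L + k))
        pos <- pos + sum(cells$CD14 & cells$CD16)
        tot <- tot + sum(cells$CD14)
    }
    expect_lt(abs(pos / tot - 0.9), 3 * sqrt(0.9 * 0.1 / tot))
})

test_that("cohorts have unique identifiers and deterministic analyte tables", {
    co <- makeCohort(nPerGroup = 3L, seed = 44L, imageShape = c(256L, 256L),
                     render = FALSE)
    expect_length(co$samples, 9L)
    expect_false(anyDuplicated(names(co$samples)) > 0L)
    co2 <- makeCohort(nPerGroup = 3L, seed = 44L, imageShape = c(256L, 256L),
                      render = FALSE)
    expect_identical(co$analytes, co2$analytes)
    expect_identical(cellTable(co$samples[[1L]]$gt), cellTable(co2$samples[[1L]]$gt))
})

test_that("analytes forced below their detection limit are fully censored", {
    co <- makeCohort(nPerGroup = 2L, seed = 45L, imageShape = c(256L, 256L),
                     render = FALSE)
    rep <- censorBelowLOD(co$analytes)
    forced <- analytePreset()$analyte[analytePreset()$forceBelowLOD]
    expect_true(all(forced %in% rep$belowLOD))
    for (a in forced)
        expect_true(all(rep$table$censored[rep$table$analyte == a]))
})
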