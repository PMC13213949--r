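.mk <- function(m, name = "CD14") new("BinaryMask", mask = m,
                                      channelName = name, windowPx = 50L)

.regmap <- function(lab, psz = 0.5) new("RegionLabelMap",
                                        labels = lab, pixelSizeUm = psz)

test_that("positive area fraction counts region pixels only", {
    lab <- matrix(0L, 10L, 10L)
    lab[1:5, ] <- regionCodes()[["ICL"]]           # 50 px ICL
    lab[6:8, ] <- regionCodes()[["EXCLUDED"]]
    m <- .regmap(lab)
    full <- .mk(matrix(TRUE, 10L, 10L))
    expect_equal(positiveAreaFraction(full, m, "ICL"), 100)
    half <- .mk(rbind(matrix(TRUE, 2L, 10L), matrix(FALSE, 8L, 10L)))
    # 20 of 50 ICL pixels positive -> 40 %; EXCLUDED positives change nothing
    withEx <- half@mask; withEx[6:8, ] <- TRUE
    expect_equal(positiveAreaFraction(.mk(withEx), m, "ICL"), 40)
    expect_error(positiveAreaFraction(full, m, "SI_V"), "SI_V is empty")
})

test_that("positive area fraction matches a counting oracle and is additive over splits", {
    set.seed(21)
    lab <- matrix(sample(c(0L, 1L, 2L, 4L), 400L, replace = TRUE), 20L)
    m <- .regmap(lab)
    mask <- matrix(runif(400) > 0.4, 20L)
    for (rg in c("ICL", "SI_V")) {
        code <- regionCodes()[[rg]]
        num <- 0L; den <- 0L
        for (i in 1:20) for (j in 1:20) {
            if (lab[i, j] == code) { den <- den + 1L; num <- num + mask[i, j] }
        }
        expect_equal(positiveAreaFraction(.mk(mask), m, rg), 100 * num / den)
    }
    split <- matrix(runif(400) > 0.5, 20L)
    a <- positiveAreaFraction(.mk(mask & split), m, "ICL")
    b <- positiveAreaFraction(.mk(mask & !split), m, "ICL")
    expect_equal(a + b, positiveAreaFraction(.mk(mask), m, "ICL"))
})

test_that("co-localization ratio reproduces the 10-to-8 worked example and its bounds", {
    lab <- matrix(regionCodes()[["ICL"]], 10L, 10L)
    m <- .regmap(lab)
    parent <- matrix(FALSE, 10L, 10L); parent[1L, 1:10] <- TRUE
    co <- matrix(FALSE, 10L, 10L); co[1L, 1:8] <- TRUE
    expect_equal(colocRatio(.mk(parent), .mk(co), m, "ICL"), 80)
    expect_equal(colocRatio(.mk(parent), .mk(parent), m, "ICL"), 100)
    expect_equal(colocRatio(.mk(parent), .mk(matrix(FALSE, 10L, 10L)), m, "ICL"), 0)
    none <- .mk(matrix(FALSE, 10L, 10L))
    r <- colocRatio(none, none, m, "ICL")
    expect_true(is.na(r))
    expect_equal(attr(r, "flag"), "undefined_parent")
    expect_error(colocRatio(none, .mk(co), m, "ICL"), "not a subset")
})

test_that("co-localization ratios from colocalize never exceed 100", {
    set.seed(22)
    lab <- matrix(regionCodes()[["SI_V"]], 30L, 30L)
    m <- .regmap(lab)
    for (i in 1:10) {
        a <- .mk(matrix(runif(900) > runif(1, 0.3, 0.9), 30L))
        b <- .mk(matrix(runif(900) > 0.5, 30L))
        r <- colocRatio(a, colocalize(a, b), m, "SI_V")
        if (!is.na(r)) expect_true(r >= 0 && r <= 100)
    }
})

test_that("vessel metrics assign by centroid and report perimeter in micrometers", {
    lab <- matrix(regionCodes()[["SI_N"]], 200L, 100L)   # 20000 px
    m <- .regmap(lab, psz = 10)                          # 2 mm^2
    sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                    c(y0, y0, y0 + s, y0 + s))
    vessels <- list(sq(10, 10, 20), sq(50, 50, 20), sq(10, 120, 20), sq(60, 150, 20))
    vm <- vesselMetrics(vessels, m)
    row <- vm[vm$region == "SI_N", ]
    expect_equal(row$count, 4L)
    expect_equal(row$countPerMm2, 2)
    expect_equal(row$meanPerimeterUm, 80 * 10)   # side 20 px at 10 um/px
    expect_equal(attr(vm, "nUnassigned"), 0L)
    # square of side 20 px at 0.5 um/px has a 40 um perimeter
    m2 <- .regmap(matrix(regionCodes()[["SI_V"]], 64L, 64L), psz = 0.5)
    vm2 <- vesselMetrics(list(sq(10, 10, 20)), m2)
    expect_equal(vm2$meanPerimeterUm[vm2$region == "SI_V"], 40)
    # 64-gon approximates a circle circumference to < 0.5 %
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    circ <- cbind(120 + 30 * cos(th), 100 + 30 * sin(th))
    m3 <- .regmap(matrix(regionCodes()[["SI_V"]], 256L, 256L), psz = 0.5)
    vm3 <- vesselMetrics(list(circ), m3)
    expect_lt(abs(vm3$meanPerimeterUm[vm3$region == "SI_V"] -
                  2 * pi * 30 * 0.5) / (2 * pi * 30 * 0.5), 0.005)
    # a centroid on background is reported unassigned, not dropped silently
    labBg <- matrix(0L, 64L, 64L)
    vm4 <- vesselMetrics(list(sq(5, 5, 10)), .regmap(labBg))
    expect_equal(attr(vm4, "nUnassigned"), 1L)
    expect_equal(sum(vm4$count), 0L)
})

test_that("measureSample emits the complete measurement schema", {
    sc <- scenarioPreset("CTRL")
    gt <- generateSection(sc, c(256L, 256L), seed = 5L, sampleID = "s1")
    img <- renderChannels(gt, sc, seed = 6L)
    labels <- rasterizeRegions(regionPolygons(gt), imageShape(gt), pixelSize(gt))
    masks <- sapply(c("CD14", "CD16", "CD206"), function(mk)
        localAdaptiveBinarize(img, 50L, mk), simplify = FALSE)
    seeds <- as.matrix(cellTable(gt)[, c("x", "y")])
    sm <- measureSample(img, masks, seeds = seeds, labels = labels,
                        vessels = vesselPolygons(gt), group = "CTRL")
    rows <- measurementRows(sm)
    expect_equal(nrow(rows), 3 * 3 + 2 * 3 + 1 + 3)
    expect_setequal(unique(rows$variable),
        c("CD14_area_pct", "CD16_area_pct", "CD206_area_pct",
          "CD14_CD16_ratio_pct", "CD14_CD206_ratio_pct",
          "cell_density", "vessel_density"))
    expect_equal(sum(rows$variable == "cell_density"), 1L)
    expect_true(all(rows$value[rows$flag == "ok" & grepl("_pct$", rows$variable)] <= 100))
})

test_that("all-empty marker masks give zero fractions and flagged missing ratios", {
    sc <- scenarioPreset("CTRL")
    gt <- generateSection(sc, c(256L, 256L), seed = 7L, sampleID = "s2")
    img <- renderChannels(gt, sc, seed = 8L)
    labels <- rasterizeRegions(regionPolygons(gt), imageShape(gt), pixelSize(gt))
    empty <- .mk(matrix(FALSE, 256L, 256L))
    masks <- list(CD14 = empty, CD16 = empty, CD206 = empty)
    seeds <- as.matrix(cellTable(gt)[, c("x", "y")])
    sm <- measureSample(img, masks, seeds = seeds, labels = labels, group = "CTRL")
    rows <- measurementRows(sm)
    expect_true(all(rows$value[grepl("_area_pct$", rows$variable)] == 0))
    rr <- rows[grepl("_ratio_pct$", rows$variable), ]
    expect_true(all(is.na(rr$value)))
    expect_true(all(rr$flag == "undefined_parent"))
})

test_that("per-cell positivity summarises cell masks against a marker mask", {
    cl <- cellMasksFromSeeds(rbind(c(20, 20), c(60, 20)), c(80L, 80L), 10L)
    mask <- matrix(FALSE, 80L, 80L); mask[, 1:40] <- TRUE  # covers cell 1 only
    cp <- cellPositivity(cl, .mk(mask))
    expect_equal(cp$positive, c(TRUE, FALSE))
    expect_equal(cp$positiveFraction[1L], 1)
})
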