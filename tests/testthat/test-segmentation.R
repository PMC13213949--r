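test_that("constant channels binarize to all-false masks", {
    for (v in c(0, 0.3, 5)) {
        for (w in c(3L, 50L)) {
            m <- localAdaptiveBinarize(matrix(v, 64L, 64L), windowPx = w)
            expect_false(any(maskMatrix(m)))
        }
    }
})

test_that("an isolated bright pixel is the only positive pixel", {
    x <- matrix(0, 64L, 64L)
    x[20L, 31L] <- 1
    m <- maskMatrix(localAdaptiveBinarize(x, windowPx = 50L))
    expect_true(m[20L, 31L])
    expect_equal(sum(m), 1L)
})

test_that("binarization equals the naive local-mean oracle on random images", {
    set.seed(11)
    for (w in c(3L, 5L, 11L)) {
        x <- matrix(runif(64L * 64L), 64L, 64L)
        got <- maskMatrix(localAdaptiveBinarize(x, windowPx = w))
        expect_identical(got, naiveLocalMeanMask(x, w))
    }
})

test_that("binarization is invariant to global rescaling of a positive image", {
    set.seed(12)
    x <- matrix(runif(64L * 64L, 0.1, 1), 64L, 64L)
    base <- maskMatrix(localAdaptiveBinarize(x, windowPx = 7L))
    for (c in c(0.25, 3, 1000))
        expect_identical(maskMatrix(localAdaptiveBinarize(c * x, windowPx = 7L)), base)
})

test_that("binarization is translation-equivariant away from borders", {
    set.seed(13)
    x <- matrix(runif(80L * 80L), 80L, 80L)
    w <- 5L
    xs <- x[11:70, 11:70]
    full <- maskMatrix(localAdaptiveBinarize(x, windowPx = w))
    sub <- maskMatrix(localAdaptiveBinarize(xs, windowPx = w))
    # interior of the crop (one window away from the crop borders)
    expect_identical(sub[(w + 1):(60 - w), (w + 1):(60 - w)],
                     full[(10 + w + 1):(70 - w), (10 + w + 1):(70 - w)])
})

test_that("oversized windows degrade to a global mean with a warning", {
    x <- matrix(c(rep(0, 90), rep(1, 10)), 10L, 10L)
    expect_warning(m <- localAdaptiveBinarize(x, windowPx = 99L), "global mean")
    expect_identical(maskMatrix(m), x > mean(x))
    expect_error(localAdaptiveBinarize(matrix(c(1, NA, 1, 1), 2L)), "non-finite")
})

test_that("colocalization is the elementwise AND with its algebraic laws", {
    set.seed(14)
    mk <- function(m) new("BinaryMask", mask = m, channelName = "x", windowPx = 50L)
    a <- mk(matrix(runif(400) > 0.5, 20L))
    b <- mk(matrix(runif(400) > 0.5, 20L))
    ab <- colocalize(a, b)
    expect_identical(maskMatrix(ab), maskMatrix(a) & maskMatrix(b))
    expect_lte(sum(maskMatrix(ab)), min(sum(maskMatrix(a)), sum(maskMatrix(b))))
    expect_identical(maskMatrix(colocalize(b, a)), maskMatrix(ab))
    expect_identical(maskMatrix(colocalize(a, a)), maskMatrix(a))
    expect_identical(maskMatrix(colocalize(a, ab)), maskMatrix(ab))  # absorption
    disj <- mk(!maskMatrix(a))
    expect_false(any(maskMatrix(colocalize(a, disj))))
    expect_error(colocalize(a, mk(matrix(TRUE, 5L, 5L))), "shapes differ")
})

test_that("a single far-from-border seed yields the brute-force digital disk", {
    cl <- cellMasksFromSeeds(cbind(100, 120), c(256L, 256L), radiusPx = 15L)
    lab <- labelMatrix(cl)
    xg <- matrix(rep(0:255, each = 256L), 256L)
    yg <- matrix(rep(0:255, 256L), 256L)
    disk <- (xg - 100)^2 + (yg - 120)^2 <= 15^2
    expect_identical(lab == 1L, disk)
    # two non-interacting seeds give two full disjoint disks
    cl2 <- cellMasksFromSeeds(rbind(c(60, 60), c(180, 60)), c(256L, 256L), 15L)
    expect_equal(sum(labelMatrix(cl2) == 1L), sum(disk))
    expect_equal(sum(labelMatrix(cl2) == 2L), sum(disk))
})

test_that("close seeds partition along the perpendicular bisector with low-index ties", {
    seeds <- rbind(c(100, 100), c(110, 100))   # 10 px apart on one axis
    cl <- cellMasksFromSeeds(seeds, c(200L, 200L), 15L)
    expect_identical(unname(labelMatrix(cl)),
                     unname(nearestSeedOracle(seeds, c(200L, 200L), 15L)))
    # tie column x = 105 belongs to seed 1
    expect_true(all(labelMatrix(cl)[, 106L][labelMatrix(cl)[, 106L] > 0L] == 1L))
})

test_that("cell label maps satisfy disjointness, the radius bound and nearest-seed optimality", {
    set.seed(15)
    seeds <- cbind(runif(25, 0, 255), runif(25, 0, 255))
    cl <- cellMasksFromSeeds(seeds, c(256L, 256L), 15L)
    expect_identical(unname(labelMatrix(cl)),
                     unname(nearestSeedOracle(seeds, c(256L, 256L), 15L)))
    lab <- labelMatrix(cl)
    idx <- which(lab > 0L, arr.ind = TRUE)
    d <- sqrt((idx[, 2L] - 1 - seeds[lab[idx], 1L])^2 +
              (idx[, 1L] - 1 - seeds[lab[idx], 2L])^2)
    expect_true(all(d <= 15))
})

test_that("enlarging the radius never shrinks well-separated cell masks", {
    set.seed(16)
    seeds <- cbind(c(40, 120, 200), c(40, 150, 60))  # pairwise distance > 2 * 20
    small <- labelMatrix(cellMasksFromSeeds(seeds, c(256L, 256L), 10L))
    big <- labelMatrix(cellMasksFromSeeds(seeds, c(256L, 256L), 20L))
    for (k in 1:3) expect_true(all(big[small == k] == k))
})

test_that("duplicate seeds are rejected with their indices and off-image seeds are empty", {
    expect_error(cellMasksFromSeeds(rbind(c(5, 5), c(9, 2), c(5, 5)),
                                    c(64L, 64L)), "duplicate seeds.*3")
    cl <- cellMasksFromSeeds(rbind(c(10, 10), c(-50, 10)), c(64L, 64L), 5L)
    expect_equal(sum(labelMatrix(cl) == 2L), 0L)
    expect_gt(sum(labelMatrix(cl) == 1L), 0L)
})

test_that("seed density is count over region area", {
    lab <- matrix(regionCodes()[["ICL"]], 20L, 100L)   # 2000 px
    m <- new("RegionLabelMap", labels = lab, pixelSizeUm = 1)  # 0.002 mm^2
    seeds <- cbind(seq(2, 92, by = 10), rep(10, 10))   # 10 seeds inside
    expect_equal(countSeedDensity(seeds, "ICL", m), 5000)
    expect_equal(countSeedDensity(cbind(numeric(0), numeric(0)), "ICL", m), 0)
})
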