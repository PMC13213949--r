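# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's implementation paths (no integral images, no scanline
# fills, no bounding-box shortcuts).

# Symmetric reflect index (edge duplicated), valid for w <= n.
.refl <- function(k, n) ifelse(k < 1L, 1L - k, ifelse(k > n, 2L * n + 1L - k, k))

# O(n * w^2) local-mean strict threshold with reflect padding.
naiveLocalMeanMask <- function(x, w) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) {
        ri <- .refl((i - w):(i + w), nr)
        for (j in seq_len(nc)) {
            ci <- .refl((j - w):(j + w), nc)
            out[i, j] <- x[i, j] > mean(x[ri, ci])
        }
    }
    out
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# coords: open ring, 0-based pixel coordinates.
pipOracle <- function(px, py, coords) {
    n <- nrow(coords)
    inside <- rep(FALSE, length(px))
    xs <- coords[, 1L]; ys <- coords[, 2L]
    for (e in seq_len(n)) {
        f <- if (e == n) 1L else e + 1L
        y1 <- ys[e]; y2 <- ys[f]; x1 <- xs[e]; x2 <- xs[f]
        cross <- ((y1 > py) != (y2 > py)) &
                 (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
        inside <- xor(inside, cross)
    }
    inside
}

# Full-image rasterization oracle with the EXCLUDED > ICL > SI_V > SI_N
# precedence, evaluated at every pixel center.
rasterOracle <- function(polygons, shape) {
    nr <- shape[1L]; nc <- shape[2L]
    codes <- regionCodes()
    out <- matrix(codes[["BACKGROUND"]], nr, nc)
    px <- rep(0:(nc - 1L), each = nr)
    py <- rep(0:(nr - 1L), nc)
    for (cls in c("SI_N", "SI_V", "ICL", "EXCLUDED")) {
        for (p in polygons) {
            if (p$class != cls) next
            ins <- pipOracle(px, py, p$coords)
            out[matrix(c(py[ins] + 1L, px[ins] + 1L), ncol = 2L)] <- codes[[cls]]
        }
    }
    out
}

# Exhaustive nearest-seed-within-radius labelling with lower-index ties.
nearestSeedOracle <- function(seeds, shape, radius) {
    nr <- shape[1L]; nc <- shape[2L]
    out <- matrix(0L, nr, nc)
    best <- matrix(Inf, nr, nc)
    xg <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
    yg <- matrix(rep(0:(nr - 1L), nc), nr, nc)
    for (k in seq_len(nrow(seeds))) {
        if (seeds[k, 1L] < 0 || seeds[k, 1L] >= nc ||
            seeds[k, 2L] < 0 || seeds[k, 2L] >= nr) next
        d2 <- (xg - seeds[k, 1L])^2 + (yg - seeds[k, 2L])^2
        take <- d2 <= radius^2 & d2 < best
        best[take] <- d2[take]
        out[take] <- k
    }
    out
}

# Star-shaped random simple polygon around a center (never self-intersects).
randomStarPolygon <- function(cx, cy, rMin, rMax, nV = 12L) {
    th <- sort(stats::runif(nV, 0, 2 * pi))
    r <- stats::runif(nV, rMin, rMax)
    cbind(cx + r * cos(th), cy + r * sin(th))
}

# Minimum distance from points to any polygon edge (for boundary-safe
# point-assignment checks).
distToEdges <- function(px, py, coords) {
    n <- nrow(coords)
    d <- rep(Inf, length(px))
    for (e in seq_len(n)) {
        f <- if (e == n) 1L else e + 1L
        ax <- coords[e, 1L]; ay <- coords[e, 2L]
        bx <- coords[f, 1L]; by <- coords[f, 2L]
        vx <- bx - ax; vy <- by - ay
        t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)))
        d <- pmin(d, sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2))
    }
    d
}

# One-way ANOVA F statistic from scratch (for permutation oracles).
rawFstat <- function(v, g) {
    m <- mean(v)
    ms <- tapply(v, g, mean); ns <- tapply(v, g, length)
    ssb <- sum(ns * (ms - m)^2)
    ssw <- sum((v - ms[g])^2)
    k <- length(ms); n <- length(v)
    (ssb / (k - 1)) / (ssw / (n - k))
}

# Minimal ground-truth section with hand-placed cells (for renderer tests).
manualSection <- function(cells, shape = c(256L, 256L), pixelSizeUm = 0.5) {
    new("GroundTruthSection", regionPolygons = list(), cells = cells,
        vessels = list(), imageShape = as.integer(shape),
        pixelSizeUm = pixelSizeUm, groupLabel = "CTRL", sampleID = "manual")
}

# Drop a repeated closing vertex (kept local to the tests).
openRingForTest <- function(coords) {
    n <- nrow(coords)
    if (n >= 2L && all(coords[1L, ] == coords[n, ])) coords[-n, , drop = FALSE]
    else coords
}

`%||%` <- function(a, b) if (is.null(a)) b else a
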