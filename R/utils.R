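# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    expr
}

# Drop a repeated closing vertex; polygons are stored as open rings.
openRing <- function(coords) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (n >= 2L && all(coords[1L, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
    coords
}

# Signed shoelace area in px^2 (positive magnitude returned).
polygonArea <- function(coords) {
    coords <- openRing(coords)
    x <- coords[, 1L]; y <- coords[, 2L]
    j <- c(2:length(x), 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
}

# Area-weighted polygon centroid (shoelace centroid), c(x, y).
polygonCentroid <- function(coords) {
    coords <- openRing(coords)
    x <- coords[, 1L]; y <- coords[, 2L]
    j <- c(2:length(x), 1L)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
    c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# Closed-ring arc length in pixels.
polygonPerimeter <- function(coords) {
    coords <- openRing(coords)
    j <- c(2:nrow(coords), 1L)
    sum(sqrt(rowSums((coords[j, , drop = FALSE] - coords)^2)))
}

# Proper self-intersection test: any two non-adjacent edges crossing.
polygonSelfIntersects <- function(coords) {
    coords <- openRing(coords)
    n <- nrow(coords)
    if (n < 4L) return(FALSE)
    p <- coords
    q <- coords[c(2:n, 1L), , drop = FALSE]
    ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    for (i in seq_len(n - 2L)) {
        js <- (i + 2L):n
        js <- js[!(i == 1L & js == n)]  # skip edges adjacent through the wrap
        if (!length(js)) next
        d1 <- ccw(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], p[js, 1L], p[js, 2L])
        d2 <- ccw(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], q[js, 1L], q[js, 2L])
        d3 <- ccw(p[js, 1L], p[js, 2L], q[js, 1L], q[js, 2L], rep(p[i, 1L], length(js)), rep(p[i, 2L], length(js)))
        d4 <- ccw(p[js, 1L], p[js, 2L], q[js, 1L], q[js, 2L], rep(q[i, 1L], length(js)), rep(q[i, 2L], length(js)))
        if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
    }
    FALSE
}

# mm^2 covered by one pixel.
pixelAreaMm2 <- function(pixelSizeUm) (pixelSizeUm / 1000)^2
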