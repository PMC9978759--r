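# Independent brute-force oracles: literal loops over 3x3 windows, written
# without reference to the package internals. Used to cross-check every
# terrain layer cell-for-cell.

bruteTerrain <- function(m, cellsize = 1, distanceWeighting = TRUE,
                         flatTol = 1e-9) {
  nr <- nrow(m); nc <- ncol(m)
  blank <- matrix(NA_real_, nr, nc)
  out <- list(tri = blank, tpi = blank, roughness = blank, slope = blank,
              aspect = blank, flowdir = blank)
  # neighbour order: E SE S SW W NW N NE with matrix-space offsets
  drs <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcs <- c(1, 1, 0, -1, -1, -1, 0, 1)
  codes <- c(1, 2, 4, 8, 16, 32, 64, 128)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    win <- m[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (any(is.na(win))) next
    z <- m[r, c]
    nb <- mapply(function(dr, dc) m[r + dr, c + dc], drs, dcs)
    out$tri[r, c] <- mean(abs(z - nb))
    out$tpi[r, c] <- z - mean(nb)
    out$roughness[r, c] <- max(win) - min(win)
    zNW <- m[r - 1, c - 1]; zN <- m[r - 1, c]; zNE <- m[r - 1, c + 1]
    zW <- m[r, c - 1]; zE <- m[r, c + 1]
    zSW <- m[r + 1, c - 1]; zS <- m[r + 1, c]; zSE <- m[r + 1, c + 1]
    p <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cellsize)
    q <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * cellsize)
    out$slope[r, c] <- atan(sqrt(p^2 + q^2)) * 180 / pi
    out$aspect[r, c] <- if (sqrt(p^2 + q^2) < flatTol) NA_real_
                        else (atan2(-p, -q) * 180 / pi) %% 360
    dists <- ifelse(drs != 0 & dcs != 0,
                    if (distanceWeighting) cellsize * sqrt(2) else cellsize,
                    cellsize)
    if (!distanceWeighting) dists[] <- 1
    drops <- (z - nb) / dists
    best <- which(drops == max(drops))
    out$flowdir[r, c] <- min(codes[best])
  }
  out
}

randomDem <- function(nr = 20, nc = 20, cellsize = NULL, naHoles = 0) {
  if (is.null(cellsize)) cellsize <- stats::runif(1, 0.5, 30)
  m <- matrix(stats::rnorm(nr * nc, 1000, 50), nr, nc)
  if (naHoles > 0) m[sample.int(nr * nc, naHoles)] <- NA_real_
  elevationGrid(m, cellsize = cellsize)
}

# An exact plane z = a*x + b*y + c sampled at cell centers.
planeDem <- function(a, b, c = 0, n = 9, cellsize = 1) {
  xs <- (seq_len(n) - 0.5) * cellsize
  ys <- rev(xs)  # row 1 = north = largest y
  elevationGrid(outer(ys, xs, function(y, x) a * x + b * y + c),
                cellsize = cellsize)
}

# Two-Monte-Carlo-SE agreement between a B-draw sample quantile and the
# exact (exhaustive) null: the sample quantile at p estimates the population
# quantile with probability-scale uncertainty sqrt(p(1-p)/B), so it must lie
# inside the exact quantile function evaluated over p -/+ 2 of those SEs.
# Mapping the band through the exact quantile function keeps the check valid
# for the lumpy (discrete-atom) subset-mean nulls of small pools, where a
# density-based SE is not.
mcQuantileAgrees <- function(exactDraws, p, mcValue, B, z = 2) {
  se <- sqrt(p * (1 - p) / B)
  plo <- max(p - z * se, 0); phi <- min(p + z * se, 1)
  # envelope over the step (type 1) and interpolated (type 7) inverses so
  # an atom straddling a band edge counts as inside
  lo <- min(stats::quantile(exactDraws, plo, names = FALSE, type = 1),
            stats::quantile(exactDraws, plo, names = FALSE, type = 7))
  hi <- max(stats::quantile(exactDraws, phi, names = FALSE, type = 1),
            stats::quantile(exactDraws, phi, names = FALSE, type = 7))
  mcValue >= lo - 1e-12 && mcValue <= hi + 1e-12
}

expectLayersEqual <- function(got, want, tol = 1e-10) {
  expect_equal(dim(got), dim(want))
  expect_equal(is.na(got), is.na(want))
  ok <- !is.na(got)
  expect_lt(max(abs(got[ok] - want[ok]), 0), tol)
}
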