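test_that("hand-enumerated 3x3 examples give the documented index values", {
  bump <- elevationGrid(matrix(c(1, 1, 1, 1, 2, 1, 1, 1, 1), 3, 3,
                               byrow = TRUE))
  expect_equal(tri(bump)[2, 2], 1.0)
  expect_equal(tpi(bump)[2, 2], 1.0)
  expect_equal(roughness(bump)[2, 2], 1.0)

  ramp <- elevationGrid(matrix(rep(c(0, 1, 2), each = 3), 3, 3))  # cols 0,1,2
  expect_equal(tri(ramp)[2, 2], 0.75)        # |diffs| = {1,1,1,0,0,1,1,1}
  expect_equal(tpi(ramp)[2, 2], 0)           # neighbour mean equals center
  expect_equal(roughness(ramp)[2, 2], 2.0)

  flat <- elevationGrid(matrix(7, 5, 5))
  inner <- function(m) m[2:4, 2:4]
  expect_true(all(inner(tri(flat)) == 0))
  expect_true(all(inner(tpi(flat)) == 0))
  expect_true(all(inner(roughness(flat)) == 0))
  expect_true(all(inner(slope(flat)) == 0))
  expect_true(all(is.na(inner(aspect(flat)))))
  expect_true(all(inner(flowdir(flat)) == 1))  # all-tie -> smallest code
})

test_that("slope, aspect and flowdir match closed forms on exact planes", {
  # z = x with unit cells: 45 degrees, descending due west
  px <- planeDem(1, 0, n = 7)
  expect_equal(px@values[4, 4] - px@values[4, 3], 1)
  expect_equal(slope(px)[4, 4], 45)
  expect_equal(aspect(px)[4, 4], 270)
  expect_equal(flowdir(px)[4, 4], 16)

  # descending due east (z falls with x) / due south (z grows with y)
  expect_equal(aspect(planeDem(-1, 0, n = 7))[4, 4], 90)
  expect_equal(aspect(planeDem(0, 2, n = 7))[4, 4], 180)
  expect_true(all(flowdir(planeDem(-1, 0, n = 7))[3:5, 3:5] == 1))
  expect_equal(flowdir(planeDem(0, 2, n = 7))[4, 4], 4)

  # z = 3x + 4y: gradient magnitude 5, downslope azimuth atan2(-3,-4)
  p34 <- planeDem(3, 4, n = 9, cellsize = 2.5)
  expect_equal(slope(p34)[5, 5], atan(5) * 180 / pi, tolerance = 1e-12)
  expect_equal(aspect(p34)[5, 5], (atan2(-3, -4) * 180 / pi) %% 360,
               tolerance = 1e-12)
  expect_equal(slope(p34, units = "radians")[5, 5], atan(5),
               tolerance = 1e-12)

  # 10 random planes: closed form to 1e-9, flowdir in the analytic octant
  set.seed(401)
  for (i in 1:10) {
    a <- stats::runif(1, -3, 3); b <- stats::runif(1, -3, 3)
    h <- stats::runif(1, 0.5, 20)
    pd <- planeDem(a, b, c = stats::runif(1, 0, 100), n = 9, cellsize = h)
    expect_equal(slope(pd)[5, 5], atan(sqrt(a^2 + b^2)) * 180 / pi,
                 tolerance = 1e-9)
    expect_equal(aspect(pd)[5, 5], (atan2(-a, -b) * 180 / pi) %% 360,
                 tolerance = 1e-9)
    # analytic steepest-descent octant: nearest of the 8 D8 azimuths
    az <- (atan2(-a, -b) * 180 / pi) %% 360
    d8az <- c(90, 135, 180, 225, 270, 315, 0, 45)
    codes <- c(1, 2, 4, 8, 16, 32, 64, 128)
    gap <- pmin(abs(d8az - az), 360 - abs(d8az - az))
    expect_equal(flowdir(pd)[5, 5], codes[which.min(gap)])
  }
})

test_that("pit cells drain towards the smallest rise, smallest code on ties", {
  pit <- elevationGrid(matrix(c(5, 4, 3, 6, 0, 2, 7, 8, 9), 3, 3,
                              byrow = TRUE))
  # east neighbour (2) is the smallest distance-weighted rise
  expect_equal(flowdir(pit)[2, 2], 1)
  # symmetric pit: all 8 rises tie after weighting off -> smallest code
  sym <- elevationGrid(matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3))
  expect_equal(flowdir(sym, distanceWeighting = FALSE)[2, 2], 1)
  # with weighting the diagonal rises are smaller: NE/SE/SW/NW tie -> code 2
  expect_equal(flowdir(sym, distanceWeighting = TRUE)[2, 2], 2)
})

test_that("every index equals the brute-force 3x3-loop oracle on random grids", {
  set.seed(402)
  for (i in 1:12) {
    dem <- randomDem(20, 20, naHoles = sample(0:6, 1))
    want <- bruteTerrain(dem@values, cellSize(dem))
    expectLayersEqual(tri(dem), want$tri, tol = 1e-12)
    expectLayersEqual(tpi(dem), want$tpi, tol = 1e-12)
    expectLayersEqual(roughness(dem), want$roughness, tol = 1e-12)
    expectLayersEqual(slope(dem), want$slope, tol = 1e-10)
    expectLayersEqual(aspect(dem), want$aspect, tol = 1e-10)
    expectLayersEqual(flowdir(dem), want$flowdir, tol = 1e-12)
  }
})

test_that("roughness >= TRI >= |TPI| at every valid cell", {
  set.seed(403)
  for (i in 1:5) {
    dem <- randomDem(40, 40)
    r <- roughness(dem); t1 <- tri(dem); t2 <- tpi(dem)
    ok <- !is.na(r)
    expect_true(all(r[ok] >= t1[ok] - 1e-12))
    expect_true(all(t1[ok] >= abs(t2[ok]) - 1e-12))
  }
})

test_that("indices respect elevation shift and scale symmetries", {
  set.seed(404)
  dem <- randomDem(15, 18)
  shifted <- elevationGrid(dem@values + 123.4, cellsize = cellSize(dem))
  scaled <- elevationGrid(dem@values * 2.5, cellsize = cellSize(dem))
  for (f in list(tri, tpi, roughness, slope, aspect, flowdir))
    expect_equal(f(dem), f(shifted), tolerance = 1e-9)
  for (f in list(tri, tpi, roughness))
    expect_equal(f(scaled), 2.5 * f(dem), tolerance = 1e-12)
  expect_equal(aspect(scaled), aspect(dem), tolerance = 1e-9)
  expect_equal(flowdir(scaled), flowdir(dem))
})

test_that("transposing the DEM reflects aspect and permutes flowdir codes", {
  set.seed(405)
  dem <- randomDem(14, 14, cellsize = 3)
  demT <- elevationGrid(t(dem@values), cellsize = 3)
  # with row 1 = north, transposing the value matrix reflects the map
  # across the NW-SE diagonal: (x, y) -> (-y, -x), so azimuths map
  # a -> (270 - a) mod 360 and the D8 codes swap E<->S, SW<->NE, W<->N
  a <- aspect(dem)
  aT <- t(aspect(demT))  # cell (r,c) of dem is cell (c,r) of demT
  ok <- !is.na(a)
  expect_identical(is.na(aT), is.na(a))
  gap <- abs(aT[ok] - ((270 - a) %% 360)[ok]) %% 360
  expect_lt(max(pmin(gap, 360 - gap)), 1e-9)
  perm <- c(`1` = 4, `2` = 2, `4` = 1, `8` = 128, `16` = 64, `32` = 32,
            `64` = 16, `128` = 8)
  f <- flowdir(dem)
  fT <- t(flowdir(demT))
  expect_equal(fT[ok], unname(perm[as.character(f[ok])]))
})

test_that("border and nodata-adjacent cells are missing in every layer", {
  set.seed(406)
  m <- matrix(stats::rnorm(100, 500, 20), 10, 10)
  m[5, 6] <- NA
  dem <- elevationGrid(m)
  stk <- computePredictorStack(dem)
  for (nm in predictorNames(stk)) {
    lay <- predictorLayer(stk, nm)
    expect_true(all(is.na(lay[1, ])) && all(is.na(lay[10, ])))
    expect_true(all(is.na(lay[, 1])) && all(is.na(lay[, 10])))
    expect_true(all(is.na(lay[4:6, 5:7])))  # the 3x3 halo of the hole
    expect_true(all(!is.na(lay[2:3, 2:4])))
  }
  # aspect is allowed extra NAs (flat cells); the other five share support
  sup <- lapply(predictorNames(stk), function(n) is.na(predictorLayer(stk, n)))
  names(sup) <- predictorNames(stk)
  for (nm in setdiff(predictorNames(stk), "aspect"))
    expect_identical(sup[[nm]], sup$tri)
})

test_that("the stack is aligned, complete, deterministic, and carries provenance", {
  dem <- generateDem(scenario(nrows = 24, ncols = 30, seed = 9))
  s1 <- computePredictorStack(dem)
  s2 <- computePredictorStack(dem)
  expect_identical(predictorNames(s1),
                   c("tri", "tpi", "roughness", "slope", "aspect", "flowdir"))
  expect_identical(dim(s1), dim(dem))
  expect_identical(s1@layers, s2@layers)
  expect_identical(cellSize(s1), cellSize(dem))
  expect_identical(gridOrigin(s1), gridOrigin(dem))
  expect_equal(s1@provenance$slopeAlgorithm, "horn")
  # Zevenbergen-Thorne flag changes slope but stays close on smooth relief
  zt <- computePredictorStack(dem, zevenbergenThorne = TRUE)
  expect_equal(zt@provenance$slopeAlgorithm, "zevenbergen-thorne")
  expect_false(identical(zt@layers$slope, s1@layers$slope))
})

test_that("terrain operations reject degenerate grids and bad options", {
  tiny <- elevationGrid(matrix(1:4, 2, 2))
  expect_error(tri(tiny), "3x3")
  expect_error(computePredictorStack(tiny), "3x3")
  dem <- elevationGrid(matrix(stats::rnorm(25), 5, 5))
  expect_error(slope(dem, units = "furlongs"))
  expect_error(elevationGrid(matrix(1:9, 3, 3), cellsize = -1),
               "cellsize")
})
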