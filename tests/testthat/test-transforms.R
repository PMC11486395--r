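test_that("computeCenter returns the bounding-box midpoint", {
  expect_equal(unname(computeCenter(PointSet(c(0, 2, 0), c(0, 0, 4)))),
               c(1, 2))
  expect_equal(unname(computeCenter(PointSet(5, 7))), c(5, 7))
  # brute-force min/max oracle on 1,000 uniform points
  pts <- withr::with_seed(1, PointSet(runif(1000, 0, 10), runif(1000, 0, 10)))
  xy <- coords(pts)
  oracle <- c((min(xy[, 1]) + max(xy[, 1])) / 2,
              (min(xy[, 2]) + max(xy[, 2])) / 2)
  expect_equal(unname(computeCenter(pts)), oracle)
  expect_error(computeCenter(matrix(numeric(0), 0, 2)), "no data")
})

test_that("scalePoints converts raw to display pixels conserving microns", {
  p100 <- PointSet(100, 50)
  expect_equal(unname(coords(scalePoints(p100, ScaleSpec(1, 1, 1)))[1, 1]),
               100)
  expect_equal(unname(coords(scalePoints(p100, ScaleSpec(2, 2, 1)))[1, 1]),
               200)
  # round trip a -> b -> a
  a <- scalePoints(p100, ScaleSpec(1, 1, 0.7))
  back <- scalePoints(a, ScaleSpec(0.7, 0.7, 1))
  expect_equal(coords(back), coords(p100), tolerance = 1e-12)
  expect_error(scalePoints(p100, new("ScaleSpec", dataScale = -1,
                                     imageScale = 1, displayScale = 1)),
               "positive")
})

test_that("scaleImage resizes by the micron-conserving rule", {
  img <- ImageRaster(matrix(runif(1000 * 40), 1000, 40), pixelSize = 1)
  expect_equal(imageWidth(scaleImage(img, ScaleSpec(1, 1, 1))), 1000)
  img05 <- ImageRaster(matrix(runif(1000 * 40), 1000, 40), pixelSize = 0.5)
  out <- scaleImage(img05, ScaleSpec(1, 0.5, 1))
  expect_equal(imageWidth(out), 500)
  expect_equal(pixelSize(out), 1)
  # physical extent in microns conserved within half an output pixel
  spec <- ScaleSpec(1, 0.73, 1.9)
  out2 <- scaleImage(img05, spec)
  physBefore <- 1000 * 0.73
  physAfter <- imageWidth(out2) * pixelSize(out2)
  expect_lt(abs(physBefore - physAfter), pixelSize(out2) / 2 + 1e-9)
})

test_that("rotation follows the pivot formulas and composes additively", {
  ps <- PointSet(1, 0)
  s <- makeSess(ps)
  expect_equal(displayCoords(rotateData(s, 0)), cbind(1, 0))
  # unit rotation about the origin-centred degenerate box (single point is
  # its own pivot), so place two symmetric points to pin the pivot at 0,0
  ps2 <- PointSet(c(1, -1), c(0, 0))
  s2 <- rotateData(makeSess(ps2), 90)
  expect_equal(displayCoords(s2), cbind(c(0, 0), c(1, -1)), tolerance = 1e-12)
  # theta1 then theta2 equals single theta1+theta2 (matrix oracle)
  pts <- makePts(500, seed = 11, annotated = FALSE)
  sA <- rotateData(rotateData(makeSess(pts), 33.3), -71.2)
  sB <- rotateData(makeSess(pts), 33.3 - 71.2)
  expect_equal(displayCoords(sA), displayCoords(sB), tolerance = 1e-9)
  ctr <- rigidState(sA)@center
  M <- oraCompose(list(list(op = "rotate", theta = 33.3 - 71.2)), ctr, 1)$M
  expect_lt(max(abs(displayCoords(sA) - oraApply(M, coords(pts)))), 1e-9)
})

test_that("translation shifts coordinates and inverts exactly", {
  ps <- PointSet(1, 1)
  s <- makeSess(ps)
  expect_equal(displayCoords(translateData(s, 0, 0)), cbind(1, 1))
  expect_equal(displayCoords(translateData(s, 3, -2)), cbind(4, -1))
  s2 <- translateData(translateData(s, 3.7, -1.1), -3.7, 1.1)
  expect_identical(displayCoords(s2), cbind(1, 1))
})

test_that("flips mirror about the pivot with rotation compensation", {
  # theta = 0: pure mirror about the vertical plane through the pivot
  ps <- PointSet(c(3, -3), c(5, -5))   # pivot at (0, 0)
  s <- flipData(makeSess(ps), "vertical")
  expect_equal(displayCoords(s), cbind(c(-3, 3), c(5, -5)))
  expect_equal(rigidState(s)@flipsV, 1L)

  # double flip with prior rotation returns to pre-flip coordinates
  pts <- makePts(500, seed = 21, annotated = FALSE)
  for (th in c(17, -123.4)) {
    base <- rotateData(makeSess(pts), th)
    twice <- flipData(flipData(base, "horizontal"), "horizontal")
    expect_lt(max(abs(displayCoords(twice) - displayCoords(base))), 1e-9)
    expect_equal(rigidState(twice)@thetaDeg, th)
  }

  # theta = 90: composite equals the oracle matrix product of the 3 steps
  base <- rotateData(makeSess(pts), 90)
  ctr <- rigidState(base)@center
  flipped <- flipData(base, "vertical")
  ora <- oraCompose(list(list(op = "rotate", theta = 90),
                         list(op = "flip", axis = "vertical")), ctr, 1)
  expect_lt(max(abs(displayCoords(flipped) - oraApply(ora$M, coords(pts)))),
            1e-9)
  expect_equal(rigidState(flipped)@thetaDeg, -90)
})

test_that("rigid operations preserve distances; flips reverse orientation", {
  pts <- makePts(60, seed = 31, annotated = FALSE)
  s <- makeSess(pts)
  d0 <- dist(coords(pts))
  area <- function(xy) {
    # signed area of the triangle of the first three points
    unname((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
             (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2]))
  }
  a0 <- area(coords(pts))
  rot <- rotateData(translateData(s, 8, -3), 77)
  expect_lt(max(abs(dist(displayCoords(rot)) - d0)), 1e-9)
  expect_equal(area(displayCoords(rot)), a0, tolerance = 1e-9)
  fl <- flipData(rot, "horizontal")
  expect_lt(max(abs(dist(displayCoords(fl)) - d0)), 1e-9)
  expect_equal(area(displayCoords(fl)), -a0, tolerance = 1e-6)
})

test_that("any linear op sequence equals the homogeneous-matrix product", {
  pts <- makePts(500, seed = 41, annotated = FALSE)
  for (seed in c(7, 19)) {
    entries <- randomEntries(30, seed)
    s <- applyEntriesToSession(makeSess(pts), entries)
    ora <- oraCompose(entries, rigidState(s)@center, 1)
    expect_lt(max(abs(displayCoords(s) - oraApply(ora$M, coords(pts)))),
              1e-9)
    expect_equal(rigidState(s)@thetaDeg, ora$theta, tolerance = 1e-9)
  }
})
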