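closedSess <- function(pts = makePts(50, seed = 1)) {
  closeLinearPhase(makeSess(pts))
}

test_that("click cycle walks idle -> draggable -> locked -> idle locally", {
  s <- closedSess()
  id <- ids(displayPoints(s))[3]
  s1 <- cycleState(s, id)
  expect_equal(unname(pointStates(displayPoints(s1))[3]), "draggable")
  s2 <- cycleState(s1, id)
  expect_equal(unname(pointStates(displayPoints(s2))[3]), "locked")
  s3 <- cycleState(s2, id)
  expect_equal(unname(pointStates(displayPoints(s3))[3]), "idle")
  # other points untouched throughout
  expect_identical(pointStates(displayPoints(s3))[-3],
                   pointStates(displayPoints(s))[-3])
  expect_error(cycleState(s, "nope"), "unknown point id")
})

test_that("drag displacement follows the linear falloff closed form", {
  # anchor at origin, neighbours at controlled distances
  pts <- PointSet(c(0, 0, 50, 100, 150), c(0, 0, 0, 0, 0),
                  ids = c("a", "coincident", "half", "edge", "beyond"))
  s <- closedSess(pts)
  s <- cycleState(s, "a")
  s <- applyDrag(s, "a", 10, 6, threshold = 100)
  xy <- coords(displayPoints(s))
  rownames(xy) <- ids(displayPoints(s))
  expect_equal(unname(xy["a", ]), c(10, 6))            # factor 1
  expect_equal(unname(xy["coincident", ]), c(10, 6))   # D = 0
  expect_equal(unname(xy["half", ]), c(50 + 5, 3))     # D = T/2 -> half
  expect_equal(unname(xy["edge", ]), c(100, 0))        # D = T -> untouched
  expect_equal(unname(xy["beyond", ]), c(150, 0))
})

test_that("drag field matches a brute-force per-point oracle", {
  pts <- makePts(200, seed = 5, annotated = FALSE, range = c(0, 800))
  s <- closedSess(pts)
  lockIds <- ids(displayPoints(s))[c(10, 20, 30)]
  for (id in lockIds) s <- cycleState(cycleState(s, id), id)
  anchor <- ids(displayPoints(s))[1]
  s <- cycleState(s, anchor)
  before <- coords(displayPoints(s))
  rownames(before) <- ids(displayPoints(s))
  drag <- withr::with_seed(5, list(dx = runif(1, -40, 40),
                                   dy = runif(1, -40, 40)))
  T <- 1000
  s <- applyDrag(s, anchor, drag$dx, drag$dy, threshold = T)
  after <- coords(displayPoints(s))
  rownames(after) <- ids(displayPoints(s))
  ax <- before[anchor, 1]
  ay <- before[anchor, 2]
  for (i in seq_len(nrow(before))) {
    id <- rownames(before)[i]
    D <- sqrt((before[i, 1] - ax)^2 + (before[i, 2] - ay)^2)
    expected <- if (id %in% lockIds || D >= T) c(0, 0) else
      c(drag$dx, drag$dy) * (T - D) / T
    expect_equal(unname(after[i, ] - before[i, ]), expected,
                 tolerance = 1e-12)
  }
  # locked points bit-identical
  expect_identical(after[lockIds, ], before[lockIds, ])
})

test_that("zero drag is the identity and drags require the elastic mode", {
  pts <- makePts(30, seed = 6)
  open <- makeSess(pts)
  id <- ids(displayPoints(open))[1]
  expect_error(applyDrag(cycleState(open, id), id, 1, 1), "mode error")
  s <- cycleState(closedSess(pts), id)
  s0 <- applyDrag(s, id, 0, 0)
  expect_identical(displayCoords(s0), displayCoords(s))
  # locked anchors refuse
  locked <- cycleState(s, id)      # draggable -> locked
  expect_error(applyDrag(locked, id, 1, 1), "locked")
  idleS <- cycleState(locked, id)  # -> idle
  expect_error(applyDrag(idleS, id, 1, 1), "draggable")
  expect_error(applyDrag(s, id, 1, 1, threshold = 0), "threshold")
})

test_that("reset strips all elastic edits but keeps the linear state", {
  pts <- makePts(80, seed = 7)
  s <- translateData(rotateData(makeSess(pts), 40), 6, 2)
  s <- closeLinearPhase(s)
  preDrag <- displayCoords(s)
  idsd <- ids(displayPoints(s))[1:3]
  for (k in 1:3) {
    s <- cycleState(s, idsd[k])
    s <- applyDrag(s, idsd[k], k * 3, -k, threshold = 500)
  }
  events <- dragRecord(s)
  expect_length(events, 3)
  r <- resetElastic(s)
  expect_identical(displayCoords(r), preDrag)
  expect_length(dragRecord(r), 0)
  expect_true(all(pointStates(displayPoints(r)) == "idle"))
  # reset with empty drag record is a no-op
  r2 <- resetElastic(r)
  expect_identical(displayCoords(r2), displayCoords(r))
  # re-applying the recorded events reproduces the pre-reset coordinates
  xy <- displayCoords(r)
  for (ev in events) {
    locked <- ids(displayPoints(r)) %in% ev@lockedIds
    xy <- smregister:::.applyDragField(xy, locked, ev@anchorXY, ev@dx,
                                       ev@dy, ev@threshold)
  }
  expect_lt(max(abs(xy - displayCoords(s))), 1e-9)
})

test_that("drag order determines the result deterministically", {
  pts <- makePts(60, seed = 8)
  base <- closedSess(pts)
  idA <- ids(displayPoints(base))[1]
  idB <- ids(displayPoints(base))[2]
  ab <- applyDrag(cycleState(base, idA), idA, 20, 0, 80)
  ab <- applyDrag(cycleState(ab, idB), idB, 0, 20, 80)
  ba <- applyDrag(cycleState(base, idB), idB, 0, 20, 80)
  ba <- applyDrag(cycleState(ba, idA), idA, 20, 0, 80)
  # replaying either order from scratch reproduces it exactly
  reAb <- replayFull(ab)
  expect_identical(unname(coords(reAb)[ab@displayIdx, , drop = FALSE]),
                   displayCoords(ab))
  reBa <- replayFull(ba)
  expect_identical(unname(coords(reBa)[ba@displayIdx, , drop = FALSE]),
                   displayCoords(ba))
})
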