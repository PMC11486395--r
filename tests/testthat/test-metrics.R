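countedPts <- function(n = 20, G = 30, seed = 1, range = c(0, 400)) {
  withr::with_seed(seed, {
    cm <- matrix(rpois(G * n, 4), G, n,
                 dimnames = list(paste0("g", seq_len(G)), NULL))
    PointSet(runif(n, range[1], range[2]), runif(n, range[1], range[2]),
             counts = cm)
  })
}

test_that("count filtering matches an exhaustive double-loop oracle", {
  pts <- countedPts(n = 30, G = 20, seed = 2)
  counts <- countsMatrix(pts)
  filt <- filterCounts(pts, minUmi = 5, minBeads = 2)
  # brute force: beads first, then genes over retained beads
  keepBead <- logical(ncol(counts))
  for (b in seq_len(ncol(counts))) keepBead[b] <- sum(counts[, b]) > 5
  keepGene <- logical(nrow(counts))
  for (g in seq_len(nrow(counts)))
    keepGene[g] <- sum(counts[g, keepBead] > 0) > 2
  expect_identical(ids(filt), ids(pts)[keepBead])
  expect_identical(rownames(countsMatrix(filt)),
                   rownames(counts)[keepGene])
  # zero thresholds on an all-positive matrix change nothing
  pos <- pts
  pos@counts <- counts + 1
  same <- filterCounts(pos, minUmi = 0, minBeads = 0)
  expect_identical(dim(countsMatrix(same)), dim(counts))
  noCounts <- makePts(5, seed = 1)
  expect_error(filterCounts(noCounts), "no count matrix")
})

test_that("binning sums raw counts per gene with half-open edges", {
  pts <- countedPts(n = 10, G = 5, seed = 3, range = c(10, 90))
  be <- binCounts(pts, binSize = 100)
  expect_equal(ncol(be@counts), 1L)     # all points in one bin
  expect_equal(unname(be@counts[, 1]), unname(rowSums(countsMatrix(pts))))

  # edge point goes to the bin whose lower edge it sits on
  edge <- PointSet(c(0, 100, 199.999), c(0, 0, 0), ids = c("a", "b", "c"),
                   counts = matrix(1, 1, 3,
                                   dimnames = list("g", c("a", "b", "c"))))
  bed <- binCounts(edge, binSize = 100)
  expect_identical(sort(bed@bins[, "i"]), c(0L, 1L))
  # the point at exactly 100 joins the higher-index bin together with 199.999
  expect_equal(unname(bed@counts["g", "1_0"]), 2)
  expect_equal(unname(bed@counts["g", "0_0"]), 1)

  # random layout vs an independent dictionary-accumulation oracle
  pts2 <- countedPts(n = 100, G = 8, seed = 11, range = c(0, 500))
  be2 <- binCounts(pts2, binSize = 100)
  dict <- new.env()
  xy <- coords(pts2)
  org <- be2@origin
  cm <- countsMatrix(pts2)
  for (p in seq_len(100)) {
    key <- paste0(floor((xy[p, 1] - org[1]) / 100), "_",
                  floor((xy[p, 2] - org[2]) / 100))
    prev <- if (!is.null(dict[[key]])) dict[[key]] else numeric(8)
    dict[[key]] <- prev + cm[, p]
  }
  expect_setequal(colnames(be2@counts), ls(dict))
  for (key in ls(dict))
    expect_equal(unname(be2@counts[, key]), unname(dict[[key]]))
  # conservation: per-gene totals preserved exactly
  expect_equal(unname(rowSums(be2@counts)), unname(rowSums(cm)))
})

test_that("matched Spearman is 1 on identical sections, NA on flat genes", {
  pts <- countedPts(n = 150, G = 12, seed = 4, range = c(0, 600))
  cm <- countsMatrix(pts)
  cm[3, ] <- 0L                      # undetected gene: constant zero bins
  pts@counts <- cm
  bp <- binPair(pts, pts, 100)
  res <- perGeneSpearman(bp$a, bp$b, "matched")
  expect_equal(res$perGene$rho[res$perGene$defined],
               rep(1, sum(res$perGene$defined)), tolerance = 1e-12)
  expect_false(res$perGene$defined[res$perGene$gene == "g3"])
  expect_equal(res$summary$medianRho, 1)
  expect_equal(res$summary$nGenes, 11)

  # symmetric under swapping sections
  sym <- perGeneSpearman(bp$b, bp$a, "matched")
  expect_equal(sym$perGene$rho, res$perGene$rho)

  # too few common bins
  tiny <- countedPts(n = 4, G = 3, seed = 5, range = c(0, 50))
  bt <- binPair(tiny, tiny, 1000)
  expect_error(perGeneSpearman(bt$a, bt$b), "insufficient")
  expect_error(perGeneSpearman(bp$a, bt$b), "same grid")
})

test_that("Spearman uses average ranks, matching a rank-then-Pearson oracle", {
  pts <- countedPts(n = 200, G = 6, seed = 6, range = c(0, 500))
  pts2 <- countedPts(n = 200, G = 6, seed = 7, range = c(0, 500))
  pts2@counts <- countsMatrix(pts) +
    withr::with_seed(66, matrix(rpois(6 * 200, 2), 6, 200))  # tied-heavy
  coords(pts2) <- coords(pts)
  bp <- binPair(pts, pts2, 100)
  res <- perGeneSpearman(bp$a, bp$b, "matched")
  common <- intersect(colnames(bp$a@counts), colnames(bp$b@counts))
  for (g in seq_len(6)) {
    oracle <- stats::cor(rank(bp$a@counts[g, common]),
                         rank(bp$b@counts[g, common]))
    expect_equal(res$perGene$rho[g], oracle, tolerance = 1e-12)
  }
})

test_that("random pairing centres near zero on spatially structured data", {
  pair <- makeSerialPair(fixtureSpec(nPoints = 6000, nGenes = 25,
                                     imageShape = c(320L, 320L), seed = 8),
                         countNoise = 0.2)
  bp <- binPair(pair$a$points, pair$b$points, 10)
  expect_gte(perGeneSpearman(bp$a, bp$b, "matched")$summary$nBins, 200)
  rnd <- perGeneSpearman(bp$a, bp$b, "random", seed = 9)
  expect_lt(abs(rnd$summary$medianRho), 0.1)
  mt <- perGeneSpearman(bp$a, bp$b, "matched")
  expect_gt(mt$summary$medianRho, rnd$summary$medianRho)
  expect_error(perGeneSpearman(bp$a, bp$b, "random"), "seed")
})

test_that("the tissue mask recovers a synthetic ellipse", {
  sec <- makeSection(fixtureSpec(seed = 10))
  m <- tissueMask(sec$image)
  # ground-truth ellipse rasterised at pixel centres
  e <- sec$spec@ellipse
  W <- imageWidth(sec$image); H <- imageHeight(sec$image)
  xs <- (seq_len(W) - 0.5) * sec$spec@pixelSize
  ys <- (H - seq_len(H) + 0.5) * sec$spec@pixelSize
  truth <- outer(((xs - e[1]) / e[3])^2, ((ys - e[2]) / e[4])^2, "+") <= 1
  iou <- sum(m@mask & truth) / sum(m@mask | truth)
  expect_gte(iou, 0.95)

  blank <- ImageRaster(matrix(1, 32, 32), 1)
  expect_warning(bm <- tissueMask(blank), "degenerate")
  expect_false(any(bm@mask))

  # polarity flag: inverted image with darkTissue = FALSE gives the same mask
  inv <- ImageRaster(1 - sec$image@pixels, pixelSize(sec$image))
  m2 <- tissueMask(inv, darkTissue = FALSE)
  expect_identical(m2@mask, m@mask)
})

test_that("overlap percent counts points on tissue pixels", {
  full <- new("TissueMask", mask = matrix(TRUE, 50, 50),
              threshold = 0.5, darkTissue = TRUE)
  pts <- makePts(40, seed = 11, range = c(1, 49))
  ov <- overlapPercent(pts, full)
  expect_equal(ov$percent, 100)
  expect_length(ov$nonOverlappingIds, 0)

  # 7 of 10 inside (3 beyond the image bounds)
  p10 <- PointSet(c(runif(7, 1, 49), 60, 70, -5), c(runif(10, 1, 49)))
  expect_equal(overlapPercent(p10, full)$percent, 70)

  # half-covered mask, uniform points: binomial expectation
  half <- matrix(FALSE, 50, 50)
  half[1:25, ] <- TRUE               # left half (x < 25) is tissue
  hm <- new("TissueMask", mask = half, threshold = 0.5, darkTissue = TRUE)
  up <- withr::with_seed(12, PointSet(runif(1000, 0, 50), runif(1000, 0, 50)))
  pct <- overlapPercent(up, hm)$percent
  sigma <- 100 * sqrt(0.25 / 1000)
  expect_lt(abs(pct - 50), 3 * sigma)
})
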