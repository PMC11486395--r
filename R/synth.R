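#' Specify a synthetic section
#'
#' Builds the parameter object for the synthetic fixture generator: an
#' elliptical "tissue" rendered dark on a bright background, spatially
#' coherent Gaussian cluster blobs inside it, and per-gene Poisson counts
#' whose log-rates combine a gene baseline, a cluster effect and a smooth
#' spatial gradient (the spatial autocorrelation that the matched-vs-random
#' bin correlation metric needs).
#'
#' @param nPoints number of observations (default 500).
#' @param nClusters number of annotation clusters (default 3).
#' @param nGenes number of genes (default 40).
#' @param imageShape image (width, height) in pixels (default 192 x 192).
#' @param pixelSize micrometres per image pixel (default 1).
#' @param ellipse tissue ellipse `c(cx, cy, rx, ry)` in micrometres;
#'   defaults to a centred ellipse spanning ~3/4 of the image.
#' @param clusterWeights mixing weights, one per cluster (default equal).
#' @param seed RNG seed (mandatory — fixtures are bit-reproducible).
#' @return A \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nPoints = 500L, nClusters = 3L, nGenes = 40L,
                        imageShape = c(192L, 192L), pixelSize = 1,
                        ellipse = NULL, clusterWeights = NULL, seed = 1L) {
  imageShape <- as.integer(imageShape)
  if (is.null(ellipse)) {
    w <- imageShape[1] * pixelSize
    h <- imageShape[2] * pixelSize
    ellipse <- c(w / 2, h / 2, 0.38 * w, 0.34 * h)
  }
  if (is.null(clusterWeights))
    clusterWeights <- rep(1 / nClusters, nClusters)
  new("FixtureSpec", nPoints = as.integer(nPoints),
      nClusters = as.integer(nClusters), nGenes = as.integer(nGenes),
      imageShape = imageShape, pixelSize = as.numeric(pixelSize),
      ellipse = as.numeric(ellipse),
      clusterWeights = clusterWeights / sum(clusterWeights),
      seed = as.integer(seed))
}

# Points are kept strictly inside a 0.9-shrunk copy of the tissue ellipse so
# that the Otsu-derived mask always covers them.
.POINT_MARGIN <- 0.9

#' Generate a synthetic section
#'
#' Draws cluster centres inside the tissue ellipse, samples points from
#' Gaussian blobs around them (rejection-sampled into a margin-shrunk
#' ellipse so every point lies on tissue), simulates Poisson gene counts
#' with cluster- and gradient-dependent log-linear rates, and renders the
#' tissue image (dark ellipse, bright background, mild noise). Fully
#' deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @return A list with `points` (\linkS4class{PointSet} with counts, raw
#'   coordinates in micrometres), `image` (\linkS4class{ImageRaster}),
#'   `rates` (the genes-by-observations Poisson rates, for resampling in
#'   [makeSerialPair()]) and `spec`.
#' @export
makeSection <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  cx <- spec@ellipse[1]
  cy <- spec@ellipse[2]
  rx <- spec@ellipse[3]
  ry <- spec@ellipse[4]
  n <- spec@nPoints
  k <- spec@nClusters
  G <- spec@nGenes
  withr::with_seed(spec@seed, {
    ang <- runif(k, 0, 2 * pi)
    rad <- sqrt(runif(k))
    centres <- cbind(cx + 0.45 * rx * rad * cos(ang),
                     cy + 0.45 * ry * rad * sin(ang))
    lab <- sample.int(k, n, replace = TRUE, prob = spec@clusterWeights)
    sd0 <- 0.22 * min(rx, ry)
    x <- numeric(n)
    y <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      px <- stats::rnorm(length(need), centres[lab[need], 1], sd0)
      py <- stats::rnorm(length(need), centres[lab[need], 2], sd0)
      ok <- ((px - cx) / (.POINT_MARGIN * rx))^2 +
            ((py - cy) / (.POINT_MARGIN * ry))^2 < 1
      x[need[ok]] <- px[ok]
      y[need[ok]] <- py[ok]
      need <- need[!ok]
    }
    alpha <- stats::rnorm(G, log(3), 0.4)
    beta <- matrix(stats::rnorm(k * G, 0, 0.6), k, G)
    gamma <- stats::rnorm(G, 0, 0.7)
    delta <- stats::rnorm(G, 0, 0.7)
    u <- (x - cx) / rx
    v <- (y - cy) / ry
    logLam <- matrix(alpha, G, n) + t(beta[lab, , drop = FALSE]) +
      outer(gamma, u) + outer(delta, v)
    rates <- exp(logLam)
    counts <- matrix(stats::rpois(G * n, rates), G, n)
    ids <- paste0("obs", seq_len(n))
    rownames(counts) <- paste0("gene", seq_len(G))
    colnames(counts) <- ids
    rownames(rates) <- rownames(counts)
    colnames(rates) <- ids

    W <- spec@imageShape[1]
    H <- spec@imageShape[2]
    xs <- (seq_len(W) - 0.5) * spec@pixelSize
    ys <- (H - seq_len(H) + 0.5) * spec@pixelSize     # row 1 = top edge, y-up
    inside <- outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, "+") <= 1
    pix <- matrix(0.93, W, H)
    pix[inside] <- 0.25
    pix <- pix + stats::rnorm(W * H, 0, 0.015)
    pix[pix < 0] <- 0
    pix[pix > 1] <- 1

    list(points = PointSet(x, y, ids = ids,
                           annotation = paste0("c", lab), counts = counts),
         image = ImageRaster(pix, spec@pixelSize, "synthetic_section"),
         rates = rates,
         spec = spec)
  })
}

#' Generate a pair of synthetic serial sections
#'
#' Section B is section A's point cloud mapped by a known rigid transform
#' (rotation by `thetaDeg` about A's bounding-box centre, then translation)
#' plus seeded positional jitter. With `countNoise = 0` B carries exactly
#' A's counts (the noise-free degenerate case, giving matched per-gene
#' correlation 1 under the identity map); with `countNoise > 0` B's counts
#' are re-drawn Poisson from A's per-location rates multiplied by log-normal
#' noise `exp(N(0, countNoise^2))` per gene and location. The exact map is
#' returned for parameter-recovery tests.
#'
#' @param spec a \linkS4class{FixtureSpec} for section A.
#' @param thetaDeg,translation the ground-truth rigid map (degrees; display
#'   units).
#' @param jitterSd standard deviation of positional jitter, micrometres.
#' @param countNoise log-normal noise scale on the count rates.
#' @param seed RNG seed for B's jitter and counts (defaults to the spec
#'   seed + 1).
#' @return A list with `a` (the [makeSection()] output), `b` (list with
#'   `points`), and `groundTruth` (list: `thetaDeg`, `translation`,
#'   `center`, `jitterSd`, `countNoise`).
#' @export
makeSerialPair <- function(spec, thetaDeg = 0, translation = c(0, 0),
                           jitterSd = 0, countNoise = 0,
                           seed = spec@seed + 1L) {
  a <- makeSection(spec)
  centre <- computeCenter(a$points)
  n <- nPoints(a$points)
  G <- nrow(a$rates)
  withr::with_seed(as.integer(seed), {
    xy <- .rotateAbout(coords(a$points), thetaDeg, centre)
    xy[, 1] <- xy[, 1] + translation[1]
    xy[, 2] <- xy[, 2] + translation[2]
    if (jitterSd > 0)
      xy <- xy + matrix(stats::rnorm(2 * n, 0, jitterSd), n, 2)
    countsB <- if (countNoise == 0) {
      countsMatrix(a$points)
    } else {
      lam <- a$rates * exp(matrix(stats::rnorm(G * n, 0, countNoise), G, n))
      m <- matrix(stats::rpois(G * n, lam), G, n,
                  dimnames = dimnames(a$rates))
      m
    }
    b <- PointSet(xy[, 1], xy[, 2], ids = ids(a$points),
                  annotation = annotation(a$points), counts = countsB)
    list(a = a, b = list(points = b),
         groundTruth = list(thetaDeg = thetaDeg, translation = translation,
                            center = centre, jitterSd = jitterSd,
                            countNoise = countNoise))
  })
}

#' Write a complete fixture input bundle
#'
#' Serialises a generated section through every input format the engine
#' reads: coordinates as CSV, XLSX and h5ad (the h5ad carries the count
#' matrix and spatial slot), and the tissue image as PNG and JPEG.
#'
#' @param section output of [makeSection()].
#' @param dir output directory (created if needed).
#' @param clusterKey annotation column name used in all formats.
#' @return Named character vector of written paths, invisibly.
#' @export
writeFixtureBundle <- function(section, dir, clusterKey = "cluster") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- section$points
  paths <- c(csv = file.path(dir, "coordinates.csv"),
             xlsx = file.path(dir, "coordinates.xlsx"),
             h5ad = file.path(dir, "section.h5ad"),
             png = file.path(dir, "image.png"),
             jpeg = file.path(dir, "image.jpeg"))
  writeCoordinates(pts, paths[["csv"]])
  ann <- annotation(pts)
  ann[is.na(ann)] <- ""
  writeXlsx(data.frame(id = ids(pts), x = coords(pts)[, 1],
                       y = coords(pts)[, 2], cluster = ann,
                       stringsAsFactors = FALSE),
            paths[["xlsx"]])
  writeH5ad(pts, paths[["h5ad"]], clusterKey = clusterKey)
  img <- EBImage::Image(section$image@pixels,
                        colormode = if (length(dim(section$image@pixels)) == 3L)
                          "Color" else "Grayscale")
  EBImage::writeImage(img, paths[["png"]], type = "png")
  EBImage::writeImage(img, paths[["jpeg"]], type = "jpeg", quality = 95)
  invisible(paths)
}
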