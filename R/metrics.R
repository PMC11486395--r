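#' Filter beads and genes by raw counts
#'
#' Standard pre-filter for bead-array sections before benchmarking:
#' observations (beads) with total UMI count strictly greater than
#' `minUmi` are retained first, then genes detected (count > 0) in strictly
#' more than `minBeads` of the retained observations. Both inequalities are
#' strict — a bead with exactly `minUmi` UMIs is removed — and the order
#' (beads, then genes) is fixed.
#'
#' @param points a \linkS4class{PointSet} carrying a count matrix.
#' @param minUmi minimum total UMI count per observation (default 50,
#'   exclusive).
#' @param minBeads minimum number of detecting observations per gene
#'   (default 5, exclusive).
#' @return The filtered \linkS4class{PointSet}.
#' @export
filterCounts <- function(points, minUmi = 50, minBeads = 5) {
  stopifnot(is(points, "PointSet"))
  counts <- points@counts
  if (is.null(counts)) stop("no count matrix present")
  keepObs <- which(colSums(counts) > minUmi)
  if (!length(keepObs)) stop("no observations pass the UMI filter")
  out <- points[keepObs]
  sub <- counts[, keepObs, drop = FALSE]
  keepGenes <- rowSums(sub > 0) > minBeads
  out@counts <- sub[keepGenes, , drop = FALSE]
  out
}

#' Sum raw counts over a square spatial grid
#'
#' Lays a grid of `binSize` x `binSize` micrometre bins over the section and
#' sums the raw counts of each gene within each occupied bin. Bins are
#' half-open (`[x0 + i*s, x0 + (i+1)*s)`): a point exactly on an edge
#' belongs to the higher-index bin whose lower edge it sits on. Empty bins
#' are absent. Binning conserves counts exactly: the per-gene sums over all
#' bins equal the per-gene totals of the section.
#'
#' @param points a \linkS4class{PointSet} with counts.
#' @param binSize bin edge length in micrometres (default 100).
#' @param origin numeric length-2 lower-left corner of bin (0, 0); defaults
#'   to the componentwise coordinate minimum. Use [binPair()] to bin two
#'   sections on one shared grid.
#' @return A \linkS4class{BinnedExpression}.
#' @export
binCounts <- function(points, binSize = 100, origin = NULL) {
  stopifnot(is(points, "PointSet"))
  if (is.null(points@counts)) stop("no count matrix present")
  if (binSize <= 0) stop("binSize must be positive")
  xy <- points@coords
  if (is.null(origin)) origin <- c(min(xy[, 1]), min(xy[, 2]))
  i <- floor((xy[, 1] - origin[1]) / binSize)
  j <- floor((xy[, 2] - origin[2]) / binSize)
  key <- paste0(i, "_", j)
  agg <- rowsum(t(points@counts), key)          # bins x genes, keys sorted
  bins <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
  storage.mode(bins) <- "integer"
  colnames(bins) <- c("i", "j")
  new("BinnedExpression", binSize = as.numeric(binSize),
      origin = stats::setNames(as.numeric(origin), c("x", "y")),
      bins = bins, counts = t(agg))
}

#' Bin two sections on a shared grid
#'
#' Uses the componentwise minimum over both sections' coordinates as the
#' common grid origin, so matched bin indices refer to the same physical
#' square in both sections.
#'
#' @param a,b \linkS4class{PointSet}s with counts (registered into a common
#'   space).
#' @param binSize bin edge length in micrometres.
#' @return List with elements `a` and `b`, both
#'   \linkS4class{BinnedExpression} on the shared grid.
#' @export
binPair <- function(a, b, binSize = 100) {
  origin <- c(min(min(a@coords[, 1]), min(b@coords[, 1])),
              min(min(a@coords[, 2]), min(b@coords[, 2])))
  list(a = binCounts(a, binSize, origin), b = binCounts(b, binSize, origin))
}

setMethod("show", "BinnedExpression", function(object) {
  cat(sprintf("BinnedExpression: %d genes x %d occupied %g-um bins\n",
              nrow(object@counts), ncol(object@counts), object@binSize))
  invisible(NULL)
})

#' Per-gene Spearman correlation between two binned sections
#'
#' Compares aggregated raw counts of two serial sections over the bins
#' occupied in both (the bin universe is the intersection). `matched`
#' pairing aligns identical bin indices — the registration-quality signal —
#' while `random` pairing permutes the second section's bins uniformly
#' (seeded), giving the null the matched correlation is judged against.
#' Spearman uses average ranks for ties. Genes with zero variance in either
#' paired vector are reported as undefined (`NA`) and excluded from the
#' median/mean summaries.
#'
#' @param a,b \linkS4class{BinnedExpression} objects on the same grid (same
#'   origin and bin size; see [binPair()]).
#' @param pairing `"matched"` or `"random"`.
#' @param seed RNG seed for the random pairing.
#' @return A list with `perGene` (data.frame: `gene`, `rho`, `defined`),
#'   `summary` (list: `medianRho`, `meanRho`, `nGenes`, `nBins`) and
#'   `pairing`.
#' @export
perGeneSpearman <- function(a, b, pairing = c("matched", "random"),
                            seed = NULL) {
  pairing <- match.arg(pairing)
  stopifnot(is(a, "BinnedExpression"), is(b, "BinnedExpression"))
  if (!isTRUE(all.equal(a@binSize, b@binSize)) ||
      max(abs(a@origin - b@origin)) > 1e-9)
    stop("sections must be binned on the same grid (origin and bin size)")
  common <- intersect(colnames(a@counts), colnames(b@counts))
  if (length(common) < 3L)
    stop("insufficient data: fewer than 3 bins occupied in both sections")
  genes <- intersect(rownames(a@counts), rownames(b@counts))
  if (!length(genes)) stop("no shared genes between sections")
  A <- a@counts[genes, common, drop = FALSE]
  B <- b@counts[genes, common, drop = FALSE]
  if (pairing == "random") {
    if (is.null(seed)) stop("seed is required for random pairing")
    perm <- withr::with_seed(as.integer(seed),
                             sample.int(length(common)))
    B <- B[, perm, drop = FALSE]
  }
  rho <- vapply(seq_along(genes), function(g) {
    va <- A[g, ]
    vb <- B[g, ]
    if (stats::var(va) == 0 || stats::var(vb) == 0) NA_real_
    else stats::cor(va, vb, method = "spearman")
  }, numeric(1))
  defined <- !is.na(rho)
  list(perGene = data.frame(gene = genes, rho = rho, defined = defined,
                            stringsAsFactors = FALSE),
       summary = list(medianRho = stats::median(rho[defined]),
                      meanRho = mean(rho[defined]),
                      nGenes = sum(defined),
                      nBins = length(common)),
       pairing = pairing)
}
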