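# Largest-remainder apportionment of N among strata with counts C.
# Quotas q_i = C_i * N / sum(C) are floored and the remaining units go to
# the largest fractional remainders (ties broken by stratum order), so that
# sum(D) == N exactly and |D_i - q_i| < 1 for every stratum.
.largestRemainder <- function(C, N) {
  q <- C * N / sum(C)
  D <- floor(q)
  rem <- as.integer(round(N - sum(D)))
  if (rem > 0L) {
    frac <- q - D
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    D[take] <- D[take] + 1
  }
  as.integer(D)
}

#' Downsample displayed points
#'
#' `stratifiedDownsample` reduces the displayed point count while
#' maintaining the distribution of annotations: each cluster `i` with `C_i`
#' of the `T` observations contributes `D_i` points derived from its
#' fraction `F_i = C_i / T` via `D_i = F_i * N`, rounded by the
#' largest-remainder method so that the quotas sum to `N` exactly, and
#' sampled uniformly without replacement. `randomDownsample` is the fallback
#' when no annotation exists: a uniform sample without replacement.
#' Both are deterministic given `seed`.
#'
#' The returned indices only govern display; [replayFull()] always applies
#' the recorded manipulations to every original observation on export.
#'
#' @param points a \linkS4class{PointSet}.
#' @param targetN requested displayed count (`0 < targetN <= nPoints`).
#' @param seed RNG seed (mandatory; there is no hidden global randomness).
#' @return `stratifiedDownsample`: a list with `indices` (sorted integer
#'   indices into `points`) and `spec`, a record with `totalT`, `targetN`,
#'   `perCluster` (data.frame with columns `label`, `C`, `F`, `D`) and
#'   `seed`. `randomDownsample`: sorted integer indices.
#' @examples
#' ps <- PointSet(runif(100), runif(100),
#'                annotation = rep(c("a", "b"), c(60, 40)))
#' ds <- stratifiedDownsample(ps, 10, seed = 1)
#' ds$spec$perCluster$D   # 6 and 4
#' @export
stratifiedDownsample <- function(points, targetN, seed) {
  stopifnot(is(points, "PointSet"))
  n <- nPoints(points)
  targetN <- as.integer(targetN)
  if (is.na(targetN) || targetN <= 0L) stop("targetN must be positive")
  if (targetN > n) stop("targetN exceeds the number of observations")
  if (!hasAnnotation(points))
    stop("no annotation present: use randomDownsample")
  ann <- points@annotation
  ann[is.na(ann)] <- "<unannotated>"
  labs <- unique(ann)
  C <- as.integer(table(factor(ann, levels = labs)))
  D <- .largestRemainder(C, targetN)
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_along(labs), function(k) {
      pool <- which(ann == labs[k])
      pool[sample.int(length(pool), D[k])]
    }), use.names = FALSE)
  })
  list(indices = sort(idx),
       spec = list(totalT = n, targetN = targetN,
                   perCluster = data.frame(label = labs, C = C,
                                           F = C / n, D = D),
                   seed = as.integer(seed)))
}

#' @rdname stratifiedDownsample
#' @export
randomDownsample <- function(points, targetN, seed) {
  stopifnot(is(points, "PointSet"))
  n <- nPoints(points)
  targetN <- as.integer(targetN)
  if (is.na(targetN) || targetN <= 0L) stop("targetN must be positive")
  if (targetN > n) stop("targetN exceeds the number of observations")
  sort(withr::with_seed(as.integer(seed), sample.int(n, targetN)))
}
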