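# Small in-code fixtures shared across test files.

makePts <- function(n = 100, seed = 1, annotated = TRUE, counts = FALSE,
                    nGenes = 10, range = c(0, 100)) {
  withr::with_seed(seed, {
    x <- runif(n, range[1], range[2])
    y <- runif(n, range[1], range[2])
    ann <- if (annotated) sample(paste0("c", 1:3), n, replace = TRUE)
    cm <- if (counts)
      matrix(rpois(nGenes * n, 3), nGenes, n,
             dimnames = list(paste0("g", seq_len(nGenes)), NULL))
    PointSet(x, y, annotation = ann, counts = cm)
  })
}

unitScales <- function() ScaleSpec(1, 1, 1)

# session over a plain point set with no downsampling
makeSess <- function(points = makePts(), scales = unitScales(), ...) {
  newSession(points, scales, ...)
}

displayCoords <- function(session) unname(coords(displayPoints(session)))
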