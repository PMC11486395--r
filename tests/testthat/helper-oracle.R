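# Independent 3x3 homogeneous-matrix oracle for the linear operations.
# Column-vector convention: p' = M %*% c(x, y, 1). Built only from base
# trigonometry and matrix products, never from the package's replay code.

oraRot <- function(thetaDeg) {
  r <- thetaDeg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

oraTrans <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)

oraMirror <- function(axis) {
  diag(c(if (axis == "vertical") -1 else 1,
         if (axis == "horizontal") -1 else 1, 1))
}

oraAbout <- function(M, center)
  oraTrans(center[1], center[2]) %*% M %*% oraTrans(-center[1], -center[2])

oraScale <- function(f) diag(c(f, f, 1))

# Compose the oracle matrix for an ordered entry list, tracking the widget
# angle and display scale exactly as the documented semantics prescribe.
oraCompose <- function(entries, center, displayScale0) {
  M <- diag(3)
  theta <- 0
  sc <- displayScale0
  for (e in entries) {
    Mi <- switch(e$op,
      rotate = {
        theta <- theta + e$theta
        oraAbout(oraRot(e$theta), center)
      },
      translate = oraTrans(e$tx, e$ty),
      flip = {
        A <- oraAbout(oraRot(-theta), center)
        B <- oraAbout(oraMirror(e$axis), center)
        theta <- -theta
        A %*% B %*% A          # step3 %*% step2 %*% step1 (A is its own kind)
      },
      rescale = {
        f <- sc / e$displayScale
        sc <- e$displayScale
        oraScale(f)
      },
      stop("oracle: unknown op ", e$op))
    M <- Mi %*% M
  }
  list(M = M, theta = theta, displayScale = sc)
}

oraApply <- function(M, xy) {
  out <- t(M %*% rbind(t(xy), 1))
  out[, 1:2, drop = FALSE]
}

# Random committed-operation sequences for property tests.
randomEntries <- function(m, seed, withRescale = TRUE) {
  withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      k <- sample.int(if (withRescale) 4L else 3L, 1)
      switch(k,
        list(op = "rotate", theta = runif(1, -180, 180)),
        list(op = "translate", tx = runif(1, -50, 50),
             ty = runif(1, -50, 50)),
        list(op = "flip", axis = sample(c("vertical", "horizontal"), 1)),
        list(op = "rescale", displayScale = runif(1, 0.5, 2)))
    })
  })
}

applyEntriesToSession <- function(session, entries) {
  for (e in entries) {
    session <- switch(e$op,
      rotate = rotateData(session, e$theta),
      translate = translateData(session, e$tx, e$ty),
      flip = flipData(session, e$axis),
      rescale = rescaleData(session, e$displayScale))
  }
  session
}
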