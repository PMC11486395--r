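---
title: "The smregister registration engine: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smregister registration engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smregister)
```

## The problem

Spatio-molecular assays (MERFISH, Slide-seq and relatives) produce
per-observation x–y coordinates, often with cluster annotations and gene
counts, while histology (H&E) or fluorescence microscopy of the same or an
adjacent section captures morphology. The two live in different scales,
orientations and coordinate origins, so relating them requires
registration. Automated methods exist, but manual registration remains
necessary for difficult samples and for producing ground-truth alignments;
what a manual tool actually *computes* is a short list of well-defined
coordinate manipulations. `smregister` implements that computational core
headlessly: every manipulation is an explicit, logged, replayable function
call, which makes scripted registration, exact export and benchmarking
possible without any GUI.

## Coordinate model

All work happens in a **display space**: a y-up Cartesian frame measured in
display pixels, each spanning `displayScale` micrometres. Raw coordinates
at `dataScale` µm/px enter via

\[ x_{display} = x_{raw} \cdot \frac{dataScale}{displayScale}, \]

and image width/height are resized by the same micrometre-conserving rule,
so a 200 µm structure spans the same number of display pixels in both.
Scales are strictly positive and always user-supplied. Images are placed
with pixel row 1 at the top edge; a point at display position $(x, y)$
falls on image column $\lfloor x\rfloor + 1$ and row
$H - \lfloor y\rfloor$.

### Rigid manipulations

With pivot $(X_C, Y_C)$ — fixed once at load as the bounding-box centre of
the scaled full point set and never recomputed, so undo/redo and replay are
exact inverses — the engine provides:

* **rotation** by $\theta$ (degrees, counterclockwise):
  $X_N = (X_O - X_C)\cos\theta - (Y_O - Y_C)\sin\theta + X_C$ and the
  corresponding $Y_N$;
* **translation**: $X_N = X_O + T_X$, $Y_N = Y_O + T_Y$;
* **flip** about the vertical or horizontal plane through the pivot. A flip
  at accumulated angle $\theta$ is the three-step rotation-compensated
  procedure: rotate all points by $-\theta$ about the pivot, mirror about
  the pivot axis, rotate by $-\theta$ again; the displayed angle is then
  set to $-\theta$ so subsequent rotations stay synchronised. This map is
  an involution — applying the same flip twice restores every coordinate —
  which the test suite verifies against an independent homogeneous-matrix
  oracle;
* **rescale** to a new display scale (multiplies all coordinates by
  `old/new`). The pivot deliberately does not move under a rescale; keeping
  it immutable is what makes the log a pure function of its entries.

Every committed operation appends one entry to the **manipulation log**.
The live display coordinates are always recomputed by replaying the log
prefix onto the original scaled coordinates — a single code path shared
with undo, redo and export, so all of them agree bit for bit. Undo moves
the cursor back one entry; redo moves it forward; any new operation
discards the redoable tail.

### Elastic manipulation

Points carry a three-state click cycle: idle → draggable → locked → idle.
Dragging a draggable anchor by $(dx, dy)$ displaces every unlocked point
$i$ at distance $D_i < T$ from the anchor's pre-drag position by

\[ (dx, dy) \cdot \frac{T - D_i}{T}, \]

a radial field with linear falloff that vanishes at the threshold $T$
(default 1000 display pixels, user-settable). Locked points never move.
Strictly $D < T$ receives displacement — at $D = T$ the factor is zero
anyway — a convention documented for bitwise reproducibility. Distances are
measured from the anchor's position at drag start, snapshotted in the drag
record together with the lock set, so replay on the full data is well
defined; within one committed event neighbours do not chase the anchor.
Elastic edits are only allowed once the linear phase is closed
(`closeLinearPhase()`), because export replays the linear log first and the
drags after it; allowing interleaving would make the recorded order
ambiguous. There is no per-drag undo, only `resetElastic()`, which restores
the pure-linear coordinates and clears the drag record.

## Downsampling and full-data replay

Displays larger than `displayN` (default 10,000, matching common display
practice for datasets of ~10⁵ observations) are thinned. With an
annotation, cluster $i$ of size $C_i$ among $T$ observations receives
$D_i = \frac{C_i}{T} N$ display slots; since these are rarely integral,
they are rounded by the **largest-remainder method** (floor all quotas,
then hand the remaining slots to the largest fractional remainders, ties by
cluster order), which keeps $\sum D_i = N$ exactly and
$|D_i/N - C_i/T| \le 1/N$. A cluster whose quota rounds to zero keeps zero
— proportionality is preserved exactly rather than imposing a minimum of
one. Without annotation, a uniform sample without replacement is taken.
Both paths require an explicit seed; nothing in the API consumes hidden
global randomness.

Downsampling governs *display only*. `replayFull()` applies the scaling,
the committed log entries and the drag events (each evaluated over all
points from its recorded anchor snapshot) to every original observation, so
the exported coordinate file always contains the complete data set, and the
points that were displayed land exactly — bitwise — where the interactive
session put them.

## Registration bundles

`writeRegistrationBundle()` writes the registered full-data CSV
(`id,x,y,cluster`, 17-significant-digit coordinates, so read-back is
lossless), the display-scaled image re-encoded as JPEG quality 95, a
plain-text `key=value` record of the registration parameters, the
manipulation log CSV (`sequence,op,param1,param2,param3`) and the drag
record CSV. The drag record carries an extra `locked_ids` column beyond the
anchor/displacement/threshold fields: without the lock snapshot a bundle
could not reproduce sessions that used locking, and self-sufficiency — raw
inputs plus bundle reproduce the registered output with no session state —
is the bundle's defining property, which `replayBundle()` and the test
suite exercise end to end. The record stores the display scale used at
load; mid-session rescales are ordinary log entries and are replayed in
order.

## Quality metrics

**Binned expression correlation.** Serial sections registered into a common
space should show correlated spatial expression. Raw counts per gene are
summed over half-open square bins (default 100 µm — coarse enough that
bead/cell-level stochasticity averages out, fine enough to preserve
structure) on a grid whose origin is the componentwise minimum over both
sections, so the grids match by construction. Binning conserves per-gene
totals exactly. Spearman correlation (average ranks for ties) is computed
per gene over bins occupied in *both* sections; matched pairing aligns
identical bin indices, random pairing permutes one side (seeded) as a null.
Genes with zero variance in either vector are reported undefined and
excluded from the median and mean summaries; both summaries are reported
because both are in common use for different assay classes. Bins occupied
in only one section are dropped rather than zero-filled; zero-filling
would reward registrations that push points off the shared support.

**Count filtering.** The conventional pre-filter retains beads with total
UMI counts strictly above `minUmi` (default 50) and then genes detected in
strictly more than `minBeads` (default 5) retained beads, in that fixed
order. The boundary is exclusive: a bead with exactly 50 UMIs is removed.

**Tissue overlap.** The image is converted to grayscale, thresholded by
Otsu's method with the darker side as tissue (a `darkTissue = FALSE` flag
handles inverted polarity), and reduced to its largest connected component
with holes filled. This mask construction is an explicit reconstruction of
a step that has no canonical published definition; the threshold is kept in
the returned object. The overlap metric is the percentage of points whose
display coordinates fall on a tissue pixel, with out-of-bounds points
counted as non-overlapping and the identifiers of non-overlapping points
returned for flagging.

## The synthetic generator

`makeSection()` emulates the features the engine and its metrics need and
nothing more: an elliptical tissue rendered dark (0.25) on a bright (0.93)
background with mild Gaussian pixel noise (sd 0.015); cluster labels from
spatially coherent Gaussian blobs (centres inside a 0.45-shrunk ellipse,
blob sd 0.22 of the smaller radius); points rejection-sampled into a
0.9-shrunk ellipse so that every point lies on tissue; and Poisson counts
with log-rates `baseline + cluster effect + linear spatial gradient`
(baseline `N(log 3, 0.4)`, cluster effects `N(0, 0.6)`, gradient slopes
`N(0, 0.7)` per normalised axis). The gradient is what gives matched bins
their correlation advantage over randomly paired bins. Everything is
seeded and bit-reproducible.

`makeSerialPair()` maps section A's points through a known rigid transform
plus optional positional jitter and returns the exact map (including the
pivot used) for recovery tests. Its `countNoise` parameter controls
section B's counts: at 0, B carries A's counts verbatim — the degenerate
noise-free case in which matched correlation is exactly 1 under the
identity map; above 0, counts are re-drawn Poisson from A's per-location
rates multiplied by log-normal noise `exp(N(0, countNoise²))`. The
generator does *not* attempt realistic optics, bead chemistry, segmentation
error or library-size variation, so passing tests demonstrate the engine's
arithmetic and bookkeeping, not performance on real tissue.

## Numerical choices and test calibration

* All coordinates are double precision; geometric test comparisons use
  1e-9 absolute tolerance, coordinate file round trips 1e-12.
* `cospi`/`sinpi` keep cardinal rotations exact.
* Largest-remainder ties break by cluster order (deterministic).
* Half-open bins make edge assignment deterministic.
* Problem sizes in tests and the acceptance script (500-point oracle
  clouds, 10,000→1,000 replay, 100 serial-pair simulations of 300 points ×
  12 genes, 2,000 downsampling resamples) were chosen so the whole suite
  runs in seconds while every property is exercised at non-trivial size.
* The random-downsampling uniformity check compares per-point inclusion
  counts over 2,000 resamples against their Binomial(2000, N/T) law. With
  500 points, a handful of 3-sigma exceedances is the binomial expectation
  itself, so the test bounds the *number* of exceedances by the 99.9th
  percentile of Binomial(500, P(|Z|>3)) and additionally requires every
  z-value to stay below 5 — a calibrated version of "inclusion frequencies
  are binomial-consistent" that a literal all-within-3-sigma rule would
  fail most of the time by chance alone.

## A worked example

```{r example}
sec <- makeSection(fixtureSpec(nPoints = 300, nGenes = 10, seed = 7))
s <- newSession(sec$points, ScaleSpec(1, 1, 1), image = sec$image)
s <- flipData(rotateData(s, 20), "vertical")
s <- translateData(s, 12, -4)
rigidState(s)

s <- closeLinearPhase(s)
anchor <- ids(displayPoints(s))[1]
s <- applyDrag(cycleState(s, anchor), anchor, 5, 5, threshold = 200)

out <- tempfile()
paths <- writeRegistrationBundle(s, out)
basename(paths)

ov <- overlapPercent(replayFull(s), tissueMask(sessionImage(s)))
ov$percent
```

## Known limitations

* Only the rescale operation touches the image raster; rotations and flips
  are applied to the data, which suffices when the image is the reference
  frame (the usual workflow) but means the exported JPEG is not rotated.
* One anchor per drag event; simultaneous multi-point drags are not
  modelled.
* The elastic field is the piecewise-linear radial form only — no
  thin-plate or spline warps.
* No automatic registration or landmark detection; the engine executes and
  records decisions, it does not make them.
* The h5ad reader supports dense and CSR/CSC `X`, string or categorical
  obs columns, and `obsm/spatial`; exotic AnnData layouts (backed mode,
  nullable arrays) are out of scope.
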