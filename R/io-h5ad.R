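# AnnData on-disk (.h5ad) support via rhdf5. Note rhdf5 presents HDF5
# datasets with dimensions reversed relative to the C-order shape, so the
# (n_obs, n_var) X matrix arrives as genes x observations and the
# (n_obs, 2) obsm/spatial array arrives as 2 x n.

.readH5ad <- function(path, clusterKey = "cluster") {
  ls <- rhdf5::h5ls(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  entry <- function(group, name) any(ls$group == group & ls$name == name)
  full <- paste(ls$group, ls$name, sep = "/")
  if (!any(full %in% c("/obsm/spatial", "//obsm/spatial")) &&
      !entry("/obsm", "spatial"))
    stop("schema error: missing obsm/spatial coordinate array in ", path)
  sp <- rhdf5::h5read(path, "obsm/spatial")
  xy <- if (nrow(sp) == 2L) t(sp) else sp
  n <- nrow(xy)
  ids <- if (entry("/obs", "_index")) {
    as.character(rhdf5::h5read(path, "obs/_index"))
  } else {
    att <- rhdf5::h5readAttributes(path, "obs")
    if (!is.null(att[["_index"]]))
      as.character(rhdf5::h5read(path, paste0("obs/", att[["_index"]])))
    else as.character(seq_len(n))
  }
  ann <- NULL
  if (entry("/obs", clusterKey)) {
    raw <- rhdf5::h5read(path, paste0("obs/", clusterKey))
    ann <- if (is.list(raw)) {
      # categorical encoding: categories + 0-based codes
      codes <- as.integer(raw$codes)
      out <- rep(NA_character_, length(codes))
      out[codes >= 0L] <- as.character(raw$categories)[codes[codes >= 0L] + 1L]
      out
    } else {
      as.character(raw)
    }
  }
  counts <- NULL
  geneNames <- if (entry("/var", "_index"))
    as.character(rhdf5::h5read(path, "var/_index")) else NULL
  if (entry("/", "X") || any(ls$group == "/X")) {
    xIsGroup <- any(ls$group == "/X")
    if (!xIsGroup) {
      counts <- rhdf5::h5read(path, "X")   # genes x obs after reversal
    } else {
      att <- rhdf5::h5readAttributes(path, "X")
      shape <- as.integer(att$shape)       # (n_obs, n_var)
      dat <- as.numeric(rhdf5::h5read(path, "X/data"))
      ind <- as.integer(rhdf5::h5read(path, "X/indices"))
      ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
      nnzPer <- diff(ptr)
      if (identical(att[["encoding-type"]], "csr_matrix")) {
        obs <- rep(seq_len(shape[1]), nnzPer)
        m <- Matrix::sparseMatrix(i = ind + 1L, j = obs, x = dat,
                                  dims = c(shape[2], shape[1]))
      } else {
        var <- rep(seq_len(shape[2]), nnzPer)
        m <- Matrix::sparseMatrix(i = var, j = ind + 1L, x = dat,
                                  dims = c(shape[2], shape[1]))
      }
      counts <- as.matrix(m)
    }
    rownames(counts) <- geneNames %||% paste0("gene", seq_len(nrow(counts)))
    colnames(counts) <- ids
  }
  PointSet(xy[, 1], xy[, 2], ids = ids, annotation = ann, counts = counts)
}

#' Write a PointSet as an AnnData-style h5ad container
#'
#' Emits the conventional layout: dense `X` (observations by genes, present
#' only when the point set carries counts), `obs` with the observation index
#' and the annotation column, `var` with gene names, and the 2-column
#' spatial coordinate array in `obsm/spatial`. Files written here open
#' unchanged in AnnData readers.
#'
#' @param points a \linkS4class{PointSet}.
#' @param path output path (conventionally `.h5ad`).
#' @param clusterKey name for the annotation observation column.
#' @return The path, invisibly.
#' @export
writeH5ad <- function(points, path, clusterKey = "cluster") {
  stopifnot(is(points, "PointSet"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({
    try(rhdf5::H5Fclose(fid), silent = TRUE)
    rhdf5::h5closeAll()
  }, add = TRUE)
  wattr <- function(obj, name, val, scalar = TRUE)
    rhdf5::h5writeAttribute(val, obj, name, variableLengthString = TRUE,
                            asScalar = scalar)
  enc <- function(nm, type, ver) {
    o <- rhdf5::H5Oopen(fid, nm)
    wattr(o, "encoding-type", type)
    wattr(o, "encoding-version", ver)
    rhdf5::H5Oclose(o)
  }
  grp <- function(nm, type = "dict", ver = "0.1.0") {
    rhdf5::h5createGroup(fid, nm)
    g <- rhdf5::H5Gopen(fid, nm)
    wattr(g, "encoding-type", type)
    wattr(g, "encoding-version", ver)
    g
  }
  strArr <- function(vals, nm) {
    rhdf5::h5write(vals, fid, nm)
    enc(nm, "string-array", "0.2.0")
  }
  wattr(fid, "encoding-type", "anndata")
  wattr(fid, "encoding-version", "0.1.0")

  counts <- points@counts
  if (!is.null(counts)) {
    rhdf5::h5write(unname(as.matrix(counts)), fid, "X")  # h5py: (n_obs, n_var)
    enc("X", "array", "0.2.0")
  }
  genes <- if (is.null(counts)) character(0) else rownames(counts)

  g <- grp("obs", "dataframe", "0.2.0")
  wattr(g, "_index", "_index")
  haveAnn <- hasAnnotation(points)
  wattr(g, "column-order", if (haveAnn) clusterKey else "obs_name",
        scalar = FALSE)
  rhdf5::H5Gclose(g)
  strArr(points@ids, "obs/_index")
  if (haveAnn) {
    ann <- points@annotation
    ann[is.na(ann)] <- "NA"
    strArr(ann, paste0("obs/", clusterKey))
  } else {
    strArr(points@ids, "obs/obs_name")
  }

  g <- grp("var", "dataframe", "0.2.0")
  wattr(g, "_index", "_index")
  wattr(g, "column-order", "feature_name", scalar = FALSE)
  rhdf5::H5Gclose(g)
  varIndex <- if (length(genes)) genes else points@ids[0]
  if (!length(varIndex)) varIndex <- "none"
  strArr(varIndex, "var/_index")
  strArr(varIndex, "var/feature_name")

  g <- grp("obsm")
  rhdf5::H5Gclose(g)
  rhdf5::h5write(t(unname(points@coords)), fid, "obsm/spatial")
  enc("obsm/spatial", "array", "0.2.0")
  for (nm in c("uns", "obsp", "varm", "varp", "layers")) {
    g <- grp(nm)
    rhdf5::H5Gclose(g)
  }
  rhdf5::H5Fclose(fid)
  on.exit(rhdf5::h5closeAll(), add = FALSE)
  rhdf5::h5closeAll()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
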