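#' Read observation coordinates
#'
#' Reads a coordinate table from CSV, XLSX or an AnnData-style `.h5ad`
#' container into a \linkS4class{PointSet}. Tables must carry numeric `x`
#' and `y` columns; a categorical annotation column (default name
#' `cluster`) and an `id` column are optional (ids default to the row
#' index). For `.h5ad`, coordinates are read from the conventional
#' `obsm/spatial` array, the annotation from the observation column named
#' by `clusterKey`, and a count matrix (dense or CSR/CSC sparse `X`) is
#' retained when present.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"xlsx"` or `"h5ad"`.
#' @param clusterKey name of the annotation column (h5ad: obs column).
#' @return A \linkS4class{PointSet}.
#' @export
readCoordinates <- function(path, format = c("auto", "csv", "xlsx", "h5ad"),
                            clusterKey = "cluster") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", xlsx = "xlsx", h5ad = "h5ad",
      stop("format error: unsupported coordinate format '.", ext, "'"))
  }
  switch(format,
    csv = {
      df <- as.data.frame(data.table::fread(path, header = TRUE))
      .tableToPointSet(df, clusterKey, path)
    },
    xlsx = {
      df <- as.data.frame(readxl::read_excel(path))
      .tableToPointSet(df, clusterKey, path)
    },
    h5ad = .readH5ad(path, clusterKey)
  )
}

.tableToPointSet <- function(df, clusterKey, path) {
  for (col in c("x", "y"))
    if (!col %in% names(df))
      stop("schema error: missing column '", col, "' in ", path)
  xy <- lapply(c("x", "y"), function(col) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
    }
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("unparseable numeric in column '", col, "' at row ", bad[1],
           " of ", path)
    v
  })
  ann <- if (clusterKey %in% names(df)) {
    a <- as.character(df[[clusterKey]])
    a[!is.na(a) & a == ""] <- NA_character_
    a
  } else NULL
  ids <- if ("id" %in% names(df)) as.character(df[["id"]]) else NULL
  PointSet(xy[[1]], xy[[2]], ids = ids, annotation = ann)
}

#' Write observation coordinates to CSV
#'
#' Writes one row per observation with header `id,x,y,cluster`, keeping the
#' `cluster` column (with empty cells) even when no annotation exists.
#' Coordinates are written with 17 significant digits, so a write/read round
#' trip reproduces the doubles exactly.
#'
#' @param points a \linkS4class{PointSet}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCoordinates <- function(points, path) {
  stopifnot(is(points, "PointSet"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  ann <- points@annotation
  ann[is.na(ann)] <- ""
  df <- data.frame(id = points@ids,
                   x = sprintf("%.17g", points@coords[, 1]),
                   y = sprintf("%.17g", points@coords[, 2]),
                   cluster = ann,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = "auto")
  invisible(path)
}
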