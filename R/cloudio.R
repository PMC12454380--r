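# Labeled point-cloud text I/O. One point per line:
#   x y z Nx Ny Nz [label1 label2]
# label1: 0 = non-seedling, 1 = seedling; label2: 0 = background, 1..K = plant
# instance. Fields separated by runs of spaces/tabs or a single comma.

#' Read a labeled point-cloud text file
#'
#' Parses the annotation format used for segmented seedling clouds: one point
#' per line with 6 columns (x y z Nx Ny Nz) for unlabeled clouds or 8 columns
#' with the semantic and instance label appended. Separators may be runs of
#' whitespace or single commas. Non-numeric lines at the head of the file
#' (headers from point-cloud editors) are skipped with a message; a malformed
#' line in the body is an error naming the line number.
#'
#' @param path file to read.
#' @param hasLabels logical; `NA` (default) autodetects from the column count
#'   of the first data line.
#' @return A \linkS4class{LabeledCloud}, rows in file order.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0 0 0 0 0 1 1 1", "1 0 0 0 0 1 1 1", "5 5 0 0 0 1 0 0"), f)
#' readLabeledTxt(f)
#' @export
readLabeledTxt <- function(path, hasLabels = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(labeledCloud(matrix(numeric(0), 0, 3)))

  parseLine <- function(s) {
    s <- gsub(",", " ", s, fixed = TRUE)
    suppressWarnings(as.numeric(strsplit(trimws(s), "[ \t]+")[[1]]))
  }
  # skip an initial run of non-numeric (header) lines
  skip <- 0L
  repeat {
    if (skip >= length(lines)) break
    v <- parseLine(lines[skip + 1L])
    if (!anyNA(v) && length(v) %in% c(6L, 8L)) break
    skip <- skip + 1L
  }
  if (skip > 0L) {
    message("readLabeledTxt: skipped ", skip, " non-numeric header line(s)")
    lines <- lines[-seq_len(skip)]
  }
  if (!length(lines)) return(labeledCloud(matrix(numeric(0), 0, 3)))

  first <- parseLine(lines[1L])
  ncolExp <- length(first)
  if (!ncolExp %in% c(6L, 8L))
    stop("line ", skip + 1L, ": expected 6 or 8 fields, found ", ncolExp)
  if (!is.na(hasLabels)) {
    want <- if (isTRUE(hasLabels)) 8L else 6L
    if (ncolExp != want)
      stop("file has ", ncolExp, " columns but hasLabels = ", hasLabels)
  }

  txt <- gsub(",", " ", lines, fixed = TRUE)
  m <- tryCatch(
    suppressWarnings(as.matrix(
      data.table::fread(text = txt, header = FALSE, sep = " ",
                        colClasses = "numeric", fill = FALSE))),
    error = function(e) NULL)
  if (is.null(m) || !is.numeric(m) || ncol(m) != ncolExp || anyNA(m)) {
    # locate the offending line for a precise error
    for (i in seq_along(lines)) {
      v <- parseLine(lines[i])
      if (length(v) != ncolExp)
        stop("line ", skip + i, ": expected ", ncolExp, " fields, found ",
             length(v))
      if (anyNA(v))
        stop("line ", skip + i, ": non-numeric field")
    }
    stop("failed to parse ", path)
  }
  sem <- if (ncolExp == 8L) as.integer(m[, 7L])
  inst <- if (ncolExp == 8L) as.integer(m[, 8L])
  if (ncolExp == 8L) {
    if (any(m[, 7L] != sem) || any(m[, 8L] != inst))
      stop("label columns must be integers")
  }
  labeledCloud(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], sem, inst)
}

#' Write a labeled point-cloud text file
#'
#' One line per point, 8 columns when both label channels are present,
#' otherwise 6. Numeric fields are written with 6 significant digits and
#' single-space separators, so write/read/write is byte-stable.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLabeledTxt <- function(cloud, path) {
  stopifnot(is(cloud, "LabeledCloud"))
  validObject(cloud)
  num <- cbind(cloud@points, cloud@normals)
  fmt <- trimws(apply(num, 2, formatC, digits = 6, format = "g"))
  if (nPoints(cloud) == 1L) fmt <- matrix(fmt, nrow = 1L)
  cols <- fmt
  if (hasLabels(cloud) && length(cloud@instance))
    cols <- cbind(fmt, as.character(cloud@semantic), as.character(cloud@instance))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(apply(cols, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Export a cloud as colored ASCII PLY
#'
#' Writes an ASCII PLY with per-vertex uchar RGB for visual inspection of
#' segmentations: distinct instances (or the seedling class) get distinct
#' saturated colors, background/noise points are gray.
#'
#' @param cloud a \linkS4class{LabeledCloud}.
#' @param colorBy `"semantic"` or `"instance"`; the channel must be present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportPLY <- function(cloud, colorBy = c("semantic", "instance"), path) {
  colorBy <- match.arg(colorBy)
  lab <- switch(colorBy, semantic = cloud@semantic, instance = cloud@instance)
  if (!length(lab))
    stop("requested label channel '", colorBy, "' is not present")
  n <- nPoints(cloud)
  ids <- sort(setdiff(unique(lab), 0L))
  pal <- if (length(ids))
    t(grDevices::col2rgb(grDevices::hcl.colors(max(2L, length(ids)), "Dark 3")))
  col <- matrix(128L, n, 3)  # gray background
  for (i in seq_along(ids)) {
    sel <- lab == ids[i]
    col[sel, ] <- matrix(pal[i, ], sum(sel), 3, byrow = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header"), con)
  body <- cbind(trimws(apply(cloud@points, 2, formatC, digits = 6, format = "g")),
                col[, 1], col[, 2], col[, 3])
  if (n == 1L) body <- matrix(body, nrow = 1L)
  if (n > 0L) writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param vertices n x 3 matrix of vertex coordinates.
#' @param triangles ntri x 3 matrix of 1-based vertex indices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMeshPLY <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (nrow(vertices))
    writeLines(apply(vertices, 1, function(r)
      paste(formatC(r, digits = 6, format = "g"), collapse = " ")), con)
  if (nrow(triangles))
    writeLines(apply(triangles - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
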