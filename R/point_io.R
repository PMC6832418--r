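#' Construct a point cloud
#'
#' A `point_cloud` is the package's core container: an N x 3 numeric matrix
#' of coordinates in metres (columns X, Y, Z; Z is up) with optional integer
#' class labels per point and an optional mapping from label ids to class
#' names.
#'
#' @param coords numeric matrix or data frame with 3 columns (X, Y, Z),
#'   metres.
#' @param labels optional integer vector of non-negative class ids, one per
#'   point.
#' @param class_names optional named character vector mapping label ids
#'   (names) to class names (values).
#' @return an object of class `point_cloud` with elements `coords`,
#'   `labels`, `class_names`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, labels = NULL, class_names = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have exactly 3 columns (X, Y, Z)")
  if (nrow(coords) < 1L)
    stop("a point cloud needs at least one point")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  colnames(coords) <- c("X", "Y", "Z")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels must have one entry per point")
    if (anyNA(labels) || any(labels < 0L))
      stop("labels must be non-negative integers")
    if (!is.null(class_names)) {
      missing_ids <- setdiff(unique(labels), as.integer(names(class_names)))
      if (length(missing_ids))
        stop("label ids without a class name: ",
             paste(missing_ids, collapse = ", "))
    }
  }
  structure(list(coords = coords, labels = labels,
                 class_names = class_names),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$coords),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels)))))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    nm <- if (is.null(x$class_names)) names(tab) else
      x$class_names[names(tab)]
    cat("  ", paste(sprintf("%s=%d", nm, tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' Read a plain-text XYZ point cloud
#'
#' One point per line, whitespace- or comma-separated, optionally followed
#' by an integer class label. Lines starting with `#` are skipped. Point
#' order is preserved.
#'
#' @param path file path.
#' @param has_label if `TRUE`, a fourth column of integer labels is
#'   expected.
#' @return a [point_cloud].
#' @export
read_xyz <- function(path, has_label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty point file: ", path)
  need <- if (has_label) 4L else 3L
  toks <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  nf <- lengths(toks)
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("line %d of %s: expected at least %d fields, found %d",
                 idx[bad[1]], path, need, nf[bad[1]]))
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[seq_len(need)]), numeric(need)))
  nonnum <- which(colSums(is.na(vals)) > 0)
  if (length(nonnum))
    stop(sprintf("line %d of %s: non-numeric field", idx[nonnum[1]], path))
  vals <- t(vals)
  point_cloud(vals[, 1:3, drop = FALSE],
              labels = if (has_label) as.integer(vals[, 4]) else NULL)
}

#' Write a plain-text XYZ point cloud
#'
#' @param cloud a [point_cloud].
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, digits = 6) {
  m <- format(round(cloud$coords, digits), trim = TRUE, scientific = FALSE)
  rows <- paste(m[, 1], m[, 2], m[, 3])
  if (!is.null(cloud$labels)) rows <- paste(rows, cloud$labels)
  writeLines(rows, path)
  invisible(path)
}

#' Read a PLY point cloud
#'
#' Accepts ascii and binary-little-endian PLY files with a vertex element
#' carrying float/double `x`, `y`, `z` properties and, optionally, an
#' integer `label` property.
#'
#' @param path file path.
#' @return a [point_cloud].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NA_integer_
  props <- character(); ptypes <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("PLY header not terminated")
    tk <- strsplit(trimws(line), "\\s+")[[1]]
    if (tk[1] == "format") fmt <- tk[2]
    else if (tk[1] == "element") {
      in_vertex <- tk[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tk[3])
    } else if (tk[1] == "property" && in_vertex) {
      props <- c(props, tk[3]); ptypes <- c(ptypes, tk[2])
    } else if (tk[1] == "end_header") break
  }
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY vertex element lacks x/y/z properties")
  if (is.na(nvert) || nvert < 1) stop("PLY file has no vertices")
  np <- length(props)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (identical(fmt, "ascii")) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))][seq_len(nvert)]
    vals <- t(vapply(strsplit(trimws(txt), "\\s+"),
                     function(t) as.numeric(t[seq_len(np)]), numeric(np)))
  } else if (identical(fmt, "binary_little_endian")) {
    vals <- matrix(NA_real_, nvert, np)
    int_like <- ptypes %in% c("char", "uchar", "int8", "uint8", "short",
                              "ushort", "int16", "int32", "uint16",
                              "uint32", "int", "uint")
    for (i in seq_len(nvert)) {
      for (j in seq_len(np)) {
        sz <- sizes[[ptypes[j]]]
        vals[i, j] <- if (int_like[j])
          readBin(con, "integer", 1, size = sz, endian = "little")
        else readBin(con, "double", 1, size = sz, endian = "little")
      }
    }
  } else stop("unsupported PLY format: ", fmt)
  xyz <- vals[, match(c("x", "y", "z"), props), drop = FALSE]
  labels <- if ("label" %in% props)
    as.integer(vals[, match("label", props)]) else NULL
  point_cloud(xyz, labels = labels)
}

#' Write a PLY point cloud
#'
#' @param cloud a [point_cloud].
#' @param path output path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path,
                      format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  has_label <- !is.null(cloud$labels)
  hdr <- c("ply", paste("format", format, "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (has_label) "property int label",
           "end_header")
  if (format == "ascii") {
    m <- format(cloud$coords, trim = TRUE, scientific = FALSE, digits = 9)
    rows <- paste(m[, 1], m[, 2], m[, 3])
    if (has_label) rows <- paste(rows, cloud$labels)
    writeLines(c(hdr, rows), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(n)) {
      writeBin(as.numeric(cloud$coords[i, ]), con, size = 4,
               endian = "little")
      if (has_label)
        writeBin(as.integer(cloud$labels[i]), con, size = 4,
                 endian = "little")
    }
  }
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' Columns are `X,Y,Z[,label],L1,PL1,SPH1,HOR1,PERCZ1,L2,...` so the file
#' is self-describing: the trailing digit of each feature name is the
#' 1-based scale index (1 = smallest diameter).
#'
#' @param features a `feature_matrix` from [extract_features()].
#' @param cloud the [point_cloud] the features were computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, cloud, path) {
  df <- data.frame(cloud$coords, check.names = FALSE)
  if (!is.null(cloud$labels)) df$label <- cloud$labels
  df <- cbind(df, as.data.frame(unclass(features)[seq_len(nrow(features)), ,
                                                  drop = FALSE]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path file path.
#' @return list with `features` (numeric matrix of the feature columns),
#'   `coords`, and `labels` (`NULL` when the file has no label column).
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- intersect(c("X", "Y", "Z", "label"), names(df))
  fcols <- setdiff(names(df), meta)
  list(features = as.matrix(df[fcols]),
       coords = as.matrix(df[c("X", "Y", "Z")]),
       labels = if ("label" %in% meta) as.integer(df$label) else NULL)
}
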