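#' Default scale ladder
#'
#' Six sphere diameters, 5 cm to 50 cm, spanning the object sizes the
#' method discriminates (thin branches and poles at the small end, trunk
#' curvature and facade patches at the large end).
#'
#' @return numeric vector of diameters in metres.
#' @export
default_scales <- function() c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50)

#' Validate a scale ladder
#'
#' @param diameters numeric vector of sphere diameters, metres.
#' @return the validated, strictly increasing ladder.
#' @export
scale_ladder <- function(diameters = default_scales()) {
  diameters <- as.numeric(diameters)
  if (!length(diameters) || any(!is.finite(diameters)) ||
      any(diameters <= 0))
    stop("scale diameters must be positive finite numbers")
  if (any(diff(diameters) <= 0))
    stop("scale diameters must be strictly increasing")
  diameters
}

#' Canonical feature column names for a ladder
#' @param diameters scale ladder.
#' @return character vector `L1,PL1,SPH1,HOR1,PERCZ1,L2,...`.
#' @export
feature_names <- function(diameters) {
  as.vector(vapply(seq_along(diameters), function(s)
    paste0(c("L", "PL", "SPH", "HOR", "PERCZ"), s), character(5)))
}

#' Spherical neighborhood of a point
#'
#' All points of the cloud (the query point included) whose Euclidean
#' distance to the query point is at most `diameter / 2`.
#'
#' @param cloud a [point_cloud].
#' @param index 1-based point index.
#' @param diameter sphere diameter, metres.
#' @return sorted integer vector of point indices.
#' @export
neighborhood <- function(cloud, index, diameter) {
  stopifnot(diameter > 0)
  p <- cloud$coords[index, ]
  d2 <- (cloud$coords[, 1] - p[1])^2 + (cloud$coords[, 2] - p[2])^2 +
    (cloud$coords[, 3] - p[3])^2
  which(d2 <= (diameter / 2)^2)
}

#' Eigendecomposition of a neighborhood's covariance matrix
#'
#' The covariance is taken about the neighborhood mean with 1/M
#' normalization and eigendecomposed; eigenvalues are clamped at zero and
#' returned in descending order with matching eigenvectors. For fewer than
#' three points (or any rank-deficient set) the trailing eigenvalues are
#' exactly zero.
#'
#' @param points M x 3 coordinate matrix.
#' @return list with `eigvals` (length 3, descending, m^2), `eigvecs`
#'   (3 x 3 matrix, columns v1, v2, v3 matching the eigenvalues) and
#'   `n_pts`.
#' @export
spectrum <- function(points) {
  points <- rbind(points)  # keeps a single point as a 1 x 3 matrix
  m <- nrow(points)
  stopifnot(m >= 1)
  ctr <- sweep(points, 2, colMeans(points))
  C <- crossprod(ctr) / m
  e <- eigen(C, symmetric = TRUE)  # descending
  list(eigvals = pmax(e$values, 0), eigvecs = e$vectors, n_pts = m)
}

#' Shape features from a neighborhood spectrum
#'
#' Linearity `(l1 - l2) / l1`, planarity `(l2 - l3) / l1`, sphericity
#' `l3 / l1`, horizontality `acos(|v3 . z|)` in degrees (v3 is the
#' smallest-eigenvalue eigenvector, the surface normal of a planar patch),
#' and the supplied vertical extent. A degenerate spectrum (l1 = 0) yields
#' zeros for the four shape features.
#'
#' @param spec a spectrum from [spectrum()].
#' @param z_span vertical extent feature (metres), passed through.
#' @return named numeric vector `c(L, PL, SPH, HOR, PERCZ)`.
#' @export
point_features <- function(spec, z_span = 0) {
  l <- spec$eigvals
  if (l[1] > 0) {
    L <- (l[1] - l[2]) / l[1]
    PL <- (l[2] - l[3]) / l[1]
    SPH <- l[3] / l[1]
    HOR <- acos(min(abs(spec$eigvecs[3, 3]), 1)) * 180 / pi
  } else {
    L <- PL <- SPH <- HOR <- 0
  }
  c(L = L, PL = PL, SPH = SPH, HOR = HOR, PERCZ = z_span)
}

#' Robust vertical extent in a cylindrical column
#'
#' The 5th-to-95th percentile span of the Z coordinates of all points whose
#' horizontal (XY) distance to the query point is at most `diameter / 2`;
#' the column is unbounded vertically. Percentiles use linear interpolation
#' between order statistics (R's default type-7 rule).
#'
#' @inheritParams neighborhood
#' @return non-negative span in metres (0 for a singleton column).
#' @export
z_range <- function(cloud, index, diameter) {
  stopifnot(diameter > 0)
  p <- cloud$coords[index, ]
  d2 <- (cloud$coords[, 1] - p[1])^2 + (cloud$coords[, 2] - p[2])^2
  z <- cloud$coords[d2 <= (diameter / 2)^2, 3]
  unname(diff(quantile(z, c(0.05, 0.95), type = 7)))
}

#' Multiscale feature extraction
#'
#' Computes the five per-point features at every scale of the ladder and
#' assigns them to the sphere's center point. Neighborhoods with fewer than
#' `min_neighbors` points fall back to zero shape features (the vertical
#' extent is still computed), so isolated noise points stay finite and
#' recognizable.
#'
#' @param cloud a [point_cloud].
#' @param scales scale ladder (sphere diameters, metres); validated with
#'   [scale_ladder()].
#' @param min_neighbors minimum sphere occupancy for the covariance to be
#'   eigendecomposed (default 3, the smallest set that can span 3D).
#' @return a `feature_matrix`: numeric matrix N x (5 * S) with columns
#'   named per [feature_names()], carrying the ladder as attribute
#'   `scales`.
#' @examples
#' pc <- point_cloud(matrix(runif(300), ncol = 3))
#' fm <- extract_features(pc, scales = c(0.2, 0.5))
#' dim(fm)
#' @export
extract_features <- function(cloud, scales = default_scales(),
                             min_neighbors = 3L) {
  scales <- scale_ladder(scales)
  if (n_points(cloud) < 1L) stop("empty cloud")
  out <- .ms_extract_cpp(cloud$coords, scales, as.integer(min_neighbors))
  colnames(out) <- feature_names(scales)
  structure(out, scales = scales, class = c("feature_matrix", "matrix"))
}
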