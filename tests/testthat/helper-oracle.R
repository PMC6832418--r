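# shared fixtures and the slow reference implementation used to
# cross-check the fast extraction path

rand_cloud <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, 0, scale), ncol = 3))
}

# O(N^2) reference: per-point features composed from the elementary
# operations (all-pairs neighbor filter, direct covariance, percentiles)
brute_force_features <- function(cloud, scales, min_neighbors = 3) {
  n <- n_points(cloud)
  out <- matrix(0, n, 5 * length(scales))
  colnames(out) <- feature_names(scales)
  for (s in seq_along(scales)) {
    for (i in seq_len(n)) {
      nb <- neighborhood(cloud, i, scales[s])
      zr <- z_range(cloud, i, scales[s])
      v <- if (length(nb) >= min_neighbors)
        point_features(spectrum(cloud$coords[nb, , drop = FALSE]), zr)
      else c(0, 0, 0, 0, zr)
      out[i, (5 * (s - 1) + 1):(5 * s)] <- v
    }
  }
  out
}

# dense regular grid plane through `center`, spanned by unit vectors u, v
grid_plane <- function(center, u, v, half_extent = 1, step = 0.01) {
  g <- expand.grid(a = seq(-half_extent, half_extent, by = step),
                   b = seq(-half_extent, half_extent, by = step))
  point_cloud(cbind(center[1] + g$a * u[1] + g$b * v[1],
                    center[2] + g$a * u[2] + g$b * v[2],
                    center[3] + g$a * u[3] + g$b * v[3]))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# hand computation of every metric straight from label pairs
hand_metrics <- function(ref, pred, classes) {
  n <- length(ref)
  per <- lapply(classes, function(c) {
    tp <- sum(ref == c & pred == c)
    fp <- sum(ref != c & pred == c)
    fn <- sum(ref == c & pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  })
  po <- mean(ref == pred)
  pe <- sum(vapply(classes, function(c)
    mean(ref == c) * mean(pred == c), 0))
  list(per_class = do.call(rbind, per), accuracy = po,
       kappa = if (pe >= 1) 0 else (po - pe) / (1 - pe))
}
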