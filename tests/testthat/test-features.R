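test_that("spherical neighborhood matches the all-pairs distance filter", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_equal(neighborhood(pc, 1, 0.5), c(1L, 2L))
  expect_equal(neighborhood(pc, 1, 0.3), 1L)

  pc <- rand_cloud(500, seed = 2)
  d <- as.matrix(dist(pc$coords))
  for (diam in c(0.1, 0.25)) {
    fast <- .radius_neighbors_cpp(pc$coords, diam / 2, FALSE)
    for (i in c(1, 57, 250, 500)) {
      expect_identical(fast[[i]], as.integer(which(d[i, ] <= diam / 2)))
      expect_identical(neighborhood(pc, i, diam), as.integer(which(d[i, ] <= diam / 2)))
    }
  }
})

test_that("neighborhood size is non-decreasing in the scale diameter", {
  pc <- rand_cloud(300, seed = 4)
  sizes <- vapply(c(0.1, 0.2, 0.4), function(d)
    lengths(.radius_neighbors_cpp(pc$coords, d / 2, FALSE)),
    integer(300))
  expect_true(all(diff(t(sizes)) >= 0))
})

test_that("covariance spectrum handles canonical degenerate sets", {
  s <- spectrum(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(s$eigvals[2:3], c(0, 0))
  expect_gt(s$eigvals[1], 0)

  # unit 2x2 planar grid: variances 0.25, 0.25, 0 about the mean
  s <- spectrum(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_equal(s$eigvals, c(0.25, 0.25, 0))

  expect_equal(spectrum(matrix(c(3, 1, 2), 1))$eigvals, c(0, 0, 0))
})

test_that("spectrum eigenvalues are rotation invariant and eigvecs orthonormal", {
  set.seed(8)
  pts <- matrix(rnorm(60), ncol = 3) %*% diag(c(3, 1, 0.2))
  s0 <- spectrum(pts)
  expect_equal(crossprod(s0$eigvecs), diag(3), tolerance = 1e-9)
  for (k in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(spectrum(pts %*% q)$eigvals, s0$eigvals,
                 tolerance = 1e-9)
  }
})

test_that("shape features hit the 1D / 2D / 3D limits", {
  lin <- point_features(list(eigvals = c(2, 0, 0),
                             eigvecs = diag(3)), 0)
  expect_equal(unname(lin[1:3]), c(1, 0, 0))

  iso <- point_features(list(eigvals = c(1, 1, 1), eigvecs = diag(3)), 0)
  expect_equal(unname(iso[1:3]), c(0, 0, 1))

  # degenerate spectrum falls back to zeros but keeps the z-span
  deg <- point_features(list(eigvals = c(0, 0, 0), eigvecs = diag(3)), 0.4)
  expect_equal(unname(deg), c(0, 0, 0, 0, 0.4))
})

test_that("horizontality is 0 deg for horizontal and 90 deg for vertical planes", {
  horiz <- grid_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0.6, 0.02)
  i <- which.min(rowSums(horiz$coords^2))
  fm <- extract_features(horiz, scales = 0.5)
  expect_lt(abs(fm[i, "HOR1"]), 2)
  expect_gt(fm[i, "PL1"], 0.95)

  vert <- grid_plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), 0.6, 0.02)
  i <- which.min(rowSums(vert$coords^2))
  fm <- extract_features(vert, scales = 0.5)
  expect_gt(fm[i, "HOR1"], 88)
  # sign flips of the normal cannot change the angle
  s <- spectrum(vert$coords[neighborhood(vert, i, 0.5), ])
  s$eigvecs[, 3] <- -s$eigvecs[, 3]
  expect_equal(unname(point_features(s, 0)["HOR"]),
               unname(fm[i, "HOR1"]), tolerance = 1e-6)
})

test_that("z-range uses 5th-95th percentiles over an unbounded vertical column", {
  col <- point_cloud(cbind(0, 0, seq(0, 1, by = 0.01)))
  expect_equal(z_range(col, 1, 0.2), 0.90)
  expect_equal(z_range(point_cloud(matrix(c(0, 0, 5), 1)), 1, 0.2), 0)

  # one gross outlier moves the robust range by far less than its size
  out <- point_cloud(rbind(col$coords, c(0, 0, 100)))
  expect_lt(abs(z_range(out, 1, 0.2) - 0.90), 0.2)

  # points beyond the XY radius are excluded no matter their height
  far <- point_cloud(rbind(col$coords, c(5, 0, 0.5)))
  expect_equal(z_range(far, 1, 0.2), 0.90)
})

test_that("extract matches the brute-force reference cell for cell", {
  pc <- rand_cloud(500, seed = 10)
  scales <- c(0.2, 0.5)
  fm <- extract_features(pc, scales)
  expect_equal(unclass(fm)[, ], brute_force_features(pc, scales),
               tolerance = 1e-9)
  expect_equal(colnames(fm),
               c("L1", "PL1", "SPH1", "HOR1", "PERCZ1",
                 "L2", "PL2", "SPH2", "HOR2", "PERCZ2"))
})

test_that("a single-point cloud yields the degenerate zero features", {
  fm <- extract_features(point_cloud(matrix(c(1, 2, 3), 1)),
                         scales = c(0.1, 0.5))
  expect_equal(unname(unclass(fm)[1, ]), rep(0, 10))
})

test_that("L + PL + SPH is exactly 1 whenever the spectrum is non-degenerate", {
  pc <- rand_cloud(400, seed = 12)
  fm <- extract_features(pc, scales = c(0.3, 0.6))
  for (s in 1:2) {
    blk <- fm[, (5 * s - 4):(5 * s - 2)]
    nz <- rowSums(blk) > 0
    expect_true(any(nz))
    expect_equal(rowSums(blk[nz, ]), rep(1, sum(nz)), tolerance = 1e-12)
  }
})

test_that("features are invariant to z-rotation plus translation", {
  pc <- rand_cloud(400, seed = 13)
  fm <- extract_features(pc, scales = c(0.3, 0.6))
  moved <- point_cloud(sweep(pc$coords %*% rot_z(1.1), 2,
                             c(10, -4, 2.5), `+`))
  fm2 <- extract_features(moved, scales = c(0.3, 0.6))
  expect_equal(unclass(fm2)[, ], unclass(fm)[, ], tolerance = 1e-6)
})

test_that("scale ladders are validated", {
  expect_error(scale_ladder(c(0.2, 0.1)), "increasing")
  expect_error(scale_ladder(numeric()), "positive")
  expect_error(scale_ladder(c(-1, 2)), "positive")
  expect_equal(scale_ladder(0.3), 0.3)
  expect_length(default_scales(), 6)
})
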