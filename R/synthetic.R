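#' Geometric primitive samplers
#'
#' Building blocks for synthetic labeled scenes. Each sampler draws `n`
#' points uniformly on (or in) the primitive, perturbs them with isotropic
#' Gaussian noise of standard deviation `noise_sd`, and labels them with
#' `label`. They realize the three local geometries the eigenfeatures are
#' designed to tell apart: 1D (segments, thin poles), 2D (planes, cylinder
#' walls at small scales) and 3D (volumetric blobs).
#'
#' @param center,start,end,base 3D positions, metres.
#' @param u,v orthogonal unit vectors spanning the plane.
#' @param extent_u,extent_v plane side lengths, metres.
#' @param radius,height cylinder / ball dimensions, metres.
#' @param n number of points (>= 1).
#' @param noise_sd isotropic Gaussian noise, metres.
#' @param label integer class id.
#' @return a labeled [point_cloud].
#' @name primitives
NULL

check_prim <- function(n, ...) {
  dims <- c(...)
  if (n < 1) stop("n must be >= 1")
  if (length(dims) && any(dims <= 0)) stop("primitive dimensions must be positive")
}

add_noise <- function(xyz, noise_sd) {
  if (noise_sd > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sd), ncol = 3)
  xyz
}

#' @rdname primitives
#' @export
sample_plane <- function(center, u, v, extent_u, extent_v, n,
                         noise_sd = 0, label = 0L) {
  check_prim(n, extent_u, extent_v)
  a <- runif(n, -extent_u / 2, extent_u / 2)
  b <- runif(n, -extent_v / 2, extent_v / 2)
  xyz <- cbind(center[1] + a * u[1] + b * v[1],
               center[2] + a * u[2] + b * v[2],
               center[3] + a * u[3] + b * v[3])
  point_cloud(add_noise(xyz, noise_sd), labels = rep(label, n))
}

#' @rdname primitives
#' @export
sample_segment <- function(start, end, n, noise_sd = 0, label = 0L) {
  len <- sqrt(sum((end - start)^2))
  check_prim(n, len)
  t <- runif(n)
  xyz <- cbind(start[1] + t * (end[1] - start[1]),
               start[2] + t * (end[2] - start[2]),
               start[3] + t * (end[3] - start[3]))
  point_cloud(add_noise(xyz, noise_sd), labels = rep(label, n))
}

#' @rdname primitives
#' @export
sample_cylinder <- function(base, radius, height, n, noise_sd = 0,
                            label = 0L) {
  check_prim(n, radius, height)
  theta <- runif(n, 0, 2 * pi)
  z <- runif(n, 0, height)
  xyz <- cbind(base[1] + radius * cos(theta),
               base[2] + radius * sin(theta),
               base[3] + z)
  point_cloud(add_noise(xyz, noise_sd), labels = rep(label, n))
}

#' @rdname primitives
#' @export
sample_pole <- function(base, height, n, radius = 0.05, noise_sd = 0,
                        label = 0L) {
  sample_cylinder(base, radius, height, n, noise_sd, label)
}

#' @rdname primitives
#' @export
sample_blob <- function(center, radius, n, noise_sd = 0, label = 0L) {
  check_prim(n, radius)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * runif(n)^(1 / 3)  # uniform in the ball
  xyz <- sweep(dir * r, 2, center, `+`)
  point_cloud(add_noise(xyz, noise_sd), labels = rep(label, n))
}

#' @rdname primitives
#' @param lx,ly,lz box side lengths, metres.
#' @export
sample_box <- function(base, lx, ly, lz, n, noise_sd = 0, label = 0L) {
  check_prim(n, lx, ly, lz)
  # sample the 5 exposed faces (no bottom) proportionally to area
  areas <- c(top = lx * ly, front = lx * lz, back = lx * lz,
             left = ly * lz, right = ly * lz)
  face <- sample(names(areas), n, replace = TRUE, prob = areas)
  a <- runif(n); b <- runif(n)
  xyz <- matrix(0, n, 3)
  xyz[face == "top", ] <- cbind(a[face == "top"] * lx,
                                b[face == "top"] * ly,
                                lz)
  xyz[face == "front", ] <- cbind(a[face == "front"] * lx, 0,
                                  b[face == "front"] * lz)
  xyz[face == "back", ] <- cbind(a[face == "back"] * lx, ly,
                                 b[face == "back"] * lz)
  xyz[face == "left", ] <- cbind(0, a[face == "left"] * ly,
                                 b[face == "left"] * lz)
  xyz[face == "right", ] <- cbind(lx, a[face == "right"] * ly,
                                  b[face == "right"] * lz)
  xyz <- sweep(xyz, 2, base, `+`)
  point_cloud(add_noise(xyz, noise_sd), labels = rep(label, n))
}

bind_clouds <- function(clouds, class_names = NULL) {
  point_cloud(do.call(rbind, lapply(clouds, `[[`, "coords")),
              labels = unlist(lapply(clouds, `[[`, "labels")),
              class_names = class_names)
}

#' Scene recipes
#'
#' Parameter bundles for the two synthetic scenarios. The forest plot has
#' three classes (rough ground, vertical trunk cylinders, thin oblique
#' branch segments); the street scene has five (ground, planar building
#' facades, thin vertical poles, volumetric vegetation blobs, car-sized
#' boxes). Default point allocations total roughly 50k points; noise is
#' 1 cm, approximating a low-cost mobile scanner. Generation is fully
#' deterministic given `seed`.
#'
#' @param extent scene footprint `c(x, y)` in metres; the train/test split
#'   cuts the footprint into disjoint halves along X.
#' @param n_ground,n_trunk,n_branch,n_building,n_pole,n_vegetation,n_car
#'   per-class point allocations.
#' @param n_trees trees in the forest plot (split over the two halves).
#' @param trunk_height trunk height, metres.
#' @param branches_per_tree branch segments per tree.
#' @param noise_sd isotropic point noise, metres.
#' @param seed integer seed.
#' @return a `scene_recipe` list.
#' @export
forest_recipe <- function(extent = c(20, 10), n_ground = 20000,
                          n_trunk = 15000, n_branch = 15000,
                          n_trees = 10, trunk_height = 6,
                          branches_per_tree = 8, noise_sd = 0.01,
                          seed = 1L) {
  stopifnot(all(extent > 0), n_ground > 0, n_trunk > 0, n_branch > 0,
            n_trees >= 2, noise_sd >= 0)
  structure(list(scenario = "forest", extent = extent,
                 n_ground = n_ground, n_trunk = n_trunk,
                 n_branch = n_branch, n_trees = n_trees,
                 trunk_height = trunk_height,
                 branches_per_tree = branches_per_tree,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 class_names = c("1" = "ground", "2" = "trunk",
                                 "3" = "branch")),
            class = "scene_recipe")
}

#' @rdname forest_recipe
#' @export
urban_recipe <- function(extent = c(40, 20), n_ground = 18000,
                         n_building = 12000, n_pole = 6000,
                         n_vegetation = 8000, n_car = 6000,
                         noise_sd = 0.01, seed = 1L) {
  stopifnot(all(extent > 0), n_ground > 0, n_building > 0, n_pole > 0,
            n_vegetation > 0, n_car > 0, noise_sd >= 0)
  structure(list(scenario = "urban", extent = extent,
                 n_ground = n_ground, n_building = n_building,
                 n_pole = n_pole, n_vegetation = n_vegetation,
                 n_car = n_car, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 class_names = c("1" = "ground", "2" = "building",
                                 "3" = "pole", "4" = "vegetation",
                                 "5" = "car")),
            class = "scene_recipe")
}

# gentle terrain undulation so the ground is rough but still near-planar
# at neighborhood scales
terrain_z <- function(x, y, extent) {
  0.1 * sin(2 * pi * 3 * x / extent[1]) * sin(2 * pi * 2 * y / extent[2])
}

# positions spread over both scene halves with a margin from the edges
# and from the split line
spread_positions <- function(k, extent, margin = 1.2) {
  half <- extent[1] / 2
  kl <- ceiling(k / 2); kr <- k - kl
  rbind(cbind(runif(kl, margin, half - margin),
              runif(kl, margin, extent[2] - margin)),
        cbind(runif(kr, half + margin, extent[1] - margin),
              runif(kr, margin, extent[2] - margin)))
}

split_counts <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Build a labeled synthetic scene
#'
#' Assembles the primitives of a [forest_recipe()] or [urban_recipe()]
#' into one labeled cloud. Objects are placed in both halves of the
#' footprint so every class is present on each side of the spatial
#' train/test split; the returned cloud carries a `region` element
#' (`"train"` for X below the midline, `"test"` above).
#'
#' @param recipe a `scene_recipe`.
#' @return a labeled [point_cloud] with an extra `region` character
#'   vector.
#' @export
build_scene <- function(recipe) {
  if (!inherits(recipe, "scene_recipe")) stop("not a scene_recipe")
  set.seed(recipe$seed)
  ex <- recipe$extent
  ns <- recipe$noise_sd
  clouds <- if (recipe$scenario == "forest")
    build_forest(recipe, ex, ns) else build_urban(recipe, ex, ns)
  cloud <- bind_clouds(clouds, class_names = recipe$class_names)
  cloud$region <- ifelse(cloud$coords[, 1] < ex[1] / 2, "train", "test")
  cloud
}

build_forest <- function(r, ex, ns) {
  clouds <- list()
  # rough ground
  gx <- runif(r$n_ground, 0, ex[1]); gy <- runif(r$n_ground, 0, ex[2])
  gz <- terrain_z(gx, gy, ex)
  clouds$ground <- point_cloud(add_noise(cbind(gx, gy, gz), ns),
                               labels = rep(1L, r$n_ground))
  # trunks: vertical cylinders rooted on the terrain
  pos <- spread_positions(r$n_trees, ex)
  radii <- runif(r$n_trees, 0.10, 0.30)
  ntr <- split_counts(r$n_trunk, r$n_trees)
  nbr_tree <- split_counts(r$n_branch, r$n_trees)
  trunks <- branches <- vector("list", r$n_trees)
  for (t in seq_len(r$n_trees)) {
    base <- c(pos[t, 1], pos[t, 2], terrain_z(pos[t, 1], pos[t, 2], ex))
    trunks[[t]] <- sample_cylinder(base, radii[t], r$trunk_height,
                                   ntr[t], ns, label = 2L)
    # thin oblique branches on the upper half of the trunk
    nb <- split_counts(nbr_tree[t], r$branches_per_tree)
    br <- vector("list", r$branches_per_tree)
    for (b in seq_len(r$branches_per_tree)) {
      h <- runif(1, 0.45 * r$trunk_height, 0.95 * r$trunk_height)
      az <- runif(1, 0, 2 * pi)
      droop <- runif(1, 10, 40) * pi / 180  # below horizontal
      len <- runif(1, 1.0, 2.0)
      start <- base + c(radii[t] * cos(az), radii[t] * sin(az), h)
      end <- start + len * c(cos(az) * cos(droop), sin(az) * cos(droop),
                             -sin(droop))
      br[[b]] <- sample_segment(start, end, nb[b], ns, label = 3L)
    }
    branches[[t]] <- bind_clouds(br)
  }
  c(clouds, trunks, branches)
}

build_urban <- function(r, ex, ns) {
  clouds <- list()
  gx <- runif(r$n_ground, 0, ex[1]); gy <- runif(r$n_ground, 0, ex[2])
  clouds$ground <- point_cloud(add_noise(cbind(gx, gy, rep(0, r$n_ground)),
                                         ns),
                               labels = rep(1L, r$n_ground))
  # facades: vertical planes along both long edges, 10 m tall,
  # split into 4 segments so both halves have building points
  nseg <- 4L
  nb <- split_counts(r$n_building, nseg)
  xs <- (seq_len(nseg) - 0.5) * ex[1] / nseg
  ys <- rep(c(0, ex[2]), length.out = nseg)
  clouds$buildings <- bind_clouds(lapply(seq_len(nseg), function(i)
    sample_plane(c(xs[i], ys[i], 5), u = c(1, 0, 0), v = c(0, 0, 1),
                 extent_u = ex[1] / nseg, extent_v = 10, nb[i], ns,
                 label = 2L)))
  # thin vertical poles, 3-8 m tall
  npol <- 10L
  pp <- spread_positions(npol, ex)
  np <- split_counts(r$n_pole, npol)
  clouds$poles <- bind_clouds(lapply(seq_len(npol), function(i)
    sample_pole(c(pp[i, 1], pp[i, 2], 0), height = runif(1, 3, 8),
                np[i], radius = 0.06, noise_sd = ns, label = 3L)))
  # vegetation: volumetric blobs resting above the ground
  nveg <- 8L
  vp <- spread_positions(nveg, ex)
  nv <- split_counts(r$n_vegetation, nveg)
  clouds$vegetation <- bind_clouds(lapply(seq_len(nveg), function(i) {
    rad <- runif(1, 1, 2)
    sample_blob(c(vp[i, 1], vp[i, 2], rad + 0.3), rad, nv[i], ns,
                label = 4L)
  }))
  # cars: low box-like slabs on the ground
  ncar <- 8L
  cp <- spread_positions(ncar, ex)
  nc <- split_counts(r$n_car, ncar)
  clouds$cars <- bind_clouds(lapply(seq_len(ncar), function(i)
    sample_box(c(cp[i, 1] - 2, cp[i, 2] - 0.9, 0), lx = 4, ly = 1.8,
               lz = 1.5, n = nc[i], noise_sd = ns, label = 5L)))
  clouds
}

#' Spatial train/test split
#'
#' Separates a scene built by [build_scene()] into its two disjoint
#' regions (halves of the footprint along X), mirroring evaluation on an
#' area not adjacent to the training area.
#'
#' @param cloud a cloud with a `region` element.
#' @return list of two [point_cloud]s, `train` and `test`.
#' @export
split_scene <- function(cloud) {
  if (is.null(cloud$region)) stop("cloud has no region tags")
  pick <- function(which) {
    i <- cloud$region == which
    point_cloud(cloud$coords[i, , drop = FALSE],
                labels = cloud$labels[i],
                class_names = cloud$class_names)
  }
  list(train = pick("train"), test = pick("test"))
}
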