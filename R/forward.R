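MU0 <- 4e-7 * pi  # vacuum permeability, T m / A

#' Construct a helmet-shaped magnetometer array
#'
#' Places `n_channels` point magnetometers quasi-uniformly (Fibonacci spiral)
#' on a spherical cap of angular extent `coverage_angle` around the vertex,
#' at distance `helmet_radius` from the head-frame origin. Orientations point
#' radially outward, as for an idealised magnetometer helmet.
#'
#' The head frame has its origin at the head-sphere centre, is right-handed,
#' in metres, with +z toward the vertex.
#'
#' @param n_channels number of magnetometers (default 248, a whole-head array).
#' @param helmet_radius distance of each sensor from the origin, metres.
#' @param coverage_angle polar angle of the cap, degrees (0 = vertex only;
#'   120 covers well below the equator of the helmet sphere).
#' @param seed integer; sets the azimuthal offset of the spiral so that
#'   distinct seeds give rotated but otherwise identical layouts.
#' @return object of class `sensor_array` with `channel_ids`, `positions`
#'   (n x 3, metres) and `orientations` (n x 3, unit radial vectors).
#' @export
build_sensor_array <- function(n_channels = 248, helmet_radius = 0.12,
                               coverage_angle = 120, seed = 1L) {
  if (!is.numeric(n_channels) || n_channels < 1)
    stop("n_channels must be a positive count, got ", n_channels)
  if (!is.numeric(helmet_radius) || helmet_radius <= 0)
    stop("helmet_radius must be > 0, got ", helmet_radius)
  if (!is.numeric(coverage_angle) || coverage_angle < 0)
    stop("coverage_angle must be >= 0 degrees, got ", coverage_angle)
  n <- as.integer(n_channels)
  theta_max <- coverage_angle * pi / 180
  # equal-area spacing in cos(theta) over the cap; golden-angle azimuth
  i <- seq_len(n)
  cos_t <- 1 - (1 - cos(theta_max)) * (i - 0.5) / n
  theta <- acos(pmin(1, pmax(-1, cos_t)))
  golden <- pi * (3 - sqrt(5))
  phi0 <- (as.integer(seed) %% 360L) * pi / 180
  phi <- i * golden + phi0
  if (n == 1L && coverage_angle == 0) {
    theta <- 0
    phi <- 0
  }
  pos <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  ori <- pos  # unit radial
  pos <- pos * helmet_radius
  structure(list(
    channel_ids = sprintf("MEG%03d", i),
    positions = pos,
    orientations = ori
  ), class = "sensor_array")
}

#' Spherical conductor head model
#'
#' A single conducting sphere, optionally with per-channel sphere overrides
#' (centre and radius per channel) in the spirit of multiple-spheres models
#' fitted per sensor. With overrides present there must be one entry per
#' channel of the array the model is used with.
#'
#' @param center 3-vector, metres, head frame.
#' @param radius sphere radius, metres (> 0).
#' @param channel_centers optional n x 3 matrix of per-channel sphere centres.
#' @param channel_radii optional length-n vector of per-channel radii.
#' @return object of class `head_model`.
#' @export
spherical_head_model <- function(center = c(0, 0, 0), radius = 0.09,
                                 channel_centers = NULL, channel_radii = NULL) {
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be > 0, got ", radius)
  if (xor(is.null(channel_centers), is.null(channel_radii)))
    stop("channel_centers and channel_radii must be given together")
  if (!is.null(channel_centers)) {
    channel_centers <- as.matrix(channel_centers)
    if (ncol(channel_centers) != 3L)
      stop("channel_centers must be an n x 3 matrix")
    if (nrow(channel_centers) != length(channel_radii))
      stop("one sphere radius per channel centre required")
    if (any(channel_radii <= 0)) stop("all per-channel radii must be > 0")
  }
  structure(list(
    center = as.numeric(center), radius = radius,
    channel_centers = channel_centers, channel_radii = channel_radii
  ), class = "head_model")
}

#' Regular source lattice inside the head sphere
#'
#' Builds a rectangular grid of candidate source points at the given spacing
#' and retains those strictly inside the sphere (distance from the centre
#' < radius - spacing/2). An `extent` restricts the grid to a sub-volume,
#' which keeps whole-brain scans affordable in simulations.
#'
#' @param head a `head_model`.
#' @param spacing lattice spacing, metres (default 0.005, i.e. 5 mm).
#' @param extent optional length-3 half-widths (metres) of a box around
#'   `origin`; default covers the whole sphere.
#' @param origin centre of the box, metres (default the sphere centre).
#' @return object of class `source_lattice`: `points` (m x 3), `spacing`,
#'   `grid_dim`, `grid_index` (position of each retained point in the full
#'   box grid) and the box axes, so volumes can be rasterised to NIfTI.
#' @export
source_lattice <- function(head, spacing = 0.005, extent = NULL,
                           origin = NULL) {
  stopifnot(inherits(head, "head_model"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(origin)) origin <- head$center
  if (is.null(extent)) extent <- rep(head$radius, 3)
  ax <- lapply(1:3, function(k) {
    nk <- floor(extent[k] / spacing)
    origin[k] + seq(-nk, nk) * spacing
  })
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d <- sqrt(rowSums(sweep(g, 2, head$center)^2))
  # the exact sphere centre is a degenerate dipole location and is dropped
  keep <- d < head$radius - spacing / 2 & d > 1e-9
  idx <- as.matrix(expand.grid(
    i = seq_along(ax[[1]]), j = seq_along(ax[[2]]), k = seq_along(ax[[3]])))
  structure(list(
    points = g[keep, , drop = FALSE],
    spacing = spacing,
    grid_dim = vapply(ax, length, 1L),
    grid_index = idx[keep, , drop = FALSE],
    axes = ax
  ), class = "source_lattice")
}

# Closed-form external field of a current dipole in a homogeneous conducting
# sphere (Sarvas solution). Positions relative to the sphere centre.
# Returns the 3-vector B at one sensor position, tesla.
sarvas_field <- function(r0, q, r) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  R <- sqrt(sum(r^2))
  ra <- sum(r0 * r)
  f <- a * (R * a + R^2 - ra)
  if (abs(f) < .Machine$double.xmin)
    stop("degenerate geometry: sensor coincides with source axis")
  adr <- sum(a_vec * r)
  grad_f <- (a^2 / R + adr / a + 2 * a + 2 * R) * r -
    (a + 2 * R + adr / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  (MU0 / (4 * pi * f^2)) * (f * qxr0 - sum(qxr0 * r) * grad_f)
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Analytic external field of a current dipole inside a homogeneous
#' conducting sphere, projected onto each magnetometer orientation. The
#' solution is linear in the dipole moment; the radial component of the
#' moment produces no external field, and the field does not depend on the
#' sphere radius (only on the centre). With per-channel sphere overrides the
#' projection is evaluated per channel in that channel's sphere frame.
#'
#' @param head a `head_model`.
#' @param location dipole position, 3-vector, metres, head frame.
#' @param moment dipole moment, 3-vector, ampere metres.
#' @param sensors a `sensor_array`.
#' @return numeric vector, one field value per channel, tesla.
#' @export
dipole_field <- function(head, location, moment, sensors) {
  stopifnot(inherits(head, "head_model"), inherits(sensors, "sensor_array"))
  location <- as.numeric(location); moment <- as.numeric(moment)
  n_ch <- nrow(sensors$positions)
  per_channel <- !is.null(head$channel_centers)
  if (per_channel && nrow(head$channel_centers) != n_ch)
    stop("head model has ", nrow(head$channel_centers),
         " per-channel spheres but the array has ", n_ch, " channels")
  check_inside <- function(center, radius) {
    d <- sqrt(sum((location - center)^2))
    if (d >= radius)
      stop(sprintf(
        "source at distance %.4g m from sphere centre lies outside radius %.4g m",
        d, radius))
    if (d < 1e-9)
      stop("source within 1e-9 m of the sphere centre: field formula degenerate")
  }
  out <- numeric(n_ch)
  if (!per_channel) {
    check_inside(head$center, head$radius)
    r0 <- location - head$center
    for (ch in seq_len(n_ch)) {
      r <- sensors$positions[ch, ] - head$center
      out[ch] <- sum(sarvas_field(r0, moment, r) * sensors$orientations[ch, ])
    }
  } else {
    for (ch in seq_len(n_ch)) {
      cc <- head$channel_centers[ch, ]
      check_inside(cc, head$channel_radii[ch])
      r0 <- location - cc
      r <- sensors$positions[ch, ] - cc
      out[ch] <- sum(sarvas_field(r0, moment, r) * sensors$orientations[ch, ])
    }
  }
  out
}

#' Lead field on a source lattice
#'
#' For every lattice point, the channels x 3 matrix whose columns are the
#' sensor fields of unit dipoles along the three canonical axes, in
#' tesla per ampere metre. The forward solution is linear, so the field of
#' an arbitrary moment q at point p is `L[[p]] %*% q`.
#'
#' @param head a `head_model`.
#' @param lattice a `source_lattice` (all points must be valid dipole
#'   locations for the head model).
#' @param sensors a `sensor_array`.
#' @return object of class `lead_field`: list `L` of channels x 3 matrices,
#'   plus the lattice and array references.
#' @export
lead_field <- function(head, lattice, sensors) {
  stopifnot(inherits(lattice, "source_lattice"))
  n_pt <- nrow(lattice$points)
  L <- vector("list", n_pt)
  for (p in seq_len(n_pt)) {
    loc <- lattice$points[p, ]
    Lp <- tryCatch(
      vapply(1:3, function(k) {
        q <- c(0, 0, 0); q[k] <- 1
        dipole_field(head, loc, q, sensors)
      }, numeric(nrow(sensors$positions))),
      error = function(e) stop("lead field failed at lattice point ", p,
                               ": ", conditionMessage(e)))
    L[[p]] <- Lp
  }
  structure(list(L = L, lattice = lattice, sensors = sensors,
                 units = "T/(A.m)", frame = "head-metres"),
            class = "lead_field")
}

#' Lead field at a single arbitrary point
#'
#' Channels x 3 forward matrix for a point that need not lie on a lattice
#' (e.g. a point of interest).
#'
#' @param head a `head_model`.
#' @param location 3-vector, metres.
#' @param sensors a `sensor_array`.
#' @return channels x 3 matrix, tesla per ampere metre.
#' @export
point_lead_field <- function(head, location, sensors) {
  vapply(1:3, function(k) {
    q <- c(0, 0, 0); q[k] <- 1
    dipole_field(head, location, q, sensors)
  }, numeric(nrow(sensors$positions)))
}

#' Serialise sensor array and head model to YAML
#' @param x a `sensor_array` or `head_model`.
#' @param path file to write.
#' @export
write_geometry_yaml <- function(x, path) {
  obj <- unclass(x)
  obj <- lapply(obj, function(v) {
    if (is.matrix(v))
      list(.matrix = TRUE, nrow = nrow(v), values = as.numeric(t(v)))
    else v
  })
  obj$class <- class(x)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a sensor array or head model written by [write_geometry_yaml()]
#' @param path YAML file.
#' @export
read_geometry_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$class
  obj$class <- NULL
  obj <- lapply(obj, function(v) {
    if (is.list(v) && isTRUE(v$.matrix))
      matrix(as.numeric(unlist(v$values)), nrow = v$nrow, byrow = TRUE)
    else if (is.list(v) && length(v) &&
             all(vapply(v, function(e) is.atomic(e) && length(e) == 1L, TRUE)))
      unlist(v)
    else v
  })
  structure(obj, class = cls)
}
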