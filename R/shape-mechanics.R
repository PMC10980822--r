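# Discretized axisymmetric membrane profiles and Helfrich bending /
# adhesion energy functionals.
#
# Coordinate convention (used everywhere in the package): x is the radial
# distance from the symmetry axis (x >= 0), z is the coordinate along the
# axis, and psi is the tangent angle with dx/ds = cos(psi), dz/ds = sin(psi)
# along the arclength s. A profile stores one tangent angle per segment of
# uniform arclength ds; node coordinates are the cumulative sums
# x_{i+1} = x_i + ds*cos(psi_i), z_{i+1} = z_i + ds*sin(psi_i).

MAX_SEGMENTS <- 400L

#' Discretized axisymmetric membrane profile
#'
#' A rotationally symmetric membrane contour parametrized by arclength:
#' `n` segments of uniform length `ds`, each with a tangent angle `psi`
#' (radians; `dx/ds = cos(psi)`, `dz/ds = sin(psi)`), starting at
#' `(x0, z0)`. Radial coordinates must remain non-negative.
#'
#' @param psi Numeric vector of tangent angles, one per segment (radians).
#' @param ds Uniform arclength per segment (nm), positive.
#' @param x0,z0 Starting node coordinates (nm).
#' @param max_segments Configured maximum number of segments.
#' @return An object of class `axisym_profile`.
#' @export
#' @examples
#' # quarter circle of radius 23 nm
#' n <- 400; R <- 23
#' prof <- axisym_profile(((seq_len(n) - 0.5) / n) * pi / 2, ds = R * pi / 2 / n)
#' tail(realize_profile(prof), 1) # close to (23, 23)
axisym_profile <- function(psi, ds, x0 = 0, z0 = 0,
                           max_segments = MAX_SEGMENTS) {
  n <- length(psi)
  if (n < 1L) stop("invalid profile: needs at least one segment")
  if (n > max_segments)
    stop(sprintf("invalid profile: %d segments exceeds maximum %d",
                 n, max_segments))
  if (!is.finite(ds) || ds <= 0) stop("invalid profile: ds must be positive")
  if (anyNA(psi)) stop("invalid profile: psi must be finite")
  if (x0 < 0) stop("invalid profile: x0 must be non-negative")
  prof <- structure(list(psi = as.numeric(psi), ds = ds, x0 = x0, z0 = z0,
                         n_segments = n),
                    class = "axisym_profile")
  realize_profile(prof) # validates radial coordinates
  prof
}

#' Node coordinates of a profile
#'
#' Realizes the `n_segments + 1` node coordinates by cumulative summation.
#' Profiles whose nodes dip below the axis (x < -1e-9) are rejected, naming
#' the first offending node.
#'
#' @param profile An [axisym_profile()].
#' @return A numeric matrix with columns `x`, `z` and `n_segments + 1` rows.
#' @export
realize_profile <- function(profile) {
  stopifnot(inherits(profile, "axisym_profile"))
  x <- profile$x0 + c(0, profile$ds * cumsum(cos(profile$psi)))
  z <- profile$z0 + c(0, profile$ds * cumsum(sin(profile$psi)))
  bad <- which(x < -1e-9)
  if (length(bad))
    stop(sprintf("invalid profile: node %d has negative radius x = %.3g nm",
                 bad[1] - 1L, x[bad[1]]))
  cbind(x = x, z = z)
}

# Midpoint geometry shared by the adhesion functional and the minimizer:
# positions and area elements at segment midpoints (half-lagged cumulative
# sums, i.e. midpoint-rule integration of the tangent).
profile_midpoint_geometry <- function(psi, ds, x0 = 0, z0 = 0) {
  n <- length(psi)
  cp <- cos(psi)
  sp <- sin(psi)
  P <- cumsum(cp) - cp / 2 # sum_{j<i} cos + cos_i/2
  Q <- cumsum(sp) - sp / 2
  xm <- x0 + ds * P
  zm <- z0 + ds * Q
  list(n = n, cp = cp, sp = sp, xm = xm, zm = zm, dA = 2 * pi * xm * ds)
}

# Bending energy on the staggered (node-based) grid: the meridional
# curvature c1 = (psi_{j+1} - psi_j)/ds lives on the node shared by two
# segments, the azimuthal curvature c2 = sin(psibar_j)/x_j uses the node
# position and the averaged tangent angle, and endpoints enter with half
# weight (one-sided c1). This discretization has no zero-energy zigzag
# mode, unlike a central difference of per-segment angles, which is why it
# is used both here and inside the shape minimizer. At on-axis nodes the
# umbilic limit c2 -> c1 applies (their area weight vanishes there too).
bending_energy_discrete <- function(psi, ds, x0, kappa) {
  n <- length(psi)
  xn <- x0 + ds * cumsum(cos(psi))
  x_all <- c(x0, xn) # nodes 0..n
  c1i <- if (n > 1L) diff(psi) / ds else numeric(0)
  c1 <- c(if (n > 1L) c1i[1] else 0, c1i, if (n > 1L) c1i[n - 1L] else 0)
  pb <- c(psi[1], if (n > 1L) (psi[-n] + psi[-1]) / 2 else numeric(0),
          psi[n])
  w <- c(ds / 2, rep(ds, max(0L, n - 1L)), ds / 2)
  on_axis <- x_all < 1e-9
  c2 <- ifelse(on_axis, c1, sin(pb) / pmax(x_all, 1e-300))
  sum(0.5 * kappa * (c1 + c2)^2 * 2 * pi * x_all * w)
}

#' Helfrich bending energy of a profile
#'
#' Discretized `(kappa/2) * integral (c1 + c2)^2 dA` on the staggered grid:
#' the meridional curvature `c1 = dpsi/ds` is the difference of the two
#' tangent angles meeting at each node, the azimuthal curvature
#' `c2 = sin(psi)/x` uses the node position and the averaged angle, and
#' `dA = 2*pi*x*ds` (endpoints half-weighted, one-sided differences). At an
#' on-axis pole the umbilic limit `c2 -> c1` is used. Spontaneous curvature
#' is zero, so the energy is non-negative; the Gaussian (saddle-splay) term
#' is omitted since topology is fixed, making it an additive constant.
#'
#' Profiles touching the axis away from their endpoints are rejected.
#'
#' @param profile An [axisym_profile()].
#' @param membrane A [membrane_model()].
#' @return Bending energy (kBT). A sphere gives `8*pi*kappa` independent of
#'   radius; a cylinder of radius R and length L gives `pi*kappa*L/R`.
#' @export
bending_energy <- function(profile, membrane) {
  stopifnot(inherits(profile, "axisym_profile"),
            inherits(membrane, "membrane_model"))
  nodes <- realize_profile(profile)
  interior <- nodes[-c(1, nrow(nodes)), "x"]
  if (length(interior) && any(interior < 1e-9))
    stop("invalid profile: touches the symmetry axis away from its endpoints")
  bending_energy_discrete(profile$psi, profile$ds, profile$x0,
                          membrane$kappa)
}

#' Adhesion energy of a profile near on-axis particles
#'
#' Discretized `integral V(l) dA` where `l` is the distance from each
#' segment midpoint to the nearest particle surface: the minimum over
#' particle centers of (Euclidean distance to the center) minus `Rp`.
#' Particles sit on the symmetry axis at the given axial positions.
#'
#' @param profile An [axisym_profile()].
#' @param particle_centers Axial (z) positions of particle centers (nm).
#' @param Rp Particle scaffold radius (nm).
#' @param pot An [adhesion_potential()].
#' @return Adhesion energy (kBT), always `<= 0`.
#' @export
adhesion_energy <- function(profile, particle_centers, Rp, pot) {
  stopifnot(inherits(profile, "axisym_profile"),
            inherits(pot, "adhesion_potential"))
  if (length(particle_centers) < 1L) stop("needs at least one particle")
  g <- profile_midpoint_geometry(profile$psi, profile$ds,
                                 profile$x0, profile$z0)
  dist <- sapply(particle_centers,
                 function(zc) sqrt(g$xm^2 + (g$zm - zc)^2))
  l <- (if (is.matrix(dist)) apply(dist, 1, min) else min(dist)) - Rp
  sum(potential_value(l, pot) * g$dA)
}

#' Bending plus adhesion energy breakdown
#'
#' @param E_bend Bending energy (kBT), non-negative.
#' @param E_adh Adhesion energy (kBT).
#' @return A list of class `energy_breakdown` with `E_bend`, `E_adh` and
#'   `E_total = E_bend + E_adh`.
#' @export
energy_breakdown <- function(E_bend, E_adh) {
  if (E_bend < -1e-9) stop("E_bend must be non-negative")
  structure(list(E_bend = E_bend, E_adh = E_adh,
                 E_total = E_bend + E_adh),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E_bend = %.4f  E_adh = %.4f  E_total = %.4f kBT\n",
              x$E_bend, x$E_adh, x$E_total))
  invisible(x)
}

#' Write a profile to CSV
#'
#' Columns: `index`, `psi_rad`, `x_nm`, `z_nm` (node coordinates; row 0
#' holds the starting node with `psi_rad = NA`). The arclength `ds` is
#' stored in a comment-free first data row convention: it is recovered on
#' read from the node spacing, so the CSV is self-contained.
#'
#' @param profile An [axisym_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
profile_to_csv <- function(profile, path) {
  nodes <- realize_profile(profile)
  df <- data.frame(index = 0:profile$n_segments,
                   psi_rad = c(NA, profile$psi),
                   x_nm = nodes[, "x"], z_nm = nodes[, "z"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile from CSV
#'
#' Inverse of [profile_to_csv()].
#'
#' @param path CSV path with columns `index`, `psi_rad`, `x_nm`, `z_nm`.
#' @return An [axisym_profile()].
#' @export
profile_from_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("index", "psi_rad", "x_nm", "z_nm") %in% names(df)))
  df <- df[order(df$index), ]
  psi <- df$psi_rad[-1]
  # each step is a chord of length ds (unit tangent), so recover it directly
  ds <- sqrt((df$x_nm[2] - df$x_nm[1])^2 + (df$z_nm[2] - df$z_nm[1])^2)
  axisym_profile(psi, ds = ds, x0 = df$x_nm[1], z0 = df$z_nm[1])
}
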