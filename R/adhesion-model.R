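#' memwrap: adhesion-energy modelling of multivalent particle wrapping
#'
#' Models the energetics of membrane wrapping of a multivalent globular
#' particle (a ~40 nm encapsulin shell displaying 180 GFP copies) bound to
#' lipid-anchored nanobody receptors. Receptor affinity is mapped to an
#' effective adhesion energy per membrane area; membrane shapes are found by
#' constrained minimization of Helfrich bending plus adhesion energy on
#' discretized axisymmetric profiles.
#'
#' Units are fixed throughout: lengths in nm, energies in units of the
#' thermal energy kBT (kBT == 1 internally), energy densities in kBT/nm^2,
#' and concentrations in nM. There is no temperature parameter.
#'
#' @keywords internal
"_PACKAGE"

# Default tilt-angle estimates (degrees) for the receptor-ligand complex.
# Projections of the 4.8 nm complex axis onto the membrane normal have mean
# exactly 4 nm and population standard deviation exactly 1 nm.
DEFAULT_TILT_DEG <- c(0, 16.1768456836487, 57.3440190708702)

#' Geometry of the membrane-anchored receptor-ligand complex
#'
#' Describes the GPI-anchored nanobody / GFP complex that tethers the
#' particle to the membrane: the offset from the membrane midplane to the
#' nanobody C-terminus (`b`), the vertical extension of the linker at the
#' GFP N-terminus (`a`), the length of the axis connecting the two linker
#' attachment sites (`axis_len`), and a finite set of tilt-angle estimates
#' of that axis relative to the membrane normal.
#'
#' @param b Membrane-midplane-to-nanobody-C-terminus distance (nm).
#' @param a Linker vertical extension at the GFP N-terminus (nm).
#' @param axis_len Nanobody-C-terminus-to-GFP-N-terminus axis length (nm).
#' @param tilt_angles_deg Non-empty numeric vector of tilt estimates, each
#'   in `[0, 90)` degrees.
#' @return An object of class `memwrap_geometry`.
#' @seealso [derive_separation_stats()]
#' @export
#' @examples
#' geom <- complex_geometry()
#' derive_separation_stats(geom) # l0 = 8 nm, sigma = 1 nm
complex_geometry <- function(b = 2.5, a = 1.5, axis_len = 4.8,
                             tilt_angles_deg = DEFAULT_TILT_DEG) {
  stopifnot(is.numeric(b), is.numeric(a), is.numeric(axis_len))
  if (b < 0 || a < 0 || axis_len < 0)
    stop("invalid geometry: b, a and axis_len must be non-negative")
  if (length(tilt_angles_deg) < 1L || anyNA(tilt_angles_deg))
    stop("invalid geometry: tilt_angles_deg must be non-empty and finite")
  if (any(tilt_angles_deg < 0 | tilt_angles_deg >= 90))
    stop("invalid geometry: tilt angles must lie in [0, 90) degrees")
  structure(
    list(b = b, a = a, axis_len = axis_len,
         tilt_angles_deg = as.numeric(tilt_angles_deg)),
    class = "memwrap_geometry")
}

#' Preferred separation and spread from complex geometry
#'
#' The preferred particle-surface-to-membrane-midplane separation is
#' `l0 = b + a + mean(axis_len * cos(theta))` over the configured tilt
#' estimates; its spread `sigma` is the population standard deviation of the
#' projections `axis_len * cos(theta)`. With the default geometry this
#' reproduces l0 = 2.5 + 1.5 + 4 = 8 nm and sigma = 1 nm.
#'
#' @param geom A [complex_geometry()] object.
#' @return A list with components `l0` and `sigma` (both nm).
#' @export
derive_separation_stats <- function(geom) {
  stopifnot(inherits(geom, "memwrap_geometry"))
  proj <- geom$axis_len * cos(geom$tilt_angles_deg * pi / 180)
  l0 <- geom$b + geom$a + mean(proj)
  sigma <- sqrt(mean((proj - mean(proj))^2)) # population form
  list(l0 = l0, sigma = sigma)
}

#' Multivalent particle model
#'
#' The particle is a rigid sphere of scaffold radius `Rp` displaying
#' `n_sites` binding sites. A membrane wrapping it at the preferred
#' separation `l0` forms a sphere of wrap radius `r = Rp + l0`, so the
#' membrane area per ligand-receptor complex is `A = 4 * pi * r^2 / n_sites`.
#' Defaults (Rp = 15 nm, 180 sites, l0 = 8 nm) give r = 23 nm and
#' A of about 37 nm^2.
#'
#' @param Rp Scaffold radius (nm).
#' @param n_sites Number of binding sites on the particle surface.
#' @param l0 Preferred surface-to-midplane separation (nm).
#' @return An object of class `memwrap_particle` with fields `Rp`,
#'   `n_sites`, `l0`, `r` and `A`.
#' @export
particle_model <- function(Rp = 15, n_sites = 180, l0 = 8) {
  if (Rp <= 0) stop("Rp must be positive")
  if (l0 <= 0) stop("l0 must be positive (wrap radius must exceed Rp)")
  if (n_sites < 1) stop("n_sites must be at least 1")
  r <- Rp + l0
  structure(
    list(Rp = Rp, n_sites = n_sites, l0 = l0, r = r,
         A = 4 * pi * r^2 / n_sites),
    class = "memwrap_particle")
}

#' Gaussian adhesion potential
#'
#' The effective adhesion potential of the multivalent bond, per membrane
#' area, as a function of the local particle-surface-to-membrane-midplane
#' separation l:  `V(l) = -U * exp(-(l - l0)^2 / (2 * sigma^2))`.
#'
#' `sigma` is interpreted as a standard deviation, i.e. the exponent
#' denominator is `2 * sigma^2` (variance form). At the default
#' sigma = 1 nm this is numerically identical to a plain `2 * sigma`
#' denominator.
#'
#' @param U Potential depth (kBT/nm^2), non-negative.
#' @param l0 Preferred separation (nm).
#' @param sigma Separation spread (nm), positive.
#' @return An object of class `adhesion_potential`.
#' @export
adhesion_potential <- function(U, l0 = 8, sigma = 1) {
  if (U < 0) stop("U must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(U = U, l0 = l0, sigma = sigma), class = "adhesion_potential")
}

#' Evaluate the adhesion potential
#'
#' @param l Separation(s) from particle surface to membrane midplane (nm).
#' @param pot An [adhesion_potential()].
#' @return Energy density (kBT/nm^2); `-U` at `l = l0`, tending to 0 far
#'   from `l0`.
#' @export
potential_value <- function(l, pot) {
  stopifnot(inherits(pot, "adhesion_potential"))
  -pot$U * exp(-(l - pot$l0)^2 / (2 * pot$sigma^2))
}

#' Membrane mechanical model
#'
#' Helfrich membrane with bending rigidity `kappa` (kBT). Spontaneous
#' curvature and tension are part of the interface but are fixed at zero in
#' this version (the wrapping threshold `2*kappa/r^2` presumes both);
#' non-zero values are rejected.
#'
#' @param kappa Bending rigidity (kBT), positive.
#' @param spontaneous_curvature Spontaneous curvature (1/nm); must be 0.
#' @param tension Membrane tension (kBT/nm^2); must be 0.
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(kappa = 20, spontaneous_curvature = 0,
                           tension = 0) {
  if (kappa <= 0) stop("kappa must be positive")
  if (spontaneous_curvature != 0)
    stop("non-zero spontaneous curvature is not supported")
  if (tension != 0)
    stop("non-zero tension is not supported")
  structure(list(kappa = kappa,
                 spontaneous_curvature = 0, tension = 0),
            class = "membrane_model")
}

#' Adhesion energy per membrane area from receptor affinity
#'
#' Depth of the effective adhesion potential for receptors with soluble
#' dissociation constant `KD`, combined receptor parameter `rho = [R]/xi`
#' (surface concentration over the 3D-to-2D conversion length, in nM), and
#' membrane area `A` per complex:
#' `U = ln(rho / KD) / A` for `KD < rho`, clamped to 0 otherwise (a
#' repulsive surface potential is outside the model: no net attraction
#' means no adhesion term).
#'
#' @param KD Dissociation constant of the soluble complex (nM).
#' @param rho Receptor ratio `[R]/xi` (nM).
#' @param A Membrane area per complex (nm^2).
#' @return Adhesion strength U (kBT/nm^2).
#' @export
adhesion_strength <- function(KD, rho = 16300, A = particle_model()$A) {
  if (any(KD <= 0) || rho <= 0 || A <= 0)
    stop("KD, rho and A must be positive")
  pmax(0, log(rho / KD) / A)
}

#' Wrapping threshold adhesion strength
#'
#' Adhesion strength above which full wrapping of a particle of effective
#' radius `r` becomes energetically favorable: `U_t = 2 * kappa / r^2`.
#' Below it the bending cost of wrapping exceeds the adhesion gain.
#'
#' @param kappa Bending rigidity (kBT).
#' @param r Wrap radius (nm).
#' @return Threshold U_t (kBT/nm^2).
#' @export
wrapping_threshold <- function(kappa, r) {
  if (kappa < 0 || r <= 0) stop("kappa must be >= 0 and r > 0")
  2 * kappa / r^2
}

#' Threshold affinity for wrapping
#'
#' The unique dissociation constant at which the adhesion strength equals
#' the wrapping threshold: `KD* = rho * exp(-U_t * A)` with
#' `U_t = 2 * kappa / r^2` (kBT == 1). With the defaults
#' (rho = 16,300 nM, kappa = 20 kBT, r = 23 nm, A = 4*pi*23^2/180) this is
#' approximately 1000 nM.
#'
#' @param rho Receptor ratio (nM).
#' @param kappa Bending rigidity (kBT).
#' @param r Wrap radius (nm).
#' @param A Membrane area per complex (nm^2).
#' @return Threshold dissociation constant KD* (nM), always below `rho`.
#' @export
threshold_affinity <- function(rho = 16300, kappa = 20, r = 23,
                               A = particle_model()$A) {
  if (rho <= 0 || kappa < 0 || r <= 0 || A <= 0)
    stop("all inputs must be positive")
  rho * exp(-wrapping_threshold(kappa, r) * A)
}

#' Binding condition: affinity plus model parameters
#'
#' Bundles a receptor affinity with the particle and membrane models and
#' derives the adhesion strength `U`, the wrapping threshold `U_t`, the
#' threshold affinity `KD_star` and the adhesion potential used by the
#' shape minimizers.
#'
#' @param KD Dissociation constant of the soluble complex (nM).
#' @param rho Receptor ratio `[R]/xi` (nM).
#' @param particle A [particle_model()].
#' @param membrane A [membrane_model()].
#' @param sigma Separation spread of the adhesion potential (nm).
#' @return An object of class `binding_condition`.
#' @export
#' @examples
#' cond <- binding_condition(KD = 600)
#' cond$U > cond$U_t # above the wrapping threshold
binding_condition <- function(KD, rho = 16300, particle = particle_model(),
                              membrane = membrane_model(), sigma = 1) {
  stopifnot(inherits(particle, "memwrap_particle"),
            inherits(membrane, "membrane_model"))
  if (KD <= 0 || rho <= 0) stop("KD and rho must be positive")
  U <- adhesion_strength(KD, rho, particle$A)
  structure(
    list(KD = KD, rho = rho, particle = particle, membrane = membrane,
         U = U,
         U_t = wrapping_threshold(membrane$kappa, particle$r),
         KD_star = threshold_affinity(rho, membrane$kappa, particle$r,
                                      particle$A),
         potential = adhesion_potential(U, l0 = particle$l0, sigma = sigma)),
    class = "binding_condition")
}

#' @export
print.binding_condition <- function(x, ...) {
  cat("Binding condition\n")
  cat(sprintf("  KD      : %g nM (rho = %g nM)\n", x$KD, x$rho))
  cat(sprintf("  U       : %.5f kBT/nm^2\n", x$U))
  cat(sprintf("  U_t     : %.5f kBT/nm^2 (kappa = %g kBT, r = %g nm)\n",
              x$U_t, x$membrane$kappa, x$particle$r))
  cat(sprintf("  KD*     : %.4g nM\n", x$KD_star))
  cat(sprintf("  regime  : %s\n",
              if (x$U > x$U_t) "wrapped (U > U_t)" else "unwrapped (U <= U_t)"))
  invisible(x)
}

#' Read model parameters from a YAML configuration file
#'
#' Recognized keys: `kappa`, `Rp`, `n_sites`, `b`, `a`, `axis_len`,
#' `tilt_angles_deg`, `rho_nM`, `sigma`. Missing keys fall back to the
#' package defaults. Returns the assembled particle and membrane models plus
#' a constructor for binding conditions at given affinities.
#'
#' @param path Path to a YAML file.
#' @return A list with `geometry`, `particle`, `membrane`, `rho`, `sigma`
#'   and `condition(KD)`.
#' @export
read_wrap_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- complex_geometry(
    b = cfg$b %||% 2.5, a = cfg$a %||% 1.5,
    axis_len = cfg$axis_len %||% 4.8,
    tilt_angles_deg = cfg$tilt_angles_deg %||% DEFAULT_TILT_DEG)
  sep <- derive_separation_stats(geom)
  particle <- particle_model(Rp = cfg$Rp %||% 15,
                             n_sites = cfg$n_sites %||% 180, l0 = sep$l0)
  membrane <- membrane_model(kappa = cfg$kappa %||% 20)
  rho <- cfg$rho_nM %||% 16300
  sigma <- cfg$sigma %||% sep$sigma
  list(geometry = geom, particle = particle, membrane = membrane,
       rho = rho, sigma = sigma,
       condition = function(KD)
         binding_condition(KD, rho = rho, particle = particle,
                           membrane = membrane, sigma = sigma))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
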