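# analytic profile fixtures, built in code

# closed sphere of radius R: psi runs 0 -> pi, midpoint-sampled
sphere_profile <- function(R, n = 400) {
  axisym_profile((seq_len(n) - 0.5) * pi / n, ds = pi * R / n)
}

# open cylinder of radius R and length L along the axis
cylinder_profile <- function(R, L, n = 400) {
  axisym_profile(rep(pi / 2, n), ds = L / n, x0 = R)
}

# catenoid x = c*cosh(z/c), arclength-parametrized, z in [-h, h]
catenoid_profile <- function(c0 = 23, h = 23, n = 400) {
  S <- c0 * sinh(h / c0) # arclength from waist to rim
  smid <- seq(-S, S, length.out = n + 1)
  smid <- (smid[-1] + smid[-(n + 1)]) / 2
  # tangent: cos(psi) = tanh(z/c), sin(psi) = 1/cosh(z/c); s = c*sinh(z/c)
  zc <- asinh(smid / c0)
  psi <- atan2(1 / cosh(zc), tanh(zc))
  x_start <- c0 * cosh(h / c0)
  axisym_profile(psi, ds = 2 * S / n, x0 = x_start, z0 = -h)
}

# spherical-cap-plus-neck trial family evaluated with the public energy
# operations, relative to the flat reference (independent minimizer oracle)
trial_family_energy <- function(cond, f, n = 200, R_out = 200) {
  tr <- memwrap:::wrap_trial_shape(f, cond$particle$r, R_out, n)
  if (is.null(tr)) return(Inf)
  prof <- try(axisym_profile(tr$psi, ds = tr$ds), silent = TRUE)
  if (inherits(prof, "try-error")) return(Inf)
  eb <- bending_energy(prof, cond$membrane)
  ea <- adhesion_energy(prof, tr$z_c, cond$particle$Rp, cond$potential)
  eb + ea - flat_reference_energy(cond, n, R_out)$E
}

# binding condition with U set to a multiple of the wrapping threshold
condition_at_U_factor <- function(fac, kappa = 20, rho = 16300) {
  particle <- particle_model()
  Ut <- wrapping_threshold(kappa, particle$r)
  KD <- rho * exp(-fac * Ut * particle$A)
  binding_condition(KD, rho = rho, particle = particle,
                    membrane = membrane_model(kappa = kappa))
}

# quick solver settings for tests (coarser, fewer iterations)
fast_ctrl <- list(maxit = 250L, maxit_light = 100L, n_outer = 4L)
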