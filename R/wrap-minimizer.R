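# Constrained minimization of bending + adhesion energy for single-particle
# wrapping and joint tubular wrapping.

default_wrap_control <- function() {
  list(
    n_continuation = 5L,  # continuation steps in U, high to target
    n_outer = 6L,         # augmented-Lagrangian outer iterations (final)
    maxit = 800L,         # inner L-BFGS iterations (final)
    maxit_light = 200L,   # inner iterations during continuation
    mu0 = 50,             # initial AL penalty weight
    factr = 1e4,          # L-BFGS relative-accuracy control
    tol_viol = 1e-6,      # max allowed constraint violation (nm)
    jitter = 1e-3,        # sd of the seeded start perturbation (rad)
    f_grid = seq(0.05, 0.95, by = 0.02), # wrap fractions for trial scan
    f_near = 0.9          # mandated near-complete-wrap start
  )
}

# memoizing L-BFGS-B driver (optim calls fn and gr separately)
lbfgs_solve <- function(par, obj, maxit, factr = 1e5,
                        lower = -Inf, upper = Inf) {
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL
  evalf <- function(p) {
    r <- obj(p, want_grad = TRUE)
    cache$key <- p
    cache$val <- r$value
    cache$grad <- r$grad
  }
  fn <- function(p) {
    if (!identical(p, cache$key)) evalf(p)
    cache$val
  }
  gr <- function(p) {
    if (!identical(p, cache$key)) evalf(p)
    cache$grad
  }
  stats::optim(par, fn, gr, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = maxit, factr = factr))
}

#' Adhesion energy of the flat reference state
#'
#' Energy of a flat membrane disc of radius `R_out` with the particle
#' resting on it at its optimal height (the height minimizing the adhesion
#' integral subject to the particle staying outside the membrane plane,
#' `z_c >= Rp`). Wrapping energies are reported relative to this state, so
#' an unwrapped configuration scores approximately zero.
#'
#' @param cond A [binding_condition()].
#' @param n_segments Number of segments of the flat disc.
#' @param R_out Disc radius (nm).
#' @return A list with `E` (kBT) and the optimal particle height `z_c` (nm).
#' @export
flat_reference_energy <- function(cond, n_segments = 400, R_out = 200) {
  pot <- cond$potential
  Rp <- cond$particle$Rp
  ds <- R_out / n_segments
  xm <- (seq_len(n_segments) - 0.5) * ds
  dA <- 2 * pi * xm * ds
  efun <- function(zc)
    sum(potential_value(sqrt(xm^2 + zc^2) - Rp, pot) * dA)
  if (pot$U == 0) return(list(E = 0, z_c = Rp + pot$l0))
  op <- stats::optimize(efun, c(Rp, Rp + pot$l0 + 8 * pot$sigma),
                        tol = 1e-9)
  list(E = op$objective, z_c = op$minimum)
}

# one augmented-Lagrangian solve of the single-wrap problem at fixed U
solve_single_at_U <- function(par, U, n, R_out, kappa, Rp, l0, sigma,
                              ctrl, final = TRUE) {
  al <- new_al_state(n, mu0 = ctrl$mu0, pairwise = TRUE)
  pen <- make_al_penalty(al, Rp, 1L, waist_all = FALSE)
  obj <- make_single_objective(n, R_out, kappa, Rp, U, l0, sigma, pen)
  n_outer <- if (final) ctrl$n_outer else 2L
  maxit <- if (final) ctrl$maxit else ctrl$maxit_light
  viol <- Inf
  for (k in seq_len(n_outer)) {
    opt <- lbfgs_solve(par, obj, maxit, ctrl$factr)
    par <- opt$par
    det <- obj(par, details = TRUE)
    rho <- sqrt(det$xm^2 + (det$zm - det$z_c)^2)
    viol <- al_update(al, det$xm, det$zm, det$ds, det$psi, rho, Rp,
                      waist_all = FALSE)
    if (viol < ctrl$tol_viol && k >= 2L && opt$convergence == 0L) break
  }
  # L-BFGS-B termination at this factr means the final iteration changed
  # the energy by less than ~1e-12 relative, well inside the 1e-8 contract
  conv <- final && viol < ctrl$tol_viol && opt$convergence == 0L
  list(par = par, det = det, viol = viol, converged = conv)
}

#' Minimum-energy shape for single-particle wrapping
#'
#' Minimizes bending plus adhesion energy over the tangent-angle sequence,
#' the arclength scale and the particle height, for an axisymmetric
#' membrane profile running from the symmetry axis (pole under the
#' particle) to a flat outer rim at radius `R_out`. Constraints: radial
#' coordinates stay non-negative, the membrane stays outside the rigid
#' particle core, and nearly closed necks respect a minimal
#' membrane-midplane separation of 5 nm (realized both as a pairwise
#' contour self-distance and as a neck diameter `2*x >= 5 nm` past the
#' first overhang).
#'
#' The solver follows a fixed restart schedule: a flat start solved
#' directly at the target adhesion strength, and analytic
#' spherical-cap-plus-neck starts (the best of a wrap-fraction scan and a
#' near-complete wrap) carried through a continuation in U from high
#' values down to the target in `n_continuation` steps. The lowest-energy
#' feasible candidate is kept. Randomness (tiny start perturbations) is
#' fully controlled by `seed`.
#'
#' Energies are reported relative to the flat reference state
#' ([flat_reference_energy()]), so an unwrapped membrane scores about 0 and
#' wrapping is favorable exactly when the total is negative.
#'
#' @param cond A [binding_condition()].
#' @param n_segments Number of profile segments (at most 400).
#' @param R_out Outer rim radius (nm); at least `5 * r`.
#' @param seed Integer seed for the restart perturbations.
#' @param control Named list overriding entries of the solver control
#'   (continuation steps, iteration limits, tolerances).
#' @return An object of class `wrap_configuration`: `profile`,
#'   `particle_height`, `energies` (an [energy_breakdown()] relative to the
#'   flat state), `converged`, and `max_constraint_violation` (nm).
#' @export
minimize_single_wrap <- function(cond, n_segments = 400, R_out = 200,
                                 seed = 1L, control = list()) {
  stopifnot(inherits(cond, "binding_condition"))
  n <- as.integer(n_segments)
  if (n < 16L || n > MAX_SEGMENTS)
    stop(sprintf("n_segments must be between 16 and %d", MAX_SEGMENTS))
  r_w <- cond$particle$r
  if (R_out < 5 * r_w) stop("R_out must be at least 5 * r")
  ctrl <- utils::modifyList(default_wrap_control(), control)
  kappa <- cond$membrane$kappa
  Rp <- cond$particle$Rp
  pot <- cond$potential
  U <- cond$U
  flat <- flat_reference_energy(cond, n, R_out)

  if (U == 0) {
    prof <- axisym_profile(rep(0, n), ds = R_out / n)
    return(structure(
      list(profile = prof, particle_height = flat$z_c,
           energies = energy_breakdown(0, 0), converged = TRUE,
           max_constraint_violation = 0),
      class = "wrap_configuration", U = 0, E_flat = 0, R_out = R_out))
  }

  # start candidates --------------------------------------------------------
  scan_obj <- make_single_objective(n, R_out, kappa, Rp, U, pot$l0,
                                    pot$sigma, NULL)
  trial_value <- function(f) {
    tr <- wrap_trial_shape(f, r_w, R_out, n)
    if (is.null(tr)) return(Inf)
    scan_obj(c(tr$psi[seq_len(n - 1L)], tr$z_c), want_grad = FALSE)
  }
  fvals <- vapply(ctrl$f_grid, trial_value, numeric(1))
  f_best <- ctrl$f_grid[which.min(fvals)]
  f_near <- ctrl$f_near
  if (is.null(wrap_trial_shape(f_near, r_w, R_out, n)))
    f_near <- max(ctrl$f_grid[is.finite(fvals)])

  start_par <- function(kind, f = NULL) {
    jit <- stats::rnorm(n - 1L, 0, ctrl$jitter)
    if (kind == "flat") return(c(jit, flat$z_c))
    tr <- wrap_trial_shape(f, r_w, R_out, n)
    c(tr$psi[seq_len(n - 1L)] + jit, tr$z_c)
  }

  run_continuation <- function(par) {
    U_hi <- max(2 * U, 2 * cond$U_t)
    sched <- exp(seq(log(U_hi), log(U), length.out = ctrl$n_continuation))
    for (U_s in sched[-length(sched)]) {
      par <- solve_single_at_U(par, U_s, n, R_out, kappa, Rp, pot$l0,
                               pot$sigma, ctrl, final = FALSE)$par
    }
    solve_single_at_U(par, U, n, R_out, kappa, Rp, pot$l0, pot$sigma,
                      ctrl, final = TRUE)
  }

  cands <- withr::with_seed(as.integer(seed), {
    out <- list()
    out$flat <- solve_single_at_U(start_par("flat"), U, n, R_out, kappa,
                                  Rp, pot$l0, pot$sigma, ctrl, final = TRUE)
    out$trial <- run_continuation(start_par("trial", f_best))
    if (abs(f_near - f_best) > 0.04)
      out$near <- run_continuation(start_par("trial", f_near))
    out
  })

  score <- vapply(cands, function(cc) {
    e <- cc$det$E_bend + cc$det$E_adh - flat$E
    if (cc$viol > 1e-3) e + 1e6 * cc$viol else e
  }, numeric(1))
  best <- cands[[which.min(score)]]

  det <- best$det
  prof <- axisym_profile(det$psi, ds = det$ds)
  structure(
    list(profile = prof, particle_height = det$z_c,
         energies = energy_breakdown(det$E_bend, det$E_adh - flat$E),
         converged = best$converged,
         max_constraint_violation = best$viol),
    class = "wrap_configuration",
    U = U, E_flat = flat$E, R_out = R_out, f_best = f_best)
}

#' @export
print.wrap_configuration <- function(x, ...) {
  cat("Single-particle wrap configuration\n")
  print(x$energies)
  cat(sprintf("  particle height %.2f nm; converged: %s; max violation %.2g nm\n",
              x$particle_height, x$converged, x$max_constraint_violation))
  invisible(x)
}

solve_tubule_at_U <- function(par, U, n, kappa, Rp, l0, sigma, ctrl,
                              lower, upper, final = TRUE) {
  al <- new_al_state(n, mu0 = ctrl$mu0, pairwise = FALSE)
  pen <- make_al_penalty(al, Rp, 2L, waist_all = TRUE)
  obj <- make_tubule_objective(n, kappa, Rp, U, l0, sigma, pen)
  n_outer <- if (final) ctrl$n_outer else 2L
  maxit <- if (final) ctrl$maxit else ctrl$maxit_light
  viol <- Inf
  for (k in seq_len(n_outer)) {
    opt <- lbfgs_solve(par, obj, maxit, ctrl$factr, lower, upper)
    par <- opt$par
    det <- obj(par, details = TRUE)
    rho <- pmin(sqrt(det$xm^2 + (det$zm - det$z_end)^2),
                sqrt(det$xm^2 + (det$zm + det$z_end)^2))
    viol <- al_update(al, det$xm, det$zm, det$ds, det$psi, rho, Rp,
                      waist_all = TRUE)
    if (viol < ctrl$tol_viol && k >= 2L && opt$convergence == 0L) break
  }
  conv <- final && viol < ctrl$tol_viol && opt$convergence == 0L
  list(par = par, det = det, viol = viol, converged = conv)
}

#' Minimum-energy tubular wrapping (periodic unit cell)
#'
#' Joint wrapping of particles in a membrane tubule, modeled as an infinite
#' periodic tubule via one mirror-symmetric unit cell around the central
#' particle: the profile runs from a neck waist (tangent parallel to the
#' tubule axis, waist radius a free variable `>= 2.5` nm) to the mirror
#' plane through the particle centre, and the cell energy is twice that of
#' the half cell. Minimization is over the tangent-angle sequence, the
#' arclength scale (which carries the particle spacing) and the waist
#' radius. The periodic neighbour particle is included in the adhesion
#' field. For `n_particles = 1` the problem reduces to
#' [minimize_single_wrap()].
#'
#' Per-particle energies are reported relative to the same flat reference
#' state as the single wrap, so they are directly comparable.
#'
#' @param cond A [binding_condition()].
#' @param n_particles Number of particles; `1` delegates to the single
#'   wrap, anything larger (including `Inf`, the default) uses the
#'   periodic unit cell for the central particle.
#' @param n_segments Segments per half unit cell (at most 400).
#' @param seed Integer seed for the restart perturbations.
#' @param control Solver control overrides, as in [minimize_single_wrap()].
#' @return An object of class `tubule_configuration`: `n_particles`,
#'   `spacing` (nm between adjacent particle centres), `waist_radius`,
#'   `unit_cell_energy` (per central particle, relative to the flat
#'   state), `profile` (half unit cell), `converged`,
#'   `max_constraint_violation`.
#' @export
minimize_tubule <- function(cond, n_particles = Inf, n_segments = 400,
                            seed = 1L, control = list()) {
  stopifnot(inherits(cond, "binding_condition"))
  if (n_particles < 1) stop("n_particles must be at least 1")
  if (n_particles == 1) {
    w <- minimize_single_wrap(cond, n_segments = n_segments, seed = seed,
                              control = control)
    return(structure(
      list(n_particles = 1, spacing = NA_real_, waist_radius = NA_real_,
           unit_cell_energy = w$energies, profile = w$profile,
           converged = w$converged,
           max_constraint_violation = w$max_constraint_violation),
      class = "tubule_configuration", U = attr(w, "U"),
      E_flat = attr(w, "E_flat"), single = w))
  }
  n <- as.integer(n_segments)
  if (n < 16L || n > MAX_SEGMENTS)
    stop(sprintf("n_segments must be between 16 and %d", MAX_SEGMENTS))
  ctrl <- utils::modifyList(default_wrap_control(), control)
  kappa <- cond$membrane$kappa
  Rp <- cond$particle$Rp
  pot <- cond$potential
  U <- cond$U
  r_w <- cond$particle$r
  flat <- flat_reference_energy(cond, n)

  lower <- c(rep(-2, n - 2L), 0.02, 2.5)
  upper <- c(rep(pi + 2, n - 2L), 5, r_w)

  scan_obj <- make_tubule_objective(n, kappa, Rp, U, pot$l0, pot$sigma, NULL)
  grid <- expand.grid(r_b = c(4, 6, 9, 12), L_cyl = c(0, 2, 5, 9),
                      a_w = c(2.5, 8, 15))
  tvals <- mapply(function(r_b, L_cyl, a_w) {
    tr <- tubule_trial_shape(r_b, L_cyl, r_w, a_w, n)
    if (is.null(tr)) return(Inf)
    scan_obj(c(tr$psi[2:(n - 1L)], tr$ds, tr$x0), want_grad = FALSE)
  }, grid$r_b, grid$L_cyl, grid$a_w)
  ord <- order(tvals)

  start_par <- function(k) {
    tr <- tubule_trial_shape(grid$r_b[k], grid$L_cyl[k], r_w, grid$a_w[k],
                             n)
    jit <- stats::rnorm(n - 2L, 0, ctrl$jitter)
    c(pmin(pmax(tr$psi[2:(n - 1L)] + jit, lower[1]), upper[1]),
      tr$ds, tr$x0)
  }

  run_continuation <- function(par) {
    U_hi <- max(2 * U, 2 * cond$U_t)
    sched <- exp(seq(log(U_hi), log(U), length.out = ctrl$n_continuation))
    for (U_s in sched[-length(sched)]) {
      par <- solve_tubule_at_U(par, U_s, n, kappa, Rp, pot$l0, pot$sigma,
                               ctrl, lower, upper, final = FALSE)$par
    }
    solve_tubule_at_U(par, U, n, kappa, Rp, pot$l0, pot$sigma, ctrl,
                      lower, upper, final = TRUE)
  }

  cands <- withr::with_seed(as.integer(seed) + 1L, {
    # best three starts with distinct waist radii (deep vs shallow states)
    ks <- ord[!duplicated(grid$a_w[ord])][1:3]
    ks <- ks[!is.na(ks) & is.finite(tvals[ks])]
    lapply(ks, function(k) run_continuation(start_par(k)))
  })

  score <- vapply(cands, function(cc) {
    e <- 2 * (cc$det$E_bend + cc$det$E_adh) - flat$E
    if (cc$viol > 1e-3) e + 1e6 * cc$viol else e
  }, numeric(1))
  best <- cands[[which.min(score)]]
  det <- best$det

  prof <- axisym_profile(det$psi, ds = det$ds, x0 = det$x0)
  structure(
    list(n_particles = n_particles, spacing = 2 * det$z_end,
         waist_radius = det$x0,
         unit_cell_energy = energy_breakdown(2 * det$E_bend,
                                             2 * det$E_adh - flat$E),
         profile = prof, converged = best$converged,
         max_constraint_violation = best$viol),
    class = "tubule_configuration", U = U, E_flat = flat$E)
}

#' @export
print.tubule_configuration <- function(x, ...) {
  cat("Tubule unit-cell configuration (per central particle)\n")
  print(x$unit_cell_energy)
  cat(sprintf("  spacing %.2f nm; waist %.2f nm; converged: %s; max violation %.2g nm\n",
              x$spacing, x$waist_radius, x$converged,
              x$max_constraint_violation))
  invisible(x)
}

#' Energy gain of joint tubular wrapping over individual wrapping
#'
#' Difference between the single-wrap minimum energy and the per-particle
#' tubule unit-cell energy, both relative to the same flat reference state:
#' `gain = E_total(single) - E_total(tubule per central particle)`.
#' Positive values mean joint wrapping in a tubule is energetically
#' favorable. Defined in the wrapped regime (`U > U_t`); below threshold
#' the gain is reported as 0 with a warning.
#'
#' @param cond A [binding_condition()].
#' @param n_segments Profile segments for both minimizations.
#' @param seed Integer seed passed to the minimizers.
#' @param control Solver control overrides.
#' @return Gain (kBT, `>= 0`), with attributes `single` and `tubule`
#'   holding the two configurations.
#' @export
tubule_gain <- function(cond, n_segments = 400, seed = 1L,
                        control = list()) {
  stopifnot(inherits(cond, "binding_condition"))
  if (cond$U <= cond$U_t) {
    warning("adhesion below the wrapping threshold; gain undefined, returning 0")
    return(structure(0, single = NULL, tubule = NULL))
  }
  single <- minimize_single_wrap(cond, n_segments = n_segments,
                                 seed = seed, control = control)
  tub <- minimize_tubule(cond, n_segments = n_segments, seed = seed,
                         control = control)
  if (!single$converged || !tub$converged)
    warning("minimizer did not fully converge; gain may be inaccurate")
  gain <- single$energies$E_total - tub$unit_cell_energy$E_total
  if (gain < -0.1)
    warning(sprintf("tubule found less favorable than single wrap by %.3f kBT",
                    -gain))
  structure(max(0, gain), single = single, tubule = tub)
}
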