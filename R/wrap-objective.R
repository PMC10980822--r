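# Internal optimization engine: discretized bending + adhesion energy with
# analytic gradients, plus augmented-Lagrangian penalty plumbing.
#
# The energy of a profile with per-segment tangent angles psi, uniform
# arclength ds and start (x0, z0) is a sum over segment midpoints of
#   e_i = [ (kappa/2) (c1_i + c2_i)^2 + V(l_i) ] * 2*pi*x_i*ds
# with c1 = dpsi/ds (midpoint differences), c2 = sin(psi)/x, and l_i the
# distance from the midpoint to the nearest particle surface. Midpoint
# positions are half-lagged cumulative sums of (cos psi, sin psi), so the
# gradient with respect to psi_k collects a direct curvature part plus
# reverse-cumulative positional parts.

# penalty_fn(xm, zm, ds, psi, rho, dz, sel) -> list(value, dx, dz, dcenters,
# viol): positional derivatives of the penalty, its derivative w.r.t. each
# particle-centre position, and the worst raw constraint violation in nm.
#
# Bending uses the staggered node grid (see bending_energy_discrete);
# adhesion and penalties use segment midpoints.
axisym_engine <- function(psi, ds, x0, z0, kappa, Rp, U, l0, sigma,
                          centers_z, penalty_fn = NULL, want_grad = TRUE) {
  n <- length(psi)
  cp <- cos(psi)
  sp <- sin(psi)
  # segment midpoints (adhesion + penalties)
  P <- cumsum(cp) - cp / 2
  Q <- cumsum(sp) - sp / 2
  xm <- x0 + ds * P
  zm <- z0 + ds * Q
  xfloor <- 1e-4 * ds
  unclamped <- as.numeric(xm >= xfloor)
  xc <- pmax(xm, xfloor)
  a <- 2 * pi * xc * ds

  # nodes 0..n (bending); ends half-weighted with one-sided c1
  xn_all <- c(x0, x0 + ds * cumsum(cp))
  c1i <- diff(psi) / ds
  c1 <- c(c1i[1], c1i, c1i[n - 1L])
  pb <- c(psi[1], (psi[-n] + psi[-1]) / 2, psi[n])
  wts <- c(ds / 2, rep(ds, n - 1L), ds / 2)
  uncl_n <- as.numeric(xn_all >= xfloor)
  xcn <- pmax(xn_all, xfloor)
  spb <- sin(pb)
  cpb <- cos(pb)
  c2 <- ifelse(xn_all < 1e-9, c1, spb / xcn)
  on_ax_n <- xn_all < 1e-9
  K <- c1 + c2
  an <- 2 * pi * pmax(xn_all, 0) * wts # true area weight (0 on axis)
  eb <- 0.5 * kappa * K^2 * an
  E_bend <- sum(eb)

  nc <- length(centers_z)
  if (nc == 1L) {
    dz <- zm - centers_z
    rho <- sqrt(xm^2 + dz^2)
    sel <- rep(1L, n)
  } else {
    dmat <- sqrt(xm^2 + outer(zm, centers_z, "-")^2)
    sel <- max.col(-dmat, ties.method = "first")
    rho <- dmat[cbind(seq_len(n), sel)]
    dz <- zm - centers_z[sel]
  }
  l <- rho - Rp
  V <- -U * exp(-(l - l0)^2 / (2 * sigma^2))
  ea <- V * a
  E_adh <- sum(ea)

  pen <- NULL
  if (!is.null(penalty_fn)) pen <- penalty_fn(xm, zm, ds, psi, rho, dz, sel)
  pen_value <- if (is.null(pen)) 0 else pen$value
  viol <- if (is.null(pen)) 0 else pen$viol
  value <- E_bend + E_adh + pen_value

  if (!want_grad)
    return(list(value = value, E_bend = E_bend, E_adh = E_adh,
                pen = pen_value, viol = viol, xm = xm, zm = zm))

  g <- numeric(n)

  # ---- bending: node-based channels -------------------------------------
  B <- kappa * K * an
  # c1 channel: node j (1..n-1) touches psi_j (-) and psi_{j+1} (+);
  # end copies touch the same pairs as their interior neighbours
  coef1 <- B / ds
  dc1 <- numeric(n) # accumulate +/- onto psi
  # interior nodes j = 1..n-1 are entries 2..n of the padded vectors
  jj <- seq_len(n - 1L)
  bi <- coef1[jj + 1L]
  dc1[jj + 1L] <- dc1[jj + 1L] + bi
  dc1[jj] <- dc1[jj] - bi
  # end node 0 copies c1 of node 1: (psi_2 - psi_1)/ds
  dc1[2] <- dc1[2] + coef1[1]
  dc1[1] <- dc1[1] - coef1[1]
  # end node n copies c1 of node n-1: (psi_n - psi_{n-1})/ds
  dc1[n] <- dc1[n] + coef1[n + 1L]
  dc1[n - 1L] <- dc1[n - 1L] - coef1[n + 1L]
  g <- g + dc1
  # c2 angle channel: d c2/d pb = cos(pb)/xc (off-axis nodes only)
  ang <- ifelse(on_ax_n, 0, B * cpb / xcn)
  g[1] <- g[1] + ang[1] # node 0: pb = psi_1
  g[jj] <- g[jj] + ang[jj + 1L] / 2 # interior: pb = (psi_j + psi_{j+1})/2
  g[jj + 1L] <- g[jj + 1L] + ang[jj + 1L] / 2
  g[n] <- g[n] + ang[n + 1L] # node n: pb = psi_n
  # node-position channel
  Gxn <- 2 * pi * wts * (0.5 * kappa * K^2) * uncl_n -
    ifelse(on_ax_n, 0, B * spb / xcn^2 * uncl_n)
  # node j >= 1 position depends on psi_k for k <= j
  RXn <- rev(cumsum(rev(Gxn[-1]))) # over nodes 1..n, indexed by k
  g <- g - ds * sp * RXn
  g_ds_b <- sum(eb) / ds - sum(B * c1) / ds +
    sum(Gxn[-1] * (xn_all[-1] - x0)) / ds
  g_x0_b <- sum(Gxn)

  # ---- adhesion + penalties: midpoint channels --------------------------
  rho_s <- pmax(rho, 1e-12)
  Vp <- V * (-(l - l0) / sigma^2)
  Gx_e <- 2 * pi * ds * V * unclamped + Vp * (xm / rho_s) * a
  Gz_e <- Vp * (dz / rho_s) * a
  g_centers <- -vapply(seq_len(nc),
                       function(j) sum(Gz_e[sel == j]), numeric(1))
  Gx <- Gx_e
  Gz <- Gz_e
  if (!is.null(pen)) {
    Gx <- Gx + pen$dx
    Gz <- Gz + pen$dz
    g_centers <- g_centers + pen$dcenters
  }
  rx <- rev(cumsum(rev(Gx))) - Gx / 2
  rz <- rev(cumsum(rev(Gz))) - Gz / 2
  g <- g - ds * sp * rx + ds * cp * rz
  g_ds_a <- sum(ea) / ds +
    sum(Gx * (xm - x0)) / ds + sum(Gz * (zm - z0)) / ds
  g_x0_a <- sum(Gx)

  list(value = value, E_bend = E_bend, E_adh = E_adh, pen = pen_value,
       viol = viol, g_psi = g, g_ds = g_ds_b + g_ds_a,
       g_x0 = g_x0_b + g_x0_a, g_centers = g_centers, xm = xm, zm = zm)
}

# Augmented-Lagrangian state shared across inner solves. Constraint
# families:
#   steric   : membrane outside the rigid particle, rho >= Rp
#   waist    : neck radius x >= 2.5 nm (tubule: everywhere; single wrap:
#              past the first overhang, psi > pi/2)
#   pairwise : membrane-midplane self-distance >= 5 nm between contour
#              points separated in arclength (single wrap necks)
new_al_state <- function(n, mu0 = 50, pairwise = FALSE) {
  e <- new.env(parent = emptyenv())
  e$mu <- mu0
  e$lam_steric <- numeric(n)
  e$lam_waist <- numeric(n)
  e$lam_pair <- if (pairwise) matrix(0, n, n) else NULL
  e$idx_gap <- if (pairwise) abs(outer(seq_len(n), seq_len(n), "-")) else NULL
  e$upper <- if (pairwise) upper.tri(matrix(0, n, n)) else NULL
  e$prev_viol <- Inf
  e
}

# raw (unpenalized) constraint violations; used for AL updates and reporting
al_constraints <- function(al, xm, zm, ds, psi, rho, Rp,
                           waist_all, d_min = 5, waist_min = 2.5) {
  n <- length(xm)
  g_steric <- Rp - rho
  if (waist_all) {
    wmask <- rep(TRUE, n)
  } else {
    over <- which(psi > pi / 2)
    wmask <- rep(FALSE, n)
    if (length(over)) wmask[over[1]:n] <- TRUE
  }
  g_waist <- ifelse(wmask, waist_min - xm, -Inf)
  out <- list(g_steric = g_steric, g_waist = g_waist, wmask = wmask)
  if (!is.null(al$lam_pair)) {
    m <- as.integer(ceiling((d_min + 1) / ds)) + 1L
    mask <- al$upper & (al$idx_gap > m)
    dxo <- outer(xm, xm, "-")
    dzo <- outer(zm, zm, "-")
    d <- sqrt(dxo^2 + dzo^2)
    out$pair <- list(mask = mask, d = pmax(d, 1e-9), dxo = dxo, dzo = dzo,
                     g = d_min - d)
  }
  out
}

make_al_penalty <- function(al, Rp, n_centers, waist_all,
                            mu_x = 1e4, d_min = 5, waist_min = 2.5) {
  function(xm, zm, ds, psi, rho, dz, sel) {
    mu <- al$mu
    con <- al_constraints(al, xm, zm, ds, psi, rho, Rp, waist_all, d_min,
                          waist_min)
    n <- length(xm)
    dx <- numeric(n)
    dzv <- numeric(n)
    dcen <- numeric(n_centers)
    value <- 0
    viol <- 0

    # non-negative radius (plain stiff quadratic; rarely active)
    xneg <- pmin(xm, 0)
    value <- value + mu_x * sum(xneg^2)
    dx <- dx + 2 * mu_x * xneg
    viol <- max(viol, -min(0, min(xm)))

    # steric: g = Rp - rho <= 0
    alpha <- pmax(0, al$lam_steric + mu * con$g_steric)
    value <- value + sum(alpha^2 - al$lam_steric^2) / (2 * mu)
    rs <- pmax(rho, 1e-12)
    dx <- dx - alpha * xm / rs
    dzv <- dzv - alpha * dz / rs
    for (j in seq_len(n_centers)) {
      sj <- sel == j
      dcen[j] <- dcen[j] + sum(alpha[sj] * dz[sj] / rs[sj])
    }
    viol <- max(viol, max(0, max(con$g_steric)))

    # waist: g = waist_min - x <= 0 on the neck region
    gw <- ifelse(con$wmask, con$g_waist, 0)
    alpha <- ifelse(con$wmask, pmax(0, al$lam_waist + mu * gw), 0)
    value <- value + sum(alpha^2 - ifelse(con$wmask, al$lam_waist^2, 0)) /
      (2 * mu)
    dx <- dx - alpha
    if (any(con$wmask)) viol <- max(viol, max(0, max(gw[con$wmask])))

    # pairwise self-distance across necks
    if (!is.null(con$pair)) {
      p <- con$pair
      am <- matrix(0, n, n)
      am[p$mask] <- pmax(0, al$lam_pair[p$mask] + mu * p$g[p$mask])
      value <- value + sum(am[p$mask]^2 - al$lam_pair[p$mask]^2) / (2 * mu)
      if (any(am > 0)) {
        ams <- am + t(am)
        dx <- dx - rowSums(ams * p$dxo / p$d)
        dzv <- dzv - rowSums(ams * p$dzo / p$d)
        viol <- max(viol, max(0, max(p$g[p$mask])))
      }
    }

    list(value = value, dx = dx, dz = dzv, dcenters = dcen, viol = viol)
  }
}

al_update <- function(al, xm, zm, ds, psi, rho, Rp, waist_all,
                      d_min = 5, waist_min = 2.5) {
  con <- al_constraints(al, xm, zm, ds, psi, rho, Rp, waist_all, d_min,
                        waist_min)
  mu <- al$mu
  al$lam_steric <- pmax(0, al$lam_steric + mu * con$g_steric)
  al$lam_waist <- ifelse(con$wmask,
                         pmax(0, al$lam_waist + mu * con$g_waist), 0)
  viol <- max(0, max(con$g_steric),
              if (any(con$wmask)) max(con$g_waist[con$wmask]) else 0,
              -min(0, min(xm)))
  if (!is.null(al$lam_pair)) {
    lp <- matrix(0, nrow(al$lam_pair), ncol(al$lam_pair))
    lp[con$pair$mask] <- pmax(0, al$lam_pair[con$pair$mask] +
                                mu * con$pair$g[con$pair$mask])
    al$lam_pair <- lp
    viol <- max(viol, max(0, max(con$pair$g[con$pair$mask])))
  }
  if (viol > 0.25 * al$prev_viol && viol > 1e-7) al$mu <- al$mu * 4
  al$prev_viol <- viol
  viol
}

# Objective for single-particle wrapping. Parameters: psi[1..n-1] (psi_n
# fixed to 0 at the flat outer rim) and the particle height z_c. The
# arclength ds is eliminated by the rim condition sum(ds*cos(psi)) = R_out.
make_single_objective <- function(n, R_out, kappa, Rp, U, l0, sigma,
                                  penalty_fn = NULL) {
  force(penalty_fn)
  function(par, want_grad = TRUE, details = FALSE) {
    psi <- c(par[seq_len(n - 1L)], 0)
    z_c <- par[n]
    cp <- cos(psi)
    C <- sum(cp)
    if (C < 0.05 * n) { # degenerate folding; push back smoothly
      if (!want_grad) return(1e8 * (0.05 * n - C))
      return(list(value = 1e8 * (0.05 * n - C),
                  grad = c(1e8 * sin(psi)[seq_len(n - 1L)], 0)))
    }
    ds <- R_out / C
    eng <- axisym_engine(psi, ds, 0, 0, kappa, Rp, U, l0, sigma,
                         centers_z = z_c, penalty_fn = penalty_fn,
                         want_grad = want_grad)
    if (details) return(c(eng, list(psi = psi, ds = ds, z_c = z_c)))
    if (!want_grad) return(eng$value)
    gpsi <- eng$g_psi + eng$g_ds * ds * sin(psi) / C
    list(value = eng$value, grad = c(gpsi[seq_len(n - 1L)], eng$g_centers))
  }
}

# Objective for the tubule half unit cell. Parameters: psi[2..n-1] (both
# end segments fixed at pi/2: tangent parallel to the axis at the neck
# waist and at the mirror plane through the particle centre), the
# arclength ds and the waist radius x0. The particle centre sits on the
# mirror plane z = z_end; its periodic neighbour is mirrored at -z_end.
make_tubule_objective <- function(n, kappa, Rp, U, l0, sigma,
                                  penalty_fn = NULL) {
  force(penalty_fn)
  function(par, want_grad = TRUE, details = FALSE) {
    psi <- c(pi / 2, par[seq_len(n - 2L)], pi / 2)
    ds <- par[n - 1L]
    x0 <- par[n]
    sp <- sin(psi)
    z_end <- ds * sum(sp)
    eng <- axisym_engine(psi, ds, x0, 0, kappa, Rp, U, l0, sigma,
                         centers_z = c(z_end, -z_end),
                         penalty_fn = penalty_fn, want_grad = want_grad)
    if (details)
      return(c(eng, list(psi = psi, ds = ds, x0 = x0, z_end = z_end)))
    if (!want_grad) return(eng$value)
    W <- eng$g_centers[1] - eng$g_centers[2]
    gpsi <- eng$g_psi + W * ds * cos(psi)
    g_ds <- eng$g_ds + W * z_end / ds
    list(value = eng$value,
         grad = c(gpsi[2:(n - 1L)], g_ds, eng$g_x0))
  }
}

# Analytic trial shapes ------------------------------------------------------

# Single wrap: spherical cap of wrap fraction f around the particle,
# unrolled into a catenoid-like turning arc of radius r_neck, then a flat
# annulus out to R_out. Returns NULL when the construction would cross the
# axis (wrap fractions too close to 1 for the chosen neck radius).
wrap_trial_shape <- function(f, r_w, R_out, n, r_neck = 6) {
  phi <- f * pi
  x_min_turn <- if (phi > pi / 2) (r_w + r_neck) * sin(phi) - r_neck else
    r_w * sin(phi)
  if (x_min_turn < 0.1) return(NULL)
  x_ct <- (r_w + r_neck) * sin(phi)
  if (x_ct >= R_out - 1) return(NULL)
  L1 <- r_w * phi
  L2 <- r_neck * phi
  L <- L1 + L2 + (R_out - x_ct)
  ds <- L / n
  smid <- (seq_len(n) - 0.5) * ds
  psi <- ifelse(smid <= L1, smid / r_w,
                ifelse(smid <= L1 + L2, phi - (smid - L1) / r_neck, 0))
  psi[n] <- 0
  list(psi = psi, ds = ds, z_c = r_w)
}

# Tubule half cell: cylindrical neck at the waist radius a_w, a turning
# arc of radius r_b, then a sphere arc hugging the particle up to its
# equator. Small a_w gives deeply wrapped bulges with thin necks; a_w
# near r_w gives the shallow cooperative states relevant close to the
# wrapping threshold.
tubule_trial_shape <- function(r_b, L_cyl, r_w, a_w, n) {
  sphi <- 1 - (r_w - a_w) / (r_b + r_w)
  if (sphi <= 0 || sphi >= 1) return(NULL)
  phi1 <- asin(sphi)
  L2 <- r_b * (pi / 2 - phi1)
  L3 <- r_w * (pi / 2 - phi1)
  L <- L_cyl + L2 + L3
  ds <- L / n
  smid <- (seq_len(n) - 0.5) * ds
  psi <- ifelse(smid <= L_cyl, pi / 2,
                ifelse(smid <= L_cyl + L2, pi / 2 - (smid - L_cyl) / r_b,
                       phi1 + (smid - L_cyl - L2) / r_w))
  psi[1] <- pi / 2
  psi[n] <- pi / 2
  list(psi = psi, ds = ds, x0 = a_w)
}
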