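# Seeded generators for every pipeline input: affinity panels, binary
# deformation outcome tables with a step around a true threshold, and
# two-channel spot stacks with programmed ground-truth overlap.
#
# All generators are pure functions of (spec, seed): the same seed always
# reproduces the same output.

#' Affinity panel specification
#'
#' A panel of `n_conditions` receptor affinities. Anchored positions carry
#' fixed dissociation constants; the remaining conditions are filled by
#' log-spacing between the neighbouring anchors. The default panel has 7
#' conditions spanning 0.036 nM to 2.3e7 nM (36 pM to 23 mM) with anchors
#' at 0.036, 600, 3800 and 2.3e7 nM; intermediate values are synthetic
#' fill, not measured affinities.
#'
#' @param n_conditions Number of conditions.
#' @param anchors Named numeric vector: names are 1-based positions in the
#'   panel, values the anchored KDs (nM). Must include positions 1 and
#'   `n_conditions` and be strictly increasing.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_conditions = 7,
                       anchors = c("1" = 0.036, "5" = 600, "6" = 3800,
                                   "7" = 2.3e7)) {
  pos <- as.integer(names(anchors))
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE))
    stop("anchor positions must be strictly increasing integers")
  if (is.unsorted(anchors, strictly = TRUE))
    stop("anchor KDs must be strictly increasing")
  if (pos[1] != 1L || pos[length(pos)] != n_conditions)
    stop("anchors must cover the first and last panel positions")
  structure(list(n_conditions = as.integer(n_conditions),
                 anchors = anchors, positions = pos),
            class = "panel_spec")
}

#' Generate an affinity panel
#'
#' Deterministically fills the panel honoring the anchors, with log-spaced
#' KDs between consecutive anchors.
#'
#' @param spec A [panel_spec()].
#' @return data.frame with columns `label`, `kd_nM` and `anchored`.
#' @export
gen_affinity_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  kd <- rep(NA_real_, spec$n_conditions)
  kd[spec$positions] <- spec$anchors
  for (i in seq_len(length(spec$positions) - 1L)) {
    a <- spec$positions[i]
    b <- spec$positions[i + 1L]
    if (b - a > 1L)
      kd[a:b] <- exp(seq(log(kd[a]), log(kd[b]), length.out = b - a + 1L))
  }
  data.frame(label = sprintf("c%02d", seq_len(spec$n_conditions)),
             kd_nM = kd,
             anchored = seq_len(spec$n_conditions) %in% spec$positions)
}

#' Ground truth for simulated deformation outcomes
#'
#' @param kd_threshold True threshold affinity (nM); defaults to the
#'   geometric midpoint of the 600-3800 nM gap.
#' @param p_high,p_low Tubulation probabilities below/above the threshold.
#' @param smoothing Logistic smoothing width in log10-KD units; 0 gives a
#'   hard step.
#' @param n Observations per condition.
#' @return An object of class `outcome_truth`.
#' @export
outcome_truth <- function(kd_threshold = sqrt(600 * 3800), p_high = 0.9,
                          p_low = 0.05, smoothing = 0, n = 50) {
  if (!(p_low >= 0 && p_low <= p_high && p_high <= 1))
    stop("need 0 <= p_low <= p_high <= 1")
  if (n < 1) stop("n must be at least 1")
  if (smoothing < 0) stop("smoothing must be non-negative")
  structure(list(kd_threshold = kd_threshold, p_high = p_high,
                 p_low = p_low, smoothing = smoothing, n = as.integer(n)),
            class = "outcome_truth")
}

#' Simulate a binary deformation outcome table
#'
#' Per condition draws `n_positive ~ Binomial(n, p(KD))` where `p` is
#' `p_high` below the true threshold and `p_low` above (a hard step), or a
#' logistic function of log10(KD) with the given smoothing width.
#'
#' @param panel An affinity panel from [gen_affinity_panel()] (or any
#'   data.frame with `label` and `kd_nM`).
#' @param truth An [outcome_truth()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An outcome table data.frame (`label`, `kd_nM`, `n_observed`,
#'   `n_positive`).
#' @export
simulate_outcomes <- function(panel, truth = outcome_truth(), seed = 1L) {
  stopifnot(inherits(truth, "outcome_truth"),
            all(c("label", "kd_nM") %in% names(panel)))
  p <- if (truth$smoothing == 0) {
    ifelse(panel$kd_nM < truth$kd_threshold, truth$p_high, truth$p_low)
  } else {
    x <- (log10(panel$kd_nM) - log10(truth$kd_threshold)) / truth$smoothing
    truth$p_low + (truth$p_high - truth$p_low) / (1 + exp(x))
  }
  npos <- withr::with_seed(as.integer(seed),
                           stats::rbinom(nrow(panel), truth$n, p))
  data.frame(label = panel$label, kd_nM = panel$kd_nM,
             n_observed = truth$n, n_positive = npos)
}

#' Ground truth for synthetic two-channel spot stacks
#'
#' @param shape Image dimensions in pixels, `c(rows, cols)`.
#' @param n_slices Number of z-slices.
#' @param n_spots Diffraction-limited particle spots per slice.
#' @param amplitude Peak spot intensity above background.
#' @param psf_sd Gaussian point-spread sd (px).
#' @param noise_sd Background Gaussian noise sd.
#' @param overlap Programmed fraction of spots with a co-centered
#'   organelle object, in `[0, 1]`.
#' @param organelle_radius Radius (px) of the disc-shaped organelle
#'   objects.
#' @return An object of class `image_truth`.
#' @export
image_truth <- function(shape = c(96, 96), n_slices = 3, n_spots = 12,
                        amplitude = 10, psf_sd = 1.5, noise_sd = 1,
                        overlap = 0.5, organelle_radius = 4) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (amplitude < 0 || noise_sd < 0)
    stop("amplitude and noise_sd must be non-negative")
  structure(list(shape = as.integer(shape), n_slices = as.integer(n_slices),
                 n_spots = as.integer(n_spots), amplitude = amplitude,
                 psf_sd = psf_sd, noise_sd = noise_sd, overlap = overlap,
                 organelle_radius = organelle_radius),
            class = "image_truth")
}

#' Generate a paired two-channel spot stack with known overlap
#'
#' The particle channel holds Gaussian spots at random well-separated
#' positions; in the organelle channel, a programmed fraction of the spots
#' receives a co-centered disc object. Both channels get Gaussian
#' background noise. Ground-truth masks are returned alongside the images.
#'
#' @param truth An [image_truth()].
#' @param seed Integer seed.
#' @return A list: `particle`, `organelle` (3-D arrays),
#'   `truth_particle_mask`, `truth_organelle_mask` (3-D integer arrays),
#'   and `truth` (the input spec).
#' @export
gen_coloc_stack <- function(truth = image_truth(), seed = 1L) {
  stopifnot(inherits(truth, "image_truth"))
  withr::with_seed(as.integer(seed), {
    nr <- truth$shape[1]
    nc <- truth$shape[2]
    nz <- truth$n_slices
    part <- array(0, c(nr, nc, nz))
    org <- array(0, c(nr, nc, nz))
    pmask <- array(0L, c(nr, nc, nz))
    omask <- array(0L, c(nr, nc, nz))
    margin <- ceiling(4 * truth$psf_sd + truth$organelle_radius) + 1
    min_sep <- 4 * truth$psf_sd + 2 * truth$organelle_radius
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(nz)) {
      centers <- place_spots(truth$n_spots, nr, nc, margin, min_sep)
      n_co <- round(truth$overlap * nrow(centers))
      co <- seq_len(n_co) # first n_co spots carry an organelle partner
      pimg <- matrix(0, nr, nc)
      oimg <- matrix(0, nr, nc)
      pm <- matrix(0L, nr, nc)
      om <- matrix(0L, nr, nc)
      for (i in seq_len(nrow(centers))) {
        d2 <- (rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2
        pimg <- pimg + truth$amplitude * exp(-d2 / (2 * truth$psf_sd^2))
        pm[d2 <= (2 * truth$psf_sd)^2] <- i
        if (i %in% co) {
          oimg[d2 <= truth$organelle_radius^2] <-
            oimg[d2 <= truth$organelle_radius^2] + truth$amplitude
          om[d2 <= truth$organelle_radius^2] <- i
        }
      }
      part[, , k] <- pimg + stats::rnorm(nr * nc, 0, truth$noise_sd)
      org[, , k] <- oimg + stats::rnorm(nr * nc, 0, truth$noise_sd)
      pmask[, , k] <- pm
      omask[, , k] <- om
    }
    list(particle = pmax(part, 0), organelle = pmax(org, 0),
         truth_particle_mask = pmask, truth_organelle_mask = omask,
         truth = truth)
  })
}

# rejection-sample spot centres with a minimum pairwise separation
place_spots <- function(n_spots, nr, nc, margin, min_sep,
                        max_tries = 2000L) {
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centers) < n_spots) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible spot packing: could not place spots with the requested separation")
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
            min_sep^2))
      centers <- rbind(centers, cand)
  }
  centers
}
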