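# Affinity axis: adhesion energy, wrapping state and tubulation gain along
# a KD grid, and change-point inference from binary deformation outcomes.

#' Sweep receptor affinities through the wrapping model
#'
#' For each dissociation constant on the grid, computes the adhesion
#' strength U, the wrapping state (`U` vs the threshold `U_t`), and, where
#' wrapped, the per-central-particle tubulation gain from the constrained
#' shape minimization. The threshold affinity `KD*` separates the two
#' states.
#'
#' @param kd_grid Sorted ascending vector of dissociation constants (nM).
#' @param cond_template A [binding_condition()] supplying `rho`, the
#'   particle and the membrane (its own `KD` is ignored).
#' @param compute_gain If `TRUE`, run the shape minimizers at every wrapped
#'   grid point (can be slow); if `FALSE`, gains are `NA` at wrapped points.
#' @param n_segments,seed,control Passed to [tubule_gain()].
#' @return A data.frame of class `phase_curve` with columns `KD_nM`, `U`,
#'   `state` (`"wrapped"`/`"unwrapped"`), `gain_kBT` and `converged`;
#'   attribute `KD_threshold` holds `KD*`.
#' @export
sweep_affinities <- function(kd_grid, cond_template = binding_condition(1000),
                             compute_gain = TRUE, n_segments = 400,
                             seed = 1L, control = list()) {
  if (is.unsorted(kd_grid, strictly = TRUE))
    stop("kd_grid must be sorted strictly ascending")
  if (any(kd_grid <= 0)) stop("kd_grid must be positive")
  tpl <- cond_template
  rows <- lapply(seq_along(kd_grid), function(i) {
    cond <- binding_condition(kd_grid[i], rho = tpl$rho,
                              particle = tpl$particle,
                              membrane = tpl$membrane,
                              sigma = tpl$potential$sigma)
    wrapped <- cond$U > cond$U_t
    gain <- if (wrapped) NA_real_ else 0
    conv <- TRUE
    if (wrapped && compute_gain) {
      g <- tubule_gain(cond, n_segments = n_segments, seed = seed + i,
                       control = control)
      gain <- as.numeric(g)
      conv <- isTRUE(attr(g, "single")$converged) &&
        isTRUE(attr(g, "tubule")$converged)
    }
    data.frame(KD_nM = kd_grid[i], U = cond$U,
               state = if (wrapped) "wrapped" else "unwrapped",
               gain_kBT = gain, converged = conv)
  })
  out <- do.call(rbind, rows)
  structure(out, KD_threshold = tpl$KD_star,
            class = c("phase_curve", "data.frame"))
}

#' Read / write binary deformation outcome tables
#'
#' CSV format with header `label,kd_nM,n_observed,n_positive`: one row per
#' affinity condition with the number of cells (or vesicles) observed and
#' the number showing tubular membrane invaginations.
#'
#' @param path CSV file path.
#' @return `read_outcome_table`: a validated data.frame.
#' @export
read_outcome_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_outcome_table(df)
}

#' @rdname read_outcome_table
#' @param table An outcome table data.frame.
#' @export
write_outcome_table <- function(table, path) {
  validate_outcome_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

validate_outcome_table <- function(df) {
  need <- c("label", "kd_nM", "n_observed", "n_positive")
  if (!all(need %in% names(df)))
    stop("outcome table needs columns: ", paste(need, collapse = ", "))
  if (any(df$kd_nM <= 0)) stop("kd_nM must be positive")
  if (anyDuplicated(df$kd_nM)) stop("kd_nM values must be distinct")
  if (any(df$n_positive < 0 | df$n_positive > df$n_observed))
    stop("need 0 <= n_positive <= n_observed")
  df
}

#' Maximum-likelihood change-point threshold from binary outcomes
#'
#' Membrane deformation across an affinity panel follows a yes-or-no
#' pattern: high-affinity (low KD) conditions tubulate with probability
#' `p_high`, low-affinity conditions with probability `p_low`. This fits a
#' two-plateau change-point model under independent binomials: for each of
#' the `k - 1` gaps between sorted KDs, `p_high` is the pooled positive
#' rate below the gap and `p_low` the pooled rate above, and the gap
#' maximizing the binomial log-likelihood (among gaps with
#' `p_high >= p_low`) is selected, ties broken toward the lower-KD gap.
#'
#' The threshold is reported as a gap interval, not a point; the point
#' summary `KD_hat` is the geometric mean of the flanking KDs (log-scale
#' symmetry of affinities).
#'
#' @param table An outcome table (see [read_outcome_table()]).
#' @return An object of class `threshold_estimate`: `KD_hat` (nM),
#'   `interval` (flanking observed KDs), `p_high`, `p_low`,
#'   `log_likelihood`.
#' @export
#' @examples
#' tab <- data.frame(label = paste0("c", 1:4), kd_nM = c(10, 600, 3800, 1e6),
#'                   n_observed = 20, n_positive = c(19, 18, 1, 0))
#' estimate_threshold(tab)
estimate_threshold <- function(table) {
  df <- validate_outcome_table(table)
  df <- df[order(df$kd_nM), ]
  k <- nrow(df)
  if (k < 2L) stop("need at least 2 distinct KD conditions")
  if (all(df$n_positive == df$n_observed))
    stop("no change point: all conditions fully positive")
  if (all(df$n_positive == 0))
    stop("no change point: all conditions fully negative")

  best <- NULL
  for (j in seq_len(k - 1L)) {
    lo <- seq_len(j)
    hi <- (j + 1L):k
    p_high <- sum(df$n_positive[lo]) / sum(df$n_observed[lo])
    p_low <- sum(df$n_positive[hi]) / sum(df$n_observed[hi])
    if (p_high < p_low) next # model is a decreasing step
    ll <- sum(stats::dbinom(df$n_positive[lo], df$n_observed[lo], p_high,
                            log = TRUE)) +
      sum(stats::dbinom(df$n_positive[hi], df$n_observed[hi], p_low,
                        log = TRUE))
    if (is.null(best) || ll > best$ll + 1e-12) # ties stay at lower-KD gap
      best <- list(j = j, ll = ll, p_high = p_high, p_low = p_low)
  }
  if (is.null(best))
    stop("no change point: no decreasing split fits the table")
  interval <- c(df$kd_nM[best$j], df$kd_nM[best$j + 1L])
  structure(
    list(KD_hat = sqrt(prod(interval)), interval = interval,
         p_high = best$p_high, p_low = best$p_low,
         log_likelihood = best$ll),
    class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Deformation threshold: KD_hat = %.4g nM (gap %.4g - %.4g nM)\n",
              x$KD_hat, x$interval[1], x$interval[2]))
  cat(sprintf("  plateaus: p_high = %.3f, p_low = %.3f; logLik = %.3f\n",
              x$p_high, x$p_low, x$log_likelihood))
  invisible(x)
}
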