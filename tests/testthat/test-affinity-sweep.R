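test_that("phase curve classifies states with a single transition", {
  panel <- gen_affinity_panel()
  pc <- sweep_affinities(panel$kd_nM, compute_gain = FALSE)
  # exactly one transition, located in the 600-3800 nM gap
  st <- pc$state == "wrapped"
  expect_equal(sum(diff(st) != 0), 1L)
  kd_thr <- attr(pc, "KD_threshold")
  expect_gt(kd_thr, 600)
  expect_lt(kd_thr, 3800)
  expect_true(all(st[pc$KD_nM <= 600]))
  expect_false(any(st[pc$KD_nM >= 3800]))
  # U non-increasing along increasing KD
  expect_true(all(diff(pc$U) <= 0))
})

test_that("grids entirely above rho are fully unwrapped with zero gain", {
  pc <- sweep_affinities(c(2e4, 5e4, 1e5), compute_gain = FALSE)
  expect_true(all(pc$state == "unwrapped"))
  expect_true(all(pc$U == 0))
  expect_true(all(pc$gain_kBT == 0))
})

test_that("phase-curve monotonicity holds across model configurations", {
  kds <- 10^seq(-1, 5, length.out = 12)
  for (kappa in c(10, 20, 40)) {
    for (rho in c(5e3, 16300, 5e4)) {
      tpl <- binding_condition(1000, rho = rho,
                               membrane = membrane_model(kappa = kappa))
      pc <- sweep_affinities(kds, tpl, compute_gain = FALSE)
      expect_true(all(diff(pc$U) <= 0))
      st <- pc$state == "wrapped"
      expect_lte(sum(diff(st) != 0), 1L)
      if (any(st) && any(!st))
        expect_true(all(which(st) < min(which(!st))))
    }
  }
})

test_that("sweep gains match an independent minimizer recomputation", {
  grid <- c(600, 5000) # one wrapped, one unwrapped point
  pc <- suppressWarnings(
    sweep_affinities(grid, compute_gain = TRUE, n_segments = 96,
                     seed = 10, control = fast_ctrl))
  expect_equal(pc$state, c("wrapped", "unwrapped"))
  expect_equal(pc$gain_kBT[2], 0)
  direct <- suppressWarnings(
    as.numeric(tubule_gain(binding_condition(600), n_segments = 96,
                           seed = 10 + 1, control = fast_ctrl)))
  expect_equal(pc$gain_kBT[1], direct, tolerance = 1e-6)
  expect_gt(pc$gain_kBT[1], 0)
})

test_that("sweep rejects malformed grids", {
  expect_error(sweep_affinities(c(10, 5, 100)), "ascending")
  expect_error(sweep_affinities(c(-1, 5)), "ascending|positive")
})

make_table <- function(kds, npos, n = 20) {
  data.frame(label = paste0("c", seq_along(kds)), kd_nM = kds,
             n_observed = n, n_positive = npos)
}

test_that("perfect step recovers the printed gap", {
  kds <- c(0.036, 1, 30, 200, 600, 3800, 2.3e7)
  tab <- make_table(kds, c(rep(20, 5), 0, 0))
  est <- estimate_threshold(tab)
  expect_equal(est$interval, c(600, 3800))
  expect_equal(est$KD_hat, sqrt(600 * 3800))
  expect_equal(est$p_high, 1)
  expect_equal(est$p_low, 0)
})

test_that("two conditions give the unique gap", {
  est <- estimate_threshold(make_table(c(100, 1e4), c(18, 2)))
  expect_equal(est$interval, c(100, 1e4))
})

test_that("degenerate tables raise explicit no-change-point errors", {
  expect_error(estimate_threshold(make_table(c(1, 10, 100), c(20, 20, 20))),
               "no change point")
  expect_error(estimate_threshold(make_table(c(1, 10, 100), c(0, 0, 0))),
               "no change point")
  expect_error(estimate_threshold(make_table(100, 10)), "at least 2")
})

test_that("estimator equals an exhaustive brute-force likelihood scan", {
  # independent oracle: plain loop over every split, recomputing pooled
  # rates and binomial log-likelihoods from scratch
  brute <- function(tab) {
    tab <- tab[order(tab$kd_nM), ]
    k <- nrow(tab)
    best_ll <- -Inf
    best_j <- NA
    for (j in 1:(k - 1)) {
      ph <- sum(tab$n_positive[1:j]) / sum(tab$n_observed[1:j])
      pl <- sum(tab$n_positive[(j + 1):k]) / sum(tab$n_observed[(j + 1):k])
      if (ph < pl) next
      ll <- 0
      for (i in 1:k) {
        p <- if (i <= j) ph else pl
        ll <- ll + dbinom(tab$n_positive[i], tab$n_observed[i], p,
                          log = TRUE)
      }
      if (ll > best_ll + 1e-12) {
        best_ll <- ll
        best_j <- j
      }
    }
    list(interval = c(tab$kd_nM[best_j], tab$kd_nM[best_j + 1]),
         ll = best_ll)
  }
  set.seed(42)
  kds <- 10^seq(-1, 6, length.out = 8)
  for (rep in 1:25) {
    npos <- rbinom(8, 30, sort(runif(8, 0.02, 0.95), decreasing = TRUE))
    tab <- make_table(kds, npos, n = 30)
    if (all(npos == 0) || all(npos == 30)) next
    est <- estimate_threshold(tab)
    or <- brute(tab)
    expect_equal(est$interval, or$interval)
    expect_equal(est$log_likelihood, or$ll, tolerance = 1e-10)
  }
})

test_that("estimate brackets its point summary", {
  est <- estimate_threshold(make_table(c(10, 600, 3800, 1e6),
                                       c(19, 18, 2, 1)))
  expect_gte(est$KD_hat, est$interval[1])
  expect_lte(est$KD_hat, est$interval[2])
  expect_gte(est$p_high, est$p_low)
})

test_that("outcome tables round-trip through CSV", {
  tab <- make_table(c(1, 100, 1e4), c(18, 15, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcome_table(tab, path)
  back <- read_outcome_table(path)
  expect_equal(back$n_positive, tab$n_positive)
  expect_equal(back$kd_nM, tab$kd_nM)
  expect_error(write_outcome_table(make_table(c(1, 1), c(1, 1)), path),
               "distinct")
})
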