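fake_fit <- function(loglik, k, n_cells = 2, n_transitions = 100,
                     converged = TRUE) {
  structure(list(loglik = loglik, n_params = k, converged = converged,
                 n_cells = n_cells, n_transitions = n_transitions),
            class = "gn_fit")
}

test_that("score_model arithmetic identities hold exactly", {
  s <- score_model(fake_fit(-100, 10))
  expect_equal(s$aic, 220)
  expect_equal(s$loglik_akaike, -110)
  expect_equal(s$neg_ll_per_cell_bin, 100 / (2 * 100))
  expect_equal(score_model(fake_fit(0, 0))$aic, 0)
  # property: identities for arbitrary values
  set.seed(90)
  for (r in 1:20) {
    ll <- rnorm(1, -500, 200); k <- sample(1:50, 1)
    s <- score_model(fake_fit(ll, k))
    expect_equal(s$aic, -2 * ll + 2 * k)
    expect_equal(s$loglik_akaike, ll - k)
    expect_equal(s$aic, -2 * s$loglik_akaike)
  }
  expect_warning(score_model(fake_fit(-10, 1, converged = FALSE)),
                 "non-converged")
})

test_that("pair partitions are disjoint, exhaustive, balanced, and reproducible", {
  p <- pair_partition(1001, fraction = 0.5, seed = 4)
  expect_length(intersect(p$train, p$test), 0)
  expect_setequal(c(p$train, p$test), 1:1000)
  expect_lte(abs(length(p$train) - length(p$test)), 1)
  for (s in 1:20)
    expect_identical(pair_partition(500, seed = s), pair_partition(500, seed = s))
  expect_error(pair_partition(1), "two time bins")
})

test_that("adding covariates never decreases training lnL but can lose after the penalty", {
  pop <- pop_20min()
  r <- pop$raster
  T_ <- ncol(r$S)
  d0 <- ki_design(design_constant(T_))
  d1 <- ki_design(design_constant(T_), design_box(pop$trajectory, 4))
  f0 <- ki_fit(r, d0, couplings = FALSE)
  f1 <- ki_fit(r, d1, couplings = FALSE)
  expect_gte(f1$loglik, f0$loglik) # nesting, 2*delta lnL >= 0
  # irrelevant covariates can lose on the corrected likelihood: add pure
  # noise columns
  set.seed(91)
  noise_comp <- gridnet:::new_component("noise", matrix(rnorm(T_ * 30), T_))
  dn <- ki_design(design_constant(T_), noise_comp)
  fn <- ki_fit(r, dn, couplings = FALSE)
  expect_gte(fn$loglik, f0$loglik)
  expect_lt(score_model(fn)$loglik_akaike, score_model(f0)$loglik_akaike)
})

test_that("cross-half likelihood prefers couplings on coupled data and overfits in the expected direction", {
  pop <- pop_coupled()
  r <- pop$raster
  d <- ki_design(design_constant(ncol(r$S)))
  with_c <- cross_half_likelihood(r, d, couplings = TRUE, seed = 5,
                                  label = "couplings")
  no_c <- cross_half_likelihood(r, d, couplings = FALSE, seed = 5,
                                label = "fields only")
  expect_gt(with_c$loglik_akaike, no_c$loglik_akaike)
  # held-out lnL below training lnL on the same number of transitions
  # (median over seeds)
  diffs <- vapply(1:5, function(s) {
    ch <- cross_half_likelihood(r, d, couplings = TRUE, seed = s)
    ch$fit$loglik - ch$loglik_heldout_raw
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("coupling stability PCCs behave at the identical, null, and modular extremes", {
  set.seed(92)
  J <- matrix(rnorm(144), 12, 12)
  cs <- coupling_stability(J, J)
  expect_equal(cs$pcc[cs$subset == "all"], 1)
  expect_equal(cs$pcc[cs$subset == "self"], 1)
  # independent matrices: PCC near zero
  J2 <- matrix(rnorm(144), 12, 12)
  cs0 <- coupling_stability(J, J2)
  expect_lt(abs(cs0$pcc[cs0$subset == "all"]),
            4 / sqrt(cs0$n[cs0$subset == "all"]))
  # module subsets partition the off-diagonal pairs with known labels
  mods <- rep(1:3, each = 4)
  csm <- coupling_stability(J, J2, modules = mods)
  expect_equal(csm$n[csm$subset == "within_module"], 3 * 4 * 3)
  expect_equal(csm$n[csm$subset == "between_module"], 12 * 11 - 36)
  # NA modules drop their pairs from both subsets
  mods_na <- mods; mods_na[1] <- NA
  csn <- coupling_stability(J, J2, modules = mods_na)
  expect_equal(csn$n[csn$subset == "within_module"], 3 * 2 + 2 * (4 * 3))
  expect_error(coupling_stability(J, J2[1:4, 1:4]), "same shape")
  # < 3 entries: NA
  small <- coupling_stability(matrix(1:4, 2), matrix(4:1, 2))
  expect_true(is.na(small$pcc[small$subset == "all"]))
})

test_that("half-data coupling fits are more stable for self than for cross couplings", {
  pop <- pop_coupled()
  r <- pop$raster
  d <- ki_design(design_constant(ncol(r$S)))
  part <- pair_partition(r, seed = 6)
  J1 <- ki_fit(r, d, pairs = part$train)$J
  J2 <- ki_fit(r, d, pairs = part$test)$J
  cs <- coupling_stability(J1, J2)
  expect_gt(cs$pcc[cs$subset == "all"], 0)
  # the true couplings are recoverable, so the halves agree strongly
  expect_gt(cs$pcc[cs$subset == "all"], 0.5)
})

test_that("module variance test matches the F closed form and is calibrated", {
  # construct couplings with exactly the reported group s.d.s
  set.seed(93)
  scale_sd <- function(x, s) s * x / sd(x)
  n <- 20
  mods <- rep(1:2, each = 10)
  off <- !diag(TRUE, n)
  same <- outer(mods, mods, "==")
  J <- matrix(0, n, n)
  J[off & same] <- scale_sd(rnorm(sum(off & same)), 0.13)
  J[off & !same] <- scale_sd(rnorm(sum(off & !same)), 0.09)
  vt <- module_variance_test(J, mods)
  expect_equal(vt$F, (0.13 / 0.09)^2, tolerance = 1e-12)
  expect_lt(vt$p, 0.001)
  expect_equal(vt$var_within, 0.13^2, tolerance = 1e-12)
  # equal variances give F = 1
  J1 <- matrix(0, n, n)
  vals <- scale_sd(rnorm(n * n), 0.1)
  J1[off & same] <- scale_sd(rnorm(sum(off & same)), 0.1)
  J1[off & !same] <- scale_sd(rnorm(sum(off & !same)), 0.1)
  expect_equal(module_variance_test(J1, mods)$F, 1, tolerance = 1e-12)
  expect_error(module_variance_test(J, rep(1, n)), "two modules")
  # calibration: all couplings from one normal population -> rejection
  # rate ~ alpha
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    Jn <- matrix(rnorm(100), 10, 10)
    module_variance_test(Jn, rep(1:2, each = 5))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("pair filters respect precession and tetrode metadata", {
  pairs <- expand.grid(i = 1:4, j = 1:4)
  pairs <- pairs[pairs$i < pairs$j, ]
  # no flags: identity
  expect_identical(pair_filters(pairs), pairs)
  prec <- c(TRUE, TRUE, FALSE, FALSE)
  f1 <- pair_filters(pairs, precessing = prec, exclude_precessing = TRUE)
  # only the (1,2) pair has both cells precessing
  expect_equal(nrow(f1), nrow(pairs) - 1)
  expect_false(any(f1$i == 1 & f1$j == 2))
  tet <- c(1, 1, 2, 2)
  f2 <- pair_filters(pairs, tetrode = tet, exclude_same_tetrode = TRUE)
  expect_true(all(tet[f2$i] != tet[f2$j]))
  expect_equal(nrow(f2), 4)
  # all cells precessing: empty result, still a data.frame
  f3 <- pair_filters(pairs, precessing = rep(TRUE, 4),
                     exclude_precessing = TRUE)
  expect_equal(nrow(f3), 0)
  expect_error(pair_filters(pairs, exclude_precessing = TRUE), "precessing")
  expect_error(pair_filters(pairs, exclude_same_tetrode = TRUE), "tetrode")
})

test_that("filtered coupling regression keeps the generative negative slope", {
  pop <- pop_coupled()
  td <- true_phase_distances(pop$truth$cells)
  r <- pop$raster
  d <- ki_design(design_constant(ncol(r$S)))
  J <- ki_fit(r, d)$J
  Jsym <- (J[cbind(td$i, td$j)] + J[cbind(td$j, td$i)]) / 2
  # mark a third of the cells "precessing" and split cells over tetrodes
  set.seed(94)
  n <- nrow(pop$truth$cells)
  prec <- seq_len(n) %in% sample(n, ceiling(n / 3))
  tet <- rep(1:3, length.out = n)
  td$J <- Jsym
  kept <- pair_filters(td, precessing = prec, tetrode = tet,
                       exclude_precessing = TRUE,
                       exclude_same_tetrode = TRUE)
  expect_lt(nrow(kept), nrow(td))
  reg <- correlation_vs_phase_regression(kept$J, kept$d)
  expect_lt(reg["slope", "estimate"], 0)
  expect_lt(reg["slope", "p"], 0.01)
})
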