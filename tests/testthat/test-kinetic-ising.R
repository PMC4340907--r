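# small random raster + design for oracle checks
rand_instance <- function(n_cells, T_, p_extra = 2, seed = 1) {
  set.seed(seed)
  S <- matrix(sample(c(-1L, 1L), n_cells * T_, replace = TRUE), n_cells, T_)
  raster <- structure(list(S = S, bin_width_s = 0.01, t0 = 0,
                           cell_ids = seq_len(n_cells)),
                      class = "gn_raster")
  X <- cbind(1, matrix(rnorm(T_ * p_extra), T_, p_extra))
  design <- structure(list(X = X, p = ncol(X),
                           components = data.frame(name = "rand", start = 1L,
                                                   end = ncol(X))),
                      class = "gn_design")
  alpha <- matrix(rnorm(n_cells * ncol(X), 0, 0.4), n_cells, ncol(X))
  J <- matrix(rnorm(n_cells^2, 0, 0.3), n_cells, n_cells)
  list(raster = raster, design = design, alpha = alpha, J = J)
}

test_that("box design is one-hot with the documented box counts", {
  traj <- simulate_trajectory(20, 0.01, 150, seed = 40)
  b4 <- design_box(traj, 4)
  expect_equal(ncol(b4$X), 16) # 37.5 cm boxes on a 150 cm arena
  expect_true(all(rowSums(b4$X) == 1))
  expect_true(all(b4$X %in% c(0, 1)))
  b20 <- design_box(traj, 20)
  expect_equal(ncol(b20$X), 400) # 7.5 cm boxes
  # K = 1 reduces to the constant field
  expect_equal(design_box(traj, 1)$X, design_constant(nrow(traj))$X)
  expect_error(design_box(traj, 0), ">= 1")
})

test_that("gaussian spatial design matches its closed form at the centers", {
  traj <- simulate_trajectory(5, 0.01, 150, seed = 41)
  g <- design_gaussian_spatial(traj, M = 15, r_cm = 8.5)
  expect_equal(ncol(g$X), 225)
  ctr <- attr(g$X, "centers")
  # place the animal exactly on a basis center: that covariate is 1
  traj2 <- traj
  traj2$x[] <- ctr[17, 1]; traj2$y[] <- ctr[17, 2]
  g2 <- design_gaussian_spatial(traj2, M = 15, r_cm = 8.5)
  expect_equal(g2$X[1, 17], 1)
  # kernel uses r^2 (not 2 r^2) in the denominator
  traj2$x[] <- ctr[17, 1] + 8.5
  g3 <- design_gaussian_spatial(traj2, M = 15, r_cm = 8.5)
  expect_equal(g3$X[1, 17], exp(-1))
})

test_that("angular design wraps, hits 1 at centers, and uses minimal angular distance", {
  a <- design_angular(c(-pi + 0.1, 0, 1), n_centers = 10)
  expect_equal(ncol(a$X), 10)
  ctr <- attr(a$X, "centers")
  expect_equal(a$X[1, which.min(abs(ctr - (-pi + 0.1)))],
               exp(-angular_distance(-pi + 0.1, ctr[1])^2 / (pi / 6)^2))
  # a center angle scores exactly 1
  aa <- design_angular(ctr[3], n_centers = 10)
  expect_equal(aa$X[1, 3], 1)
  # adding 2*pi wraps (with a warning) to the identical row
  expect_warning(b <- design_angular(c(-pi + 0.1 + 2 * pi, 0, 1)),
                 "wrapped")
  expect_equal(b$X, a$X)
  # minimal angular distance across the wrap: d(pi-0.1, -pi+0.1) = 0.2,
  # matching a brute-force search over 2*pi shifts
  brute <- min(abs((pi - 0.1) - (-pi + 0.1) + 2 * pi * (-2:2)))
  expect_equal(angular_distance(pi - 0.1, -pi + 0.1), 0.2, tolerance = 1e-12)
  expect_equal(angular_distance(pi - 0.1, -pi + 0.1), brute)
})

test_that("speed covariate averages a centred 100 ms window with edge truncation", {
  tr <- data.frame(t = seq(0, 0.2, by = 0.01), x = 0, y = 0,
                   head_direction = 0, speed = seq(0, 20, length.out = 21))
  attr(tr, "dt") <- 0.01
  class(tr) <- c("gn_trajectory", "data.frame")
  sp <- design_speed(tr)$X[, 1]
  # linear ramp: interior windows average to the midpoint value
  expect_equal(sp[11], tr$speed[11])
  expect_equal(sp[6:16], tr$speed[6:16])
  # edge bins truncate the window (mean of samples 1..6 at the left edge)
  expect_equal(sp[1], mean(tr$speed[1:6]))
  # constant speed gives a constant covariate
  tr$speed <- 12
  expect_true(all(design_speed(tr)$X == 12))
})

test_that("conditional probability and total field match closed forms and a double-loop oracle", {
  expect_equal(conditional_prob(1, 0), 0.5)
  expect_equal(conditional_prob(-1, 0), 0.5)
  H <- seq(-30, 30, by = 0.7)
  expect_equal(conditional_prob(1, H) + conditional_prob(-1, H),
               rep(1, length(H)))
  expect_equal(round(conditional_prob(1, 0.5), 5), 0.73106)
  set.seed(42)
  n <- 4; T_ <- 6
  h <- matrix(rnorm(n * T_), n, T_)
  J <- matrix(rnorm(n * n), n, n)
  S <- matrix(sample(c(-1, 1), n * T_, replace = TRUE), n, T_)
  H2 <- total_field(h, J, S)
  oracle <- h
  for (i in seq_len(n)) for (t in seq_len(T_)) for (j in seq_len(n))
    oracle[i, t] <- oracle[i, t] + J[i, j] * S[j, t]
  expect_equal(max(abs(H2 - oracle)), 0, tolerance = 1e-12)
  expect_equal(total_field(h, matrix(0, n, n), S), h)
  expect_equal(total_field(h * 0, J, matrix(1, n, T_))[, 1], rowSums(J))
  expect_error(total_field(h, J[1:3, 1:3], S), "mismatch")
})

test_that("log-likelihood matches hand evaluation and exhaustive enumeration", {
  r1 <- structure(list(S = matrix(c(1L, -1L), 1, 2), bin_width_s = 0.01,
                       t0 = 0, cell_ids = 1L), class = "gn_raster")
  d1 <- structure(list(X = matrix(1, 2, 1), p = 1,
                       components = data.frame(name = "constant", start = 1L,
                                               end = 1L)),
                  class = "gn_design")
  expect_equal(ki_loglik(r1, d1, alpha = matrix(0, 1, 1)), -log(2))
  # random 2-neuron, T = 3 instance vs. per-bin probability product
  inst <- rand_instance(2, 3, seed = 43)
  ll <- ki_loglik(inst$raster, inst$design, inst$alpha, inst$J)
  H <- inst$alpha %*% t(inst$design$X) + inst$J %*% inst$raster$S
  ll_oracle <- 0
  for (i in 1:2) for (t in 1:2)
    ll_oracle <- ll_oracle +
      log(conditional_prob(inst$raster$S[i, t + 1], H[i, t]))
  expect_equal(ll, ll_oracle, tolerance = 1e-12)
  # identity: sum of log conditional probabilities on a bigger instance
  inst2 <- rand_instance(3, 50, seed = 44)
  H2 <- inst2$alpha %*% t(inst2$design$X) + inst2$J %*% inst2$raster$S
  expect_equal(
    ki_loglik(inst2$raster, inst2$design, inst2$alpha, inst2$J),
    sum(log(conditional_prob(inst2$raster$S[, -1], H2[, -50]))),
    tolerance = 1e-10)
  bad <- inst2$raster; bad$S[1, 1] <- 0L
  expect_error(ki_loglik(bad, inst2$design, inst2$alpha), "-1 or \\+1")
})

test_that("analytic gradient matches central finite differences and closed-form stationarity", {
  inst <- rand_instance(3, 120, seed = 45)
  g <- ki_gradient(inst$raster, inst$design, inst$alpha, inst$J)
  eps <- 1e-5
  fd <- function(bump) {
    (do.call(ki_loglik, bump(eps)) - do.call(ki_loglik, bump(-eps))) /
      (2 * eps)
  }
  for (probe in list(c(1, 1), c(2, 3), c(3, 2))) {
    fd_a <- fd(function(e) {
      a <- inst$alpha; a[probe[1], probe[2]] <- a[probe[1], probe[2]] + e
      list(inst$raster, inst$design, a, inst$J)
    })
    expect_equal(g$alpha[probe[1], probe[2]], fd_a, tolerance = 1e-5)
    fd_j <- fd(function(e) {
      J <- inst$J; J[probe[1], probe[2]] <- J[probe[1], probe[2]] + e
      list(inst$raster, inst$design, inst$alpha, J)
    })
    expect_equal(g$J[probe[1], probe[2]], fd_j, tolerance = 1e-5)
  }
  # at the uncoupled ML solution h_i = atanh(mean S_i(t+1)), the constant-
  # field gradient vanishes
  S <- inst$raster$S
  d1 <- structure(list(X = matrix(1, 120, 1), p = 1,
                       components = data.frame(name = "constant", start = 1L,
                                               end = 1L)),
                  class = "gn_design")
  hhat <- matrix(atanh(rowMeans(S[, -1])), 3, 1)
  g0 <- ki_gradient(inst$raster, d1, hhat)
  expect_lt(max(abs(g0$alpha)), 1e-9)
  # zero residuals give a zero J gradient: saturate the field toward the
  # realized next states
  alpha_sat <- matrix(0, 3, ncol(inst$design$X))
  r_det <- inst$raster
  r_det$S <- rbind(S[1, ], S[2, ], S[3, ])
  Hbig <- 40 * r_det$S[, -1, drop = FALSE]
  # direct residual check through the exported gradient: with H = +-40 and
  # matching signs, tanh(H) equals S(t+1) to machine precision
  U <- r_det$S[, -1] - tanh(Hbig)
  expect_lt(max(abs(U)), 1e-12)
})

test_that("ki_fit agrees with glm logistic regression on every coefficient", {
  inst <- rand_instance(3, 2000, seed = 46)
  # resample states from an actual model so the fit is well-posed
  h <- inst$alpha %*% t(inst$design$X)
  r <- sample_kinetic_ising(h, inst$J * 0.5, seed = 47)
  fit <- ki_fit(r, inst$design)
  expect_true(fit$converged)
  ll_glm <- 0
  for (i in 1:3) {
    y01 <- (r$S[i, -1] + 1) / 2
    W <- cbind(inst$design$X[-2000, ], t(r$S[, -2000, drop = FALSE]))
    gf <- suppressWarnings(
      glm.fit(2 * W, y01, family = binomial(), intercept = FALSE))
    theta_glm <- gf$coefficients
    expect_equal(unname(c(fit$alpha[i, ], fit$J[i, ])), unname(theta_glm),
                 tolerance = 1e-5)
    p_hat <- gf$fitted.values
    ll_glm <- ll_glm + sum(log(ifelse(y01 == 1, p_hat, 1 - p_hat)))
  }
  expect_equal(fit$loglik, ll_glm, tolerance = 1e-6)
})

test_that("constant field maximum likelihood lands within 3 SE of the truth", {
  h_true <- 0.2
  T_ <- 1e6
  r <- sample_kinetic_ising(matrix(h_true, 1, T_), matrix(0, 1, 1),
                            seed = 48)
  fit <- ki_fit(r, ki_design(design_constant(T_)), couplings = FALSE)
  se <- 1 / sqrt((T_ - 1) * (1 - tanh(h_true)^2)) # Fisher information
  expect_lt(abs(fit$alpha[1, 1] - h_true), 3 * se)
})

test_that("couplings are recovered from long synthetic runs (PCC >= 0.95)", {
  rec <- ji_recovery()
  expect_true(rec$fit$converged)
  pcc <- cor(as.vector(rec$fit$J), as.vector(rec$J_true))
  expect_gte(pcc, 0.95)
  # fields land within 4 observed-information standard errors of truth
  S <- rec$raster$S
  T_ <- ncol(S)
  W <- cbind(1, t(S[, -T_, drop = FALSE]))
  for (i in seq_len(nrow(S))) {
    H <- as.vector(W %*% c(rec$fit$alpha[i, 1], rec$fit$J[i, ]))
    info <- crossprod(W, W * (1 - tanh(H)^2))
    se_h <- sqrt(solve(info)[1, 1])
    expect_lt(abs(rec$fit$alpha[i, 1] - rec$h_true[i]), 4 * se_h)
  }
})

test_that("nested models never lose training likelihood and self-couplings can be dropped", {
  inst <- rand_instance(3, 1500, seed = 49)
  h <- inst$alpha %*% t(inst$design$X)
  r <- sample_kinetic_ising(h, inst$J * 0.4, seed = 50)
  d <- inst$design
  f0 <- ki_fit(r, d, couplings = FALSE)
  f1 <- ki_fit(r, d, couplings = TRUE, self_couplings = FALSE)
  f2 <- ki_fit(r, d, couplings = TRUE)
  expect_gte(f1$loglik, f0$loglik)
  expect_gte(f2$loglik, f1$loglik)
  expect_true(all(diag(f1$J) == 0))
  expect_equal(f1$n_params, 3 * ncol(d$X) + 3 * 2)
  # degenerate input: a cell that never spikes warns about an unbounded
  # field, and ridge keeps it finite
  r2 <- r; r2$S[1, ] <- -1L
  expect_warning(ki_fit(r2, ki_design(design_constant(1500)),
                        couplings = FALSE), "never spikes")
  fr <- suppressWarnings(ki_fit(r2, ki_design(design_constant(1500)),
                                couplings = FALSE, lambda = 1e-3))
  expect_true(is.finite(fr$alpha[1, 1]))
})

test_that("the fitted gaussian-field model reproduces a grid cell's rate map", {
  # a 40-minute, 5 Hz session: the 225-coefficient spatial field needs
  # enough spikes that the check probes bias, not estimation noise
  cells <- single_module_cells(1, seed = 105)
  cells$mean_rate <- 5
  pop <- generate_population(list(cells = cells, duration_s = 2400,
                                  dt_s = 0.01, mode = "rate_bernoulli"),
                             seed = 15)
  traj <- pop$trajectory
  des <- ki_design(design_constant(nrow(traj)),
                   design_gaussian_spatial(traj, 15, 8.5))
  fit <- ki_fit(pop$raster, des, couplings = FALSE)
  expect_true(fit$converged)
  # model-predicted rate per 3 cm spatial bin vs the generator's true rate
  p_spike <- conditional_prob(1, as.vector(fit$alpha %*% t(des$X)))
  pred_rate <- -log(1 - pmin(p_spike, 1 - 1e-12)) / 0.01
  bx <- pmin(floor(traj$x / 3) + 1, 50); by <- pmin(floor(traj$y / 3) + 1, 50)
  bin <- (by - 1) * 50 + bx
  pred_map <- tapply(pred_rate, bin, mean)
  cells <- pop$truth$cells
  true_rate <- grid_rate(as.list(cells[1, ]), traj$x, traj$y)
  true_map <- tapply(true_rate, bin, mean)
  expect_gt(cor(pred_map, true_map), 0.9)
})
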