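# shared fixtures, built once per session and cached across test files
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# random spatial phases inside one lattice unit cell
random_phases <- function(n, spacing, orientation) {
  B <- gridnet:::hex_basis(spacing, orientation)
  uv <- matrix(runif(2 * n), n, 2)
  uv %*% t(B)
}

# a single-module cell table in the style of a small grid-cell recording
single_module_cells <- function(n = 8, spacing = 46.4, orientation = 31.5,
                                mean_rate = 2.4, seed = 100) {
  set.seed(seed)
  ph <- random_phases(n, spacing, orientation)
  data.frame(spacing = spacing, orientation = orientation,
             phase_x = ph[, 1], phase_y = ph[, 2],
             peak_rate = 15, mean_rate = mean_rate, module = 1L)
}

# three modules with the spacing/orientation statistics of a large MEC
# recording (46.4/54.9/93.2 cm; 31.5/27.6/35.0 deg)
three_module_cells <- function(seed = 101) {
  set.seed(seed)
  specs <- list(c(8, 46.4, 31.5), c(7, 54.9, 27.6), c(7, 93.2, 35.0))
  do.call(rbind, lapply(seq_along(specs), function(m) {
    s <- specs[[m]]
    cells <- single_module_cells(s[1], s[2], s[3], seed = seed + m)
    cells$spacing <- s[2] + rnorm(s[1], 0, 0.02 * s[2])
    cells$orientation <- s[3] + rnorm(s[1], 0, 0.8)
    cells$module <- m
    cells
  }))
}

# 20-minute single-module session, rate-driven spiking
pop_20min <- function() fixture("pop_20min", function() {
  generate_population(list(cells = single_module_cells(6, seed = 100),
                           duration_s = 1200, dt_s = 0.01,
                           mode = "rate_bernoulli"),
                      seed = 7)
})

# 20-minute three-module session for geometry round trips
pop_modules <- function() fixture("pop_modules", function() {
  generate_population(list(cells = three_module_cells(101),
                           duration_s = 1200, dt_s = 0.01,
                           mode = "rate_bernoulli"),
                      seed = 8)
})

# rate maps for the three-module session
maps_modules <- function() fixture("maps_modules", function() {
  pop <- pop_modules()
  lapply(seq_len(nrow(pop$truth$cells)), function(i)
    compute_rate_map(pop$spikes, pop$trajectory, cell = i, bin_cm = 3))
})

# Mexican-hat coupling profile keyed to normalized phase distance
mexican_hat_J <- function(cells, a = 0.35, sig1 = 0.18, b = 0.12,
                          sig2 = 0.45) {
  n <- nrow(cells)
  J <- matrix(0, n, n)
  sp <- mean(cells$spacing); or <- mean(cells$orientation)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    off <- c(cells$phase_x[i] - cells$phase_x[j],
             cells$phase_y[i] - cells$phase_y[j])
    d <- normalized_phase_distance(off, sp, or)
    J[i, j] <- a * exp(-(d / sig1)^2) - b * exp(-(d / sig2)^2)
  }
  J
}

# 20-minute single-module session driven by the kinetic Ising model with
# Mexican-hat ground-truth couplings (the generative version of the
# phase-dependent connectivity headline)
pop_coupled <- function() fixture("pop_coupled", function() {
  cells <- single_module_cells(12, seed = 103)
  J <- mexican_hat_J(cells)
  generate_population(list(cells = cells, duration_s = 1200, dt_s = 0.01,
                           mode = "kinetic_ising", J = J),
                      seed = 9)
})

# smoothed rates and visit table for the coupled session
visits_coupled <- function() fixture("visits_coupled", function() {
  pop <- pop_coupled()
  rates <- smooth_rates(pop$spikes, t_range = c(0, 1200),
                        n_cells = nrow(pop$truth$cells))
  segment_visits(pop$trajectory, 20, rates)
})

# noise correlations of the coupled session
noisecorr_coupled <- function() fixture("noisecorr_coupled", function() {
  noise_correlation_matrix(visits_coupled())
})

# constant-field coupling recovery at T = 5e5 (shared with the acceptance
# suite): data sampled from known (h, J), refit with constant fields
ji_recovery <- function() fixture("ji_recovery", function() {
  set.seed(13)
  n <- 10
  T_ <- 5e5
  J <- matrix(rnorm(n * n, 0, 0.3), n, n)
  p <- 1 - exp(-2.4 * 0.01)
  h <- matrix(atanh(2 * p - 1), n, T_)
  raster <- sample_kinetic_ising(h, J, seed = 14)
  fit <- ki_fit(raster, ki_design(design_constant(T_)))
  list(J_true = J, h_true = h[, 1], fit = fit, raster = raster)
})

# a small raster holding only one cell of a population raster
single_cell_raster <- function(raster, cell) {
  raster$S <- raster$S[cell, , drop = FALSE]
  if (!is.null(raster$cell_ids)) raster$cell_ids <- raster$cell_ids[cell]
  raster
}

# true normalized phase distances for a cell table (single module)
true_phase_distances <- function(cells) {
  n <- nrow(cells)
  sp <- mean(cells$spacing); or <- mean(cells$orientation)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    normalized_phase_distance(
      c(cells$phase_x[i] - cells$phase_x[j],
        cells$phase_y[i] - cells$phase_y[j]), sp, or)
  }, numeric(1))
  data.frame(i = idx[, 1], j = idx[, 2], d = d)
}
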