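#' Simulate a foraging trajectory in a square arena
#'
#' Generates a smooth random walk emulating a rat foraging in an open-field
#' box: the heading diffuses as an Ornstein-Uhlenbeck-driven angle, running
#' speed follows an Ornstein-Uhlenbeck process around `speed_mean`, and the
#' walls reflect the path. Head direction equals the heading plus a small
#' jitter, so head and running direction are correlated but not identical,
#' as in freely behaving animals.
#'
#' Default Ornstein-Uhlenbeck parameters are set so that a 20-minute walk
#' visits at least 95% of 7.5 cm spatial bins two or more times, the
#' coverage a noise-correlation analysis needs.
#'
#' @param duration_s Session length in seconds.
#' @param dt_s Sample step in seconds (default 0.01, i.e. 10 ms bins).
#' @param arena_side_cm Side of the square arena in cm (default 150).
#' @param speed_mean,speed_sd Mean and stationary s.d. of running speed
#'   (cm/s); speed is clipped at 0.
#' @param seed Optional integer seed for reproducibility.
#' @param heading_sigma Diffusion of the heading angle (rad per sqrt(s)).
#' @param speed_tau Relaxation time of the speed process (s).
#' @param hd_jitter_sd S.d. of the head-direction jitter around the heading
#'   (rad).
#' @return A `data.frame` of class `gn_trajectory` with columns `t`, `x`,
#'   `y` (cm), `head_direction` (rad in (-pi, pi]) and `speed` (cm/s), and
#'   attributes `arena_side` and `dt`.
#' @examples
#' traj <- simulate_trajectory(60, 0.01, 150, seed = 1)
#' range(traj$x)
#' @export
simulate_trajectory <- function(duration_s, dt_s = 0.01, arena_side_cm = 150,
                                speed_mean = 15, speed_sd = 5, seed = NULL,
                                heading_sigma = 1.6, speed_tau = 1,
                                hd_jitter_sd = 0.1) {
  stop_if_not_positive(duration_s = duration_s, dt_s = dt_s,
                       arena_side_cm = arena_side_cm)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s / dt_s))
  t <- (seq_len(n) - 1) * dt_s
  # speed: OU with stationary sd speed_sd -> sigma = speed_sd * sqrt(2/tau)
  sp <- ou_path(n, dt_s, speed_mean, speed_tau, speed_sd * sqrt(2 / speed_tau))
  sp <- pmax(sp, 0)
  heading <- cumsum(c(runif(1, -pi, pi), heading_sigma * sqrt(dt_s) * rnorm(n - 1)))
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, arena_side_cm)
  y[1] <- runif(1, 0, arena_side_cm)
  L <- arena_side_cm
  for (i in 2:n) {
    xi <- x[i - 1] + sp[i] * dt_s * cos(heading[i])
    yi <- y[i - 1] + sp[i] * dt_s * sin(heading[i])
    if (xi < 0 || xi > L) {
      xi <- if (xi < 0) -xi else 2 * L - xi
      heading[i:n] <- pi - heading[i:n]
    }
    if (yi < 0 || yi > L) {
      yi <- if (yi < 0) -yi else 2 * L - yi
      heading[i:n] <- -heading[i:n]
    }
    x[i] <- min(max(xi, 0), L)
    y[i] <- min(max(yi, 0), L)
  }
  hd <- wrap_angle(heading + hd_jitter_sd * rnorm(n))
  out <- data.frame(t = t, x = x, y = y, head_direction = hd, speed = sp)
  attr(out, "arena_side") <- arena_side_cm
  attr(out, "dt") <- dt_s
  class(out) <- c("gn_trajectory", "data.frame")
  out
}

#' Grid-cell firing-rate function
#'
#' Rate of a grid cell at positions `(x, y)`: a sum of isotropic Gaussian
#' bumps centred on the vertices of the hexagonal lattice defined by the
#' cell's spacing, orientation and spatial phase, normalized so the rate at
#' a field centre equals `peak_rate`. Bump width (Gaussian s.d.) defaults to
#' a quarter of the spacing, giving well-separated, strictly positive,
#' smooth fields.
#'
#' @param params A list or one-row `data.frame` with `spacing` (cm),
#'   `orientation` (degrees), `phase_x`, `phase_y` (cm, offset of the
#'   nearest vertex from the origin) and `peak_rate` (Hz).
#' @param x,y Positions (cm); vectors of equal length.
#' @param bump_sd Gaussian s.d. of each firing field (cm); default
#'   `spacing / 4`.
#' @return Rates in Hz, same length as `x`.
#' @examples
#' p <- list(spacing = 46.4, orientation = 31.5, phase_x = 0, phase_y = 0,
#'           peak_rate = 15)
#' grid_rate(p, 0, 0) # peak_rate at a vertex
#' @export
grid_rate <- function(params, x, y, bump_sd = NULL) {
  sp <- params$spacing
  if (!is.numeric(sp) || sp <= 0) stop("`spacing` must be positive")
  if (is.null(bump_sd)) bump_sd <- sp / 4
  phase <- c(params$phase_x, params$phase_y)
  lo <- min(x, y, 0); hi <- max(x, y, 0)
  V <- hex_vertices(sp, params$orientation, phase, lo, hi, margin = 6 * bump_sd)
  bump_sum <- function(px, py) {
    s <- numeric(length(px))
    for (k in seq_len(nrow(V)))
      s <- s + exp(-((px - V[k, 1])^2 + (py - V[k, 2])^2) / (2 * bump_sd^2))
    s
  }
  # normalization: bump sum evaluated at a vertex with a full neighbour
  # shell (neighbours contribute a small but nonzero amount, so divide
  # rather than assume 1)
  norm <- max(bump_sum(V[, 1], V[, 2]))
  params$peak_rate * bump_sum(x, y) / norm
}

#' Simulate a theta-band LFP with known phase
#'
#' Produces a theta-rhythm local field potential: a sinusoid whose
#' instantaneous frequency and amplitude drift slowly
#' (Ornstein-Uhlenbeck jitter), plus white noise, together with the true
#' instantaneous phase. The true phase lets round-trip tests validate phase
#' extraction from the trace.
#'
#' @param duration_s Length in seconds.
#' @param dt_s Sample step in seconds (e.g. 0.004 for a 250 Hz LFP).
#' @param freq_hz Centre frequency, must lie in the theta band `[4, 12]` Hz.
#' @param seed Optional integer seed.
#' @param freq_jitter_sd S.d. of the slow frequency drift (Hz).
#' @param amp_jitter_sd S.d. of the slow amplitude drift (fraction of 1).
#' @param noise_sd S.d. of additive white noise (units of the unit-amplitude
#'   sinusoid).
#' @return An object of class `gn_theta` with fields `t`, `lfp`, `phase`
#'   (true instantaneous phase, wrapped to (-pi, pi]), `freq_hz` and `fs`.
#' @export
simulate_theta <- function(duration_s, dt_s = 0.004, freq_hz = 8, seed = NULL,
                           freq_jitter_sd = 0.3, amp_jitter_sd = 0.1,
                           noise_sd = 0) {
  stop_if_not_positive(duration_s = duration_s, dt_s = dt_s)
  if (freq_hz < 4 || freq_hz > 12)
    stop("`freq_hz` must lie in the theta band [4, 12] Hz")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s / dt_s))
  t <- (seq_len(n) - 1) * dt_s
  f <- rep(freq_hz, n)
  if (freq_jitter_sd > 0)
    f <- f + ou_path(n, dt_s, 0, 2, freq_jitter_sd * sqrt(2 / 2), x0 = 0)
  a <- 1
  if (amp_jitter_sd > 0)
    a <- 1 + ou_path(n, dt_s, 0, 2, amp_jitter_sd * sqrt(2 / 2), x0 = 0)
  phase_unwrapped <- cumsum(2 * pi * f * dt_s) - 2 * pi * f[1] * dt_s
  lfp <- a * cos(phase_unwrapped)
  if (noise_sd > 0) lfp <- lfp + noise_sd * rnorm(n)
  structure(
    list(t = t, lfp = lfp, phase = wrap_angle(phase_unwrapped),
         freq_hz = freq_hz, fs = 1 / dt_s),
    class = "gn_theta"
  )
}

#' Sample spike states from the kinetic Ising model
#'
#' Draws a binary spike raster `S` (entries -1/+1) sequentially from the
#' one-step-memory maximum-entropy model: given the previous population
#' state,
#' `P(S_i(t) = s) = exp(s * H_i(t-1)) / (2 cosh H_i(t-1))` with
#' `H_i(t-1) = h_i(t-1) + sum_j J_ij S_j(t-1)`. The first column is drawn
#' from the field alone (uniform when the field is zero) and should be
#' excluded from likelihood-based comparisons.
#'
#' @param h Matrix of external fields, cells x time-bins.
#' @param J Square coupling matrix (`J[i, j]` couples cell `j` at `t` to
#'   cell `i` at `t + 1`); self-couplings live on the diagonal.
#' @param seed Optional integer seed.
#' @param bin_width_s Time-bin width recorded on the returned raster
#'   (default 0.01 s).
#' @return A [binary raster][binarize_spikes] (`gn_raster`).
#' @export
sample_kinetic_ising <- function(h, J, seed = NULL, bin_width_s = 0.01) {
  h <- as.matrix(h)
  J <- as.matrix(J)
  if (nrow(J) != nrow(h) || ncol(J) != nrow(h))
    stop("`J` must be square with one row per cell of `h`")
  if (!is.null(seed)) set.seed(seed)
  S <- .sample_ki_cpp(h, J)
  new_raster(S, bin_width_s = bin_width_s, t0 = 0)
}

#' Generate a synthetic grid-cell population with ground truth
#'
#' Builds a full synthetic session: a foraging trajectory, a theta rhythm,
#' per-cell hexagonal firing-rate functions (optionally theta- and
#' head-direction-modulated) and spike trains, returned together with the
#' ground truth that produced them. Spikes are drawn either independently
#' per 10 ms bin with probability `1 - exp(-rate * dt)`
#' (`mode = "rate_bernoulli"`) or from the kinetic Ising model itself with
#' per-bin fields matched to those probabilities and user-supplied
#' ground-truth couplings (`mode = "kinetic_ising"`). With `J = 0` the two
#' modes are distributionally identical.
#'
#' Theta modulation is multiplicative,
#' `rate * (1 + m cos(theta - theta_pref))`, and head-direction tuning
#' likewise with the head direction; when a `mean_rate` column is present
#' each cell's rate trace is rescaled to hit that session-mean target.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{cells}{`data.frame`, one row per cell: `spacing`,
#'       `orientation`, `phase_x`, `phase_y`, `peak_rate`; optional
#'       `module`, `mean_rate`, `theta_mod` (in `[0, 1)`), `theta_pref`,
#'       `hd_mod`, `hd_pref`.}
#'     \item{duration_s}{session length (default 1200 s).}
#'     \item{dt_s}{time-bin width (default 0.01 s).}
#'     \item{arena_side_cm}{arena side (default 150).}
#'     \item{mode}{`"rate_bernoulli"` or `"kinetic_ising"`.}
#'     \item{J}{coupling matrix for `kinetic_ising` mode (default 0).}
#'     \item{theta_freq}{theta frequency in Hz (default 8).}
#'     \item{trajectory, theta}{optional pre-built inputs.}
#'   }
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `gn_population`: `spikes` (data.frame `cell_id`,
#'   `t`), `raster` (`gn_raster`), `trajectory`, `theta`, and `truth`
#'   (cell parameters, couplings `J`, per-bin fields `h`, rates, seed).
#' @export
generate_population <- function(config, seed = 1) {
  cells <- config$cells
  if (is.null(cells) || nrow(cells) == 0) stop("`config$cells` must list at least one cell")
  duration <- config$duration_s %||% 1200
  dt <- config$dt_s %||% 0.01
  arena <- config$arena_side_cm %||% 150
  mode <- config$mode %||% "rate_bernoulli"
  if (!mode %in% c("rate_bernoulli", "kinetic_ising"))
    stop("`mode` must be 'rate_bernoulli' or 'kinetic_ising'")
  set.seed(seed)
  traj <- config$trajectory %||%
    simulate_trajectory(duration, dt, arena, seed = NULL)
  n_t <- nrow(traj)
  theta <- config$theta %||%
    simulate_theta(duration, dt, config$theta_freq %||% 8, seed = NULL)
  # theta phase at trajectory samples (theta may be finer-sampled)
  th_idx <- pmin(pmax(findInterval(traj$t, theta$t), 1), length(theta$phase))
  th_phase <- theta$phase[th_idx]
  n_cells <- nrow(cells)
  rates <- matrix(0, n_cells, n_t)
  for (i in seq_len(n_cells)) {
    ci <- as.list(cells[i, ])
    r <- grid_rate(ci, traj$x, traj$y)
    m <- ci$theta_mod %||% 0
    if (!is.null(m) && !is.na(m) && m > 0)
      r <- r * (1 + m * cos(th_phase - (ci$theta_pref %||% 0)))
    hm <- ci$hd_mod %||% 0
    if (!is.null(hm) && !is.na(hm) && hm > 0)
      r <- r * (1 + hm * cos(traj$head_direction - (ci$hd_pref %||% 0)))
    tgt <- ci$mean_rate %||% NA_real_
    if (!is.na(tgt) && mean(r) > 0) r <- r * tgt / mean(r)
    rates[i, ] <- r
  }
  p_spike <- 1 - exp(-rates * dt)
  # field matched to the per-bin spike probability: P(+1) = (1 + tanh h)/2
  h_true <- atanh(pmin(pmax(2 * p_spike - 1, -1 + 1e-12), 1 - 1e-12))
  J <- config$J %||% matrix(0, n_cells, n_cells)
  if (mode == "rate_bernoulli") {
    S <- matrix(ifelse(runif(n_cells * n_t) < p_spike, 1L, -1L), n_cells, n_t)
    raster <- new_raster(S, bin_width_s = dt, t0 = 0)
  } else {
    # mean-field correction: subtract the expected coupling drive
    # J %*% E[S] so realized rates stay on target when J != 0
    m <- rowMeans(2 * p_spike - 1)
    h_true <- h_true - as.vector(J %*% m)
    raster <- sample_kinetic_ising(h_true, J, seed = NULL, bin_width_s = dt)
  }
  spk <- which(raster$S == 1L, arr.ind = TRUE)
  spikes <- data.frame(
    cell_id = spk[, 1],
    t = traj$t[spk[, 2]] + dt / 2
  )
  spikes <- spikes[order(spikes$cell_id, spikes$t), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(
    list(spikes = spikes, raster = raster, trajectory = traj, theta = theta,
         truth = list(cells = cells, J = J, h = h_true, rates = rates,
                      seed = seed, mode = mode)),
    class = "gn_population"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
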