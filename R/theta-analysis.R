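#' Extract theta phase from an LFP trace
#'
#' Finds the dominant theta frequency as the maximum Fourier component of
#' the LFP between 4 and 12 Hz, band-passes the trace around it
#' (+-`band_hw` Hz, by zeroing Fourier coefficients), takes the analytic
#' signal, and reads the instantaneous phase. The per-time-bin phase is
#' the circular mean of the sample phases falling in each bin.
#'
#' @param lfp Numeric LFP trace, or a [gn_theta][simulate_theta] object
#'   (its `lfp` field is used).
#' @param fs Sampling rate in Hz (> 24); taken from a `gn_theta` input.
#' @param bin_width_s Output bin width (default 0.01 s).
#' @param band_hw Half-width of the pass band around the dominant
#'   frequency (default 2 Hz).
#' @return Object of class `gn_theta_bins`: list with `phase` (per-bin
#'   circular mean, (-pi, pi]), `freq_hz` (dominant frequency),
#'   `sample_phase` (per-sample instantaneous phase), `bin_width_s`.
#' @export
extract_theta_phase <- function(lfp, fs = NULL, bin_width_s = 0.01,
                                band_hw = 2) {
  if (inherits(lfp, "gn_theta")) { fs <- lfp$fs; lfp <- lfp$lfp }
  if (is.null(fs) || fs <= 24) stop("`fs` must be given and exceed 24 Hz")
  n <- length(lfp)
  if (n < fs) stop("trace must be at least 1 s long")
  if (n * 4 / fs < 1) stop("trace shorter than one theta cycle")
  x <- lfp - mean(lfp)
  F <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  band <- which(freqs >= 4 & freqs <= 12)
  if (!length(band)) stop("trace too short to resolve the theta band")
  f0 <- freqs[band[which.max(Mod(F[band]))]]
  # analytic signal restricted to the pass band: keep positive frequencies
  # within f0 +- band_hw, doubled; zero elsewhere
  keep <- freqs >= max(f0 - band_hw, 0.5) & freqs <= f0 + band_hw &
    seq_len(n) <= floor(n / 2) + 1
  Fa <- rep(0 + 0i, n)
  Fa[keep] <- 2 * F[keep]
  z <- fft(Fa, inverse = TRUE) / n
  sample_phase <- Arg(z)
  # per-bin circular mean
  bin <- floor((seq_len(n) - 1) / fs / bin_width_s) + 1
  n_bins <- max(bin)
  cs <- vapply(split(sample_phase, bin), circ_mean, numeric(1))
  phase <- rep(NA_real_, n_bins)
  phase[as.integer(names(cs))] <- cs
  structure(list(phase = wrap_angle(phase), freq_hz = f0,
                 sample_phase = sample_phase, bin_width_s = bin_width_s),
            class = "gn_theta_bins")
}

# wrapped (von Mises kernel) density estimate on a grid; returns
# list(theta, density)
vm_kde <- function(angles, kappa, n_grid = 512) {
  grid <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  dens <- vapply(grid, function(g)
    mean(exp(kappa * cos(g - angles))), numeric(1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = FALSE))
  list(theta = grid, density = dens)
}

# leave-one-out cross-validated concentration for the von Mises KDE
vm_kde_cv_kappa <- function(angles, kappas = c(2, 4, 8, 16, 32, 64)) {
  n <- length(angles)
  D <- cos(outer(angles, angles, "-"))
  diag(D) <- NA
  scores <- vapply(kappas, function(k) {
    K <- exp(k * D)
    li <- rowSums(K, na.rm = TRUE) / ((n - 1) * 2 * pi * besselI(k, 0))
    sum(log(pmax(li, 1e-300)))
  }, numeric(1))
  kappas[which.max(scores)]
}

#' Theta-phase preference of a cell
#'
#' The peak of a circular (von Mises) kernel density estimate of the theta
#' phases at which the cell spiked. The kernel concentration is chosen by
#' leave-one-out cross-validation unless given. Cells whose phase
#' distribution is nearly uniform (mean resultant length below
#' `min_resultant`) are flagged.
#'
#' @param spike_phases Theta phase at each spike (rad).
#' @param kappa Optional fixed von Mises concentration.
#' @param min_spikes Minimum spikes required (default 10); fewer returns
#'   `NA`.
#' @param min_resultant Resultant-length threshold below which the
#'   preference is flagged as low-concentration (default 0.05).
#' @return The preferred phase in (-pi, pi] with attributes `resultant`,
#'   `low_concentration`, `kappa`; `NA` if too few spikes.
#' @export
theta_preference <- function(spike_phases, kappa = NULL, min_spikes = 10,
                             min_resultant = 0.05) {
  spike_phases <- spike_phases[is.finite(spike_phases)]
  if (length(spike_phases) < min_spikes) return(NA_real_)
  if (is.null(kappa)) {
    sub <- if (length(spike_phases) > 2000)
      sample(spike_phases, 2000) else spike_phases
    kappa <- vm_kde_cv_kappa(sub)
  }
  kde <- vm_kde(spike_phases, kappa)
  pref <- kde$theta[which.max(kde$density)]
  r <- circ_resultant(spike_phases)
  structure(pref, resultant = r, low_concentration = r < min_resultant,
            kappa = kappa)
}

#' Number of modes of the preference distribution
#'
#' Counts local maxima of a circular kernel density estimate of the
#' per-cell theta preferences; used as the cluster count for
#' [circular_kmeans()].
#'
#' @param preferences Per-cell preferred phases (rad).
#' @param kappa von Mises concentration of the KDE (default 4, a broad
#'   kernel appropriate for tens of cells).
#' @return Integer number of local density maxima (>= 1).
#' @export
count_phase_modes <- function(preferences, kappa = 4) {
  preferences <- preferences[is.finite(preferences)]
  kde <- vm_kde(preferences, kappa, n_grid = 256)
  d <- kde$density
  n <- length(d)
  up <- d > d[c(n, 1:(n - 1))] & d >= d[c(2:n, 1)]
  max(1L, sum(up))
}

#' Circular k-means clustering
#'
#' k-means on the circle: assignment by minimal angular distance to the
#' centres, centres updated as circular means of their members, iterated
#' to a fixed point; best of `n_restarts` seeded restarts by the summed
#' squared angular distance. An emptied cluster is re-seeded at the point
#' farthest from its assigned centre.
#'
#' @param angles Angles to cluster (rad).
#' @param k Number of clusters; default `NULL` counts the modes of the
#'   input density ([count_phase_modes()]).
#' @param n_restarts Random restarts (default 10).
#' @param seed Seed for the restarts.
#' @return List with `cluster` (labels 1..k), `centers` (rad), `withinss`
#'   (summed squared angular distances), `k`.
#' @export
circular_kmeans <- function(angles, k = NULL, n_restarts = 10, seed = 1) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (is.null(k)) k <- count_phase_modes(angles)
  if (k < 1 || n < k) stop("need `n >= k >= 1`")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- angles[sample(n, k)]
    for (iter in 1:100) {
      D <- vapply(centers, function(ck) angular_distance(angles, ck),
                  numeric(n))
      D <- matrix(D, nrow = n)
      lab <- max.col(-D, ties.method = "first")
      for (g in seq_len(k)) {
        if (!any(lab == g)) {
          far <- which.max(D[cbind(seq_len(n), lab)])
          lab[far] <- g
        }
      }
      new_centers <- vapply(seq_len(k), function(g)
        circ_mean(angles[lab == g]), numeric(1))
      if (max(angular_distance(new_centers, centers)) < 1e-10) {
        centers <- new_centers; break
      }
      centers <- new_centers
    }
    D <- matrix(vapply(centers, function(ck)
      angular_distance(angles, ck), numeric(n)), nrow = n)
    lab <- max.col(-D, ties.method = "first")
    wss <- sum(D[cbind(seq_len(n), lab)]^2)
    if (is.null(best) || wss < best$withinss)
      best <- list(cluster = lab, centers = centers, withinss = wss, k = k)
  }
  best
}

# circular-linear association: squared correlation of Mardia (1976)
circ_lin_r2 <- function(x, theta) {
  rcx <- cor(x, cos(theta)); rsx <- cor(x, sin(theta))
  rcs <- cor(cos(theta), sin(theta))
  (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
}

# circular-linear regression slope (rad per unit x) by maximizing the
# resultant length of theta - 2*pi*b*x over a slope grid
circ_lin_slope <- function(x, theta, slope_range = c(-1, 1), n_grid = 201) {
  bs <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  R <- vapply(bs, function(b) circ_resultant(theta - b * x), numeric(1))
  b0 <- bs[which.max(R)]
  opt <- optimize(function(b) -circ_resultant(theta - b * x),
                  interval = c(b0 - diff(slope_range) / n_grid,
                               b0 + diff(slope_range) / n_grid))
  opt$minimum
}

#' Test a cell for theta phase precession
#'
#' Classifies a cell as phase precessing by correlating, at each in-field
#' spike, the animal's signed distance to the nearest field peak projected
#' onto the current running direction with the theta phase of the spike.
#' The association statistic is the circular-linear correlation; its
#' significance comes from a permutation test (shuffling spike phases),
#' and a precessing call additionally requires a negative phase-vs-
#' distance slope (phase advances as the field is traversed).
#'
#' @param spike_times One cell's spike times (s).
#' @param ratemap The cell's [gn_ratemap][compute_rate_map]; its local
#'   maxima above `peak_frac` of the map maximum are the field peaks.
#' @param trajectory The session [gn_trajectory][simulate_trajectory].
#' @param theta A [gn_theta_bins][extract_theta_phase] (or
#'   [gn_theta][simulate_theta], whose true per-sample phase is used).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Phase permutations (default 1000).
#' @param peak_frac Field-peak detection threshold (default 0.2 of max).
#' @param field_radius_cm In-field radius around a peak; default half the
#'   median inter-peak distance.
#' @param min_spikes Minimum in-field spikes (default 30).
#' @param seed Seed for the permutations.
#' @return Object of class `gn_precession`: list with `statistic`
#'   (circular-linear r^2), `p`, `slope` (rad/cm), `precessing` (logical),
#'   `n_spikes`; `NA` fields when the cell has no usable field or too few
#'   spikes.
#' @export
phase_precession_test <- function(spike_times, ratemap, trajectory, theta,
                                  alpha = 0.05, n_perm = 1000,
                                  peak_frac = 0.2, field_radius_cm = NULL,
                                  min_spikes = 30, seed = 1) {
  empty <- structure(list(statistic = NA_real_, p = NA_real_,
                          slope = NA_real_, precessing = NA, n_spikes = 0L),
                     class = "gn_precession")
  R <- ratemap$rate
  if (!any(is.finite(R))) return(empty)
  pk <- find_peaks(ifelse(is.finite(R), R, 0), smooth_sd = 1)
  pk <- pk[pk$value >= peak_frac * max(R, na.rm = TRUE), , drop = FALSE]
  if (nrow(pk) == 0) return(empty)
  peaks <- cbind((pk$x - 0.5) * ratemap$bin_cm, (pk$y - 0.5) * ratemap$bin_cm)
  if (is.null(field_radius_cm)) {
    if (nrow(peaks) >= 2) {
      dd <- as.matrix(dist(peaks)); diag(dd) <- Inf
      field_radius_cm <- median(apply(dd, 1, min)) / 2
    } else field_radius_cm <- 2 * ratemap$bin_cm
  }
  dt <- attr(trajectory, "dt") %||% median(diff(trajectory$t))
  idx <- pmin(pmax(round((spike_times - trajectory$t[1]) / dt) + 1, 1),
              nrow(trajectory))
  px <- trajectory$x[idx]; py <- trajectory$y[idx]
  # nearest peak and signed projected distance along the running direction
  rd <- running_direction(trajectory)[idx]
  dmat <- outer(px, peaks[, 1], "-")^2 + outer(py, peaks[, 2], "-")^2
  nearest <- max.col(-dmat, ties.method = "first")
  dx <- px - peaks[nearest, 1]; dy <- py - peaks[nearest, 2]
  dist_peak <- sqrt(dx^2 + dy^2)
  infield <- dist_peak <= field_radius_cm
  proj <- dx * cos(rd) + dy * sin(rd)
  # spike theta phase
  ph <- if (inherits(theta, "gn_theta_bins")) {
    b <- pmin(pmax(floor(spike_times / theta$bin_width_s) + 1, 1),
              length(theta$phase))
    theta$phase[b]
  } else if (inherits(theta, "gn_theta")) {
    b <- pmin(pmax(round(spike_times * theta$fs) + 1, 1), length(theta$phase))
    theta$phase[b]
  } else stop("`theta` must be a gn_theta or gn_theta_bins object")
  ok <- infield & is.finite(ph) & is.finite(proj)
  x <- proj[ok]; th <- ph[ok]
  if (length(x) < min_spikes) return(empty)
  res <- precession_pvalue(x, th, n_perm = n_perm, seed = seed)
  structure(list(statistic = res$statistic, p = res$p, slope = res$slope,
                 precessing = (res$p < alpha) && (res$slope < 0),
                 n_spikes = length(x)),
            class = "gn_precession")
}

# permutation test of circular-linear association between projected
# distance x and spike phase theta; shared by phase_precession_test and
# by calibration studies
precession_pvalue <- function(x, theta, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stat <- circ_lin_r2(x, theta)
  perm <- vapply(seq_len(n_perm), function(i)
    circ_lin_r2(x, sample(theta)), numeric(1))
  list(statistic = stat,
       p = (1 + sum(perm >= stat)) / (n_perm + 1),
       slope = circ_lin_slope(x, theta))
}
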