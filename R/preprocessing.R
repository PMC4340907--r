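# constructor for the binary spike raster: cells x time-bins over {-1, +1}
new_raster <- function(S, bin_width_s, t0 = 0, cell_ids = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "integer"
  if (!all(S == 1L | S == -1L)) stop("raster entries must be -1 or +1")
  structure(
    list(S = S, bin_width_s = bin_width_s, t0 = t0,
         cell_ids = cell_ids %||% seq_len(nrow(S))),
    class = "gn_raster"
  )
}

#' @export
print.gn_raster <- function(x, ...) {
  cat(sprintf("<gn_raster> %d cells x %d bins of %g ms; spike-bin fraction %.4f\n",
              nrow(x$S), ncol(x$S), 1000 * x$bin_width_s, mean(x$S == 1L)))
  invisible(x)
}

#' Binarize spike times into a -1/+1 raster
#'
#' Bins each cell's spike train into half-open time bins `[t, t + dt)`; a
#' bin is `+1` if the cell emitted one or more spikes in it and `-1`
#' otherwise. This is the binary state matrix the kinetic Ising model is
#' fit to; 10 ms is the standard bin width (5 and 20 ms give similar
#' results and are supported).
#'
#' @param spikes `data.frame` with columns `cell_id` and `t` (seconds).
#' @param bin_width_s Bin width in seconds (default 0.01).
#' @param t_range Length-2 numeric, time span to bin; defaults to
#'   `c(0, max(spikes$t))` rounded up to a whole bin.
#' @param n_cells Number of cells (defaults to `max(cell_id)`); cells
#'   without spikes get all `-1` rows.
#' @return A `gn_raster`: list with integer matrix `S` (cells x bins over
#'   -1/+1), `bin_width_s`, `t0`, `cell_ids`.
#' @export
binarize_spikes <- function(spikes, bin_width_s = 0.01, t_range = NULL,
                            n_cells = NULL) {
  if (is.null(t_range)) {
    tmax <- if (nrow(spikes)) max(spikes$t) else bin_width_s
    t_range <- c(0, ceiling(tmax / bin_width_s) * bin_width_s)
  }
  if (diff(t_range) <= 0) stop("`t_range` must span a positive duration")
  n_bins <- as.integer(ceiling((t_range[2] - t_range[1]) / bin_width_s - 1e-9))
  n_cells <- n_cells %||% (if (nrow(spikes)) max(spikes$cell_id) else 1L)
  S <- matrix(-1L, n_cells, n_bins)
  keep <- spikes$t >= t_range[1] & spikes$t < t_range[1] + n_bins * bin_width_s
  sp <- spikes[keep, , drop = FALSE]
  if (nrow(sp)) {
    b <- floor((sp$t - t_range[1]) / bin_width_s) + 1
    S[cbind(sp$cell_id, b)] <- 1L
  }
  new_raster(S, bin_width_s, t0 = t_range[1])
}

#' Gaussian-smoothed instantaneous firing rates
#'
#' Bins spikes at millisecond resolution and convolves the counts with a
#' normalized Gaussian kernel (s.d. 20 ms by default), returning rates in
#' Hz. This is the representation over which visit-wise mean rates, and
#' hence noise correlations, are computed.
#'
#' @param spikes `data.frame` with `cell_id`, `t` (s).
#' @param t_range Time span (s); default covers the data.
#' @param dt_s Fine bin width (default 0.001 s).
#' @param gaussian_sd_s Kernel s.d. in seconds (default 0.020).
#' @param n_cells Number of cells (default `max(cell_id)`).
#' @return Object of class `gn_rates`: list with `R` (cells x fine-bins
#'   matrix, Hz), `dt_s`, `t0`, `gaussian_sd_s`.
#' @export
smooth_rates <- function(spikes, t_range = NULL, dt_s = 0.001,
                         gaussian_sd_s = 0.020, n_cells = NULL) {
  if (is.null(t_range)) {
    tmax <- if (nrow(spikes)) max(spikes$t) else dt_s
    t_range <- c(0, ceiling(tmax / dt_s) * dt_s)
  }
  n_bins <- as.integer(ceiling((t_range[2] - t_range[1]) / dt_s - 1e-9))
  n_cells <- n_cells %||% (if (nrow(spikes)) max(spikes$cell_id) else 1L)
  half <- as.integer(ceiling(4 * gaussian_sd_s / dt_s))
  kern <- exp(-0.5 * ((-half:half) * dt_s / gaussian_sd_s)^2)
  kern <- kern / sum(kern)
  R <- matrix(0, n_cells, n_bins)
  keep <- spikes$t >= t_range[1] & spikes$t < t_range[2]
  sp <- spikes[keep, , drop = FALSE]
  for (i in seq_len(n_cells)) {
    ti <- sp$t[sp$cell_id == i]
    cnt <- tabulate(floor((ti - t_range[1]) / dt_s) + 1, nbins = n_bins)
    # pad so kernel mass is not lost at the edges of the convolution
    padded <- c(numeric(half), cnt, numeric(half))
    sm <- convolve(padded, kern, type = "open")
    # FFT round-off can leave tiny negative values; rates are nonnegative
    R[i, ] <- pmax(sm[(2 * half + 1):(2 * half + n_bins)], 0) / dt_s
  }
  structure(list(R = R, dt_s = dt_s, t0 = t_range[1],
                 gaussian_sd_s = gaussian_sd_s),
            class = "gn_rates")
}

# light 2-D Gaussian blur with border renormalization (mask-aware)
blur2d <- function(M, sd_bins, mask = NULL) {
  if (sd_bins <= 0) return(M)
  half <- max(1L, as.integer(ceiling(3 * sd_bins)))
  k <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  k <- k / sum(k)
  if (is.null(mask)) mask <- matrix(1, nrow(M), ncol(M))
  M0 <- M * mask
  M0[!is.finite(M0)] <- 0 # masked-out NAs must not poison the convolution
  pass <- function(A) {
    A1 <- apply(A, 2, function(col) {
      p <- c(numeric(half), col, numeric(half))
      convolve(p, k, type = "open")[(2 * half + 1):(2 * half + length(col))]
    })
    t(apply(A1, 1, function(row) {
      p <- c(numeric(half), row, numeric(half))
      convolve(p, k, type = "open")[(2 * half + 1):(2 * half + length(row))]
    }))
  }
  num <- pass(M0)
  den <- pass(mask)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-12] <- NA_real_
  out
}

#' Spatial firing-rate map
#'
#' Assigns each spike to the trajectory sample nearest in time, counts
#' spikes and occupancy per square spatial bin (3 cm by default), smooths
#' both with a Gaussian filter (s.d. 2 bins by default) and divides,
#' yielding a rate map in Hz. Bins never visited are `NA`.
#'
#' @param spikes `data.frame` with `cell_id`, `t`; pass one cell's spikes
#'   or use `cell` to select.
#' @param trajectory A [gn_trajectory][simulate_trajectory] (or data.frame
#'   with `t`, `x`, `y` and attribute `arena_side`).
#' @param cell Optional cell id to filter `spikes` by.
#' @param bin_cm Spatial bin size (default 3 cm).
#' @param smooth_sd_bins Gaussian s.d. of the smoothing filter in bins
#'   (default 2).
#' @param arena_side_cm Arena side; defaults to the trajectory attribute.
#' @return Object of class `gn_ratemap`: list with `rate` (n x n matrix,
#'   Hz; rows index x-bins, columns y-bins), `occupancy` (seconds,
#'   unsmoothed), `bin_cm`, `valid` (logical matrix).
#' @export
compute_rate_map <- function(spikes, trajectory, cell = NULL, bin_cm = 3,
                             smooth_sd_bins = 2, arena_side_cm = NULL) {
  if (!is.null(cell)) spikes <- spikes[spikes$cell_id == cell, , drop = FALSE]
  L <- arena_side_cm %||% attr(trajectory, "arena_side") %||%
    max(trajectory$x, trajectory$y)
  dt <- attr(trajectory, "dt") %||% median(diff(trajectory$t))
  n <- as.integer(ceiling(L / bin_cm - 1e-9))
  bin_of <- function(v) pmin(pmax(floor(v / bin_cm) + 1L, 1L), n)
  bx <- bin_of(trajectory$x); by <- bin_of(trajectory$y)
  occ_counts <- matrix(tabulate((by - 1L) * n + bx, nbins = n * n), n, n)
  occupancy <- occ_counts * dt
  spk_counts <- matrix(0, n, n)
  if (nrow(spikes)) {
    out_of_range <- spikes$t < min(trajectory$t) - dt |
      spikes$t > max(trajectory$t) + dt
    if (any(out_of_range)) {
      warning(sprintf("%d spikes outside the trajectory time range dropped",
                      sum(out_of_range)))
      spikes <- spikes[!out_of_range, , drop = FALSE]
    }
    idx <- pmin(pmax(round((spikes$t - trajectory$t[1]) / dt) + 1, 1),
                nrow(trajectory))
    sb <- (bin_of(trajectory$y[idx]) - 1L) * n + bin_of(trajectory$x[idx])
    spk_counts <- matrix(tabulate(sb, nbins = n * n), n, n)
  }
  mask <- (occ_counts > 0) * 1
  sm_spk <- blur2d(spk_counts, smooth_sd_bins, mask)
  sm_occ <- blur2d(occupancy, smooth_sd_bins, mask)
  rate <- sm_spk / sm_occ
  valid <- is.finite(rate) & occ_counts >= 0 & !is.na(sm_occ) & sm_occ > 0
  rate[!valid] <- NA_real_
  structure(list(rate = rate, occupancy = occupancy, bin_cm = bin_cm,
                 valid = valid, n_bins = n),
            class = "gn_ratemap")
}

#' Segment a trajectory into per-bin visits
#'
#' Divides the arena into `n_bins_per_side^2` equal square bins and defines
#' a visit as a maximal run of consecutive trajectory samples inside one
#' bin. For each visit and each cell, stores the mean of the cell's
#' smoothed 1 ms firing rate over the visit's time span - the per-visit
#' rates that noise correlations are computed from.
#'
#' @param trajectory A [gn_trajectory][simulate_trajectory].
#' @param n_bins_per_side Positive integer; 20 (7.5 cm bins on a 150 cm
#'   arena) gives the most stable noise-correlation estimates.
#' @param rates A [gn_rates][smooth_rates] object from the same session.
#' @param arena_side_cm Defaults to the trajectory attribute.
#' @return Object of class `gn_visits`: list with `visits` (`data.frame`
#'   `bin`, `start`, `end` sample indices), `rate_means` (visits x cells
#'   matrix), `n_bins_per_side`, `bin_cm`.
#' @export
segment_visits <- function(trajectory, n_bins_per_side, rates,
                           arena_side_cm = NULL) {
  if (!is.numeric(n_bins_per_side) || n_bins_per_side < 1)
    stop("`n_bins_per_side` must be a positive integer")
  n <- as.integer(n_bins_per_side)
  L <- arena_side_cm %||% attr(trajectory, "arena_side") %||%
    max(trajectory$x, trajectory$y)
  bin_cm <- L / n
  bin_of <- function(v) pmin(pmax(floor(v / bin_cm) + 1L, 1L), n)
  bin_id <- (bin_of(trajectory$y) - 1L) * n + bin_of(trajectory$x)
  r <- rle(bin_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  visits <- data.frame(bin = r$values, start = starts, end = ends)
  dt_traj <- attr(trajectory, "dt") %||% median(diff(trajectory$t))
  n_cells <- nrow(rates$R)
  rm_mat <- matrix(NA_real_, nrow(visits), n_cells)
  # map trajectory sample spans to fine rate bins
  n_fine <- ncol(rates$R)
  f0 <- function(i) pmin(pmax(as.integer(round(
    (trajectory$t[i] - rates$t0) / rates$dt_s)) + 1L, 1L), n_fine)
  for (v in seq_len(nrow(visits))) {
    a <- f0(visits$start[v])
    b <- pmin(as.integer(round((trajectory$t[visits$end[v]] + dt_traj -
                                  rates$t0) / rates$dt_s)), n_fine)
    if (b < a) b <- a
    rm_mat[v, ] <- rowMeans(rates$R[, a:b, drop = FALSE])
  }
  structure(list(visits = visits, rate_means = rm_mat,
                 n_bins_per_side = n, bin_cm = bin_cm),
            class = "gn_visits")
}
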