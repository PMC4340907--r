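#' Read and write the delimited session tables
#'
#' Plain-text I/O for the three session inputs: spike tables (`cell_id`,
#' `t` in seconds), trajectory tables (`t`, `x`, `y` in cm,
#' `head_direction` in rad, optional `speed`) and LFP tables (`t`,
#' `value`). Headers are mandatory; columns are tab-separated.
#'
#' @param path File path.
#' @param arena_side_cm Arena side recorded on the trajectory (default:
#'   max coordinate rounded up).
#' @return `read_spike_table`: data.frame `cell_id`, `t`.
#' @name session_io
#' @export
read_spike_table <- function(path) {
  d <- read.delim(path)
  if (!all(c("cell_id", "t") %in% names(d)))
    stop("spike table needs columns `cell_id`, `t`")
  d[order(d$cell_id, d$t), c("cell_id", "t"), drop = FALSE]
}

#' @rdname session_io
#' @return `read_trajectory`: a `gn_trajectory`.
#' @export
read_trajectory <- function(path, arena_side_cm = NULL) {
  d <- read.delim(path)
  need <- c("t", "x", "y")
  if (!all(need %in% names(d)))
    stop("trajectory table needs columns `t`, `x`, `y`")
  if (is.null(d$head_direction)) d$head_direction <- NA_real_
  if (is.null(d$speed)) {
    dt <- median(diff(d$t))
    disp <- sqrt(diff(d$x)^2 + diff(d$y)^2) / dt
    d$speed <- c(disp[1], disp)
  }
  attr(d, "arena_side") <- arena_side_cm %||% ceiling(max(d$x, d$y))
  attr(d, "dt") <- median(diff(d$t))
  class(d) <- c("gn_trajectory", "data.frame")
  d
}

#' @rdname session_io
#' @return `read_lfp`: data.frame `t`, `value`, with attribute `fs`.
#' @export
read_lfp <- function(path) {
  d <- read.delim(path)
  if (!all(c("t", "value") %in% names(d)))
    stop("LFP table needs columns `t`, `value`")
  attr(d, "fs") <- 1 / median(diff(d$t))
  d
}

#' @rdname session_io
#' @param x Object to write (spike/trajectory/LFP data.frame).
#' @export
write_session_table <- function(x, path) {
  write.table(as.data.frame(x)[, , drop = FALSE], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fit result as text
#'
#' Writes the coupling matrix as CSV and the remaining fit metadata
#' (field coefficients, likelihood, parameter count, convergence) as JSON
#' next to it.
#'
#' @param fit A [gn_fit][ki_fit].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"fit"`).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, prefix = "fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j_path <- file.path(dir, paste0(prefix, "_J.csv"))
  utils::write.csv(fit$J, j_path, row.names = FALSE)
  meta <- list(loglik = fit$loglik, n_params = fit$n_params,
               converged = fit$converged, grad_max = fit$grad_max,
               couplings = fit$couplings,
               self_couplings = fit$self_couplings,
               bin_width_s = fit$bin_width_s,
               components = fit$design$components,
               alpha = fit$alpha)
  m_path <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, m_path, auto_unbox = TRUE, digits = NA)
  invisible(c(j_path, m_path))
}

#' Run the full analysis pipeline on a synthetic or loaded session
#'
#' Ties the stages together: simulate (or ingest) a session, preprocess
#' (raster, smoothed rates, rate maps), estimate grid geometry (spacing,
#' orientation, pairwise phase distances, modules), compute noise
#' correlations and their phase regression, fit the kinetic Ising model
#' under the requested field designs, and score the models. Writes result
#' tables and a JSON manifest of seeds and settings when `outdir` is
#' given.
#'
#' @param config A list: either `simulate` (a [generate_population()]
#'   config) or `paths` (named `spikes`, `trajectory`, optional `lfp`),
#'   plus optional `bin_width_s` (0.01), `n_bins_per_side` (20),
#'   `rate_map_bin_cm` (3), `models` (character subset of
#'   `c("constant", "gaussian")`, default both), `couplings` (TRUE),
#'   `gaussian` (list `M`, `r_cm`).
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Optional output directory.
#' @return A list with `geometry` (per-cell estimates and modules),
#'   `pair_table` (per-pair phase distance, noise correlation, couplings),
#'   `noise` (`gn_noisecorr`), `noise_regression`, `fits`, `scores`, and
#'   `session` (raster, trajectory, rates).
#' @export
run_pipeline <- function(config, seed = 1, outdir = NULL) {
  set.seed(seed)
  dt <- config$bin_width_s %||% 0.01
  if (!is.null(config$simulate)) {
    pop <- generate_population(config$simulate, seed = seed)
    spikes <- pop$spikes; traj <- pop$trajectory
    raster <- pop$raster
    theta_bins <- NULL
  } else if (!is.null(config$paths)) {
    spikes <- read_spike_table(config$paths$spikes)
    traj <- read_trajectory(config$paths$trajectory)
    t_range <- c(0, max(traj$t) + (attr(traj, "dt") %||% 0.01))
    raster <- binarize_spikes(spikes, dt, t_range)
    theta_bins <- if (!is.null(config$paths$lfp)) {
      lfp <- read_lfp(config$paths$lfp)
      extract_theta_phase(lfp$value, attr(lfp, "fs"), bin_width_s = dt)
    }
  } else stop("config needs either `simulate` or `paths`")
  n_cells <- nrow(raster$S)
  t_range <- c(0, ncol(raster$S) * dt)

  message("preprocess: smoothing rates and building rate maps")
  rates <- smooth_rates(spikes, t_range, n_cells = n_cells)
  maps <- lapply(seq_len(n_cells), function(i)
    compute_rate_map(spikes, traj, cell = i,
                     bin_cm = config$rate_map_bin_cm %||% 3))

  message("geometry: spacing, orientation, phase distances, modules")
  geo <- lapply(maps, function(m) {
    tryCatch(estimate_spacing_orientation(spatial_autocorrelogram(m)),
             error = function(e) list(spacing_cm = NA, orientation_deg = NA))
  })
  spacing <- vapply(geo, `[[`, numeric(1), "spacing_cm")
  orientation <- vapply(geo, `[[`, numeric(1), "orientation_deg")
  mod <- if (sum(is.finite(spacing)) >= 2) {
    ok <- is.finite(spacing)
    m <- rep(NA_integer_, n_cells)
    a <- assign_modules(spacing[ok], orientation[ok])
    m[ok] <- a$module
    list(module = m, summary = a$summary)
  } else list(module = rep(1L, n_cells), summary = NULL)
  pair_idx <- which(upper.tri(matrix(0, n_cells, n_cells)), arr.ind = TRUE)
  pair_table <- data.frame(i = pair_idx[, 1], j = pair_idx[, 2])
  pair_table$phase_distance <- vapply(seq_len(nrow(pair_table)), function(r) {
    i <- pair_table$i[r]; j <- pair_table$j[r]
    mi <- mod$module[i]
    if (is.na(mi) || is.na(mod$module[j]) || mi != mod$module[j])
      return(NA_real_)
    sp_m <- mean(spacing[which(mod$module == mi)], na.rm = TRUE)
    off <- tryCatch(phase_offset(maps[[i]], maps[[j]]),
                    error = function(e) c(NA, NA))
    if (!all(is.finite(off))) return(NA_real_)
    normalized_phase_distance(off, sp_m, mean(orientation[mod$module == mi],
                                              na.rm = TRUE))
  }, numeric(1))

  message("noise correlations")
  visits <- segment_visits(traj, config$n_bins_per_side %||% 20, rates)
  noise <- noise_correlation_matrix(visits)
  pair_table$noise_corr <- noise$C[cbind(pair_table$i, pair_table$j)]
  noise_reg <- tryCatch(
    correlation_vs_phase_regression(pair_table$noise_corr,
                                    pair_table$phase_distance),
    error = function(e) NULL)

  models <- config$models %||% c("constant", "gaussian")
  fits <- list(); scores <- list()
  for (m in models) {
    message("fit: ", m, " field model")
    des <- switch(
      m,
      constant = ki_design(design_constant(nrow(traj))),
      gaussian = ki_design(design_constant(nrow(traj)),
                           design_gaussian_spatial(
                             traj, config$gaussian$M %||% 15,
                             config$gaussian$r_cm %||% 8.5)),
      stop(sprintf("unknown field model '%s'", m))
    )
    fits[[m]] <- ki_fit(raster, des,
                        couplings = config$couplings %||% TRUE)
    scores[[m]] <- score_model(fits[[m]], label = m)
    pair_table[[paste0("J_", m)]] <-
      fits[[m]]$J[cbind(pair_table$i, pair_table$j)]
  }

  out <- list(
    geometry = list(spacing_cm = spacing, orientation_deg = orientation,
                    module = mod$module, module_summary = mod$summary),
    pair_table = pair_table, noise = noise, noise_regression = noise_reg,
    fits = fits, scores = scores,
    session = list(raster = raster, trajectory = traj, rates = rates,
                   maps = maps, visits = visits, theta = theta_bins)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pair_table, file.path(outdir, "pair_table.csv"),
                     row.names = FALSE)
    utils::write.csv(noise$C, file.path(outdir, "noise_correlations.csv"),
                     row.names = FALSE)
    for (m in names(fits)) write_fit(fits[[m]], outdir, prefix = m)
    manifest <- list(
      seed = seed, bin_width_s = dt,
      n_bins_per_side = config$n_bins_per_side %||% 20,
      models = models,
      package_version = as.character(utils::packageVersion("gridnet")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
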