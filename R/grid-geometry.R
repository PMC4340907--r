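# Pearson correlation of two maps over their jointly valid bins; NA if
# fewer than min_n bins overlap or either side is constant
masked_cor <- function(A, B, min_n = 20) {
  ok <- is.finite(A) & is.finite(B)
  if (sum(ok) < min_n) return(NA_real_)
  a <- A[ok]; b <- B[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# generic lag-wise Pearson correlogram of two equally sized maps
lag_correlogram <- function(A, B, min_overlap = 20) {
  n1 <- nrow(A); n2 <- ncol(A)
  out <- matrix(NA_real_, 2 * n1 - 1, 2 * n2 - 1)
  for (dx in -(n1 - 1):(n1 - 1)) {
    xa <- max(1, 1 + dx):min(n1, n1 + dx)
    xb <- xa - dx
    for (dy in -(n2 - 1):(n2 - 1)) {
      ya <- max(1, 1 + dy):min(n2, n2 + dy)
      yb <- ya - dy
      out[dx + n1, dy + n2] <-
        masked_cor(A[xa, ya, drop = FALSE], B[xb, yb, drop = FALSE],
                   min_overlap)
    }
  }
  out
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the rate map with itself at every 2-D spatial
#' lag, computed over the overlapping valid bins. The six innermost peaks
#' of the autocorrelogram carry the grid spacing and orientation.
#'
#' @param ratemap A [gn_ratemap][compute_rate_map].
#' @param min_overlap Minimum number of jointly valid bins for a lag to be
#'   defined (default 20).
#' @return Object of class `gn_correlogram`: list with `ac`
#'   ((2n-1) x (2n-1) matrix), `bin_cm`.
#' @export
spatial_autocorrelogram <- function(ratemap, min_overlap = 20) {
  R <- ratemap$rate
  if (!any(is.finite(R))) stop("rate map has no valid bins")
  ac <- lag_correlogram(R, R, min_overlap)
  structure(list(ac = ac, bin_cm = ratemap$bin_cm), class = "gn_correlogram")
}

# local maxima of a matrix over 8-neighbourhoods after light smoothing;
# returns data.frame(x, y, value) in bin units centred on the matrix centre
find_peaks <- function(M, smooth_sd = 1, refine = TRUE) {
  Ms <- blur2d(M, smooth_sd, mask = (is.finite(M)) * 1)
  n1 <- nrow(Ms); n2 <- ncol(Ms)
  px <- integer(0); py <- integer(0); pv <- numeric(0)
  for (i in 2:(n1 - 1)) for (j in 2:(n2 - 1)) {
    v <- Ms[i, j]
    if (!is.finite(v)) next
    nb <- Ms[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb, na.rm = TRUE) && sum(nb == v, na.rm = TRUE) == 1) {
      px <- c(px, i); py <- c(py, j); pv <- c(pv, v)
    }
  }
  fx <- as.numeric(px); fy <- as.numeric(py)
  if (refine && length(px)) {
    # parabolic sub-bin refinement along each axis
    for (k in seq_along(px)) {
      i <- px[k]; j <- py[k]
      cx <- Ms[(i - 1):(i + 1), j]; cy <- Ms[i, (j - 1):(j + 1)]
      if (all(is.finite(cx))) {
        d <- (cx[1] - cx[3]) / (2 * (cx[1] - 2 * cx[2] + cx[3]))
        if (is.finite(d) && abs(d) <= 0.5) fx[k] <- i + d
      }
      if (all(is.finite(cy))) {
        d <- (cy[1] - cy[3]) / (2 * (cy[1] - 2 * cy[2] + cy[3]))
        if (is.finite(d) && abs(d) <= 0.5) fy[k] <- j + d
      }
    }
  }
  data.frame(x = fx, y = fy, value = pv)
}

#' Estimate grid spacing and orientation from an autocorrelogram
#'
#' Finds local maxima of the autocorrelogram (8-neighbourhood, after light
#' smoothing, with parabolic sub-bin refinement), takes the six peaks
#' nearest the centre (excluding the centre itself), and reports
#' spacing = median peak distance and orientation = circular mean (period
#' 60 degrees) of the peak angles, in `[0, 60)`.
#'
#' @param correlogram A [gn_correlogram][spatial_autocorrelogram].
#' @param peak_smooth_sd Smoothing (bins) before peak detection (default 1).
#' @return List with `spacing_cm`, `orientation_deg`, and `peaks`
#'   (data.frame of the six peak offsets in cm).
#' @export
estimate_spacing_orientation <- function(correlogram, peak_smooth_sd = 1) {
  ac <- correlogram$ac
  c1 <- (nrow(ac) + 1) / 2; c2 <- (ncol(ac) + 1) / 2
  pk <- find_peaks(ac, peak_smooth_sd)
  pk$dx <- (pk$x - c1) * correlogram$bin_cm
  pk$dy <- (pk$y - c2) * correlogram$bin_cm
  pk$r <- sqrt(pk$dx^2 + pk$dy^2)
  pk <- pk[pk$r > correlogram$bin_cm, , drop = FALSE] # drop the centre
  if (nrow(pk) < 6)
    stop(sprintf(paste0("only %d off-centre peaks found; need 6 ",
                        "(map too small or not grid-like)"), nrow(pk)))
  pk <- pk[order(pk$r), , drop = FALSE][1:6, ]
  spacing <- median(pk$r)
  ang <- atan2(pk$dy, pk$dx) * 180 / pi
  # circular mean with period 60 degrees
  z <- mean(exp(1i * ang * pi / 30))
  orientation <- (Arg(z) * 30 / pi) %% 60
  list(spacing_cm = spacing, orientation_deg = orientation,
       peaks = pk[, c("dx", "dy", "r", "value")])
}

#' Spatial phase offset between two grid cells
#'
#' Cross-correlates the two rate maps and returns the location of the
#' cross-correlogram peak nearest zero lag - the shortest displacement
#' mapping one cell's firing pattern onto the other's. Intended for cells
#' of the same module (similar spacing and orientation).
#'
#' @param ratemap_i,ratemap_j [gn_ratemap][compute_rate_map] objects on the
#'   same grid of bins.
#' @param peak_smooth_sd Smoothing before peak detection (default 1 bin).
#' @param min_overlap Minimum jointly valid bins per lag.
#' @return Length-2 numeric, offset in cm (ties broken by smaller
#'   magnitude, then smaller angle).
#' @export
phase_offset <- function(ratemap_i, ratemap_j, peak_smooth_sd = 1,
                         min_overlap = 20) {
  cc <- lag_correlogram(ratemap_i$rate, ratemap_j$rate, min_overlap)
  if (!any(is.finite(cc)) || max(cc, na.rm = TRUE) == min(cc, na.rm = TRUE))
    stop("flat cross-correlogram; cannot locate a phase offset")
  c1 <- (nrow(cc) + 1) / 2; c2 <- (ncol(cc) + 1) / 2
  pk <- find_peaks(cc, peak_smooth_sd)
  if (nrow(pk) == 0) stop("no peaks in the cross-correlogram")
  dx <- (pk$x - c1) * ratemap_i$bin_cm
  dy <- (pk$y - c2) * ratemap_i$bin_cm
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  ord <- order(r, ang)
  c(dx[ord[1]], dy[ord[1]])
}

#' Normalized spatial phase distance
#'
#' Length of a phase offset after folding into the fundamental domain of
#' the hexagonal lattice (the shortest equivalent offset under lattice
#' translations), divided by the module's mean spacing. Ranges from 0
#' (identical phase) to `0.5 / cos(30 deg) ~ 0.577` (maximally offset
#' patterns); the latter is the geometric ceiling quoted for two commonly
#' oriented hexagonal patterns.
#'
#' @param offset Length-2 numeric offset in cm.
#' @param spacing_cm Module mean spacing (cm), must be positive.
#' @param orientation_deg Module orientation (degrees; default 0 - the
#'   folded length is invariant to the value used as long as it matches
#'   the lattice the offset refers to).
#' @param fold_range Lattice translations `m, n` in `-fold_range:fold_range`
#'   are searched (default 2; exact for all physical offsets).
#' @return Dimensionless scalar in `[0, 0.5/cos(pi/6)]`.
#' @export
normalized_phase_distance <- function(offset, spacing_cm,
                                      orientation_deg = 0, fold_range = 2) {
  if (!is.numeric(spacing_cm) || spacing_cm <= 0)
    stop("`spacing_cm` must be positive")
  B <- hex_basis(spacing_cm, orientation_deg)
  # centre the search on the nearest lattice point so arbitrarily large
  # offsets still fold correctly
  ctr <- round(solve(B, as.numeric(offset)[1:2]))
  mn <- as.matrix(expand.grid(m = ctr[1] + (-fold_range:fold_range),
                              n = ctr[2] + (-fold_range:fold_range)))
  shifts <- mn %*% t(B)
  d2 <- (offset[1] - shifts[, 1])^2 + (offset[2] - shifts[, 2])^2
  sqrt(min(d2)) / spacing_cm
}

#' Maximum achievable normalized phase distance
#'
#' Brute-force maximization of [normalized_phase_distance()] over a dense
#' grid of offsets spanning one unit cell of a hexagonal lattice. The
#' analytic value is `0.5 / cos(30 deg) = 0.57735...`, attained when one
#' lattice's vertices sit at the centres of the other's triangles.
#'
#' @param n_grid Offsets per lattice axis (default 200).
#' @param spacing_cm Lattice spacing (result is scale-free; default 1).
#' @return List with `max_distance` and the maximizing `offset`.
#' @export
max_phase_distance <- function(n_grid = 200, spacing_cm = 1) {
  B <- hex_basis(spacing_cm, 0)
  u <- (seq_len(n_grid) - 1) / n_grid
  g <- as.matrix(expand.grid(a = u, b = u))
  offsets <- g %*% t(B)
  mn <- as.matrix(expand.grid(m = -2:2, n = -2:2))
  shifts <- mn %*% t(B)
  d2min <- rep(Inf, nrow(offsets))
  for (k in seq_len(nrow(shifts))) {
    d2 <- (offsets[, 1] + shifts[k, 1])^2 + (offsets[, 2] + shifts[k, 2])^2
    d2min <- pmin(d2min, d2)
  }
  d <- sqrt(d2min) / spacing_cm
  i <- which.max(d)
  list(max_distance = d[i], offset = offsets[i, ])
}

#' Assign grid cells to modules
#'
#' Clusters cells by (log spacing, weighted orientation) with k-means,
#' choosing the number of modules k in 1..`k_max` by recursive bisection:
#' a cluster is split in two while the 2-means sub-split of its members
#' reaches a mean silhouette of at least `silhouette_min` AND exceeds the
#' 95th percentile of silhouettes obtained on Gaussian reference samples
#' matched to the cluster's covariance (small noise clusters routinely
#' reach silhouettes near 0.6, so a fixed threshold alone over-splits).
#' Splitting
#' locally avoids the global-silhouette failure mode where one very
#' distant module masks the separation between two nearby ones; k = 1 is
#' declared when the first split already fails the threshold. Cells
#' farther than 3 within-cluster s.d. of spacing from their module mean
#' are left unassigned (`NA`).
#'
#' @param spacing_cm Per-cell spacing estimates (cm).
#' @param orientation_deg Per-cell orientation estimates (degrees in
#'   `[0, 60)`).
#' @param k_max Maximum number of modules tried (default 4).
#' @param orientation_weight Scale applied to orientation (per degree)
#'   relative to log-spacing (default 0.02).
#' @param silhouette_min Minimum mean silhouette to accept k >= 2
#'   (default 0.5).
#' @param seed Seed for the k-means restarts.
#' @return List with `module` (integer labels, `NA` = unassigned), `k`,
#'   and `summary` (`data.frame` of per-module mean/s.d. of spacing and
#'   orientation and cell counts).
#' @export
assign_modules <- function(spacing_cm, orientation_deg, k_max = 4,
                           orientation_weight = 0.02, silhouette_min = 0.5,
                           seed = 1) {
  n <- length(spacing_cm)
  if (n < 1) stop("need at least one cell")
  X <- cbind(log(spacing_cm), orientation_deg * orientation_weight)
  set.seed(seed)
  mean_sil <- function(Ds, cls) {
    m <- length(cls)
    mean(vapply(seq_len(m), function(i) {
      own <- cls[i]
      a <- mean(Ds[i, cls == own & seq_len(m) != i])
      if (!is.finite(a)) return(0)
      b <- min(vapply(setdiff(unique(cls), own), function(g)
        mean(Ds[i, cls == g]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  split_sil <- function(Xs) {
    km <- tryCatch(kmeans(Xs, centers = 2, nstart = 20),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2) return(NULL)
    list(cluster = km$cluster, sil = mean_sil(as.matrix(dist(Xs)),
                                              km$cluster))
  }
  # 95th percentile of the 2-means silhouette on Gaussian reference data
  # matched to the cluster's covariance: small clusters of pure noise
  # routinely reach silhouettes ~0.6, so a fixed threshold cannot separate
  # them from genuine module structure
  null_sil_95 <- function(Xs, B = 100) {
    m <- nrow(Xs)
    L <- chol(cov(Xs) + diag(1e-10, ncol(Xs)))
    vals <- replicate(B, {
      s <- split_sil(matrix(rnorm(m * ncol(Xs)), m) %*% L)
      if (is.null(s)) 1 else s$sil
    })
    quantile(vals, 0.95, names = FALSE)
  }
  cl <- rep(1L, n)
  repeat {
    changed <- FALSE
    for (g in unique(cl)) {
      if (length(unique(cl)) >= k_max) break
      idx <- which(cl == g)
      if (length(idx) < 3) next
      s <- split_sil(X[idx, , drop = FALSE])
      if (is.null(s) || !is.finite(s$sil)) next
      if (s$sil >= silhouette_min &&
          s$sil > null_sil_95(X[idx, , drop = FALSE])) {
        cl[idx[s$cluster == 2]] <- max(cl) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # order module labels by mean spacing for stable, reportable labels
  means <- tapply(spacing_cm, cl, mean)
  relab <- match(cl, as.integer(names(sort(means))))
  # outlier rule: > 3 within-module s.d. of spacing from the module mean
  module <- as.integer(relab)
  for (g in unique(module)) {
    idx <- which(module == g)
    s <- sd(spacing_cm[idx])
    if (is.finite(s) && s > 0) {
      far <- abs(spacing_cm[idx] - mean(spacing_cm[idx])) > 3 * s
      module[idx[far]] <- NA_integer_
    }
  }
  summ <- do.call(rbind, lapply(sort(unique(module[!is.na(module)])), function(g) {
    idx <- which(module == g)
    data.frame(module = g, n = length(idx),
               spacing_mean = mean(spacing_cm[idx]),
               spacing_sd = sd(spacing_cm[idx]),
               orientation_mean = mean(orientation_deg[idx]),
               orientation_sd = sd(orientation_deg[idx]))
  }))
  list(module = module, k = length(unique(cl)), summary = summ)
}
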