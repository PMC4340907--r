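#' Pearson correlation coefficient with explicit degeneracy handling
#'
#' The product-moment correlation of two rate vectors over the visits to a
#' spatial bin. Unlike [stats::cor()], a zero-variance input is signalled
#' as `NA` with an attribute rather than an error or a silent `NA`, so the
#' bin-averaging in [noise_correlation_matrix()] can count skipped bins.
#'
#' @param u,v Numeric vectors of equal length `k >= 2`.
#' @return The correlation, or `NA` (with attribute `reason`) when either
#'   vector has zero variance.
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4)) # 0.9820
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (length(u) < 2) stop("need at least 2 observations")
  if (sd(u) == 0 || sd(v) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  cor(u, v)
}

#' Trajectory-conditioned noise correlations
#'
#' For every cell pair (i, j), computes `C_ij` as the unweighted mean over
#' spatial bins `a` of the Pearson correlation between the two cells'
#' per-visit mean firing rates in that bin. Conditioning each correlation
#' on the spatial bin removes the rate covariation produced by overlapping
#' firing fields, leaving the "noise" component. Bins with fewer than two
#' visits, or where either cell's per-visit rates have zero variance, are
#' skipped and counted.
#'
#' @param visits A [gn_visits][segment_visits] table built from the same
#'   session as the smoothed rates it carries.
#' @param min_visits Minimum visits for a bin to qualify (default 2).
#' @return Object of class `gn_noisecorr`: list with `C` (symmetric cells x
#'   cells matrix, diagonal `NA`), `n_bins_used` (pairwise counts of
#'   contributing bins), `n_bins_skipped`, `n_bins_per_side`.
#' @export
noise_correlation_matrix <- function(visits, min_visits = 2) {
  n_cells <- ncol(visits$rate_means)
  Csum <- matrix(0, n_cells, n_cells)
  Cnum <- matrix(0L, n_cells, n_cells)
  skipped <- matrix(0L, n_cells, n_cells)
  for (b in unique(visits$visits$bin)) {
    rows <- which(visits$visits$bin == b)
    if (length(rows) < min_visits) next
    Rb <- visits$rate_means[rows, , drop = FALSE]
    sds <- apply(Rb, 2, sd)
    ok <- sds > 0
    skipped <- skipped + outer(!ok, !ok, "|") * 1L
    if (sum(ok) >= 2) {
      rho <- suppressWarnings(cor(Rb[, ok, drop = FALSE]))
      idx <- which(ok)
      fin <- is.finite(rho)
      Csum[idx, idx] <- Csum[idx, idx] + ifelse(fin, rho, 0)
      Cnum[idx, idx] <- Cnum[idx, idx] + fin * 1L
    }
  }
  C <- Csum / Cnum
  C[Cnum == 0] <- NA_real_
  diag(C) <- NA_real_
  structure(list(C = C, n_bins_used = Cnum, n_bins_skipped = skipped,
                 n_bins_per_side = visits$n_bins_per_side),
            class = "gn_noisecorr")
}

#' Randomly split visits into two halves
#'
#' For every spatial bin, assigns a randomly chosen half of its visits to
#' one partition and the rest to the other (an odd visit goes to a random
#' side). Recomputing noise correlations on the two halves and correlating
#' them measures estimator stability against sampling noise.
#'
#' @param visits A [gn_visits][segment_visits] table.
#' @param seed Integer seed.
#' @return List of two `gn_visits` objects whose visits are disjoint and
#'   jointly exhaustive.
#' @export
split_visits <- function(visits, seed = 1) {
  if (nrow(visits$visits) == 0) stop("empty visit table")
  set.seed(seed)
  take1 <- logical(nrow(visits$visits))
  for (b in unique(visits$visits$bin)) {
    rows <- which(visits$visits$bin == b)
    k <- length(rows)
    n1 <- floor(k / 2) + (k %% 2 == 1 && runif(1) < 0.5)
    take1[sample(rows, n1)] <- TRUE
  }
  sub <- function(keep) {
    structure(list(visits = visits$visits[keep, , drop = FALSE],
                   rate_means = visits$rate_means[keep, , drop = FALSE],
                   n_bins_per_side = visits$n_bins_per_side,
                   bin_cm = visits$bin_cm),
              class = "gn_visits")
  }
  list(sub(take1), sub(!take1))
}

#' Stability of noise correlations across visit halves
#'
#' Repeatedly splits the visits in half ([split_visits()]), recomputes the
#' noise-correlation matrix on each half, and correlates the two halves'
#' off-diagonal entries. The mean over repeats is the consistency metric
#' used to pick the spatial bin size.
#'
#' @param visits A [gn_visits][segment_visits] table.
#' @param n_splits Number of random splits (default 20).
#' @param seed Base seed; split `s` uses `seed + s - 1`.
#' @return List with `mean_pcc`, `pcc` (per split), and `replicates`
#'   (list of per-split pairs of `gn_noisecorr` matrices).
#' @export
noise_correlation_stability <- function(visits, n_splits = 20, seed = 1) {
  pcc <- numeric(n_splits)
  reps <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    halves <- split_visits(visits, seed = seed + s - 1)
    C1 <- noise_correlation_matrix(halves[[1]])$C
    C2 <- noise_correlation_matrix(halves[[2]])$C
    u <- C1[upper.tri(C1)]; v <- C2[upper.tri(C2)]
    ok <- is.finite(u) & is.finite(v)
    pcc[s] <- if (sum(ok) >= 3) cor(u[ok], v[ok]) else NA_real_
    reps[[s]] <- list(C1 = C1, C2 = C2)
  }
  list(mean_pcc = mean(pcc, na.rm = TRUE), pcc = pcc, replicates = reps)
}

#' Regression of pairwise values on phase distance
#'
#' Ordinary least squares of a per-pair quantity (noise correlations
#' `C_ij`, or inferred couplings `J_ij`) on the pairs' normalized spatial
#' phase distance, with two-sided t-tests on slope and intercept. A
#' negative slope is the signature of phase-dependent connectivity.
#'
#' @param values Per-pair numeric values.
#' @param phase_distance Per-pair normalized phase distances.
#' @return A `data.frame` with rows `intercept` and `slope`: `estimate`,
#'   `std_error`, `t`, `p`; attribute `n` gives the pair count used.
#' @export
correlation_vs_phase_regression <- function(values, phase_distance) {
  ok <- is.finite(values) & is.finite(phase_distance)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(phase_distance[ok]) == 0)
    stop("phase distances are all equal; regression is degenerate")
  fit <- lm(values[ok] ~ phase_distance[ok])
  sm <- summary(fit)$coefficients
  out <- data.frame(
    term = c("intercept", "slope"),
    estimate = sm[, 1], std_error = sm[, 2], t = sm[, 3], p = sm[, 4]
  )
  rownames(out) <- out$term
  attr(out, "n") <- sum(ok)
  out
}
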