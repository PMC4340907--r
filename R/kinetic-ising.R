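# numerically safe log(2 cosh x)
log2cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x)))

new_component <- function(name, X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("covariate rows must be finite")
  structure(list(name = name, X = X), class = "gn_field_component")
}

#' Constant external field component
#'
#' A single all-ones covariate: the per-cell bias `h_i`, constant over
#' time and space.
#'
#' @param n_t Number of time bins.
#' @return A field component (see [ki_design()]).
#' @export
design_constant <- function(n_t) {
  new_component("constant", matrix(1, n_t, 1))
}

#' Box-discretized spatial field component
#'
#' Divides the arena into `K_per_side^2` equal square boxes and emits a
#' one-hot indicator per time bin marking the occupied box, so each cell
#' gets one field coefficient per box. `K_per_side = 1` reduces to a
#' constant field.
#'
#' @param trajectory A [gn_trajectory][simulate_trajectory] sampled at the
#'   raster's time bins.
#' @param K_per_side Boxes per arena side (4 gives 37.5 cm boxes on a
#'   150 cm arena; 20 gives 7.5 cm).
#' @param arena_side_cm Defaults to the trajectory attribute.
#' @return A field component with `K_per_side^2` covariates.
#' @export
design_box <- function(trajectory, K_per_side, arena_side_cm = NULL) {
  if (K_per_side < 1) stop("`K_per_side` must be >= 1")
  L <- arena_side_cm %||% attr(trajectory, "arena_side") %||%
    max(trajectory$x, trajectory$y)
  K <- as.integer(K_per_side)
  bin_cm <- L / K
  bof <- function(v) pmin(pmax(floor(v / bin_cm) + 1L, 1L), K)
  id <- (bof(trajectory$y) - 1L) * K + bof(trajectory$x)
  X <- matrix(0, nrow(trajectory), K * K)
  X[cbind(seq_len(nrow(trajectory)), id)] <- 1
  new_component(sprintf("box%d", K), X)
}

#' Gaussian-basis spatial field component
#'
#' Spatial field built as a weighted sum of isotropic Gaussian basis
#' functions centred on an evenly spaced `M x M` square lattice spanning
#' the arena: covariate `jk` at time `t` is
#' `exp(-((x(t)-x_jk)^2 + (y(t)-y_jk)^2) / r^2)`. The defaults `M = 15`
#' and `r = 8.5` cm maximize Akaike-adjusted likelihood on open-field
#' recordings; pair this with [design_constant()] for the additive `h_i`.
#'
#' @param trajectory A [gn_trajectory][simulate_trajectory].
#' @param M Basis lattice side (default 15).
#' @param r_cm Basis width (default 8.5 cm); note the kernel uses `r^2`,
#'   not `2 r^2`, in the denominator.
#' @param arena_side_cm Defaults to the trajectory attribute.
#' @return A field component with `M^2` covariates.
#' @export
design_gaussian_spatial <- function(trajectory, M = 15, r_cm = 8.5,
                                    arena_side_cm = NULL) {
  if (M < 1 || r_cm <= 0) stop("need `M` >= 1 and `r_cm` > 0")
  L <- arena_side_cm %||% attr(trajectory, "arena_side") %||%
    max(trajectory$x, trajectory$y)
  ctr <- (seq_len(M) - 0.5) * L / M
  centers <- as.matrix(expand.grid(x = ctr, y = ctr))
  X <- matrix(0, nrow(trajectory), M * M)
  for (k in seq_len(M * M)) {
    X[, k] <- exp(-((trajectory$x - centers[k, 1])^2 +
                      (trajectory$y - centers[k, 2])^2) / r_cm^2)
  }
  attr(X, "centers") <- centers
  new_component(sprintf("gauss%d", M), X)
}

#' Angular (theta / head-direction / running-direction) field component
#'
#' Gaussian bumps on the circle: covariate `k` at time `t` is
#' `exp(-d(angle(t), c_k)^2 / width^2)` with `d` the minimal angular
#' distance and `c_k` one of `n_centers` equally spaced angles. Used for
#' LFP theta phase, head direction and running direction alike.
#'
#' @param angles Per-bin angle in radians; values outside `(-pi, pi]` are
#'   wrapped with a warning.
#' @param n_centers Number of angular basis functions (default 10).
#' @param width Kernel width in radians (default `pi/6`).
#' @param name Component label (default `"angular"`; use e.g. `"theta"`,
#'   `"head_direction"`).
#' @return A field component with `n_centers` covariates.
#' @export
design_angular <- function(angles, n_centers = 10, width = pi / 6,
                           name = "angular") {
  if (any(angles <= -pi | angles > pi, na.rm = TRUE)) {
    warning("angles outside (-pi, pi] wrapped")
    angles <- wrap_angle(angles)
  }
  centers <- -pi + (seq_len(n_centers) - 0.5) * 2 * pi / n_centers
  X <- matrix(vapply(centers, function(ck)
    exp(-angular_distance(angles, ck)^2 / width^2),
    numeric(length(angles))), nrow = length(angles))
  attr(X, "centers") <- centers
  new_component(name, X)
}

#' Running-direction angles from a trajectory
#'
#' Direction of the displacement vector between consecutive trajectory
#' samples (the last sample repeats the previous direction), wrapped to
#' `(-pi, pi]`. Feed into [design_angular()].
#'
#' @param trajectory A [gn_trajectory][simulate_trajectory].
#' @return Angles in radians, one per sample.
#' @export
running_direction <- function(trajectory) {
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  a <- atan2(dy, dx)
  a[dx == 0 & dy == 0] <- NA
  # carry the last defined direction through stationary samples
  for (i in seq_along(a)) if (is.na(a[i])) a[i] <- if (i > 1) a[i - 1] else 0
  wrap_angle(c(a, a[length(a)]))
}

#' Speed field component
#'
#' A single scalar covariate: the average running speed in the 100 ms
#' window centred on each time bin (truncated at the session edges).
#'
#' @param trajectory A [gn_trajectory][simulate_trajectory].
#' @param window_s Averaging window (default 0.1 s).
#' @return A field component with one covariate.
#' @export
design_speed <- function(trajectory, window_s = 0.1) {
  dt <- attr(trajectory, "dt") %||% median(diff(trajectory$t))
  half <- max(0L, as.integer(round(window_s / dt / 2)))
  n <- nrow(trajectory)
  s <- trajectory$speed
  cs <- cumsum(c(0, s))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  X <- matrix((cs[hi + 1] - cs[lo]) / (hi - lo + 1), n, 1)
  new_component("speed", X)
}

#' Assemble an external-field design
#'
#' Binds field components into the design matrix of the kinetic Ising
#' model: one covariate row per time bin, whose inner product with a
#' cell's coefficient vector gives that cell's external field `h_i(t)`.
#'
#' @param ... Field components (from the `design_*` builders), or a single
#'   list of them.
#' @return Object of class `gn_design`: list with `X` (time-bins x
#'   covariates), `components` (`data.frame` name/start/end), `p`.
#' @examples
#' traj <- simulate_trajectory(10, 0.01, 150, seed = 1)
#' d <- ki_design(design_constant(nrow(traj)), design_box(traj, 4))
#' d$p # 17 covariates
#' @export
ki_design <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && !inherits(comps[[1]], "gn_field_component"))
    comps <- comps[[1]]
  if (!length(comps)) stop("need at least one field component")
  n_t <- nrow(comps[[1]]$X)
  Xs <- lapply(comps, function(cc) {
    if (nrow(cc$X) != n_t) stop("components disagree on the number of time bins")
    cc$X
  })
  X <- do.call(cbind, Xs)
  sizes <- vapply(comps, function(cc) ncol(cc$X), integer(1))
  ends <- cumsum(sizes)
  structure(
    list(X = X, p = ncol(X),
         components = data.frame(
           name = vapply(comps, `[[`, character(1), "name"),
           start = ends - sizes + 1L, end = ends)),
    class = "gn_design"
  )
}

#' Conditional spike probability of the kinetic Ising model
#'
#' `P(S = s | H) = exp(sH) / (2 cosh H)`, computed in an overflow-safe
#' logistic form `1 / (1 + exp(-2sH))`.
#'
#' @param s Spike state, -1 or +1 (vectorized).
#' @param H Total field (vectorized).
#' @return Probabilities in (0, 1).
#' @export
conditional_prob <- function(s, H) {
  1 / (1 + exp(-2 * s * H))
}

#' Total field of the kinetic Ising model
#'
#' `H_i(t) = h_i(t) + sum_j J_ij S_j(t)`: external field plus the coupling
#' drive from the population state.
#'
#' @param h External fields, cells x time-bins.
#' @param J Coupling matrix.
#' @param S State matrix (-1/+1), cells x time-bins.
#' @return Matrix of total fields, cells x time-bins.
#' @export
total_field <- function(h, J, S) {
  h <- as.matrix(h); S <- as.matrix(S); J <- as.matrix(J)
  if (nrow(h) != nrow(S) || ncol(h) != ncol(S) ||
      nrow(J) != nrow(S) || ncol(J) != nrow(S))
    stop("dimension mismatch between `h`, `J` and `S`")
  h + J %*% S
}

# internal: per-cell field matrix h (cells x T) from design and coefficients
field_matrix <- function(design, alpha) {
  alpha %*% t(design$X)
}

check_raster <- function(raster) {
  if (!inherits(raster, "gn_raster")) stop("`raster` must be a gn_raster")
  if (!all(raster$S == 1L | raster$S == -1L))
    stop("raster entries must be -1 or +1")
  invisible(TRUE)
}

#' Log-likelihood of a spike raster under the kinetic Ising model
#'
#' The natural-log likelihood
#' `L = sum_{i,t} [S_i(t+1) H_i(t) - log 2 cosh H_i(t)]`, summed over the
#' selected transition pairs (all `T - 1` of them by default; the first
#' bin has no predecessor and never enters).
#'
#' @param raster A [gn_raster][binarize_spikes].
#' @param design A [gn_design][ki_design] with one row per raster bin.
#' @param alpha Field coefficients, cells x covariates.
#' @param J Coupling matrix (cells x cells), or `NULL` for no couplings.
#' @param pairs Integer indices `t` of the transitions `(t, t+1)` to sum
#'   over, in `1..T-1`; default all.
#' @return The log-likelihood (scalar).
#' @export
ki_loglik <- function(raster, design, alpha, J = NULL, pairs = NULL) {
  check_raster(raster)
  S <- raster$S
  T_ <- ncol(S)
  if (T_ < 2) stop("need at least two time bins")
  pairs <- pairs %||% seq_len(T_ - 1)
  H <- field_matrix(design, alpha)[, pairs, drop = FALSE]
  if (!is.null(J)) H <- H + as.matrix(J) %*% S[, pairs, drop = FALSE]
  Snext <- S[, pairs + 1, drop = FALSE]
  sum(Snext * H - log2cosh(H))
}

#' Analytic gradient of the kinetic Ising log-likelihood
#'
#' Residual form: with `u_i(t) = S_i(t+1) - tanh H_i(t)`,
#' `dL/dJ_ij = sum_t u_i(t) S_j(t)` and the gradient of a field
#' coefficient is the same residual times the covariate value.
#'
#' @inheritParams ki_loglik
#' @return List with `alpha` (cells x covariates) and, when `J` is given,
#'   `J` (cells x cells).
#' @export
ki_gradient <- function(raster, design, alpha, J = NULL, pairs = NULL) {
  check_raster(raster)
  S <- raster$S
  T_ <- ncol(S)
  pairs <- pairs %||% seq_len(T_ - 1)
  Sprev <- S[, pairs, drop = FALSE]
  H <- field_matrix(design, alpha)[, pairs, drop = FALSE]
  if (!is.null(J)) H <- H + as.matrix(J) %*% Sprev
  U <- S[, pairs + 1, drop = FALSE] - tanh(H)
  out <- list(alpha = U %*% design$X[pairs, , drop = FALSE])
  if (!is.null(J)) out$J <- U %*% t(Sprev)
  out
}

# Newton ascent with step halving for one cell's concave logistic problem.
# W: observations x params, y in {-1, +1}. Returns coefficients etc.
newton_cell <- function(W, y, lambda = 0, tol = 1e-5, max_iter = 100) {
  p <- ncol(W)
  theta <- numeric(p)
  H <- as.vector(W %*% theta)
  ll <- sum(y * H - log2cosh(H)) - lambda * sum(theta^2)
  converged <- FALSE
  it <- 0
  gmax <- Inf
  while (it < max_iter) {
    it <- it + 1
    th <- tanh(H)
    u <- y - th
    g <- crossprod(W, u) - 2 * lambda * theta
    gmax <- max(abs(g))
    if (gmax < tol) { converged <- TRUE; break }
    wgt <- pmax(1 - th^2, 1e-12)
    Hmat <- crossprod(W, W * wgt)
    diag(Hmat) <- diag(Hmat) + 2 * lambda + 1e-10
    step <- tryCatch(solve(Hmat, g), error = function(e) g / max(diag(Hmat)))
    s <- 1
    repeat {
      theta_new <- theta + s * as.vector(step)
      H_new <- as.vector(W %*% theta_new)
      ll_new <- sum(y * H_new - log2cosh(H_new)) - lambda * sum(theta_new^2)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { theta_new <- theta; H_new <- H; ll_new <- ll; break }
    }
    # parameter-precision optimum: the step no longer moves theta in
    # double precision, so the remaining gradient is numerical residue
    if (max(abs(theta_new - theta)) < 1e-11 * (1 + max(abs(theta)))) {
      theta <- theta_new; H <- H_new; ll <- ll_new
      converged <- TRUE
      break
    }
    theta <- theta_new; H <- H_new; ll <- ll_new
  }
  # final gradient check
  g <- crossprod(W, y - tanh(H)) - 2 * lambda * theta
  gmax <- max(abs(g))
  list(theta = theta, loglik = sum(y * H - log2cosh(H)),
       converged = converged || gmax < tol, grad_max = gmax, iterations = it)
}

#' Fit the kinetic Ising model by maximum likelihood
#'
#' Maximizes the log-likelihood over all field coefficients and couplings.
#' The likelihood factorizes over cells, and each cell's problem is a
#' concave logistic-type objective, solved here by damped Newton ascent
#' (quadratic convergence near the optimum; the optimum is what matters,
#' not the path). Initialization at zero; convergence when the gradient
#' max-norm falls below `tol`.
#'
#' With `lambda > 0` an L2 (ridge) penalty `lambda * ||theta||^2` is
#' subtracted, useful when covariates are collinear or a cell never (or
#' always) spikes; the default is unpenalized.
#'
#' @param raster A [gn_raster][binarize_spikes].
#' @param design A [gn_design][ki_design].
#' @param couplings Include pairwise couplings `J`? (default TRUE)
#' @param self_couplings Include the diagonal `J_ii`? (default TRUE;
#'   ignored when `couplings = FALSE`)
#' @param lambda Ridge penalty (default 0).
#' @param pairs Transition indices to fit on (default all `T - 1`).
#' @param tol Gradient max-norm tolerance (default 1e-5).
#' @param max_iter Newton iteration cap per cell (default 100).
#' @return Object of class `gn_fit`: `J` (cells x cells, zero when
#'   couplings are off), `alpha` (cells x covariates), `loglik`,
#'   `n_params`, `converged`, `grad_max`, `iterations`, plus bookkeeping
#'   (`design`, `couplings`, `self_couplings`, `pairs`, `lambda`).
#' @export
ki_fit <- function(raster, design, couplings = TRUE, self_couplings = TRUE,
                   lambda = 0, pairs = NULL, tol = 1e-5, max_iter = 100) {
  check_raster(raster)
  S <- raster$S
  n <- nrow(S); T_ <- ncol(S)
  if (T_ < 2) stop("need at least two time bins")
  pairs <- pairs %||% seq_len(T_ - 1)
  X <- design$X[pairs, , drop = FALSE]
  p <- ncol(X)
  Sprev <- t(S[, pairs, drop = FALSE]) # observations x cells
  if (couplings) W_full <- cbind(X, Sprev) else W_full <- X
  alpha <- matrix(0, n, p)
  J <- matrix(0, n, n)
  ll <- 0; conv <- TRUE; gmax <- 0; iters <- integer(n)
  for (i in seq_len(n)) {
    y <- S[i, pairs + 1]
    if (all(y == y[1]) && lambda == 0)
      warning(sprintf(paste0("cell %d %s spikes in every fitted bin; its ",
                             "field is unbounded (consider lambda > 0)"),
                      i, if (y[1] == 1) "" else "never"))
    if (couplings && !self_couplings) {
      W <- W_full[, -(p + i), drop = FALSE]
      res <- newton_cell(W, y, lambda, tol, max_iter)
      alpha[i, ] <- res$theta[seq_len(p)]
      J[i, -i] <- res$theta[-seq_len(p)]
    } else {
      res <- newton_cell(W_full, y, lambda, tol, max_iter)
      alpha[i, ] <- res$theta[seq_len(p)]
      if (couplings) J[i, ] <- res$theta[p + seq_len(n)]
    }
    ll <- ll + res$loglik
    conv <- conv && res$converged
    gmax <- max(gmax, res$grad_max)
    iters[i] <- res$iterations
  }
  n_params <- n * p +
    if (couplings) (if (self_couplings) n * n else n * (n - 1)) else 0
  structure(
    list(J = J, alpha = alpha, loglik = ll, n_params = n_params,
         converged = conv, grad_max = gmax, iterations = iters,
         design = design, couplings = couplings,
         self_couplings = self_couplings, pairs = pairs, lambda = lambda,
         n_cells = n, n_transitions = length(pairs),
         bin_width_s = raster$bin_width_s),
    class = "gn_fit"
  )
}

#' @export
print.gn_fit <- function(x, ...) {
  cat(sprintf(paste0("<gn_fit> %d cells, %d transitions, %d parameters ",
                     "(%s couplings)\n  lnL = %.2f, converged: %s ",
                     "(max |grad| = %.2e)\n"),
              x$n_cells, x$n_transitions, x$n_params,
              if (x$couplings) "with" else "no", x$loglik,
              x$converged, x$grad_max))
  invisible(x)
}
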