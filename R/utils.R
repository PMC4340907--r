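#' @useDynLib gridnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif sd var median kmeans lm coef pf pt var.test
#' @importFrom stats convolve fft optimize quantile complete.cases setNames dist
#' @importFrom utils read.delim write.table head tail
NULL

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Minimal angular distance
#'
#' Shortest distance between two angles on the circle, i.e. the minimum of
#' `|a - b + 2*pi*n|` over integer wraps `n`. Used by the angular basis
#' functions of the field model and by all circular statistics.
#'
#' @param a,b Angles in radians (any range; wrapping is handled). Recycled
#'   against each other.
#' @return Distances in `[0, pi]`.
#' @examples
#' angular_distance(pi - 0.1, -pi + 0.1) # 0.2
#' @export
angular_distance <- function(a, b) {
  abs(wrap_angle(a - b))
}

# circular mean of angles; returns NA for empty input
circ_mean <- function(a, w = NULL) {
  if (length(a) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(a))
  atan2(sum(w * sin(a)), sum(w * cos(a)))
}

# mean resultant length
circ_resultant <- function(a) {
  if (length(a) == 0) return(NA_real_)
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

# hexagonal lattice basis vectors as columns of a 2 x 2 matrix;
# orientation in degrees, spacing in cm
hex_basis <- function(spacing, orientation_deg) {
  th <- orientation_deg * pi / 180
  cbind(
    spacing * c(cos(th), sin(th)),
    spacing * c(cos(th + pi / 3), sin(th + pi / 3))
  )
}

# all lattice vertices m*a1 + n*a2 + phase with coordinates inside
# [lo - margin, hi + margin]^2; returns k x 2 matrix
hex_vertices <- function(spacing, orientation_deg, phase, lo, hi, margin) {
  B <- hex_basis(spacing, orientation_deg)
  corners <- rbind(
    c(lo - margin, lo - margin), c(lo - margin, hi + margin),
    c(hi + margin, lo - margin), c(hi + margin, hi + margin)
  )
  mn <- t(solve(B, t(sweep(corners, 2, phase))))
  mr <- floor(min(mn[, 1])):ceiling(max(mn[, 1]))
  nr <- floor(min(mn[, 2])):ceiling(max(mn[, 2]))
  g <- as.matrix(expand.grid(m = mr, n = nr))
  V <- g %*% t(B)
  V[, 1] <- V[, 1] + phase[1]
  V[, 2] <- V[, 2] + phase[2]
  keep <- V[, 1] >= lo - margin & V[, 1] <= hi + margin &
    V[, 2] >= lo - margin & V[, 2] <= hi + margin
  V[keep, , drop = FALSE]
}

# Ornstein-Uhlenbeck path: dx = -(x - mu)/tau dt + sigma sqrt(dt) dW
ou_path <- function(n, dt, mu, tau, sigma, x0 = mu) {
  x <- numeric(n)
  x[1] <- x0
  a <- dt / tau
  noise <- sigma * sqrt(dt) * rnorm(n - 1)
  for (i in 2:n) x[i] <- x[i - 1] - a * (x[i - 1] - mu) + noise[i - 1]
  x
}

stop_if_not_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  invisible(TRUE)
}
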