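#' Score a fitted model (AIC and Akaike-corrected likelihood)
#'
#' Computes `AIC = -2 lnL + 2k` and the Akaike-corrected log-likelihood
#' `lnL - k` (equivalently `-AIC/2`) for a fitted kinetic Ising model,
#' plus the negative log-likelihood per cell per time bin used for
#' model-comparison bar charts. The corrected likelihood penalizes every
#' inferred parameter - covariate coefficients and couplings alike.
#'
#' @param fit A [gn_fit][ki_fit].
#' @param loglik Override the log-likelihood to score (e.g. a held-out
#'   one); defaults to the fit's training log-likelihood.
#' @param n_transitions Number of transitions the log-likelihood sums over
#'   (defaults to the fit's).
#' @param label Model label carried through to reports.
#' @return Object of class `gn_score`: list with `label`, `loglik`, `k`,
#'   `aic`, `loglik_akaike`, `neg_ll_per_cell_bin`, `converged`.
#' @export
score_model <- function(fit, loglik = NULL, n_transitions = NULL,
                        label = NULL) {
  if (inherits(fit, "gn_fit") && !fit$converged)
    warning("scoring a non-converged fit")
  ll <- loglik %||% fit$loglik
  k <- fit$n_params
  nt <- n_transitions %||% fit$n_transitions
  structure(
    list(label = label %||% "model", loglik = ll, k = k,
         aic = -2 * ll + 2 * k, loglik_akaike = ll - k,
         neg_ll_per_cell_bin = -ll / (fit$n_cells * nt),
         converged = if (inherits(fit, "gn_fit")) fit$converged else NA),
    class = "gn_score"
  )
}

#' Random partition of transition pairs
#'
#' Treats the raster as `T - 1` consecutive pairs `(S(t), S(t+1))` and
#' randomly assigns a fraction of them to a training set, the rest held
#' out. Both subsets index transitions usable by [ki_loglik()] and
#' [ki_fit()] via their `pairs` argument.
#'
#' @param raster A [gn_raster][binarize_spikes], or the number of bins `T`.
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return List with `train` and `test` (sorted integer indices; disjoint,
#'   jointly exhaustive, sizes differing by at most 1 at `fraction = 0.5`).
#' @export
pair_partition <- function(raster, fraction = 0.5, seed = 1) {
  T_ <- if (inherits(raster, "gn_raster")) ncol(raster$S) else raster
  if (T_ < 2) stop("need at least two time bins")
  set.seed(seed)
  idx <- seq_len(T_ - 1)
  n_train <- round(fraction * (T_ - 1))
  train <- sort(sample(idx, n_train))
  list(train = train, test = setdiff(idx, train))
}

#' Held-out (cross-half) likelihood of a model
#'
#' Fits the model on a random half of the transition pairs and evaluates
#' the log-likelihood of the other half at the fitted parameters, with the
#' Akaike parameter penalty applied to the held-out value as well (the
#' paper-style correction; the uncorrected held-out value is also
#' returned). Ranking models by this score asks which covariates genuinely
#' explain the data rather than overfit it.
#'
#' @param raster A [gn_raster][binarize_spikes].
#' @param design A [gn_design][ki_design].
#' @param couplings,self_couplings,lambda Passed to [ki_fit()].
#' @param fraction Training fraction (default 0.5).
#' @param seed Partition seed.
#' @param label Model label.
#' @return A [gn_score][score_model] for the held-out half, with extra
#'   fields `loglik_heldout_raw` and `fit` (the training fit).
#' @export
cross_half_likelihood <- function(raster, design, couplings = TRUE,
                                  self_couplings = TRUE, lambda = 0,
                                  fraction = 0.5, seed = 1, label = NULL) {
  part <- pair_partition(raster, fraction, seed)
  fit <- ki_fit(raster, design, couplings = couplings,
                self_couplings = self_couplings, lambda = lambda,
                pairs = part$train)
  ll_out <- ki_loglik(raster, design, fit$alpha,
                      J = if (couplings) fit$J else NULL,
                      pairs = part$test)
  sc <- score_model(fit, loglik = ll_out, n_transitions = length(part$test),
                    label = label)
  sc$loglik_heldout_raw <- ll_out
  sc$fit <- fit
  sc
}

#' Stability of couplings across data halves
#'
#' Pearson correlations between two coupling matrices (typically inferred
#' from complementary halves of the data), computed over entry subsets:
#' all off-diagonal couplings, self-couplings (diagonal), within-module
#' off-diagonal and between-module pairs. Higher within-module than
#' between-module stability indicates module-local functional networks.
#'
#' @param J1,J2 Coupling matrices of equal shape, same cell order.
#' @param modules Optional per-cell module labels (`NA` = unassigned).
#' @return A `data.frame` with columns `subset`, `pcc`, `n`; subsets with
#'   fewer than 3 entries get `NA`.
#' @export
coupling_stability <- function(J1, J2, modules = NULL) {
  if (!all(dim(J1) == dim(J2))) stop("matrices must have the same shape")
  n <- nrow(J1)
  off <- !diag(TRUE, n)
  subsets <- list(all = off, self = diag(TRUE, n))
  if (!is.null(modules)) {
    same <- outer(modules, modules, "==")
    same[is.na(same)] <- FALSE
    subsets$within_module <- off & same
    subsets$between_module <- off & !same &
      outer(!is.na(modules), !is.na(modules), "&")
  }
  rows <- lapply(names(subsets), function(nm) {
    m <- subsets[[nm]]
    u <- J1[m]; v <- J2[m]
    ok <- is.finite(u) & is.finite(v)
    data.frame(subset = nm, n = sum(ok),
               pcc = if (sum(ok) >= 3) cor(u[ok], v[ok]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' F test for within- vs between-module coupling variance
#'
#' Two-sample F test comparing the variance of within-module off-diagonal
#' couplings against between-module ones. A larger within-module variance
#' (more strong couplings of either sign inside a module) is the signature
#' of module-local connectivity.
#'
#' @param J Coupling matrix.
#' @param modules Per-cell module labels (`NA` = unassigned; those cells'
#'   pairs are dropped).
#' @param alternative Passed to [stats::var.test()]; `"greater"` tests
#'   within > between (default `"two.sided"`).
#' @return List with `F`, `p`, `df`, `var_within`, `var_between`,
#'   `n_within`, `n_between`.
#' @export
module_variance_test <- function(J, modules, alternative = "two.sided") {
  n <- nrow(J)
  if (length(unique(modules[!is.na(modules)])) < 2)
    stop("need at least two modules")
  off <- !diag(TRUE, n)
  known <- outer(!is.na(modules), !is.na(modules), "&")
  same <- outer(modules, modules, "==")
  same[is.na(same)] <- FALSE
  w <- J[off & same & known]
  b <- J[off & !same & known]
  if (length(w) < 3 || length(b) < 3)
    stop("need at least 3 couplings in each group")
  vt <- var.test(w, b, alternative = alternative)
  list(F = unname(vt$statistic), p = vt$p.value, df = unname(vt$parameter),
       var_within = var(w), var_between = var(b),
       n_within = length(w), n_between = length(b))
}

#' Filter cell pairs by precession and tetrode metadata
#'
#' Subsets a table of cell pairs, excluding pairs where both cells phase
#' precess and/or pairs recorded on the same tetrode - the robustness
#' filters applied before regressing couplings on phase distance.
#'
#' @param pairs `data.frame` with columns `i`, `j` (cell indices; other
#'   columns pass through).
#' @param precessing Per-cell logical flags; required when
#'   `exclude_precessing`.
#' @param tetrode Per-cell tetrode ids; required when
#'   `exclude_same_tetrode`.
#' @param exclude_precessing Drop pairs where *both* cells precess
#'   (default FALSE). Pairs with at least one non-precessing cell are
#'   kept.
#' @param exclude_same_tetrode Drop pairs sharing a tetrode (default
#'   FALSE).
#' @return The filtered `pairs` data.frame (possibly empty).
#' @export
pair_filters <- function(pairs, precessing = NULL, tetrode = NULL,
                         exclude_precessing = FALSE,
                         exclude_same_tetrode = FALSE) {
  keep <- rep(TRUE, nrow(pairs))
  if (exclude_precessing) {
    if (is.null(precessing))
      stop("`precessing` flags are required for exclude_precessing")
    keep <- keep & !(precessing[pairs$i] & precessing[pairs$j])
  }
  if (exclude_same_tetrode) {
    if (is.null(tetrode))
      stop("`tetrode` ids are required for exclude_same_tetrode")
    keep <- keep & tetrode[pairs$i] != tetrode[pairs$j]
  }
  pairs[keep, , drop = FALSE]
}
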