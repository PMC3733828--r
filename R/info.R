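#' Mutual information between one feature and the stage label
#'
#' Estimates I(X; Y) in nats between a single expression feature and the
#' stage label.  The default backend is moment-matched Gaussian:
#' I = H(X) - sum_y p(y) H(X | y) with each differential entropy computed
#' from a (population) variance, which reduces to
#' 0.5 * (log marginal variance - sum_y p(y) log conditional variance).
#' It is exact when the class-conditional distributions are Gaussian and is
#' deterministic.  The alternative backend discretizes X into
#' equal-frequency bins and uses the plug-in discrete MI.
#' Negative numerical estimates are clamped to zero.
#'
#' @param values numeric vector, one value per sample.
#' @param labels stage label per sample; at least two stages, each with at
#'   least two samples.
#' @param backend \code{"gaussian"} (default) or \code{"binned"}.
#' @param n_bins number of equal-frequency bins for the binned backend.
#' @param sigma_min variance floor is \code{sigma_min^2}.
#' @param min_stage_n smallest admissible per-stage sample count; the
#'   default 2 guards against zero-variance stages, and 1 admits
#'   leave-one-out resampling (the floored variance then carries the
#'   stage).
#' @return Non-negative scalar, nats.
#' @export
gene_stage_mi <- function(values, labels,
                          backend = c("gaussian", "binned"),
                          n_bins = 8, sigma_min = 1e-6, min_stage_n = 2) {
  backend <- match.arg(backend)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("at least two stages are required to compute MI with the label")
  if (any(table(labels) < min_stage_n))
    stop("every stage needs at least ", min_stage_n, " samples")
  if (backend == "gaussian") {
    vfloor <- sigma_min^2
    pv <- function(v) max(mean(v^2) - mean(v)^2, vfloor)
    p <- as.numeric(table(labels)) / length(labels)
    cond <- vapply(split(values, labels), pv, 0)
    mi <- 0.5 * (log(pv(values)) - sum(p * log(cond)))
  } else {
    br <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(0)  # constant feature
    b <- cut(values, breaks = br, include.lowest = TRUE)
    tab <- table(b, labels)
    pj <- tab / sum(tab)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    mi <- sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  }
  max(mi, 0)
}

#' Per-feature MI with the stage label
#'
#' Applies [gene_stage_mi()] to each row of a feature x sample matrix.
#'
#' @param mat numeric matrix, features x samples.
#' @inheritParams gene_stage_mi
#' @return Named non-negative vector aligned with \code{rownames(mat)}.
#' @export
mi_vector <- function(mat, labels, backend = c("gaussian", "binned"),
                      n_bins = 8, sigma_min = 1e-6, min_stage_n = 2) {
  backend <- match.arg(backend)
  stats::setNames(apply(mat, 1, gene_stage_mi, labels = labels,
                        backend = backend, n_bins = n_bins,
                        sigma_min = sigma_min, min_stage_n = min_stage_n),
                  rownames(mat))
}

#' Feature-selection distribution from MI values
#'
#' P(X_i) proportional to I(X_i; Y)^eta.  With eta = 0 every feature is
#' selected with equal probability; larger eta concentrates selection on
#' high-MI features.  If all MI values are zero the distribution falls
#' back to uniform.
#'
#' @param mi non-negative MI vector.
#' @param eta non-negative concentration exponent.
#' @return Probability vector summing to one, same names as \code{mi}.
#' @export
selection_distribution <- function(mi, eta = 1) {
  if (!length(mi)) stop("'mi' must be non-empty")
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta < 0)
    stop("'eta' must be a single non-negative number")
  w <- mi^eta
  if (eta == 0 || sum(w) == 0) w <- rep(1, length(mi))
  stats::setNames(w / sum(w), names(mi))
}

#' Gaussian total correlation of a covariance matrix
#'
#' Multi-information of a Gaussian vector:
#' TC = 0.5 * log( prod_i cov_ii / det(cov) ).  Zero iff the variables are
#' uncorrelated; invariant under per-variable rescaling.  Small negative
#' numerical values are clamped to zero.
#'
#' @param cov symmetric positive-definite covariance matrix (callers are
#'   expected to ridge-regularize sample covariances first).
#' @return Non-negative scalar, nats.
#' @export
gaussian_total_correlation <- function(cov) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("'cov' must be a square matrix")
  if (!isSymmetric(unname(cov), tol = 1e-8))
    stop("'cov' must be symmetric")
  ld <- determinant(cov, logarithm = TRUE)
  if (ld$sign <= 0)
    stop("'cov' must be positive definite (ridge-regularize first)")
  max(0.5 * (sum(log(diag(cov))) - as.numeric(ld$modulus)), 0)
}

# population covariance of samples x variables, plus ridge
.pop_cov <- function(m, ridge_eps = 1e-6) {
  m <- m - rep(colMeans(m), each = nrow(m))
  crossprod(m) / nrow(m) + diag(ridge_eps, ncol(m))
}

# total correlation without input validation (hot path)
.tc <- function(S) {
  max(0.5 * (sum(log(diag(S))) -
               as.numeric(determinant(S, logarithm = TRUE)$modulus)), 0)
}

#' Multivariate mutual information between a variable set and the label
#'
#' Interaction-information-style quantity for a hyperedge's member set:
#' I(X_1..X_k; Y) = I(X_1..X_k) - E_Y[ I(X_1..X_k | Y) ], estimated as the
#' Gaussian total correlation of the marginal covariance minus the
#' class-frequency-weighted total correlation of the stage-conditional
#' covariances.  Positive values mean the dependency structure among the
#' members changes with the stage; the value may legitimately be negative
#' (stage-conditional dependence exceeding marginal dependence) and is not
#' clamped.
#'
#' @param submatrix numeric matrix, samples x members (k >= 2 columns).
#' @param labels stage label per sample.
#' @param ridge_eps ridge added to each sample covariance diagonal.
#' @return Scalar, nats (possibly negative).
#' @export
multivariate_mi_with_class <- function(submatrix, labels, ridge_eps = 1e-6) {
  submatrix <- as.matrix(submatrix)
  if (ncol(submatrix) < 2)
    stop("at least two member variables are required")
  labels <- droplevels(as.factor(labels))
  cnt <- table(labels)
  if (any(cnt < ncol(submatrix) + 1))
    warning("some stage has fewer samples than members + 1; ",
            "the ridge term dominates the conditional covariance")
  p <- as.numeric(cnt) / length(labels)
  tc_marg <- .tc(.pop_cov(submatrix, ridge_eps))
  tc_cond <- vapply(levels(labels), function(y) {
    .tc(.pop_cov(submatrix[labels == y, , drop = FALSE], ridge_eps))
  }, 0)
  tc_marg - sum(p * tc_cond)
}
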