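#' Learning configuration
#'
#' Collects every tunable of the hypergraph learner.  Defaults follow the
#' reference parameterization: hyperedges of 3 miRNAs + 5 mRNAs, 100
#' structure-learning iterations of 20 parameter-learning epochs each,
#' kernel sharpness beta = 1, MI-selection exponent eta = 1, MMI weight
#' ratio kappa = 1, learning rate gamma = 1, and a replacement schedule
#' decaying from R_max = 0.9 to R_min = 0.5.
#'
#' @param l miRNAs per hyperedge.
#' @param m mRNAs per hyperedge.
#' @param n_hyperedges population size (constant through a run).
#' @param structure_epochs structure-learning iterations.
#' @param parameter_epochs gradient-descent epochs per structure iteration.
#' @param beta Gaussian-kernel sharpness in the matching probability.
#' @param eta exponent of the MI-proportional selection distribution.
#' @param kappa weight of the multivariate-MI term in initial weights.
#' @param gamma gradient-descent learning rate.
#' @param R_max,R_min replacement-ratio bounds, 0 < R_min <= R_max <= 1.
#' @param sigma_min standard-deviation floor.
#' @param ridge_eps covariance ridge.
#' @param mi_backend per-gene MI estimator, \code{"gaussian"} or
#'   \code{"binned"}.
#' @param n_bins bins for the binned MI backend.
#' @param degree_mode \code{"split"} draws l miRNAs and m mRNAs from their
#'   separate pools; \code{"joint"} draws l + m members from the combined
#'   pool ignoring the miRNA/mRNA distinction (used when the two blocks
#'   are an arbitrary split of one homogeneous variable set, as in the
#'   simulation experiments).
#' @param update \code{"batch"} accumulates weight deltas over the whole
#'   training set with pre-update posteriors and applies them once per
#'   epoch; \code{"online"} applies them sample by sample.
#' @param seed integer seed; all randomness of a training run flows from
#'   it.
#' @return An object of class \code{"hg_control"}.
#' @export
hg_control <- function(l = 3, m = 5, n_hyperedges = 200,
                       structure_epochs = 100, parameter_epochs = 20,
                       beta = 1, eta = 1, kappa = 1, gamma = 1,
                       R_max = 0.9, R_min = 0.5,
                       sigma_min = 1e-6, ridge_eps = 1e-6,
                       mi_backend = c("gaussian", "binned"), n_bins = 8,
                       degree_mode = c("split", "joint"),
                       update = c("batch", "online"), seed = 1) {
  ctl <- list(l = as.integer(l), m = as.integer(m),
              n_hyperedges = as.integer(n_hyperedges),
              structure_epochs = as.integer(structure_epochs),
              parameter_epochs = as.integer(parameter_epochs),
              beta = beta, eta = eta, kappa = kappa, gamma = gamma,
              R_max = R_max, R_min = R_min,
              sigma_min = sigma_min, ridge_eps = ridge_eps,
              mi_backend = match.arg(mi_backend), n_bins = as.integer(n_bins),
              degree_mode = match.arg(degree_mode),
              update = match.arg(update), seed = as.integer(seed))
  if (ctl$l + ctl$m < 2) stop("hyperedge degree l + m must be at least 2")
  if (ctl$l < 0 || ctl$m < 0) stop("'l' and 'm' must be non-negative")
  if (ctl$n_hyperedges < 1) stop("'n_hyperedges' must be positive")
  if (ctl$structure_epochs < 0 || ctl$parameter_epochs < 0)
    stop("epoch counts must be non-negative")
  if (ctl$beta <= 0) stop("'beta' must be positive")
  if (ctl$eta < 0 || ctl$kappa < 0 || ctl$gamma < 0)
    stop("'eta', 'kappa' and 'gamma' must be non-negative")
  if (!(ctl$R_min > 0 && ctl$R_min <= ctl$R_max && ctl$R_max <= 1))
    stop("need 0 < R_min <= R_max <= 1")
  if (ctl$sigma_min <= 0) stop("'sigma_min' must be positive")
  class(ctl) <- "hg_control"
  ctl
}

#' @export
print.hg_control <- function(x, ...) {
  cat("Hypergraph learning configuration\n")
  cat(sprintf("  degree: %d miRNA + %d mRNA (%s pool), population %d\n",
              x$l, x$m, x$degree_mode, x$n_hyperedges))
  cat(sprintf("  epochs: %d structure x %d parameter (%s updates)\n",
              x$structure_epochs, x$parameter_epochs, x$update))
  cat(sprintf("  beta=%g eta=%g kappa=%g gamma=%g R=[%g, %g]\n",
              x$beta, x$eta, x$kappa, x$gamma, x$R_min, x$R_max))
  cat(sprintf("  MI backend: %s; sigma_min=%g ridge=%g; seed=%d\n",
              x$mi_backend, x$sigma_min, x$ridge_eps, x$seed))
  invisible(x)
}
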