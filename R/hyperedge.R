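#' Fit per-stage statistics of a hyperedge
#'
#' A hyperedge groups l miRNAs and m mRNAs (l + m >= 2).  For every stage
#' it stores the member mean vector, per-member standard deviations
#' (population estimator, floored at \code{sigma_min}) and the full
#' member covariance matrix (ridge-regularized with \code{ridge_eps} on
#' the diagonal), all computed on that stage's samples only.  The marginal
#' covariance over all samples and the multivariate MI with the stage
#' label ([multivariate_mi_with_class()]) are stored alongside.
#'
#' Only the diagonal (the standard deviations) enters the matching
#' distance; the full covariance is kept for the multivariate-MI
#' estimator.
#'
#' @param dataset an [hg_dataset].
#' @param members character vector of member feature identifiers (miRNAs
#'   and/or mRNAs), unique, length >= 2.
#' @param sigma_min standard-deviation floor (> 0).
#' @param ridge_eps covariance ridge.
#' @param min_stage_n smallest admissible per-stage sample count
#'   (default 2; a stage below it raises a degenerate-stage error).
#' @return An object of class \code{"hyperedge"}: members split by type,
#'   \code{mu} and \code{sigma} (members x stages matrices), \code{cov}
#'   (list of per-stage matrices), \code{cov_marginal}, \code{mmi},
#'   \code{stages}.
#' @export
fit_hyperedge_stats <- function(dataset, members, sigma_min = 1e-6,
                                ridge_eps = 1e-6, min_stage_n = 2) {
  members <- as.character(members)
  if (anyDuplicated(members)) stop("hyperedge members must be unique")
  if (length(members) < 2) stop("a hyperedge needs at least two members")
  known <- c(dataset$mirna_ids, dataset$mrna_ids)
  bad <- setdiff(members, known)
  if (length(bad))
    stop("unknown feature identifier(s): ", paste(bad, collapse = ", "))
  cnt <- table(dataset$labels)
  if (any(cnt < min_stage_n))
    stop("degenerate stage (fewer than ", min_stage_n, " samples): ",
         paste(names(cnt)[cnt < min_stage_n], collapse = ", "))
  mir <- members[members %in% dataset$mirna_ids]
  mr <- members[members %in% dataset$mrna_ids]
  .fit_edge(.combined(dataset), .stage_idx(dataset), dataset$stages,
            mir, mr, sigma_min, ridge_eps)
}

# per-stage sample index list
.stage_idx <- function(dataset) {
  lapply(stats::setNames(dataset$stages, dataset$stages),
         function(y) which(dataset$labels == y))
}

# hot-path edge fit: X combined features x samples, idx per-stage indices
.fit_edge <- function(X, idx, stages, mir, mr, sigma_min, ridge_eps) {
  members <- c(mir, mr)                       # miRNAs first, fixed order
  sub <- t(X[members, , drop = FALSE])        # samples x k
  k <- length(members)
  S <- length(stages)
  mu <- sigma <- matrix(0, k, S, dimnames = list(members, stages))
  covs <- vector("list", S); names(covs) <- stages
  tc_cond <- p <- numeric(S)
  for (j in seq_len(S)) {
    sy <- sub[idx[[j]], , drop = FALSE]
    cm <- colMeans(sy)
    mu[, j] <- cm
    sigma[, j] <- pmax(sqrt(pmax(colMeans(sy^2) - cm^2, 0)), sigma_min)
    covs[[j]] <- .pop_cov(sy, ridge_eps)
    dimnames(covs[[j]]) <- list(members, members)
    tc_cond[j] <- .tc(covs[[j]])
    p[j] <- nrow(sy)
  }
  cov_marg <- .pop_cov(sub, ridge_eps)
  dimnames(cov_marg) <- list(members, members)
  mmi <- .tc(cov_marg) - sum(p / sum(p) * tc_cond)
  structure(list(mirna = mir, mrna = mr, members = members,
                 mu = mu, sigma = sigma, cov = covs,
                 cov_marginal = cov_marg, mmi = mmi, stages = stages),
            class = "hyperedge")
}

#' @export
print.hyperedge <- function(x, ...) {
  cat("Hyperedge: ", length(x$mirna), " miRNA + ", length(x$mrna),
      " mRNA {", paste(x$members, collapse = ", "), "}\n", sep = "")
  cat("MMI with stage:", format(x$mmi, digits = 4), "\n")
  if (!is.null(x$weights))
    cat("Stage weights:", paste(sprintf("%s=%.4g", names(x$weights),
                                        x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Matching probability of a profile against a hyperedge
#'
#' Gaussian-kernel match in the hyperedge's subdimension: the distance is
#' the per-member-standardized Euclidean distance to the stage mean,
#' scaled by 1/|e| (outside the square root),
#' d = (1/|e|) * sqrt( sum_j ((v_j - mu_j) / sigma_j)^2 ),
#' and the matching probability is exp(-beta * d).  Probability 1 holds
#' exactly when the profile sits on the stage means.
#'
#' @param profile named numeric vector covering all edge members (a full
#'   combined expression profile is fine; extra entries are ignored).
#' @param edge a \code{"hyperedge"}.
#' @param stage stage label.
#' @param beta positive kernel sharpness; larger beta shrinks the
#'   probability faster with distance.
#' @return List with \code{distance} (>= 0) and \code{probability}
#'   (in (0, 1]).
#' @export
match_probability <- function(profile, edge, stage, beta = 1) {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta <= 0)
    stop("'beta' must be a single positive number")
  if (!stage %in% edge$stages) stop("unknown stage: ", stage)
  miss <- setdiff(edge$members, names(profile))
  if (length(miss))
    stop("profile is missing member value(s): ", paste(miss, collapse = ", "))
  v <- profile[edge$members]
  d <- sqrt(sum(((v - edge$mu[, stage]) / edge$sigma[, stage])^2)) /
    length(edge$members)
  list(distance = d, probability = exp(-beta * d))
}

# ---- internal vectorized forward path ------------------------------------

# match probabilities of all edges x all samples for one stage.
# X: combined features x samples matrix.
.match_rows <- function(edges, X, stage, beta) {
  n <- ncol(X)
  out <- vapply(edges, function(e) {
    Z <- (X[e$members, , drop = FALSE] - e$mu[, stage]) / e$sigma[, stage]
    exp(-beta * sqrt(.colSums(Z^2, nrow(Z), ncol(Z))) / length(e$members))
  }, numeric(n))
  t(matrix(out, nrow = n))
}

# list (per stage) of edge x sample match matrices
.match_list <- function(edges, X, stages, beta) {
  m <- lapply(stages, function(y) .match_rows(edges, X, y, beta))
  names(m) <- stages
  m
}

# stage x sample score matrix from weights (edges x stages) and match list
.score_matrix <- function(W, M) {
  n <- ncol(M[[1]])
  out <- vapply(seq_along(M),
                function(j) .colSums(W[, j] * M[[j]], nrow(M[[j]]), n),
                numeric(n))
  t(matrix(out, nrow = n))
}

# posterior matrix: logistic of mean-centered scores (stages x samples)
.posterior_matrix <- function(C) {
  stats::plogis(sweep(C, 2, colMeans(C)))
}

.predict_idx <- function(C) apply(C, 2, which.max)

#' Stage score of a profile under a hypergraph model
#'
#' c_y = sum_i w(e_i | y) * P(match | e_i, y): the weighted sum over all
#' hyperedges of the profile's matching probability for the given stage.
#'
#' @param profile named numeric combined expression vector.
#' @param model a fitted [mirhyper] model.
#' @param stage stage label.
#' @return Scalar score (linear in the weights).
#' @export
stage_score <- function(profile, model, stage) {
  if (!stage %in% model$stages) stop("unknown stage: ", stage)
  if (!length(model$edges)) stop("the model has no hyperedges")
  p <- vapply(model$edges, function(e)
    match_probability(profile, e, stage, model$control$beta)$probability, 0)
  sum(model$weights[, stage] * p)
}

#' Predict the stage of a single profile
#'
#' Argmax over stages of [stage_score()]; exact ties are broken by the
#' fixed stage order of the model (first stage wins), so prediction is
#' deterministic.
#'
#' @inheritParams stage_score
#' @return Stage label (character).
#' @export
predict_stage <- function(profile, model) {
  s <- vapply(model$stages, function(y) stage_score(profile, model, y), 0)
  model$stages[which.max(s)]
}

#' Posterior stage probability of a profile
#'
#' Logistic of the mean-centered stage score:
#' P(y | profile, H) = logistic( c_y - mean_y' c_y' ).  Mean-centering
#' makes the posterior invariant to adding a constant to all stage
#' scores; the value is strictly inside (0, 1) and increases with the
#' stage's own score.
#'
#' @inheritParams stage_score
#' @return Probability in (0, 1).
#' @export
stage_posterior <- function(profile, model, stage) {
  if (!stage %in% model$stages) stop("unknown stage: ", stage)
  s <- vapply(model$stages, function(y) stage_score(profile, model, y), 0)
  stats::plogis(s[stage] - mean(s))[[1]]
}
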