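#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{k} folds so that every stage is
#' spread as evenly as possible across folds.  Uses the current RNG
#' state.  When \code{k} equals the sample count the assignment is
#' leave-one-out; otherwise every stage must have at least \code{k}
#' samples so that each fold sees every stage.
#'
#' @param labels stage label per sample.
#' @param k number of folds.
#' @return Integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop("'k' must be between 2 and the sample count")
  if (k == n) return(sample(n))          # leave-one-out
  cnt <- table(labels)
  if (any(cnt < k))
    stop("stratification impossible: stage(s) with fewer samples than ",
         "folds: ", paste(names(cnt)[cnt < k], collapse = ", "))
  folds <- integer(n)
  for (y in levels(labels)) {
    idx <- sample(which(labels == y))
    folds[idx] <- rep_len(sample(k), length(idx))
  }
  folds
}

# derived per-(repeat, fold) seed, kept inside 32-bit integer range
.derive_seed <- function(seed, r, f = 0L) {
  as.integer((as.numeric(seed) + 7919 * r + 104729 * f) %% 2147483647)
}

#' Repeated stratified cross-validation of the hypergraph model
#'
#' Runs \code{repeats} rounds of stratified \code{folds}-fold
#' cross-validation, training one [mirhyper] model per training fold and
#' scoring held-out accuracy (fraction of correct stage predictions).
#' Fold assignment and per-fold training seeds are all derived from
#' \code{control$seed}, so the whole harness is reproducible and
#' [knn_baseline()] called with the same seed sees identical folds.
#'
#' @param dataset an [hg_dataset] (already normalized if desired).
#' @param control an [hg_control].
#' @param folds folds per repeat (default 10).
#' @param repeats repeats (default 10).
#' @param keep_models keep the per-fold trained models (needed for
#'   [module_recovery_count()] / [appearance_count()]).
#' @return An object of class \code{"hg_cv"}: \code{accuracy} (repeats x
#'   folds matrix), \code{mean}, \code{sd} (sample SD over the repeats'
#'   mean accuracies), \code{fold_assignments}, and \code{models} (list
#'   of lists, \code{models[[repeat]][[fold]]}) when kept.
#' @export
cross_validate <- function(dataset, control = hg_control(), folds = 10,
                           repeats = 10, keep_models = TRUE) {
  n <- ncol(dataset$mirna)
  acc <- matrix(NA_real_, repeats, folds,
                dimnames = list(paste0("rep", seq_len(repeats)),
                                paste0("fold", seq_len(folds))))
  models <- if (keep_models) vector("list", repeats)
  assign_list <- vector("list", repeats)
  min_n <- if (folds == n) 1L else 2L
  for (r in seq_len(repeats)) {
    set.seed(.derive_seed(control$seed, r))
    fa <- stratified_folds(dataset$labels, folds)
    assign_list[[r]] <- fa
    if (keep_models) models[[r]] <- vector("list", folds)
    for (f in seq_len(folds)) {
      ctl <- control
      ctl$seed <- .derive_seed(control$seed, r, f)
      fit <- mirhyper(.subset_samples(dataset, fa != f), ctl,
                      min_stage_n = min_n)
      test <- .subset_samples(dataset, fa == f)
      pred <- predict(fit, test)
      acc[r, f] <- mean(as.character(pred) == as.character(test$labels))
      if (keep_models) models[[r]][[f]] <- fit
    }
  }
  rep_means <- rowMeans(acc)
  structure(list(accuracy = acc, mean = mean(acc),
                 sd = stats::sd(rep_means), repeat_means = rep_means,
                 fold_assignments = assign_list, models = models,
                 folds = folds, repeats = repeats, control = control),
            class = "hg_cv")
}

#' @export
print.hg_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation\n", x$repeats, x$folds))
  cat(sprintf("Accuracy: %.4f +/- %.4f (SD over repeat means)\n",
              x$mean, x$sd))
  invisible(x)
}

#' k-nearest-neighbour baseline under the same folds
#'
#' Euclidean k-NN on the combined (miRNA + mRNA) feature space with
#' majority vote; vote ties are broken by the smallest mean distance of
#' the tied stages' voting neighbours, then by stage order.  With the
#' same \code{seed}, \code{folds} and \code{repeats} as
#' [cross_validate()] the fold structure is identical, giving a paired
#' comparison.
#'
#' @param dataset an [hg_dataset].
#' @param k neighbours (default 3); must be smaller than every training
#'   fold.
#' @param folds,repeats as in [cross_validate()].
#' @param seed harness seed.
#' @return An object of class \code{"hg_cv"} (without models).
#' @export
knn_baseline <- function(dataset, k = 3, folds = 10, repeats = 10,
                         seed = 1) {
  X <- .combined(dataset)
  n <- ncol(X)
  D <- as.matrix(stats::dist(t(X)))
  stages <- dataset$stages
  y <- as.character(dataset$labels)
  acc <- matrix(NA_real_, repeats, folds)
  assign_list <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(.derive_seed(seed, r))
    fa <- stratified_folds(dataset$labels, folds)
    assign_list[[r]] <- fa
    for (f in seq_len(folds)) {
      train <- which(fa != f); test <- which(fa == f)
      if (k >= length(train))
        stop("'k' must be smaller than the training fold size")
      ok <- vapply(test, function(i) {
        d <- D[i, train]
        nn <- train[order(d)[seq_len(k)]]
        votes <- table(factor(y[nn], levels = stages))
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1) {
          md <- vapply(top, function(s) mean(D[i, nn[y[nn] == s]]), 0)
          top <- top[order(md, match(top, stages))][1]
        }
        top == y[i]
      }, TRUE)
      acc[r, f] <- mean(ok)
    }
  }
  rep_means <- rowMeans(acc)
  structure(list(accuracy = acc, mean = mean(acc),
                 sd = stats::sd(rep_means), repeat_means = rep_means,
                 fold_assignments = assign_list, models = NULL,
                 folds = folds, repeats = repeats, k = k),
            class = "hg_cv")
}

#' Appearance count of features across learned models
#'
#' Stability measure: the number of models (e.g. the 100 models from 10
#' repeats of 10-fold CV) in which a feature occurs in at least one
#' hyperedge.  It is an indicator count per model, not a multiplicity:
#' a feature in five hyperedges of one model counts once.
#'
#' @param models list of [mirhyper] models (a nested list, as stored by
#'   [cross_validate()], is flattened).
#' @param features character vector of feature identifiers.
#' @return Named integer vector, one count in 0..length(models) per
#'   feature.
#' @export
appearance_count <- function(models, features) {
  models <- .flatten_models(models)
  sets <- lapply(models, function(m)
    unique(unlist(lapply(m$edges, `[[`, "members"))))
  vapply(stats::setNames(features, features), function(f)
    sum(vapply(sets, function(s) f %in% s, TRUE)), 0L)
}

.flatten_models <- function(models) {
  if (inherits(models, "mirhyper")) return(list(models))
  out <- list()
  for (m in models)
    out <- c(out, if (inherits(m, "mirhyper")) list(m)
                  else .flatten_models(m))
  out
}

#' Module recovery count
#'
#' Number of models (typically one per CV fold) containing at least one
#' hyperedge whose member set is a superset of \code{target_set}.  A
#' hyperedge covering only part of the target does not count.
#'
#' @param models list of [mirhyper] models.
#' @param target_set character vector of feature identifiers.
#' @return Integer in 0..length(models).
#' @export
module_recovery_count <- function(models, target_set) {
  models <- .flatten_models(models)
  sum(vapply(models, function(m)
    any(vapply(m$edges, function(e) all(target_set %in% e$members), TRUE)),
    TRUE))
}

#' Accuracy grid over hyperedge degrees
#'
#' Cross-validates the model for every (l, m) degree pair and returns the
#' grid of mean held-out accuracies, mirroring a degree-sweep analysis of
#' how many miRNAs and mRNAs a hyperedge should contain.
#'
#' @param dataset an [hg_dataset].
#' @param l_values,m_values degree values to sweep.
#' @param control base [hg_control]; l and m are overridden per cell.
#' @param folds,repeats per-cell cross-validation shape.
#' @return Numeric matrix (length(l_values) x length(m_values)) of mean
#'   accuracies, dimnames l/m.
#' @export
degree_sweep <- function(dataset, l_values, m_values,
                         control = hg_control(), folds = 10, repeats = 1) {
  grid <- matrix(NA_real_, length(l_values), length(m_values),
                 dimnames = list(sprintf("l%d", as.integer(l_values)),
                                 sprintf("m%d", as.integer(m_values))))
  for (i in seq_along(l_values)) for (j in seq_along(m_values)) {
    ctl <- control
    ctl$l <- as.integer(l_values[i]); ctl$m <- as.integer(m_values[j])
    grid[i, j] <- cross_validate(dataset, ctl, folds = folds,
                                 repeats = repeats,
                                 keep_models = FALSE)$mean
  }
  grid
}
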