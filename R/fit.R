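#' Sample one hyperedge member set
#'
#' Draws l miRNAs and m mRNAs without replacement, each pool proportional
#' to its selection distribution ([selection_distribution()]).  If the
#' drawn member set (as a set) already occurs in \code{existing}, the draw
#' is repeated, so a population never contains duplicate hyperedges.
#'
#' @param mirna_dist named probability vector over the miRNA pool.
#' @param mrna_dist named probability vector over the mRNA pool.
#' @param l,m members drawn from each pool.
#' @param existing list of character vectors (member sets already in the
#'   population) that the new set must differ from.
#' @param max_tries resampling attempts before giving up.
#' @return Character vector of members, miRNAs first.
#' @export
sample_hyperedge <- function(mirna_dist, mrna_dist, l, m,
                             existing = list(), max_tries = 10000) {
  if (l > length(mirna_dist))
    stop("'l' exceeds the miRNA pool size")
  if (m > length(mrna_dist))
    stop("'m' exceeds the mRNA pool size")
  nm_x <- names(mirna_dist); nm_z <- names(mrna_dist)
  nx <- length(mirna_dist); nz <- length(mrna_dist)
  # member sets as sorted integer indices into (miRNA pool, mRNA pool)
  pool <- c(nm_x, nm_z)
  keys <- vapply(existing, function(s) {
    if (!length(s)) "" else paste(sort.int(match(s, pool)), collapse = ".")
  }, "")
  for (i in seq_len(max_tries)) {
    ii <- c(if (l > 0) sample.int(nx, l, prob = mirna_dist),
            if (m > 0) nx + sample.int(nz, m, prob = mrna_dist))
    if (!(paste(sort.int(ii), collapse = ".") %in% keys))
      return(pool[ii])
  }
  stop("could not sample a hyperedge distinct from the population (",
       max_tries, " attempts)")
}

#' Initial weight of a hyperedge for one stage
#'
#' w0(e | y) = kappa * I(e) + sum_j 1 / sigma_j|y^2, where I(e) is the
#' multivariate MI of the member set with the stage label and the second
#' term rewards members whose expression is tight (low variance) within
#' the stage.  kappa balances the two terms and scales the MMI term only.
#' The standard-deviation floor keeps the inverse-variance sum finite.
#'
#' @param edge a \code{"hyperedge"}.
#' @param stage stage label.
#' @param kappa non-negative MMI weight.
#' @param mmi multivariate MI of the member set; defaults to the value
#'   stored on the edge.
#' @return Scalar initial weight.
#' @export
initial_weight <- function(edge, stage, kappa = 1, mmi = edge$mmi) {
  if (!stage %in% edge$stages) stop("unknown stage: ", stage)
  kappa * mmi + sum(1 / edge$sigma[, stage]^2)
}

# initial weight row over all stages
.init_weights <- function(edge, kappa) {
  vapply(edge$stages, function(y) initial_weight(edge, y, kappa), 0)
}

#' Replacement ratio schedule
#'
#' Fraction of the population replaced at structure-learning iteration t
#' (0-based): R_t = (R_max - R_min) * exp(-t) + R_min.  Strictly
#' decreasing from R_max at t = 0 towards the asymptote R_min, so early
#' iterations explore aggressively while later ones preserve
#' high-discriminative hyperedges.
#'
#' @param t iteration index (0-based), vectorized.
#' @param R_max,R_min bounds with R_min <= R_max.
#' @return Ratio in [R_min, R_max].
#' @export
replacement_ratio <- function(t, R_max = 0.9, R_min = 0.5) {
  if (R_min > R_max) stop("'R_min' must not exceed 'R_max'")
  if (any(t < 0)) stop("'t' must be non-negative")
  (R_max - R_min) * exp(-t) + R_min
}

# ---- gradient-descent weight updates -------------------------------------

# one batch epoch on precomputed match matrices.
# W: edges x stages, M: per-stage list of edge x sample matrices,
# y_idx: true stage index per sample.
.batch_update <- function(W, M, y_idx, gamma) {
  C <- .score_matrix(W, M)
  P <- .posterior_matrix(C)
  dW <- W * 0
  for (j in seq_along(M)) {
    g <- gamma * P[j, ] * (1 - P[j, ]) * ((y_idx == j) - P[j, ])
    dW[, j] <- as.numeric(M[[j]] %*% g)
  }
  W + dW
}

.online_update <- function(W, M, y_idx, gamma) {
  S <- length(M)
  for (n in seq_along(y_idx)) {
    mn <- matrix(vapply(M, function(mm) mm[, n], numeric(nrow(W))),
                 nrow = nrow(W))                             # edges x stages
    cn <- colSums(W * mn)
    pn <- stats::plogis(cn - mean(cn))
    g <- gamma * pn * (1 - pn) * ((y_idx[n] == seq_len(S)) - pn)
    W <- W + sweep(mn, 2, g, "*")
  }
  W
}

#' One parameter-learning epoch
#'
#' Gradient-descent refinement of the per-stage hyperedge weights.  For
#' every training sample and every stage y the weight of hyperedge e_i
#' receives
#' delta_w = gamma * P(y|d) * (1 - P(y|d)) * (delta(y~, y) - P(y|d)) *
#' P(match | e_i, y), where P(y|d) is the logistic posterior
#' ([stage_posterior()]) and delta(y~, y) indicates the sample's true
#' stage.  In batch mode (default) posteriors are computed with the
#' pre-update weights and the summed deltas are applied once; in online
#' mode the weights advance after each sample.
#'
#' @param model a fitted [mirhyper] model.
#' @param dataset the training [hg_dataset] (same feature space).
#' @param gamma learning rate; defaults to the model's configuration.
#' @param update \code{"batch"} or \code{"online"}.
#' @return The model with updated weights.
#' @export
parameter_update_epoch <- function(model, dataset,
                                   gamma = model$control$gamma,
                                   update = model$control$update) {
  if (!all(levels(dataset$labels) %in% model$stages))
    stop("dataset contains stage labels absent from the model: ",
         paste(setdiff(levels(dataset$labels), model$stages), collapse = ", "))
  X <- .combined(dataset)
  M <- .match_list(model$edges, X, model$stages, model$control$beta)
  y_idx <- match(as.character(dataset$labels), model$stages)
  f <- if (update == "online") .online_update else .batch_update
  model$weights <- f(model$weights, M, y_idx, gamma)
  model
}

#' Replace the lowest-weight hyperedges
#'
#' Evolutionary structure step: the ceiling(ratio * |H|) hyperedges with
#' the lowest max-over-stages weight are removed and replaced by freshly
#' sampled (MI-guided, duplicate-free), freshly fitted hyperedges with
#' initial weights from [initial_weight()].  The population size never
#' changes.
#'
#' @param model a fitted [mirhyper] model (carries the MI-derived
#'   selection distributions computed at training time).
#' @param ratio fraction in [0, 1] of the population to replace.
#' @param dataset the training [hg_dataset].
#' @return The model with the replaced hyperedges and weights.
#' @export
replace_hyperedges <- function(model, ratio, dataset) {
  if (ratio < 0 || ratio > 1) stop("'ratio' must be in [0, 1]")
  n <- length(model$edges)
  n_rep <- ceiling(ratio * n)
  if (n_rep == 0) return(model)
  ctl <- model$control
  drop_idx <- order(apply(model$weights, 1, max))[seq_len(n_rep)]
  member_sets <- lapply(model$edges, `[[`, "members")
  X <- .combined(dataset)
  idx <- .stage_idx(dataset)
  mirna_ids <- dataset$mirna_ids
  for (i in drop_idx) {
    member_sets[[i]] <- character(0)  # freed slot
    mem <- .sample_members(model$dists, ctl, member_sets,
                           model$combo_cache)
    e <- .fit_edge(X, idx, dataset$stages,
                   mem[mem %in% mirna_ids], mem[!mem %in% mirna_ids],
                   ctl$sigma_min, ctl$ridge_eps)
    model$edges[[i]] <- e
    model$weights[i, ] <- .init_weights(e, ctl$kappa)
    member_sets[[i]] <- e$members
  }
  model
}

# draw one member set respecting the degree mode
.sample_members <- function(dists, ctl, existing, cache = NULL) {
  if (!is.null(cache)) {
    keys <- vapply(existing, function(s) {
      if (!length(s)) "" else
        paste(sort.int(match(s, cache$pool)), collapse = ".")
    }, "")
    p <- cache$prob
    p[cache$keys %in% keys] <- 0
    if (sum(p) <= 0)
      stop("could not sample a hyperedge distinct from the population")
    return(cache$pool[cache$combos[
      sample.int(length(p), 1, prob = p), ]])
  }
  if (ctl$degree_mode == "joint")
    sample_hyperedge(dists$joint, numeric(0), ctl$l + ctl$m, 0, existing)
  else
    sample_hyperedge(dists$mirna, dists$mrna, ctl$l, ctl$m, existing)
}

# all permutations of 1..k (k! x k), k small
.perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(seq_len(k)[-i][sub], nrow(sub)))
  }))
}

# Exact set-probability table of k-subsets under sequential weighted
# sampling without replacement from 'dist'.  The probability of a set is
# the sum over member orderings of prod_j p_j / (1 - sum of earlier p).
# Used on small pools so that duplicate-free draws can be taken from the
# renormalized conditional in one step; distribution-equivalent to the
# resampling loop of sample_hyperedge().
.make_combo_cache <- function(dist, k, max_work = 2e5) {
  n <- length(dist)
  if (k > 6 || choose(n, k) * factorial(k) > max_work) return(NULL)
  combos <- t(utils::combn(n, k))
  pm <- .perms(k)
  prob <- apply(combos, 1, function(ii) {
    q <- matrix(dist[ii][pm], nrow(pm))
    cs <- t(apply(q, 1, cumsum))
    denom <- cbind(1, 1 - cs[, -k, drop = FALSE])
    sum(exp(rowSums(log(q)) - rowSums(log(denom))))
  })
  list(pool = names(dist), combos = combos,
       keys = apply(combos, 1, paste, collapse = "."),
       prob = prob)
}

# ---- main fitting function -----------------------------------------------

#' Fit a hypergraph-based stage classifier
#'
#' Learns a population of weighted hyperedges (higher-order miRNA-mRNA
#' modules) discriminating the stage labels of a matched expression
#' dataset.  Training iterates two phases:
#'
#' * structure learning: hyperedges are sampled with probability
#'   proportional to each feature's MI with the stage label
#'   ([selection_distribution()]), given initial weights combining the
#'   member set's multivariate MI and inverse stage variances
#'   ([initial_weight()]), and the lowest-weight fraction of the
#'   population is replaced every iteration at a ratio decaying from
#'   \code{R_max} to \code{R_min} ([replacement_ratio()]);
#' * parameter learning: per-stage weights are refined by gradient
#'   descent on the squared posterior error
#'   ([parameter_update_epoch()]).
#'
#' Per-gene MI values and the selection distributions depend only on the
#' training data and are computed once.  All randomness flows from
#' \code{control$seed}; two runs with the same data and control are
#' identical.
#'
#' The caller is expected to pass normalized data (see
#' [normalize_dataset()]); no normalization happens here.
#'
#' @param data an [hg_dataset].
#' @param control an [hg_control] configuration.
#' @param min_stage_n smallest admissible per-stage training sample count
#'   (passed to [fit_hyperedge_stats()]; lowering it to 1 permits
#'   leave-one-out resampling of tiny datasets, at the price of floored
#'   standard deviations for the singleton stage).
#' @return An object of class \code{"mirhyper"}: \code{edges} (list of
#'   \code{"hyperedge"}), \code{weights} (edges x stages matrix),
#'   \code{stages}, \code{mi} (per-pool MI vectors), \code{dists}
#'   (selection distributions), \code{trace} (per-iteration data frame
#'   with mean population MMI, training accuracy before and after
#'   parameter learning, and the replacement ratio), \code{control},
#'   \code{call}.
#' @seealso [predict.mirhyper()], [cross_validate()],
#'   [build_stage_network()]
#' @examples
#' ds <- simulate_threshold_data(n_instances = 200,
#'                               balance_targets = c(40, 40, 120), seed = 1)
#' ctl <- hg_control(l = 2, m = 2, n_hyperedges = 10, structure_epochs = 5,
#'                   parameter_epochs = 5, degree_mode = "joint", seed = 1)
#' fit <- mirhyper(ds, ctl)
#' fit
#' @export
mirhyper <- function(data, control = hg_control(), min_stage_n = 2) {
  stopifnot(inherits(data, "hg_dataset"))
  stopifnot(inherits(control, "hg_control"))
  cl <- match.call()
  set.seed(control$seed)
  X <- .combined(data)
  y_idx <- match(as.character(data$labels), data$stages)

  mi_mirna <- mi_vector(data$mirna, data$labels, control$mi_backend,
                        control$n_bins, control$sigma_min, min_stage_n)
  mi_mrna <- mi_vector(data$mrna, data$labels, control$mi_backend,
                       control$n_bins, control$sigma_min, min_stage_n)
  dists <- list(mirna = selection_distribution(mi_mirna, control$eta),
                mrna = selection_distribution(mi_mrna, control$eta),
                joint = selection_distribution(c(mi_mirna, mi_mrna),
                                               control$eta))

  # initial population
  cnt <- table(data$labels)
  if (any(cnt < min_stage_n))
    stop("degenerate stage (fewer than ", min_stage_n, " samples): ",
         paste(names(cnt)[cnt < min_stage_n], collapse = ", "))
  idx <- .stage_idx(data)
  cache <- if (control$degree_mode == "joint")
    .make_combo_cache(dists$joint, control$l + control$m)
  member_sets <- vector("list", control$n_hyperedges)
  edges <- vector("list", control$n_hyperedges)
  for (i in seq_len(control$n_hyperedges)) {
    mem <- .sample_members(dists, control, member_sets, cache)
    edges[[i]] <- .fit_edge(X, idx, data$stages,
                            mem[mem %in% data$mirna_ids],
                            mem[!mem %in% data$mirna_ids],
                            control$sigma_min, control$ridge_eps)
    member_sets[[i]] <- edges[[i]]$members
  }
  W <- t(vapply(edges, .init_weights, numeric(length(data$stages)),
                kappa = control$kappa))
  colnames(W) <- data$stages

  model <- structure(
    list(edges = edges, weights = W, stages = data$stages,
         mi = list(mirna = mi_mirna, mrna = mi_mrna), dists = dists,
         feature_types = .feature_types(data), combo_cache = cache,
         trace = NULL, control = control, min_stage_n = min_stage_n,
         call = cl),
    class = "mirhyper")

  T_ <- control$structure_epochs
  trace <- data.frame(iteration = seq_len(T_) - 1L,
                      mean_mmi = numeric(T_),
                      accuracy_init = numeric(T_),
                      accuracy = numeric(T_),
                      replacement_ratio = numeric(T_))
  model$initial_mmi <- mean(vapply(edges, `[[`, 0, "mmi"))
  M <- .match_list(model$edges, X, model$stages, control$beta)
  upd <- if (control$update == "online") .online_update else .batch_update

  for (t in seq_len(T_)) {
    trace$accuracy_init[t] <- mean(.predict_idx(.score_matrix(model$weights,
                                                              M)) == y_idx)
    for (ep in seq_len(control$parameter_epochs))
      model$weights <- upd(model$weights, M, y_idx, control$gamma)
    trace$accuracy[t] <- mean(.predict_idx(.score_matrix(model$weights,
                                                         M)) == y_idx)
    r <- replacement_ratio(t - 1L, control$R_max, control$R_min)
    trace$replacement_ratio[t] <- r
    if (t < T_) {
      # removal/regeneration opens the next structure iteration; after the
      # final parameter-learning phase the population is left as learned
      old_edges <- model$edges
      model <- replace_hyperedges(model, r, data)
      changed <- which(!vapply(seq_along(old_edges), function(i)
        identical(old_edges[[i]]$members, model$edges[[i]]$members), TRUE))
      for (y in model$stages)
        M[[y]][changed, ] <- .match_rows(model$edges[changed], X, y,
                                         control$beta)
    }
    trace$mean_mmi[t] <- mean(vapply(model$edges, `[[`, 0, "mmi"))
  }
  model$trace <- trace
  model
}
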