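#' Save a fitted model as JSON
#'
#' Serializes stages, configuration snapshot, feature typing and every
#' hyperedge's members, per-stage means, standard deviations, covariances
#' and weights to a canonical JSON document.  Numeric fields are written
#' at full double precision, so members and weights survive a round trip
#' bit-exactly and save -> load -> save is byte-identical.
#'
#' The training trace is a diagnostic of the run, not part of the model,
#' and is not serialized.
#'
#' @param model a fitted [mirhyper] model.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  num <- function(x) unname(as.numeric(x))
  doc <- list(
    format = "mirhyper-model",
    version = 1L,
    stages = as.list(model$stages),
    control = unclass(model$control),
    features = list(
      mirna_ids = as.list(names(model$feature_types)[
        model$feature_types == "miRNA"]),
      mrna_ids = as.list(names(model$feature_types)[
        model$feature_types == "mRNA"])),
    mi = list(mirna = num(model$mi$mirna), mrna = num(model$mi$mrna)),
    min_stage_n = model$min_stage_n,
    edges = lapply(seq_along(model$edges), function(i) {
      e <- model$edges[[i]]
      list(mirna = as.list(e$mirna), mrna = as.list(e$mrna),
           mmi = e$mmi,
           mu = lapply(model$stages, function(y) num(e$mu[, y])),
           sigma = lapply(model$stages, function(y) num(e$sigma[, y])),
           cov = lapply(model$stages, function(y)
             apply(e$cov[[y]], 1, num, simplify = FALSE)),
           cov_marginal = apply(e$cov_marginal, 1, num, simplify = FALSE),
           weights = num(model$weights[i, ]))
    }))
  # 17 significant digits: lossless decimal round-trip for IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file.
#' @return A [mirhyper] model (without training trace).
#' @export
load_model <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "mirhyper-model"))
    stop("'", path, "' is not a mirhyper model file")
  stages <- unlist(doc$stages)
  ctl <- doc$control
  control <- do.call(hg_control, ctl[setdiff(names(ctl), character(0))])
  mirna_ids <- unlist(c(doc$features$mirna_ids, character(0)))
  mrna_ids <- unlist(c(doc$features$mrna_ids, character(0)))
  feature_types <- stats::setNames(
    rep(c("miRNA", "mRNA"), c(length(mirna_ids), length(mrna_ids))),
    c(mirna_ids, mrna_ids))
  mi <- list(mirna = stats::setNames(unlist(doc$mi$mirna), mirna_ids),
             mrna = stats::setNames(unlist(doc$mi$mrna), mrna_ids))
  dists <- list(mirna = selection_distribution(mi$mirna, control$eta),
                mrna = selection_distribution(mi$mrna, control$eta),
                joint = selection_distribution(c(mi$mirna, mi$mrna),
                                               control$eta))
  n_edges <- length(doc$edges)
  W <- matrix(0, n_edges, length(stages),
              dimnames = list(NULL, stages))
  edges <- vector("list", n_edges)
  for (i in seq_len(n_edges)) {
    de <- doc$edges[[i]]
    mir <- unlist(c(de$mirna, character(0)))
    mr <- unlist(c(de$mrna, character(0)))
    members <- c(mir, mr)
    k <- length(members)
    mu <- sigma <- matrix(0, k, length(stages),
                          dimnames = list(members, stages))
    covs <- vector("list", length(stages)); names(covs) <- stages
    for (j in seq_along(stages)) {
      mu[, j] <- unlist(de$mu[[j]])
      sigma[, j] <- unlist(de$sigma[[j]])
      covs[[j]] <- do.call(rbind, lapply(de$cov[[j]], unlist))
      dimnames(covs[[j]]) <- list(members, members)
    }
    covm <- do.call(rbind, lapply(de$cov_marginal, unlist))
    dimnames(covm) <- list(members, members)
    edges[[i]] <- structure(
      list(mirna = mir, mrna = mr, members = members, mu = mu,
           sigma = sigma, cov = covs, cov_marginal = covm,
           mmi = de$mmi, stages = stages),
      class = "hyperedge")
    W[i, ] <- unlist(de$weights)
  }
  structure(list(edges = edges, weights = W, stages = stages, mi = mi,
                 dists = dists, feature_types = feature_types,
                 combo_cache = if (control$degree_mode == "joint")
                   .make_combo_cache(dists$joint, control$l + control$m),
                 trace = NULL, control = control,
                 min_stage_n = if (is.null(doc$min_stage_n)) 2L
                               else doc$min_stage_n,
                 call = NULL),
            class = "mirhyper")
}
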