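#' @export
print.mirhyper <- function(x, ...) {
  cat("Hypergraph-based stage classifier\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("%d hyperedges (%d miRNA + %d mRNA each, %s pool), stages: %s\n",
              length(x$edges), x$control$l, x$control$m,
              x$control$degree_mode, paste(x$stages, collapse = ", ")))
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("After %d structure iterations: mean MMI %.4f, ",
                nrow(x$trace), last$mean_mmi))
    cat(sprintf("training accuracy %.4f\n", last$accuracy))
  }
  invisible(x)
}

#' Summarize a fitted hypergraph model
#'
#' @param object a [mirhyper] model.
#' @param n_top number of top-weight hyperedges to display.
#' @param ... unused.
#' @export
summary.mirhyper <- function(object, n_top = 5, ...) {
  wmax <- apply(object$weights, 1, max)
  top <- order(wmax, decreasing = TRUE)[seq_len(min(n_top,
                                                    length(wmax)))]
  out <- list(model = object, n_top = n_top, top_idx = top,
              weight_summary = summary(wmax),
              mmi = vapply(object$edges, `[[`, 0, "mmi"))
  class(out) <- "summary.mirhyper"
  out
}

#' @export
print.summary.mirhyper <- function(x, ...) {
  print(x$model)
  cat("\nMax-over-stage hyperedge weights:\n")
  print(x$weight_summary)
  cat(sprintf("Mean population MMI: %.4f\n", mean(x$mmi)))
  cat("\nTop hyperedges by max weight:\n")
  for (i in x$top_idx) {
    e <- x$model$edges[[i]]
    w <- x$model$weights[i, ]
    cat(sprintf("  {%s}  stage=%s  w=%.4g  MMI=%.4f\n",
                paste(e$members, collapse = ", "),
                x$model$stages[which.max(w)], max(w), e$mmi))
  }
  invisible(x)
}

#' Hyperedge weight matrix
#'
#' @param object a [mirhyper] model.
#' @param ... unused.
#' @return Numeric matrix, hyperedges x stages.
#' @export
coef.mirhyper <- function(object, ...) object$weights

#' Predict cancer stages for new profiles
#'
#' Computes per-stage scores c_y = sum_i w(e_i|y) P(match | e_i, y) for
#' every sample and returns, depending on \code{type}, the argmax stage
#' (ties to the first stage in the model's stage order), the score
#' matrix, or the logistic posterior of the mean-centered scores.
#'
#' @param object a fitted [mirhyper] model.
#' @param newdata an [hg_dataset], or a combined numeric matrix
#'   (features x samples) whose row names cover all model members.
#' @param type \code{"class"}, \code{"score"} or \code{"posterior"}.
#' @param ... unused.
#' @return A factor of stage labels, or a stages x samples numeric
#'   matrix.
#' @export
predict.mirhyper <- function(object, newdata,
                             type = c("class", "score", "posterior"),
                             ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "hg_dataset")) .combined(newdata)
       else as.matrix(newdata)
  need <- unique(unlist(lapply(object$edges, `[[`, "members")))
  miss <- setdiff(need, rownames(X))
  if (length(miss))
    stop("newdata is missing model feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...")
  M <- .match_list(object$edges, X, object$stages, object$control$beta)
  C <- .score_matrix(object$weights, M)
  dimnames(C) <- list(object$stages, colnames(X))
  switch(type,
         class = factor(object$stages[.predict_idx(C)],
                        levels = object$stages),
         score = C,
         posterior = {P <- .posterior_matrix(C); dimnames(P) <- dimnames(C); P})
}

#' Plot training curves of a fitted model
#'
#' Two panels against the structure-learning iteration: the mean
#' multivariate mutual information of the hyperedge population (the
#' structure-learning progress measure) and the training accuracy after
#' each iteration's parameter-learning epochs.
#'
#' @param x a [mirhyper] model with a non-empty trace.
#' @param ... passed to [plot.default()].
#' @export
plot.mirhyper <- function(x, ...) {
  tr <- x$trace
  if (is.null(tr) || !nrow(tr)) stop("model has no training trace")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(tr$iteration, tr$mean_mmi, type = "l", xlab = "structure iteration",
       ylab = "mean MMI of population", main = "Structure learning", ...)
  plot(tr$iteration, tr$accuracy, type = "l", xlab = "structure iteration",
       ylab = "training accuracy", main = "Parameter learning", ...)
  invisible(x)
}
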