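#' Stage assignment of a hyperedge
#'
#' A hyperedge carries one weight per stage; for network construction it
#' is merged into the network of its highest-weighted stage (argmax over
#' stages, exact ties broken by the fixed stage order).  Together with
#' [build_stage_network()] this partitions the hyperedges of a model
#' across the stage networks.
#'
#' @param edge a \code{"hyperedge"} carrying a named \code{weights}
#'   vector (as returned by [hyperedges()]), or a plain named numeric
#'   weight vector.
#' @return Stage label (character).
#' @export
assign_stage <- function(edge) {
  w <- if (is.numeric(edge)) edge else edge$weights
  if (is.null(w)) stop("edge carries no per-stage weights")
  names(w)[which.max(w)]
}

#' Extract hyperedges with their weights
#'
#' @param model a fitted [mirhyper] model.
#' @return List of \code{"hyperedge"} objects, each with a named
#'   \code{weights} vector attached.
#' @export
hyperedges <- function(model) {
  lapply(seq_along(model$edges), function(i) {
    e <- model$edges[[i]]
    e$weights <- stats::setNames(model$weights[i, ], model$stages)
    e
  })
}

#' Clique expansion of a hyperedge
#'
#' All unordered member pairs of the hyperedge, each carrying
#' max(w(e | stage), 0): a non-positive stage weight yields zero-weight
#' pairs, which are dropped during network assembly.
#'
#' @param edge a \code{"hyperedge"} with attached weights (see
#'   [hyperedges()]).
#' @param stage stage label.
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{weight}; C(k, 2) rows for k members.
#' @export
hyperedge_to_clique <- function(edge, stage) {
  k <- length(edge$members)
  pairs <- t(utils::combn(edge$members, 2))
  data.frame(source = pairs[, 1], target = pairs[, 2],
             weight = rep(max(edge$weights[[stage]], 0), nrow(pairs)),
             stringsAsFactors = FALSE)
}

#' Build a stage-specific interaction network
#'
#' Converts one or more learned hypergraphs into an ordinary weighted
#' graph for one stage: every hyperedge is assigned to its
#' highest-weighted stage ([assign_stage()]); hyperedges assigned to
#' \code{stage} are clique-expanded ([hyperedge_to_clique()]); weights of
#' identical node pairs are summed across all contributing hyperedges and
#' models; and the \code{top_k} pairs with the highest summed weight are
#' kept (ties at the cutoff broken by lexicographic node-pair order).
#' Zero-weight pairs are dropped.
#'
#' @param models a [mirhyper] model or list of models sharing the feature
#'   space and stage set.
#' @param stage stage label.
#' @param top_k edges to keep (default 500).
#' @return An object of class \code{"hg_network"}: \code{stage},
#'   \code{edges} (source, target, weight; weight > 0), \code{nodes}
#'   (id, type, regulation — regulation is NA until
#'   [annotate_regulation()]).
#' @export
build_stage_network <- function(models, stage, top_k = 500) {
  models <- .flatten_models(models)
  if (!length(models)) stop("'models' must contain at least one model")
  if (!stage %in% models[[1]]$stages) stop("unknown stage: ", stage)
  if (top_k < 0) stop("'top_k' must be non-negative")
  all_keys <- character(0); all_w <- numeric(0)
  types <- character(0)
  for (m in models) {
    types <- c(types, m$feature_types[setdiff(names(m$feature_types),
                                              names(types))])
    for (e in hyperedges(m)) {
      if (assign_stage(e) != stage) next
      w <- max(e$weights[[stage]], 0)
      if (w <= 0) next
      pairs <- utils::combn(sort(e$members), 2)
      all_keys <- c(all_keys, paste(pairs[1, ], pairs[2, ], sep = "\t"))
      all_w <- c(all_w, rep(w, ncol(pairs)))
    }
  }
  edges <- if (length(all_keys)) {
    w <- rowsum(all_w, all_keys)[, 1]   # summed weight per node pair
    keys <- names(w)
    ord <- order(-w, keys)
    keep <- ord[seq_len(min(top_k, length(ord)))]
    parts <- do.call(rbind, strsplit(keys[keep], "\t", fixed = TRUE))
    data.frame(source = parts[, 1], target = parts[, 2],
               weight = unname(w[keep]), stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), target = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  }
  ids <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.frame(id = ids,
                      type = unname(types[ids]),
                      regulation = rep(NA_character_, length(ids)),
                      stringsAsFactors = FALSE)
  structure(list(stage = stage, edges = edges, nodes = nodes),
            class = "hg_network")
}

#' @export
print.hg_network <- function(x, ...) {
  cat("Stage-specific interaction network (", x$stage, "): ",
      nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "miRNA"), " miRNA, ",
      sum(x$nodes$type == "mRNA"), " mRNA), ",
      nrow(x$edges), " weighted edges\n", sep = "")
  invisible(x)
}

#' Annotate up/down regulation of network nodes
#'
#' Flags each node \code{"up"} if its mean expression within the
#' network's stage strictly exceeds its grand mean over all samples, and
#' \code{"down"} otherwise (a constant feature is therefore "down").
#'
#' @param network an [build_stage_network()] result.
#' @param dataset the [hg_dataset] the models were trained on (all
#'   network nodes must exist in it).
#' @return The network with the \code{regulation} column filled.
#' @export
annotate_regulation <- function(network, dataset) {
  X <- .combined(dataset)
  bad <- setdiff(network$nodes$id, rownames(X))
  if (length(bad))
    stop("network node(s) not in the dataset: ", paste(bad, collapse = ", "))
  in_stage <- dataset$labels == network$stage
  if (!any(in_stage)) stop("no samples of stage ", network$stage)
  sub <- X[network$nodes$id, , drop = FALSE]
  stage_mean <- rowMeans(sub[, in_stage, drop = FALSE])
  grand_mean <- rowMeans(sub)
  network$nodes$regulation <- ifelse(stage_mean > grand_mean, "up", "down")
  network
}

#' Write a network in SIF format
#'
#' One line per edge, \code{node1 pp node2}, as consumed by Cytoscape.
#'
#' @param network an \code{"hg_network"}.
#' @param path output file.
#' @export
write_sif <- function(network, path) {
  writeLines(paste(network$edges$source, "pp", network$edges$target),
             path)
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' Columns: source, target, weight, stage.
#'
#' @inheritParams write_sif
#' @export
write_edge_tsv <- function(network, path) {
  df <- network$edges
  df$stage <- rep(network$stage, nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write node attributes as TSV
#'
#' Columns: id, type (miRNA/mRNA), regulation (up/down).
#'
#' @inheritParams write_sif
#' @export
write_node_tsv <- function(network, path) {
  utils::write.table(network$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Exports the weighted graph with node \code{type} and
#' \code{regulation} attributes via igraph.
#'
#' @inheritParams write_sif
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a stage network to an igraph object
#'
#' @param network an \code{"hg_network"}.
#' @return An undirected weighted \code{igraph} graph with \code{type}
#'   and \code{regulation} vertex attributes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}
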