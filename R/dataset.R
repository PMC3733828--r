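#' Matched miRNA/mRNA expression dataset
#'
#' Bundles a miRNA expression matrix and an mRNA expression matrix
#' (features in rows, samples in columns) with one cancer-stage label per
#' sample.  Both matrices must describe the same samples in the same order.
#'
#' The stage set is the levels of \code{labels}: if \code{labels} is a
#' factor its level order is kept, otherwise levels are taken in order of
#' first appearance.  That order is the fixed label ordering used for all
#' deterministic tie-breaks (prediction, stage assignment of hyperedges).
#'
#' @param mirna numeric matrix of miRNA expression, features x samples.
#' @param mrna numeric matrix of mRNA expression, features x samples.
#' @param labels stage label per sample (factor or character); at least two
#'   distinct stages.
#' @param mirna_ids,mrna_ids feature identifiers; default the row names.
#' @return An object of class \code{"hg_dataset"} with elements
#'   \code{mirna}, \code{mrna}, \code{labels}, \code{mirna_ids},
#'   \code{mrna_ids}, \code{stages}.
#' @examples
#' x <- matrix(rnorm(20), 2, 10, dimnames = list(c("mir1", "mir2"), NULL))
#' z <- matrix(rnorm(30), 3, 10, dimnames = list(paste0("g", 1:3), NULL))
#' ds <- hg_dataset(x, z, rep(c("normal", "primary"), each = 5))
#' @export
hg_dataset <- function(mirna, mrna, labels,
                       mirna_ids = rownames(mirna),
                       mrna_ids = rownames(mrna)) {
  mirna <- as.matrix(mirna)
  mrna <- as.matrix(mrna)
  if (is.null(mirna_ids)) mirna_ids <- paste0("mir", seq_len(nrow(mirna)))
  if (is.null(mrna_ids)) mrna_ids <- paste0("gene", seq_len(nrow(mrna)))
  if (ncol(mirna) != ncol(mrna))
    stop("miRNA and mRNA matrices must have the same number of samples")
  if (length(labels) != ncol(mirna))
    stop("'labels' must have one entry per sample")
  if (!is.numeric(mirna) || !is.numeric(mrna))
    stop("expression matrices must be numeric")
  if (anyNA(mirna) || anyNA(mrna))
    stop("expression matrices must not contain NA/NaN")
  ids <- c(mirna_ids, mrna_ids)
  if (anyDuplicated(ids))
    stop("duplicate feature identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- if (is.factor(labels)) labels
            else factor(labels, levels = unique(as.character(labels)))
  if (nlevels(labels) < 2)
    stop("at least two distinct stage labels are required")
  rownames(mirna) <- mirna_ids
  rownames(mrna) <- mrna_ids
  structure(list(mirna = mirna, mrna = mrna, labels = labels,
                 mirna_ids = mirna_ids, mrna_ids = mrna_ids,
                 stages = levels(labels)),
            class = "hg_dataset")
}

#' @export
print.hg_dataset <- function(x, ...) {
  cat("Matched expression dataset: ", nrow(x$mirna), " miRNAs, ",
      nrow(x$mrna), " mRNAs, ", ncol(x$mirna), " samples\n", sep = "")
  cat("Stages:", paste(sprintf("%s (n=%d)", x$stages, table(x$labels)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hg_dataset <- function(x) {
  c(features = nrow(x$mirna) + nrow(x$mrna), samples = ncol(x$mirna))
}

# combined (miRNA above mRNA) expression matrix
.combined <- function(dataset) rbind(dataset$mirna, dataset$mrna)

# named vector feature -> "miRNA"/"mRNA"
.feature_types <- function(dataset) {
  stats::setNames(rep(c("miRNA", "mRNA"),
                      c(length(dataset$mirna_ids), length(dataset$mrna_ids))),
                  c(dataset$mirna_ids, dataset$mrna_ids))
}

# subset samples, keeping stage level order
.subset_samples <- function(dataset, idx) {
  hg_dataset(dataset$mirna[, idx, drop = FALSE],
             dataset$mrna[, idx, drop = FALSE],
             factor(dataset$labels[idx], levels = dataset$stages),
             dataset$mirna_ids, dataset$mrna_ids)
}

#' Read a matched expression pair from delimited files
#'
#' Reads a miRNA matrix, an mRNA matrix and a sample-to-stage label table
#' and aligns them by sample identifier.  Matrices are TSV or CSV
#' (extension \code{.csv} selects comma separation) with feature
#' identifiers in the first column and sample identifiers in the header.
#' The label file has two columns, \code{sample} and \code{stage}.
#' Sample order in the files is irrelevant; the three sample sets must be
#' identical, otherwise the error names the differing samples.
#'
#' @param mirna_path,mrna_path paths to the expression matrices.
#' @param labels_path path to the sample/stage table.
#' @return An [hg_dataset].
#' @export
read_expression_pair <- function(mirna_path, mrna_path, labels_path) {
  read_mat <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate feature ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric expression values in ", path)
    rownames(m) <- ids
    m
  }
  x <- read_mat(mirna_path)
  z <- read_mat(mrna_path)
  sep <- if (grepl("\\.csv$", labels_path, ignore.case = TRUE)) "," else "\t"
  lab <- utils::read.table(labels_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2)
    stop("label file must have columns 'sample' and 'stage'")
  samples <- as.character(lab[[1]])
  sets <- list(miRNA = colnames(x), mRNA = colnames(z), labels = samples)
  all_ids <- sort(unique(unlist(sets)))
  for (nm in names(sets)) {
    miss <- setdiff(all_ids, sets[[nm]])
    if (length(miss))
      stop("samples missing from the ", nm, " file: ",
           paste(miss, collapse = ", "))
  }
  x <- x[, samples, drop = FALSE]
  z <- z[, samples, drop = FALSE]
  hg_dataset(x, z, as.character(lab[[2]]))
}

#' Write a dataset to delimited files
#'
#' Inverse of [read_expression_pair()]; used for round-trip checks and for
#' exporting simulated data.
#'
#' @param dataset an [hg_dataset].
#' @param mirna_path,mrna_path,labels_path output paths (TSV, or CSV when
#'   the extension is \code{.csv}).
#' @export
write_expression_pair <- function(dataset, mirna_path, mrna_path,
                                  labels_path) {
  if (is.null(colnames(dataset$mirna))) {
    ids <- paste0("s", seq_len(ncol(dataset$mirna)))
    colnames(dataset$mirna) <- colnames(dataset$mrna) <- ids
  }
  write_mat <- function(m, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(feature = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  write_mat(dataset$mirna, mirna_path)
  write_mat(dataset$mrna, mrna_path)
  sep <- if (grepl("\\.csv$", labels_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data.frame(sample = colnames(dataset$mirna),
                                stage = as.character(dataset$labels)),
                     labels_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Normalize a matched expression dataset
#'
#' Default preprocessing: a sample-wise z-score within each block (each
#' sample's miRNA values are centred and scaled across miRNA features, and
#' likewise for mRNA, so the two platforms are normalized separately),
#' followed by a feature-wise z-score across samples.  Standard deviations
#' are population (n-denominator) estimates floored at \code{sigma_min},
#' so constant rows or columns map to zeros rather than NaN.
#'
#' The feature-wise step is idempotent: applying \code{mode =
#' "feature"} to an already feature-normalized dataset is a no-op up to
#' floating-point error.
#'
#' @param dataset an [hg_dataset].
#' @param mode \code{"sample_then_feature"} (default), \code{"sample"},
#'   \code{"feature"} or \code{"none"}.
#' @param sigma_min standard-deviation floor.
#' @return A normalized [hg_dataset].
#' @export
normalize_dataset <- function(dataset,
                              mode = c("sample_then_feature", "sample",
                                       "feature", "none"),
                              sigma_min = 1e-6) {
  mode <- match.arg(mode)
  zs_cols <- function(m) {
    mu <- colMeans(m)
    sd <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
    scale(m, center = mu, scale = pmax(sd, sigma_min))[, , drop = FALSE]
  }
  zs_rows <- function(m) t(zs_cols(t(m)))
  x <- dataset$mirna; z <- dataset$mrna
  if (mode %in% c("sample_then_feature", "sample")) {
    x <- zs_cols(x); z <- zs_cols(z)
  }
  if (mode %in% c("sample_then_feature", "feature")) {
    x <- zs_rows(x); z <- zs_rows(z)
  }
  dimnames(x) <- dimnames(dataset$mirna)
  dimnames(z) <- dimnames(dataset$mrna)
  hg_dataset(x, z, dataset$labels, dataset$mirna_ids, dataset$mrna_ids)
}
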