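#' Threshold-rule verification dataset
#'
#' Generates the three-class verification dataset used for model
#' checking: instances of \code{n_variables} independent N(0, sd^2)
#' variables x1..x7 (plus optional extra noise variables), labelled
#'
#' * class \code{c1} if x2 > threshold and x3 > threshold and
#'   x4 > threshold,
#' * class \code{c2} if x5 < -threshold and x6 < -threshold and
#'   x7 < -threshold (and the c1 rule does not fire),
#' * class \code{c3} otherwise.
#'
#' With sd = 1 and threshold = 2 the unconditional tail probability of a
#' non-c3 class is (1 - pnorm(2))^3, about 1.2e-5, so the
#' \code{"literal"} variant yields an essentially single-class draw at
#' n = 500.  The \code{"balanced"} variant (default) therefore
#' conditionally samples the three defining coordinates of c1/c2
#' instances from the appropriate truncated normal and rejection-samples
#' c3 instances, producing exactly \code{balance_targets} instances per
#' class.  Both variants are kept so the discrepancy between the
#' unconditional process and a class-balanced design is inspectable.
#'
#' The first three variables form the "miRNA" block and the rest the
#' "mRNA" block; the split is arbitrary and only exercises the
#' paired-matrix interface (use \code{degree_mode = "joint"} when
#' training on this data).
#'
#' @param n_instances number of samples (default 500).
#' @param n_variables number of variables, >= 7.
#' @param sd common standard deviation.
#' @param threshold positive class-rule threshold.
#' @param variant \code{"balanced"} or \code{"literal"}.
#' @param balance_targets per-class counts (c1, c2, c3) summing to
#'   \code{n_instances}; balanced variant only.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return An [hg_dataset] with labels \code{c1}, \code{c2}, \code{c3}.
#' @export
simulate_threshold_data <- function(n_instances = 500, n_variables = 7,
                                    sd = 1, threshold = 2,
                                    variant = c("balanced", "literal"),
                                    balance_targets = c(100, 100, 300),
                                    seed = NULL) {
  variant <- match.arg(variant)
  if (n_variables < 7) stop("'n_variables' must be at least 7")
  if (threshold <= 0) stop("'threshold' must be positive")
  if (!is.null(seed)) set.seed(seed)
  classify <- function(m) {
    ifelse(m[2, ] > threshold & m[3, ] > threshold & m[4, ] > threshold,
           "c1",
           ifelse(m[5, ] < -threshold & m[6, ] < -threshold &
                    m[7, ] < -threshold, "c2", "c3"))
  }
  if (variant == "literal") {
    m <- matrix(stats::rnorm(n_variables * n_instances, 0, sd),
                n_variables, n_instances)
    lab <- classify(m)
  } else {
    if (length(balance_targets) != 3 || sum(balance_targets) != n_instances)
      stop("'balance_targets' must be 3 class counts summing to ",
           "'n_instances'")
    rtrunc_above <- function(n) {         # N(0, sd^2) conditioned > threshold
      p0 <- stats::pnorm(threshold, sd = sd)
      stats::qnorm(stats::runif(n, p0, 1), sd = sd)
    }
    draw_class <- function(target_class, n_needed) {
      out <- matrix(NA_real_, n_variables, 0)
      while (ncol(out) < n_needed) {
        nb <- n_needed - ncol(out)
        m <- matrix(stats::rnorm(n_variables * nb, 0, sd), n_variables, nb)
        if (target_class == "c1") m[2:4, ] <- rtrunc_above(3 * nb)
        if (target_class == "c2") m[5:7, ] <- -rtrunc_above(3 * nb)
        out <- cbind(out, m[, classify(m) == target_class, drop = FALSE])
      }
      out
    }
    m <- cbind(draw_class("c1", balance_targets[1]),
               draw_class("c2", balance_targets[2]),
               draw_class("c3", balance_targets[3]))
    lab <- rep(c("c1", "c2", "c3"), balance_targets)
    perm <- sample(n_instances)
    m <- m[, perm, drop = FALSE]
    lab <- lab[perm]
  }
  rownames(m) <- paste0("x", seq_len(n_variables))
  colnames(m) <- sprintf("s%d", seq_len(n_instances))
  if (n_instances == 0) lab <- character(0)
  hg_dataset(m[1:3, , drop = FALSE],
             m[4:n_variables, , drop = FALSE],
             factor(lab, levels = c("c1", "c2", "c3")))
}

#' Planted-module miRNA-mRNA expression generator
#'
#' Synthetic matched expression data with stage-conditional co-regulated
#' modules.  Background features are independent N(0, noise_sd^2) in
#' every stage.  Each planted module names a set of miRNAs and mRNAs, a
#' designated stage and an effect size: in that stage only, the module's
#' miRNAs are shifted by -effect and its mRNAs by +effect (a repressed
#' miRNA with de-repressed targets), and all module members share a
#' per-sample latent factor giving within-module correlation
#' \code{module_cor} in the designated stage.  The latent factor and
#' noise are mixed so that every feature keeps per-stage variance
#' noise_sd^2 in every stage — co-regulation changes the dependency
#' structure, not the scale, mirroring what feature normalization
#' enforces on real profiles.
#'
#' The default plants two 2-miRNA + 2-mRNA modules, one in the
#' \code{primary} and one in the \code{metastatic} stage, at effect size
#' 3 against unit noise — a strong but realistically sized
#' differential-coexpression signal.  The default pools (60 miRNAs, 120
#' mRNAs against 8 planted features and hyperedge populations of a few
#' hundred member slots) keep the feature space much larger than the
#' model capacity, as in real expression panels; appearance-count
#' rankings are only informative in that regime.
#'
#' @param n_per_stage samples per stage.
#' @param n_mirna,n_mrna pool sizes.
#' @param stages stage labels.
#' @param modules list of modules, each
#'   \code{list(mirna=, mrna=, stage=, effect=)}; planted features must
#'   not overlap across modules.  NULL plants the two default modules.
#' @param effect_size default effect for the default modules.
#' @param noise_sd per-feature SD in every stage.
#' @param module_cor within-module correlation in the designated stage,
#'   in [0, 1).
#' @param seed integer seed, or NULL.
#' @return An [hg_dataset]; the planted modules are attached as
#'   \code{attr(., "modules")}.
#' @export
simulate_planted_modules <- function(n_per_stage = 100, n_mirna = 60,
                                     n_mrna = 120,
                                     stages = c("normal", "primary",
                                                "metastatic"),
                                     modules = NULL, effect_size = 3,
                                     noise_sd = 1, module_cor = 0.5,
                                     seed = NULL) {
  if (module_cor < 0 || module_cor >= 1)
    stop("'module_cor' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  mirna_ids <- paste0("mir", seq_len(n_mirna))
  mrna_ids <- paste0("gene", seq_len(n_mrna))
  if (is.null(modules)) {
    if (length(stages) < 3 || n_mirna < 4 || n_mrna < 4)
      stop("default modules need >= 3 stages, >= 4 miRNAs and >= 4 mRNAs")
    modules <- list(
      list(mirna = mirna_ids[1:2], mrna = mrna_ids[1:2],
           stage = stages[2], effect = effect_size),
      list(mirna = mirna_ids[3:4], mrna = mrna_ids[3:4],
           stage = stages[3], effect = effect_size))
  }
  planted <- unlist(lapply(modules, function(md) c(md$mirna, md$mrna)))
  if (anyDuplicated(planted))
    stop("planted features overlap across modules: ",
         paste(unique(planted[duplicated(planted)]), collapse = ", "))
  bad <- setdiff(planted, c(mirna_ids, mrna_ids))
  if (length(bad))
    stop("planted feature(s) outside the pools: ",
         paste(bad, collapse = ", "))
  n <- n_per_stage * length(stages)
  lab <- factor(rep(stages, each = n_per_stage), levels = stages)
  X <- matrix(stats::rnorm(n_mirna * n, 0, noise_sd), n_mirna, n,
              dimnames = list(mirna_ids, paste0("s", seq_len(n))))
  Z <- matrix(stats::rnorm(n_mrna * n, 0, noise_sd), n_mrna, n,
              dimnames = list(mrna_ids, paste0("s", seq_len(n))))
  a <- sqrt(module_cor) * noise_sd       # factor loading
  b <- sqrt(1 - module_cor)              # noise shrinkage, keeps variance
  for (md in modules) {
    idx <- which(lab == md$stage)
    if (!length(idx)) stop("module stage not in 'stages': ", md$stage)
    f <- stats::rnorm(length(idx))
    for (g in md$mirna) X[g, idx] <- b * X[g, idx] - md$effect + a * f
    for (g in md$mrna) Z[g, idx] <- b * Z[g, idx] + md$effect + a * f
  }
  perm <- sample(n)
  ds <- hg_dataset(X[, perm, drop = FALSE], Z[, perm, drop = FALSE],
                   lab[perm])
  attr(ds, "modules") <- modules
  ds
}
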