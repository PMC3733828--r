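# Small two-stage dataset with one informative miRNA (mirA shifted by
# stage) and the rest noise; built fresh under a fixed seed.
toy_dataset <- function(n_per = 15, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per
  sn <- paste0("s", seq_len(n))
  lab <- rep(c("early", "late"), each = n_per)
  x <- rbind(mirA = rnorm(n) + 2 * (lab == "late"),
             mirB = rnorm(n),
             mirC = rnorm(n))
  z <- rbind(gene1 = rnorm(n) - 1.5 * (lab == "late"),
             gene2 = rnorm(n),
             gene3 = rnorm(n),
             gene4 = rnorm(n))
  colnames(x) <- colnames(z) <- sn
  hg_dataset(x, z, lab)
}

# Minimal hand-built hyperedge: constant per-stage mean/SD across members.
hand_edge <- function(members, stages, mu, sigma, types = NULL,
                      weights = NULL, mmi = 0) {
  k <- length(members)
  mu_m <- matrix(mu, k, length(stages), byrow = TRUE,
                 dimnames = list(members, stages))
  sd_m <- matrix(sigma, k, length(stages), byrow = TRUE,
                 dimnames = list(members, stages))
  covs <- lapply(stats::setNames(stages, stages), function(y)
    diag(sd_m[, y]^2, k))
  e <- structure(list(mirna = members[1], mrna = members[-1],
                      members = members, mu = mu_m, sigma = sd_m,
                      cov = covs, cov_marginal = diag(k),
                      mmi = mmi, stages = stages),
                 class = "hyperedge")
  if (!is.null(weights)) e$weights <- stats::setNames(weights, stages)
  e
}

# Minimal model wrapping hand-built edges; enough structure for the
# forward path, parameter updates and network construction.
hand_model <- function(edges, weights, stages, beta = 1, gamma = 1,
                       feature_types = NULL) {
  W <- matrix(weights, nrow = length(edges), byrow = TRUE,
              dimnames = list(NULL, stages))
  members <- unique(unlist(lapply(edges, `[[`, "members")))
  if (is.null(feature_types))
    feature_types <- stats::setNames(rep("mRNA", length(members)), members)
  structure(list(edges = edges, weights = W, stages = stages,
                 mi = NULL, dists = NULL, feature_types = feature_types,
                 combo_cache = NULL, trace = NULL,
                 control = hg_control(beta = beta, gamma = gamma),
                 min_stage_n = 2L, call = NULL),
            class = "mirhyper")
}
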