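# Standard planted-module learning runs shared by the learning-curve and
# module-recovery checks: default generator (effect size 3), populations
# of 40 hyperedges (3 miRNA + 5 mRNA), 40 structure iterations of 10
# parameter epochs, one run per seed.  Memoized so the two test blocks
# reuse one computation.
.planted_env <- new.env(parent = emptyenv())

planted_runs <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.planted_env[[key]])) return(.planted_env[[key]])
  runs <- lapply(seeds, function(s) {
    ds <- simulate_planted_modules(seed = s)
    nd <- normalize_dataset(ds)
    ctl <- hg_control(l = 3, m = 5, n_hyperedges = 40,
                      structure_epochs = 40, parameter_epochs = 10,
                      seed = s)
    fit <- mirhyper(nd, ctl)
    list(fit = fit, modules = attr(ds, "modules"),
         mirna_ids = ds$mirna_ids, mrna_ids = ds$mrna_ids)
  })
  .planted_env[[key]] <- runs
  runs
}
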