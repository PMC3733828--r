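test_that("hyperedge statistics use stage-wise population moments with floors", {
  x <- matrix(c(0, 2, 5, 5,
                1, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("mirA", "mirB"), NULL))
  z <- matrix(c(1, 3, -1, -3), 1, 4, dimnames = list("gene1", NULL))
  ds <- hg_dataset(x, z, c("a", "a", "b", "b"))
  e <- fit_hyperedge_stats(ds, c("mirA", "gene1"))

  # two samples 0 and 2 in stage a: mean 1, population SD 1
  expect_equal(unname(e$mu["mirA", "a"]), 1)
  expect_equal(unname(e$sigma["mirA", "a"]), 1)
  # constant within stage a: SD floored
  e2 <- fit_hyperedge_stats(ds, c("mirB", "gene1"))
  expect_equal(unname(e2$mu["mirB", "a"]), 1)
  expect_equal(unname(e2$sigma["mirB", "a"]), 1e-6)
  # covariance: symmetric, ridge-regularized, PD
  for (y in c("a", "b")) {
    expect_true(isSymmetric(e$cov[[y]]))
    expect_true(all(eigen(e$cov[[y]], only.values = TRUE)$values > 0))
  }
  # members are reordered miRNAs-first
  e3 <- fit_hyperedge_stats(ds, c("gene1", "mirA"))
  expect_identical(e3$members, c("mirA", "gene1"))

  expect_error(fit_hyperedge_stats(ds, c("mirA", "nope")), "nope")
  expect_error(fit_hyperedge_stats(ds, "mirA"), "two members")
  expect_error(fit_hyperedge_stats(ds, c("mirA", "mirA", "gene1")),
               "unique")
  ds1 <- hg_dataset(x[, 1:3], z[, 1:3, drop = FALSE], c("a", "a", "b"))
  expect_error(fit_hyperedge_stats(ds1, c("mirA", "gene1")),
               "degenerate stage")
})

test_that("matching probability follows the normalized subdimensional distance", {
  e <- hand_edge(c("u", "v"), c("s1", "s2"), mu = c(0, 0), sigma = c(1, 1))
  # profile on the stage means: distance 0, probability exactly 1
  m0 <- match_probability(c(u = 0, v = 0), e, "s1", beta = 1)
  expect_equal(m0$distance, 0)
  expect_equal(m0$probability, 1)

  # hand-evaluated: d = (1/2) sqrt(1 + 1), p = exp(-d)
  m1 <- match_probability(c(u = 1, v = 1), e, "s1", beta = 1)
  expect_equal(m1$distance, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(m1$probability, exp(-sqrt(2) / 2), tolerance = 1e-12)

  expect_error(match_probability(c(u = 1, v = 1), e, "s1", beta = 0),
               "positive")
  expect_error(match_probability(c(u = 1), e, "s1"), "missing member")

  # probability in (0, 1], decreasing in each coordinate's deviation
  set.seed(3)
  for (i in 1:20) {
    p1 <- match_probability(c(u = runif(1), v = runif(1)), e, "s1",
                            beta = runif(1, 0.1, 3))$probability
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
  d_near <- match_probability(c(u = 0.5, v = 0), e, "s1")$distance
  d_far <- match_probability(c(u = 1.5, v = 0), e, "s1")$distance
  expect_gt(d_far, d_near)
})

test_that("stage scores sum weighted match probabilities and drive prediction", {
  stages <- c("normal", "primary", "metastatic")
  # edge 1 matches profile 0 perfectly in every stage; edge 2 is offset
  e1 <- hand_edge(c("u", "v"), stages, mu = c(0, 0), sigma = c(1, 1))
  e2 <- hand_edge(c("u", "w"), stages, mu = c(2, 2), sigma = c(1, 1))
  prof <- c(u = 0, v = 0, w = 0)

  # one edge, weight 2, match 0.5: score = 1
  mod1 <- hand_model(list(e1), c(2, 0, 0), stages)
  p <- match_probability(prof, e1, "normal")$probability  # = 1
  expect_equal(stage_score(prof, mod1, "normal"), 2 * p)

  # two edges (w, P) = (1, 0.4), (3, 0.2): score 1.0
  mod2 <- hand_model(list(e1, e2), rep(0, 6), stages)
  p1 <- match_probability(prof, e1, "primary")$probability
  p2 <- match_probability(prof, e2, "primary")$probability
  mod2$weights[1, "primary"] <- 0.4 / p1 * 1
  mod2$weights[2, "primary"] <- 0.2 / p2 * 3
  expect_equal(stage_score(prof, mod2, "primary"),
               1 * 0.4 + 3 * 0.2, tolerance = 1e-12)

  # all weights zero: every score 0, tie resolved to the first stage
  mod0 <- hand_model(list(e1), rep(0, 3), stages)
  for (y in stages) expect_equal(stage_score(prof, mod0, y), 0)
  expect_identical(predict_stage(prof, mod0), "normal")

  # unique maximum wins; composition with the two-edge example
  expect_identical(predict_stage(prof, mod2), "primary")
  expect_error(stage_score(prof, mod2, "relapse"), "unknown stage")

  # linearity: doubling all weights doubles scores, prediction unchanged
  mod3 <- mod2; mod3$weights <- 2 * mod2$weights
  for (y in stages)
    expect_equal(stage_score(prof, mod3, y), 2 * stage_score(prof, mod2, y))
  expect_identical(predict_stage(prof, mod3), predict_stage(prof, mod2))
})

test_that("posterior is a logistic of the mean-centered score", {
  stages <- c("normal", "primary", "metastatic")
  e1 <- hand_edge(c("u", "v"), stages, mu = c(0, 0), sigma = c(1, 1))
  prof <- c(u = 0, v = 0)

  # equal scores: posterior exactly 1/2 everywhere
  mod0 <- hand_model(list(e1), c(3, 3, 3), stages)
  for (y in stages) expect_equal(stage_posterior(prof, mod0, y), 0.5)

  # scores (2, 0, 0): posterior(normal) = logistic(2 - 2/3)
  mod1 <- hand_model(list(e1), c(2, 0, 0), stages)
  expect_equal(stage_posterior(prof, mod1, "normal"), plogis(4 / 3),
               tolerance = 1e-12)

  # raising a stage's own score raises its posterior
  mod2 <- hand_model(list(e1), c(2.5, 0, 0), stages)
  expect_gt(stage_posterior(prof, mod2, "normal"),
            stage_posterior(prof, mod1, "normal"))

  # adding a constant to every stage score leaves posteriors unchanged:
  # a second edge matching perfectly in all stages with weight c does that
  e_const <- hand_edge(c("u", "v"), stages, mu = c(0, 0), sigma = c(1, 1))
  mod3 <- hand_model(list(e1, e_const), c(2, 0, 0, 5, 5, 5), stages)
  for (y in stages)
    expect_equal(stage_posterior(prof, mod3, y),
                 stage_posterior(prof, mod1, y), tolerance = 1e-12)
  for (y in stages) {
    po <- stage_posterior(prof, mod1, y)
    expect_gt(po, 0); expect_lt(po, 1)
  }
})

test_that("vectorized prediction agrees with the per-profile path", {
  ds <- toy_dataset()
  fit <- mirhyper(ds, hg_control(l = 1, m = 2, n_hyperedges = 6,
                                 structure_epochs = 3, parameter_epochs = 3,
                                 seed = 9))
  pred <- predict(fit, ds)
  X <- rbind(ds$mirna, ds$mrna)
  single <- vapply(seq_len(ncol(X)), function(i)
    predict_stage(X[, i], fit), "")
  expect_identical(as.character(pred), single)

  # posterior matrix consistent with stage_posterior
  post <- predict(fit, ds, type = "posterior")
  expect_equal(unname(post["early", 3]),
               stage_posterior(X[, 3], fit, "early"), tolerance = 1e-12)
})
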