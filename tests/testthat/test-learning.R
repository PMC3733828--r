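test_that("initial weight combines scaled MMI and inverse stage variances", {
  e <- hand_edge(c("u", "v"), c("s1", "s2"), mu = c(0, 0), sigma = c(1, 1),
                 mmi = 0.2)
  expect_equal(initial_weight(e, "s1", kappa = 1), 0.2 + 2)
  expect_equal(initial_weight(e, "s1", kappa = 0), 2)
  expect_equal(initial_weight(e, "s1", kappa = 2.5, mmi = 0.4), 1 + 2)
  # shrinking any member's stage variance strictly increases the weight
  e_t <- e; e_t$sigma["v", "s1"] <- 0.5
  expect_gt(initial_weight(e_t, "s1"), initial_weight(e, "s1"))
})

test_that("replacement ratio decays from R_max to R_min", {
  expect_equal(replacement_ratio(0), 0.9)
  expect_equal(replacement_ratio(1), 0.4 * exp(-1) + 0.5, tolerance = 1e-12)
  expect_equal(replacement_ratio(1e6), 0.5)
  r <- replacement_ratio(0:30)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0.5 & r <= 0.9))
  expect_error(replacement_ratio(1, R_max = 0.4, R_min = 0.5), "R_min")
  expect_error(replacement_ratio(-1), "non-negative")
})

test_that("gradient epoch applies the analytic batch delta", {
  stages <- c("s1", "s2")
  # edge matching the single profile with probability 0.4 in s1 and 1 in s2
  m1 <- sqrt(2) * log(1 / 0.4)
  e <- hand_edge(c("mirU", "geneV"), stages, mu = c(0, 0), sigma = c(1, 1))
  e$mu[, "s1"] <- m1
  mod <- hand_model(list(e), c(1, 0.4), stages,
                    feature_types = c(mirU = "miRNA", geneV = "mRNA"))
  # scores: c(s1) = 1 * 0.4, c(s2) = 0.4 * 1  ->  posteriors 0.5 and 0.5
  ds <- hg_dataset(matrix(0, 1, 2, dimnames = list("mirU", NULL)),
                   matrix(0, 1, 2, dimnames = list("geneV", NULL)),
                   c("s1", "s2"))
  ds1 <- mirhyper:::.subset_samples(ds, 1)        # one sample, stage s1
  upd <- parameter_update_epoch(mod, ds1, gamma = 1)
  # true stage:  0.5 * 0.5 * (1 - 0.5) * 0.4 = 0.05
  # other stage: 0.5 * 0.5 * (0 - 0.5) * 1  = -0.125
  expect_equal(unname(upd$weights[1, ]), c(1 + 0.05, 0.4 - 0.125),
               tolerance = 1e-10)

  # gamma = 0 never changes weights
  upd0 <- parameter_update_epoch(mod, ds1, gamma = 0)
  expect_equal(upd0$weights, mod$weights)

  # saturated posterior: logistic-derivative factor wipes the update
  mod_sat <- mod; mod_sat$weights[1, ] <- c(1e4, 0)
  upd_sat <- parameter_update_epoch(mod_sat, ds1, gamma = 1)
  expect_equal(upd_sat$weights, mod_sat$weights, tolerance = 1e-8)

  # a correctly labeled, well-matched sample pushes the true stage up
  expect_gt(upd$weights[1, "s1"], mod$weights[1, "s1"])

  # online mode applies the same first-sample delta
  on1 <- parameter_update_epoch(mod, ds1, gamma = 1, update = "online")
  expect_equal(on1$weights, upd$weights, tolerance = 1e-10)

  expect_error(parameter_update_epoch(mod,
    hg_dataset(matrix(0, 1, 2, dimnames = list("mirU", NULL)),
               matrix(0, 1, 2, dimnames = list("geneV", NULL)),
               c("s1", "s3")), gamma = 1), "absent")
})

test_that("hyperedge sampling respects pools, distributions and uniqueness", {
  px <- c(a = 0.5, b = 0.5)
  pz <- c(g1 = 1 / 3, g2 = 1 / 3, g3 = 1 / 3)
  # forced selection: pool sizes equal the degrees
  expect_setequal(sample_hyperedge(px, pz, 2, 3), c("a", "b", "g1", "g2", "g3"))
  expect_error(sample_hyperedge(px, pz, 3, 1), "exceeds the miRNA")
  expect_error(sample_hyperedge(px, pz, 1, 4), "exceeds the mRNA")

  # seed contract
  set.seed(123); s1 <- sample_hyperedge(px, pz, 1, 2)
  set.seed(123); s2 <- sample_hyperedge(px, pz, 1, 2)
  expect_identical(s1, s2)

  # duplicate avoidance: with C(3,2) mRNA pairs and one miRNA, only 3
  # distinct sets exist; drawing 3 with exclusions yields all of them
  ex <- list()
  for (i in 1:3) ex[[i]] <- sample_hyperedge(c(a = 1), pz, 1, 2, ex)
  keys <- vapply(ex, function(s) paste(sort(s), collapse = "+"), "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_error(sample_hyperedge(c(a = 1), pz, 1, 2, ex, max_tries = 50),
               "distinct")

  # a near-certain feature appears in (almost) every draw
  pz2 <- c(g1 = 1 - 1e-9, g2 = 5e-10, g3 = 5e-10)
  set.seed(99)
  draws <- replicate(300, "g1" %in% sample_hyperedge(px, pz2, 1, 1))
  expect_true(all(draws))
})

test_that("enumerated conditional sampler matches rejection frequencies", {
  # internal fast path used on small joint pools must draw member sets
  # with the same distribution as the duplicate-free rejection loop
  d <- selection_distribution(c(x1 = 0.05, x2 = 1, x3 = 0.7, x4 = 0.4))
  cache <- mirhyper:::.make_combo_cache(d, 2)
  expect_equal(sum(cache$prob), 1, tolerance = 1e-12)
  ex <- list(c("x2", "x3"))
  set.seed(42)
  n <- 4000
  ctl <- hg_control(l = 2, m = 0, degree_mode = "joint")
  fast <- replicate(n, paste(sort(
    mirhyper:::.sample_members(list(joint = d), ctl, ex, cache)),
    collapse = "+"))
  slow <- replicate(n, paste(sort(
    sample_hyperedge(d, numeric(0), 2, 0, ex)), collapse = "+"))
  tf <- table(factor(fast, levels = sort(unique(c(fast, slow))))) / n
  ts <- table(factor(slow, levels = sort(unique(c(fast, slow))))) / n
  expect_false("x2+x3" %in% names(tf)[tf > 0])
  expect_equal(as.numeric(tf), as.numeric(ts), tolerance = 0.05)
})

test_that("replacement removes the lowest max-over-stage weights only", {
  ds <- toy_dataset()
  ctl <- hg_control(l = 1, m = 2, n_hyperedges = 4, structure_epochs = 0,
                    seed = 5)
  mod <- mirhyper(ds, ctl)
  mod$weights <- matrix(c(1, 0, 2, 1, 3, 0, 4, 2), 4, 2, byrow = TRUE,
                        dimnames = list(NULL, mod$stages))
  set.seed(1)
  rep0 <- replace_hyperedges(mod, 0, ds)
  expect_identical(rep0$edges, mod$edges)

  set.seed(1)
  rep_half <- replace_hyperedges(mod, 0.5, ds)
  kept <- vapply(3:4, function(i)
    identical(rep_half$edges[[i]]$members, mod$edges[[i]]$members), TRUE)
  expect_true(all(kept))
  changed <- vapply(1:2, function(i)
    identical(rep_half$edges[[i]]$members, mod$edges[[i]]$members), TRUE)
  expect_false(any(changed))
  expect_length(rep_half$edges, 4)

  set.seed(2)
  rep_all <- replace_hyperedges(mod, 1, ds)
  expect_length(rep_all$edges, 4)
  # replaced edges carry fresh initial weights
  for (i in 1:2)
    expect_equal(unname(rep_half$weights[i, ]),
                 unname(mirhyper:::.init_weights(rep_half$edges[[i]],
                                                 ctl$kappa)))
  expect_error(replace_hyperedges(mod, 1.2, ds), "ratio")
})

test_that("training is reproducible, conserves the population and can improve", {
  ds <- toy_dataset(n_per = 20, seed = 2)
  ctl <- hg_control(l = 1, m = 2, n_hyperedges = 8, structure_epochs = 4,
                    parameter_epochs = 3, seed = 77)
  f1 <- mirhyper(ds, ctl)
  f2 <- mirhyper(ds, ctl)
  expect_identical(lapply(f1$edges, `[[`, "members"),
                   lapply(f2$edges, `[[`, "members"))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trace, f2$trace)

  # population size constant; trace has one row per structure iteration
  expect_length(f1$edges, 8)
  expect_identical(nrow(f1$trace), 4L)
  expect_true(all(f1$trace$replacement_ratio >= ctl$R_min &
                    f1$trace$replacement_ratio <= ctl$R_max))

  # structure_epochs = 0 returns the initialized population untouched
  ctl0 <- ctl; ctl0$structure_epochs <- 0L
  f0 <- mirhyper(ds, ctl0)
  expect_identical(nrow(f0$trace), 0L)
  expect_equal(unname(f0$weights),
               unname(t(vapply(f0$edges, mirhyper:::.init_weights,
                               numeric(2), kappa = ctl$kappa))))

  # gamma = 0 freezes weights through parameter learning
  ctlg <- ctl; ctlg$gamma <- 0
  fg <- mirhyper(ds, ctlg)
  expect_equal(fg$trace$accuracy, fg$trace$accuracy_init)
})
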