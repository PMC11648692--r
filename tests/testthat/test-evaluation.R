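test_that("stratified folds balance classes and totals", {
  y <- rep(c("HC", "uHC"), each = 10)
  f <- stratified_kfold(y, 5, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab == 2))

  y2 <- rep(c("HC", "uHC"), c(97, 24))
  f2 <- stratified_kfold(y2, 10, seed = 2)
  per_fold_u <- table(f2[y2 == "uHC"])
  expect_true(all(per_fold_u %in% c(2, 3)))
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1)

  expect_identical(stratified_kfold(y2, 10, seed = 7),
                   stratified_kfold(y2, 10, seed = 7))
  expect_error(stratified_kfold(rep(c("HC", "uHC"), c(50, 3)), 5),
               "fewer samples than k")
})

test_that("undersampling matches minority size and loses nothing else", {
  tab <- small_cohort(n_hc = 97, n_uhc = 24, seed = 5)
  bal <- undersample_majority(tab, seed = 9)
  expect_identical(as.integer(table(bal$group)), c(24L, 24L))
  expect_true(all(bal$subject_id[bal$group == "uHC"] %in%
                    tab$subject_id[tab$group == "uHC"]))
  # union of kept and discarded majority rows reconstructs the input
  discarded <- setdiff(tab$subject_id, bal$subject_id)
  expect_equal(sort(c(bal$subject_id, discarded)), sort(tab$subject_id))
  expect_true(all(discarded %in% tab$subject_id[tab$group == "HC"]))

  already <- small_cohort(n_hc = 24, n_uhc = 24, seed = 6)
  expect_equal(nrow(undersample_majority(already, 1)), 48)
})

test_that("imbalance delta is the majority/minority ratio", {
  expect_equal(imbalance_delta(rep(c("HC", "uHC"), c(97, 24))), 97 / 24)
  expect_equal(round(imbalance_delta(rep(c("HC", "uHC"), c(97, 24))), 4),
               4.0417)
  expect_equal(imbalance_delta(rep(c("HC", "uHC"), each = 50)), 1)
  expect_error(imbalance_delta(rep("HC", 10)), "non-empty")
})

test_that("bayes_opt finds known optima in continuous and discrete spaces", {
  space <- list(list(name = "x", kind = "real", lower = 0, upper = 10,
                     log_scale = FALSE))
  hits <- vapply(1:20, function(s) {
    r <- bayes_opt(function(p) (p$x - 3)^2, space, budget = 30, seed = s)
    abs(r$best_params$x - 3) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  disc <- list(list(name = "lvl", kind = "categorical",
                    categories = letters[1:6]))
  target <- c(a = 5, b = 4, c = 0.5, d = 2, e = 3, f = 9)
  r <- bayes_opt(function(p) target[[p$lvl]], disc, budget = 25, seed = 3)
  expect_equal(r$best_params$lvl, "c")

  # budget equal to the initial design reduces to random search
  r2 <- bayes_opt(function(p) (p$x - 3)^2, space, budget = 10, seed = 5)
  r3 <- bayes_opt(function(p) (p$x - 3)^2, space, budget = 10, seed = 5,
                  method = "random")
  expect_equal(r2$trace$value, r3$trace$value)

  expect_error(
    bayes_opt(function(p) NaN, space, budget = 12, seed = 1),
    "non-finite")
})

test_that("nested CV keeps holdouts clean and detects an oracle feature", {
  tab <- small_cohort(n_hc = 60, n_uhc = 30, seed = 41, null_effects = TRUE)
  df <- as.data.frame(tab)
  df$oracle <- ifelse(df$group == "uHC", 1, 0) + rnorm(nrow(df), 0, 1e-3)
  df$oracle <- df$oracle + 2  # keep positive
  tab2 <- feature_table(df, c(volume_cols(tab), "oracle"))
  cfg <- evaluation_config(k_outer = 5, opt_budget = 5, mode = "imbalanced",
                           optimizer = "random")
  res <- nested_cv_evaluate(tab2, "oracle", classifier_spec("logistic"),
                            cfg, seed = 4)
  expect_gt(res$metrics$acc, 0.95)
  # every sample predicted exactly once
  expect_equal(res$confusion$total, nrow(df))
  expect_equal(res$failed_folds, 0L)
})

test_that("majority dummy reproduces the base-rate accuracy exactly", {
  tab <- small_cohort(n_hc = 413, n_uhc = 106, seed = 3)
  cfg <- evaluation_config(k_outer = 5, opt_budget = 2)
  res <- nested_cv_evaluate(tab, "Hippocampus", classifier_spec("majority"),
                            cfg, seed = 10)
  expect_equal(res$metrics$acc, 413 / 519)
})

test_that("direct estimates are optimistic for tuned KNN on pure noise", {
  set.seed(55)
  gaps <- vapply(1:20, function(r) {
    n <- 60
    df <- data.frame(
      subject_id = paste0("s", 1:n),
      group = rep(c("HC", "uHC"), each = n / 2),
      sex = "Male", age = 70, education = 16, mmse = 29, icv = 1.5e6
    )
    for (j in 1:8) df[[paste0("noise", j)]] <- runif(n, 1, 2)
    tab <- feature_table(df, paste0("noise", 1:8))
    spec <- classifier_spec("knn", space = list(
      list(name = "n_neighbors", kind = "integer", lower = 1, upper = 30,
           log_scale = FALSE),
      list(name = "distance", kind = "categorical",
           categories = c("euclidean", "cityblock", "chebychev"))))
    cfg <- evaluation_config(k_outer = 5, opt_budget = 12,
                             mode = "balanced", optimizer = "random")
    res <- nested_cv_evaluate(tab, paste0("noise", 1:8), spec, cfg,
                              seed = 100 + r)
    res$direct_metrics$acc - res$metrics$acc
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  # one-sided sign test on the per-replication gaps
  bt <- binom.test(sum(gaps > 0), sum(gaps != 0), alternative = "greater")
  expect_lt(bt$p.value, 0.05)
})

test_that("monte carlo runs are deterministic and factorially complete", {
  tab <- small_cohort(n_hc = 50, n_uhc = 20, seed = 13)
  subsets <- list(D = c("Hippocampus", "entorhinal"))
  classifiers <- list(naive_bayes = classifier_spec("naive_bayes"))
  cfg <- evaluation_config(k_outer = 3, mc_reps = 2, opt_budget = 4,
                           mode = "imbalanced", master_seed = 5,
                           optimizer = "random")
  r1 <- monte_carlo_run(list(synthetic = tab), c("uncorrected", "residual"),
                        subsets, classifiers, cfg)
  r2 <- monte_carlo_run(list(synthetic = tab), c("uncorrected", "residual"),
                        subsets, classifiers, cfg)
  expect_identical(r1, r2)
  got <- unique(r1[, c("harmonization", "replication", "estimate_type")])
  expect_equal(nrow(got), 2 * 2 * 2)
  expect_true(all(is.finite(r1$value)))
  expect_true(all(r1$metric[r1$estimate_type == "direct"] != "aroc"))
  # a different master seed changes values but not the design
  cfg2 <- cfg; cfg2$master_seed <- 6L
  r3 <- monte_carlo_run(list(synthetic = tab), c("uncorrected", "residual"),
                        subsets, classifiers, cfg2)
  expect_equal(dim(r3), dim(r1))
  expect_false(isTRUE(all.equal(r3$value, r1$value)))
})
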