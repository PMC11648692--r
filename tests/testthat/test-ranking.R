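test_that("anova score matches the F = t^2 identity and degenerates to 0", {
  expect_equal(anova_score(rep(5, 10), rep(c("HC", "uHC"), 5))$score, 0)

  set.seed(2)
  x <- c(rnorm(50), rnorm(50, 2))
  g <- rep(c("HC", "uHC"), each = 50)
  a <- anova_score(x, g)
  expect_lt(a$p, 1e-6)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  expect_equal(a$score, -log(a$p))
  # permutation oracle agrees within Monte Carlo error on a weak effect
  set.seed(5)
  xw <- c(rnorm(25), rnorm(25, 0.5)); gw <- rep(c("HC", "uHC"), each = 25)
  obs <- anova_score(xw, gw)$statistic
  perm <- replicate(2000, anova_score(xw, sample(gw))$statistic)
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - anova_score(xw, gw)$p), 0.04)
})

test_that("kruskal score is rank-invariant and matches small-n enumeration", {
  expect_equal(kruskal_score(rep(3, 8), rep(c("a", "b"), 4))$score, 0)

  set.seed(3)
  x <- rlnorm(40); g <- rep(c("HC", "uHC"), 20)
  expect_equal(kruskal_score(x, g)$score,
               kruskal_score(exp(x), g)$score, tolerance = 1e-12)

  # n = 6: exhaustive enumeration of all 3/3 label assignments
  x6 <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  g6 <- c("a", "a", "a", "b", "b", "b")
  obs <- kruskal_score(x6, g6)
  combos <- combn(6, 3)
  hs <- apply(combos, 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"
    unname(kruskal.test(x6, factor(lab))$statistic)
  })
  p_exact <- mean(hs >= obs$statistic - 1e-12)
  expect_equal(obs$statistic,
               unname(kruskal.test(x6, factor(g6))$statistic))
  # chi-square approximation is within coarse agreement of the exact null
  expect_lt(abs(obs$p - p_exact), 0.25)
})

test_that("ancova absorbs confounded effects and is calibrated under null", {
  set.seed(8)
  n <- 150
  age <- runif(n, 60, 86)
  g <- rep(c("HC", "uHC"), length.out = n)
  age[g == "uHC"] <- age[g == "uHC"] + 6
  covs <- data.frame(age = age,
                     sex = sample(c("Male", "Female"), n, TRUE),
                     education = sample(12:20, n, TRUE),
                     icv = rnorm(n, 1.5e6, 1e5))
  y <- 8000 - 30 * age + rnorm(n, 0, 300)   # effect only through age
  p_anova <- anova_score(y, g)$p
  p_ancova <- ancova_score(y, g, covs)$p
  expect_lt(p_anova, 0.01)
  expect_gt(p_ancova / p_anova, 10)

  # orthogonal covariates leave the p-value essentially unchanged
  y2 <- ifelse(g == "uHC", 1, 0) * 200 + rnorm(n, 0, 300)
  covs2 <- covs; covs2$age <- runif(n, 60, 86)
  expect_lt(abs(log(ancova_score(y2, g, covs2)$p) -
                  log(anova_score(y2, g)$p)), 3)

  # type-I calibration at nominal 0.05
  set.seed(21)
  rej <- mean(replicate(400, {
    yn <- rnorm(200)
    gn <- rep(c("HC", "uHC"), 100)
    cv <- data.frame(age = runif(200, 60, 86),
                     sex = sample(c("Male", "Female"), 200, TRUE),
                     education = sample(12:20, 200, TRUE),
                     icv = rnorm(200, 1.5e6, 1e5))
    ancova_score(yn, gn, cv)$p <= 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)

  covs_col <- covs; covs_col$education <- covs_col$age * 2
  expect_error(ancova_score(y, g, covs_col), "collinear")
})

test_that("chi-square scoring handles separation, nulls and 2x2 tables", {
  # perfectly separating feature, disjoint supports
  x <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  g <- rep(c("HC", "uHC"), each = 20)
  s <- chi2_score(x, g)
  # disjoint supports give the maximal statistic n on the 2 x k table;
  # exact chi-square oracle on that table
  expect_equal(s$statistic, 40, tolerance = 1e-10)
  expect_equal(s$p, pchisq(40, df = 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(s$p, 1e-4)
  # 2x2 table (20,0;0,20): chi2 = n = 40
  xb <- rep(c(0, 1), each = 20)
  expect_equal(chi2_score(xb, g)$statistic, 40)
  # independent feature: mean -ln(p) near 1 under the null
  set.seed(6)
  scores <- replicate(300, chi2_score(rnorm(60),
                                      sample(rep(c("a", "b"), 30)))$score)
  expect_lt(abs(mean(scores) - 1), 0.25)
  expect_error(chi2_score(x, g, n_bins = 1), "n_bins")
})

test_that("relieff matches the exhaustive k=1 oracle and signs separation", {
  # constant feature has weight exactly 0
  X <- cbind(a = c(0, 0, 1, 1, 2, 2), b = rep(7, 6))
  y <- factor(c("HC", "HC", "HC", "uHC", "uHC", "uHC"))
  w <- relieff_score(X, y, k_neighbors = 1)
  expect_equal(unname(w["b"]), 0)

  set.seed(13)
  for (i in 1:10) {
    X6 <- matrix(runif(12), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
    y6 <- factor(sample(rep(c("HC", "uHC"), 3)))
    expect_equal(unname(relieff_score(X6, y6, k_neighbors = 1)),
                 unname(relieff_bruteforce_k1(X6, y6)), tolerance = 1e-12)
  }

  # fully separated single feature at values {0} vs {1}: positive weight;
  # permuted labels destroy it
  set.seed(19)
  Xs <- matrix(rep(c(0, 1), each = 15), ncol = 1,
               dimnames = list(NULL, "f"))
  ys <- factor(rep(c("HC", "uHC"), each = 15))
  expect_gt(relieff_score(Xs, ys, 1)["f"], 0)
  shuffles <- replicate(40, relieff_score(Xs, sample(ys), 1)["f"])
  expect_gte(mean(shuffles <= 0), 0.9)
})

test_that("percentages normalize over positive scores and sum to 100", {
  sc <- c(a = 2, b = 1, c = 0, d = -1)
  p <- to_percentages(sc)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(unname(p["a"]), 200 / 3)
  expect_equal(unname(p[c("c", "d")]), c(0, 0))
  expect_equal(unname(to_percentages(c(x = 5))["x"]), 100)
  expect_warning(pz <- to_percentages(c(a = -1, b = 0)), "no positive")
  expect_equal(unname(pz), c(0, 0))

  set.seed(30)
  for (i in 1:20) {
    s <- rnorm(15)
    if (all(s <= 0)) next
    p <- to_percentages(s)
    expect_equal(sum(p), 100, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni_adjust(0.001, 40), 0.04)
  expect_equal(bonferroni_adjust(0.5, 40), 1)
  set.seed(1)
  p <- runif(25)
  expect_equal(bonferroni_adjust(p, 25), pmin(1, 25 * p))
  expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("subset rules: tie handling, inclusion, provenance", {
  tab <- small_cohort(n_hc = 120, n_uhc = 40, seed = 77)
  models <- fit_all_reference_models(tab)
  hz <- harmonize(tab, models, "zscore")
  rs <- rank_features(hz, uncorrected = tab)
  sb <- suppressWarnings(build_subsets(rs))
  # C is the intersection of all criteria, so it is inside B
  expect_true(all(sb$subset_c %in% sb$subset_b))
  expect_true(all(sb$subset_c %in% sb$subset_a))
  expect_true(all(unlist(sb[c("subset_a", "subset_b", "subset_c",
                              "subset_d")]) %in% rs$feature))
  # identical scores put every feature at the median: all selected in A
  rs_tie <- rs
  rs_tie$chi2_pct <- rs_tie$anova_pct <- rs_tie$kruskal_pct <-
    rs_tie$relieff_pct <- rep(2.5, nrow(rs))
  rs_tie$average_pct <- rep(2.5, nrow(rs))
  sb_tie <- suppressWarnings(build_subsets(rs_tie))
  expect_equal(sort(sb_tie$subset_a), sort(rs$feature))
  expect_equal(sum(sb$provenance$total),
               sum(vapply(sb$provenance[, 2:7], sum, numeric(1))))
})
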