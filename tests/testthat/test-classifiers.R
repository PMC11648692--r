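test_that("kernel densities have closed forms and integrate to one", {
  # single point, box kernel, w = 2, query at the point
  expect_equal(kernel_density(5, "box", 2, 5), 0.25)
  set.seed(2)
  train <- rnorm(20, 3, 2)
  grid <- seq(-30, 40, length.out = 20001)
  dx <- diff(grid)[1]
  for (k in c("box", "epanechnikov", "normal", "triangle")) {
    dens <- kernel_density(train, k, 1.3, grid)
    expect_equal(sum(dens) * dx, 1, tolerance = 1e-3)
  }
  # normal kernel equals the direct sum of Gaussian pdfs
  q <- c(-1, 0, 2.5, 3.7, 9)
  direct <- vapply(q, function(x)
    mean(dnorm((x - train) / 1.3)) / 1.3, numeric(1))
  expect_equal(kernel_density(train, "normal", 1.3, q), direct,
               tolerance = 1e-12)
  expect_error(kernel_density(train, "box", 0, 1), "positive")
})

test_that("gaussian naive Bayes separates well-separated classes", {
  set.seed(4)
  X <- matrix(c(rnorm(100, 0), rnorm(100, 10)), ncol = 1)
  y <- factor(rep(c("HC", "uHC"), each = 100), levels = c("HC", "uHC"))
  m <- naive_bayes_fit(X, y, distribution = "normal")
  pr <- naive_bayes_predict(m, X)
  expect_equal(mean(pr$labels == y), 1)
  # equal priors, symmetric classes: boundary at the midpoint
  left <- naive_bayes_predict(m, matrix(4.7))$labels
  right <- naive_bayes_predict(m, matrix(5.3))$labels
  expect_equal(as.character(left), "HC")
  expect_equal(as.character(right), "uHC")
})

test_that("kernel NB beats gaussian NB on a bimodal class by > 10 points", {
  set.seed(9)
  n <- 150
  # interleaved two-lobe mixtures with equal pooled spread: a single
  # Gaussian per class cannot separate them, kernel densities can
  x_h <- c(rnorm(n / 2, -3, 0.5), rnorm(n / 2, 3, 0.5))
  x_u <- c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 6, 0.5))
  X <- matrix(c(x_h, x_u), ncol = 1)
  y <- factor(rep(c("HC", "uHC"), each = n), levels = c("HC", "uHC"))
  acc <- function(distribution) {
    m <- naive_bayes_fit(X, y, distribution = distribution,
                         kernel_type = "normal")
    mean(naive_bayes_predict(m, X)$labels == y)
  }
  expect_gt(acc("kernel") - acc("normal"), 0.10)
})

test_that("cost matrix shifts the NB posterior-odds threshold analytically", {
  set.seed(5)
  X <- matrix(c(rnorm(200, 0), rnorm(200, 2)), ncol = 1)
  y <- factor(rep(c("HC", "uHC"), each = 200), levels = c("HC", "uHC"))
  spec1 <- classifier_spec("naive_bayes")
  spec5 <- apply_cost_matrix(spec1, 5)
  m1 <- naive_bayes_fit(X, y, spec1, distribution = "normal")
  m5 <- naive_bayes_fit(X, y, spec5, distribution = "normal")
  q <- matrix(seq(-2, 4, length.out = 400))
  p1 <- naive_bayes_predict(m1, q)
  p5 <- naive_bayes_predict(m5, q)
  # analytic rule: predict uHC iff delta * P(uHC|x) > P(HC|x)
  expect_equal(p1$labels == "uHC", p1$scores > 1 - p1$scores)
  expect_equal(p5$labels == "uHC", 5 * p5$scores > 1 - p5$scores)
  # delta = 1 is the identity on decisions
  spec_id <- apply_cost_matrix(spec1, 1)
  m_id <- naive_bayes_fit(X, y, spec_id, distribution = "normal")
  expect_equal(naive_bayes_predict(m_id, q)$labels, p1$labels)
  expect_error(apply_cost_matrix(spec1, 0), "positive")
})

test_that("delta cost strictly raises minority TPR under 10:1 imbalance", {
  set.seed(7)
  n_maj <- 300; n_min <- 30
  X <- rbind(matrix(rnorm(n_maj * 2, 0), ncol = 2),
             matrix(rnorm(n_min * 2, 1.2), ncol = 2))
  y <- factor(rep(c("HC", "uHC"), c(n_maj, n_min)),
              levels = c("HC", "uHC"))
  spec <- classifier_spec("naive_bayes")
  params <- list(distribution = "normal", kernel_type = "normal",
                 width_mult = 1)
  fit1 <- make_classifier(spec, params, X, y)
  fit10 <- make_classifier(apply_cost_matrix(spec, 10), params, X, y)
  tpr <- function(fit) {
    pr <- predict_classifier(fit, X)
    compute_metrics(confusion(y, pr$labels))$tpr
  }
  expect_gt(tpr(fit10), tpr(fit1))
})

test_that("memorizing learners are exact on training data", {
  d <- toy_xy(n_per_class = 25, shift = 3, seed = 12)
  spec_knn <- classifier_spec("knn",
                              space = list(
                                list(name = "n_neighbors", kind = "integer",
                                     lower = 1, upper = 30,
                                     log_scale = FALSE),
                                list(name = "distance", kind = "categorical",
                                     categories = "euclidean")))
  fit <- make_classifier(spec_knn,
                         list(n_neighbors = 1L, distance = "euclidean"),
                         d$X, d$y)
  expect_equal(mean(predict_classifier(fit, d$X)$labels == d$y), 1)

  fit_svm <- make_classifier(classifier_spec("svm"),
                             list(kernel = "linear", kernel_scale = 1,
                                  box_constraint = 10), d$X, d$y)
  expect_equal(mean(predict_classifier(fit_svm, d$X)$labels == d$y), 1)
})

test_that("every KNN distance and both SVM kernel aliases run", {
  d <- toy_xy(n_per_class = 15, shift = 2, seed = 3)
  metrics <- c("cityblock", "chebychev", "correlation", "cosine",
               "euclidean", "hamming", "jaccard", "mahalanobis",
               "minkowski", "seuclidean", "spearman")
  for (m in metrics) {
    fit <- make_classifier(classifier_spec("knn"),
                           list(n_neighbors = 5L, distance = m), d$X, d$y)
    pr <- predict_classifier(fit, d$X)
    expect_equal(length(pr$labels), nrow(d$X))
  }
  for (k in c("gaussian", "rbf")) {
    fit <- make_classifier(classifier_spec("svm"),
                           list(kernel = k, kernel_scale = 1,
                                box_constraint = 1), d$X, d$y)
    expect_gt(mean(predict_classifier(fit, d$X)$labels == d$y), 0.8)
  }
})

test_that("heavy lasso penalty shrinks all slopes to zero", {
  set.seed(8)
  X <- scale(matrix(rnorm(100 * 6), ncol = 6))
  y <- factor(sample(rep(c("HC", "uHC"), 50)), levels = c("HC", "uHC"))
  fit <- make_classifier(classifier_spec("logistic"),
                         list(lambda = 10, score_transform = "none"),
                         X, y)
  expect_equal(max(abs(as.numeric(fit$model$fit$beta))), 0)
  # monotone score transforms never change the labels
  for (tr in c("logit", "invlogit", "doublelogit")) {
    fit_t <- make_classifier(classifier_spec("logistic"),
                             list(lambda = 0.01, score_transform = tr),
                             X, y)
    fit_n <- make_classifier(classifier_spec("logistic"),
                             list(lambda = 0.01, score_transform = "none"),
                             X, y)
    expect_equal(predict_classifier(fit_t, X)$labels,
                 predict_classifier(fit_n, X)$labels)
  }
})

test_that("rusboost learns a separable problem and is seed-deterministic", {
  d <- toy_xy(n_per_class = 40, shift = 3, seed = 6)
  params <- list(n_cycles = 20L, learning_rate = 0.5, max_splits = 7L)
  fit1 <- make_classifier(classifier_spec("rusboost"), params, d$X, d$y,
                          seed = 33)
  fit2 <- make_classifier(classifier_spec("rusboost"), params, d$X, d$y,
                          seed = 33)
  expect_gt(mean(predict_classifier(fit1, d$X)$labels == d$y), 0.9)
  expect_equal(predict_classifier(fit1, d$X)$scores,
               predict_classifier(fit2, d$X)$scores)
})

test_that("out-of-space hyperparameters are rejected naming the bound", {
  spec <- classifier_spec("knn")
  expect_error(make_classifier(spec, list(n_neighbors = 3L,
                                          distance = "euclidean"),
                               matrix(rnorm(20), 10),
                               factor(rep(c("HC", "uHC"), 5))),
               "outside \\[5, 30\\]")
  expect_error(make_classifier(spec, list(n_neighbors = 10L,
                                          distance = "manhattan"),
                               matrix(rnorm(20), 10),
                               factor(rep(c("HC", "uHC"), 5))),
               "not among")
})

test_that("classifiers are invariant to row order given a fixed seed", {
  d <- toy_xy(n_per_class = 30, shift = 1.5, seed = 10)
  perm <- sample(nrow(d$X))
  for (fam in c("naive_bayes", "logistic")) {
    spec <- classifier_spec(fam)
    params <- if (fam == "naive_bayes")
      list(distribution = "normal", kernel_type = "normal", width_mult = 1)
    else list(lambda = 0.05, score_transform = "none")
    f1 <- make_classifier(spec, params, d$X, d$y)
    f2 <- make_classifier(spec, params, d$X[perm, ], d$y[perm])
    expect_equal(predict_classifier(f1, d$X)$labels,
                 predict_classifier(f2, d$X)$labels)
  }
})

test_that("kernel NB converges to gaussian NB on truly Gaussian classes", {
  set.seed(15)
  n <- 2000
  X <- matrix(c(rnorm(n, 0), rnorm(n, 1.5)), ncol = 1)
  y <- factor(rep(c("HC", "uHC"), each = n), levels = c("HC", "uHC"))
  mg <- naive_bayes_fit(X, y, distribution = "normal")
  mk <- naive_bayes_fit(X, y, distribution = "kernel",
                        kernel_type = "normal")
  q <- matrix(seq(-3, 4.5, length.out = 500))
  agree <- mean(naive_bayes_predict(mg, q)$labels ==
                  naive_bayes_predict(mk, q)$labels)
  expect_gte(agree, 0.95)
})
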