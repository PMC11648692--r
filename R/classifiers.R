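#' Classifier specification
#'
#' Bundles a classifier family with its hyperparameter search space and a
#' 2x2 misclassification cost matrix (rows = true class HC then uHC,
#' columns = predicted). The default cost matrix `[[0,1],[1,0]]` is
#' symmetric; [apply_cost_matrix()] installs the imbalance-compensating
#' `[[0,1],[delta,0]]`.
#'
#' @param family One of `"naive_bayes"`, `"knn"`, `"svm"`, `"logistic"`,
#'   `"rusboost"`, `"majority"` (constant-prediction baseline).
#' @param space Hyperparameter space; default [default_space()] for the
#'   family.
#' @param cost_matrix 2x2 numeric, zero diagonal, non-negative off-diagonal.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("naive_bayes", "knn", "svm",
                                       "logistic", "rusboost", "majority"),
                            space = default_space(family),
                            cost_matrix = matrix(c(0, 1, 1, 0), 2,
                                                 byrow = TRUE)) {
  family <- match.arg(family)
  if (any(diag(cost_matrix) != 0) || any(cost_matrix < 0)) {
    stop("cost_matrix needs zero diagonal and non-negative costs")
  }
  structure(list(family = family, space = space, cost_matrix = cost_matrix),
            class = "classifier_spec")
}

#' Install the delta cost matrix
#'
#' Sets the cost of predicting the majority (HC) class when the true class
#' is the minority (uHC) to `delta`, realized throughout the package as
#' class weights (w_uHC = delta, w_HC = 1) entering training or the
#' decision rule of each backend.
#'
#' @param spec A `classifier_spec`.
#' @param delta Positive cost ratio (majority/minority cardinality ratio in
#'   the imbalanced pipeline).
#' @return The spec with `cost_matrix = [[0,1],[delta,0]]`.
#' @export
apply_cost_matrix <- function(spec, delta) {
  if (delta <= 0) stop("delta must be positive")
  spec$cost_matrix <- matrix(c(0, 1, delta, 0), 2, byrow = TRUE)
  spec
}

class_weights <- function(spec) {
  # cost of missing a true uHC (row 2, col 1) relative to missing a true HC
  c(HC = spec$cost_matrix[1, 2], uHC = spec$cost_matrix[2, 1])
}

param_real <- function(name, lower, upper, log_scale = FALSE) {
  list(name = name, kind = "real", lower = lower, upper = upper,
       log_scale = log_scale)
}
param_int <- function(name, lower, upper, log_scale = FALSE) {
  list(name = name, kind = "integer", lower = lower, upper = upper,
       log_scale = log_scale)
}
param_cat <- function(name, categories) {
  list(name = name, kind = "categorical", categories = categories)
}

#' Default hyperparameter space per classifier family
#'
#' Mirrors the tunable options of the source pipeline: naive Bayes
#' distribution/kernel/width; KNN neighbours in `[5, 30]` over eleven
#' distance functions; SVM kernel, scale and box constraint in `[0.1, 10]`;
#' lasso-logistic lambda in `[1e-3, 10]` plus a monotone score
#' transformation; RUSBoost cycles, shrinkage in `(0, 1]` and maximal
#' splits. Unbounded-positive parameters (NB kernel width, RUSBoost cycles
#' and splits) are boxed to finite ranges so surrogate optimization is
#' well-posed; the NB width is a multiplier of each feature's robust SD.
#'
#' @param family Classifier family name.
#' @return List of parameter definitions.
#' @export
default_space <- function(family) {
  switch(family,
    naive_bayes = list(
      param_cat("distribution", c("normal", "kernel")),
      param_cat("kernel_type", c("box", "epanechnikov", "normal", "triangle")),
      param_real("width_mult", 1e-2, 1e2, log_scale = TRUE)
    ),
    knn = list(
      param_int("n_neighbors", 5, 30),
      param_cat("distance", c("cityblock", "chebychev", "correlation",
                              "cosine", "euclidean", "hamming", "jaccard",
                              "mahalanobis", "minkowski", "seuclidean",
                              "spearman"))
    ),
    svm = list(
      param_cat("kernel", c("gaussian", "rbf", "linear", "polynomial")),
      param_real("kernel_scale", 0.1, 10, log_scale = TRUE),
      param_real("box_constraint", 0.1, 10, log_scale = TRUE)
    ),
    logistic = list(
      param_real("lambda", 1e-3, 10, log_scale = TRUE),
      param_cat("score_transform", c("none", "logit", "invlogit",
                                     "doublelogit"))
    ),
    rusboost = list(
      param_int("n_cycles", 10, 200, log_scale = TRUE),
      param_real("learning_rate", 0.01, 1),
      param_int("max_splits", 1, 128, log_scale = TRUE)
    ),
    majority = list(),
    stop("unknown classifier family: ", family)
  )
}

validate_hyperparams <- function(space, params) {
  for (p in space) {
    if (!p$name %in% names(params)) stop("missing hyperparameter: ", p$name)
    v <- params[[p$name]]
    if (p$kind == "categorical") {
      if (!v %in% p$categories) {
        stop("hyperparameter ", p$name, " = ", v, " not among {",
             paste(p$categories, collapse = ", "), "}")
      }
    } else {
      if (v < p$lower || v > p$upper) {
        stop("hyperparameter ", p$name, " = ", v, " outside [",
             p$lower, ", ", p$upper, "]")
      }
      if (p$kind == "integer" && v != round(v)) {
        stop("hyperparameter ", p$name, " must be an integer")
      }
    }
  }
  invisible(TRUE)
}

#' Univariate kernel density estimate
#'
#' `density(x) = (1/(n w)) sum_i K((x - x_i)/w)` with the four smoother
#' types of the source toolbox: `normal` (standard Gaussian pdf), `box`
#' (1/2 on |u| <= 1), `triangle` (max(0, 1-|u|)) and `epanechnikov`
#' (3/4 max(0, 1-u^2)).
#'
#' @param train Numeric training values (n >= 1).
#' @param kernel Kernel name.
#' @param w Bandwidth, > 0.
#' @param query Numeric query points.
#' @return Density values at `query`.
#' @export
kernel_density <- function(train,
                           kernel = c("box", "epanechnikov", "normal",
                                      "triangle"),
                           w, query) {
  kernel <- match.arg(kernel)
  if (w <= 0) stop("bandwidth w must be positive")
  if (!length(train)) stop("need at least one training value")
  K <- switch(kernel,
    normal = function(u) stats::dnorm(u),
    box = function(u) 0.5 * (abs(u) <= 1),
    triangle = function(u) pmax(0, 1 - abs(u)),
    epanechnikov = function(u) 0.75 * pmax(0, 1 - u^2)
  )
  vapply(query, function(x) sum(K((x - train) / w)) / (length(train) * w),
         numeric(1))
}

robust_sd <- function(x) {
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(s) || s <= 0) s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

#' Fit a naive Bayes classifier (normal or kernel densities)
#'
#' Class priors come from training frequencies. `distribution = "normal"`
#' models each feature per class as Gaussian (variances floored at
#' 1e-9 x overall feature variance); `"kernel"` uses [kernel_density()]
#' with per-feature bandwidth `width_mult x robust SD` (the default
#' `width_mult = NULL` applies Silverman's factor `0.9 n^(-1/5)`).
#' Predictions minimize cost-weighted risk under the spec's cost matrix.
#'
#' @param X Numeric matrix (n x p).
#' @param y Labels (HC/uHC), >= 2 samples per class.
#' @param spec A `classifier_spec` (for the cost matrix).
#' @param distribution `"normal"` or `"kernel"`.
#' @param kernel_type Kernel smoother for `"kernel"` mode.
#' @param width_mult Bandwidth multiplier (see above).
#' @return Model handle for [naive_bayes_predict()].
#' @export
naive_bayes_fit <- function(X, y, spec = classifier_spec("naive_bayes"),
                            distribution = c("normal", "kernel"),
                            kernel_type = "normal", width_mult = NULL) {
  distribution <- match.arg(distribution)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features")
  y <- factor(y, levels = c("HC", "uHC"))
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  classes <- levels(y)
  priors <- table(y) / length(y)
  if (is.null(width_mult)) width_mult <- 0.9 * nrow(X)^(-1 / 5)
  per_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    if (distribution == "normal") {
      mu <- colMeans(Xc)
      v <- apply(Xc, 2, stats::var)
      floor_v <- 1e-9 * pmax(apply(X, 2, stats::var), .Machine$double.eps)
      list(mu = mu, var = pmax(v, floor_v))
    } else {
      list(train = Xc,
           bw = apply(X, 2, robust_sd) * width_mult)
    }
  })
  names(per_class) <- classes
  structure(list(distribution = distribution, kernel_type = kernel_type,
                 per_class = per_class, priors = priors, classes = classes,
                 weights = class_weights(spec)),
            class = "naive_bayes_model")
}

#' Predict with a naive Bayes model
#'
#' @param model From [naive_bayes_fit()].
#' @param X Numeric matrix of query rows.
#' @return List with `labels` (factor HC/uHC) and `scores` (posterior
#'   probability of uHC, cost-free).
#' @export
naive_bayes_predict <- function(model, X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features")
  loglik <- sapply(model$classes, function(cl) {
    par <- model$per_class[[cl]]
    ll <- numeric(nrow(X))
    for (j in seq_len(ncol(X))) {
      if (model$distribution == "normal") {
        dens <- stats::dnorm(X[, j], par$mu[j], sqrt(par$var[j]))
      } else {
        dens <- kernel_density(par$train[, j], model$kernel_type,
                               par$bw[j], X[, j])
      }
      ll <- ll + log(pmax(dens, 1e-300))
    }
    ll + log(as.numeric(model$priors[[cl]]))
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  # normalized posteriors
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  # risk-minimizing decision: predict uHC iff w_uHC P(uHC) > w_HC P(HC)
  w <- model$weights
  lab <- ifelse(w[["uHC"]] * post[, "uHC"] > w[["HC"]] * post[, "HC"],
                "uHC", "HC")
  list(labels = factor(lab, levels = c("HC", "uHC")),
       scores = post[, "uHC"])
}

# ---- distance functions for KNN -------------------------------------------

knn_distance <- function(metric, Xq, Xt, prep) {
  n_q <- nrow(Xq); n_t <- nrow(Xt)
  if (metric %in% c("hamming", "jaccard")) {
    Bq <- sweep(Xq, 2, prep$median, ">") * 1
    Bt <- sweep(Xt, 2, prep$median, ">") * 1
    D <- matrix(0, n_q, n_t)
    for (i in seq_len(n_q)) {
      diffs <- abs(sweep(Bt, 2, Bq[i, ], "-"))
      if (metric == "hamming") {
        D[i, ] <- rowMeans(diffs)
      } else {
        either <- sweep(Bt, 2, Bq[i, ], "+") > 0
        denom <- rowSums(either)
        D[i, ] <- ifelse(denom == 0, 0, rowSums(diffs) / denom)
      }
    }
    return(D)
  }
  if (metric %in% c("correlation", "cosine", "spearman")) {
    prep_rows <- function(M) {
      if (metric == "spearman") M <- t(apply(M, 1, rank))
      if (metric != "cosine") M <- M - rowMeans(M)
      nrm <- sqrt(rowSums(M^2))
      M / ifelse(nrm > 0, nrm, 1)
    }
    D <- 1 - tcrossprod(prep_rows(Xq), prep_rows(Xt))
    D[!is.finite(D)] <- 1
    return(D)
  }
  if (metric == "mahalanobis") {
    S_inv <- prep$cov_inv
    D <- matrix(0, n_q, n_t)
    for (i in seq_len(n_q)) {
      del <- sweep(Xt, 2, Xq[i, ], "-")
      D[i, ] <- sqrt(pmax(rowSums((del %*% S_inv) * del), 0))
    }
    return(D)
  }
  if (metric == "seuclidean") {
    Xq <- sweep(Xq, 2, prep$sd, "/")
    Xt <- sweep(Xt, 2, prep$sd, "/")
    metric <- "euclidean"
  }
  p <- switch(metric, cityblock = 1, euclidean = 2, minkowski = 3,
              chebychev = Inf)
  D <- matrix(0, n_q, n_t)
  for (i in seq_len(n_q)) {
    del <- abs(sweep(Xt, 2, Xq[i, ], "-"))
    D[i, ] <- if (is.infinite(p)) apply(del, 1, max) else
      rowSums(del^p)^(1 / p)
  }
  D
}

knn_fit <- function(X, y, spec, n_neighbors, distance) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("HC", "uHC"))
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  prep <- list(sd = sds, median = apply(X, 2, stats::median))
  if (distance == "mahalanobis") {
    S <- stats::cov(X) + diag(1e-6 * mean(diag(stats::cov(X))), ncol(X))
    prep$cov_inv <- solve(S)
  }
  structure(list(X = X, y = y, k = n_neighbors, distance = distance,
                 prep = prep, weights = class_weights(spec)),
            class = "knn_model")
}

knn_predict <- function(model, X) {
  D <- knn_distance(model$distance, as.matrix(X), model$X, model$prep)
  w <- model$weights
  lab <- character(nrow(D))
  score <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    nn <- order(D[i, ])[seq_len(min(model$k, ncol(D)))]
    votes <- table(model$y[nn])
    frac_u <- votes[["uHC"]] / sum(votes)
    score[i] <- frac_u
    lab[i] <- if (w[["uHC"]] * frac_u > w[["HC"]] * (1 - frac_u))
      "uHC" else "HC"
  }
  list(labels = factor(lab, levels = c("HC", "uHC")), scores = score)
}

svm_fit <- function(X, y, spec, kernel, kernel_scale, box_constraint) {
  y <- factor(y, levels = c("HC", "uHC"))
  kern <- switch(kernel, gaussian = "radial", rbf = "radial",
                 linear = "linear", polynomial = "polynomial")
  w <- class_weights(spec)
  fit <- e1071::svm(
    x = as.matrix(X), y = y, scale = TRUE, kernel = kern,
    gamma = if (kern == "radial") 1 / kernel_scale^2 else
      1 / (ncol(X) * kernel_scale^2),
    degree = 3, cost = box_constraint,
    class.weights = c(HC = w[["HC"]], uHC = w[["uHC"]])
  )
  structure(list(fit = fit), class = "svm_model")
}

svm_predict <- function(model, X) {
  pred <- stats::predict(model$fit, as.matrix(X), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient the signed decision value so larger = more uHC-like
  score <- if (grepl("^uHC", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  list(labels = factor(as.character(pred), levels = c("HC", "uHC")),
       scores = as.numeric(score))
}

logistic_fit <- function(X, y, spec, lambda, score_transform = "none") {
  y <- factor(y, levels = c("HC", "uHC"))
  w <- class_weights(spec)
  obs_w <- ifelse(y == "uHC", w[["uHC"]], w[["HC"]])
  X <- as.matrix(X)
  if (ncol(X) == 1) X <- cbind(X, `.const` = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(as.matrix(X), y, family = "binomial",
                        alpha = 1, lambda = lambda, weights = obs_w,
                        standardize = TRUE)
  structure(list(fit = fit, lambda = lambda,
                 score_transform = score_transform),
            class = "logistic_model")
}

logistic_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) == 1) X <- cbind(X, `.const` = 0)
  p <- as.numeric(stats::predict(model$fit, X, type = "response"))
  # monotone transforms cannot change the argmax label; applied to scores
  score <- switch(model$score_transform,
    none = p,
    logit = stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)),
    invlogit = stats::plogis(p),
    doublelogit = stats::plogis(2 * stats::qlogis(
      pmin(pmax(p, 1e-12), 1 - 1e-12))))
  list(labels = factor(ifelse(p >= 0.5, "uHC", "HC"),
                       levels = c("HC", "uHC")),
       scores = score)
}

rusboost_fit <- function(X, y, n_cycles, learning_rate, max_splits,
                         seed = 1L) {
  set.seed(as.integer(seed))
  y <- factor(y, levels = c("HC", "uHC"))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  n <- nrow(df)
  ysign <- ifelse(y == "uHC", 1, -1)
  minority <- names(which.min(table(y)))
  D <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(
    maxdepth = min(30, ceiling(log2(max_splits + 1))),
    cp = 0, minsplit = 2, minbucket = 1, xval = 0,
    maxcompete = 0, maxsurrogate = 0
  )
  trees <- list(); alphas <- numeric(0)
  for (t in seq_len(n_cycles)) {
    min_idx <- which(y == minority)
    maj_idx <- which(y != minority)
    take <- min(length(min_idx), length(maj_idx))
    samp_maj <- sample(maj_idx, take, prob = D[maj_idx])
    idx <- c(min_idx, samp_maj)
    dat <- cbind(df[idx, , drop = FALSE], .y = y[idx])
    tree <- rpart::rpart(.y ~ ., data = dat, weights = D[idx] / sum(D[idx]),
                         method = "class", control = ctrl)
    ph <- stats::predict(tree, df, type = "class")
    hsign <- ifelse(ph == "uHC", 1, -1)
    wrong <- hsign != ysign
    eps <- sum(D[wrong])
    if (eps >= 0.5) next                   # reject and resample next round
    eps <- max(eps, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - eps) / eps)
    trees[[length(trees) + 1]] <- tree
    alphas <- c(alphas, alpha)
    D <- D * exp(-alpha * hsign * ysign)
    D <- D / sum(D)
    if (eps <= 1e-10) break
  }
  if (!length(trees)) {                    # degenerate: fall back to prior
    trees <- list(NULL); alphas <- 0
  }
  structure(list(trees = trees, alphas = alphas,
                 prior_sign = ifelse(
                   sum(y == "uHC") >= sum(y == "HC"), 1, -1)),
            class = "rusboost_model")
}

rusboost_predict <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  agg <- numeric(nrow(df))
  for (t in seq_along(model$trees)) {
    tree <- model$trees[[t]]
    h <- if (is.null(tree)) rep(model$prior_sign, nrow(df)) else
      ifelse(stats::predict(tree, df, type = "class") == "uHC", 1, -1)
    agg <- agg + model$alphas[t] * h
  }
  denom <- sum(abs(model$alphas))
  score <- if (denom > 0) agg / denom else rep(0, nrow(df))
  list(labels = factor(ifelse(score > 0, "uHC", "HC"),
                       levels = c("HC", "uHC")),
       scores = score)
}

#' Fit any supported classifier under a uniform contract
#'
#' Validates the hyperparameters against the spec's space, then dispatches
#' to the family backend. All fits are deterministic given `seed`.
#'
#' @param spec A `classifier_spec`.
#' @param hyperparams Named list matching the spec's space.
#' @param X Numeric feature matrix.
#' @param y Labels (HC/uHC).
#' @param seed Integer seed for stochastic learners (RUSBoost).
#' @return Fitted-model handle with class `fitted_classifier`.
#' @export
make_classifier <- function(spec, hyperparams, X, y, seed = 1L) {
  validate_hyperparams(spec$space, hyperparams)
  h <- hyperparams
  model <- switch(spec$family,
    naive_bayes = naive_bayes_fit(X, y, spec,
                                  distribution = h$distribution,
                                  kernel_type = h$kernel_type,
                                  width_mult = h$width_mult),
    knn = knn_fit(X, y, spec, h$n_neighbors, h$distance),
    svm = svm_fit(X, y, spec, h$kernel, h$kernel_scale, h$box_constraint),
    logistic = logistic_fit(X, y, spec, h$lambda,
                            h$score_transform %||% "none"),
    rusboost = rusboost_fit(X, y, h$n_cycles, h$learning_rate,
                            h$max_splits, seed = seed),
    majority = {
      tab <- table(factor(y, levels = c("HC", "uHC")))
      structure(list(label = names(tab)[which.max(tab)],
                     prior_u = tab[["uHC"]] / sum(tab)),
                class = "majority_model")
    }
  )
  structure(list(family = spec$family, model = model,
                 hyperparams = hyperparams),
            class = "fitted_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict with a fitted classifier
#'
#' @param fitted A `fitted_classifier` from [make_classifier()].
#' @param X Feature matrix.
#' @return List with `labels` (factor HC/uHC) and numeric `scores`
#'   (larger = more uHC-like).
#' @export
predict_classifier <- function(fitted, X) {
  switch(fitted$family,
    naive_bayes = naive_bayes_predict(fitted$model, X),
    knn = knn_predict(fitted$model, X),
    svm = svm_predict(fitted$model, X),
    logistic = logistic_predict(fitted$model, X),
    rusboost = rusboost_predict(fitted$model, X),
    majority = list(
      labels = factor(rep(fitted$model$label, nrow(as.matrix(X))),
                      levels = c("HC", "uHC")),
      scores = rep(fitted$model$prior_u, nrow(as.matrix(X))))
  )
}
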