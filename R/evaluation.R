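#' Evaluation configuration
#'
#' Nested-CV / Monte Carlo settings. Paper-scale values are `k_outer = 10`,
#' `mc_reps = 20`, `opt_budget = 200`; the desk-scale preset
#' (`k_outer = 5`, `mc_reps = 5`, `opt_budget = 30`) is what the test suite
#' and worked examples use.
#'
#' @param k_outer Outer folds (>= 2); the inner loop uses `k_outer - 1`
#'   folds.
#' @param mc_reps Monte Carlo replications.
#' @param opt_budget Bayesian-optimization iterations per outer fold.
#' @param mode `"imbalanced"` (delta cost compensation) or `"balanced"`
#'   (fresh random undersample per replication).
#' @param master_seed Integer master seed; all partition/undersample/
#'   optimizer seeds derive from it.
#' @param pooling `"pooled"` (one confusion per replication from pooled
#'   holdout predictions; primary) or `"fold_average"`.
#' @param optimizer `"gp"` (Gaussian-process expected improvement) or
#'   `"random"` (pure random search behind the same contract).
#' @return Object of class `evaluation_config`.
#' @export
evaluation_config <- function(k_outer = 5, mc_reps = 5, opt_budget = 30,
                              mode = c("imbalanced", "balanced"),
                              master_seed = 1L,
                              pooling = c("pooled", "fold_average"),
                              optimizer = c("gp", "random")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  optimizer <- match.arg(optimizer)
  if (k_outer < 2) stop("k_outer must be >= 2")
  structure(list(k_outer = as.integer(k_outer),
                 mc_reps = as.integer(mc_reps),
                 opt_budget = as.integer(opt_budget), mode = mode,
                 master_seed = as.integer(master_seed), pooling = pooling,
                 optimizer = optimizer),
            class = "evaluation_config")
}

#' Deterministic seed derivation
#'
#' Mixes a master seed with stream indices into a 31-bit seed so every
#' replication/combination gets an independent, reproducible stream.
#'
#' @param master_seed Integer.
#' @param ... Further integer indices.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  idx <- c(master_seed, ...)
  h <- 0
  for (v in idx) h <- (h * 69069 + as.numeric(v) * 2654435761) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Stratified k-fold assignment
#'
#' Per-class counts across folds differ by at most one, and so do total
#' fold sizes (extras always go to the currently smallest folds).
#'
#' @param labels Class labels.
#' @param k Number of folds; every class must have >= k samples? No --
#'   every class must have >= 1 sample per *used* fold, so `k` must not
#'   exceed the smallest class size.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per observation.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  set.seed(as.integer(seed))
  labels <- factor(labels)
  if (min(table(labels)) < k) {
    stop("smallest class (", min(table(labels)),
         ") has fewer samples than k = ", k)
  }
  fold <- integer(length(labels))
  totals <- numeric(k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    q <- n_c %/% k
    r <- n_c %% k
    per_fold <- rep(q, k)
    if (r > 0) {
      recipients <- order(totals, stats::runif(k))[seq_len(r)]
      per_fold[recipients] <- per_fold[recipients] + 1
    }
    assignment <- rep(seq_len(k), times = per_fold)
    fold[idx] <- assignment
    totals <- totals + per_fold
  }
  fold
}

#' Randomly undersample the majority group
#'
#' @param table A `feature_table` with both groups.
#' @param seed Integer seed.
#' @return The table with the majority group subsampled (without
#'   replacement) to the minority size; minority rows untouched.
#' @export
undersample_majority <- function(table, seed = 1L) {
  set.seed(as.integer(seed))
  counts <- table(table$group)
  if (any(counts == 0)) stop("both groups must be present")
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  if (minority == majority) return(table)
  keep_min <- which(table$group == minority)
  maj_idx <- which(table$group == majority)
  keep_maj <- sort(sample(maj_idx, counts[[minority]]))
  out <- table[sort(c(keep_min, keep_maj)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority/minority cardinality ratio
#'
#' @param labels Group labels (both groups non-empty). Computed on the
#'   training fold inside the pipeline, never on the full dataset.
#' @return `n_majority / n_minority` (>= 1).
#' @export
imbalance_delta <- function(labels) {
  counts <- table(factor(labels))
  counts <- counts[counts > 0]
  if (length(counts) < 2) stop("both groups must be non-empty")
  as.numeric(max(counts)) / as.numeric(min(counts))
}

# ---- Bayesian optimization -------------------------------------------------

encode_params <- function(space, params) {
  out <- numeric(0)
  for (p in space) {
    v <- params[[p$name]]
    if (p$kind == "categorical") {
      onehot <- as.numeric(p$categories == v)
      out <- c(out, onehot / sqrt(2))
    } else {
      lo <- p$lower; hi <- p$upper
      if (isTRUE(p$log_scale)) {
        out <- c(out, (log(v) - log(lo)) / (log(hi) - log(lo)))
      } else {
        out <- c(out, (v - lo) / (hi - lo))
      }
    }
  }
  out
}

sample_params <- function(space) {
  out <- list()
  for (p in space) {
    if (p$kind == "categorical") {
      out[[p$name]] <- sample(p$categories, 1)
    } else if (isTRUE(p$log_scale)) {
      v <- exp(stats::runif(1, log(p$lower), log(p$upper)))
      out[[p$name]] <- if (p$kind == "integer") as.integer(round(v)) else v
    } else {
      v <- stats::runif(1, p$lower, p$upper)
      out[[p$name]] <- if (p$kind == "integer") as.integer(round(v)) else v
    }
  }
  out
}

gp_fit <- function(X, y) {
  n <- nrow(X)
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  d2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.2, 0.5, 1.0)) {
    for (sn2 in c(1e-4, 1e-2, 1e-1)) {
      K <- exp(-0.5 * d2 / ell^2) + diag(sn2, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      logml <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) -
        0.5 * n * log(2 * pi)
      if (is.null(best) || logml > best$logml) {
        best <- list(logml = logml, ell = ell, sn2 = sn2, chol = ch,
                     alpha = alpha, X = X, mu = mu, sdy = sdy)
      }
    }
  }
  best
}

gp_predict <- function(gp, Xq) {
  d2 <- outer(rowSums(Xq^2), rowSums(gp$X^2), "+") -
    2 * Xq %*% t(gp$X)
  Ks <- exp(-0.5 * pmax(d2, 0) / gp$ell^2)
  mean_s <- Ks %*% gp$alpha
  v <- forwardsolve(t(gp$chol), t(Ks))
  var_s <- pmax(1 + gp$sn2 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mean_s) * gp$sdy + gp$mu,
       sd = sqrt(var_s) * gp$sdy)
}

#' Sequential model-based hyperparameter optimization
#'
#' Minimizes a (possibly noisy) objective over a mixed hyperparameter
#' space: an initial random design of `max(10, budget/5)` points, then a
#' Gaussian-process surrogate (squared-exponential kernel over unit-scaled,
#' log-transformed reals and one-hot categoricals) with expected-improvement
#' acquisition over random candidate sets. `method = "random"` is a pure
#' random search behind the same contract. Returns the argmin of the
#' observed objective values.
#'
#' @param objective Function taking a named hyperparameter list, returning
#'   a scalar (lower = better). Non-finite returns at more than half the
#'   evaluations abort the search.
#' @param space Parameter definitions (see [default_space()]).
#' @param budget Total number of objective evaluations.
#' @param seed Integer seed.
#' @param method `"gp"` or `"random"`.
#' @param n_candidates Candidate points scored per acquisition step.
#' @return List with `best_params`, `best_value`, and the evaluation
#'   `trace` (data frame of values).
#' @export
bayes_opt <- function(objective, space, budget, seed = 1L,
                      method = c("gp", "random"), n_candidates = 256) {
  method <- match.arg(method)
  set.seed(as.integer(seed))
  if (!length(space)) {
    val <- objective(list())
    return(list(best_params = list(), best_value = val,
                trace = data.frame(iteration = 1, value = val)))
  }
  n_init <- min(budget, max(10, floor(budget / 5)))
  evals <- list(); values <- numeric(0); n_bad <- 0
  eval_point <- function(params) {
    force(params)  # draw the candidate before snapshotting the RNG
    # the objective may reseed the global RNG (e.g. internal CV splits);
    # shield the optimizer's own stream from it
    state <- get(".Random.seed", envir = globalenv())
    v <- tryCatch(objective(params), error = function(e) NA_real_)
    assign(".Random.seed", state, envir = globalenv())
    if (!is.finite(v)) { n_bad <<- n_bad + 1; v <- NA_real_ }
    evals[[length(evals) + 1]] <<- params
    values <<- c(values, v)
    if (n_bad > 0.5 * length(values) && length(values) >= 4) {
      stop("objective returned non-finite values at > 50% of evaluations")
    }
  }
  for (i in seq_len(n_init)) eval_point(sample_params(space))
  while (length(values) < budget) {
    if (method == "random" || all(is.na(values))) {
      eval_point(sample_params(space))
      next
    }
    ok <- which(is.finite(values))
    y <- values
    y[!is.finite(y)] <- max(values[ok])      # penalize failed points
    d_enc <- length(encode_params(space, evals[[1]]))
    Xobs <- matrix(vapply(evals, function(p) encode_params(space, p),
                          numeric(d_enc)),
                   ncol = d_enc, byrow = TRUE)
    gp <- gp_fit(Xobs, y)
    if (is.null(gp)) { eval_point(sample_params(space)); next }
    cands <- replicate(n_candidates, sample_params(space),
                       simplify = FALSE)
    Xc <- matrix(vapply(cands, function(p) encode_params(space, p),
                        numeric(d_enc)),
                 ncol = d_enc, byrow = TRUE)
    pr <- gp_predict(gp, Xc)
    fmin <- min(y)
    z <- (fmin - pr$mean) / pr$sd
    ei <- pr$sd * (z * stats::pnorm(z) + stats::dnorm(z))
    eval_point(cands[[which.max(ei)]])
  }
  best <- which.min(values)
  list(best_params = evals[[best]], best_value = values[best],
       trace = data.frame(iteration = seq_along(values), value = values))
}

# ---- nested cross-validation ----------------------------------------------

# cost-weighted misclassification rate of predictions
weighted_error <- function(truth, pred, w) {
  wt <- ifelse(truth == "uHC", w[["uHC"]], w[["HC"]])
  sum(wt * (truth != pred)) / sum(wt)
}

inner_cv <- function(X, y, spec, params, k_inner, seed,
                     return_confusion = FALSE) {
  folds <- stratified_kfold(y, k_inner, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = c("HC", "uHC"))
  for (f in seq_len(k_inner)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) stop("inner fold lost a class")
    fit <- make_classifier(spec, params, X[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, f))
    pred[!tr] <- predict_classifier(fit, X[!tr, , drop = FALSE])$labels
  }
  err <- weighted_error(y, pred, class_weights(spec))
  if (return_confusion) list(error = err, confusion = confusion(y, pred))
  else err
}

#' Nested cross-validation evaluation of one combination
#'
#' Outer stratified K-fold loop: on each 90% training part, hyperparameters
#' are tuned by [bayes_opt()] minimizing the cost-weighted
#' misclassification of an internal (K-1)-fold CV; the winner is refit on
#' the full training part and predicts the holdout. Holdout predictions are
#' pooled into one confusion table per replication (the nested estimate);
#' the inner-CV confusion of each fold's selected configuration is pooled
#' into the optimism-prone direct estimate. In imbalanced mode the delta
#' cost (majority/minority ratio of the outer-training fold) is applied to
#' every classifier except RUSBoost, whose undersampling already
#' compensates.
#'
#' @param table A `feature_table` (uncorrected or harmonized).
#' @param features Character vector of feature columns to use (non-empty).
#' @param spec A `classifier_spec`.
#' @param config An [evaluation_config()].
#' @param seed Integer seed for this replication.
#' @return Object of class `replication_result`: pooled nested confusion +
#'   metrics (+ AROC from pooled holdout scores), direct confusion +
#'   metrics, per-fold chosen hyperparameters, failed-fold count.
#' @export
nested_cv_evaluate <- function(table, features, spec, config, seed = 1L) {
  if (!length(features)) stop("feature subset is empty")
  stopifnot(all(features %in% names(table)))
  y <- factor(table$group, levels = c("HC", "uHC"))
  X <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  k <- config$k_outer
  folds <- stratified_kfold(y, k, derive_seed(seed, 11L))
  holdout_pred <- factor(rep(NA_character_, length(y)),
                         levels = c("HC", "uHC"))
  holdout_score <- numeric(length(y))
  chosen <- vector("list", k)
  direct_tp <- direct_fn <- direct_fp <- direct_tn <- 0
  fold_metrics <- vector("list", k)
  failed <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    spec_f <- spec
    if (config$mode == "imbalanced" && spec$family != "rusboost") {
      spec_f <- apply_cost_matrix(spec, imbalance_delta(y[tr]))
    }
    res <- tryCatch({
      opt <- bayes_opt(
        function(params) inner_cv(X[tr, , drop = FALSE], y[tr], spec_f,
                                  params, k - 1, derive_seed(seed, 20L, f)),
        spec_f$space, config$opt_budget,
        seed = derive_seed(seed, 30L, f), method = config$optimizer
      )
      inner <- inner_cv(X[tr, , drop = FALSE], y[tr], spec_f,
                        opt$best_params, k - 1, derive_seed(seed, 20L, f),
                        return_confusion = TRUE)
      fit <- make_classifier(spec_f, opt$best_params,
                             X[tr, , drop = FALSE], y[tr],
                             seed = derive_seed(seed, 40L, f))
      pr <- predict_classifier(fit, X[!tr, , drop = FALSE])
      list(opt = opt, inner = inner, pr = pr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning("fold ", f, " failed: ", conditionMessage(res))
      next
    }
    holdout_pred[!tr] <- res$pr$labels
    holdout_score[!tr] <- res$pr$scores
    chosen[[f]] <- res$opt$best_params
    ic <- res$inner$confusion
    direct_tp <- direct_tp + ic$tp; direct_fn <- direct_fn + ic$fn
    direct_fp <- direct_fp + ic$fp; direct_tn <- direct_tn + ic$tn
    fold_metrics[[f]] <- compute_metrics(confusion(y[!tr], res$pr$labels))
  }
  ok <- !is.na(holdout_pred)
  ct <- confusion(y[ok], holdout_pred[ok])
  metrics <- if (config$pooling == "pooled") compute_metrics(ct) else {
    ms <- Filter(Negate(is.null), fold_metrics)
    nm <- setdiff(names(ms[[1]]), "degenerate")
    out <- lapply(nm, function(m) mean(vapply(ms, `[[`, numeric(1), m)))
    names(out) <- nm
    out$degenerate <- any(vapply(ms, `[[`, logical(1), "degenerate"))
    out
  }
  metrics$aroc <- tryCatch(aroc(holdout_score[ok], y[ok]),
                           error = function(e) NA_real_)
  direct_ct <- confusion_from_counts(direct_tp, direct_fn, direct_fp,
                                     direct_tn)
  structure(
    list(confusion = ct, metrics = metrics,
         direct_confusion = direct_ct,
         direct_metrics = compute_metrics(direct_ct),
         chosen_hyperparams = chosen, folds = folds,
         failed_folds = failed, seed = seed),
    class = "replication_result"
  )
}

#' Monte Carlo evaluation over the full factorial design
#'
#' Runs [nested_cv_evaluate()] for every (dataset x harmonization x subset
#' x classifier) combination, `mc_reps` times, with per-replication seeds
#' derived from the master seed. In balanced mode a fresh undersample of
#' each dataset precedes every replication.
#'
#' @param datasets Named list of uncorrected `feature_table`s.
#' @param harmonizations Character subset of
#'   `c("uncorrected", "residual", "zscore")`.
#' @param subsets Named list of feature-name vectors (e.g. A-D).
#' @param classifiers Named list of `classifier_spec`s.
#' @param config An [evaluation_config()].
#' @return Long-format results data frame (one row per replication x
#'   combination x metric x estimate type), plus attribute `failures`.
#' @export
monte_carlo_run <- function(datasets, harmonizations, subsets, classifiers,
                            config) {
  stopifnot(length(datasets) > 0, length(subsets) > 0,
            length(classifiers) > 0)
  harmonizations <- match.arg(harmonizations,
                              c("uncorrected", "residual", "zscore"),
                              several.ok = TRUE)
  rows <- list()
  failures <- list()
  metric_names <- c("acc", "f1", "mcc", "mcc_prime", "tpr", "tnr",
                    "ppv", "npv", "aroc")
  combo <- 0L
  for (ds in names(datasets)) {
    models_by_h <- list()
    for (h in harmonizations) {
      models_by_h[[h]] <- if (h == "uncorrected") NULL else
        fit_all_reference_models(datasets[[ds]])
    }
    for (h in harmonizations) {
      full_tab <- if (h == "uncorrected") datasets[[ds]] else
        harmonize(datasets[[ds]], models_by_h[[h]], method = h)
      for (sb in names(subsets)) {
        if (!length(subsets[[sb]])) next
        for (cl in names(classifiers)) {
          combo <- combo + 1L
          for (r in seq_len(config$mc_reps)) {
            seed_r <- derive_seed(config$master_seed, r, combo)
            tab_r <- if (config$mode == "balanced")
              undersample_majority(full_tab, derive_seed(seed_r, 7L))
            else full_tab
            rep_res <- tryCatch(
              nested_cv_evaluate(tab_r, subsets[[sb]], classifiers[[cl]],
                                 config, seed = seed_r),
              error = function(e) e
            )
            if (inherits(rep_res, "error")) {
              failures[[length(failures) + 1]] <-
                list(dataset = ds, harmonization = h, subset = sb,
                     classifier = cl, replication = r,
                     message = conditionMessage(rep_res))
              next
            }
            for (est in c("nested", "direct")) {
              mm <- if (est == "nested") rep_res$metrics else
                rep_res$direct_metrics
              for (m in metric_names) {
                if (is.null(mm[[m]])) next
                rows[[length(rows) + 1]] <- data.frame(
                  replication = r, dataset = ds, harmonization = h,
                  subset = sb, classifier = cl, mode = config$mode,
                  estimate_type = est, metric = m,
                  value = as.numeric(mm[[m]]),
                  stringsAsFactors = FALSE
                )
              }
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}
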