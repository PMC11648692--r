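#' Univariate feature scores
#'
#' One-way ANOVA, Kruskal-Wallis and chi-square scores for a single feature
#' against the two-group label; each returns the test statistic, the
#' p-value, and the score `-log(p)` (natural log by default, base-10 via
#' `log_base = 10`).
#'
#' @param values Numeric feature values.
#' @param labels Two-level group labels.
#' @param log_base Base for the `-log(p)` score; `exp(1)` (default) or 10.
#' @return List with elements `statistic`, `p`, `score`.
#' @name univariate_scores
NULL

score_from_p <- function(p, log_base = exp(1)) {
  if (!is.finite(p) || p >= 1) return(0)
  -log(p, base = log_base)
}

#' @rdname univariate_scores
#' @export
anova_score <- function(values, labels, log_base = exp(1)) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2 || min(table(labels)) < 2) {
    stop("anova_score needs two groups with >= 2 values each")
  }
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p = 1, score = 0))
  }
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  p <- fit$p.value
  list(statistic = unname(fit$statistic), p = p,
       score = score_from_p(p, log_base))
}

#' @rdname univariate_scores
#' @export
kruskal_score <- function(values, labels, log_base = exp(1)) {
  labels <- factor(labels)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p = 1, score = 0))
  }
  kt <- stats::kruskal.test(values, labels)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       score = score_from_p(kt$p.value, log_base))
}

#' ANCOVA p-value for the group term
#'
#' Linear model `value ~ group + age + sex + education + icv`; reports the
#' partial (type-III-style) F-test p-value for the group term, with sex
#' coded as a binary indicator.
#'
#' @param values Numeric feature values.
#' @param labels Two-level group labels.
#' @param covariates Data frame with columns `age`, `sex`, `education`,
#'   `icv` (any subset accepted).
#' @return List with `statistic` (partial F), `p`.
#' @export
ancova_score <- function(values, labels, covariates) {
  labels <- factor(labels)
  cov_df <- as.data.frame(covariates)
  if (anyNA(cov_df)) stop("covariates must be complete")
  if ("sex" %in% names(cov_df)) {
    cov_df$sex <- as.numeric(factor(cov_df$sex)) - 1
  }
  X <- as.matrix(cov_df)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    cors <- suppressWarnings(stats::cor(X))
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear covariates: ",
         paste(colnames(X)[worst], collapse = " and "))
  }
  dat <- data.frame(.y = values, .g = labels, cov_df)
  full <- stats::lm(.y ~ ., data = dat)
  reduced <- stats::lm(.y ~ . - .g, data = dat)
  an <- stats::anova(reduced, full)
  list(statistic = an$F[2], p = an$`Pr(>F)`[2])
}

#' @rdname univariate_scores
#' @param n_bins Number of equal-frequency bins used to discretize the
#'   feature before the chi-square independence test (default 10).
#' @export
chi2_score <- function(values, labels, n_bins = 10, log_base = exp(1)) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  labels <- factor(labels)
  if (length(unique(values)) <= n_bins) {
    # few distinct values: treat them as categories directly
    bins <- factor(values)
    if (nlevels(bins) < 2) return(list(statistic = 0, p = 1, score = 0))
  } else {
    br <- unique(stats::quantile(values,
                                 probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(list(statistic = 0, p = 1, score = 0))
    bins <- cut(values, breaks = br, include.lowest = TRUE)
  }
  tab <- table(bins, labels)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]  # empty bins dropped, dof adjusts
  if (nrow(tab) < 2) return(list(statistic = 0, p = 1, score = 0))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       score = score_from_p(ct$p.value, log_base))
}

#' ReliefF feature weights
#'
#' ReliefF (Kononenko variant) with every observation used as an anchor:
#' for each anchor, the k nearest same-class neighbours (hits) and k nearest
#' other-class neighbours (misses; prior-weighted) are found by Manhattan
#' distance on range-scaled features, and each feature's weight accumulates
#' `- mean hit diff + weighted mean miss diff`, averaged over anchors.
#' `diff(f, a, b) = |a_f - b_f| / (max_f - min_f)`; constant features have
#' diff 0 and therefore weight exactly 0.
#'
#' @param X Numeric matrix (observations x features), no missing values.
#' @param y Class labels (two or more classes), >= k+1 samples per class.
#' @param k_neighbors Number of hits/misses per anchor (default 10, capped
#'   at class size - 1).
#' @return Named numeric vector of feature weights.
#' @export
relieff_score <- function(X, y, k_neighbors = 10) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("ReliefF requires complete finite features")
  y <- factor(y)
  n <- nrow(X)
  cls_counts <- table(y)
  if (min(cls_counts) < 2) stop("each class needs >= 2 samples")
  rng <- apply(X, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, 1)           # constant features: diff := 0
  Xs <- sweep(X, 2, scale, "/")
  Xs[, rng == 0] <- 0
  priors <- cls_counts / n
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- colSums(abs(t(Xs) - Xs[i, ]))       # Manhattan distances to anchor
    d[i] <- Inf
    ci <- y[i]
    hits <- which(y == ci)
    hits <- hits[order(d[hits])][seq_len(min(k_neighbors, length(hits) - 1))]
    hit_term <- colMeans(abs(Xs[hits, , drop = FALSE] -
                             rep(Xs[i, ], each = length(hits))))
    miss_term <- numeric(ncol(X))
    for (cj in levels(y)[levels(y) != ci]) {
      mj <- which(y == cj)
      mj <- mj[order(d[mj])][seq_len(min(k_neighbors, length(mj)))]
      wj <- priors[[cj]] / (1 - priors[[ci]])
      miss_term <- miss_term +
        wj * colMeans(abs(Xs[mj, , drop = FALSE] -
                          rep(Xs[i, ], each = length(mj))))
    }
    W <- W - hit_term / n + miss_term / n
  }
  names(W) <- colnames(X)
  W
}

#' Convert raw scores to percentages
#'
#' `percentage = 100 * score / sum(positive scores)`; non-positive scores
#' map to 0. With no positive score at all, every percentage is 0 and a
#' warning is raised.
#'
#' @param scores Named numeric scores for one method.
#' @return Percentages (same names), summing to 100 over the positive
#'   scores when any exist.
#' @export
to_percentages <- function(scores) {
  pos <- scores > 0
  total <- sum(scores[pos])
  if (total <= 0) {
    warning("no positive scores; all percentages set to 0")
    return(stats::setNames(numeric(length(scores)), names(scores)))
  }
  out <- ifelse(pos, 100 * scores / total, 0)
  stats::setNames(out, names(scores))
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p_values)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Score every feature by every ranking criterion
#'
#' Runs chi-square, ANOVA, Kruskal-Wallis and ReliefF over the volume
#' features of `table` (classifier-app-style scores), plus ANCOVA on the
#' uncorrected values of `uncorrected` with age/sex/education/ICV
#' covariates (statistical-analysis-style significance). `-log(p)` scores
#' are converted to percentages per method; for ReliefF the percentages are
#' computed over positive-weight features only.
#'
#' @param table A `feature_table` (typically harmonized) used for the four
#'   ranking criteria.
#' @param uncorrected The uncorrected `feature_table` used for ANCOVA; must
#'   align row-wise with `table`. Defaults to `table`.
#' @param k_neighbors ReliefF neighbourhood size.
#' @param n_bins chi-square discretization bins.
#' @return Object of class `ranking_scores`: data frame with one row per
#'   feature and columns `<method>_score`, `<method>_pct`, `<method>_p`
#'   where applicable, plus `average_pct` (mean of the four method
#'   percentages, non-positive ReliefF contributing 0).
#' @export
rank_features <- function(table, uncorrected = table, k_neighbors = 10,
                          n_bins = 10) {
  feats <- volume_cols(table)
  labels <- table$group
  X <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  covs <- as.data.frame(uncorrected)[, c("age", "sex", "education", "icv")]

  chi2 <- t(vapply(feats, function(f) {
    s <- chi2_score(X[, f], labels, n_bins = n_bins)
    c(s$statistic, s$p, s$score)
  }, numeric(3)))
  anov <- t(vapply(feats, function(f) {
    s <- anova_score(X[, f], labels)
    c(s$statistic, s$p, s$score)
  }, numeric(3)))
  krus <- t(vapply(feats, function(f) {
    s <- kruskal_score(X[, f], labels)
    c(s$statistic, s$p, s$score)
  }, numeric(3)))
  anc <- t(vapply(feats, function(f) {
    s <- ancova_score(as.data.frame(uncorrected)[[f]],
                      uncorrected$group, covs)
    c(s$statistic, s$p)
  }, numeric(2)))
  relief <- relieff_score(X, labels, k_neighbors = k_neighbors)

  out <- data.frame(
    feature = feats,
    chi2_score = chi2[, 3], chi2_p = chi2[, 2],
    anova_score = anov[, 3], anova_p = anov[, 2],
    kruskal_score = krus[, 3], kruskal_p = krus[, 2],
    ancova_p = anc[, 2],
    relieff_score = as.numeric(relief),
    stringsAsFactors = FALSE
  )
  out$chi2_pct <- to_percentages(stats::setNames(out$chi2_score, feats))
  out$anova_pct <- to_percentages(stats::setNames(out$anova_score, feats))
  out$kruskal_pct <- to_percentages(stats::setNames(out$kruskal_score, feats))
  out$relieff_pct <- to_percentages(stats::setNames(out$relieff_score, feats))
  out$average_pct <- average_score_pct(out$chi2_pct, out$anova_pct,
                                       out$kruskal_pct, out$relieff_pct)
  class(out) <- c("ranking_scores", "data.frame")
  out
}

#' Average score percentage across the four ranking methods
#'
#' Mean of the chi-square, ANOVA, Kruskal-Wallis and ReliefF percentages;
#' a feature whose ReliefF weight was non-positive has ReliefF percentage 0
#' (not a missing value), so it still divides by four.
#'
#' @param chi2_pct,anova_pct,kruskal_pct,relieff_pct Percentage vectors.
#' @return Numeric vector of per-feature averages.
#' @export
average_score_pct <- function(chi2_pct, anova_pct, kruskal_pct,
                              relieff_pct) {
  (chi2_pct + anova_pct + kruskal_pct + relieff_pct) / 4
}

#' Build the four feature subsets A-D
#'
#' (A) features whose mean-of-four-percentages is at or above the median of
#' those means (ties included); (B) positive ReliefF weight; (C) features
#' selected by every contributing criterion (per-method percentage at or
#' above that method's median, ReliefF positivity, the average-score rule,
#' and the significance rule); (D) Bonferroni-adjusted p <= `alpha` in
#' ANOVA, ANCOVA and Kruskal-Wallis simultaneously.
#'
#' @param scores A `ranking_scores` data frame from [rank_features()].
#' @param alpha Significance level for subset D after Bonferroni adjustment
#'   over the number of features (default 0.05).
#' @return List with `subset_a` .. `subset_d` (character vectors) and
#'   `provenance`, a per-feature tally of which criteria selected it.
#' @export
build_subsets <- function(scores, alpha = 0.05) {
  feats <- scores$feature
  m <- length(feats)
  sel <- list(
    chi2 = scores$chi2_pct >= stats::median(scores$chi2_pct),
    relieff = scores$relieff_score > 0,
    anova = scores$anova_pct >= stats::median(scores$anova_pct),
    kruskal = scores$kruskal_pct >= stats::median(scores$kruskal_pct),
    average = scores$average_pct >= stats::median(scores$average_pct),
    significance = bonferroni_adjust(scores$anova_p, m) <= alpha &
      bonferroni_adjust(scores$ancova_p, m) <= alpha &
      bonferroni_adjust(scores$kruskal_p, m) <= alpha
  )
  provenance <- data.frame(feature = feats,
                           as.data.frame(sel),
                           total = Reduce(`+`, lapply(sel, as.integer)))
  subsets <- list(
    subset_a = feats[sel$average],
    subset_b = feats[sel$relieff],
    subset_c = feats[Reduce(`&`, sel)],
    subset_d = feats[sel$significance]
  )
  empty <- names(subsets)[vapply(subsets, length, integer(1)) == 0]
  if (length(empty)) {
    warning("empty feature subset(s): ", paste(empty, collapse = ", "))
  }
  c(subsets, list(provenance = provenance))
}
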