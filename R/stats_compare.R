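#' N-way ANOVA on replication metrics
#'
#' Least-squares decomposition of a metric over design factors (classifier,
#' harmonization, subset, ...), main effects by default with optional
#' two-way interactions. Metric values are analyzed untransformed (a logit
#' option is provided since they live in [0, 1]).
#'
#' @param design Data frame with a numeric `response` column and factor
#'   columns.
#' @param factors Character vector of factor column names (>= 2 levels
#'   each).
#' @param interactions If `TRUE`, adds all two-way interactions.
#' @param transform `"none"` or `"logit"` applied to the response.
#' @return Data frame with one row per model term: `term`, `df`, `F`, `p`.
#' @export
nway_anova <- function(design, factors, interactions = FALSE,
                       transform = c("none", "logit")) {
  transform <- match.arg(transform)
  stopifnot("response" %in% names(design), all(factors %in% names(design)))
  dat <- design
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2) stop("factor ", f, " has < 2 levels")
  }
  y <- dat$response
  if (transform == "logit") {
    eps <- 1e-6
    y <- stats::qlogis(pmin(pmax(y, eps), 1 - eps))
  }
  dat$response <- y
  if (stats::var(y) == 0) {
    # constant response: nothing to attribute to any factor
    nterms <- if (interactions)
      length(factors) + choose(length(factors), 2) else length(factors)
    term_names <- factors
    if (interactions) {
      term_names <- c(factors, utils::combn(factors, 2, paste,
                                            collapse = ":"))
    }
    return(data.frame(term = term_names,
                      df = vapply(term_names, function(f)
                        if (f %in% factors)
                          nlevels(dat[[f]]) - 1L else NA_integer_,
                        integer(1), USE.NAMES = FALSE),
                      F = rep(0, nterms), p = rep(1, nterms),
                      stringsAsFactors = FALSE))
  }
  rhs <- paste(factors, collapse = if (interactions) " * " else " + ")
  if (interactions) {
    rhs <- paste(paste(factors, collapse = " + "), "+",
                 paste(utils::combn(factors, 2, function(x)
                   paste(x, collapse = ":")), collapse = " + "))
  }
  fml <- stats::as.formula(paste("response ~", rhs))
  mm <- stats::model.matrix(fml, data = dat)
  if (qr(mm)$rank < ncol(mm)) stop("aliased factors in design")
  fit <- stats::aov(fml, data = dat)
  if (stats::df.residual(fit) < 1) stop("no residual degrees of freedom")
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  keep <- terms != "Residuals"
  Fv <- an$`F value`[keep]
  pv <- an$`Pr(>F)`[keep]
  zero_ss <- an$`Sum Sq`[keep] <= 1e-12 * max(an$`Sum Sq`, 1e-300)
  Fv[zero_ss] <- 0  # constant response: no variance to attribute
  pv[zero_ss] <- 1
  data.frame(term = terms[keep], df = an$Df[keep], F = Fv, p = pv,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up rule: reject every p at or below `p_(k*)` with
#' `k* = max{k : p_(k) <= k q / m}`; adjusted p-values by the usual
#' monotone cumulative minimum (equal to `p.adjust(..., "BH")`).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q Target FDR (default 0.05).
#' @return List with logical `reject` (in input order) and `adjusted_p`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  sorted <- p_values[ord]
  thresh <- seq_len(m) * q / m
  below <- which(sorted <= thresh)
  reject <- rep(FALSE, m)
  if (length(below)) {
    k_star <- max(below)
    reject[ord[seq_len(k_star)]] <- TRUE
  }
  adj <- rev(cummin(rev(sorted * m / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[ord] <- pmin(adj, 1)
  list(reject = reject, adjusted_p = adjusted)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range tests on group means with a pooled error variance;
#' unequal group sizes handled by the Tukey-Kramer standard error.
#'
#' @param means Named vector of group means (>= 2 groups).
#' @param mse Pooled error mean square (> 0).
#' @param n_per_group Named vector of group sizes (aligned with `means`).
#' @param df_error Error degrees of freedom; default
#'   `sum(n_per_group) - length(means)`.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q` (studentized-range statistic), `p`, `significant`.
#' @export
tukey_hsd <- function(means, mse, n_per_group,
                      df_error = sum(n_per_group) - length(means),
                      alpha = 0.05) {
  k <- length(means)
  if (k < 2) stop("need >= 2 groups")
  if (mse <= 0) stop("mse must be positive")
  nm <- names(means)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / n_per_group[i] + 1 / n_per_group[j]))
    qstat <- abs(means[[i]] - means[[j]]) / se
    p <- stats::ptukey(qstat, nmeans = k, df = df_error,
                       lower.tail = FALSE)
    c(diff = means[[i]] - means[[j]], q = unname(qstat), p = unname(p))
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             diff = out["diff", ], q = out["q", ], p = out["p", ],
             significant = out["p", ] <= alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked comparison report over a results table
#'
#' For one metric, pools the four feature subsets (as the headline
#' comparisons do), ranks (classifier x harmonization) combinations by
#' mean metric, and annotates each classifier's pairwise comparisons
#' against the others (per harmonization) with BH-FDR-adjusted
#' significance from Tukey HSD on the replication values. Replications are
#' treated as independent observations; because replications share
#' underlying data, the p-values are approximate.
#'
#' @param results Long-format results data frame ([monte_carlo_run()]).
#' @param metric Metric name (e.g. `"f1"`, `"mcc_prime"`).
#' @param estimate_type `"nested"` (default) or `"direct"`.
#' @param q FDR level for pairwise annotations.
#' @return List with `ranking` (per classifier x harmonization means),
#'   `pairwise` (Tukey + BH annotations) and `missing` combinations.
#' @export
compare_report <- function(results, metric, estimate_type = "nested",
                           q = 0.05) {
  sub <- results[results$metric == metric &
                   results$estimate_type == estimate_type, ]
  if (!nrow(sub)) stop("no rows for metric ", metric)
  expected <- expand.grid(
    classifier = unique(results$classifier),
    harmonization = unique(results$harmonization),
    subset = unique(results$subset), stringsAsFactors = FALSE
  )
  have <- unique(sub[, c("classifier", "harmonization", "subset")])
  missing <- expected[!do.call(paste, expected) %in% do.call(paste, have), ]

  agg <- stats::aggregate(value ~ classifier + harmonization, data = sub,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v)))
  ranking <- data.frame(classifier = agg$classifier,
                        harmonization = agg$harmonization,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean), ]
  rownames(ranking) <- NULL

  pairwise <- list()
  for (h in unique(sub$harmonization)) {
    sh <- sub[sub$harmonization == h, ]
    groups <- split(sh$value, sh$classifier)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) < 2) next
    means <- vapply(groups, mean, numeric(1))
    sizes <- vapply(groups, length, numeric(1))
    mse <- sum(vapply(groups, function(v)
      sum((v - mean(v))^2), numeric(1))) / (sum(sizes) - length(groups))
    if (mse <= 0) mse <- .Machine$double.eps
    tk <- tukey_hsd(means, mse, sizes, alpha = q)
    tk$harmonization <- h
    pairwise[[h]] <- tk
  }
  pairwise <- do.call(rbind, pairwise)
  if (!is.null(pairwise) && nrow(pairwise)) {
    fdr <- bh_fdr(pairwise$p, q = q)
    pairwise$p_fdr <- fdr$adjusted_p
    pairwise$significant_fdr <- fdr$reject
    rownames(pairwise) <- NULL
  }
  list(ranking = ranking, pairwise = pairwise, missing = missing)
}
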