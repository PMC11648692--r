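#' Fit a per-sex polynomial reference model for one feature
#'
#' Ordinary least squares of the feature on (age, ICV) over the reference
#' (HC) rows of each sex. Degree `"poly11"` fits the plane 1 + age + icv;
#' `"poly22"` adds age^2, age*icv and icv^2. The residual variance and the
#' inverse Gram matrix are retained so prediction-level standard deviations
#' can be computed for the z-score transform.
#'
#' @param table A `feature_table`.
#' @param feature Region name (one of [volume_cols()]).
#' @param degree `"poly11"` (default) or `"poly22"`.
#' @param reference_group Group used to fit; default `"HC"`.
#' @return Named list (Male, Female) of `poly_surface_model` objects with
#'   fields `coefficients`, `mse`, `gram_inverse`, `n_ref`, `degree`,
#'   `sex_stratum`.
#' @export
fit_reference_model <- function(table, feature,
                                degree = c("poly11", "poly22"),
                                reference_group = "HC") {
  degree <- match.arg(degree)
  if (!feature %in% names(table)) stop("unknown feature: ", feature)
  ref <- table[table$group == reference_group, ]
  sexes <- intersect(c("Male", "Female"), unique(as.character(table$sex)))
  models <- lapply(sexes, function(sx) {
    sub <- ref[ref$sex == sx, ]
    X <- design_matrix(sub$age, sub$icv, degree)
    p <- ncol(X)
    if (nrow(X) < p + 2) {
      stop("too few ", reference_group, " reference rows for sex ", sx,
           " (need >= ", p + 2, ", have ", nrow(X), ")")
    }
    y <- sub[[feature]]
    qrX <- qr(X)
    if (qrX$rank < p) stop("rank-deficient reference design for sex ", sx)
    beta <- qr.coef(qrX, y)
    resid <- y - X %*% beta
    mse <- sum(resid^2) / (nrow(X) - p)
    structure(
      list(sex_stratum = sx, degree = degree,
           coefficients = as.numeric(beta),
           mse = mse,
           gram_inverse = chol2inv(qr.R(qrX)),
           n_ref = nrow(X),
           age_range = range(sub$age), icv_range = range(sub$icv)),
      class = "poly_surface_model"
    )
  })
  names(models) <- sexes
  models
}

design_matrix <- function(age, icv, degree) {
  if (degree == "poly11") {
    cbind(1, age, icv)
  } else {
    cbind(1, age, icv, age^2, age * icv, icv^2)
  }
}

#' Predicted mean and standard deviation at a covariate point
#'
#' `mu_hat = x0' beta`. By default `sigma_hat` is the observation-level
#' prediction SD, `sqrt(mse * (1 + x0' (X'X)^-1 x0))`, matching the interval
#' routine the reference fits emulate; `level = "mean"` drops the `1 +`
#' (SD of the fitted mean only). Queries outside the reference covariate
#' hull are computed but flagged.
#'
#' @param model A `poly_surface_model`.
#' @param age,icv Covariate values (vectorized).
#' @param level `"observation"` (default) or `"mean"`.
#' @return List with `mu_hat`, `sigma_hat`, and logical `extrapolated`.
#' @export
predict_mean_sd <- function(model, age, icv,
                            level = c("observation", "mean")) {
  level <- match.arg(level)
  X0 <- design_matrix(age, icv, model$degree)
  mu <- as.numeric(X0 %*% model$coefficients)
  lev <- rowSums((X0 %*% model$gram_inverse) * X0)
  add <- if (level == "observation") 1 else 0
  sigma <- sqrt(model$mse * (add + lev))
  extrap <- age < model$age_range[1] | age > model$age_range[2] |
    icv < model$icv_range[1] | icv > model$icv_range[2]
  list(mu_hat = mu, sigma_hat = sigma, extrapolated = extrap)
}

#' Fit reference models for every volume feature
#'
#' @inheritParams fit_reference_model
#' @return Named list (feature -> per-sex model pair).
#' @export
fit_all_reference_models <- function(table, degree = "poly11",
                                     reference_group = "HC") {
  feats <- volume_cols(table)
  models <- lapply(feats, function(f) {
    fit_reference_model(table, f, degree = degree,
                        reference_group = reference_group)
  })
  names(models) <- feats
  models
}

#' Harmonize a feature table against reference models
#'
#' Residual harmonization subtracts the sex-specific predicted mean
#' (`x1 = y - mu_hat`); z-score harmonization also divides by the predicted
#' SD (`x2 = (y - mu_hat) / sigma_hat`). Non-reference (uHC) rows are scored
#' with the reference-fitted model of their sex -- never refit.
#'
#' @param table A `feature_table`.
#' @param models Output of [fit_all_reference_models()] (or a subset
#'   covering the features to harmonize).
#' @param method `"residual"` or `"zscore"`.
#' @param sigma_level Passed to [predict_mean_sd()] for the z-score SD.
#' @return A `feature_table` with volumes replaced by harmonized values
#'   (positivity no longer enforced) and attribute
#'   `harmonization` in `{"residual", "zscore"}`. Extrapolated rows are
#'   counted in attribute `n_extrapolated`.
#' @export
harmonize <- function(table, models, method = c("residual", "zscore"),
                      sigma_level = "observation") {
  method <- match.arg(method)
  feats <- names(models)
  missing <- setdiff(feats, names(table))
  if (length(missing)) stop("features absent from table: ",
                            paste(missing, collapse = ", "))
  out <- as.data.frame(table)
  n_extrap <- 0L
  for (f in feats) {
    vals <- out[[f]]
    for (sx in c("Male", "Female")) {
      idx <- which(out$sex == sx)
      if (!length(idx)) next
      pr <- predict_mean_sd(models[[f]][[sx]], out$age[idx], out$icv[idx],
                            level = sigma_level)
      n_extrap <- n_extrap + sum(pr$extrapolated)
      if (method == "residual") {
        vals[idx] <- out[[f]][idx] - pr$mu_hat
      } else {
        if (any(pr$sigma_hat < 1e-10)) {
          stop("sigma_hat below tolerance for feature ", f,
               "; z-score harmonization undefined")
        }
        vals[idx] <- (out[[f]][idx] - pr$mu_hat) / pr$sigma_hat
      }
    }
    out[[f]] <- vals
  }
  attr(out, "volume_cols") <- volume_cols(table)
  attr(out, "harmonization") <- method
  attr(out, "n_extrapolated") <- n_extrap
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Harmonization tag of a table
#' @param table A `feature_table`.
#' @return `"uncorrected"`, `"residual"` or `"zscore"`.
#' @export
harmonization_tag <- function(table) {
  tag <- attr(table, "harmonization")
  if (is.null(tag)) "uncorrected" else tag
}
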