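# Statistical stages: hierarchical block regression with R^2-change F
# tests, collinearity diagnostics, the quadratic age model, leave-site-out
# cross-validation with Levene's test, and the impairment-rate summary.

#' Hierarchical (block) multiple regression
#'
#' Fits a sequence of nested ordinary-least-squares models with intercept:
#' model k uses all predictors of blocks 1..k. Reports per block the model
#' R^2, adjusted R^2, overall F and p, the increment Delta R^2 over the
#' previous block, and the partial F test
#' \deqn{\Delta F_k = \frac{(R^2_k - R^2_{k-1}) / q}{(1 - R^2_k)/(n - p_k - 1)}}
#' with q the number of predictors added and p_k the total predictors in
#' model k. Coefficients of every model are reported raw (B) and
#' standardized (beta = B * sd(x) / sd(y)), with two-tailed p values.
#'
#' The canonical block order is: covariates (age, gender) in block 1,
#' single-layer structural and functional network metrics in block 2, and
#' the multiplex metric in block 3, so that block 3's Delta F tests the
#' added value of the multiplex measure.
#'
#' @param data data.frame holding the outcome and every predictor.
#' @param blocks List of character vectors: predictor names per block, in
#'   entry order.
#' @param outcome Name of the outcome column.
#' @return A `block_regression` object: list with `blocks` (data.frame of
#'   per-block statistics), `coefficients` (final-model terms with
#'   `b_raw`, `b_std`, `p_value`), `model_coefficients` (the same per
#'   model), `n`, and the fitted final `lm` as `fit`.
#' @export
hierarchical_regression <- function(data, blocks, outcome) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  preds <- unlist(blocks)
  if (anyDuplicated(preds)) {
    stop("predictor names must be unique across blocks", call. = FALSE)
  }
  miss <- setdiff(c(outcome, preds), names(data))
  if (length(miss) > 0) {
    stop("columns not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, c(outcome, preds)]), ,
               drop = FALSE]
  n <- nrow(data)
  if (n <= length(preds) + 1) {
    stop(sprintf("n = %d too small for %d predictors", n, length(preds)),
         call. = FALSE)
  }
  const <- preds[vapply(preds, function(p) stats::sd(data[[p]]) == 0,
                        logical(1))]
  if (length(const) > 0) {
    stop("constant-valued predictor(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }

  y <- data[[outcome]]
  sd_y <- stats::sd(y)
  block_rows <- vector("list", length(blocks))
  model_coefs <- vector("list", length(blocks))
  r2_prev <- 0
  fit <- NULL
  for (k in seq_along(blocks)) {
    preds_k <- unlist(blocks[seq_len(k)])
    fml <- stats::reformulate(preds_k, response = outcome)
    fit <- stats::lm(fml, data = data)
    if (any(is.na(stats::coef(fit)))) {
      alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; collinear term(s): ",
           paste(alias, collapse = ", "), call. = FALSE)
    }
    s <- summary(fit)
    p_k <- length(preds_k)
    r2 <- s$r.squared
    q <- length(blocks[[k]])
    delta_r2 <- r2 - r2_prev
    df2 <- n - p_k - 1
    f_stat <- (r2 / p_k) / ((1 - r2) / df2)
    f_p <- stats::pf(f_stat, p_k, df2, lower.tail = FALSE)
    denom <- (1 - r2) / df2
    delta_f <- if (denom > 0) (delta_r2 / q) / denom else Inf
    delta_f_p <- stats::pf(delta_f, q, df2, lower.tail = FALSE)
    block_rows[[k]] <- data.frame(
      block = k, n_predictors = p_k, r2 = r2, adj_r2 = s$adj.r.squared,
      f_stat = f_stat, f_p = f_p, delta_r2 = delta_r2,
      delta_f = delta_f, delta_f_p = delta_f_p
    )
    ct <- s$coefficients
    terms_k <- rownames(ct)
    sd_x <- vapply(terms_k, function(t) {
      if (t == "(Intercept)") NA_real_ else stats::sd(data[[t]])
    }, numeric(1))
    model_coefs[[k]] <- data.frame(
      model = k, term = terms_k, b_raw = ct[, 1],
      b_std = ct[, 1] * sd_x / sd_y,
      p_value = ct[, 4], row.names = NULL
    )
    r2_prev <- r2
  }
  structure(
    list(blocks = do.call(rbind, block_rows),
         coefficients = model_coefs[[length(blocks)]],
         model_coefficients = do.call(rbind, model_coefs),
         n = n, outcome = outcome, block_spec = blocks, fit = fit),
    class = "block_regression"
  )
}

#' @export
print.block_regression <- function(x, digits = 4, ...) {
  cat(sprintf("Hierarchical regression of '%s' (n = %d)\n", x$outcome, x$n))
  print(format(x$blocks, digits = digits), row.names = FALSE)
  cat("Final model coefficients:\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Collinearity diagnostics for a set of predictors
#'
#' Variance inflation factors VIF_j = 1 / (1 - R^2_j), where R^2_j comes
#' from regressing predictor j on all the others, plus the full bivariate
#' correlation table. Perfect collinearity yields `Inf` (flag, not error).
#'
#' @param data data.frame with the predictor columns.
#' @param predictors Character vector of >= 2 column names.
#' @return List with `vif` (named numeric) and `correlations` (matrix).
#' @export
collinearity_diagnostics <- function(data, predictors) {
  stopifnot(length(predictors) >= 2)
  X <- data[, predictors, drop = FALSE]
  vif <- vapply(predictors, function(p) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, p),
                                        response = p), data = X)
    # perfect fits are the Inf-flag case, not worth a summary.lm warning
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  list(vif = vif, correlations = stats::cor(X))
}

#' Quadratic age model for a network metric
#'
#' Hierarchical regression with the metric as outcome: raw age in block 1,
#' age squared in block 2, so block 2's Delta F tests for an inverted-U
#' (or U) relation beyond the linear trend. The block-2 increment is
#' invariant to affine rescaling of age.
#'
#' @param metric Numeric per-subject metric (e.g. multiplex ECfpn).
#' @param age Numeric ages in years.
#' @return A [hierarchical_regression] result with blocks (age), (age^2).
#' @export
quadratic_age_model <- function(metric, age) {
  df <- data.frame(metric = metric, age = age, age_sq = age^2)
  hierarchical_regression(df, list("age", "age_sq"), "metric")
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA F test on the absolute deviations of each observation from
#' its group centre (classic mean-centred variant by default; the
#' median-centred Brown-Forsythe variant is available). Groups with fewer
#' than 2 observations are dropped with a warning.
#'
#' @param x Numeric observations (e.g. pooled cross-validation residuals).
#' @param group Group labels (e.g. acquisition site), same length as `x`.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `f_stat`, `p_value`, `df1`, `df2`, `n_groups`.
#' @export
levene_test <- function(x, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- as.character(group)
  stopifnot(length(x) == length(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    x <- x[keep]; group <- group[keep]
  }
  k <- length(unique(group))
  if (k < 2) stop("need >= 2 groups with >= 2 observations", call. = FALSE)
  centre_fun <- if (center == "mean") mean else stats::median
  z <- abs(x - stats::ave(x, group, FUN = centre_fun))
  N <- length(z)
  zbar <- mean(z)
  zbar_g <- tapply(z, group, mean)
  n_g <- tapply(z, group, length)
  ss_between <- sum(n_g * (zbar_g - zbar)^2)
  ss_within <- sum((z - stats::ave(z, group, FUN = mean))^2)
  df1 <- k - 1L
  df2 <- N - k
  f <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / (ss_within / df2)
  }
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f_stat = f, p_value = p, df1 = df1, df2 = df2, n_groups = k)
}

#' Leave-site-out cross-validation of the full regression model
#'
#' For each acquisition site, the full model (all predictors of all blocks)
#' is trained by OLS on every other site and evaluated on the held-out
#' site: out-of-sample R^2 = 1 - SS_res / SS_tot. By default SS_tot is
#' taken about the held-out fold's own outcome mean (the stricter
#' convention; `ss_tot = "train"` uses the training mean instead). Negative
#' R^2 — the model predicting worse than the fold mean — is expected
#' behaviour for weak effects. Levene's test on the pooled residuals,
#' grouped by site, checks whether error variance is consistent across
#' sites.
#'
#' @param data data.frame with outcome, predictors and a site column.
#' @param blocks Block structure as in [hierarchical_regression] (all
#'   predictors are pooled into one full model).
#' @param outcome Outcome column name.
#' @param site_col Name of the site column (default `"site"`).
#' @param ss_tot `"test"` (default) or `"train"`: which mean anchors SS_tot.
#' @param levene_center Passed to [levene_test].
#' @return A `lso_cv` object: list with `folds` (data.frame: held_out_site,
#'   n_test, test_r2), `mean_r2`, `sd_r2`, `levene` and `residuals`
#'   (data.frame site/residual).
#' @export
leave_site_out_cv <- function(data, blocks, outcome, site_col = "site",
                              ss_tot = c("test", "train"),
                              levene_center = "mean") {
  ss_tot <- match.arg(ss_tot)
  preds <- unlist(blocks)
  stopifnot(site_col %in% names(data))
  sites <- unique(as.character(data[[site_col]]))
  if (length(sites) < 2) stop("need >= 2 sites", call. = FALSE)
  fml <- stats::reformulate(preds, response = outcome)
  folds <- vector("list", length(sites))
  resids <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    test <- data[data[[site_col]] == s, , drop = FALSE]
    train <- data[data[[site_col]] != s, , drop = FALSE]
    fit <- stats::lm(fml, data = train)
    pred <- stats::predict(fit, newdata = test)
    res <- test[[outcome]] - pred
    anchor <- if (ss_tot == "test") mean(test[[outcome]])
              else mean(train[[outcome]])
    sst <- sum((test[[outcome]] - anchor)^2)
    r2 <- if (sst == 0) NA_real_ else 1 - sum(res^2) / sst
    folds[[i]] <- data.frame(held_out_site = s, n_test = nrow(test),
                             test_r2 = r2)
    resids[[i]] <- data.frame(site = s, residual = res)
  }
  folds <- do.call(rbind, folds)
  resids <- do.call(rbind, resids)
  lev <- levene_test(resids$residual, resids$site, center = levene_center)
  structure(
    list(folds = folds, mean_r2 = mean(folds$test_r2, na.rm = TRUE),
         sd_r2 = stats::sd(folds$test_r2, na.rm = TRUE),
         levene = lev, residuals = resids),
    class = "lso_cv"
  )
}

#' @export
print.lso_cv <- function(x, ...) {
  cat(sprintf("Leave-site-out CV: %d folds, mean test R^2 = %.3f (SD %.3f)\n",
              nrow(x$folds), x$mean_r2, x$sd_r2))
  cat(sprintf("Levene on residuals by site: F = %.3f, p = %.3f\n",
              x$levene$f_stat, x$levene$p_value))
  invisible(x)
}

#' Cognitive impairment rate
#'
#' Count and proportion of subjects with a standardized cognition score
#' strictly below a threshold (conventionally z < -1.5).
#'
#' @param z Numeric z-scores.
#' @param threshold Impairment cutoff (default -1.5).
#' @return List with `count` and `proportion`.
#' @export
impairment_rate <- function(z, threshold = -1.5) {
  stopifnot(all(is.finite(z)))
  count <- sum(z < threshold)
  list(count = count, proportion = count / length(z))
}
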