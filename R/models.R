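#' Root mean square error
#'
#' RMSE = sqrt(mean((P_i - M_i)^2)) between predicted and measured values.
#'
#' @param predicted,measured equal-length numeric vectors.
#' @return RMSE in the response units.
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured) || !length(predicted))
    stop("predicted and measured must have equal positive length",
         call. = FALSE)
  sqrt(mean((predicted - measured)^2))
}

#' Sample standard deviation (n - 1 denominator)
#'
#' @param values numeric vector of length >= 2.
#' @return standard deviation in the same units.
#' @export
std <- function(values) {
  if (length(values) < 2)
    stop("need at least two values for a standard deviation", call. = FALSE)
  stats::sd(values)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between measured and predicted values; the
#' p-value comes from the t transform with n - 2 degrees of freedom.
#'
#' @param measured,predicted equal-length vectors (n >= 3), neither
#'   constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 3)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(measured, predicted, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(measured))
}

#' Exponential regression model Y = a exp(sum b_j x_j)
#'
#' @param a multiplicative coefficient (> 0), the response at all-zero
#'   predictors.
#' @param b named vector of rate coefficients (one per predictor).
#' @param response response name.
#' @param method fit method tag.
#' @return An `exponential_model`.
#' @export
exponential_model <- function(a, b, response = "y", method = "log_ols") {
  if (a <= 0) stop("multiplicative coefficient must be positive", call. = FALSE)
  if (is.null(names(b)) || any(!nzchar(names(b))))
    stop("rate coefficients must be named after their predictors",
         call. = FALSE)
  structure(list(a = a, b = b, response = response, method = method),
            class = "exponential_model")
}

#' @export
print.exponential_model <- function(x, ...) {
  cat(sprintf("Y = %.4g * exp(%s)   [%s, %s]\n", x$a,
              paste(sprintf("%.4g * %s", x$b, names(x$b)), collapse = " + "),
              x$response, x$method))
  invisible(x)
}

#' Fit an exponential model by least squares on the log response
#'
#' Fits ln y = ln a + sum b_j x_j by ordinary least squares (the
#' multiplicative-error model natural to strictly positive biomass);
#' `method = "nls"` refines the log-linear solution by nonlinear least
#' squares on the original scale (additive error) for sensitivity
#' analysis.
#'
#' @param X data frame or matrix of predictors (named columns).
#' @param y strictly positive response vector.
#' @param method `"log_ols"` (default) or `"nls"`.
#' @param response response name carried on the model.
#' @return An [exponential_model()].
#' @export
fit_exponential <- function(X, y, method = c("log_ols", "nls"),
                            response = "y") {
  method <- match.arg(method)
  X <- as.data.frame(X)
  if (any(y <= 0))
    stop("exponential fitting requires strictly positive responses",
         call. = FALSE)
  if (nrow(X) <= ncol(X) + 1)
    stop("need n > k + 1 observations", call. = FALSE)
  dat <- cbind(X, .logy = log(y))
  fml <- stats::as.formula(paste(".logy ~", paste(names(X), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear predictors: rank-deficient fit", call. = FALSE)
  cf <- stats::coef(fit)
  a <- unname(exp(cf[1]))
  b <- cf[-1]
  names(b) <- names(X)
  if (method == "nls") {
    expr <- paste("a0 * exp(", paste(sprintf("b%d * %s", seq_along(b),
                                             names(X)), collapse = " + "), ")")
    start <- c(list(a0 = a), stats::setNames(as.list(unname(b)),
                                             paste0("b", seq_along(b))))
    ndat <- cbind(X, .y = y)
    nfit <- stats::nls(stats::as.formula(paste(".y ~", expr)),
                       data = ndat, start = start)
    ncf <- stats::coef(nfit)
    a <- unname(ncf["a0"])
    b <- stats::setNames(unname(ncf[paste0("b", seq_along(b))]), names(X))
  }
  exponential_model(a, b, response = response, method = method)
}

#' Predict from an exponential model
#'
#' @param object an [exponential_model()].
#' @param newdata data frame containing the model's predictor columns.
#' @param ... unused.
#' @return positive response vector.
#' @export
predict.exponential_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(names(object$b), names(newdata))
  if (length(missing))
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lin <- as.matrix(newdata[names(object$b)]) %*% object$b
  as.numeric(object$a * exp(lin))
}

#' Seeded 4:1 train/test split
#'
#' @param n sample count (>= 5).
#' @param test_fraction held-out fraction; test size is
#'   `round(n * test_fraction)`.
#' @param seed integer seed.
#' @return list of disjoint exhaustive `train` and `test` index vectors.
#' @export
train_test_split <- function(n, test_fraction = 0.2, seed = 1L) {
  if (n < 5) stop("need at least 5 samples to split", call. = FALSE)
  n_test <- round(n * test_fraction)
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' k-fold cross-validation of an exponential model
#'
#' Randomly partitions the data into k near-equal folds; each fold is held
#' out once while the model is fitted on the remainder; reports the mean of
#' the k fold RMSEs and their standard deviation.
#'
#' @param X predictor data frame.
#' @param y positive response vector.
#' @param k number of folds (default 10); `k = n` gives leave-one-out.
#' @param seed integer seed for the partition.
#' @param method passed to [fit_exponential()].
#' @return list of class `eval_result`: `rmse` (mean fold RMSE), `std` (sd
#'   of fold RMSEs), `fold_rmses`, `k`, `n`.
#' @export
kfold_cv <- function(X, y, k = 10, seed = 1L, method = "log_ols") {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (k < 2 || n < k) stop("need n >= k >= 2", call. = FALSE)
  folds <- with_seed(seed, {
    idx <- sample.int(n)
    split(idx, rep(seq_len(k), length.out = n))
  })
  fold_rmses <- vapply(folds, function(hold) {
    fit <- fit_exponential(X[-hold, , drop = FALSE], y[-hold], method = method)
    rmse(predict(fit, X[hold, , drop = FALSE]), y[hold])
  }, numeric(1))
  structure(list(rmse = mean(fold_rmses),
                 std = if (k >= 2) std(fold_rmses) else NA_real_,
                 fold_rmses = unname(fold_rmses), k = k, n = n),
            class = "eval_result")
}

#' Evaluate a fitted model on held-out data
#'
#' @param model an [exponential_model()].
#' @param X_test,y_test held-out predictors and measured responses.
#' @return `eval_result` list: `rmse`, `r`, `p_value`, `n`. If predictions
#'   are constant the correlation is `NA` (RMSE still reported).
#' @export
evaluate_on_test <- function(model, X_test, y_test) {
  p <- predict(model, X_test)
  res <- list(rmse = rmse(p, y_test), r = NA_real_, p_value = NA_real_,
              n = length(y_test))
  r <- try(pearson_r(y_test, p), silent = TRUE)
  if (!inherits(r, "try-error")) {
    res$r <- r$r; res$p_value <- r$p_value
  } else {
    warning("correlation undefined on the test set (constant vector)",
            call. = FALSE)
  }
  structure(res, class = "eval_result")
}

#' Pairwise Pearson correlation matrix of candidate predictors
#'
#' @param traits data frame.
#' @param columns columns to correlate (default: all numeric).
#' @param threshold admissibility threshold carried on the result.
#' @return symmetric correlation matrix of class `correlation_matrix`.
#' @export
correlation_matrix <- function(traits, columns = NULL, threshold = 0.69) {
  df <- as.data.frame(traits)
  if (is.null(columns))
    columns <- names(df)[vapply(df, is.numeric, logical(1))]
  df <- df[stats::complete.cases(df[columns]), columns, drop = FALSE]
  if (nrow(df) < 3) stop("need >= 3 complete rows", call. = FALSE)
  const <- vapply(df, function(x) stats::sd(x) == 0, logical(1))
  if (any(const))
    stop("constant column(s): ", paste(columns[const], collapse = ", "),
         call. = FALSE)
  m <- stats::cor(df)
  structure(m, class = c("correlation_matrix", class(m)),
            threshold = threshold)
}

#' Admissible predictor sets under a collinearity threshold
#'
#' Returns every unordered pair of predictors with |r| below the threshold
#' (in the matrix's column order), plus any caller-supplied larger sets
#' whose internal pairs all satisfy the same bound; violating extra sets
#' are rejected with the offending pair reported in the `rejected`
#' attribute.
#'
#' @param corr a [correlation_matrix()] (or plain symmetric matrix).
#' @param threshold admissibility bound on |r| (strict).
#' @param extra_sets list of character vectors of predictor names.
#' @return list of character vectors, with attribute `rejected` (tibble of
#'   set, reason).
#' @export
admissible_predictor_sets <- function(corr, threshold = 0.69,
                                      extra_sets = list()) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  nms <- colnames(corr)
  sets <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    if (abs(corr[i, j]) < threshold) sets[[length(sets) + 1L]] <- nms[c(i, j)]
  }
  rejected <- tibble::tibble(set = character(0), reason = character(0))
  for (s in extra_sets) {
    unknown <- setdiff(s, nms)
    if (length(unknown))
      stop("extra set references unknown trait(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- NULL
    cmb <- utils::combn(s, 2)
    for (p in seq_len(ncol(cmb))) {
      r <- corr[cmb[1, p], cmb[2, p]]
      if (abs(r) >= threshold) { bad <- c(cmb[, p], sprintf("%.2f", r)); break }
    }
    if (is.null(bad)) {
      sets[[length(sets) + 1L]] <- s
    } else {
      rejected <- rbind(rejected, tibble::tibble(
        set = paste(s, collapse = "+"),
        reason = sprintf("|r(%s, %s)| = %s >= %.2f",
                         bad[1], bad[2], bad[3], threshold)))
    }
  }
  attr(sets, "rejected") <- rejected
  sets
}

#' Two-sample Student's t-test between treatment groups
#'
#' Pooled-variance Student's t with n1 + n2 - 2 degrees of freedom
#' (two-sided); `welch = TRUE` drops the equal-variance assumption.
#'
#' @param values numeric vector.
#' @param groups vector with exactly two levels, aligned with `values`.
#' @param welch use the Welch form.
#' @return list of class `ttest_result`: `t`, `p_value`, `group_means`,
#'   `group_sizes`, `df`.
#' @export
treatment_ttest <- function(values, groups, welch = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) stop("each group needs >= 2 values", call. = FALSE)
  means <- tapply(values, groups, mean)
  if (stats::sd(values[groups == levels(groups)[1]]) == 0 &&
      stats::sd(values[groups == levels(groups)[2]]) == 0) {
    # zero within-group variance: t is 0 (equal means) or +/-Inf
    d <- means[1] - means[2]
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               p.value = if (d == 0) 1 else 0,
               parameter = sum(sizes) - 2)
  } else {
    tt <- stats::t.test(values ~ groups, var.equal = !welch)
  }
  structure(list(t = unname(tt$statistic), p_value = unname(tt$p.value),
                 group_means = means, group_sizes = as.integer(sizes),
                 df = unname(tt$parameter)),
            class = "ttest_result")
}

#' Correlate vegetation indices with laboratory traits
#'
#' Joins trait rows to lab measurements by plot (and date, when both carry
#' one), pooling matched records across dates, and reports Pearson r and p
#' per (VI, lab trait) pair. Pairs with fewer than 3 matches are flagged
#' with `NA` rather than computed; unmatched records are counted in the
#' `n_unmatched` attribute.
#'
#' @param traits table with `plot_id` (optionally `date`) and VI columns.
#' @param lab table with `plot_id` (optionally `date`) and lab columns.
#' @param vi_cols VI column names in `traits`.
#' @param lab_cols lab trait column names in `lab`.
#' @return tibble of `vi`, `lab_trait`, `r`, `p_value`, `n`.
#' @export
correlate_vi_with_lab <- function(traits, lab,
                                  vi_cols = c("ndvi", "gndvi", "ci_green",
                                              "ci_rededge", "ndre"),
                                  lab_cols = c("chlorophyll", "leaf_N_pct")) {
  keys <- intersect(c("plot_id", "date"),
                    intersect(names(traits), names(lab)))
  merged <- merge(as.data.frame(traits), as.data.frame(lab), by = keys)
  n_unmatched <- nrow(lab) - nrow(merged)
  out <- list()
  for (v in vi_cols) for (l in lab_cols) {
    ok <- stats::complete.cases(merged[c(v, l)])
    if (sum(ok) < 3) {
      out[[length(out) + 1L]] <- tibble::tibble(
        vi = v, lab_trait = l, r = NA_real_, p_value = NA_real_,
        n = sum(ok))
      next
    }
    pr <- pearson_r(merged[[l]][ok], merged[[v]][ok])
    out[[length(out) + 1L]] <- tibble::tibble(
      vi = v, lab_trait = l, r = pr$r, p_value = pr$p_value, n = pr$n)
  }
  res <- do.call(rbind, out)
  attr(res, "n_unmatched") <- n_unmatched
  res
}

#' Generate-and-refit coefficient recovery
#'
#' Simulates data from a known exponential model (predictors drawn
#' uniformly over stated ranges, multiplicative log-normal noise), refits
#' by log-linear least squares, and averages the recovered coefficients
#' over seeded replicates. Used to verify that the fitting procedure
#' recovers published model coefficients.
#'
#' @param model the generating [exponential_model()].
#' @param ranges named list of `c(min, max)` predictor ranges.
#' @param n samples per replicate.
#' @param reps number of replicates.
#' @param noise_sd sd of the log-scale noise.
#' @param seed root seed.
#' @return list: `a` (mean fitted multiplicative coefficient), `b` (named
#'   mean rate coefficients), `per_rep` (tibble of all fits).
#' @export
recover_model_coefficients <- function(model, ranges, n = 2000, reps = 20,
                                       noise_sd = 0.05, seed = 1L) {
  stopifnot(setequal(names(ranges), names(model$b)))
  fits <- vector("list", reps)
  for (r in seq_len(reps)) {
    fits[[r]] <- with_seed(derive_seed(seed, paste0("recover", r)), {
      X <- as.data.frame(lapply(ranges[names(model$b)], function(rg)
        stats::runif(n, rg[1], rg[2])))
      y <- predict(model, X) * exp(stats::rnorm(n, 0, noise_sd))
      fit <- fit_exponential(X, y)
      c(a = fit$a, fit$b)
    })
  }
  m <- do.call(rbind, fits)
  means <- colMeans(m)
  list(a = unname(means["a"]),
       b = means[names(model$b)],
       per_rep = tibble::as_tibble(as.data.frame(m)))
}
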