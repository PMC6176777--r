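test_that("rmse, std and pearson match brute-force formula oracles", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(21)
  p <- runif(50); m <- runif(50)
  expect_equal(rmse(3 * p, 3 * m), 3 * rmse(p, m), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal")

  expect_equal(std(c(5, 5, 5)), 0)
  expect_equal(std(c(1, 3)), sqrt(2))
  expect_equal(std(p + 100), std(p), tolerance = 1e-12)
  expect_error(std(1), "at least two")

  expect_equal(pearson_r(m, 2 * m + 1)$r, 1.0)
  expect_equal(pearson_r(m, -m)$r, -1.0)
  set.seed(22)
  a <- rnorm(1000); b <- 0.3 * a + rnorm(1000)
  expect_equal(pearson_r(a, b)$r, oracle_pearson(a, b), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("noiseless exponential data are recovered to machine precision", {
  x <- seq(0, 1, by = 0.1)
  y <- 2 * exp(3 * x)
  fit <- fit_exponential(data.frame(x = x), y)
  expect_lt(abs(fit$a - 2) / 2, 1e-10)
  expect_lt(abs(fit$b[["x"]] - 3) / 3, 1e-10)
  set.seed(23)
  X2 <- data.frame(x1 = runif(40), x2 = runif(40))
  y2 <- 5 * exp(0.4 * X2$x1 + 0.2 * X2$x2)
  fit2 <- fit_exponential(X2, y2)
  expect_equal(unname(c(fit2$a, fit2$b)), c(5, 0.4, 0.2), tolerance = 1e-8)
  expect_equal(predict(fit2, X2), y2, tolerance = 1e-8)
  expect_error(fit_exponential(data.frame(x = x), y - 10), "positive")
  expect_error(fit_exponential(data.frame(x1 = x, x2 = 2 * x), 2 * exp(x)),
               "collinear")
})

test_that("the nonlinear-least-squares option agrees in the noiseless case", {
  set.seed(29)
  X <- data.frame(x = runif(60, 0, 2))
  y <- 1.5 * exp(0.8 * X$x) * exp(rnorm(60, 0, 1e-3))
  fit <- fit_exponential(X, y, method = "nls")
  expect_equal(unname(c(fit$a, fit$b)), c(1.5, 0.8), tolerance = 1e-2)
})

test_that("prediction follows Y = a exp(sum b x)", {
  m <- exponential_model(21.22, c(PH = 0.005))
  expect_equal(predict(m, data.frame(PH = 0)), 21.22)
  expect_equal(predict(m, data.frame(PH = c(100, 200))),
               21.22 * exp(0.005 * c(100, 200)))
  expect_error(predict(m, data.frame(CC = 1)), "lacks predictor")
  expect_error(exponential_model(-1, c(PH = 1)), "positive")
})

test_that("the 4:1 split reproduces the 290/73 partition at n = 363", {
  sp <- train_test_split(363, 0.2, seed = 1)
  expect_length(sp$train, 290)
  expect_length(sp$test, 73)
  expect_setequal(c(sp$train, sp$test), 1:363)
  sp5 <- train_test_split(5, 0.2, seed = 9)
  expect_length(sp5$train, 4)
  expect_length(sp5$test, 1)
  expect_identical(train_test_split(100, seed = 3),
                   train_test_split(100, seed = 3))
  expect_error(train_test_split(4), "at least 5")
})

test_that("k-fold CV partitions exactly and nails a perfect model", {
  set.seed(24)
  X <- data.frame(x = runif(53, 0, 2))
  y <- 2 * exp(1.3 * X$x)
  res <- kfold_cv(X, y, k = 10, seed = 7)
  expect_lt(res$rmse, 1e-8)
  expect_length(res$fold_rmses, 10)
  # partition property via a noisy response and the same seed
  folds <- withr::with_seed(7, {
    idx <- sample.int(53)
    split(idx, rep(1:10, length.out = 53))
  })
  sizes <- lengths(folds)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unlist(folds), 1:53)
  loo <- kfold_cv(X, y, k = nrow(X), seed = 1)
  expect_length(loo$fold_rmses, nrow(X))
  expect_error(kfold_cv(X, y, k = 54), "n >= k")
})

test_that("correlation matrices are symmetric and match pairwise pearson", {
  set.seed(25)
  df <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  df$d <- df$a
  cm <- correlation_matrix(df)
  expect_equal(cm["a", "d"], 1.0)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(cm["a", "b"], oracle_pearson(df$a, df$b), tolerance = 1e-12)
  df$e <- 1
  expect_error(correlation_matrix(df), "constant column.*e")
})

test_that("admissibility screening reproduces the published predictor sets", {
  cm <- reference_predictor_correlations()
  pairs <- admissible_predictor_sets(cm, 0.69)
  expect_length(pairs, 9)
  with_triple <- admissible_predictor_sets(
    cm, 0.69, extra_sets = list(c("PH", "CC", "NDRE")))
  expect_length(with_triple, 10)
  want <- reference_predictor_sets()
  norm <- function(l) sort(vapply(l, function(s)
    paste(sort(s), collapse = "+"), character(1)))
  expect_identical(norm(with_triple), norm(want))
  # the CC-RGBVI pair (r = 0.75) is rejected from any extra set
  rej <- admissible_predictor_sets(cm, 0.69,
                                   extra_sets = list(c("CC", "RGBVI", "PH")))
  expect_length(rej, 9)
  expect_match(attr(rej, "rejected")$reason, "0.75")
  expect_error(admissible_predictor_sets(cm, 0.69,
                                         extra_sets = list(c("PH", "LAI"))),
               "unknown trait")
  m <- diag(3); dimnames(m) <- list(letters[1:3], letters[1:3])
  expect_length(admissible_predictor_sets(m, 1.0), 3)
})

test_that("the Student's t-test matches the pooled-variance formula", {
  set.seed(26)
  x <- rnorm(40); grp <- rep(c("lo", "hi"), each = 20)
  res <- treatment_ttest(x, grp)
  expect_equal(res$t, oracle_student_t(x[grp == "hi"], x[grp == "lo"]),
               tolerance = 1e-10)
  expect_equal(res$df, 38)
  same <- treatment_ttest(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  sep <- treatment_ttest(c(0, 0, 0, 0, 1, 1, 1, 1),
                         rep(c("a", "b"), each = 4))
  expect_lt(sep$p_value, 1e-6)
  expect_lt(sep$t, 0)  # first group mean lower
  expect_error(treatment_ttest(1:3, c("a", "a", "b")), ">= 2")
})

test_that("VI-lab correlation joins by plot and flags sparse pairs", {
  traits <- data.frame(plot_id = sprintf("P%02d", 1:10),
                       ndre = seq(0.2, 0.4, length.out = 10))
  lab <- data.frame(plot_id = sprintf("P%02d", c(1:10, 11)),
                    chlorophyll = c(seq(0.2, 0.4, length.out = 10), 99))
  res <- correlate_vi_with_lab(traits, lab, vi_cols = "ndre",
                               lab_cols = "chlorophyll")
  expect_equal(res$r[1], 1.0, tolerance = 1e-12)
  expect_equal(res$n[1], 10)
  expect_equal(attr(res, "n_unmatched"), 1)
  sparse <- correlate_vi_with_lab(traits[1:2, ], lab[1:2, ],
                                  vi_cols = "ndre", lab_cols = "chlorophyll")
  expect_true(is.na(sparse$r[1]))
})

test_that("simulated nitrogen recovers the generative correlation at n = 250", {
  cfg <- scene_config()
  design <- build_field_design(cfg)
  rs <- vapply(1:20, function(s) {
    truth <- simulate_plot_truths(design, seed = s)
    sub <- truth[withr::with_seed(s, sample.int(nrow(truth), 250)), ]
    res <- correlate_vi_with_lab(
      data.frame(plot_id = sub$plot_id, ndre = sub$ndre_latent),
      sub[, c("plot_id", "leaf_N_pct")], vi_cols = "ndre",
      lab_cols = "leaf_N_pct")
    res$r[1]
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.12)
})

test_that("test-set evaluation composes rmse and pearson", {
  set.seed(27)
  X <- data.frame(x = runif(30))
  y <- 4 * exp(0.9 * X$x)
  fit <- fit_exponential(X, y)
  ev <- evaluate_on_test(fit, X, y)
  expect_lt(ev$rmse, 1e-8)
  expect_equal(ev$r, 1.0, tolerance = 1e-8)
  yn <- y * exp(rnorm(30, 0, 0.1))
  ev2 <- evaluate_on_test(fit, X, yn)
  expect_equal(ev2$rmse, rmse(predict(fit, X), yn), tolerance = 1e-12)
  expect_equal(ev2$r, pearson_r(yn, predict(fit, X))$r, tolerance = 1e-12)
  const <- exponential_model(2, c(x = 0))
  expect_warning(ev3 <- evaluate_on_test(const, X, yn), "constant")
  expect_true(is.finite(ev3$rmse))
  expect_true(is.na(ev3$r))
})

test_that("published model tables are internally consistent", {
  fresh <- reference_biomass_models("fresh")
  dry <- reference_biomass_models("dry")
  expect_equal(nrow(fresh), 16)
  expect_equal(nrow(dry), 16)
  expect_equal(sum(fresh$model_type == "SER"), 6)
  m <- reference_model_as_object(fresh[fresh$predictors == "PH", ])
  expect_equal(predict(m, data.frame(PH = 0)), 21.22)
  triple <- reference_model_as_object(dry[dry$predictors == "PH+CC+NDRE", ])
  expect_equal(unname(triple$b), c(0.003, 0.345, 0.87))
})
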