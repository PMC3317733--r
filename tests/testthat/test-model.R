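test_that("stratified folds partition instances into near-equal sets", {
  labels <- rep(c(1, -1), each = 300)
  folds <- make_cv_folds(labels, 10, seed = 9)
  expect_length(folds, 10L)
  expect_equal(vapply(folds, length, integer(1)), rep(60L, 10))
  expect_equal(sort(unlist(folds)), 1:600)
  # stratification: each fold holds 30 of each class
  for (f in folds) expect_equal(sum(labels[f] == 1), 30L)
  expect_identical(folds, make_cv_folds(labels, 10, seed = 9))
  expect_false(identical(folds, make_cv_folds(labels, 10, seed = 10)))
  # uneven case still differs by at most one overall and per class
  labels2 <- c(rep(1, 17), rep(-1, 26))
  folds2 <- make_cv_folds(labels2, 7, seed = 1)
  sizes <- vapply(folds2, length, integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  pos_sizes <- vapply(folds2, function(f) sum(labels2[f] == 1), integer(1))
  expect_lte(max(pos_sizes) - min(pos_sizes), 1L)
  expect_error(make_cv_folds(rep(c(1, -1), 5), folds = 12),
               "cannot build 12")
})

test_that("grid search picks the better pair, breaking ties toward small C", {
  withr::with_seed(501, blobs <- separable_blobs(30))
  one <- pssm_svm(blobs$x, blobs$labels, c_grid = 1, gamma_grid = 0.1,
                  folds = 5, seed = 1)
  expect_equal(one$C, 1)
  expect_equal(one$gamma, 0.1)
  expect_equal(nrow(one$grid), 1L)
  # a sensible gamma separates the blobs; an absurdly large one cannot
  two <- pssm_svm(blobs$x, blobs$labels, c_grid = 1,
                  gamma_grid = c(1e6, 0.1), folds = 5, seed = 1)
  expect_equal(two$gamma, 0.1)
  expect_gte(max(two$grid$accuracy), 0.98)
  # exact tie: both pairs perfect -> smallest C then smallest gamma
  tie <- pssm_svm(blobs$x, blobs$labels, c_grid = c(8, 1),
                  gamma_grid = c(0.2, 0.05), folds = 5, seed = 1)
  expect_equal(max(tie$grid$accuracy), tie$cv$mean_fold_accuracy)
  best_rows <- tie$grid[tie$grid$accuracy == max(tie$grid$accuracy), ]
  expect_equal(tie$C, min(best_rows$C))
  expect_equal(tie$gamma,
               min(best_rows$gamma[best_rows$C == tie$C]))
})

test_that("selected accuracy equals the maximum of the reported grid table", {
  withr::with_seed(502, blobs <- separable_blobs(15, gap = 1.5))
  fit <- pssm_svm(blobs$x, blobs$labels, c_grid = 2^c(-1, 3),
                  gamma_grid = 2^c(-5, -1), folds = 5, seed = 3)
  expect_equal(fit$cv$mean_fold_accuracy, max(fit$grid$accuracy))
  # pooled accuracy and fold-mean agree when folds are equal-sized
  expect_equal(fit$cv$ACC, fit$cv$mean_fold_accuracy, tolerance = 1e-12)
})

test_that("CV on separable blobs is near-perfect; label shuffling kills it", {
  withr::with_seed(503, blobs <- separable_blobs(100))
  rep_sep <- evaluate_cv(blobs$x, blobs$labels, folds = 10, seed = 17)
  expect_gte(rep_sep$mean_fold_accuracy, 0.98)
  withr::with_seed(77, shuffled <- sample(blobs$labels))
  rep_null <- evaluate_cv(blobs$x, shuffled, folds = 10, seed = 17,
                          c_grid = 2^seq(-5, 15, 4),
                          gamma_grid = 2^seq(-15, 3, 4))
  expect_gte(rep_null$mean_fold_accuracy, 0.40)
  expect_lte(rep_null$mean_fold_accuracy, 0.60)
})

test_that("predictions recover training labels on separable data", {
  withr::with_seed(504, blobs <- separable_blobs(20))
  fit <- pssm_svm(blobs$x, blobs$labels, c_grid = 1, gamma_grid = 0.1,
                  folds = 5, seed = 1)
  pred <- predict(fit, blobs$x)
  expect_equal(pred$label, blobs$labels)
  expect_true(all(is.finite(pred$score)))
  expect_equal(pred$label, ifelse(pred$score >= 0, 1, -1))
  # resubstitution on separable data is perfect
  rep_ind <- evaluate_independent(fit, blobs$x, blobs$labels)
  expect_equal(rep_ind$ACC, 1)
})

test_that("prediction rejects mismatched dimensions and empty sets", {
  withr::with_seed(505, blobs <- separable_blobs(15))
  fit <- pssm_svm(blobs$x, blobs$labels, c_grid = 1, gamma_grid = 0.1,
                  folds = 5, seed = 1)
  wide <- cbind(blobs$x, blobs$x)
  expect_error(predict(fit, wide), "expects 5 features, got 10")
  expect_error(predict(fit, blobs$x[0, , drop = FALSE]), "empty")
  expect_error(evaluate_independent(fit, blobs$x[0, , drop = FALSE],
                                    numeric(0)), "empty test set")
})

test_that("the zero decision score maps to class +1", {
  expect_equal(lumipred:::score_to_label(c(-0.2, 0, 0.3)), c(-1, 1, 1))
})

test_that("models survive save/load and guard against encoder mismatch", {
  withr::with_seed(506, {
    profs <- lapply(1:24, function(i) random_profile(30, sprintf("p%02d", i)))
    labels <- rep(c(1, -1), 12)
  })
  fit <- pssm_svm(profs, labels, encoder = "pssm-ac", lg = 2,
                  c_grid = c(1, 4), gamma_grid = c(0.01, 0.1),
                  folds = 4, seed = 2)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  withr::with_seed(99, newp <- lapply(1:10, function(i)
    random_profile(25, sprintf("n%02d", i))))
  expect_identical(predict(fit, newp), predict(back, newp))

  f400 <- encode_dataset(profs, "pssm-400")
  expect_error(predict(back, f400), "encoder mismatch")

  corrupt <- tempfile(fileext = ".rds")
  writeLines("not a model", corrupt)
  expect_error(load_model(corrupt), "cannot read model file")
  wrong <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), wrong)
  expect_error(load_model(wrong), "not a lumipred-pssm-svm/1")
})

test_that("the whole fit is reproducible from the seed", {
  withr::with_seed(507, {
    profs <- lapply(1:20, function(i) random_profile(40, sprintf("r%02d", i)))
    labels <- rep(c(1, -1), 10)
  })
  a <- pssm_svm(profs, labels, encoder = "pssm-ac", lg = 3,
                c_grid = c(1, 8), gamma_grid = c(0.01, 0.1),
                folds = 4, seed = 42)
  b <- pssm_svm(profs, labels, encoder = "pssm-ac", lg = 3,
                c_grid = c(1, 8), gamma_grid = c(0.01, 0.1),
                folds = 4, seed = 42)
  expect_identical(a$folds, b$folds)
  expect_identical(a$grid, b$grid)
  expect_identical(unclass(a$cv), unclass(b$cv))
  expect_identical(c(a$C, a$gamma), c(b$C, b$gamma))
})

test_that("lag sweep selects the strongest lag and validates lengths", {
  withr::with_seed(508, {
    spec <- synth_spec(n_pos = 25, n_neg = 25, length_range = c(30, 40),
                       rho_pos = 0.8, rho_neg = 0, seed = 31)
    corp <- generate_profiles(spec)
  })
  sw <- sweep_lag(corp$profiles, corp$labels, lag_values = c(1, 4),
                  c_grid = 2^seq(-3, 9, 4), gamma_grid = 2^seq(-11, -1, 4),
                  folds = 5, seed = 31)
  expect_equal(sw$lags, c(1L, 4L))
  expect_equal(sw$best_accuracy, max(sw$accuracies))
  expect_equal(sw$best_lag, sw$lags[which.max(sw$accuracies)])
  single <- sweep_lag(corp$profiles, corp$labels, lag_values = 4,
                      c_grid = 1, gamma_grid = 0.01, folds = 5, seed = 31)
  expect_equal(single$best_lag, 4L)
  expect_error(sweep_lag(corp$profiles, corp$labels, lag_values = c(1, 50)),
               "too short for maximum lag 50")
  expect_error(sweep_lag(corp$profiles, corp$labels, lag_values = integer(0)),
               "non-empty")
})

test_that("imbalanced independent tests compute cleanly, Sp dominating ACC", {
  withr::with_seed(509, {
    train <- separable_blobs(30, gap = 2.5)
    n_neg <- 390  # 3 positives per 390 negatives: ~1:130 screening regime
    test_x <- rbind(matrix(rnorm(3 * 5), ncol = 5),
                    matrix(rnorm(n_neg * 5, mean = 2.5), ncol = 5))
    test_y <- c(rep(1, 3), rep(-1, n_neg))
  })
  fit <- pssm_svm(train$x, train$labels, c_grid = 1, gamma_grid = 0.1,
                  folds = 5, seed = 1)
  rep_ind <- evaluate_independent(fit, test_x, test_y)
  expect_true(is.finite(rep_ind$ACC))
  expect_equal(sum(rep_ind$counts), 393L)
  # with 130:1 negatives the accuracy is essentially the specificity
  expect_lt(abs(rep_ind$ACC - rep_ind$Sp), 0.05)
})

test_that("training refuses single-class corpora and bad grids", {
  withr::with_seed(510, blobs <- separable_blobs(10))
  expect_error(pssm_svm(blobs$x, rep(1, 20), c_grid = 1, gamma_grid = 0.1),
               "both classes")
  expect_error(pssm_svm(blobs$x, blobs$labels, c_grid = numeric(0),
                        gamma_grid = 0.1, folds = 5), "non-empty")
  expect_error(pssm_svm(blobs$x, blobs$labels, c_grid = -1,
                        gamma_grid = 0.1, folds = 5), "positive")
})
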