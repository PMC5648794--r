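# helper: a feature frame over real registry names of one category
cat_frame <- function(category, n, k, seed) {
  set.seed(seed)
  nm <- feature_registry()
  nm <- nm$name[nm$category == category][seq_len(k)]
  df <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(df) <- nm
  df
}

test_that("mutual information identifies a label-determining feature", {
  set.seed(1)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  df <- cat_frame("shape", n, 6, seed = 2)
  df[[3]] <- y + rnorm(n, 0, 1e-6)   # effectively equal to the label
  top <- mrmr_rank_per_category(df, y, "shape", k = 1)
  expect_equal(top, names(df)[3])
  # oracle: direct MI from the joint histogram dominates the noise features
  mi <- vapply(df, function(f) {
    mutual_information(nucmorph:::discretize_ef(f, 8), y)
  }, numeric(1))
  expect_equal(which.max(mi), 3, ignore_attr = TRUE)
})

test_that("an exact duplicate is not selected second (redundancy penalty)", {
  set.seed(4)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  df <- cat_frame("texture", n, 5, seed = 5)
  df[[1]] <- y + rnorm(n, 0, 0.3)
  df[[2]] <- df[[1]]                 # exact copy
  ranked <- mrmr_rank_per_category(df, y, "texture", k = 3)
  expect_equal(ranked[1], names(df)[1])
  expect_false(ranked[2] == names(df)[2])
  # oracle: hand-evaluated criterion — the copy's score is rel - MI(self) which
  # is below every independent feature's score
  d1 <- nucmorph:::discretize_ef(df[[1]], 8)
  rel_copy <- mutual_information(d1, y)
  red_copy <- mutual_information(d1, d1)
  scores_others <- vapply(3:5, function(i) {
    di <- nucmorph:::discretize_ef(df[[i]], 8)
    mutual_information(di, y) - mutual_information(di, d1)
  }, numeric(1))
  expect_true(all(rel_copy - red_copy < scores_others))
})

test_that("category-wise selection yields exactly 15 candidates", {
  set.seed(6)
  n <- 80
  reg <- feature_registry()
  df <- as.data.frame(matrix(rnorm(n * 242), n, 242))
  names(df) <- reg$name
  y <- rbinom(n, 1, 0.5)
  cands <- unlist(lapply(unique(reg$category), function(cc) {
    mrmr_rank_per_category(df, y, cc, k = 3)
  }))
  expect_length(cands, 15)
  expect_length(unique(cands), 15)
  expect_equal(unname(table(feature_category(cands))[unique(reg$category)]),
               rep(3L, 5), ignore_attr = TRUE)
})

test_that("subset search recovers the informative pair at tiny scale", {
  set.seed(9)
  n <- 90
  df <- cat_frame("graph_global", n, 5, seed = 10)
  y <- rbinom(n, 1, 0.5)
  df[[1]] <- df[[1]] + 3 * y        # A
  df[[2]] <- df[[2]] - 3 * y        # B
  sr <- qda_subset_search(names(df), df, y, subset_size = 2,
                          n_iter = 20, n_folds = 3, seed = 1)
  expect_setequal(sr$selected, names(df)[1:2])
  expect_identical(sr, qda_subset_search(names(df), df, y, subset_size = 2,
                                         n_iter = 20, n_folds = 3, seed = 1))
})

test_that("degenerate full-size search equals plain cross-validated QDA", {
  set.seed(11)
  n <- 60
  df <- cat_frame("shape", n, 5, seed = 12)
  y <- rbinom(n, 1, 0.5)
  df[[1]] <- df[[1]] + 1.5 * y
  sr <- qda_subset_search(names(df), df, y, subset_size = 5,
                          n_iter = 10, n_folds = 3, seed = 3)
  expect_length(sr$selected, 5)
  expect_equal(ncol(sr$subsets), 1)
  # oracle: R-level QDA over the same fold stream
  X <- as.matrix(df)
  set.seed(3)
  folds <- vapply(1:10, function(i) nucmorph:::stratified_folds(y, 3), integer(n))
  accs <- c()
  for (q in 1:10) for (k in 1:3) {
    tr <- folds[, q] != k; te <- !tr
    fit <- nucmorph:::gaussian_fit(X[tr, ], y[tr])
    sc <- nucmorph:::gaussian_log_odds(fit, X[te, , drop = FALSE])
    accs <- c(accs, mean((sc > 0) == (y[te] == 1)))
  }
  expect_equal(sr$cv_accuracy, mean(accs), tolerance = 1e-10)
})

test_that("all three classifiers separate a linearly separable toy set", {
  set.seed(13)
  n <- 40
  df <- cat_frame("orientation", n, 2, seed = 14)
  y <- rep(c(0L, 1L), each = n / 2)
  df[[1]] <- df[[1]] + 6 * y          # wide margin: all three must separate
  for (kind in c("QDA", "LDA", "SVM")) {
    m <- recurrence_classifier(df, y, names(df), kind)
    pr <- predict(m, df)
    expect_equal(mean(pr$call == (y == 1)), 1, info = kind)
  }
})

test_that("QDA beats LDA on equal-mean, unequal-variance classes", {
  set.seed(15)
  n <- 2000
  y <- rep(c(0, 1), each = n / 2)
  sd_ <- ifelse(y == 1, 3, 1)
  df <- cat_frame("texture", n, 2, seed = 16)
  df[[1]] <- rnorm(n, 0, sd_); df[[2]] <- rnorm(n, 0, sd_)
  qda <- recurrence_classifier(df, y, names(df), "QDA")
  lda <- recurrence_classifier(df, y, names(df), "LDA")
  acc <- function(m) mean(predict(m, df)$call == (y == 1))
  expect_gt(acc(qda), 0.8)
  expect_lt(abs(acc(lda) - 0.5), 0.1)
})

test_that("in-package QDA posteriors agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(17)
  n <- 120
  df <- cat_frame("shape", n, 3, seed = 18)
  y <- rbinom(n, 1, 0.5)
  df[[1]] <- df[[1]] + y
  m <- recurrence_classifier(df, y, names(df), "QDA")
  pr <- predict(m, df)
  Z <- scale(as.matrix(df))
  mm <- MASS::qda(Z, grouping = factor(y))
  post <- predict(mm, Z)$posterior[, "1"]
  expect_equal(pr$score, unname(post), tolerance = 1e-8)
})

test_that("prediction on unseen columns fails naming the column", {
  set.seed(19)
  df <- cat_frame("shape", 30, 2, seed = 20)
  y <- rbinom(30, 1, 0.5)
  m <- recurrence_classifier(df, y, names(df), "LDA")
  expect_error(predict(m, df[, 1, drop = FALSE]), names(df)[2])
})

test_that("evaluation reproduces published confusion-matrix metrics", {
  ev <- metrics_from_confusion(tp = 51, fp = 19, fn = 3, tn = 46)
  expect_equal(round(100 * ev$recall, 1), 94.4)
  expect_equal(round(100 * ev$ppv, 1), 72.9)
  expect_equal(round(100 * ev$accuracy), 82)
  ev3 <- metrics_from_confusion(tp = 17, fp = 8, fn = 21, tn = 70)
  expect_equal(round(100 * ev3$accuracy), 75)
})

test_that("AUC is 1 for perfect ranking, 0.5 for constant scores, and is
           invariant to monotone transforms", {
  truth <- c(rep(FALSE, 10), rep(TRUE, 10))
  sc <- c(seq(0.1, 0.4, length.out = 10), seq(0.6, 0.9, length.out = 10))
  ev <- evaluate_classifier(sc > 0.5, sc, truth)
  expect_equal(ev$auc, 1)
  ev_const <- evaluate_classifier(rep(FALSE, 20), rep(0.3, 20), truth)
  expect_equal(ev_const$auc, 0.5)
  ev_mono <- evaluate_classifier(sc > 0.5, exp(7 * sc) - 2, truth)
  expect_equal(ev_mono$auc, ev$auc)
  expect_warning(ev1 <- evaluate_classifier(rep(TRUE, 3), 1:3, rep(TRUE, 3)),
                 "single class")
  expect_true(is.nan(ev1$auc))
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  truth <- rbinom(60, 1, 0.45)
  sc <- truth + rnorm(60)
  ev <- evaluate_classifier(sc > 0.5, sc, truth)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, sc, quiet = TRUE)))
  expect_equal(ev$auc, as.numeric(ref), tolerance = 1e-10)
})
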