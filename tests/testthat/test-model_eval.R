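test_that("age binning follows the floor rule with stated anchoring", {
  b5 <- age_binning(17, 67, 5)
  expect_equal(bin_ages(c(17, 21, 22, 67), b5), c(0L, 0L, 1L, 10L))
  b50 <- age_binning(17, 67, 50)
  expect_equal(bin_ages(c(17, 40, 66.9, 67), b50), c(0L, 0L, 0L, 1L))
  # width 5 over [17, 67] admits 11 distinct labels
  expect_length(unique(bin_ages(seq(17, 67, by = 0.25), b5)), 11)
  expect_error(bin_ages(c(30, 70), b5), "70")
})

test_that("confusion metrics match the defining formulas", {
  # binary: first class is the positive one
  cm <- matrix(c(9, 0, 1, 90), 2) # rows truth: (9,1),(0,90)
  m <- confusion_metrics(cm)
  expect_equal(unname(m), c(0.99, 0.9, 1.0))
  # perfect diagonal
  expect_equal(unname(confusion_metrics(diag(c(3, 4, 5)))), c(1, 1, 1))
  # 3-class one-vs-rest macro averaging, oracle expanded by hand
  cm3 <- rbind(c(5, 0, 0), c(0, 4, 1), c(0, 2, 3))
  m3 <- confusion_metrics(cm3)
  expect_equal(unname(m3["accuracy"]), 12 / 15)
  expect_equal(unname(m3["sensitivity"]), (1 + 0.8 + 0.6) / 3)
  expect_equal(unname(m3["specificity"]), (1 + 0.8 + 0.9) / 3)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("well-separated clusters are classified nearly perfectly", {
  set.seed(60)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 4), n)
  X[y == "b", 1] <- X[y == "b", 1] + 10 # 10-sigma separation
  colnames(X) <- paste0("v", 1:4)
  tbl <- fake_feature_table(X)
  for (cl in c("knn", "lda", "qda", "dt")) {
    r <- train_eval(tbl, y, cl, k = 5, seed = 3, smote = FALSE)
    expect_gte(r$accuracy, 0.95)
  }
})

test_that("permuted labels yield near-chance accuracy", {
  set.seed(61)
  n <- 300
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  tbl <- fake_feature_table(X)
  y <- sample(rep(letters[1:5], each = n / 5))
  accs <- vapply(1:3, function(s)
    train_eval(tbl, y, "lda", k = 5, seed = s, smote = FALSE)$accuracy, 0)
  expect_gte(mean(accs), 0.1)
  expect_lte(mean(accs), 0.35)
})

test_that("evaluation is deterministic given the seed", {
  set.seed(62)
  X <- matrix(rnorm(120 * 4), 120, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c("a", "b", "c"), each = 40)
  X[y == "b", 2] <- X[y == "b", 2] + 1.5
  tbl <- fake_feature_table(X)
  r1 <- train_eval(tbl, y, "rf", k = 4, seed = 17)
  r2 <- train_eval(tbl, y, "rf", k = 4, seed = 17)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(train_eval(tbl, y, "mystery", k = 4), "unknown|arg")
  expect_error(train_eval(tbl, c("solo", y[-1]), "lda"), "single member")
})

test_that("in-house QDA agrees with the reference QDA when well-posed", {
  set.seed(63)
  n <- 300
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 3), n)
  X[y == "b", ] <- X[y == "b", ] %*% chol(matrix(c(2, .5, 0, .5, 1, 0,
                                                   0, 0, 0.5), 3)) + 1
  colnames(X) <- paste0("v", 1:3)
  tr <- seq_len(n) %% 2 == 0
  ref <- MASS::qda(X[tr, ], y[tr])
  own <- exhalr:::qda_shrink(X[tr, ], y[tr], reg = 1e-6)
  agree <- mean(predict(ref, X[!tr, ])$class == predict(own, X[!tr, ]))
  expect_gte(agree, 0.98)
})

test_that("paired comparisons handle degenerate and ordinary cases", {
  mk <- function(name, accs, folds = rep(1:5, 4)) {
    list(classifier = name, per_fold = data.frame(accuracy = accs),
         folds = folds)
  }
  a <- mk("a", c(0.9, 0.9, 0.9, 0.9, 0.9))
  b <- mk("b", c(0.5, 0.5, 0.5, 0.5, 0.5))
  # compared with itself: p = 1, not significant
  same <- compare_classifiers(list(a, mk("a2", a$per_fold$accuracy)))
  expect_equal(same$p_values["a", "a2"], 1)
  expect_false(same$significant["a", "a2"])
  # constant non-zero difference: exact, significant
  diffc <- compare_classifiers(list(a, b))
  expect_equal(diffc$p_values["a", "b"], 0)
  expect_true(diffc$significant["a", "b"])
  # type-I control: same-distribution fold accuracies rarely reject
  set.seed(64)
  rejections <- vapply(1:20, function(i) {
    r1 <- mk("x", runif(5, 0.4, 0.6))
    r2 <- mk("y", runif(5, 0.4, 0.6))
    any(compare_classifiers(list(r1, r2))$significant[1, 2])
  }, TRUE)
  expect_lte(mean(rejections), 0.05 + 1e-9)
  expect_error(compare_classifiers(list(a, mk("c", runif(4)))),
               "mismatched")
})

test_that("fold-internal SMOTE avoids the leakage that corpus SMOTE shows", {
  set.seed(65)
  n <- 100
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  tbl <- fake_feature_table(X)
  y <- sample(rep(c("a", "b", "c", "d"), c(40, 30, 20, 10)))
  honest <- train_eval(tbl, y, "knn", k = 5, seed = 2, paper_mode = FALSE)
  leaky <- train_eval(tbl, y, "knn", k = 5, seed = 2, paper_mode = TRUE)
  # labels carry no signal, so honest evaluation sits near chance while
  # corpus-level balancing, whose synthetic rows straddle the fold split,
  # scores markedly higher
  expect_gt(leaky$accuracy, honest$accuracy + 0.1)
  expect_lt(honest$accuracy, 0.45)
})

test_that("the experiment grid has the width x classifier structure", {
  set.seed(66)
  n <- 120
  age <- runif(n, 17, 67)
  X <- cbind(sig1 = age + rnorm(n, sd = 3), sig2 = -0.5 * age + rnorm(n),
             nz = rnorm(n), gender = rep(0:1, n / 2))
  tbl <- fake_feature_table(X, age = age)
  rep <- run_experiment(tbl, widths = c(10, 25), classifiers = c("lda", "qda"),
                        k = 4, seed = 5)
  expect_equal(nrow(rep$report), 4)
  expect_setequal(rep$report$width, c(10, 25))
  expect_setequal(rep$report$classifier, c("lda", "qda"))
  expect_true(all(rep$report$accuracy >= 0 & rep$report$accuracy <= 1))
  expect_equal(rep$report$smote_mode, rep("fold", 4))
  expect_named(rep$significance, c("10", "25"))
  # coarser bins are easier on an age-informative table
  acc <- tapply(rep$report$accuracy, rep$report$width, mean)
  expect_gte(acc["25"], acc["10"])
  # CSV round trip of the report
  f <- tempfile(fileext = ".csv")
  write.csv(rep$report, f, row.names = FALSE)
  expect_equal(read.csv(f), data.frame(rep$report, row.names = NULL),
               tolerance = 1e-12)
})
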