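test_that("generic CSV loading parses features and maps labels", {
  p <- file.path(tempdir(), "tiny.csv")
  writeLines(c("f1,f2,class", "0.1,2,1", "0.2,3,0", "0.3,4,1"), p)
  d <- load_table(p, label_column = "class", positive_label = 1)
  expect_s3_class(d, "igk_dataset")
  expect_equal(dim(d), c(3L, 2L))
  expect_equal(as.character(d$labels), c("positive", "negative", "positive"))
  expect_equal(d$features[, "f2"], c(2, 3, 4))
})

test_that("loading rejects malformed inputs", {
  expect_error(load_table(file.path(tempdir(), "nope.csv")), "not found")
  p <- file.path(tempdir(), "bad.csv")
  writeLines(c("f1,class", "1,a", "2,b", "3,c"), p)
  expect_error(load_table(p, label_column = "class", positive_label = "a"),
               "two classes")
  writeLines(c("f1,class", "x,1", "y,0", "1,1"), p)
  expect_error(load_table(p, label_column = "class", positive_label = 1),
               "non-numeric")
  writeLines(c("f1,f2", "1,2", "3,4"), p)
  expect_error(load_table(p, label_column = "class", positive_label = 1),
               "label column")
})

test_that("parkinson adapter handles the voice-measure layout", {
  p <- write_synthetic_parkinson(file.path(tempdir(), "park.csv"))
  d <- load_table(p, adapter = "parkinson")
  expect_equal(dim(d), c(195L, 22L))
  expect_equal(sum(d$labels == "positive"), 147)
  expect_equal(sum(d$labels == "negative"), 48)
  expect_false("name" %in% colnames(d$features))
})

test_that("wdbc adapter drops the ID column and maps M to positive", {
  p <- write_synthetic_wdbc(file.path(tempdir(), "wdbc.csv"))
  d <- load_table(p, adapter = "wdbc")
  expect_equal(dim(d), c(569L, 30L))
  expect_equal(sum(d$labels == "negative"), 357)  # benign
  expect_equal(unname(d$label_values["positive"]), "M")
})

test_that("min-max scaling maps endpoints to +/-1 and constants to 0", {
  X <- cbind(a = c(0, 5, 10), b = c(-1, 0, 1), c = c(7, 7, 7))
  d <- dataset(X, c(1, 0, 1), positive_label = 1)
  s <- normalize_minmax(d)
  expect_equal(s$features[, "a"], c(-1, 0, 1))
  expect_equal(s$features[, "b"], c(-1, 0, 1))
  expect_equal(s$features[, "c"], c(0, 0, 0))
  expect_equal(d$features[, "a"], c(0, 5, 10))  # input untouched
})

test_that("min-max scaling is idempotent", {
  d <- random_dataset(n = 25, p = 4, seed = 3)
  once <- normalize_minmax(d)
  twice <- normalize_minmax(once)
  expect_lt(max(abs(once$features - twice$features)), 1e-12)
})

test_that("write/load round-trips the feature matrix exactly", {
  withr::with_seed(5, {
    X <- matrix(signif(rnorm(60), 15), 20)  # <= 15 significant digits
  })
  d <- dataset(X, rep(c("yes", "no"), 10), positive_label = "yes")
  p <- file.path(tempdir(), "rt.csv")
  write_dataset(d, p)
  d2 <- load_table(p, label_column = "class", positive_label = "yes")
  expect_identical(unname(d2$features), unname(d$features))
  expect_equal(as.character(d2$labels), as.character(d$labels))
})

test_that("synthetic generation is deterministic with the stated dimensions", {
  spec <- synthetic_spec(100, 5, 0, 15, class_separation = 2,
                         positive_fraction = 0.5, seed = 1)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$labels, d2$labels)
  expect_equal(dim(d1), c(100L, 20L))
})

test_that("synthetic label proportions match positive_fraction within one", {
  for (pf in c(0.25, 0.5, 0.754)) {
    d <- generate_synthetic(synthetic_spec(81, 2, 0, 1, seed = 4,
                                           positive_fraction = pf))
    expect_lte(abs(sum(d$labels == "positive") - pf * 81), 1)
  }
})

test_that("redundant features correlate with the informative block", {
  d <- generate_synthetic(synthetic_spec(200, 3, 2, 0, seed = 9))
  r2 <- summary(lm(d$features[, "red_1"] ~ d$features[, 1:3]))$r.squared
  expect_gt(r2, 0.9)
})

test_that("zero separation gives chance-level accuracy, wide separation high", {
  d0 <- normalize_minmax(generate_synthetic(
    synthetic_spec(100, 5, 0, 5, class_separation = 0, seed = 2)))
  p0 <- subset_fitness(rep(1, 10), d0)$accuracy
  expect_gt(p0, 0.35)
  expect_lt(p0, 0.65)
  # independent oracle: logistic regression CV on the separated data
  d4 <- normalize_minmax(generate_synthetic(
    synthetic_spec(100, 5, 0, 5, class_separation = 4, seed = 2)))
  p4 <- subset_fitness(rep(1, 10), d4)$accuracy
  expect_gt(p4, 0.9)
  df <- data.frame(d4$features, y = as.integer(d4$labels == "positive"))
  folds <- make_cv_plan(d4$labels, k = 10, repeats = 1, seed = 33)$folds[[1]]
  correct <- 0
  for (f in 1:10) {
    fit <- suppressWarnings(
      glm(y ~ ., data = df[folds != f, ], family = binomial))
    pr <- predict(fit, newdata = df[folds == f, ], type = "response") >= 0.5
    correct <- correct + sum(pr == (df$y[folds == f] == 1))
  }
  expect_gt(correct / 100, 0.9)
})
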