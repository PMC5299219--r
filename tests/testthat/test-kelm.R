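# independent transcription of the kernel and the regularized solve, used
# as the oracle throughout this file
oracle_kernel <- function(X, Y, gamma) {
  K <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(nrow(Y)))
      K[i, j] <- exp(-sum((X[i, ] - Y[j, ])^2) / (2 * gamma^2))
  K
}

oracle_decision <- function(data, X_new, C, gamma) {
  X <- data$features
  T_vec <- ifelse(data$labels == "positive", 1, -1)
  Omega <- oracle_kernel(X, X, gamma)
  W <- solve(Omega + diag(1 / C, nrow(X)), T_vec)
  drop(oracle_kernel(as.matrix(X_new), X, gamma) %*% W)
}

test_that("rbf kernel follows the 2-gamma-squared convention", {
  expect_equal(rbf_kernel(matrix(0), matrix(1), gamma = 0.5)[1, 1],
               exp(-2), tolerance = 1e-12)
  # the common exp(-gamma * d2) convention would give exp(-0.5) here
  expect_false(isTRUE(all.equal(rbf_kernel(matrix(0), matrix(1), 0.5)[1, 1],
                                exp(-0.5))))
  X <- matrix(rnorm(12), 4)
  K <- rbf_kernel(X, X, gamma = 1.3)
  expect_equal(diag(K), rep(1, 4))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_error(rbf_kernel(matrix(0, 1, 2), matrix(0, 1, 3), 1), "columns")
  expect_error(rbf_kernel(matrix(0), matrix(0), -1), "positive")
})

test_that("regularized solve matches the 1x1 closed form", {
  # one training sample, target +1, C = 32: w = (1 + 1/32)^-1 = 32/33
  W <- igwokelm:::kelm_solve(matrix(1 + 1 / 32), matrix(1))
  expect_equal(W[1, 1], 32 / 33, tolerance = 1e-12)
})

test_that("training matches an independent dense solve", {
  for (s in 1:5) {
    d <- random_dataset(n = 30, p = 5, seed = s)
    m <- kelm_train(d, kelm_config(C = 32, gamma = 0.5))
    expect_lt(m$residual, 1e-8)
    Xnew <- matrix(rnorm(20), 4)
    expect_equal(kelm_decision(m, Xnew),
                 oracle_decision(d, Xnew, 32, 0.5), tolerance = 1e-8)
  }
})

test_that("duplicated training rows keep the system solvable", {
  d <- random_dataset(n = 10, p = 3, seed = 2)
  d$features <- rbind(d$features, d$features)
  d$labels <- factor(rep(as.character(d$labels), 2),
                     levels = c("negative", "positive"))
  m <- kelm_train(d)
  expect_lt(m$residual, 1e-8)
})

test_that("regularized kernel matrix is positive definite", {
  for (s in 1:5) {
    d <- random_dataset(n = 15, p = 4, seed = 10 + s)
    C <- 2^sample(-5:5, 1)
    Omega <- rbf_kernel(d$features, d$features, 0.5)
    ev <- eigen(Omega + diag(1 / C, 15), symmetric = TRUE, only.values = TRUE)
    expect_gte(min(ev$values), 1 / C - 1e-10)
  }
})

test_that("predictions are invariant to permuting training rows", {
  d <- random_dataset(n = 25, p = 4, seed = 6)
  perm <- withr::with_seed(1, sample(25))
  dp <- d
  dp$features <- d$features[perm, ]
  dp$labels <- d$labels[perm]
  Xnew <- matrix(rnorm(40), 10)
  expect_equal(kelm_decision(kelm_train(d), Xnew),
               kelm_decision(kelm_train(dp), Xnew), tolerance = 1e-10)
})

test_that("vanishing regularization interpolates the training targets", {
  d <- random_dataset(n = 30, p = 4, seed = 3)
  m <- kelm_train(d, kelm_config(C = 1e8, gamma = 0.5))
  f <- kelm_decision(m, d$features)
  t_vec <- ifelse(d$labels == "positive", 1, -1)
  expect_equal(f, t_vec, tolerance = 1e-5)
  expect_identical(kelm_predict(m, d$features, encoded = TRUE), t_vec)
})

test_that("tiny kernel width shrinks decisions to C/(C+1) of the target", {
  d <- random_dataset(n = 12, p = 3, seed = 4)
  C <- 8
  m <- kelm_train(d, kelm_config(C = C, gamma = 1e-4))
  f <- kelm_decision(m, d$features)
  t_vec <- ifelse(d$labels == "positive", 1, -1)
  expect_equal(f, t_vec * C / (C + 1), tolerance = 1e-9)
})

test_that("sign rule breaks ties toward the positive class", {
  d <- random_dataset(n = 10, p = 2, seed = 5)
  m <- kelm_train(d)
  m$output_weights[] <- 0  # force decision values of exactly zero
  expect_true(all(kelm_predict(m, d$features, encoded = TRUE) == 1))
})

test_that("training accuracy is non-decreasing in C", {
  d <- normalize_minmax(random_dataset(n = 40, p = 5, seed = 8))
  t_vec <- ifelse(d$labels == "positive", 1, -1)
  acc <- vapply(2^(-5:5), function(C) {
    m <- kelm_train(d, kelm_config(C = C, gamma = 0.5))
    mean(kelm_predict(m, d$features, encoded = TRUE) == t_vec)
  }, numeric(1))
  # allow at most one sample of non-monotonicity
  expect_true(all(diff(acc) >= -1 / 40 - 1e-12))
})

test_that("model serialization round-trips predictions bit-exactly", {
  d <- random_dataset(n = 20, p = 4, seed = 9)
  m <- kelm_train(d)
  p <- file.path(tempdir(), "model.json")
  save_kelm(m, p)
  m2 <- load_kelm(p)
  Xnew <- matrix(rnorm(32), 8)
  expect_identical(kelm_decision(m2, Xnew), kelm_decision(m, Xnew))
  expect_identical(kelm_predict(m2, Xnew), kelm_predict(m, Xnew))
})
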