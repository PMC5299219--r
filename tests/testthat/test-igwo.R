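test_that("thresholding flags features at 0.5 and repairs empty subsets", {
  expect_equal(binarize(c(0.7, 0.2, 0.5)), c(1L, 0L, 1L))
  expect_equal(binarize(c(0.4, 0.1, 0.3)), c(1L, 0L, 0L))  # argmax repair
  expect_equal(binarize(c(0.2, 0.4, 0.4)), c(0L, 1L, 0L))  # tie -> lowest
  expect_equal(binarize(rep(1, 4)), rep(1L, 4))
  b <- binarize(c(1, 0, 1, 0))
  expect_identical(binarize(b), b)  # idempotent on binary input
  expect_error(binarize(c(0.5, 1.2)), "0, 1")
})

test_that("fitness arithmetic follows the accuracy/size scalarization", {
  w <- fitness_weights(0.99)
  expect_equal(w$beta, 0.01)
  expect_equal(fitness_from_accuracy(1, 22, 22, w), 0.99, tolerance = 1e-12)
  expect_equal(fitness_from_accuracy(0.9745, 9, 22, w),
               0.9706640909090909, tolerance = 1e-12)
  expect_equal(fitness_from_accuracy(0, 22, 22, w), 0)
  # bound: alpha + beta * (N - 1) / N is the maximum at L = 1
  withr::with_seed(2, {
    for (i in 1:50) {
      N <- sample(2:30, 1); L <- sample(N, 1); P <- runif(1)
      f <- fitness_from_accuracy(P, L, N, w)
      expect_gte(f, 0)
      expect_lte(f, 0.99 + 0.01 * (N - 1) / N)
    }
  })
})

test_that("subset scoring restricts columns and hits 0.99 when separable", {
  d <- normalize_minmax(separable_dataset(n = 40, n_pad = 3))
  full <- subset_fitness(rep(1, 4), d)
  expect_equal(full$accuracy, 1)
  expect_equal(full$fitness, 0.99, tolerance = 1e-12)
  solo <- subset_fitness(c(1, 0, 0, 0), d)
  expect_equal(solo$fitness, 0.99 * 1 + 0.01 * 3 / 4, tolerance = 1e-12)
})

test_that("training-accuracy and holdout inner plans are available", {
  d <- normalize_minmax(separable_dataset(n = 30, n_pad = 2))
  tr <- subset_fitness(c(1, 1, 1), d, eval_plan = inner_eval_plan("train"))
  expect_equal(tr$accuracy, 1)
  ho <- subset_fitness(c(1, 1, 1), d,
                       eval_plan = inner_eval_plan("holdout", seed = 5))
  expect_gte(ho$accuracy, 0.9)
})

test_that("wrapper histories are elitist and reproducible in every mode", {
  d <- normalize_minmax(separable_dataset(n = 30, n_pad = 4))
  for (mode in c("IGWO", "GWO", "GA")) {
    r1 <- run_wrapper(d, mode, pop_size = 5, iterations = 12, seed = 3,
                      eval_plan = inner_eval_plan(k = 5))
    r2 <- run_wrapper(d, mode, pop_size = 5, iterations = 12, seed = 3,
                      eval_plan = inner_eval_plan(k = 5))
    expect_identical(r1, r2)
    expect_length(r1$best_fitness_per_iteration, 13)
    expect_true(all(diff(r1$best_fitness_per_iteration) >= 0))
    expect_equal(r1$best_fitness_per_iteration[13], r1$best_fitness)
    expect_lte(r1$iterations_to_convergence, 12)
    expect_equal(r1$subset_size, sum(r1$best_flags))
  }
})

test_that("a perfectly separating feature is always selected", {
  # one separator among constant padding: any subset without it is at
  # chance accuracy, so the fitness gap is decisive
  withr::with_seed(31, {
    y <- rep(c(1, 0), 20)
    X <- cbind(ifelse(y == 1, 1, -1) + rnorm(40, sd = 0.05),
               matrix(0, 40, 9))
    colnames(X) <- c("signal", paste0("flat", 1:9))
  })
  d <- normalize_minmax(dataset(X, y, positive_label = 1))
  for (s in 1:10) {
    r <- run_wrapper(d, "IGWO", pop_size = 5, iterations = 15, seed = s,
                     eval_plan = inner_eval_plan(k = 5))
    expect_equal(unname(r$best_flags["signal"]), 1L)
  }
})

test_that("GA seeding starts the search at least as fit as a random start", {
  d <- normalize_minmax(generate_synthetic(
    synthetic_spec(100, 5, 0, 15, class_separation = 2, seed = 21)))
  wins <- 0
  for (s in 1:10) {
    a <- run_wrapper(d, "IGWO", iterations = 1, seed = s)
    b <- run_wrapper(d, "GWO", iterations = 1, seed = s)
    wins <- wins + (a$best_fitness_per_iteration[1] >=
                      b$best_fitness_per_iteration[1])
  }
  expect_gte(wins, 7)
})

test_that("selected features subset the dataset with names preserved", {
  d <- normalize_minmax(separable_dataset(n = 30, n_pad = 4))
  r <- run_wrapper(d, "GA", pop_size = 4, iterations = 5, seed = 2,
                   eval_plan = inner_eval_plan(k = 5))
  sel <- select_features(r, d)
  expect_equal(ncol(sel$features), r$subset_size)
  expect_true(all(colnames(sel$features) %in% colnames(d$features)))
  r$best_flags[] <- 1L
  r$subset_size <- 5L
  expect_identical(select_features(r, d)$features, d$features)
})

test_that("run artifacts are written as plot-ready CSV", {
  d <- normalize_minmax(separable_dataset(n = 30, n_pad = 2))
  r <- run_wrapper(d, "GA", pop_size = 4, iterations = 5, seed = 2,
                   eval_plan = inner_eval_plan(k = 5))
  hp <- file.path(tempdir(), "hist.csv")
  mp <- file.path(tempdir(), "mask.csv")
  write_run(r, hp, mp)
  h <- data.table::fread(hp)
  expect_equal(nrow(h), 6)
  expect_equal(h$best_fitness, r$best_fitness_per_iteration)
  m <- data.table::fread(mp)
  expect_equal(m$selected, unname(as.integer(r$best_flags)))
})
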