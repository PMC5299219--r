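#' Accuracy-vs-size weights of the subset objective
#'
#' The wrapper's scalar objective is
#' `fitness = alpha * P + beta * (N - L) / N`, where `P` is the
#' classification accuracy (a fraction in [0, 1]) of the candidate subset,
#' `L` the number of selected features, `N` the total feature count, and
#' `beta = 1 - alpha`. The default `alpha = 0.99` makes accuracy dominate
#' while still preferring the smaller of two equally accurate subsets.
#'
#' @param accuracy_weight Alpha in [0, 1]; default 0.99.
#' @return An object of class `igk_fitness_weights` with fields `alpha` and
#'   `beta`.
#' @export
fitness_weights <- function(accuracy_weight = 0.99) {
  stopifnot(accuracy_weight >= 0, accuracy_weight <= 1)
  structure(list(alpha = accuracy_weight, beta = 1 - accuracy_weight),
            class = "igk_fitness_weights")
}

#' Subset objective from a known accuracy
#'
#' The arithmetic of the scalarized objective, exposed separately so its
#' value can be checked against hand calculation.
#'
#' @param P Accuracy as a fraction in [0, 1].
#' @param L Number of selected features, `1 <= L <= N`.
#' @param N Total number of features.
#' @param weights A [fitness_weights()].
#' @return The fitness value in `[0, alpha + beta * (N - 1) / N]`.
#' @export
fitness_from_accuracy <- function(P, L, N, weights = fitness_weights()) {
  stopifnot(P >= 0, P <= 1, L >= 1, L <= N)
  weights$alpha * P + weights$beta * (N - L) / N
}

#' Threshold a continuous position into a feature flag vector
#'
#' Bit i is 1 when position i is at least 0.5. An all-zero result is
#' repaired by switching on the largest-valued component (ties to the
#' lowest index), because an empty subset cannot be scored.
#'
#' @param position Numeric vector with entries in [0, 1].
#' @return Integer 0/1 flag vector with at least one 1.
#' @export
binarize <- function(position) {
  if (any(position < 0 | position > 1)) stop("position entries must lie in [0, 1]")
  flags <- as.integer(position >= 0.5)
  if (all(flags == 0L)) flags[which.max(position)] <- 1L
  flags
}

# stochastic sigmoid transfer alternative: bit i is 1 with probability
# sigmoid(10 * (x - 0.5)); fitness still depends only on the realized flags
binarize_sigmoid <- function(position, rng = stats::runif) {
  s <- 1 / (1 + exp(-10 * (position - 0.5)))
  flags <- as.integer(rng(length(position)) < s)
  if (all(flags == 0L)) flags[which.max(position)] <- 1L
  flags
}

#' Inner evaluation plan for the subset objective
#'
#' How the accuracy `P` of a candidate subset is measured inside the
#' wrapper. The default is stratified k-fold cross-validation (k = 10) on
#' the data handed to the wrapper, with its own fixed seed independent of
#' the optimizer seed — this makes the objective a deterministic function
#' of the flag vector. Alternatives: `"train"` (apparent accuracy on the
#' training data) and `"holdout"` (single stratified split with
#' `holdout_fraction` held out).
#'
#' @param method One of `"cv"`, `"train"`, `"holdout"`.
#' @param k Folds for `"cv"`; capped at the smaller class size so every
#'   fold keeps both classes.
#' @param seed Seed of the inner split, independent of the optimizer seed.
#' @param holdout_fraction Test fraction for `"holdout"`.
#' @return An object of class `igk_eval_plan`.
#' @export
inner_eval_plan <- function(method = c("cv", "train", "holdout"), k = 10,
                            seed = 20211, holdout_fraction = 0.3) {
  method <- match.arg(method)
  stopifnot(k >= 2, holdout_fraction > 0, holdout_fraction < 1)
  structure(list(method = method, k = as.integer(k), seed = as.integer(seed),
                 holdout_fraction = holdout_fraction),
            class = "igk_eval_plan")
}

# materialize the inner split once per dataset so every fitness evaluation
# reuses identical folds
inner_folds <- function(data, plan) {
  if (plan$method == "train") return(NULL)
  k <- min(plan$k, min(table(data$labels)))
  if (k < 2) stop("inner evaluation needs at least two samples per class")
  if (plan$method == "cv") {
    cv <- make_cv_plan(data$labels, k = k, repeats = 1, seed = plan$seed)
    return(cv$folds[[1]])
  }
  # holdout: fold 1 = test, fold 2 = train
  withr::with_seed(plan$seed, {
    test <- logical(length(data$labels))
    for (cl in levels(data$labels)) {
      idx <- which(data$labels == cl)
      n_test <- max(1L, round(plan$holdout_fraction * length(idx)))
      test[sample(idx, n_test)] <- TRUE
    }
    ifelse(test, 1L, 2L)
  })
}

# accuracy of a KELM on the flagged features under a materialized split
subset_accuracy <- function(flags, data, kelm_config, plan, folds) {
  d <- subset_dataset(data, flags)
  if (plan$method == "train") {
    model <- kelm_train(d, kelm_config)
    pred <- kelm_predict(model, d$features, encoded = TRUE)
    return(mean(pred == label_targets(d)))
  }
  fold_ids <- if (plan$method == "holdout") 1L else sort(unique(folds))
  correct <- 0L; total <- 0L
  for (f in fold_ids) {
    test <- folds == f
    train_data <- d
    train_data$features <- d$features[!test, , drop = FALSE]
    train_data$labels <- d$labels[!test]
    model <- kelm_train(train_data, kelm_config)
    pred <- kelm_predict(model, d$features[test, , drop = FALSE], encoded = TRUE)
    correct <- correct + sum(pred == label_targets(d)[test])
    total <- total + sum(test)
  }
  correct / total
}

#' Score one feature subset
#'
#' Restricts the dataset to the flagged features, measures the KELM
#' accuracy `P` under the inner evaluation plan, and returns the scalarized
#' objective `alpha * P + beta * (N - L) / N`.
#'
#' @param flags 0/1 flag vector over all features (at least one 1).
#' @param data An [dataset()] object, already normalized.
#' @param kelm_config A [kelm_config()].
#' @param weights A [fitness_weights()].
#' @param eval_plan An [inner_eval_plan()].
#' @return List with `fitness` and `accuracy` (P as a fraction).
#' @export
subset_fitness <- function(flags, data, kelm_config = igwokelm::kelm_config(),
                           weights = fitness_weights(),
                           eval_plan = inner_eval_plan()) {
  stopifnot(inherits(data, "igk_dataset"))
  folds <- inner_folds(data, eval_plan)
  P <- subset_accuracy(flags, data, kelm_config, eval_plan, folds)
  list(fitness = fitness_from_accuracy(P, sum(flags), length(flags), weights),
       accuracy = P)
}
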