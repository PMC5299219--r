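#' Evaluate a feature-selection method under repeated stratified k-fold CV
#'
#' The reporting protocol: for each repeat, the wrapper is run once (with a
#' repeat-specific optimizer seed) to pick a feature subset, and the KELM
#' restricted to that subset is then scored over the repeat's k test folds;
#' the confusion counts are pooled across the folds (micro-averaging) and
#' converted to the six metrics. The report aggregates mean and standard
#' deviation over repeats, together with the subset size and a per-feature
#' selection-frequency table.
#'
#' Running the selection once per repeat on the full data matches the
#' one-subset-size-per-repeat bookkeeping of the published protocol but
#' lets the test folds influence selection; `per_fold = TRUE` switches to
#' the leakage-safe variant (selection re-run on every training fold, k
#' wrapper runs per repeat, frequency counted per fold in `0..k`).
#' Macro-averaging (metrics per fold, then averaged) is available with
#' `average = "macro"`.
#'
#' @param data An [dataset()] object.
#' @param mode Wrapper search mode: `"IGWO"`, `"GWO"` or `"GA"`.
#' @param plan An [make_cv_plan()]; defaults to 10 x 10-fold stratified CV
#'   seeded from `seed`.
#' @param pop_size,iterations Wrapper settings; defaults 8 and 100.
#' @param kelm_config,weights,eval_plan Passed to [run_wrapper()].
#' @param normalize `"global"` (scale the whole table once, the published
#'   protocol), `"per_fold"` (scaling fitted on each training fold only) or
#'   `"none"` (data already scaled).
#' @param per_fold Re-run selection inside every training fold (see above).
#' @param average `"micro"` (pool confusion counts across folds, default)
#'   or `"macro"`.
#' @param f_beta F-measure weight; default 1.
#' @param seed Base seed; repeat r uses optimizer seed `seed + 7919 * r`.
#' @return An object of class `igk_eval`: `per_repeat` (data frame of the
#'   six metrics and subset size per repeat), `summary` (mean and sd per
#'   quantity), `frequency` (per-feature selection counts: over repeats, or
#'   mean per-fold counts in `0..k` when `per_fold = TRUE`), `mode`, `plan`.
#' @export
evaluate_method <- function(data, mode = "IGWO", plan = NULL, pop_size = 8,
                            iterations = 100, kelm_config = igwokelm::kelm_config(),
                            weights = fitness_weights(),
                            eval_plan = inner_eval_plan(),
                            normalize = c("global", "per_fold", "none"),
                            per_fold = FALSE,
                            average = c("micro", "macro"),
                            f_beta = 1, seed = 1) {
  normalize <- match.arg(normalize)
  average <- match.arg(average)
  stopifnot(inherits(data, "igk_dataset"))
  if (is.null(plan)) plan <- make_cv_plan(data$labels, seed = seed)
  if (normalize == "global") data <- normalize_minmax(data)

  n_feat <- ncol(data$features)
  freq <- numeric(n_feat)
  rows <- vector("list", plan$repeats)

  for (r in seq_len(plan$repeats)) {
    folds <- plan$folds[[r]]
    run_seed <- as.integer(seed) + 7919L * r
    if (!per_fold) {
      run <- run_wrapper(data, mode = mode, pop_size = pop_size,
                         iterations = iterations, kelm_config = kelm_config,
                         weights = weights, eval_plan = eval_plan,
                         seed = run_seed)
      flags_per_fold <- rep(list(run$best_flags), plan$k)
      freq <- freq + run$best_flags
      size_r <- run$subset_size
    } else {
      flags_per_fold <- vector("list", plan$k)
      for (f in seq_len(plan$k)) {
        tr <- fold_subset(data, folds != f)
        run_f <- run_wrapper(tr, mode = mode, pop_size = pop_size,
                             iterations = iterations,
                             kelm_config = kelm_config, weights = weights,
                             eval_plan = eval_plan,
                             seed = run_seed + f)
        flags_per_fold[[f]] <- run_f$best_flags
      }
      sel <- Reduce(`+`, flags_per_fold)
      freq <- freq + sel / plan$k        # mean per-fold count, still 0..1 per repeat scale below
      size_r <- mean(vapply(flags_per_fold, sum, numeric(1)))
    }
    rows[[r]] <- score_repeat(data, folds, flags_per_fold, kelm_config,
                              normalize, average, f_beta)
    rows[[r]]$subset_size <- size_r
    rows[[r]]$repeat_id <- r
  }

  per_repeat <- do.call(rbind, lapply(rows, as.data.frame))
  per_repeat <- per_repeat[, c("repeat_id", "subset_size", metric_names)]
  qty <- c("subset_size", metric_names)
  summary <- data.frame(
    quantity = qty,
    mean = vapply(qty, function(q) mean(per_repeat[[q]]), numeric(1)),
    sd = vapply(qty, function(q) sd(per_repeat[[q]]), numeric(1)),
    row.names = NULL
  )
  frequency <- data.frame(
    feature = colnames(data$features),
    times_selected = if (per_fold) plan$k * freq / plan$repeats else freq,
    row.names = NULL
  )
  structure(list(mode = mode, per_repeat = per_repeat, summary = summary,
                 frequency = frequency, per_fold = per_fold,
                 plan = plan, seed = as.integer(seed)),
            class = "igk_eval")
}

fold_subset <- function(data, keep) {
  out <- data
  out$features <- data$features[keep, , drop = FALSE]
  out$labels <- data$labels[keep]
  out
}

# score one repeat: train on k-1 folds / test on the held-out fold with the
# repeat's selected features; pool or macro-average across folds
score_repeat <- function(data, folds, flags_per_fold, kelm_config,
                         normalize, average, f_beta) {
  k <- max(folds)
  cms <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    flags <- flags_per_fold[[f]]
    tr <- fold_subset(data, !test)
    te_feat <- data$features[test, , drop = FALSE]
    if (normalize == "per_fold") {
      fit <- minmax_fit(tr$features)
      tr$features <- minmax_apply(tr$features, fit)
      te_feat <- minmax_apply(te_feat, fit)
    }
    model <- kelm_train(subset_dataset(tr, flags), kelm_config)
    pred <- kelm_predict(model, te_feat[, flags == 1, drop = FALSE],
                         encoded = TRUE)
    cms[[f]] <- confusion(label_targets(data)[test], pred, positive = 1)
  }
  if (average == "micro") {
    pooled <- structure(list(TP = sum(vapply(cms, `[[`, 0L, "TP")),
                             FP = sum(vapply(cms, `[[`, 0L, "FP")),
                             FN = sum(vapply(cms, `[[`, 0L, "FN")),
                             TN = sum(vapply(cms, `[[`, 0L, "TN"))),
                        class = "igk_confusion")
    m <- classification_metrics(pooled, f_beta)
    return(m[metric_names])
  }
  per <- lapply(cms, classification_metrics, f_beta = f_beta)
  out <- lapply(metric_names, function(nm)
    mean(vapply(per, `[[`, numeric(1), nm)))
  names(out) <- metric_names
  out
}

#' @export
print.igk_eval <- function(x, ...) {
  cat(sprintf("<igk_eval> %s, %d x %d-fold CV\n",
              x$mode, x$plan$repeats, x$plan$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$quantity[i] == "subset_size") {
      cat(sprintf("  %-12s %6.2f +/- %.2f\n", "features", s$mean[i], s$sd[i]))
    } else {
      cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", s$quantity[i],
                  100 * s$mean[i], 100 * s$sd[i]))
    }
  }
  invisible(x)
}

#' Compare the three search modes side by side
#'
#' Runs [evaluate_method()] for IGWO, GWO and GA on the same CV plan and
#' returns the stacked summaries (the layout of the published comparison
#' tables).
#'
#' @inheritParams evaluate_method
#' @param modes Character vector of modes to compare.
#' @return List with `table` (data frame: method, quantity, mean, sd) and
#'   `evals` (the per-mode `igk_eval` objects).
#' @export
compare_methods <- function(data, modes = c("IGWO", "GWO", "GA"),
                            plan = NULL, ..., seed = 1) {
  if (is.null(plan)) plan <- make_cv_plan(data$labels, seed = seed)
  evals <- lapply(modes, function(m)
    evaluate_method(data, mode = m, plan = plan, ..., seed = seed))
  names(evals) <- modes
  tab <- do.call(rbind, lapply(modes, function(m)
    cbind(method = m, evals[[m]]$summary)))
  list(table = tab, evals = evals)
}

#' Sweep one wrapper parameter
#'
#' Re-evaluates a method for each value of `pop_size` or `iterations`,
#' holding everything else fixed — the layout used to justify the default
#' population size (4..20 step 4) and iteration count (50..250 step 50).
#'
#' @inheritParams evaluate_method
#' @param parameter `"pop_size"` or `"iterations"`.
#' @param values Numeric vector of parameter values (non-empty).
#' @return Data frame with one row per value: the parameter value, then
#'   mean and sd of subset size and each metric.
#' @export
sweep_parameter <- function(data, parameter = c("pop_size", "iterations"),
                            values, mode = "IGWO", plan = NULL, ...,
                            seed = 1) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1)
  if (is.null(plan)) plan <- make_cv_plan(data$labels, seed = seed)
  rows <- lapply(values, function(v) {
    args <- list(data = data, mode = mode, plan = plan, seed = seed, ...)
    args[[parameter]] <- v
    ev <- do.call(evaluate_method, args)
    s <- ev$summary
    row <- data.frame(value = v)
    for (i in seq_len(nrow(s))) {
      row[[paste0(s$quantity[i], "_mean")]] <- s$mean[i]
      row[[paste0(s$quantity[i], "_sd")]] <- s$sd[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- parameter
  out
}
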