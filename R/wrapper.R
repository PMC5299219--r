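#' Run the feature-selection wrapper
#'
#' The three search modes share the subset objective
#' `alpha * P + beta * (N - L) / N` ([subset_fitness()]):
#'
#' * `"IGWO"` — the GA-diversified grey wolf search: a single-pass genetic
#'   algorithm ([generate_initial_positions()]) seeds the initial binary
#'   positions, then the grey-wolf update moves continuous positions in
#'   `[0, 1]^N`, which are thresholded to flag vectors only for fitness
#'   evaluation. GA seeding is not counted against the iteration budget.
#' * `"GWO"` — identical, but seeded with random binary positions (the GA
#'   initialization step without the genetic refinement pass), so the two
#'   wolf modes differ only in the seeding scheme.
#' * `"GA"` — a pure genetic algorithm (roulette selection, single-point
#'   crossover, uniform mutation, elitism of one) run for `iterations`
#'   generations, as the comparison baseline.
#'
#' Leaders (or the GA elite) are best-so-far, so the recorded best-fitness
#' history is monotone non-decreasing. Because the inner evaluation seed is
#' fixed, fitness is a pure function of the flag vector and evaluations are
#' memoized within the run.
#'
#' @param data A normalized [dataset()] object.
#' @param mode One of `"IGWO"`, `"GWO"`, `"GA"`.
#' @param pop_size Population size (>= 3 for the wolf modes); default 8.
#' @param iterations Update iterations / GA generations; default 100.
#' @param kelm_config A [kelm_config()] for the inner classifier.
#' @param weights A [fitness_weights()].
#' @param eval_plan An [inner_eval_plan()] for measuring P.
#' @param ga_config An [ga_config()]; used for IGWO seeding and GA mode
#'   (its `pop_size` is overridden by `pop_size`).
#' @param transfer Rule mapping a continuous position to flags at
#'   evaluation time. `"sigmoid"` (default): bit i is 1 with probability
#'   `1/(1 + exp(-10 * (x_i - 0.5)))`, the stochastic transfer standard in
#'   binary swarm optimizers — it keeps the discrete search sampling new
#'   subsets even after the continuous positions have contracted onto the
#'   leaders. `"threshold"`: deterministic bit = position >= 0.5; simpler,
#'   but once the population collapses onto the leaders every subsequent
#'   evaluation repeats the same subset, so the discrete search
#'   effectively stops at that point.
#' @param seed Integer seed for the optimizer; independent of the inner
#'   evaluation seed.
#' @return An object of class `igk_run`: `mode`, `seed`,
#'   `best_fitness_per_iteration` (length `iterations + 1`), `best_flags`
#'   (named 0/1 vector), `best_fitness`, `best_accuracy` (P of the best
#'   subset), `subset_size`, `iterations_to_convergence` (first iteration
#'   index after which the best fitness never changes), and
#'   `n_evaluations` (distinct subsets scored).
#' @export
run_wrapper <- function(data, mode = c("IGWO", "GWO", "GA"), pop_size = 8,
                        iterations = 100, kelm_config = igwokelm::kelm_config(),
                        weights = fitness_weights(),
                        eval_plan = inner_eval_plan(),
                        ga_config = NULL,
                        transfer = c("sigmoid", "threshold"), seed = 1) {
  mode <- match.arg(mode)
  transfer <- match.arg(transfer)
  stopifnot(inherits(data, "igk_dataset"), iterations >= 1)
  if (mode != "GA" && pop_size < 3)
    stop("the wolf modes need a population of at least 3")
  if (is.null(ga_config)) ga_config <- igwokelm::ga_config(pop_size = pop_size)
  ga_config$pop_size <- as.integer(pop_size)
  n_feat <- ncol(data$features)

  folds <- inner_folds(data, eval_plan)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fit_fn <- function(flags) {
    key <- paste(flags, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    P <- subset_accuracy(flags, data, kelm_config, eval_plan, folds)
    res <- list(fitness = fitness_from_accuracy(P, sum(flags), n_feat, weights),
                accuracy = P)
    stopifnot(res$fitness >= 0,
              res$fitness <= weights$alpha + weights$beta * (n_feat - 1) / n_feat)
    cache[[key]] <- res
    res
  }

  out <- withr::with_seed(as.integer(seed), {
    if (mode == "GA") {
      wrapper_ga(n_feat, fit_fn, ga_config, iterations)
    } else {
      wrapper_gwo(n_feat, fit_fn, mode, pop_size, iterations, ga_config,
                  transfer)
    }
  })

  names(out$best_flags) <- colnames(data$features)
  history <- out$history
  last <- history[length(history)]
  # first index (0-based iteration) after which best fitness never changes
  changed <- which(history != last)
  conv_iter <- if (length(changed) == 0) 0L else as.integer(max(changed))
  structure(list(mode = mode, seed = as.integer(seed),
                 best_fitness_per_iteration = history,
                 best_flags = out$best_flags,
                 best_fitness = out$best_fitness,
                 best_accuracy = out$best_accuracy,
                 subset_size = sum(out$best_flags),
                 iterations_to_convergence = conv_iter,
                 n_evaluations = length(ls(cache))),
            class = "igk_run")
}

#' @export
print.igk_run <- function(x, ...) {
  cat(sprintf("<igk_run> mode=%s seed=%d: best fitness %.6f (P=%.4f, %d/%d features), converged at iteration %d\n",
              x$mode, x$seed, x$best_fitness, x$best_accuracy,
              x$subset_size, length(x$best_flags),
              x$iterations_to_convergence))
  invisible(x)
}

# wolf-mode main loop: continuous positions, binarized per evaluation
wrapper_gwo <- function(n_feat, fit_fn, mode, pop_size, iterations,
                        ga_config, transfer) {
  bin <- if (transfer == "threshold") binarize else binarize_sigmoid
  # GWO starts from the same random binary encoding the GA initialization
  # uses, so GA refinement is the only difference between the two modes.
  # Solutions scored during GA seeding were "obtained" by the search, so
  # they join the best-so-far leader bookkeeping (their flag vectors are
  # themselves valid binary positions).
  seed_archive <- list()
  pos <- if (mode == "IGWO") {
    generate_initial_positions(n_feat, function(fl) {
      ev <- fit_fn(fl)
      seed_archive[[length(seed_archive) + 1L]] <<- list(flags = fl, ev = ev)
      ev$fitness
    }, ga_config)
  } else {
    genes <- init_chromosomes(pop_size, n_feat)
    storage.mode(genes) <- "double"
    genes
  }
  flag_list <- lapply(seq_len(pop_size), function(i) bin(pos[i, ]))
  evals <- lapply(flag_list, fit_fn)
  fitness <- vapply(evals, `[[`, numeric(1), "fitness")
  leaders <- init_leaders(fitness, lapply(seq_len(pop_size), function(i)
    list(pos = pos[i, ], flags = flag_list[[i]],
         accuracy = evals[[i]]$accuracy)))
  for (rec in seed_archive) {
    leaders <- update_leaders(leaders, 0L, rec$ev$fitness,
                              list(pos = as.double(rec$flags),
                                   flags = rec$flags,
                                   accuracy = rec$ev$accuracy))
  }
  history <- numeric(iterations + 1)
  history[1] <- leaders[[1]]$fitness
  for (t in seq_len(iterations)) {
    a <- coefficient_a(t, iterations)
    lead_pos <- lapply(leaders, function(l) l$payload$pos)
    for (i in seq_len(pop_size)) {
      pos[i, ] <- update_position(pos[i, ], lead_pos, a, lo = 0, hi = 1)
      flags <- bin(pos[i, ])
      ev <- fit_fn(flags)
      leaders <- update_leaders(leaders, i, ev$fitness,
                                list(pos = pos[i, ], flags = flags,
                                     accuracy = ev$accuracy))
    }
    history[t + 1] <- leaders[[1]]$fitness
  }
  list(history = history,
       best_flags = leaders[[1]]$payload$flags,
       best_fitness = leaders[[1]]$fitness,
       best_accuracy = leaders[[1]]$payload$accuracy)
}

# pure-GA baseline: generational replacement with elitism of one
wrapper_ga <- function(n_feat, fit_fn, ga_config, iterations) {
  genes <- init_chromosomes(ga_config$pop_size, n_feat)
  evals <- lapply(seq_len(nrow(genes)), function(i) fit_fn(genes[i, ]))
  fitness <- vapply(evals, `[[`, numeric(1), "fitness")
  best_i <- which.max(fitness)
  best <- list(flags = genes[best_i, ], fitness = fitness[best_i],
               accuracy = evals[[best_i]]$accuracy)
  history <- numeric(iterations + 1)
  history[1] <- best$fitness
  for (g in seq_len(iterations)) {
    genes <- ga_generation(genes, fitness, ga_config)
    genes[1, ] <- best$flags  # elitism of one
    evals <- lapply(seq_len(nrow(genes)), function(i) fit_fn(genes[i, ]))
    fitness <- vapply(evals, `[[`, numeric(1), "fitness")
    best_i <- which.max(fitness)
    if (fitness[best_i] > best$fitness) {
      best <- list(flags = genes[best_i, ], fitness = fitness[best_i],
                   accuracy = evals[[best_i]]$accuracy)
    }
    history[g + 1] <- best$fitness
  }
  list(history = history, best_flags = best$flags,
       best_fitness = best$fitness, best_accuracy = best$accuracy)
}

#' Restrict a dataset to a run's selected features
#'
#' @param run An [run_wrapper()] result.
#' @param data The [dataset()] the run was performed on.
#' @return The column-restricted [dataset()] with feature names preserved.
#' @export
select_features <- function(run, data) {
  stopifnot(inherits(run, "igk_run"), inherits(data, "igk_dataset"),
            length(run$best_flags) == ncol(data$features))
  subset_dataset(data, run$best_flags)
}

#' Write a run's convergence history and feature mask
#'
#' Emits the plot-ready convergence-curve data (iteration, best fitness)
#' and the named 0/1 feature mask as CSV files.
#'
#' @param run An [run_wrapper()] result.
#' @param history_path,mask_path Output CSV paths (either may be `NULL` to
#'   skip).
#' @return `run`, invisibly.
#' @export
write_run <- function(run, history_path = NULL, mask_path = NULL) {
  stopifnot(inherits(run, "igk_run"))
  if (!is.null(history_path)) {
    data.table::fwrite(data.frame(
      iteration = seq_along(run$best_fitness_per_iteration) - 1L,
      best_fitness = run$best_fitness_per_iteration), history_path)
  }
  if (!is.null(mask_path)) {
    data.table::fwrite(data.frame(feature = names(run$best_flags),
                                  selected = as.integer(run$best_flags)),
                       mask_path)
  }
  invisible(run)
}
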