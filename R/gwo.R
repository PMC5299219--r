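#' Replay a pre-recorded uniform stream
#'
#' The optimizer draws its randomness through a stream abstraction: any
#' function `f(n)` returning `n` uniforms on (0, 1). `replay_rng` builds such
#' a stream from a fixed vector, which lets a test transcribe the position
#' update step by step against recorded draws.
#'
#' @param values Numeric vector of draws to replay in order.
#' @return A function `f(n)`; errors when the recording is exhausted.
#' @export
replay_rng <- function(values) {
  pos <- 0L
  function(n) {
    if (pos + n > length(values)) stop("replay_rng: recording exhausted")
    out <- values[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
}

#' Exploration coefficient schedule
#'
#' The scalar `a` decays linearly from 2 at the first iteration to 0 at the
#' last: `2 * (1 - t/T)`. Early iterations (|A| can exceed 1) explore; late
#' iterations (|A| < 1) converge on the leaders.
#'
#' @param t Iteration index, `0 <= t <= T`.
#' @param T_max Total iterations, >= 1.
#' @return The coefficient value in [0, 2].
#' @export
coefficient_a <- function(t, T_max) {
  if (T_max < 1) stop("T_max must be >= 1")
  if (t < 0 || t > T_max) stop("t must lie in [0, T_max]")
  2 * (1 - t / T_max)
}

#' Rank a population into alpha/beta/delta leaders
#'
#' Indices of the three largest fitness values in descending order, ties
#' broken toward the lowest index.
#'
#' @param fitnesses Numeric vector, length >= 3; higher is better.
#' @return Integer vector `c(alpha, beta, delta)`.
#' @export
rank_wolves <- function(fitnesses) {
  if (length(fitnesses) < 3) stop("at least three wolves are required")
  order(fitnesses, seq_along(fitnesses), decreasing = c(TRUE, FALSE),
        method = "radix")[1:3]
}

#' One grey-wolf position update
#'
#' For each leader l in order (alpha, beta, delta) the update draws, per
#' dimension, fresh `r1` then `r2`, forms `A = 2*a*r1 - a` and `C = 2*r2`,
#' computes the encircling distance `D = |C * X_l - X|` and the candidate
#' `X_l' = X_l - A * D`. The new position is the mean of the three
#' candidates, clipped to the box `[lo, hi]`.
#'
#' @param wolf Numeric position vector.
#' @param leaders List of three position vectors (alpha, beta, delta) or a
#'   3-row matrix.
#' @param a Scalar in [0, 2] from [coefficient_a()].
#' @param rng Uniform stream `f(n)`; defaults to the ambient R RNG. Draw
#'   order is r1 (all dims) then r2 (all dims), leader by leader.
#' @param lo,hi Box constraints of the search domain.
#' @return Updated, clipped position vector.
#' @export
update_position <- function(wolf, leaders, a, rng = stats::runif,
                            lo = 0, hi = 1) {
  if (is.matrix(leaders)) leaders <- lapply(seq_len(nrow(leaders)), function(i) leaders[i, ])
  stopifnot(length(leaders) == 3, a >= 0, a <= 2)
  d <- length(wolf)
  if (any(vapply(leaders, length, integer(1)) != d))
    stop("wolf and leaders must share a dimension")
  acc <- numeric(d)
  for (l in leaders) {
    r1 <- rng(d)
    r2 <- rng(d)
    A <- 2 * a * r1 - a
    C <- 2 * r2
    D <- abs(C * l - wolf)
    acc <- acc + (l - A * D)
  }
  pmin(pmax(acc / 3, lo), hi)
}

# strict-improvement leader bookkeeping: incumbents with equal fitness are
# kept (stability), and leaders are best-so-far across all iterations.
update_leaders <- function(leaders, idx, fitness, payload) {
  if (fitness > leaders[[1]]$fitness) {
    leaders[[3]] <- leaders[[2]]; leaders[[2]] <- leaders[[1]]
    leaders[[1]] <- list(fitness = fitness, payload = payload, idx = idx)
  } else if (fitness > leaders[[2]]$fitness) {
    leaders[[3]] <- leaders[[2]]
    leaders[[2]] <- list(fitness = fitness, payload = payload, idx = idx)
  } else if (fitness > leaders[[3]]$fitness) {
    leaders[[3]] <- list(fitness = fitness, payload = payload, idx = idx)
  }
  leaders
}

init_leaders <- function(fitnesses, payloads) {
  top <- rank_wolves(fitnesses)
  lapply(top, function(i) list(fitness = fitnesses[i], payload = payloads[[i]],
                               idx = i))
}

#' Continuous grey wolf optimization
#'
#' Maximizes `objective` over a box. Positions start uniform in the domain;
#' each iteration updates the decay coefficient, moves every wolf toward the
#' alpha/beta/delta leaders via [update_position()], re-evaluates and
#' re-ranks. Leaders are best-so-far, so the best-fitness history is
#' monotone non-decreasing.
#'
#' @param objective Function position-vector -> finite scalar fitness
#'   (higher is better).
#' @param dim Problem dimension.
#' @param pop_size Number of wolves (>= 3); default 8.
#' @param iterations Number of update iterations; default 100.
#' @param domain Numeric `c(lo, hi)` box applied to every dimension.
#' @param seed Integer seed; runs are bit-identical given the same seed.
#' @return List with `best_position`, `best_fitness`, and `history` (best
#'   fitness after initialization and after each iteration; length
#'   `iterations + 1`).
#' @export
gwo_minimize <- function(objective, dim, pop_size = 8, iterations = 100,
                         domain = c(0, 1), seed = 1) {
  stopifnot(pop_size >= 3, iterations >= 1, dim >= 1,
            length(domain) == 2, domain[1] < domain[2])
  withr::with_seed(as.integer(seed), {
    lo <- domain[1]; hi <- domain[2]
    pos <- matrix(runif(pop_size * dim, lo, hi), pop_size, dim)
    evals <- apply(pos, 1, objective)
    if (any(!is.finite(evals))) stop("objective returned a non-finite value")
    leaders <- init_leaders(evals, lapply(seq_len(pop_size), function(i) pos[i, ]))
    history <- numeric(iterations + 1)
    history[1] <- leaders[[1]]$fitness
    for (t in seq_len(iterations)) {
      a <- coefficient_a(t, iterations)
      lead_pos <- lapply(leaders, `[[`, "payload")
      for (i in seq_len(pop_size)) {
        pos[i, ] <- update_position(pos[i, ], lead_pos, a, lo = lo, hi = hi)
      }
      evals <- apply(pos, 1, objective)
      if (any(!is.finite(evals))) stop("objective returned a non-finite value")
      for (i in seq_len(pop_size)) {
        leaders <- update_leaders(leaders, i, evals[i], pos[i, ])
      }
      history[t + 1] <- leaders[[1]]$fitness
    }
    list(best_position = leaders[[1]]$payload,
         best_fitness = leaders[[1]]$fitness,
         history = history)
  })
}
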