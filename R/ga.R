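#' Genetic-algorithm settings for population seeding
#'
#' @param crossover_prob Probability of single-point crossover per selected
#'   pair; default 0.8.
#' @param mutation_prob Per-gene flip probability of uniform mutation;
#'   default 0.01.
#' @param generations Number of selection/crossover/mutation passes before
#'   decoding; default 1, matching the single-pass seeding scheme. Larger
#'   values add generational replacement with elitism of one.
#' @param pop_size Number of chromosomes.
#' @return An object of class `igk_ga_config`.
#' @export
ga_config <- function(crossover_prob = 0.8, mutation_prob = 0.01,
                      generations = 1, pop_size = 8) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            generations >= 1, pop_size >= 2)
  structure(list(crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 generations = as.integer(generations),
                 pop_size = as.integer(pop_size)),
            class = "igk_ga_config")
}

# an empty gene vector selects no features and cannot be scored; switch one
# uniformly chosen gene on
repair_all_zero <- function(genes, rng = stats::runif) {
  if (any(genes == 1)) return(genes)
  genes[floor(rng(1) * length(genes)) + 1L] <- 1L
  genes
}

#' Random initial chromosomes
#'
#' Each gene is an independent fair coin; all-zero chromosomes are repaired
#' by switching on one uniformly chosen gene, since an empty feature subset
#' cannot be scored.
#'
#' @param pop_size Number of chromosomes (>= 2).
#' @param n_features Genes per chromosome (>= 1).
#' @param rng Uniform stream `f(n)`; defaults to the ambient R RNG.
#' @return Integer 0/1 matrix `pop_size x n_features`.
#' @export
init_chromosomes <- function(pop_size, n_features, rng = stats::runif) {
  stopifnot(pop_size >= 2, n_features >= 1)
  genes <- matrix(as.integer(rng(pop_size * n_features) < 0.5),
                  pop_size, n_features)
  for (i in seq_len(pop_size)) genes[i, ] <- repair_all_zero(genes[i, ], rng)
  genes
}

#' Fitness-proportional (roulette-wheel) selection
#'
#' @param fitnesses Non-negative weights with a positive sum; selection
#'   probability of index i is `fitnesses[i] / sum(fitnesses)`.
#' @param rng Uniform stream `f(n)`.
#' @return A selected index.
#' @export
roulette_select <- function(fitnesses, rng = stats::runif) {
  if (any(fitnesses < 0)) stop("roulette selection needs non-negative fitness")
  tot <- sum(fitnesses)
  if (tot <= 0) stop("at least one fitness must be strictly positive")
  findInterval(rng(1) * tot, cumsum(fitnesses), left.open = TRUE) + 1L
}

#' Single-point crossover
#'
#' With probability `crossover_prob`, a cut point is drawn uniformly from
#' the `n - 1` interior positions and the tails are swapped; otherwise the
#' parents are copied unchanged.
#'
#' @param p1,p2 Equal-length 0/1 gene vectors (length >= 2).
#' @param crossover_prob Crossover probability.
#' @param rng Uniform stream `f(n)`.
#' @return List of two offspring gene vectors.
#' @export
single_point_crossover <- function(p1, p2, crossover_prob = 0.8,
                                   rng = stats::runif) {
  n <- length(p1)
  if (length(p2) != n) stop("parents must have equal length")
  if (n < 2) stop("chromosomes must have at least two genes")
  if (rng(1) < crossover_prob) {
    cut <- floor(rng(1) * (n - 1)) + 1L  # cut after gene `cut`, in 1..n-1
    tail_idx <- (cut + 1L):n
    tmp <- p1[tail_idx]
    p1[tail_idx] <- p2[tail_idx]
    p2[tail_idx] <- tmp
  }
  list(p1, p2)
}

#' Uniform mutation
#'
#' Every gene flips independently with probability `mutation_prob`.
#'
#' @param genes 0/1 gene vector.
#' @param mutation_prob Per-gene flip probability.
#' @param rng Uniform stream `f(n)`.
#' @return Mutated gene vector.
#' @export
uniform_mutation <- function(genes, mutation_prob = 0.01, rng = stats::runif) {
  flip <- rng(length(genes)) < mutation_prob
  as.integer(xor(genes, flip))
}

# one selection -> crossover -> mutation generation; fitness_values are the
# roulette weights of the incoming population
ga_generation <- function(genes, fitness_values, config, rng = stats::runif) {
  pop <- nrow(genes)
  children <- matrix(0L, pop, ncol(genes))
  i <- 1L
  while (i <= pop) {
    a <- roulette_select(fitness_values, rng)
    b <- roulette_select(fitness_values, rng)
    off <- single_point_crossover(genes[a, ], genes[b, ],
                                  config$crossover_prob, rng)
    children[i, ] <- repair_all_zero(
      uniform_mutation(off[[1]], config$mutation_prob, rng), rng)
    if (i + 1L <= pop)
      children[i + 1L, ] <- repair_all_zero(
        uniform_mutation(off[[2]], config$mutation_prob, rng), rng)
    i <- i + 2L
  }
  children
}

#' GA-diversified initial positions for the wrapper
#'
#' Runs the seeding scheme: random chromosomes, then `generations` passes of
#' roulette selection (weighted by the wrapper fitness of each chromosome's
#' feature subset), single-point crossover and uniform mutation; the final
#' chromosomes decode one-to-one into binary positions. With
#' `generations > 1` the best chromosome survives each pass unchanged
#' (elitism of one).
#'
#' @param n_features Number of genes per chromosome.
#' @param fitness_fn Function taking a 0/1 flag vector and returning a
#'   non-negative scalar fitness (the subset objective).
#' @param config An [ga_config()].
#' @param rng Uniform stream `f(n)`; defaults to the ambient R RNG.
#' @return Numeric 0/1 matrix `pop_size x n_features` of initial positions.
#' @export
generate_initial_positions <- function(n_features, fitness_fn,
                                       config = ga_config(),
                                       rng = stats::runif) {
  stopifnot(inherits(config, "igk_ga_config"))
  genes <- init_chromosomes(config$pop_size, n_features, rng)
  fit <- apply(genes, 1, fitness_fn)
  for (g in seq_len(config$generations)) {
    elite <- genes[which.max(fit), ]
    genes <- ga_generation(genes, fit, config, rng)
    fit <- apply(genes, 1, fitness_fn)
    if (config$generations > 1L) {
      worst <- which.min(fit)
      genes[worst, ] <- elite
      fit[worst] <- fitness_fn(elite)
    }
  }
  storage.mode(genes) <- "double"
  genes
}
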