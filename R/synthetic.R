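#' Specify a synthetic two-class dataset
#'
#' Describes a table in the style of small clinical diagnostic datasets: a
#' minority of class-informative continuous features, optional redundant
#' features (noisy linear combinations of the informative ones) and
#' class-independent noise features.
#'
#' @param n_samples Number of rows (>= 2).
#' @param n_informative Features drawn from class-conditional Gaussians with
#'   means +/- `class_separation`/2 and unit variance.
#' @param n_redundant Features formed as unit-norm random linear combinations
#'   of the informative block plus Gaussian noise (sd 0.1).
#' @param n_noise Standard-Gaussian features independent of the class.
#' @param class_separation Distance between the class means along each
#'   informative dimension, in units of the within-class standard deviation.
#'   0 gives data with no signal; 2 gives overlapping but learnable classes;
#'   4 gives near-separable classes.
#' @param positive_fraction Fraction of rows in the positive class, in (0,1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `igk_synth_spec`.
#' @export
synthetic_spec <- function(n_samples, n_informative = 5, n_redundant = 0,
                           n_noise = 15, class_separation = 2,
                           positive_fraction = 0.5, seed = 1) {
  stopifnot(n_samples >= 2, n_informative >= 0, n_redundant >= 0, n_noise >= 0,
            n_informative + n_redundant + n_noise >= 1,
            class_separation >= 0,
            positive_fraction > 0, positive_fraction < 1)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant features require at least one informative feature")
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 class_separation = class_separation,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)),
            class = "igk_synth_spec")
}

#' Generate a synthetic dataset with known informative structure
#'
#' @param spec An [synthetic_spec()] object.
#' @return An [dataset()] object with feature names `inf_*`, `red_*`,
#'   `noise_*` in that column order, so tests can identify which features
#'   carry signal.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "igk_synth_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    n_pos <- round(spec$positive_fraction * n)
    if (n_pos < 1 || n_pos > n - 1)
      stop("positive_fraction leaves a class empty at this sample size")
    y <- sample(c(rep(1, n_pos), rep(0, n - n_pos)))
    sign_mean <- ifelse(y == 1, 1, -1) * spec$class_separation / 2

    blocks <- list()
    if (spec$n_informative > 0) {
      inf <- matrix(rnorm(n * spec$n_informative), n) + sign_mean
      colnames(inf) <- paste0("inf_", seq_len(spec$n_informative))
      blocks$inf <- inf
    }
    if (spec$n_redundant > 0) {
      coef <- matrix(rnorm(spec$n_informative * spec$n_redundant),
                     spec$n_informative)
      coef <- sweep(coef, 2, sqrt(colSums(coef^2)), "/")
      red <- blocks$inf %*% coef + matrix(rnorm(n * spec$n_redundant, sd = 0.1), n)
      colnames(red) <- paste0("red_", seq_len(spec$n_redundant))
      blocks$red <- red
    }
    if (spec$n_noise > 0) {
      noi <- matrix(rnorm(n * spec$n_noise), n)
      colnames(noi) <- paste0("noise_", seq_len(spec$n_noise))
      blocks$noise <- noi
    }
    X <- do.call(cbind, blocks)
    dataset(X, y, positive_label = 1)
  })
}
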