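#' Stratified repeated k-fold cross-validation plan
#'
#' Builds `repeats` independent stratified partitions of the samples into
#' `k` folds. Within every repeat, overall fold sizes differ by at most one
#' sample and each fold's class counts are within one of the proportional
#' share (the per-class remainders are greedily assigned to the currently
#' smallest folds).
#'
#' @param labels Factor or vector of class labels.
#' @param k Number of folds (default 10); every class must have at least
#'   `k` samples in stratified mode.
#' @param repeats Number of repeated partitions (default 10).
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return An object of class `igk_cv_plan`: `k`, `repeats`, `seed`, and
#'   `folds`, a list of integer vectors (fold id in `1..k` per sample) per
#'   repeat.
#' @export
make_cv_plan <- function(labels, k = 10, repeats = 10, stratified = TRUE,
                         seed = 1) {
  labels <- as.factor(labels)
  n <- length(labels)
  stopifnot(k >= 2, repeats >= 1, n >= k)
  if (stratified && any(table(labels) < k))
    stop("every class needs at least k samples for stratified folds")
  withr::with_seed(as.integer(seed), {
    folds <- lapply(seq_len(repeats), function(r) {
      assign_folds(labels, k, stratified)
    })
  })
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), stratified = stratified,
                 folds = folds),
            class = "igk_cv_plan")
}

# one stratified partition; consumes the ambient RNG
assign_folds <- function(labels, k, stratified) {
  n <- length(labels)
  fold_of <- integer(n)
  if (!stratified) {
    fold_of <- sample(rep_len(seq_len(k), n))
    return(fold_of)
  }
  totals <- integer(k)
  # largest class first so its remainder placement constrains the rest
  for (cl in names(sort(table(labels), decreasing = TRUE))) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    counts <- rep(n_c %/% k, k)
    for (e in seq_len(n_c %% k)) {
      # put each extra sample in the currently smallest fold (ties: lowest)
      tgt <- which.min(totals + counts)
      counts[tgt] <- counts[tgt] + 1L
    }
    fold_of[idx] <- rep(seq_len(k), counts)
    totals <- totals + counts
  }
  fold_of
}
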