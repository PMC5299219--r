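# All fixtures are generated in code; files written under tempdir() only.

# one perfectly separating feature plus uninformative padding
separable_dataset <- function(n = 40, n_pad = 5, seed = 101) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), length.out = n)
    sep <- ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.05)
    pad <- matrix(rnorm(n * n_pad), n)
    X <- cbind(sep = sep, pad)
    colnames(X) <- c("sep", paste0("pad", seq_len(n_pad)))
    dataset(X, y, positive_label = 1)
  })
}

random_dataset <- function(n = 30, p = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    y <- rep(c("a", "b"), length.out = n)
    dataset(X, y, positive_label = "a")
  })
}

# a file in the UCI Parkinson column layout (subject name column, 22 voice
# measures, status label) with synthetic values; the class counts mirror
# the real table
write_synthetic_parkinson <- function(path, seed = 7) {
  withr::with_seed(seed, {
    n <- 195
    status <- c(rep(1L, 147), rep(0L, 48))
    X <- matrix(round(rnorm(n * 22, mean = 100, sd = 20), 4), n)
    colnames(X) <- paste0("voice", 1:22)
    df <- data.frame(name = sprintf("phon_R%03d", seq_len(n)), X,
                     status = status)
    data.table::fwrite(df, path)
  })
  path
}

# a file in the UCI WDBC layout (ID, diagnosis M/B, 30 features) with
# synthetic values; 357 benign as in the real table
write_synthetic_wdbc <- function(path, seed = 8) {
  withr::with_seed(seed, {
    n <- 569
    diagnosis <- c(rep("B", 357), rep("M", n - 357))
    X <- matrix(round(rnorm(n * 30), 4), n)
    colnames(X) <- paste0("feat", 1:30)
    df <- data.frame(id = seq_len(n) + 8e5, diagnosis = diagnosis, X)
    data.table::fwrite(df, path)
  })
  path
}

# fast wrapper settings for tests that exercise plumbing, not search power
quick_plan <- function(labels, repeats = 2, k = 5, seed = 1) {
  make_cv_plan(labels, k = k, repeats = repeats, seed = seed)
}
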