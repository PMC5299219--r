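#' Construct a two-class tabular dataset
#'
#' The container used throughout the package: a numeric feature matrix plus
#' a binary label factor with levels `c("negative", "positive")`. Internally
#' the classifier encodes positive as +1 and negative as -1 (symmetric
#' targets for the kernel ELM solve).
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#' @param labels Vector of length `nrow(features)` with exactly two distinct
#'   values.
#' @param positive_label The value in `labels` designating the positive
#'   class. The other observed value becomes the negative class.
#' @param feature_names Optional character vector of unique column names;
#'   defaults to `colnames(features)` or `f1, f2, ...`.
#'
#' @return An object of class `igk_dataset`: a list with `features`
#'   (named numeric matrix), `labels` (factor, levels negative/positive) and
#'   `label_values` (the original positive/negative values).
#' @export
dataset <- function(features, labels, positive_label, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features))
    stop("feature_names length must equal the number of feature columns")
  if (anyDuplicated(feature_names))
    stop("feature names must be unique")
  colnames(features) <- feature_names
  if (length(labels) != nrow(features))
    stop("labels length must equal the number of rows")
  if (anyNA(features) || anyNA(labels))
    stop("missing values are not supported; clean the data first")
  vals <- unique(labels)
  if (length(vals) != 2L)
    stop("exactly two label values are required, found ", length(vals))
  if (!positive_label %in% vals)
    stop("positive_label '", positive_label, "' not present in labels")
  if (nrow(features) < 2L)
    stop("at least two samples are required")
  negative_label <- vals[vals != positive_label]
  lab <- factor(ifelse(labels == positive_label, "positive", "negative"),
                levels = c("negative", "positive"))
  structure(
    list(features = features, labels = lab,
         label_values = c(negative = as.character(negative_label),
                          positive = as.character(positive_label))),
    class = "igk_dataset"
  )
}

#' @export
print.igk_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<igk_dataset> %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$features), ncol(x$features), tab[["positive"]], tab[["negative"]]))
  cat("features:", paste(head(colnames(x$features), 6), collapse = ", "),
      if (ncol(x$features) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.igk_dataset <- function(x) dim(x$features)

# +1/-1 targets for the KELM solve
label_targets <- function(data) {
  ifelse(data$labels == "positive", 1, -1)
}

#' Read a delimited two-class table into a dataset
#'
#' Generic CSV/TSV reader plus named adapters for the two UCI medical
#' layouts commonly used with this method: `"parkinson"` (a `name` column to
#' drop, `status` label, positive = 1) and `"wdbc"` (leading ID column,
#' `diagnosis` label, positive = `"M"`). The generic adapter requires an
#' explicit `label_column` and `positive_label`. Non-numeric feature cells
#' and missing values are errors, not imputed.
#'
#' @param path Path to a delimited text file.
#' @param label_column Column name or index holding the class label
#'   (generic adapter).
#' @param positive_label Label value mapped to the positive class.
#' @param adapter One of `"generic"`, `"parkinson"`, `"wdbc"`.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param header Whether the file has a header row; `NA` auto-detects.
#' @return An [dataset()] object.
#' @export
load_table <- function(path, label_column = NULL, positive_label = NULL,
                       adapter = c("generic", "parkinson", "wdbc"),
                       sep = ",", header = NA) {
  adapter <- match.arg(adapter)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = header, data.table = FALSE)

  drop_cols <- character(0)
  if (adapter == "parkinson") {
    drop_cols <- intersect(c("name", "subject"), names(dt))
    if (is.null(label_column)) label_column <- "status"
    if (is.null(positive_label)) positive_label <- 1
  } else if (adapter == "wdbc") {
    nm <- tolower(names(dt))
    if ("diagnosis" %in% nm) {
      label_column <- names(dt)[match("diagnosis", nm)]
      drop_cols <- names(dt)[nm %in% c("id", "id_number")]
    } else {
      # headerless UCI layout: ID, diagnosis, 30 features
      label_column <- names(dt)[2]
      drop_cols <- names(dt)[1]
    }
    if (is.null(positive_label)) positive_label <- "M"
  } else if (is.null(label_column)) {
    stop("the generic adapter requires an explicit label_column")
  }

  if (is.numeric(label_column)) label_column <- names(dt)[label_column]
  if (is.na(label_column) || !label_column %in% names(dt))
    stop("label column not found")
  labels <- dt[[label_column]]
  feats <- dt[, setdiff(names(dt), c(label_column, drop_cols)), drop = FALSE]
  non_num <- !vapply(feats, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric feature column(s): ", paste(names(feats)[non_num], collapse = ", "))
  if (length(unique(labels)) > 2L)
    stop("more than two classes in label column '", label_column, "'")
  if (is.null(positive_label)) stop("positive_label is required")
  dataset(as.matrix(feats), labels, positive_label)
}

#' Write a dataset back to CSV
#'
#' Features are written with round-trip precision (shortest decimal text
#' that restores the same double), followed by a `class` column holding the
#' original label values.
#'
#' @param data An [dataset()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "igk_dataset"))
  df <- as.data.frame(data$features)
  df$class <- unname(data$label_values[as.character(data$labels)])
  data.table::fwrite(df, path)
  invisible(path)
}

# per-column linear map parameters onto [-1, 1]; constant columns -> 0
minmax_fit <- function(features) {
  list(min = apply(features, 2, min), max = apply(features, 2, max))
}

minmax_apply <- function(features, fit) {
  rng <- fit$max - fit$min
  out <- features
  for (j in seq_len(ncol(features))) {
    if (rng[j] == 0) {
      out[, j] <- 0
    } else {
      out[, j] <- 2 * (features[, j] - fit$min[j]) / rng[j] - 1
    }
  }
  # columns scaled with a fit from other rows can exceed the target range
  pmin(pmax(out, -1), 1)
}

#' Min-max scale every feature column into [-1, 1]
#'
#' Linear per-column map sending the column minimum to -1 and maximum to +1.
#' Constant columns map to 0 (the zero-range convention keeps the column in
#' range without dividing by zero). Idempotent; the input is not modified.
#'
#' @param data An [dataset()] object.
#' @return A new scaled [dataset()] object.
#' @export
normalize_minmax <- function(data) {
  stopifnot(inherits(data, "igk_dataset"))
  scaled <- minmax_apply(data$features, minmax_fit(data$features))
  out <- data
  out$features <- scaled
  out
}

# restrict a dataset to the flagged feature columns
subset_dataset <- function(data, flags) {
  stopifnot(length(flags) == ncol(data$features), sum(flags) >= 1)
  out <- data
  out$features <- data$features[, flags == 1, drop = FALSE]
  out
}
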