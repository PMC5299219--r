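#' Kernel ELM hyperparameters
#'
#' @param C Positive regularization constant; larger values interpolate the
#'   training targets more closely. Default 32 (= 2^5), the grid optimum
#'   reported for both reference medical datasets.
#' @param gamma Positive RBF width. NOTE: the kernel here is
#'   `exp(-||x - y||^2 / (2 * gamma^2))` — the 2-gamma-squared denominator
#'   convention, not `exp(-gamma * ||.||^2)`. Parameter grids from the other
#'   convention do not transfer. Default 0.5 (= 2^-1).
#' @return An object of class `igk_kelm_config`.
#' @export
kelm_config <- function(C = 32, gamma = 0.5) {
  stopifnot(is.numeric(C), length(C) == 1, C > 0,
            is.numeric(gamma), length(gamma) == 1, gamma > 0)
  structure(list(C = C, gamma = gamma), class = "igk_kelm_config")
}

#' Gaussian (RBF) kernel matrix
#'
#' Entry (i, j) is `exp(-||x_i - y_j||^2 / (2 * gamma^2))`, in (0, 1].
#'
#' @param X,Y Numeric matrices with equal column counts (rows are samples).
#' @param gamma Positive kernel width.
#' @return A `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
rbf_kernel <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of columns")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # clamp tiny negative rounding in the expanded norm
  exp(-d2 / (2 * gamma^2))
}

# SPD solve of (Omega + I/C) W = T with one step of iterative refinement,
# which keeps the residual tight even at very large C.
kelm_solve <- function(A, T_mat) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  solve_one <- if (!is.null(R)) {
    function(b) backsolve(R, forwardsolve(t(R), b))
  } else {
    function(b) solve(A, b)
  }
  W <- solve_one(T_mat)
  W + solve_one(T_mat - A %*% W)
}

#' Train a kernel extreme learning machine
#'
#' Closed-form training: build the RBF kernel Gram matrix Omega on the
#' training samples and solve the regularized linear system
#' `(Omega + I/C) W = T`, where `T` is a single column of +1/-1 class
#' targets. Omega is positive semidefinite, so the regularized system is
#' positive definite and the solve is deterministic — no random hidden
#' layer is ever materialized.
#'
#' @param data An [dataset()] object (both classes present).
#' @param config A [kelm_config()].
#' @return An object of class `igk_kelm`: training features, output weight
#'   column, the config, the label mapping, and the achieved solve residual
#'   `max|(Omega + I/C) W - T|`.
#' @export
kelm_train <- function(data, config = kelm_config()) {
  stopifnot(inherits(data, "igk_dataset"), inherits(config, "igk_kelm_config"))
  X <- data$features
  T_mat <- matrix(label_targets(data), ncol = 1)
  Omega <- rbf_kernel(X, X, config$gamma)
  A <- Omega + diag(1 / config$C, nrow(X))
  W <- kelm_solve(A, T_mat)
  structure(
    list(train_features = X, output_weights = W, config = config,
         label_values = data$label_values,
         residual = max(abs(A %*% W - T_mat))),
    class = "igk_kelm"
  )
}

#' @export
print.igk_kelm <- function(x, ...) {
  cat(sprintf("<igk_kelm> m=%d training samples, n=%d features, C=%g, gamma=%g\n",
              nrow(x$train_features), ncol(x$train_features),
              x$config$C, x$config$gamma))
  invisible(x)
}

#' Real-valued KELM decision values
#'
#' `K(X_new, X_train) %*% W`; the sign carries the class, the magnitude the
#' confidence.
#'
#' @param model A trained [kelm_train()] model.
#' @param X_new Numeric matrix with the model's feature count.
#' @return Numeric vector of decision values.
#' @export
kelm_decision <- function(model, X_new) {
  stopifnot(inherits(model, "igk_kelm"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$train_features))
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         ncol(model$train_features))
  drop(rbf_kernel(X_new, model$train_features, model$config$gamma) %*%
         model$output_weights)
}

#' Predict class labels with a trained KELM
#'
#' Sign rule on the decision value; exact zeros break to the positive class.
#'
#' @inheritParams kelm_decision
#' @param encoded If `TRUE` return +1/-1; otherwise the dataset's original
#'   label values.
#' @return Label vector of length `nrow(X_new)`.
#' @export
kelm_predict <- function(model, X_new, encoded = FALSE) {
  f <- kelm_decision(model, X_new)
  pm <- ifelse(f >= 0, 1, -1)
  if (encoded) return(pm)
  unname(model$label_values[ifelse(pm > 0, "positive", "negative")])
}

#' Save / load a trained KELM model
#'
#' JSON container holding the training matrix, output weights, config and
#' label map at full (round-trip) decimal precision, so reloaded models
#' reproduce predictions bit-exactly on the same platform.
#'
#' @param model A trained [kelm_train()] model.
#' @param path File path for the JSON model container.
#' @return `save_kelm`: `path` invisibly. `load_kelm`: the restored model.
#' @export
save_kelm <- function(model, path) {
  stopifnot(inherits(model, "igk_kelm"))
  obj <- list(
    format = "igwokelm/kelm-model",
    version = 1L,
    C = model$config$C,
    gamma = model$config$gamma,
    label_values = as.list(model$label_values),
    feature_names = colnames(model$train_features),
    train_features = model$train_features,
    output_weights = drop(model$output_weights),
    residual = model$residual
  )
  # I(17) = 17 significant digits, enough to restore every double exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_kelm
#' @export
load_kelm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "igwokelm/kelm-model"))
    stop("not an igwokelm KELM model file: ", path)
  X <- as.matrix(obj$train_features)
  colnames(X) <- obj$feature_names
  structure(
    list(train_features = X,
         output_weights = matrix(obj$output_weights, ncol = 1),
         config = kelm_config(C = obj$C, gamma = obj$gamma),
         label_values = unlist(obj$label_values),
         residual = obj$residual),
    class = "igk_kelm"
  )
}
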