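#' Fit an extreme learning machine classifier
#'
#' An ELM is a single-hidden-layer feed-forward network whose hidden layer is
#' random and fixed: input weights `w` (L x n) and biases `b` are drawn once
#' from U(-1, 1), the hidden activations form `H[j, i] = g(<w_i, x_j> + b_i)`,
#' and only the output weights `beta` are learned, as the minimum-norm
#' least-squares solution of `H beta = Y` with one-hot (0/1) class targets:
#' `beta = pinv(H) Y` via the Moore-Penrose pseudoinverse, or the ridge
#' solution `beta = (H'H + lambda I)^{-1} H'Y` when `lambda > 0`.
#'
#' @param x A [feature_table()], or a numeric matrix (then `y` is required).
#' @param y Integer class labels in `[0, C-1]` (ignored when `x` is a
#'   feature table).
#' @param L Number of hidden nodes (>= 1). `L > N` (more nodes than samples)
#'   is permitted with a warning: the system is underdetermined and the
#'   minimum-norm solution is returned.
#' @param activation One of `"sigmoid"`, `"relu"`, `"tanh"`.
#' @param lambda Ridge coefficient (>= 0; default 0 gives the pure
#'   pseudoinverse solution).
#' @param seed Integer seed for the hidden layer.
#' @return An object of class `elm` with components `w`, `b`, `activation`,
#'   `beta`, `L`, `n`, `n_classes`, `lambda`, `seed`, `labels_seen`, and the
#'   training residual `residual` (`||H beta - Y||_F`).
#' @examples
#' ft <- generate_feature_table(c(30, 30), n_features = 4, class_sep = 3, seed = 1)
#' fit <- elm(ft, L = 25, seed = 1)
#' mean(predict(fit, ft$X) == ft$labels)
#' @export
elm <- function(x, y = NULL, L = 50,
                activation = c("sigmoid", "relu", "tanh"),
                lambda = 0, seed = 1) {
  activation <- match.arg(activation)
  if (inherits(x, "feature_table")) { y <- x$labels; x <- x$X }
  x <- as.matrix(x)
  if (is.null(y)) stop_config("class labels y are required")
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_config("nrow(x) != length(y)")
  if (any(!is.finite(x))) stop_config("x contains non-finite values")
  if (L < 1) stop_config("L must be >= 1")
  if (lambda < 0) stop_config("lambda must be >= 0")
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop_config("training data contains a single class (%d); need >= 2",
                classes[1])
  }
  n_classes <- max(y) + 1L
  N <- nrow(x); n <- ncol(x)
  if (L > N) {
    warning(sprintf("L = %d exceeds N = %d: underdetermined system, minimum-norm solution returned",
                    L, N), call. = FALSE)
  }
  model <- with_local_seed(seed, {
    w <- matrix(stats::runif(L * n, -1, 1), L, n)
    b <- stats::runif(L, -1, 1)
    structure(list(w = w, b = b, activation = activation, beta = NULL,
                   L = as.integer(L), n = n, n_classes = n_classes,
                   lambda = lambda, seed = as.integer(seed)),
              class = "elm")
  })
  H <- hidden_matrix(x, model)
  Y <- matrix(0, N, n_classes)
  Y[cbind(seq_len(N), y + 1L)] <- 1            # one-hot {0,1} targets
  beta <- if (lambda == 0) {
    pinv(H) %*% Y
  } else {
    solve(crossprod(H) + diag(lambda, ncol(H)), crossprod(H, Y))
  }
  model$beta <- beta
  model$labels_seen <- classes
  model$residual <- sqrt(sum((H %*% beta - Y)^2))
  model
}

#' Hidden-layer activation matrix
#'
#' `H[j, i] = g(<w_i, x_j> + b_i)` for sample `j` and hidden node `i`.
#'
#' @param X Numeric matrix, samples x inputs; must match `model$n`.
#' @param model An [elm()] model (only `w`, `b`, `activation` are used, so a
#'   partially built model is accepted).
#' @return The N x L activation matrix.
#' @export
hidden_matrix <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$w)) {
    stop_config("X has %d columns but the model expects %d", ncol(X), ncol(model$w))
  }
  if (any(!is.finite(X))) stop_config("X contains non-finite values")
  A <- X %*% t(model$w)
  A <- sweep(A, 2, model$b, "+")
  switch(model$activation,
         sigmoid = 1 / (1 + exp(-A)),
         relu = pmax(A, 0),
         tanh = tanh(A))
}

# Moore-Penrose pseudoinverse by SVD with singular values below
# max(dim) * eps * sigma_max treated as zero.
pinv <- function(A) {
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Predict classes from an ELM
#'
#' Scores are the rows of `H beta`; the predicted label is the argmax column,
#' ties broken toward the lowest class index.
#'
#' @param object An [elm()] model.
#' @param newdata Numeric matrix or [feature_table()].
#' @param type `"class"` (default) for 0-based integer labels, `"score"` for
#'   the raw N x C score matrix.
#' @param ... Unused.
#' @return Integer labels or a score matrix.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$X
  S <- hidden_matrix(newdata, object) %*% object$beta
  if (type == "score") return(S)
  max.col(S, ties.method = "first") - 1L
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("Extreme learning machine: %d inputs -> %d hidden (%s) -> %d classes\n",
              x$n, x$L, x$activation, x$n_classes))
  cat(sprintf("lambda = %g, training residual ||H beta - Y|| = %.4g\n",
              x$lambda, x$residual))
  invisible(x)
}

#' @export
summary.elm <- function(object, ...) {
  out <- list(L = object$L, n = object$n, n_classes = object$n_classes,
              activation = object$activation, lambda = object$lambda,
              residual = object$residual,
              beta_norm = sqrt(sum(object$beta^2)))
  class(out) <- "summary.elm"
  out
}

#' @export
print.summary.elm <- function(x, ...) {
  cat("ELM summary\n")
  cat(sprintf("  hidden nodes     : %d\n", x$L))
  cat(sprintf("  inputs / classes : %d / %d\n", x$n, x$n_classes))
  cat(sprintf("  activation       : %s\n", x$activation))
  cat(sprintf("  ridge lambda     : %g\n", x$lambda))
  cat(sprintf("  train residual   : %.6g\n", x$residual))
  cat(sprintf("  ||beta||_F       : %.6g\n", x$beta_norm))
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) object$beta

#' Residuals of an ELM fit
#'
#' Returns `H beta - Y` on the training design if the training data is
#' supplied, i.e. the one-hot regression residual matrix the least-squares
#' solve minimizes.
#'
#' @param object An [elm()] model.
#' @param x Training inputs (matrix or feature table).
#' @param y Training labels (when `x` is a matrix).
#' @param ... Unused.
#' @return N x C residual matrix.
#' @export
residuals.elm <- function(object, x, y = NULL, ...) {
  if (inherits(x, "feature_table")) { y <- x$labels; x <- x$X }
  N <- nrow(x)
  Y <- matrix(0, N, object$n_classes)
  Y[cbind(seq_len(N), as.integer(y) + 1L)] <- 1
  hidden_matrix(x, object) %*% object$beta - Y
}

#' Serialize / restore an ELM model as JSON
#'
#' All weights and metadata in one JSON document (plain text).
#'
#' @param model An [elm()] model.
#' @param path Output / input JSON path.
#' @return `path` (writer) or an `elm` object (reader).
#' @export
write_elm <- function(model, path) {
  obj <- list(w = model$w, b = model$b, activation = model$activation,
              beta = model$beta, L = model$L, n = model$n,
              n_classes = model$n_classes, lambda = model$lambda,
              seed = model$seed, residual = model$residual)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(w = matrix(obj$w, obj$L, obj$n, byrow = FALSE),
                b = as.numeric(obj$b), activation = obj$activation,
                beta = matrix(obj$beta, ncol = obj$n_classes),
                L = as.integer(obj$L), n = as.integer(obj$n),
                n_classes = as.integer(obj$n_classes),
                lambda = obj$lambda, seed = as.integer(obj$seed),
                residual = obj$residual)
  class(model) <- "elm"
  model
}
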