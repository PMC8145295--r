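## Kernel extreme learning machine: a kernelized single-shot classifier.
## With Gram matrix Omega of the training rows and one-hot targets T, the
## output weights solve (I/C + Omega) beta = T; prediction scores are
## K(X, train) beta with arg-max decoding.

kernel_matrix <- function(x, y, kernel, gamma, degree, coef0) {
  switch(kernel,
         linear = tcrossprod(x, y),
         polynomial = (gamma * tcrossprod(x, y) + coef0)^degree,
         rbf = {
           d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
           exp(-gamma * pmax(d2, 0))
         },
         stop("unknown kernel: ", kernel))
}

## median pairwise Euclidean distance (subsampled for large n)
median_heuristic_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 300) sample.int(n, 300) else seq_len(n)
  d2 <- stats::dist(x[idx, , drop = FALSE])
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

#' Fit a kernel extreme learning machine classifier
#'
#' @param x N x d training feature matrix.
#' @param y per-row class labels (at least two classes).
#' @param kernel `"rbf"` (default; bandwidth from the median pairwise
#'   distance heuristic unless `gamma` is given), `"linear"`, or
#'   `"polynomial"`.
#' @param C regularization scalar > 0 (default 100); larger C fits the
#'   training data more closely.
#' @param gamma kernel coefficient (rbf: `exp(-gamma * ||x - y||^2)`;
#'   polynomial: `(gamma * <x, y> + coef0)^degree`; default rbf median
#'   heuristic, polynomial `1/d`).
#' @param degree,coef0 polynomial kernel parameters.
#' @return object of class `kelm` with `output_weights` (n_train x
#'   n_classes), `support_data`, `classes`, and the kernel spec.
#' @export
kelm <- function(x, y, kernel = c("rbf", "linear", "polynomial"), C = 100,
                 gamma = NULL, degree = 3, coef0 = 1) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be positive")
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (is.null(gamma))
    gamma <- switch(kernel, rbf = median_heuristic_gamma(x),
                    polynomial = 1 / ncol(x), linear = 1)
  omega <- kernel_matrix(x, x, kernel, gamma, degree, coef0)
  targets <- stats::model.matrix(~ y - 1)
  colnames(targets) <- levels(y)
  n <- nrow(x)
  beta <- tryCatch(solve(diag(n) / C + omega, targets),
                   error = function(e)
                     stop("kernel system is singular beyond regularization ",
                          "(ill-conditioned Gram matrix): ",
                          conditionMessage(e)))
  # For the linear kernel the push-through identity
  #   X' (I/C + X X')^{-1} T = (X'X + I/C)^{-1} X' T
  # gives the same scores from a d x d system; this primal form stays
  # accurate at very large C where the dual weights grow like C.
  primal <- if (kernel == "linear")
    solve(crossprod(x) + diag(ncol(x)) / C, crossprod(x, targets))
  else NULL
  structure(list(kernel = kernel, C = C, gamma = gamma, degree = degree,
                 coef0 = coef0, support_data = x, output_weights = beta,
                 primal_weights = primal,
                 classes = levels(y)), class = "kelm")
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("Kernel ELM: %s kernel | C = %g | %d training rows | classes: %s\n",
              x$kernel, x$C, nrow(x$support_data),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict classes or scores from a fitted KELM
#'
#' @param object a [kelm()] model.
#' @param newdata matrix with the training feature width.
#' @param type `"class"` (arg-max decoding, ties to the first class in
#'   class order) or `"score"` (raw score matrix).
#' @param ... unused.
#' @return factor of labels, or the N x n_classes score matrix.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$support_data))
    stop("feature width ", ncol(newdata), " does not match training width ",
         ncol(object$support_data))
  scores <- if (object$kernel == "linear")
    newdata %*% object$primal_weights
  else kernel_matrix(newdata, object$support_data, object$kernel,
                     object$gamma, object$degree, object$coef0) %*%
    object$output_weights
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Multiclass classification report
#'
#' Accuracy, row-percentage confusion matrix, macro sensitivity (unweighted
#' mean of the diagonal row percentages over classes present in the truth)
#' and FNR = 100 - sensitivity.
#'
#' @param pred_labels predicted labels.
#' @param true_labels reference labels; every predicted label must belong
#'   to the reference class set.
#' @return object of class `classification_report` with `accuracy`,
#'   `sensitivity`, `fnr` (all percentages) and `confusion` (row-normalized
#'   percentages, rows = true classes).
#' @export
evaluate_classification <- function(pred_labels, true_labels) {
  true_labels <- factor(true_labels)
  classes <- levels(true_labels)
  if (!all(as.character(pred_labels) %in% classes))
    stop("prediction contains labels outside the reference class set")
  pred_labels <- factor(as.character(pred_labels), levels = classes)
  if (length(pred_labels) != length(true_labels)) stop("length mismatch")
  counts <- table(true = true_labels, pred = pred_labels)
  present <- rowSums(counts) > 0
  conf <- sweep(counts, 1L, pmax(rowSums(counts), 1L), "/") * 100
  acc <- 100 * sum(diag(counts)) / length(true_labels)
  sens <- mean(diag(as.matrix(conf))[present])
  structure(list(accuracy = acc, sensitivity = sens, fnr = 100 - sens,
                 confusion = as.matrix(conf)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification: accuracy %.2f%% | sensitivity %.2f%% | FNR %.2f%%\n",
              x$accuracy, x$sensitivity, x$fnr))
  cat("Confusion matrix (row %):\n")
  print(round(x$confusion, 2))
  invisible(x)
}
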