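#' Preprocess an expression table into a response
#'
#' Optionally removes genes not detected in any sample and applies the
#' log transform used for count-like expression data.  Synthetic
#' expression from [simulate_expression()] is already on the linear
#' (log) scale and should use `transform = "none"`.
#'
#' @param expression Genes x samples matrix (or vector).
#' @param transform `"log1p"` (log(x + 1)) or `"none"`.
#' @param drop_undetected Remove genes that are zero in every sample.
#' @return Transformed matrix/vector with the same orientation.
#' @export
preprocess_expression <- function(expression,
                                  transform = c("log1p", "none"),
                                  drop_undetected = TRUE) {
  transform <- match.arg(transform)
  x <- expression
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  if (drop_undetected) {
    keep <- rowSums(x != 0) > 0
    x <- x[keep, , drop = FALSE]
  }
  if (transform == "log1p") {
    if (any(x < 0)) stop("negative expression values under log1p")
    x <- log1p(x)
  }
  if (vec) drop(x) else x
}

#' Fit a lasso model with cross-validated penalty
#'
#' Standardizes the predictors (mean 0, SD 1; zero-variance columns are
#' dropped with a warning), centers the response, and fits the l1-penalized
#' regression over a log-spaced penalty grid, choosing the penalty that
#' minimizes the 10-fold cross-validated mean squared error; coefficients
#' are refit at that penalty on the full data.
#'
#' @param x Feature matrix (genes x variables), no missing values.
#' @param y Response vector.
#' @param nfolds Folds for the penalty-selection CV.
#' @param seed Seed controlling the fold assignment.
#' @param thresh Coordinate-descent convergence tolerance.  The default
#'   1e-5 (on standardized data) resolves coefficients far below the
#'   scales interpreted here; composition features are exactly collinear
#'   within each region (percentages sum to 100), where looser tolerances
#'   converge much faster with negligible coefficient differences.
#' @return An object of class `fitted_lasso`: `intercept` (on the response
#'   scale), `beta` (named coefficients on the standardized-predictor
#'   scale), `lambda`, `standardization` (per-variable center/scale),
#'   `response_center`, `dropped` (zero-variance variables), `cvfit`.
#' @export
fit_lasso_cv <- function(x, y, nfolds = 10, seed = NULL, thresh = 1e-5) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values; drop incomplete genes first")
  std <- standardize_columns(x)
  yc <- y - mean(y)
  if (ncol(std$x) < 2) {
    ## degenerate width: plain least squares on the surviving column
    b <- if (ncol(std$x) == 1) sum(std$x * yc) / sum(std$x^2) else numeric(0)
    beta <- setNames(b, colnames(std$x))
    return(structure(list(intercept = mean(y), beta = beta, lambda = 0,
                          standardization = list(center = std$center,
                                                 scale = std$scale),
                          response_center = mean(y), dropped = std$dropped,
                          cvfit = NULL),
                     class = "fitted_lasso"))
  }
  foldid <- make_folds(length(y), nfolds, seed)
  cvfit <- cv.glmnet(std$x, yc, foldid = foldid, standardize = FALSE,
                     intercept = FALSE, thresh = thresh)
  beta <- drop(as.matrix(coef(cvfit, s = "lambda.min")))[-1]
  structure(list(intercept = mean(y), beta = beta,
                 lambda = cvfit$lambda.min,
                 standardization = list(center = std$center,
                                        scale = std$scale),
                 response_center = mean(y), dropped = std$dropped,
                 cvfit = cvfit),
            class = "fitted_lasso")
}

#' @export
print.fitted_lasso <- function(x, ...) {
  cat("fitted_lasso:", sum(x$beta != 0), "of", length(x$beta),
      "variables selected, lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Predict from a fitted lasso model
#'
#' @param object A [fit_lasso_cv()] result.
#' @param newdata Raw (unstandardized) feature matrix with the training
#'   variables.
#' @param ... Unused.
#' @return Predicted expression vector.
#' @export
predict.fitted_lasso <- function(object, newdata, ...) {
  vars <- names(object$beta)
  xs <- scale(as.matrix(newdata)[, vars, drop = FALSE],
              center = object$standardization$center,
              scale = object$standardization$scale)
  drop(xs %*% object$beta) + object$intercept
}

#' Cross-validated evaluation of the lasso model
#'
#' Splits genes into k folds; each fold is held out once while the model
#' -- including the penalty selection -- is trained on the remaining
#' genes, so a gene's prediction never uses information about that gene.
#' Pooled out-of-fold predictions are scored by Spearman correlation
#' (average ranks for ties) and mean squared error; per-gene absolute
#' errors feed the error-tree stratification.
#'
#' @param x Feature matrix (genes x variables).
#' @param y Response vector.
#' @param k Number of evaluation folds.
#' @param seed Seed for the fold assignment (inner folds derive from it).
#' @param inner_nfolds Folds of the nested penalty-selection CV.
#' @return An object of class `cv_evaluation`: `spearman_rho`, `mse`,
#'   `n_genes`, `cv_predictions`, `per_gene_abs_error`, `fold_assignment`.
#' @export
evaluate_cv <- function(x, y, k = 10, seed = 1, inner_nfolds = 10) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(k >= 2, n >= k, nrow(x) == n)
  fold <- make_folds(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (ncol(x) >= 2) {
      fit <- suppressWarnings(
        fit_lasso_cv(x[!test, , drop = FALSE], y[!test],
                     nfolds = inner_nfolds, seed = seed * 1000L + f))
    } else {
      fit <- suppressWarnings(
        fit_lasso_cv(x[!test, , drop = FALSE], y[!test]))
    }
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  err <- abs(y - pred)
  names(pred) <- names(err) <- names(fold) <- rownames(x)
  structure(list(spearman_rho = spearman(pred, y),
                 mse = mean((y - pred)^2),
                 n_genes = n,
                 cv_predictions = pred,
                 per_gene_abs_error = err,
                 fold_assignment = fold),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat("cv_evaluation:", x$n_genes, "genes, Spearman rho =",
      round(x$spearman_rho, 3), ", MSE =", round(x$mse, 3), "\n")
  invisible(x)
}

#' Randomization control: permute variables within each gene
#'
#' Independently permutes each gene's values across the variables,
#' breaking the link between variable combinations and expression while
#' preserving each gene's value multiset exactly.
#'
#' @param x Feature matrix.
#' @param seed Seed.
#' @return Matrix of the same shape.
#' @export
permute_within_genes <- function(x, seed = 1) {
  x <- as.matrix(x)
  set.seed(seed)
  if (ncol(x) == 1) return(x)
  out <- t(apply(x, 1, sample))
  dimnames(out) <- dimnames(x)
  out
}

#' Max-variable control
#'
#' Reduces the matrix to a single predictive variable per gene: the
#' maximum across all variables.
#'
#' @param x Feature matrix with at least one column.
#' @return One-column matrix named `max_variable`.
#' @export
max_variable_control <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1)
  out <- matrix(apply(x, 1, max), ncol = 1,
                dimnames = list(rownames(x), "max_variable"))
  out
}
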