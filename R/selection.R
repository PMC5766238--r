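#' Forward selection over region feature blocks
#'
#' Greedy ranking of regions by their contribution to prediction: (i) all
#' regions are evaluated separately and the one with the highest
#' cross-validated Spearman correlation is the seed; (ii) each remaining
#' region is added separately to the current model and the best addition
#' is kept; (iii) repeat until all regions are in the model.  Ties break
#' by region-name order.
#'
#' @param feature_blocks Named list: region -> feature matrix (same genes,
#'   same row order).
#' @param y Response vector.
#' @param k Evaluation folds (see [evaluate_cv()]).
#' @param seed Seed.
#' @param inner_nfolds Nested penalty-selection folds.
#' @param max_steps Stop after this many steps (default: rank all regions).
#' @return An object of class `forward_path`: data.frame with one row per
#'   step (`step`, `region`, `rho`, `increment`).
#' @export
forward_select_regions <- function(feature_blocks, y, k = 10, seed = 1,
                                   inner_nfolds = 10, max_steps = Inf) {
  stopifnot(is.list(feature_blocks), length(feature_blocks) >= 1,
            !is.null(names(feature_blocks)))
  regions <- sort(names(feature_blocks))
  chosen <- character(0)
  path <- data.frame(step = integer(0), region = character(0),
                     rho = numeric(0), increment = numeric(0))
  current_rho <- NA_real_
  while (length(chosen) < length(regions) && nrow(path) < max_steps) {
    candidates <- base::setdiff(regions, chosen)
    rhos <- vapply(candidates, function(r) {
      xb <- do.call(cbind, feature_blocks[c(chosen, r)])
      evaluate_cv(xb, y, k = k, seed = seed,
                  inner_nfolds = inner_nfolds)$spearman_rho
    }, numeric(1))
    best <- candidates[which.max(rhos)]  # ties: first in sorted order
    inc <- if (is.na(current_rho)) max(rhos) else max(rhos) - current_rho
    current_rho <- max(rhos)
    path <- rbind(path, data.frame(step = length(chosen) + 1L,
                                   region = best, rho = current_rho,
                                   increment = inc))
    chosen <- c(chosen, best)
  }
  structure(path, class = c("forward_path", "data.frame"))
}

#' Stability selection under subsampling and random penalty weights
#'
#' Repeats the lasso fit many times, each time on a random half of the
#' genes with each standardized variable rescaled by an independent
#' uniform weight in `weight_range` (equivalent to randomized penalty
#' factors).  A variable's selection frequency is the fraction of
#' iterations in which its coefficient is nonzero at that iteration's
#' CV-chosen penalty; variables above `threshold` form the stable set,
#' whose effect signs come from an ordinary least-squares refit
#' ([effect_signs()]).
#'
#' @param x Feature matrix.
#' @param y Response vector.
#' @param n_iter Number of subsampling iterations.
#' @param subsample Fraction of genes drawn (without replacement) per
#'   iteration.
#' @param weight_range Range of the uniform random variable weights.
#' @param threshold Selection-frequency cutoff for stability.
#' @param nfolds Folds of the per-iteration penalty CV.
#' @param seed Seed.
#' @return An object of class `stability_report`: data.frame with columns
#'   `variable`, `frequency`, `stable`, `sign`, `coefficient`; attributes
#'   `n_iter`, `threshold`.
#' @export
stability_select <- function(x, y, n_iter = 500, subsample = 0.5,
                             weight_range = c(0.5, 1), threshold = 0.7,
                             nfolds = 5, seed = 1) {
  x <- as.matrix(x)
  stopifnot(n_iter >= 2, subsample > 0, subsample < 1,
            nrow(x) == length(y))
  n <- nrow(x); p <- ncol(x)
  m <- floor(n * subsample)
  if (m < 50) stop("subsample yields ", m, " genes (< 50); increase n")
  set.seed(seed)
  hits <- numeric(p)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, m)
    std <- standardize_columns(x[idx, , drop = FALSE], warn = FALSE)
    w <- runif(ncol(std$x), weight_range[1], weight_range[2])
    xw <- sweep(std$x, 2, w, "*")
    yc <- y[idx] - mean(y[idx])
    cvfit <- cv.glmnet(xw, yc, nfolds = nfolds, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-5)
    b <- drop(as.matrix(coef(cvfit, s = "lambda.min")))[-1]
    sel <- names(b)[b != 0]
    hits[match(sel, colnames(x))] <- hits[match(sel, colnames(x))] + 1
  }
  freq <- round(hits / n_iter, 3)
  stable <- freq > threshold
  rep_df <- data.frame(variable = colnames(x), frequency = freq,
                       stable = stable, sign = NA_character_,
                       coefficient = NA_real_, stringsAsFactors = FALSE)
  if (any(stable)) {
    es <- effect_signs(scale(x[, stable, drop = FALSE]), y)
    rep_df$sign[stable] <- es$sign
    rep_df$coefficient[stable] <- es$coefficient
  }
  structure(rep_df, class = c("stability_report", "data.frame"),
            n_iter = n_iter, threshold = threshold)
}

#' Effect signs of stable variables
#'
#' Ordinary least-squares fit of the response on the standardized stable
#' variables only; each variable's activating (+) or inhibiting (-)
#' effect is the sign of its coefficient.  A collinear stable set falls
#' back to the minimum-norm solution with a warning.
#'
#' @param x_stable Standardized matrix of the stable variables.
#' @param y Response vector.
#' @return data.frame with `variable`, `coefficient`, `sign`.
#' @export
effect_signs <- function(x_stable, y) {
  x_stable <- as.matrix(x_stable)
  stopifnot(ncol(x_stable) >= 1, nrow(x_stable) == length(y))
  df <- data.frame(y = y, x_stable, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  b <- coef(fit)[-1]
  if (anyNA(b)) {
    warning("collinear stable set; using minimum-norm solution")
    xc <- cbind(1, x_stable)
    b <- drop(MASS::ginv(xc) %*% y)[-1]
  }
  data.frame(variable = colnames(x_stable),
             coefficient = unname(b),
             sign = ifelse(b > 0, "+", ifelse(b < 0, "-", "0")),
             stringsAsFactors = FALSE)
}
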