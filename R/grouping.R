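#' Stratify genes by model error with a regression tree
#'
#' Fits a CART regression tree of the per-gene absolute prediction error
#' on the composition features, prunes it with the cost-complexity
#' penalty chosen by 10-fold cross-validation to minimize mean squared
#' error, and returns the leaves as gene groups (at least `min_leaf`
#' genes per leaf).
#'
#' @param features Feature matrix (genes x variables).
#' @param abs_error Per-gene absolute errors (same gene order), e.g.
#'   `evaluate_cv(...)$per_gene_abs_error`.
#' @param min_leaf Minimum genes per leaf.
#' @param xval Cross-validation folds for the pruning criterion.
#' @param seed Seed (rpart's internal CV is randomized).
#' @param sample_id Optional label recorded with each group.
#' @return An object of class `error_tree`: list with `tree` (pruned
#'   rpart), `groups` (data.frame: `sample`, `group`, `gene`,
#'   `mean_abs_error`, `path`), `first_split` (variable of the root
#'   split, NA for a root-only tree).
#' @export
fit_error_tree <- function(features, abs_error, min_leaf = 100, xval = 10,
                           seed = 1, sample_id = NA_character_) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(abs_error) == n)
  if (n < 2 * min_leaf || var(abs_error) == 0) {
    groups <- data.frame(sample = sample_id, group = "g1",
                         gene = rownames(features),
                         mean_abs_error = mean(abs_error),
                         path = "root", stringsAsFactors = FALSE)
    return(structure(list(tree = NULL, groups = groups,
                          first_split = NA_character_),
                     class = "error_tree"))
  }
  safe <- make.names(colnames(features), unique = TRUE)
  name_map <- setNames(colnames(features), safe)
  df <- data.frame(.err = abs_error, features)
  colnames(df) <- c(".err", safe)
  set.seed(seed)
  full <- rpart(.err ~ ., data = df, method = "anova",
                control = rpart.control(minbucket = min_leaf,
                                        minsplit = 2 * min_leaf,
                                        cp = 0, xval = xval))
  cpt <- full$cptable
  best_cp <- cpt[which.min(cpt[, "xerror"]), "CP"]
  tree <- prune(full, cp = best_cp)

  leaf_node <- as.integer(rownames(tree$frame))[tree$where]
  nodes <- sort(unique(leaf_node))
  paths <- path.rpart(tree, nodes = nodes, print.it = FALSE)
  path_str <- vapply(paths, function(p) {
    p <- p[-1]
    if (!length(p)) return("root")
    for (s in names(name_map)) p <- gsub(s, name_map[[s]], p, fixed = TRUE)
    paste(p, collapse = " & ")
  }, "")
  grp_of <- match(leaf_node, nodes)
  groups <- data.frame(sample = sample_id,
                       group = sprintf("g%d", grp_of),
                       gene = rownames(features),
                       mean_abs_error = ave(abs_error, grp_of),
                       path = path_str[grp_of],
                       stringsAsFactors = FALSE)
  first <- as.character(tree$frame$var[1])
  first_split <- if (first == "<leaf>") NA_character_ else
    unname(name_map[first])
  structure(list(tree = tree, groups = groups, first_split = first_split),
            class = "error_tree")
}

#' @export
print.error_tree <- function(x, ...) {
  ng <- length(unique(x$groups$group))
  cat("error_tree:", ng, "group(s); first split:",
      if (is.na(x$first_split)) "none" else x$first_split, "\n")
  invisible(x)
}

#' Flag well-predicted gene groups
#'
#' Pools the mean absolute errors of all groups (across samples), computes
#' their first quartile (linear-interpolation quantile, type 7), and keeps
#' groups whose mean error is strictly below it.
#'
#' @param groups data.frame with at least `sample`, `group`,
#'   `mean_abs_error` (one row per group, or per gene -- duplicates are
#'   collapsed per sample/group).
#' @param per_sample Compute the quartile within each sample instead of
#'   pooled over all groups.
#' @return The per-group data.frame with a logical `flagged` column.
#' @export
flag_well_predicted <- function(groups, per_sample = FALSE) {
  g <- unique(groups[, c("sample", "group", "mean_abs_error")])
  if (nrow(g) < 4) stop("need at least 4 groups to define a quartile")
  if (per_sample) {
    q1 <- ave(g$mean_abs_error, g$sample,
              FUN = function(v) quantile(v, 0.25, type = 7))
  } else {
    q1 <- quantile(g$mean_abs_error, 0.25, type = 7)
  }
  g$flagged <- g$mean_abs_error < q1
  rownames(g) <- NULL
  g
}
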