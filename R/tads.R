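#' Assign genes to TADs
#'
#' A gene belongs to a TAD when the midpoint of its span lies inside the
#' TAD interval.
#'
#' @param genes GRanges of gene spans (named by gene id, or with a
#'   `gene_id` metadata column).
#' @param tads GRanges of TAD intervals (named, or with a `name` column).
#' @return Named character vector gene id -> TAD id (NA when the midpoint
#'   falls in no TAD).
#' @export
assign_genes_to_tads <- function(genes, tads) {
  gid <- names(genes)
  if (is.null(gid)) gid <- mcols(genes)$gene_id
  tid <- names(tads)
  if (is.null(tid)) tid <- mcols(tads)$name
  stopifnot(!is.null(gid), !is.null(tid))
  mids <- GRanges(seqnames(genes), IRanges(mid(ranges(genes)), width = 1))
  hit <- findOverlaps(mids, tads, select = "first", ignore.strand = TRUE)
  setNames(tid[hit], gid)
}

#' TAD nucleotide-signature tests
#'
#' For every TAD with more than `min_genes` member genes and every
#' configured variable, compares the variable's distribution over the
#' TAD's genes with that over all other genes by a two-sample
#' Kolmogorov-Smirnov test.  Benjamini-Hochberg correction is applied
#' jointly over all (TAD, variable) tests; a TAD carries a signature when
#' any of its tests has q below `fdr`.
#'
#' @param features Feature matrix (genes x variables).
#' @param tad_membership Named gene -> TAD vector (NA = no TAD), e.g. from
#'   [assign_genes_to_tads()].
#' @param min_genes TADs with at most this many genes are excluded.
#' @param fdr FDR level for the signature flag.
#' @param variables Columns to test (default all).
#' @return An object of class `tad_signature`: list with `tests`
#'   (data.frame: `tad`, `variable`, `D`, `p`, `q`), `flags` (named
#'   logical per TAD), `excluded` (TADs below the size filter).
#' @export
tad_signature_tests <- function(features, tad_membership, min_genes = 10,
                                fdr = 0.05, variables = colnames(features)) {
  features <- as.matrix(features)
  stopifnot(!is.null(rownames(features)))
  memb <- tad_membership[rownames(features)]
  sizes <- table(memb[!is.na(memb)])
  keep_tads <- names(sizes)[sizes > min_genes]
  excluded <- base::setdiff(names(sizes), keep_tads)
  if (length(keep_tads) < 2) {
    stop("fewer than 2 TADs pass the min_genes filter")
  }
  res <- list()
  for (td in keep_tads) {
    inside <- !is.na(memb) & memb == td
    for (v in variables) {
      xin <- features[inside, v]; xout <- features[!inside, v]
      xin <- xin[!is.na(xin)]; xout <- xout[!is.na(xout)]
      kt <- suppressWarnings(ks.test(xin, xout))
      res[[length(res) + 1L]] <- data.frame(
        tad = td, variable = v, D = unname(kt$statistic),
        p = kt$p.value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, res)
  tests$q <- p.adjust(tests$p, method = "BH")
  flags <- tapply(tests$q < fdr, tests$tad, any)
  structure(list(tests = tests,
                 flags = setNames(as.logical(flags), names(flags)),
                 excluded = excluded, fdr = fdr),
            class = "tad_signature")
}

#' @export
print.tad_signature <- function(x, ...) {
  cat("tad_signature:", length(x$flags), "TADs tested,",
      sum(x$flags), "flagged at FDR", x$fdr, "\n")
  invisible(x)
}

#' TAD enrichment within gene groups
#'
#' Tests the over-representation of each qualifying TAD within each gene
#' group with the upper-tail hypergeometric probability
#' `P(X >= k)` for `k` group genes in the TAD, given the TAD's gene count
#' and the shared gene universe.  Reported per group is whether any TAD is
#' enriched at raw `p < alpha`; BH-adjusted q values are emitted
#' alongside.
#'
#' @param groups data.frame with columns `group` and `gene` (one row per
#'   gene; an optional `sample` column distinguishes trees).
#' @param tad_membership Named gene -> TAD vector.
#' @param min_genes TADs with at most this many genes are excluded.
#' @param alpha Raw p-value cutoff for the per-group enrichment flag.
#' @return An object of class `tad_enrichment`: list with `tests`
#'   (data.frame: `group`, `tad`, `k`, `n`, `K`, `N`, `p`, `q`),
#'   `group_enriched` (named logical), `fraction_enriched`.
#' @export
tad_group_enrichment <- function(groups, tad_membership, min_genes = 10,
                                 alpha = 0.05) {
  stopifnot(all(c("group", "gene") %in% colnames(groups)))
  if ("sample" %in% colnames(groups)) {
    gkey <- paste(groups$sample, groups$group, sep = ":")
  } else {
    gkey <- as.character(groups$group)
  }
  universe <- names(tad_membership)
  gl <- split(groups$gene, gkey)
  gl <- lapply(gl, function(gs) base::intersect(unique(gs), universe))
  gl <- gl[lengths(gl) > 0]
  N <- length(universe)
  sizes <- table(tad_membership[!is.na(tad_membership)])
  keep_tads <- names(sizes)[sizes > min_genes]
  res <- list()
  for (g in names(gl)) {
    gs <- gl[[g]]
    memb_g <- tad_membership[gs]
    for (td in keep_tads) {
      K <- as.integer(sizes[[td]])
      k <- sum(!is.na(memb_g) & memb_g == td)
      p <- phyper(k - 1, K, N - K, length(gs), lower.tail = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        group = g, tad = td, k = k, n = length(gs), K = K, N = N, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, res)
  tests$q <- p.adjust(tests$p, method = "BH")
  enriched <- tapply(tests$p < alpha, tests$group, any)
  enriched <- setNames(as.logical(enriched), names(enriched))
  structure(list(tests = tests, group_enriched = enriched,
                 fraction_enriched = mean(enriched), alpha = alpha),
            class = "tad_enrichment")
}

#' @export
print.tad_enrichment <- function(x, ...) {
  cat("tad_enrichment:", length(x$group_enriched), "groups,",
      round(100 * x$fraction_enriched, 1),
      "% with >= 1 enriched TAD (p <", x$alpha, ")\n")
  invisible(x)
}

#' Density of query intervals over gene regions
#'
#' Count mode: total number of query items falling in the regions divided
#' by the total region length (e.g. cis-eQTLs or SNPs per bp).  Length
#' mode: total intersection length divided by total region length (e.g.
#' enhancer coverage).
#'
#' @param query GRanges of query items (points as 1-bp intervals, spans
#'   as-is).
#' @param regions GRanges of the per-gene region intervals.
#' @param mode `"count"` or `"length"`.
#' @return A single density value.
#' @export
interval_density <- function(query, regions, mode = c("count", "length")) {
  mode <- match.arg(mode)
  total <- sum(as.numeric(width(regions)))
  if (total == 0) stop("zero total region length: density undefined")
  if (mode == "count") {
    ## a query item inside two genes' regions counts once per region
    sum(countOverlaps(query, regions, ignore.strand = TRUE)) / total
  } else {
    ## the query acts as a set (overlapping items unioned), but the
    ## per-gene regions are NOT unioned: the intersection length is
    ## summed over regions
    q <- reduce(query, ignore.strand = TRUE)
    ov <- findOverlaps(q, regions, ignore.strand = TRUE)
    pieces <- IRanges::pintersect(
      `strand<-`(q[S4Vectors::queryHits(ov)], value = "*"),
      `strand<-`(regions[S4Vectors::subjectHits(ov)], value = "*"))
    sum(as.numeric(width(pieces))) / total
  }
}

#' Gini coefficient of per-sample expression
#'
#' Relative mean absolute difference,
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`, in `[0, 1)`: 0 for a gene
#' expressed uniformly in all samples, `(n-1)/n` for a gene expressed in
#' a single sample.
#'
#' @param values Non-negative expression values of one gene across
#'   samples; all-zero input is missing-coded (NA).
#' @return The Gini coefficient.
#' @export
gini <- function(values) {
  stopifnot(all(values >= 0))
  n <- length(values)
  if (all(values == 0)) return(NA_real_)
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * mean(values))
}

#' Correlation between model error and expression ubiquity
#'
#' Spearman correlation between per-gene Gini coefficients (expression
#' ubiquity) and per-gene model absolute errors, plus a two-sided
#' rank-sum (Wilcoxon) comparison of the errors in the bottom vs top
#' quartile of the Gini distribution.
#'
#' @param gini_values Named per-gene Gini coefficients.
#' @param abs_error Named per-gene absolute errors.
#' @return List with `spearman_rho`, `n`, `wilcoxon_p`, and the two
#'   quartile gene counts.
#' @export
error_ubiquity_correlation <- function(gini_values, abs_error) {
  common <- base::intersect(names(gini_values), names(abs_error))
  if (length(common) < 10) stop("fewer than 10 common genes")
  g <- gini_values[common]; e <- abs_error[common]
  qs <- quantile(g, c(0.25, 0.75), type = 7)
  lo <- e[g <= qs[1]]; hi <- e[g >= qs[2]]
  wt <- suppressWarnings(wilcox.test(lo, hi))
  list(spearman_rho = spearman(g, e), n = length(common),
       wilcoxon_p = wt$p.value, n_low = length(lo), n_high = length(hi))
}
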