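#' Pipeline configuration
#'
#' Collects the inputs and options of an end-to-end run.  Inputs may be
#' file paths (FASTA genome, GTF annotation, TSV expression, BED6 TADs,
#' PFM motifs, TSV shape table) or the in-memory objects the io functions
#' return.
#'
#' @param genome DNAStringSet or FASTA path.
#' @param annotation GTF-style GRanges or GTF path.
#' @param expression Genes x samples matrix or TSV path.
#' @param out_dir Run directory (created if needed).
#' @param tads Optional GRanges or BED path.
#' @param pwms Optional list of [pwm] or PFM path.
#' @param shape_table Optional shape table or TSV path.
#' @param tss_choice Passed to [select_tss()].
#' @param level `"gene"` or `"transcript"`.
#' @param transform Expression transform (`"none"` for already-log data,
#'   `"log1p"` for raw counts).
#' @param percent_regions,k,double_strand Feature families (see
#'   [build_feature_matrix()]).
#' @param folds Evaluation folds.
#' @param seed Master seed.
#' @param control `"none"`, `"permute"` or `"max"` negative control.
#' @param stability Run stability selection per sample (slower).
#' @param stability_iters Iterations when `stability` is TRUE.
#' @param min_leaf Minimum genes per error-tree leaf.
#' @param tad_min_genes TAD size filter.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, expression, out_dir,
                            tads = NULL, pwms = NULL, shape_table = NULL,
                            tss_choice = "second",
                            level = "gene",
                            transform = c("none", "log1p"),
                            percent_regions = REGION_KINDS,
                            k = c(1, 2),
                            double_strand = FALSE,
                            folds = 10, seed = 1,
                            control = c("none", "permute", "max"),
                            stability = FALSE, stability_iters = 200,
                            min_leaf = 100, tad_min_genes = 10) {
  structure(list(genome = genome, annotation = annotation,
                 expression = expression, out_dir = out_dir, tads = tads,
                 pwms = pwms, shape_table = shape_table,
                 tss_choice = tss_choice, level = level,
                 transform = match.arg(transform),
                 percent_regions = percent_regions, k = k,
                 double_strand = double_strand, folds = folds,
                 seed = as.integer(seed), control = match.arg(control),
                 stability = stability, stability_iters = stability_iters,
                 min_leaf = min_leaf, tad_min_genes = tad_min_genes),
            class = "pipeline_config")
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full pipeline
#'
#' Orchestrates region derivation, feature construction, per-sample
#' cross-validated lasso evaluation (optionally on a negative control),
#' error-tree gene grouping, group flagging, and -- when TADs are
#' supplied -- TAD signature tests and group enrichment.  All stage
#' outputs are written as TSV/JSON into the run directory together with a
#' manifest of MD5 content hashes; repeated runs with the same
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `evaluations`, `groups`,
#'   `flagged_groups`, `stability`, `tad_signature`, `tad_enrichment`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] ", "seqexpr"), sprintf(...), "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  genome <- load_input(config$genome, readDNAStringSet)
  names(genome) <- sub("\\s.*", "", names(genome))
  annotation <- load_input(config$annotation, read_gtf)
  expr <- load_input(config$expression, read_matrix_tsv)
  tads <- if (!is.null(config$tads)) load_input(config$tads, read_bed)
  pwms <- if (!is.null(config$pwms)) load_input(config$pwms, read_pfm)
  shape <- if (!is.null(config$shape_table)) {
    load_input(config$shape_table,
               function(p) read.delim(p, stringsAsFactors = FALSE))
  }
  logf("inputs: %d chromosomes, %d annotation records, %d x %d expression",
       length(genome), length(annotation), nrow(expr), ncol(expr))

  catalog <- build_catalog(annotation, genome, tss_choice = config$tss_choice,
                           level = config$level)
  features <- build_feature_matrix(catalog,
                                   percent_regions = config$percent_regions,
                                   k = config$k, pwms = pwms,
                                   shape_table = shape,
                                   double_strand = config$double_strand)
  logf("features: %d x %d", nrow(features), ncol(features))

  y_all <- preprocess_expression(expr, transform = config$transform,
                                 drop_undetected = config$transform == "log1p")
  common <- base::intersect(rownames(features), rownames(y_all))
  features <- features[common, , drop = FALSE]
  y_all <- y_all[common, , drop = FALSE]
  fx <- drop_incomplete_genes(features, y_all)
  features <- fx$features; y_all <- fx$y

  x_model <- switch(config$control,
                    none = features,
                    permute = permute_within_genes(features,
                                                   seed = config$seed),
                    max = max_variable_control(features))

  samples <- colnames(y_all)
  evals <- list(); groups_all <- list(); stab <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    ev <- evaluate_cv(x_model, y_all[, si], k = config$folds,
                      seed = config$seed + si)
    evals[[s]] <- ev
    tr <- fit_error_tree(features, ev$per_gene_abs_error,
                         min_leaf = config$min_leaf,
                         seed = config$seed + si, sample_id = s)
    groups_all[[s]] <- tr$groups
    if (config$stability) {
      stab[[s]] <- stability_select(x_model, y_all[, si],
                                    n_iter = config$stability_iters,
                                    seed = config$seed + si)
    }
    logf("sample %s: rho=%.4f mse=%.4f groups=%d", s, ev$spearman_rho,
         ev$mse, length(unique(tr$groups$group)))
  }
  groups <- do.call(rbind, groups_all)
  rownames(groups) <- NULL
  flagged <- tryCatch(flag_well_predicted(groups), error = function(e) NULL)

  tad_sig <- NULL; tad_enr <- NULL
  if (!is.null(tads)) {
    genes_gr <- annotation[mcols(annotation)$type == "gene"]
    names(genes_gr) <- mcols(genes_gr)$gene_id
    memb <- assign_genes_to_tads(genes_gr[common], tads)
    tad_sig <- tryCatch(
      tad_signature_tests(features, memb,
                          min_genes = config$tad_min_genes),
      error = function(e) { logf("tad signature skipped: %s",
                                 conditionMessage(e)); NULL })
    if (!is.null(flagged) && any(flagged$flagged)) {
      fg <- flagged[flagged$flagged, ]
      sel <- groups[paste(groups$sample, groups$group) %in%
                      paste(fg$sample, fg$group), ]
      tad_enr <- tryCatch(
        tad_group_enrichment(sel, memb, min_genes = config$tad_min_genes),
        error = function(e) { logf("tad enrichment skipped: %s",
                                   conditionMessage(e)); NULL })
    }
  }

  ## write artifacts
  od <- config$out_dir
  files <- character(0)
  wf <- function(obj, name, writer) {
    p <- file.path(od, name); writer(obj, p); files <<- c(files, p); p
  }
  wf(features, "features.tsv", write_matrix_tsv)
  ev_df <- data.frame(sample = samples,
                      spearman_rho = vapply(evals, `[[`, 0, "spearman_rho"),
                      mse = vapply(evals, `[[`, 0, "mse"),
                      n_genes = vapply(evals, `[[`, 0, "n_genes"),
                      control = config$control)
  wf(ev_df, "evaluation.tsv", function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  err_mat <- sapply(evals, `[[`, "per_gene_abs_error")
  rownames(err_mat) <- common
  wf(err_mat, "abs_error.tsv", write_matrix_tsv)
  wf(groups, "groups.tsv", function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  if (!is.null(flagged)) {
    wf(flagged, "groups_flagged.tsv", function(o, p)
      write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (length(stab)) {
    sdf <- do.call(rbind, lapply(names(stab), function(s)
      cbind(sample = s, as.data.frame(stab[[s]]))))
    wf(sdf, "stability.tsv", function(o, p)
      write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (!is.null(tad_sig)) {
    wf(tad_sig$tests, "tad_signature.tsv", function(o, p)
      write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if (!is.null(tad_enr)) {
    wf(tad_enr$tests, "tad_enrichment.tsv", function(o, p)
      write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  files <- c(files, log_path)
  manifest <- write_manifest(od, files,
                             extra = list(seed = config$seed,
                                          control = config$control,
                                          n_genes = nrow(features),
                                          n_samples = length(samples)))
  invisible(list(features = features, evaluations = evals, groups = groups,
                 flagged_groups = flagged, stability = stab,
                 tad_signature = tad_sig, tad_enrichment = tad_enr,
                 manifest = manifest))
}
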