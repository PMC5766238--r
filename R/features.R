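#' Nucleotide percentages
#'
#' Percentage of each of A, C, G, T in a sequence, computed over the
#' unambiguous bases only: `100 * #N / l` with `l` the count of A/C/G/T.
#' Sequences with no unambiguous base are missing-coded (NA row) with a
#' warning.
#'
#' @param seqs DNAStringSet (or character vector) of sequences.
#' @return Numeric matrix, one row per sequence, columns A, C, G, T.
#' @export
nt_percentage <- function(seqs) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  counts <- letterFrequency(seqs, NUCS)
  tot <- rowSums(counts)
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " sequence(s) empty or all-ambiguous; missing-coded")
  }
  out <- 100 * counts / ifelse(tot == 0, NA_real_, tot)
  colnames(out) <- NUCS
  rownames(out) <- names(seqs)
  out
}

#' k-mer percentages
#'
#' Percentage of each k-mer over the valid windows of each sequence:
#' `100 * #kmer / n_windows`, where windows containing ambiguous bases are
#' excluded from both numerator and denominator.  With no ambiguity the
#' denominator is `l - k + 1` (the dinucleotide denominator `l - 1`).
#'
#' @param seqs DNAStringSet (or character vector).
#' @param k Word size, 2 (dinucleotides) or 3 (trinucleotides).
#' @return Matrix, one row per sequence; columns named `ApA`, `ApC`, ...
#'   (`ApApA`, ... for k = 3).  Sequences with no valid window are NA.
#' @export
kmer_percentage <- function(seqs, k = 2) {
  stopifnot(k %in% c(2, 3))
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  counts <- oligonucleotideFrequency(seqs, k)
  tot <- rowSums(counts)
  out <- 100 * counts / ifelse(tot == 0, NA_real_, tot)
  colnames(out) <- kmer_label(colnames(counts))
  rownames(out) <- names(seqs)
  out
}

## complement-pairing of features for the double-strand mode:
## nucleotide N merges with its complement, k-mer N1..Nk with comp(N1)..
## comp(Nk); 4 nt -> 2 classes, 16 dinucleotides -> 8 classes.
ds_class <- function(feature) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(feature, function(f) {
    nts <- strsplit(kmer_unlabel(f), "")[[1]]
    if (!all(nts %in% NUCS)) return(NA_character_)
    partner <- paste(comp[nts], collapse = "")
    pair <- sort(c(paste(nts, collapse = ""), partner))
    paste(kmer_label(pair), collapse = "|")
  }, "")
}

#' Collapse single-strand composition features to double-strand classes
#'
#' Merges each nucleotide or dinucleotide percentage with that of its
#' complement on the opposite strand by summation, reducing 4 nucleotides
#' to 2 classes (A|T, C|G) and 16 dinucleotides to 8 classes (e.g.
#' CpG|GpC, ApC|TpG).  The classes partition the inputs, so collapsed
#' percentages still sum to 100 per gene and region.
#'
#' @param features Feature matrix whose composition columns are named
#'   `<kmer>_<REGION>`; non-composition columns pass through unchanged.
#' @return Matrix with collapsed composition columns.
#' @export
collapse_double_strand <- function(features) {
  features <- as.matrix(features)
  info <- parse_variable(colnames(features))
  cls <- ds_class(info$feature)
  newname <- ifelse(is.na(cls), info$variable,
                    paste0(cls, "_", info$region))
  uniq <- unique(newname)
  out <- vapply(uniq, function(nm) {
    rowSums(features[, newname == nm, drop = FALSE])
  }, numeric(nrow(features)))
  if (nrow(features) == 1) out <- matrix(out, 1, dimnames = list(NULL, uniq))
  rownames(out) <- rownames(features)
  out
}

## log-odds score matrix of a PWM against a prior
pwm_lo <- function(w, prior = NULL) {
  if (is.null(prior)) prior <- w$prior
  prior <- prior[NUCS]
  log(w$probs / prior)
}

#' PWM log-odds score at one position
#'
#' `score(w, s, i) = sum_j log(P(s[i+j] | w_j) / P(s[i+j]))` with natural
#' logarithm; `i` is the 0-based window offset, matching the formula's
#' indexing (`i = 0` scores the window starting at the first base).
#'
#' @param w A [pwm].
#' @param s A single sequence (character or DNAString).
#' @param i 0-based window offset, `0 <= i <= l - |w|`.
#' @param prior Optional background probabilities overriding `w$prior`.
#' @return The log-odds score; NA if the window contains an ambiguous base.
#' @export
pwm_score_at <- function(w, s, i, prior = NULL) {
  s <- as.character(s)
  m <- ncol(w$probs)
  if (i < 0 || i > nchar(s) - m) stop("window offset out of range")
  win <- strsplit(substr(s, i + 1, i + m), "")[[1]]
  code <- match(win, NUCS)
  if (anyNA(code)) return(NA_real_)
  lo <- pwm_lo(w, prior)
  sum(lo[cbind(code, seq_len(m))])
}

## all window scores of one PWM along one encoded sequence
pwm_window_scores <- function(lo, code) {
  m <- ncol(lo)
  nw <- length(code) - m + 1L
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  valid <- !is.na(code)
  ok <- rep(TRUE, nw)
  for (j in seq_len(m)) {
    cj <- code[j:(j + nw - 1L)]
    v <- lo[cbind(cj, j)]
    ok <- ok & !is.na(cj)
    sc <- sc + ifelse(is.na(v), 0, v)
  }
  sc[!ok] <- NA_real_
  sc
}

#' Maximal and summed PWM scores over a sequence
#'
#' The motif score of a sequence is the maximum (or the sum) of the
#' per-position log-odds scores over all windows `i = 0 .. l - |w|`;
#' windows containing ambiguous bases are skipped.  With no valid window
#' the score is NA.  Ties in the maximum resolve to the smallest offset.
#'
#' @param w A [pwm].
#' @param s A single sequence.
#' @param prior Optional background probabilities overriding `w$prior`.
#' @param both_strands If TRUE, also scan the reverse complement and take
#'   the max (resp. the sum over both strands).
#' @return Numeric score.
#' @export
pwm_score_max <- function(w, s, prior = NULL, both_strands = FALSE) {
  sc <- pwm_all_scores(w, s, prior, both_strands)
  if (!length(sc) || all(is.na(sc))) return(NA_real_)
  max(sc, na.rm = TRUE)
}

#' @rdname pwm_score_max
#' @export
pwm_score_sum <- function(w, s, prior = NULL, both_strands = FALSE) {
  sc <- pwm_all_scores(w, s, prior, both_strands)
  if (!length(sc) || all(is.na(sc))) return(NA_real_)
  sum(sc, na.rm = TRUE)
}

pwm_all_scores <- function(w, s, prior = NULL, both_strands = FALSE) {
  s <- as.character(s)
  lo <- pwm_lo(w, prior)
  code <- match(strsplit(toupper(s), "")[[1]], NUCS)
  sc <- pwm_window_scores(lo, code)
  if (both_strands) {
    rc <- as.character(reverseComplement(DNAStringSet(s)))
    code2 <- match(strsplit(rc, "")[[1]], NUCS)
    sc <- c(sc, pwm_window_scores(lo, code2))
  }
  sc
}

#' Mean DNA-shape scores of a sequence
#'
#' Slides a pentamer window along the sequence, looks each pentamer up in
#' the shape table (falling back to its reverse complement), and returns
#' the mean of the per-window values for each shape feature.  Windows with
#' ambiguous bases are skipped; sequences shorter than 5 bp are NA.
#'
#' @param seqs DNAStringSet (or character vector).
#' @param table data.frame with columns `pentamer` plus one column per
#'   shape feature (e.g. MGW, HelT, ProT, Roll), as from
#'   [synthetic_shape_table()] or a measured pentamer table.
#' @return Matrix, sequences x shape features.
#' @export
shape_means <- function(seqs, table) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  stopifnot("pentamer" %in% colnames(table))
  shapes <- setdiff(colnames(table), "pentamer")
  lut <- as.matrix(table[, shapes, drop = FALSE])
  rownames(lut) <- table$pentamer
  rc <- as.character(reverseComplement(DNAStringSet(table$pentamer)))
  add <- !(rc %in% rownames(lut))
  if (any(add)) lut <- rbind(lut, `rownames<-`(lut[add, , drop = FALSE],
                                               rc[add]))
  out <- matrix(NA_real_, length(seqs), length(shapes),
                dimnames = list(names(seqs), shapes))
  chars <- as.character(seqs)
  for (i in seq_along(chars)) {
    l <- nchar(chars[i])
    if (l < 5) next
    win <- substring(chars[i], 1:(l - 4), 5:l)
    valid <- grepl("^[ACGT]{5}$", win)
    if (!any(valid)) next
    hit <- match(win[valid], rownames(lut))
    if (anyNA(hit)) {
      stop("pentamer(s) absent from shape table (and reverse complement): ",
           paste(head(unique(win[valid][is.na(hit)]), 3), collapse = ", "))
    }
    out[i, ] <- colMeans(lut[hit, , drop = FALSE])
  }
  out
}

#' Assemble the genes x variables feature matrix
#'
#' Computes the configured feature families for each region and binds them
#' into one matrix with `<feature>_<REGION>` column names (e.g.
#' `CpG_CORE`, `motif:MA0001.1_CORE`, `shape:MGW_DU`).  The default full
#' model is the 4 nucleotide + 16 dinucleotide percentages in all 8
#' regions (160 columns).  Genes whose region sequence is empty are
#' missing-coded (NA), never 0.
#'
#' @param catalog A [build_catalog()] result.
#' @param percent_regions Regions for (di)nucleotide percentages.
#' @param k k-mer orders for `percent_regions` (subset of 1, 2, 3).
#' @param trinucleotide_regions Extra regions receiving the 64
#'   trinucleotide percentages (when 3 is not in `k`).
#' @param pwms Optional list of [pwm] objects for motif scores.
#' @param motif_regions Regions scanned with the PWMs (default CORE).
#' @param motif_stat `"max"` or `"sum"` window score.
#' @param scan_both_strands Scan both strands for motif scores.
#' @param prior Motif background: `"scanned"` (composition of the scanned
#'   sequences, the default) or `"uniform"`.
#' @param shape_table Optional pentamer shape table (see [shape_means()]).
#' @param shape_regions Regions for shape means (default DU, CORE, DD).
#' @param double_strand Collapse composition features to double-strand
#'   classes (2 nt + 8 dinucleotide per region).
#' @return Numeric matrix, genes x variables.
#' @export
build_feature_matrix <- function(catalog,
                                 percent_regions = REGION_KINDS,
                                 k = c(1, 2),
                                 trinucleotide_regions = NULL,
                                 pwms = NULL,
                                 motif_regions = "CORE",
                                 motif_stat = c("max", "sum"),
                                 scan_both_strands = FALSE,
                                 prior = c("scanned", "uniform"),
                                 shape_table = NULL,
                                 shape_regions = c("DU", "CORE", "DD"),
                                 double_strand = FALSE) {
  stopifnot(inherits(catalog, "region_catalog"))
  motif_stat <- match.arg(motif_stat)
  prior <- match.arg(prior)
  stopifnot(all(percent_regions %in% REGION_KINDS),
            all(k %in% 1:3))
  blocks <- list()
  add_block <- function(m, region) {
    colnames(m) <- paste0(colnames(m), "_", region)
    blocks[[length(blocks) + 1L]] <<- m
  }
  for (r in percent_regions) {
    s <- catalog$seqs[[r]]
    if (1 %in% k) add_block(suppressWarnings(nt_percentage(s)), r)
    if (2 %in% k) add_block(kmer_percentage(s, 2), r)
    if (3 %in% k) add_block(kmer_percentage(s, 3), r)
  }
  if (!is.null(trinucleotide_regions)) {
    stopifnot(all(trinucleotide_regions %in% REGION_KINDS))
    for (r in setdiff(trinucleotide_regions,
                      if (3 %in% k) percent_regions else character(0))) {
      add_block(kmer_percentage(catalog$seqs[[r]], 3), r)
    }
  }
  if (!is.null(pwms)) {
    stopifnot(all(motif_regions %in% REGION_KINDS))
    for (r in motif_regions) {
      s <- catalog$seqs[[r]]
      pr <- if (prior == "uniform") c(A = .25, C = .25, G = .25, T = .25)
        else scanned_prior(s)
      scores <- sapply(pwms, function(w) {
        f <- if (motif_stat == "max") pwm_score_max else pwm_score_sum
        vapply(as.character(s), f, numeric(1), w = w, prior = pr,
               both_strands = scan_both_strands, USE.NAMES = FALSE)
      })
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(s))
      colnames(scores) <- paste0("motif:", vapply(pwms, `[[`, "", "id"))
      rownames(scores) <- names(s)
      add_block(scores, r)
    }
  } else if (!identical(motif_regions, "CORE") && length(motif_regions)) {
    ## non-default motif request without PWMs is a configuration error
    stop("motif regions requested but no PWMs supplied")
  }
  if (!is.null(shape_table)) {
    stopifnot(all(shape_regions %in% REGION_KINDS))
    for (r in shape_regions) {
      m <- shape_means(catalog$seqs[[r]], shape_table)
      colnames(m) <- paste0("shape:", colnames(m))
      add_block(m, r)
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- catalog$ids
  if (double_strand) out <- collapse_double_strand(out)
  out
}

## background composition of the scanned sequences
scanned_prior <- function(seqs) {
  counts <- colSums(letterFrequency(seqs, NUCS))
  if (sum(counts) == 0) return(c(A = .25, C = .25, G = .25, T = .25))
  counts / sum(counts)
}

#' Drop genes with missing features
#'
#' Genes with any missing configured feature are removed before model
#' fitting, with a message stating the count.
#'
#' @param features Feature matrix.
#' @param y Optional response vector/matrix filtered in step.
#' @return The filtered matrix, or `list(features, y)` when `y` is given.
#' @export
drop_incomplete_genes <- function(features, y = NULL) {
  keep <- complete.cases(features)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with missing features dropped (",
            sum(keep), " retained)")
  }
  features <- features[keep, , drop = FALSE]
  if (is.null(y)) return(features)
  y <- if (is.matrix(y)) y[keep, , drop = FALSE] else y[keep]
  list(features = features, y = y)
}
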