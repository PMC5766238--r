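NUCS <- c("A", "C", "G", "T")

# "CG" -> "CpG", "ACG" -> "ApCpG"
kmer_label <- function(kmers) {
  vapply(strsplit(kmers, ""), paste, "", collapse = "p")
}

kmer_unlabel <- function(labels) gsub("p", "", labels, fixed = TRUE)

#' Split a variable name into feature and region
#'
#' Variable names follow the `<feature>_<REGION>` convention (e.g.
#' `"CpG_CORE"`, `"motif:MA0001.1_CORE"`); the region is the suffix after
#' the last underscore and must be one of [REGION_KINDS].
#'
#' @param x Character vector of variable names.
#' @return A data.frame with columns `variable`, `feature`, `region`.
#' @export
parse_variable <- function(x) {
  m <- regmatches(x, regexpr("_[^_]+$", x))
  region <- sub("^_", "", m)
  feature <- sub("_[^_]+$", "", x)
  bad <- !(region %in% REGION_KINDS) | !nzchar(feature)
  if (any(bad)) {
    stop("variable name(s) not of the form <feature>_<REGION>: ",
         paste(x[bad], collapse = ", "))
  }
  data.frame(variable = x, feature = feature, region = region,
             stringsAsFactors = FALSE)
}

## Vectorized sequence extraction from an in-memory genome.  Minus-strand
## ranges are reverse-complemented so sequences read in transcription
## orientation.
extract_seq <- function(genome, gr) {
  stopifnot(is(genome, "DNAStringSet"), is(gr, "GRanges"))
  out <- vector("list", length(gr))
  chrom <- as.character(seqnames(gr))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  res <- DNAStringSet(rep("", length(gr)))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    subj <- genome[[ch]]
    s <- start(gr)[idx]; e <- end(gr)[idx]
    if (any(s < 1L) || any(e > length(subj))) {
      stop("interval outside genome bounds on ", ch)
    }
    v <- DNAStringSet(Views(subj, start = s, end = e))
    neg <- as.character(strand(gr))[idx] == "-"
    if (any(neg)) v[neg] <- reverseComplement(v[neg])
    res[idx] <- v
  }
  names(res) <- names(gr)
  res
}

## Random DNA: iid draws, or a first-order Markov chain when dinucleotide
## shifts are requested (shift = target additive change in dinucleotide
## frequency; implemented by boosting the corresponding transition).
random_dna <- function(n, base_composition, dinuc_shift = NULL) {
  p <- base_composition[NUCS]
  if (is.null(dinuc_shift) || !length(dinuc_shift)) {
    return(paste(sample(NUCS, n, replace = TRUE, prob = p), collapse = ""))
  }
  trans <- matrix(rep(p, each = 4), nrow = 4, dimnames = list(NUCS, NUCS))
  for (d in names(dinuc_shift)) {
    nm <- strsplit(kmer_unlabel(d), "")[[1]]
    if (length(nm) != 2 || !all(nm %in% NUCS)) {
      stop("dinucleotide shift name must be like 'CpG': ", d)
    }
    from <- nm[1]; to <- nm[2]
    delta <- dinuc_shift[[d]] / p[from]
    old <- trans[from, to]
    new <- old + delta
    if (new <= 0 || new >= 1) stop("dinucleotide shift too large: ", d)
    others <- setdiff(NUCS, to)
    trans[from, others] <- trans[from, others] * (1 - new) / (1 - old)
    trans[from, to] <- new
  }
  ## cumulative rows for inverse-CDF sampling
  cum <- t(apply(trans, 1, cumsum))
  x <- integer(n)
  u <- runif(n)
  x[1] <- sample.int(4, 1, prob = p)
  for (i in 2:n) {
    x[i] <- findInterval(u[i], cum[x[i - 1], ], left.open = TRUE) + 1L
  }
  paste(NUCS[x], collapse = "")
}

## Column standardization (mean 0, SD 1); zero-variance columns dropped
## with a warning.  Returns list(x, center, scale, dropped).
standardize_columns <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (any(!keep) && warn) {
    warning(sum(!keep), " zero-variance variable(s) dropped: ",
            paste(head(colnames(x)[!keep], 5), collapse = ", "))
  }
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = sds[keep])
  attr(xs, "scaled:center") <- NULL
  attr(xs, "scaled:scale") <- NULL
  list(x = xs, center = ctr[keep], scale = sds[keep],
       dropped = colnames(x)[!keep])
}

## Deterministic fold assignment for n items into k folds.
make_folds <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

spearman <- function(x, y) {
  suppressWarnings(cor(x, y, method = "spearman"))
}
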