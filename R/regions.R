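#' Choose a TSS among alternatives
#'
#' Genes commonly have several annotated transcription start sites.  The
#' promoter can be anchored on the first (5'-most), second, third or last
#' (most downstream) TSS; when the requested rank does not exist the
#' previous one is used (second falls back to first, third to second).
#' `last` always returns the most downstream TSS.
#'
#' @param tss_list Numeric positions ordered 5' to 3' in transcription
#'   direction (non-empty).
#' @param choice One of `"first"`, `"second"`, `"third"`, `"last"`.
#' @return The selected TSS position.
#' @export
select_tss <- function(tss_list, choice = c("second", "first", "third",
                                            "last")) {
  choice <- match.arg(choice)
  n <- length(tss_list)
  if (n == 0) stop("empty TSS list: annotation error")
  k <- switch(choice, first = 1L, second = min(2L, n), third = min(3L, n),
              last = n)
  tss_list[[k]]
}

#' Segment a promoter into DU, CORE and DD
#'
#' In transcription coordinates the promoter is cut at -2000/-500 (distal
#' upstream, DU), -500/+500 (core promoter, wider than the classical core
#' promoter) and +500/+2000 (distal downstream, DD).  On the minus strand
#' the DU and DD genomic intervals are mirrored about the TSS so that DU
#' stays transcriptionally upstream.  Segments are clipped at chromosome
#' bounds with a warning; a segment clipped away entirely is dropped.
#'
#' @param tss TSS position(s), 1-based genomic coordinate.
#' @param strand `"+"` or `"-"` (recycled).
#' @param chrom Chromosome name(s) (recycled).
#' @param chrom_len Chromosome length(s) for clipping (NA = no upper clip).
#' @return A GRanges with metadata columns `region` (DU/CORE/DD) and
#'   `tss_index` (index of the input TSS).
#' @export
segment_promoter <- function(tss, strand = "+", chrom = "chr",
                             chrom_len = NA_integer_) {
  n <- length(tss)
  strand <- rep_len(strand, n); chrom <- rep_len(chrom, n)
  chrom_len <- rep_len(chrom_len, n)
  neg <- strand == "-"
  s_du <- ifelse(neg, tss + 500, tss - 2000)
  e_du <- ifelse(neg, tss + 1999, tss - 501)
  s_dd <- ifelse(neg, tss - 2000, tss + 500)
  e_dd <- ifelse(neg, tss - 501, tss + 1999)
  df <- data.frame(
    chrom = rep(chrom, 3), tss_index = rep(seq_len(n), 3),
    strand = rep(strand, 3),
    region = rep(c("DU", "CORE", "DD"), each = n),
    start = c(s_du, tss - 500, s_dd),
    end = c(e_du, tss + 499, e_dd),
    len = rep(chrom_len, 3))
  clipped <- df$start < 1 | (!is.na(df$len) & df$end > df$len)
  df$start <- pmax(df$start, 1)
  df$end <- ifelse(is.na(df$len), df$end, pmin(df$end, df$len))
  empty <- df$start > df$end
  if (any(clipped)) {
    warning(sum(clipped), " promoter segment(s) clipped at chromosome ",
            "bounds (", sum(empty), " dropped)")
  }
  df <- df[!empty, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$region <- df$region
  mcols(gr)$tss_index <- df$tss_index
  gr
}

#' Merge intervals and concatenate their sequence
#'
#' Overlapping or bookended intervals are unioned (BedTools-merge
#' semantics) and the merged intervals' sequences are concatenated in
#' transcription order; minus-strand sequence is reverse-complemented.
#'
#' @param gr GRanges on a single chromosome and strand.
#' @param genome DNAStringSet genome.
#' @return List with `intervals` (merged GRanges) and `seq` (DNAString).
#' @export
merge_and_concatenate <- function(gr, genome) {
  if (length(unique(as.character(seqnames(gr)))) > 1 ||
      length(unique(as.character(strand(gr)))) > 1) {
    stop("intervals must share one chromosome and strand")
  }
  merged <- reduce(gr)
  neg <- length(merged) && as.character(strand(merged))[1] == "-"
  ord <- if (neg) order(-start(merged)) else order(start(merged))
  seqs <- extract_seq(genome, merged[ord])
  list(intervals = merged, seq = unlist(seqs))
}

#' Derive constitutive introns
#'
#' Set difference of the gene span and the union of its exonic (UTR/CDS)
#' intervals, as maximal disjoint intervals.
#'
#' @param gene_span GRanges of length 1.
#' @param exonic GRanges of exonic intervals within the span.
#' @return GRanges of intronic intervals (possibly empty).
#' @export
derive_introns <- function(gene_span, exonic) {
  GenomicRanges::setdiff(gene_span, reduce(exonic))
}

#' Derive the downstream flanking region (DFR)
#'
#' The 1 kb immediately after the gene end in transcription direction:
#' `[end+1, end+1000]` on the plus strand, `[start-1000, start-1]` on the
#' minus strand, clipped at chromosome bounds with a warning.
#'
#' @param gene GRanges of gene span(s).
#' @param chrom_len Chromosome length(s) for clipping (NA = none).
#' @param size DFR width in bp.
#' @return GRanges of DFR intervals (zero-width ranges dropped).
#' @export
derive_dfr <- function(gene, chrom_len = NA_integer_, size = 1000L) {
  neg <- as.character(strand(gene)) == "-"
  s <- ifelse(neg, start(gene) - size, end(gene) + 1L)
  e <- ifelse(neg, start(gene) - 1L, end(gene) + size)
  len <- rep_len(chrom_len, length(gene))
  clipped <- s < 1 | (!is.na(len) & e > len)
  s2 <- pmax(s, 1); e2 <- ifelse(is.na(len), e, pmin(e, len))
  if (any(clipped)) {
    warning(sum(clipped), " DFR interval(s) clipped at chromosome bounds")
  }
  keep <- s2 <= e2
  gr <- GRanges(seqnames(gene)[keep], IRanges(s2[keep], e2[keep]),
                strand = strand(gene)[keep])
  names(gr) <- names(gene)[keep]
  gr
}

## Concatenate per-unit region sequences in transcription order.
## grl: GRangesList named by unit id (may contain empty elements).
concat_by_unit <- function(grl, genome, ids) {
  ul <- unlist(grl, use.names = FALSE)
  unit <- rep(names(grl), S4Vectors::elementNROWS(grl))
  if (!length(ul)) {
    out <- DNAStringSet(rep("", length(ids))); names(out) <- ids
    return(out)
  }
  neg <- as.character(strand(ul)) == "-"
  ord <- order(match(unit, ids), ifelse(neg, -start(ul), start(ul)))
  seqs <- extract_seq(genome, ul[ord])
  spl <- S4Vectors::split(seqs, factor(unit[ord], levels = ids))
  out <- unstrsplit(spl)
  names(out) <- ids
  out
}

#' Build the per-gene region catalog
#'
#' Derives the eight region kinds for every gene (or transcript) of an
#' annotation and extracts their sequences in transcription orientation:
#' promoter segments DU/CORE/DD around the chosen TSS, merged 5'UTR, CDS
#' and 3'UTR, constitutive introns (gene span minus all UTR/CDS), and the
#' 1 kb downstream flanking region.
#'
#' @param annotation GTF-style GRanges with `type` (gene, transcript,
#'   five_prime_utr, CDS, three_prime_utr), `gene_id`, `transcript_id`,
#'   as returned by [read_gtf()] or [generate_annotation()].
#' @param genome DNAStringSet genome (chromosome lengths are taken from it
#'   for boundary clipping).
#' @param tss_choice Passed to [select_tss()].
#' @param level `"gene"` or `"transcript"` (isoform-level mode: the same
#'   regions derived per transcript).
#' @return An object of class `region_catalog`: list with `level`, `ids`,
#'   `tss` (list of ordered TSS positions), `tss_used`, `intervals` (list
#'   region kind -> GRangesList by unit), `seqs` (list region kind ->
#'   DNAStringSet by unit), `flags` (data.frame of empty regions),
#'   `skipped` (units without TSS).
#' @export
build_catalog <- function(annotation, genome, tss_choice = "second",
                          level = c("gene", "transcript")) {
  level <- match.arg(level)
  stopifnot(is(annotation, "GRanges"), is(genome, "DNAStringSet"))
  chrlen <- setNames(width(genome), names(genome))
  typ <- mcols(annotation)$type

  if (level == "gene") {
    units <- annotation[typ == "gene"]
    unit_id <- mcols(units)$gene_id
    key <- "gene_id"
  } else {
    units <- annotation[typ == "transcript"]
    unit_id <- mcols(units)$transcript_id
    key <- "transcript_id"
  }
  if (!length(units)) stop("annotation has no ", level, " records")
  names(units) <- unit_id
  ids <- unit_id
  st <- setNames(as.character(strand(units)), ids)
  chrom <- setNames(as.character(seqnames(units)), ids)

  ## TSS lists from transcript records (gene level) or the unit itself
  tx <- annotation[typ == "transcript"]
  tx_owner <- if (level == "gene") mcols(tx)$gene_id else
    mcols(tx)$transcript_id
  tx_tss <- ifelse(as.character(strand(tx)) == "+", start(tx), end(tx))
  tss_by_unit <- base::split(tx_tss, factor(tx_owner, levels = ids))
  tss <- lapply(setNames(ids, ids), function(id) {
    pos <- sort(unique(tss_by_unit[[id]]))
    if (st[id] == "-") rev(pos) else pos
  })
  skipped <- ids[lengths(tss) == 0]
  if (length(skipped)) {
    warning(length(skipped), " ", level, "(s) without TSS skipped: ",
            paste(head(skipped, 5), collapse = ", "))
    ids <- setdiff(ids, skipped)
    units <- units[ids]; st <- st[ids]; chrom <- chrom[ids]
    tss <- tss[ids]
  }
  tss_used <- vapply(tss, select_tss, numeric(1), choice = tss_choice)

  ## promoter segments
  prom <- suppressWarnings(
    segment_promoter(tss_used, st, chrom, chrlen[chrom]))
  intervals <- list()
  for (r in c("DU", "CORE", "DD")) {
    sub <- prom[mcols(prom)$region == r]
    f <- factor(ids[mcols(sub)$tss_index], levels = ids)
    intervals[[r]] <- S4Vectors::split(sub, f)
  }

  ## UTR / CDS regions merged per unit
  owner_all <- if (level == "gene") mcols(annotation)$gene_id else
    mcols(annotation)$transcript_id
  for (r in c("UTR5", "CDS", "UTR3")) {
    gtf_type <- c(UTR5 = "five_prime_utr", CDS = "CDS",
                  UTR3 = "three_prime_utr")[[r]]
    sub <- annotation[typ == gtf_type & owner_all %in% ids]
    f <- factor(if (level == "gene") mcols(sub)$gene_id else
      mcols(sub)$transcript_id, levels = ids)
    intervals[[r]] <- reduce(S4Vectors::split(sub, f))
  }

  ## constitutive introns: unit span minus all exonic sequence
  exonic <- reduce(S4Vectors::pc(intervals$UTR5, intervals$CDS,
                                 intervals$UTR3))
  intervals$INTR <- GenomicRanges::psetdiff(units, exonic)

  ## downstream flanking region
  dfr <- suppressWarnings(derive_dfr(units, chrlen[chrom]))
  intervals$DFR <- S4Vectors::split(dfr, factor(names(dfr), levels = ids))

  seqs <- lapply(intervals, concat_by_unit, genome = genome, ids = ids)
  flags <- do.call(rbind, lapply(REGION_KINDS, function(r) {
    w <- width(seqs[[r]])
    data.frame(id = ids, region = r, empty = w == 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(level = level, ids = ids, strand = st, tss = tss,
                 tss_used = tss_used, intervals = intervals[REGION_KINDS],
                 seqs = seqs[REGION_KINDS],
                 flags = flags[flags$empty, , drop = FALSE],
                 skipped = skipped),
            class = "region_catalog")
}

#' @export
print.region_catalog <- function(x, ...) {
  cat("region_catalog:", length(x$ids), x$level, "units x",
      length(x$seqs), "region kinds\n")
  cat("  empty regions:", nrow(x$flags),
      " skipped units:", length(x$skipped), "\n")
  invisible(x)
}

#' Region length report
#'
#' @param catalog A [build_catalog()] result.
#' @return Matrix of concatenated sequence lengths, units x region kinds.
#' @export
region_lengths <- function(catalog) {
  stopifnot(inherits(catalog, "region_catalog"))
  sapply(catalog$seqs, width)
}
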