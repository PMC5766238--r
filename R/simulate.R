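#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' The generator plants a known sparse linear model over standardized
#' composition features, optional TAD-level dinucleotide shifts, and a
#' controllable gene/TSS architecture, so that every downstream stage of
#' the pipeline can be tested against ground truth.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_samples Number of expression samples (columns) to generate.
#' @param region_length_means Named numeric vector of mean lengths (bp) for
#'   the variable-length gene parts: `UTR5`, `CDS`, `UTR3`, `INTR` (total
#'   intronic length per gene).  Promoter segments and DFR have fixed
#'   definitions (-2000/-500, -500/+500, +500/+2000, and gene end + 1 kb).
#' @param n_tss_range Integer `(min, max)` number of alternative TSSs per
#'   gene; minimum must be >= 1.
#' @param tad_count Number of TADs; each TAD occupies its own simulated
#'   chromosome and holds exactly `genes_per_tad` genes.
#' @param genes_per_tad Genes per TAD.  `n_genes` must be at least
#'   `tad_count * genes_per_tad`; surplus genes are placed on a TAD-free
#'   chromosome.
#' @param planted_support Named numeric vector of true coefficients on the
#'   standardized feature scale; names must parse as `<feature>_<REGION>`.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param base_composition Named probability vector over A, C, G, T; must
#'   sum to 1.
#' @param tad_shift Optional named list: `tad_shift[[tad_id]]` is a named
#'   numeric vector of additive dinucleotide-frequency shifts (e.g.
#'   `list(tad1 = c(CpG = 0.04))`), realized through a first-order Markov
#'   chain on that TAD's chromosome.
#' @param intercept True intercept of the generative expression model.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes,
                              n_samples = 1L,
                              region_length_means = c(UTR5 = 300, CDS = 1200,
                                                      UTR3 = 500, INTR = 2000),
                              n_tss_range = c(1L, 4L),
                              tad_count = 0L,
                              genes_per_tad = 0L,
                              planted_support = numeric(0),
                              noise_sd = 1,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                              tad_shift = NULL,
                              intercept = 0,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1, noise_sd >= 0)
  req <- c("UTR5", "CDS", "UTR3", "INTR")
  if (!all(req %in% names(region_length_means))) {
    stop("region_length_means must name ", paste(req, collapse = ", "))
  }
  if (any(region_length_means < 1)) stop("region lengths must be >= 1")
  if (length(n_tss_range) != 2 || n_tss_range[1] < 1 ||
      n_tss_range[2] < n_tss_range[1]) {
    stop("n_tss_range must be (min, max) with min >= 1")
  }
  if (any(base_composition < 0) ||
      abs(sum(base_composition[NUCS]) - 1) > 1e-12) {
    stop("base_composition must be non-negative and sum to 1")
  }
  if (tad_count > 0) {
    stopifnot(genes_per_tad >= 1)
    if (n_genes < tad_count * genes_per_tad) {
      stop("n_genes (", n_genes, ") too small for tad_count * genes_per_tad (",
           tad_count * genes_per_tad, ")")
    }
  }
  if (length(planted_support)) parse_variable(names(planted_support))
  if (!is.null(tad_shift)) {
    stopifnot(is.list(tad_shift), !is.null(names(tad_shift)))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 region_length_means = region_length_means,
                 n_tss_range = as.integer(n_tss_range),
                 tad_count = as.integer(tad_count),
                 genes_per_tad = as.integer(genes_per_tad),
                 planted_support = planted_support,
                 noise_sd = noise_sd,
                 base_composition = base_composition[NUCS],
                 tad_shift = tad_shift,
                 intercept = intercept,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Draw a positive length around a mean (~20% CV), floored at a minimum.
rlen <- function(n, mean, min = 60) {
  pmax(min, round(rnorm(n, mean, 0.2 * mean)))
}

#' Generate a synthetic genome, annotation and TADs
#'
#' Lays genes on simulated chromosomes (one chromosome per TAD plus one
#' for TAD-free genes, which avoids interval edge effects), draws the
#' genome sequence i.i.d. from `base_composition` -- or from a first-order
#' Markov chain on chromosomes whose TAD carries a dinucleotide shift --
#' and emits gene models from which all eight region kinds are derivable.
#' Each gene has a 5'UTR exon, a CDS exon and a 3'UTR exon separated by
#' two introns, and one transcript per alternative TSS.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, FASTA (`genome.fa`), GTF
#'   (`annotation.gtf`) and BED6 TADs (`tads.bed`) files are written there.
#' @return A list with elements `genome` (DNAStringSet), `annotation`
#'   (GTF-style GRanges with `type`, `gene_id`, `transcript_id`), `genes`
#'   (GRanges of gene spans), `tads` (GRanges, possibly empty),
#'   `tad_assignments` (named character: gene id -> TAD id or NA), and
#'   `files` (paths, when `dir` was given).
#' @export
generate_annotation <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rlm <- config$region_length_means
  n <- config$n_genes

  ## per-gene part lengths
  l5 <- rlen(n, rlm["UTR5"])
  lc <- rlen(n, rlm["CDS"])
  l3 <- rlen(n, rlm["UTR3"])
  li <- rlen(n, rlm["INTR"], min = 120)
  li1 <- pmax(60, round(li / 2)); li2 <- pmax(60, li - li1)
  span <- l5 + li1 + lc + li2 + l3
  strand_g <- sample(c("+", "-"), n, replace = TRUE)
  ntss <- sample(seq(config$n_tss_range[1], config$n_tss_range[2]),
                 n, replace = TRUE)

  ## chromosome layout: margin accommodates DU (2 kb) and DFR (1 kb)
  margin <- 3000L; gap <- 5000L
  in_tad <- config$tad_count * config$genes_per_tad
  chrom_of <- character(n); gstart <- integer(n)
  chroms <- character(0); chrlen <- integer(0)
  tad_id_of <- rep(NA_character_, n)
  place <- function(gidx, chrom_name) {
    k <- length(gidx)
    starts <- margin + c(0L, cumsum(span[gidx] + gap)[-k])
    list(starts = starts + 1L,  # 1-based gene starts
         len = margin + sum(span[gidx]) + (k - 1L) * gap + margin)
  }
  gi <- 0L
  tad_rows <- list()
  if (config$tad_count > 0) {
    for (t in seq_len(config$tad_count)) {
      gidx <- gi + seq_len(config$genes_per_tad); gi <- gi + config$genes_per_tad
      nm <- sprintf("chrT%d", t)
      pl <- place(gidx, nm)
      chrom_of[gidx] <- nm; gstart[gidx] <- pl$starts
      chroms <- c(chroms, nm); chrlen <- c(chrlen, pl$len)
      tid <- sprintf("tad%d", t)
      tad_id_of[gidx] <- tid
      tad_rows[[t]] <- data.frame(chrom = nm, start = margin - 500L + 1L,
                                  end = pl$len - margin + 500L,
                                  name = tid, stringsAsFactors = FALSE)
    }
  }
  if (gi < n) {
    gidx <- (gi + 1L):n
    pl <- place(gidx, "chrFree")
    chrom_of[gidx] <- "chrFree"; gstart[gidx] <- pl$starts
    chroms <- c(chroms, "chrFree"); chrlen <- c(chrlen, pl$len)
  }
  if (any(chrlen > 5e8)) {
    stop("chromosome capacity exceeded; reduce n_genes, genes_per_tad or ",
         "region_length_means")
  }

  ## genome sequence
  seqs <- character(length(chroms))
  names(seqs) <- chroms
  for (i in seq_along(chroms)) {
    nm <- chroms[i]
    shift <- NULL
    if (!is.null(config$tad_shift) && grepl("^chrT", nm)) {
      tid <- sprintf("tad%s", sub("chrT", "", nm))
      shift <- config$tad_shift[[tid]]
    }
    seqs[i] <- random_dna(chrlen[i], config$base_composition, shift)
  }
  genome <- DNAStringSet(seqs)

  ## gene models -> GTF-style records (vectorized over genes/transcripts)
  gene_ids <- sprintf("gene%04d", seq_len(n))
  gend <- gstart + span - 1L
  pos <- strand_g == "+"
  ## transcription-ordered part boundaries (genomic coordinates)
  u5s <- ifelse(pos, gstart, gend - l5 + 1L)
  u5e <- ifelse(pos, gstart + l5 - 1L, gend)
  cdss <- ifelse(pos, u5e + li1 + 1L, u5s - li1 - lc)
  cdse <- ifelse(pos, u5e + li1 + lc, u5s - li1 - 1L)
  u3s <- ifelse(pos, cdse + li2 + 1L, gstart)
  u3e <- ifelse(pos, gend, cdss - li2 - 1L)
  ## alternative TSS offsets within the 5'UTR exon
  offs <- lapply(seq_len(n), function(g) {
    max_off <- max(0L, l5[g] - 60L)
    extra <- if (ntss[g] > 1 && max_off > 0) {
      sort(sample.int(max_off, min(ntss[g] - 1L, max_off)))
    } else integer(0)
    c(0L, extra)
  })
  ntx <- lengths(offs)
  tg <- rep(seq_len(n), ntx)                 # gene index per transcript
  off <- unlist(offs)
  tid <- sprintf("%s.t%d", gene_ids[tg],
                 unlist(lapply(ntx, seq_len)))
  t5s <- ifelse(pos[tg], u5s[tg] + off, u5s[tg])
  t5e <- ifelse(pos[tg], u5e[tg], u5e[tg] - off)
  tspan_s <- pmin(t5s, cdss[tg], u3s[tg])
  tspan_e <- pmax(t5e, cdse[tg], u3e[tg])
  adf <- data.frame(
    type = c(rep("gene", n),
             rep(c("transcript", "exon", "exon", "exon", "five_prime_utr",
                   "CDS", "three_prime_utr"), each = length(tg))),
    start = c(gstart,
              tspan_s, t5s, cdss[tg], u3s[tg], t5s, cdss[tg], u3s[tg]),
    end = c(gend,
            tspan_e, t5e, cdse[tg], u3e[tg], t5e, cdse[tg], u3e[tg]),
    transcript_id = c(rep(NA_character_, n), rep(tid, 7)),
    gene_id = c(gene_ids, rep(gene_ids[tg], 7)),
    chrom = c(chrom_of, rep(chrom_of[tg], 7)),
    strand = c(strand_g, rep(strand_g[tg], 7)),
    stringsAsFactors = FALSE)
  ## stable order: by gene, gene record first, then transcript records
  adf <- adf[order(match(adf$gene_id, gene_ids),
                   !is.na(adf$transcript_id),
                   match(adf$transcript_id, tid),
                   match(adf$type, c("gene", "transcript", "exon",
                                     "five_prime_utr", "CDS",
                                     "three_prime_utr")),
              adf$start), ]
  annotation <- GRanges(adf$chrom, IRanges(adf$start, adf$end),
                        strand = adf$strand)
  mcols(annotation)$type <- adf$type
  mcols(annotation)$gene_id <- adf$gene_id
  mcols(annotation)$transcript_id <- adf$transcript_id
  seqlengths(annotation) <- chrlen[match(seqlevels(annotation), chroms)]

  genes <- annotation[annotation$type == "gene"]
  names(genes) <- genes$gene_id

  tads <- if (length(tad_rows)) {
    td <- do.call(rbind, tad_rows)
    g <- GRanges(td$chrom, IRanges(td$start, td$end), name = td$name)
    names(g) <- td$name
    g
  } else GRanges()

  names(tad_id_of) <- gene_ids
  out <- list(genome = genome, annotation = annotation, genes = genes,
              tads = tads, tad_assignments = tad_id_of)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "annotation.gtf"),
               tads = file.path(dir, "tads.bed"))
    writeXStringSet(genome, files["genome"])
    write_gtf(annotation, files["annotation"])
    if (length(tads)) write_bed(tads, files["tads"]) else
      files <- files[c("genome", "annotation")]
    out$files <- files
  }
  out
}

#' Simulate expression from planted standardized features
#'
#' Generates `y(g) = a + sum_i b_i * x~_{i,g} + e(g)` per sample, where
#' `x~` is the column-standardized feature matrix, `b` the planted
#' coefficients and `e ~ N(0, noise_sd^2)` independent across genes and
#' samples.  Expression is produced on the already-log scale (the
#' generative model is linear in y), so no log transform should be applied
#' downstream.
#'
#' @param features Feature matrix (genes x variables) as produced by
#'   [build_feature_matrix()].
#' @param config A [simulation_config()]; uses `planted_support`,
#'   `noise_sd`, `intercept`, `n_samples` and `seed`.
#' @param tad_assignments Optional named gene -> TAD vector recorded in the
#'   returned ground truth.
#' @return A list with `expression` (genes x samples matrix) and `truth`
#'   (list: `true_beta`, `true_intercept`, `tad_assignments`,
#'   `shifted_tads`).
#' @export
simulate_expression <- function(features, config, tad_assignments = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  b <- config$planted_support
  missing_vars <- setdiff(names(b), colnames(features))
  if (length(missing_vars)) {
    stop("planted variable(s) missing from features: ",
         paste(missing_vars, collapse = ", "))
  }
  set.seed(config$seed + 1L)
  n <- nrow(features)
  signal <- rep(config$intercept, n)
  if (length(b)) {
    xs <- scale(features[, names(b), drop = FALSE])
    if (any(!is.finite(xs))) stop("planted variable has zero variance or NAs")
    signal <- signal + drop(xs %*% b)
  }
  y <- matrix(signal, n, config$n_samples) +
    matrix(rnorm(n * config$n_samples, 0, config$noise_sd),
           n, config$n_samples)
  rownames(y) <- rownames(features)
  colnames(y) <- sprintf("sample%02d", seq_len(config$n_samples))
  shifted <- if (is.null(config$tad_shift)) character(0) else
    names(config$tad_shift)
  list(expression = y,
       truth = list(true_beta = b, true_intercept = config$intercept,
                    tad_assignments = tad_assignments,
                    shifted_tads = shifted))
}

#' Generate random PWMs
#'
#' Draws position frequency matrices with Dirichlet-like column
#' distributions (sharpened so motifs are informative) and returns them as
#' [pwm] objects; optionally writes a JASPAR-style PFM text file.
#'
#' @param n_motifs Number of motifs.
#' @param length_range `(min, max)` motif lengths; minimum >= 2.
#' @param seed Integer seed.
#' @param file Optional path for a JASPAR PFM text file.
#' @param depth Total count per column in the emitted PFM.
#' @return A list of [pwm] objects (invisibly also written to `file`).
#' @export
generate_pwms <- function(n_motifs, length_range = c(6L, 12L), seed = 1L,
                          file = NULL, depth = 100L) {
  stopifnot(n_motifs >= 1, length_range[1] >= 2,
            length_range[2] >= length_range[1])
  set.seed(seed)
  pwms <- lapply(seq_len(n_motifs), function(i) {
    m <- sample(seq(length_range[1], length_range[2]), 1)
    counts <- sapply(seq_len(m), function(j) {
      a <- rgamma(4, shape = 0.5)
      as.integer(round(depth * a / sum(a)))
    })
    rownames(counts) <- NUCS
    pwm(counts, id = sprintf("SM%04d", i), name = sprintf("synthetic%d", i))
  })
  names(pwms) <- vapply(pwms, function(p) p$id, "")
  if (!is.null(file)) write_pfm(pwms, file)
  pwms
}

#' Synthetic pentamer DNA-shape table
#'
#' Builds a full 1024-pentamer lookup table with random but reproducible
#' MGW, HelT, ProT and Roll values, for testing the shape-feature path
#' when no measured table is supplied.  Values are arbitrary units; this
#' is a synthetic stand-in, not biophysical data.
#'
#' @param seed Integer seed.
#' @return data.frame with columns `pentamer`, `MGW`, `HelT`, `ProT`,
#'   `Roll`.
#' @export
synthetic_shape_table <- function(seed = 1L) {
  set.seed(seed)
  pent <- apply(expand.grid(NUCS, NUCS, NUCS, NUCS, NUCS,
                            stringsAsFactors = FALSE)[, 5:1],
                1, paste, collapse = "")
  data.frame(pentamer = pent,
             MGW = round(rnorm(1024, 5, 0.5), 3),
             HelT = round(rnorm(1024, 34, 1.5), 3),
             ProT = round(rnorm(1024, -7, 2), 3),
             Roll = round(rnorm(1024, -0.5, 2), 3),
             stringsAsFactors = FALSE)
}
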