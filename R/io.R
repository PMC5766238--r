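#' Position weight matrix
#'
#' Builds a PWM from a 4 x m count (or probability) matrix with rows
#' A, C, G, T.  A pseudocount is added per column and columns renormalized
#' to probabilities, so no entry is zero and log-odds scores are finite.
#'
#' @param counts 4 x m numeric matrix, rows in A, C, G, T order.
#' @param id Motif identifier.
#' @param name Motif name (optional).
#' @param pseudocount Added to each column entry (after scaling counts to
#'   probabilities) before renormalization.
#' @param prior Background probabilities (named, A/C/G/T); default uniform.
#' @return An object of class `pwm` with elements `id`, `name`, `probs`
#'   (4 x m, columns summing to 1), `counts`, `prior`.
#' @export
pwm <- function(counts, id = "motif", name = id, pseudocount = 1e-3,
                prior = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 2) stop("PWM length must be >= 2")
  rownames(counts) <- NUCS
  if (any(counts < 0)) stop("negative PWM entries")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("PWM column with zero total count")
  probs <- sweep(counts, 2, cs, "/") + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  prior <- prior[NUCS]
  if (abs(sum(prior) - 1) > 1e-9 || any(prior <= 0)) {
    stop("prior must be positive and sum to 1")
  }
  structure(list(id = id, name = name, probs = probs, counts = counts,
                 prior = prior),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, paste0("(", x$name, ")"), "length", ncol(x$probs), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts both the bracketed 2016 dialect (`A [ 0 3 79 ... ]`) and bare
#' 4-row count blocks, each preceded by a `>ID NAME` header.
#'
#' @param path File path.
#' @param pseudocount,prior Passed to [pwm()].
#' @return Named list of [pwm] objects.
#' @export
read_pfm <- function(path, pseudocount = 1e-3,
                     prior = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers in PFM file: ", path)
  out <- list()
  for (h in seq_along(hdr)) {
    i0 <- hdr[h]
    i1 <- if (h < length(hdr)) hdr[h + 1] - 1 else length(lines)
    block <- lines[(i0 + 1):i1]
    if (length(block) < 4) {
      stop("malformed PFM record at line ", i0, " of ", path,
           ": expected 4 count rows")
    }
    block <- block[1:4]
    parts <- strsplit(trimws(sub(">", "", lines[i0])), "\\s+")[[1]]
    id <- parts[1]
    nm <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    rows <- lapply(seq_along(block), function(k) {
      ln <- gsub("[][]", " ", block[k])
      ln <- sub("^\\s*[ACGTacgt]\\s+", " ", paste0(" ", ln))
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (!length(v) || any(is.na(v))) {
        stop("malformed PFM row (file ", path, ", line ", i0 + k,
             "): ", block[k])
      }
      v
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("ragged PFM rows in record ", id, " of ", path)
    }
    out[[id]] <- pwm(do.call(rbind, rows), id = id, name = nm,
                     pseudocount = pseudocount, prior = prior)
  }
  out
}

#' Write PWMs as a JASPAR-style PFM text file
#'
#' @param pwms List of [pwm] objects.
#' @param path Output path.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (n in NUCS) {
      writeLines(sprintf("%s [ %s ]", n,
                         paste(format(p$counts[n, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write a GTF annotation
#'
#' Thin wrappers around rtracklayer that keep the `type`, `gene_id` and
#' `transcript_id` attributes the package needs.  GTF files are 1-based
#' inclusive; the returned GRanges uses the same convention.
#'
#' @param path File path.
#' @return `read_gtf`: a GRanges with `type`, `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  for (f in c("type", "gene_id", "transcript_id")) {
    if (!f %in% names(mcols(gr))) mcols(gr)[[f]] <- NA_character_
  }
  gr
}

#' @rdname read_gtf
#' @param gr GRanges with `type`, `gene_id`, `transcript_id` metadata.
#' @export
write_gtf <- function(gr, path) {
  mcols(gr)$source <- "seqexpr"
  if (is.null(mcols(gr)$phase)) {
    mcols(gr)$phase <- ifelse(mcols(gr)$type == "CDS", 0L, NA_integer_)
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write BED6 intervals
#'
#' BED is 0-based half-open on disk; rtracklayer converts to/from the
#' 1-based GRanges convention.
#'
#' @param path File path.
#' @return `read_bed`: a GRanges (named from the BED name column).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(mcols(gr)$name)) names(gr) <- mcols(gr)$name
  gr
}

#' @rdname read_bed
#' @param gr GRanges; a `name` metadata column (or names) is written to
#'   the BED name field.
#' @export
write_bed <- function(gr, path) {
  if (is.null(mcols(gr)$name) && !is.null(names(gr))) {
    mcols(gr)$name <- names(gr)
  }
  if (is.null(mcols(gr)$score)) mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read/write a numeric TSV matrix
#'
#' Tab-separated, UTF-8, header row of column ids, first column row ids,
#' `NA` as missing code -- the interchange format for feature and
#' expression matrices.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param x Matrix (or data.frame) with row and column names.
#' @param row_label Header of the row-id column.
#' @export
write_matrix_tsv <- function(x, path, row_label = "id") {
  df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  colnames(df)[1] <- row_label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a simulation ground-truth record
#'
#' Serializes the `truth` element of [simulate_expression()] (planted
#' coefficients, intercept, TAD assignments, shifted TADs) as JSON so a
#' simulated study can be archived next to its FASTA/GTF/TSV inputs.
#'
#' @param truth Ground-truth list from [simulate_expression()].
#' @param path File path.
#' @return `read_truth_json`: the truth list, with `true_beta` and
#'   `tad_assignments` restored as named vectors.
#' @export
write_truth_json <- function(truth, path) {
  enc <- truth
  for (f in c("true_beta", "tad_assignments")) {
    if (!is.null(enc[[f]])) enc[[f]] <- as.list(enc[[f]])  # keep names
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$true_beta <- unlist(truth$true_beta)
  if (!is.null(truth$tad_assignments)) {
    truth$tad_assignments <- unlist(truth$tad_assignments)
  }
  truth
}

#' Write a manifest of run outputs
#'
#' Records each file with its MD5 content hash; determinism checks compare
#' manifests of repeated runs.
#'
#' @param dir Run directory.
#' @param files Character vector of file paths (within `dir`).
#' @param extra Named list of additional metadata to record.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, files, extra = list()) {
  hashes <- tools::md5sum(files)
  manifest <- c(list(files = lapply(seq_along(files), function(i) {
    list(path = basename(files[i]), md5 = unname(hashes[i]))
  })), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
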