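test_that("TSS choice falls back to the previous rank when absent", {
  expect_equal(select_tss(c(100), "second"), 100)
  expect_equal(select_tss(c(100, 300), "third"), 300)
  expect_equal(select_tss(c(100, 300, 900), "last"), 900)
  expect_equal(select_tss(c(100, 300, 900), "first"), 100)
  expect_equal(select_tss(c(100, 300, 900), "second"), 300)
  expect_error(select_tss(numeric(0)), "empty")
})

## spec'd promoter arithmetic, quoted below in 0-based half-open
## coordinates; GRanges is 1-based inclusive (start0 = start1 - 1).
test_that("promoter segments follow the -2000/-500/+500/+2000 cuts", {
  gr <- segment_promoter(10001, "+")  # 0-based TSS 10000
  df <- data.frame(region = gr$region, start0 = start(gr) - 1, end0 = end(gr))
  expect_equal(df[df$region == "DU", 2:3], data.frame(start0 = 8000, end0 = 9500),
               ignore_attr = TRUE)
  expect_equal(df[df$region == "CORE", 2:3], data.frame(start0 = 9500, end0 = 10500),
               ignore_attr = TRUE)
  expect_equal(df[df$region == "DD", 2:3], data.frame(start0 = 10500, end0 = 12000),
               ignore_attr = TRUE)

  ## minus strand: DU/DD mirrored, CORE symmetric
  grm <- segment_promoter(10001, "-")
  dfm <- data.frame(region = grm$region, start0 = start(grm) - 1, end0 = end(grm))
  expect_equal(dfm[dfm$region == "DU", 2:3], data.frame(start0 = 10500, end0 = 12000),
               ignore_attr = TRUE)
  expect_equal(dfm[dfm$region == "CORE", 2:3], data.frame(start0 = 9500, end0 = 10500),
               ignore_attr = TRUE)
  expect_equal(dfm[dfm$region == "DD", 2:3], data.frame(start0 = 8000, end0 = 9500),
               ignore_attr = TRUE)
})

test_that("promoter segments clip at chromosome bounds with a warning", {
  expect_warning(gr <- segment_promoter(301, "+", chrom_len = 100000),
                 "clipped")
  expect_false("DU" %in% gr$region)  # clipped away entirely
  core <- gr[gr$region == "CORE"]
  expect_equal(c(start(core) - 1, end(core)), c(0, 800))
})

test_that("merging uses bookended-union semantics and concatenates in order", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 25), collapse = "")))
  ## 0-based [10,20) + [15,30) -> [10,30), length 20
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 16), c(20, 30)),
                               strand = "+")
  mc <- merge_and_concatenate(gr, genome)
  expect_equal(length(mc$intervals), 1)
  expect_equal(length(mc$seq), 20)

  ## bookended 0-based [10,20) + [20,30) merge too; oracle = naive
  ## position-wise union
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 21), c(20, 30)),
                                strand = "+")
  mc2 <- merge_and_concatenate(gr2, genome)
  naive <- sort(unique(c(11:20, 21:30)))
  expect_equal(length(mc2$intervals), 1)
  expect_equal(start(mc2$intervals), min(naive))
  expect_equal(end(mc2$intervals), max(naive))

  single <- merge_and_concatenate(gr2[1], genome)
  expect_equal(as.data.frame(single$intervals)[, 1:3],
               as.data.frame(gr2[1])[, 1:3])

  ## minus-strand concatenation is reverse-complemented, 3'-most first
  grm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(4, 54)),
                                strand = "-")
  mcm <- merge_and_concatenate(grm, genome)
  fwd <- paste0(as.character(Biostrings::DNAStringSet(
    Biostrings::Views(genome[[1]], start = c(1, 51), end = c(4, 54)))),
    collapse = "")
  expect_equal(as.character(mcm$seq),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
})

test_that("intron derivation is the set difference with the exonic union", {
  span <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 1000), strand = "+")
  ex <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 101, 901),
                                                     c(100, 200, 1000)),
                               strand = "+")
  intr <- derive_introns(span, ex)
  expect_equal(c(start(intr) - 1, end(intr)), c(200, 900))

  expect_length(derive_introns(span, GenomicRanges::GRanges(
    "c", IRanges::IRanges(1, 1000), strand = "+")), 0)

  ## position-wise membership oracle on 0-based [0,100) minus {[20,40),[60,80)}
  span2 <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100), strand = "+")
  ex2 <- GenomicRanges::GRanges("c", IRanges::IRanges(c(21, 61), c(40, 80)),
                                strand = "+")
  intr2 <- derive_introns(span2, ex2)
  member <- setdiff(1:100, c(21:40, 61:80))
  got <- unlist(lapply(seq_along(intr2),
                       function(i) start(intr2)[i]:end(intr2)[i]))
  expect_identical(sort(got), sort(member))
  expect_length(intr2, 3)
})

test_that("DFR is the 1 kb after the transcription end, clipped in bounds", {
  g <- GenomicRanges::GRanges("c", IRanges::IRanges(4001, 5000), strand = "+")
  names(g) <- "g1"
  d <- derive_dfr(g, chrom_len = 100000)
  expect_equal(c(start(d) - 1, end(d)), c(5000, 6000))

  gm <- GenomicRanges::GRanges("c", IRanges::IRanges(5001, 6000), strand = "-")
  names(gm) <- "g2"
  dm <- derive_dfr(gm, chrom_len = 100000)
  expect_equal(c(start(dm) - 1, end(dm)), c(4000, 5000))

  gend <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 9800), strand = "+")
  names(gend) <- "g3"
  expect_warning(dc <- derive_dfr(gend, chrom_len = 10000), "clipped")
  expect_equal(GenomicRanges::width(dc), 200)
})

test_that("the catalog populates all 8 regions and respects the span identity", {
  fx <- fixture_sim()
  ct <- fx$catalog
  expect_s3_class(ct, "region_catalog")
  expect_length(ct$ids, 30)
  expect_identical(names(ct$seqs), REGION_KINDS)
  lens <- region_lengths(ct)
  expect_identical(dim(lens), c(30L, 8L))
  ## INTR + UTR5/CDS/UTR3 tile the gene span
  spans <- GenomicRanges::width(fx$sim$genes[ct$ids])
  body <- rowSums(lens[, c("UTR5", "CDS", "UTR3", "INTR")])
  expect_equal(unname(body), unname(spans))
  ## concatenated sequence length equals the sum of interval lengths
  for (r in REGION_KINDS) {
    expect_equal(unname(Biostrings::width(ct$seqs[[r]])),
                 unname(sum(GenomicRanges::width(ct$intervals[[r]]))))
  }
})

test_that("region extraction is strand-covariant", {
  cfg <- simulation_config(n_genes = 8, seed = 13)
  sim <- generate_annotation(cfg)
  ct <- build_catalog(sim$annotation, sim$genome)

  ## mirror the genome and annotation
  L <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  gflip <- Biostrings::reverseComplement(sim$genome)
  a <- sim$annotation
  len <- L[as.character(GenomicRanges::seqnames(a))]
  aflip <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(a),
    IRanges::IRanges(len - GenomicRanges::end(a) + 1,
                     len - GenomicRanges::start(a) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(a)) == "+", "-", "+"))
  S4Vectors::mcols(aflip) <- S4Vectors::mcols(a)
  GenomeInfoDb::seqlengths(aflip) <- GenomeInfoDb::seqlengths(a)
  ct2 <- build_catalog(aflip, gflip)
  ## gene-body and flanking regions are exactly covariant
  for (r in c("UTR5", "CDS", "UTR3", "INTR", "DFR")) {
    expect_identical(as.character(ct2$seqs[[r]][ct$ids]),
                     as.character(ct$seqs[[r]][ct$ids]),
                     label = paste("region", r))
  }
  ## promoter segments keep their width and, mapped back to the original
  ## coordinates, shift by at most 1 bp (endpoint-mirroring convention)
  for (r in c("DU", "CORE", "DD")) {
    a1 <- unlist(ct$intervals[[r]][ct$ids])
    a2 <- unlist(ct2$intervals[[r]][ct$ids])
    expect_equal(GenomicRanges::width(a2), GenomicRanges::width(a1))
    l2 <- L[as.character(GenomicRanges::seqnames(a2))]
    back_start <- l2 - GenomicRanges::end(a2) + 1
    expect_true(all(abs(back_start - GenomicRanges::start(a1)) <= 1))
  }
})

test_that("transcript-level catalogs share the DFR only for shared ends", {
  fx <- fixture_sim()
  ct <- build_catalog(fx$sim$annotation, fx$sim$genome, level = "transcript")
  expect_gt(length(ct$ids), 30)
  ## all transcripts of one gene end together here, so DFRs coincide
  g1tx <- grep("^gene0001\\.", ct$ids, value = TRUE)
  if (length(g1tx) > 1) {
    d <- unique(as.data.frame(unlist(ct$intervals$DFR[g1tx]))[, 1:3])
    expect_equal(nrow(d), 1)
  }
})
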