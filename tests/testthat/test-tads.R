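test_that("genes are assigned to the TAD containing their midpoint", {
  genes <- GenomicRanges::GRanges("c", IRanges::IRanges(
    c(100, 900, 2000), c(500, 1400, 2400)))
  names(genes) <- c("g1", "g2", "g3")
  tads <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 1000),
                                                       c(1000, 1800)))
  names(tads) <- c("t1", "t2")
  memb <- assign_genes_to_tads(genes, tads)
  ## g2 midpoint 1150 is in t2; g3 midpoint 2200 in no TAD
  expect_identical(unname(memb), c("t1", "t2", NA))
})

test_that("KS signature tests flag a planted composition shift", {
  set.seed(61)
  n <- 400
  X <- cbind(CpG_INTR = rnorm(n, 8, 1), GpC_INTR = rnorm(n, 8, 1))
  rownames(X) <- sprintf("g%04d", 1:n)
  memb <- setNames(rep(NA_character_, n), rownames(X))
  memb[1:20] <- "t1"; memb[21:40] <- "t2"; memb[41:60] <- "t3"
  X[memb %in% "t1", "CpG_INTR"] <- X[memb %in% "t1", "CpG_INTR"] + 4
  ts <- tad_signature_tests(X, memb)
  expect_s3_class(ts, "tad_signature")
  expect_true(ts$flags[["t1"]])
  expect_identical(sort(unique(ts$tests$tad)), c("t1", "t2", "t3"))
  expect_true(all(ts$tests$q >= ts$tests$p))

  ## identical in/out samples give D = 0, p = 1
  kt <- suppressWarnings(ks.test(rep(1:5, 4), rep(1:5, 40)))
  expect_equal(unname(kt$statistic), 0)
  expect_equal(kt$p.value, 1)

  ## TADs at or below the size filter are excluded
  memb2 <- memb; memb2[41:51] <- NA; memb2[52:60] <- "t3"
  ts2 <- tad_signature_tests(X, memb2, min_genes = 10)
  expect_true("t3" %in% ts2$excluded)
})

test_that("the KS statistic matches a brute-force ECDF computation", {
  set.seed(62)
  for (i in 1:60) {
    x <- rnorm(sample(10:40, 1)); y <- rnorm(sample(10:40, 1), 0.3)
    D <- suppressWarnings(ks.test(x, y)$statistic)
    expect_equal(unname(D), bf_ks_D(x, y), tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  ## spec'd worked case: all 5 group genes in a 5-gene TAD of a 10-gene
  ## universe -> p = 1/252
  universe <- sprintf("g%02d", 1:10)
  memb <- setNames(c(rep("t1", 5), rep(NA, 5)), universe)
  grp <- data.frame(group = "G", gene = universe[1:5])
  en <- tad_group_enrichment(grp, memb, min_genes = 4)
  expect_equal(en$tests$p, 1 / 252, tolerance = 1e-12)
  expect_true(en$group_enriched[["G"]])

  ## zero overlap has upper-tail probability 1
  grp0 <- data.frame(group = "G0", gene = universe[6:10])
  en0 <- tad_group_enrichment(grp0, memb, min_genes = 4)
  expect_equal(en0$tests$p, 1)

  ## random small instances against factorial enumeration
  set.seed(63)
  for (i in 1:100) {
    N <- sample(8:30, 1); K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1); k <- sample(0:min(n, K), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 bf_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("interval densities follow the count and length formulas", {
  regions <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
  pts <- GenomicRanges::GRanges("c", IRanges::IRanges(c(3, 10, 20, 50, 99),
                                                      width = 1))
  expect_equal(interval_density(pts, regions, "count"), 0.05)
  expect_equal(interval_density(regions, regions, "length"), 1.0)

  ## two genes with region lengths 100 and 300, intersections 10 and 30
  regions2 <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 201),
                                                           c(100, 500)))
  q2 <- GenomicRanges::GRanges("c", IRanges::IRanges(c(91, 201),
                                                     c(100, 230)))
  expect_equal(interval_density(q2, regions2, "length"), 40 / 400)
  expect_error(interval_density(pts, regions[0], "count"), "undefined")
})

test_that("the Gini coefficient equals the pairwise mean difference", {
  expect_equal(gini(rep(4, 10)), 0)
  expect_equal(gini(c(rep(0, 9), 1)), 0.9)  # one-hot: (n-1)/n
  expect_equal(gini(c(1, 3)), 0.25)
  expect_true(is.na(gini(rep(0, 5))))
  set.seed(64)
  for (i in 1:40) {
    v <- rexp(sample(3:12, 1))
    expect_equal(gini(v), bf_gini(v), tolerance = 1e-12)
  }
})

test_that("error-ubiquity correlation handles monotone and null cases", {
  set.seed(65)
  g <- setNames(runif(200), sprintf("g%03d", 1:200))
  mono <- error_ubiquity_correlation(g, g^2 + 1)
  expect_equal(mono$spearman_rho, 1)
  expect_lt(mono$wilcoxon_p, 1e-10)
  nullc <- error_ubiquity_correlation(g, setNames(rnorm(200), names(g)))
  expect_lt(abs(nullc$spearman_rho), 0.2)
  expect_error(error_ubiquity_correlation(g[1:5], g[1:5]), "10 common")
})

test_that("BH adjustment is monotone over ranked p-values and capped at 1", {
  set.seed(66)
  p <- runif(200)^2
  q <- p.adjust(p, method = "BH")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q <= 1))
  expect_true(all(q >= p))
})
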