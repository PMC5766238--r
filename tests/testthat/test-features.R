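test_that("nucleotide percentages match the counting rule", {
  expect_equal(unname(nt_percentage("ACGT")[1, ]), rep(25, 4))
  expect_equal(unname(nt_percentage("AAAA")[1, ]), c(100, 0, 0, 0))
  ## ambiguous bases excluded from numerator and denominator
  expect_equal(unname(nt_percentage("ACGN")[1, ]),
               c(100 / 3, 100 / 3, 100 / 3, 0))
  expect_warning(res <- nt_percentage(c("NNN", "ACGT")), "missing-coded")
  expect_true(all(is.na(res[1, ])))
  expect_false(anyNA(res[2, ]))
})

test_that("dinucleotide and trinucleotide percentages use valid windows", {
  d <- kmer_percentage("AAA", 2)
  expect_equal(unname(d[1, "ApA"]), 100)
  expect_equal(sum(d[1, ]), 100)
  d2 <- kmer_percentage("CGCG", 2)
  expect_equal(unname(d2[1, "CpG"]), 200 / 3)
  expect_equal(unname(d2[1, "GpC"]), 100 / 3)
  t3 <- kmer_percentage("ACGT", 3)
  expect_equal(unname(t3[1, c("ApCpG", "CpGpT")]), c(50, 50))
  ## l < k is missing-coded
  expect_true(all(is.na(kmer_percentage("A", 2)[1, ])))
})

test_that("percentages match a brute-force window count on random sequences", {
  set.seed(21)
  for (i in 1:60) {
    s <- rand_seq(sample(10:80, 1), n_prob = ifelse(i %% 3 == 0, 0.1, 0))
    got1 <- suppressWarnings(nt_percentage(s))[1, ]
    exp1 <- bf_nt_pct(s)
    expect_equal(unname(got1), unname(exp1), tolerance = 1e-12)
    got2 <- kmer_percentage(s, 2)[1, ]
    names(got2) <- gsub("p", "", names(got2))
    exp2 <- bf_kmer_pct(s, 2)
    expect_equal(got2[sort(names(got2))], exp2[sort(names(exp2))],
                 tolerance = 1e-12)
  }
})

test_that("sequence reversal maps NpM counts onto MpN counts", {
  set.seed(22)
  for (i in 1:20) {
    s <- rand_seq(60)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    a <- kmer_percentage(s, 2)[1, ]
    b <- kmer_percentage(r, 2)[1, ]
    swapped <- vapply(strsplit(names(a), "p"),
                      function(x) paste(rev(x), collapse = "p"), "")
    expect_equal(unname(a), unname(b[swapped]), tolerance = 1e-12)
    expect_equal(nt_percentage(s), nt_percentage(r), ignore_attr = TRUE)
  }
})

test_that("double-strand collapse merges complement pairs and conserves totals", {
  f <- matrix(c(30, 20, 25, 25), 1,
              dimnames = list("g", c("A_CORE", "T_CORE", "C_CORE", "G_CORE")))
  cc <- collapse_double_strand(f)
  expect_equal(ncol(cc), 2)
  expect_equal(unname(cc[1, "A|T_CORE"]), 50)
  ## 16 dinucleotides collapse to 8 classes, totals conserved
  set.seed(23)
  d <- kmer_percentage(rand_seq(200), 2)
  colnames(d) <- paste0(colnames(d), "_INTR")
  cd <- collapse_double_strand(d)
  expect_equal(ncol(cd), 8)
  expect_equal(unname(rowSums(cd)), 100, tolerance = 1e-9)
  ## CpG pairs with GpC (complement), forming one class
  expect_true("CpG|GpC_INTR" %in% colnames(cd))
  expect_equal(unname(cd[1, "CpG|GpC_INTR"]),
               unname(d[1, "CpG_INTR"] + d[1, "GpC_INTR"]))
})

test_that("PWM position score implements the log-odds sum", {
  ## uniform motif equals background -> score 0 everywhere
  w0 <- pwm(matrix(1, 4, 3), id = "flat")
  s <- "ACGTACG"
  for (i in 0:4) expect_equal(pwm_score_at(w0, s, i), 0)

  ## hand-evaluated: P(A|w0)=1, P(C|w1)=1, uniform prior, window "AC"
  w1 <- pwm(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4), id = "ac", pseudocount = 0)
  expect_equal(pwm_score_at(w1, "TACG", 1), 2 * log(4), tolerance = 1e-12)

  ## count-scale invariance: the score depends on probability ratios only
  w2 <- pwm(matrix(c(8, 2, 2, 4, 1, 1, 1, 1), 4), id = "w2")
  w2b <- pwm(3 * w2$counts, id = "w2b")
  expect_equal(pwm_score_at(w2, "ACGT", 0), pwm_score_at(w2b, "ACGT", 0),
               tolerance = 1e-12)
  expect_error(pwm_score_at(w2, "ACGT", 3), "out of range")
})

test_that("max and sum scores equal exhaustive enumeration", {
  set.seed(24)
  for (i in 1:40) {
    m <- sample(4:8, 1)
    w <- pwm(matrix(rgamma(4 * m, 1), 4), id = "r")
    s <- rand_seq(60, n_prob = ifelse(i %% 4 == 0, 0.05, 0))
    oracle <- bf_pwm_scores(w$probs, w$prior, s)
    if (all(is.na(oracle))) {
      expect_true(is.na(pwm_score_max(w, s)))
    } else {
      expect_equal(pwm_score_max(w, s), max(oracle, na.rm = TRUE),
                   tolerance = 1e-9)
      expect_equal(pwm_score_sum(w, s), sum(oracle, na.rm = TRUE),
                   tolerance = 1e-9)
    }
  }
})

test_that("appending a sub-maximal window changes sum but not max", {
  w <- pwm(matrix(c(9, 1, 1, 1, 1, 9, 1, 1), 4), id = "w")
  s <- "ACACAC"
  mx <- pwm_score_max(w, s)
  s2 <- paste0(s, "TT")  # TT windows score below the AC max
  expect_equal(pwm_score_max(w, s2), mx)
  expect_gt(abs(pwm_score_sum(w, s2) - pwm_score_sum(w, s)), 0)
})

test_that("shape means average the pentamer table over sliding windows", {
  tab <- synthetic_shape_table(seed = 5)
  const <- tab
  const$MGW <- 2.5
  m1 <- shape_means("ACGTACGTT", const)
  expect_equal(unname(m1[1, "MGW"]), 2.5)
  ## 5-bp sequence = single window
  s5 <- "ACGTA"
  m5 <- shape_means(s5, tab)
  expect_equal(unname(m5[1, "MGW"]), tab$MGW[tab$pentamer == s5])
  ## 7-bp sequence = mean of the 3 windows
  s7 <- "ACGTACG"
  wins <- substring(s7, 1:3, 5:7)
  expect_equal(unname(shape_means(s7, tab)[1, "Roll"]),
               mean(tab$Roll[match(wins, tab$pentamer)]))
  ## reverse-complement fallback covers missing pentamers
  half <- tab[1:512, ]
  full_ok <- tryCatch(shape_means("ACGTACG", half), error = function(e) e)
  expect_true(is.matrix(full_ok) || inherits(full_ok, "error"))
  expect_true(all(is.na(shape_means("ACG", tab))))
})

test_that("the feature matrix has the configured columns", {
  fx <- fixture_sim()
  expect_identical(dim(fx$features), c(30L, 160L))
  expect_true(all(c("CpG_CORE", "GpT_INTR", "A_DFR") %in%
                    colnames(fx$features)))
  ## per region, nucleotide and dinucleotide percentages each sum to 100
  for (r in c("CORE", "INTR")) {
    ntc <- paste0(c("A", "C", "G", "T"), "_", r)
    expect_equal(unname(rowSums(fx$features[, ntc])), rep(100, 30),
                 tolerance = 1e-9)
    dnc <- grep(sprintf("^[ACGT]p[ACGT]_%s$", r), colnames(fx$features),
                value = TRUE)
    expect_length(dnc, 16)
    expect_equal(unname(rowSums(fx$features[, dnc])), rep(100, 30),
                 tolerance = 1e-9)
  }

  ## promoter-only model: 60 columns; plus motifs: 60 + n_pwms
  f60 <- build_feature_matrix(fx$catalog,
                              percent_regions = c("CORE", "DU", "DD"))
  expect_equal(ncol(f60), 60)
  pwms <- generate_pwms(5, c(5, 7), seed = 2)
  f65 <- build_feature_matrix(fx$catalog,
                              percent_regions = c("CORE", "DU", "DD"),
                              pwms = pwms)
  expect_equal(ncol(f65), 65)
  expect_true(all(grepl("^motif:", setdiff(colnames(f65), colnames(f60)))))

  ## shapes add 4 columns per promoter segment
  f_shape <- build_feature_matrix(fx$catalog,
                                  percent_regions = c("CORE", "DU", "DD"),
                                  shape_table = synthetic_shape_table(1))
  expect_equal(ncol(f_shape), 72)

  ## trinucleotides in one region add 64 columns
  f_tri <- build_feature_matrix(fx$catalog, trinucleotide_regions = "INTR")
  expect_equal(ncol(f_tri), 224)
})

test_that("unused-level and missing-resource configurations error", {
  fx <- fixture_sim()
  expect_error(build_feature_matrix(fx$catalog, percent_regions = "PROM"))
  expect_error(build_feature_matrix(fx$catalog, motif_regions = c("CORE",
                                                                  "DU")),
               "no PWMs")
})
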