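## Small shared simulation fixtures, built once per test run.

fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 30, n_samples = 2,
                               tad_count = 4, genes_per_tad = 5,
                               planted_support = c(CpG_CORE = 1,
                                                   GpT_INTR = -0.8),
                               noise_sd = 0.5, seed = 42)
      sim <- generate_annotation(cfg)
      catalog <- build_catalog(sim$annotation, sim$genome)
      features <- build_feature_matrix(catalog)
      cache <<- list(config = cfg, sim = sim, catalog = catalog,
                     features = features)
    }
    cache
  }
})

## large fixture for recovery/calibration checks: 2000 genes, full
## 160-variable composition matrix from the generator, built once
fixture_big <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 2000, seed = 2024)
      sim <- generate_annotation(cfg)
      catalog <- build_catalog(sim$annotation, sim$genome)
      features <- build_feature_matrix(catalog)
      cache <<- list(sim = sim, catalog = catalog, features = features)
    }
    cache
  }
})

## n random uniform-composition sequences of a fixed length, fast
rand_seq_set <- function(n, len) {
  big <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
               collapse = "")
  starts <- seq(1, n * len, by = len)
  setNames(substring(big, starts, starts + len - 1),
           sprintf("g%04d", seq_len(n)))
}

## genes x variables gaussian matrix with composition-style names
gauss_features <- function(n, p, region = "CORE", prefix = "V") {
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("g%04d", seq_len(n)),
                         sprintf("%s%02d_%s", prefix, seq_len(p), region)))
}
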