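## Brute-force oracles, kept deliberately naive and independent of the
## package implementations they check.

bf_nt_pct <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(ch)) return(setNames(rep(NA_real_, 4), c("A", "C", "G", "T")))
  vapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(n) 100 * sum(ch == n) / length(ch), numeric(1))
}

bf_kmer_pct <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  l <- length(ch)
  wins <- if (l < k) character(0) else
    vapply(1:(l - k + 1), function(i) paste(ch[i:(i + k - 1)], collapse = ""),
           "")
  wins <- wins[grepl(sprintf("^[ACGT]{%d}$", k), wins)]
  all_k <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1],
                 1, paste, collapse = "")
  out <- setNames(rep(NA_real_, length(all_k)), sort(all_k))
  if (!length(wins)) return(out)
  for (km in names(out)) out[km] <- 100 * sum(wins == km) / length(wins)
  out
}

bf_pwm_scores <- function(probs, prior, s) {
  ch <- strsplit(s, "")[[1]]
  m <- ncol(probs)
  sapply(seq_len(length(ch) - m + 1), function(i) {
    win <- ch[i:(i + m - 1)]
    if (!all(win %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(m), function(j) {
      log(probs[win[j], j] / prior[win[j]])
    }, numeric(1)))
  })
}

bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

## upper-tail hypergeometric P(X >= k) by exact enumeration (N small)
bf_hyper_upper <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(vapply(js, function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, numeric(1))) / choose(N, n)
}

bf_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

## random DNA with occasional ambiguous bases
rand_seq <- function(len, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}
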