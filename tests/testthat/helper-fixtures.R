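# Shared fixture builders: everything is generated in code at test time.

# wide count tibble from a matrix-like specification
make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(feature_id = genes), out)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force BH step-up straight from the definition; independent of the
# package's vectorised implementation
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact upper-tail hypergeometric by combinatorial enumeration
hyper_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# two-sided Fisher exact p by enumeration over tables with fixed margins
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  prob <- function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  }
  pobs <- prob(a)
  ps <- vapply(lo:hi, prob, 0)
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# small two-group log-intensity tibble with planted effects
make_log_intensities <- function(n_prot, n_per_group = 5, effect = 0,
                                 sd = 0.5, seed = 1) {
  set.seed(seed)
  samples <- omicsconcord::sample_table(
    c(paste0("F1F", seq_len(n_per_group)), paste0("F1M", seq_len(n_per_group))),
    rep(c("F1F", "F1M"), each = n_per_group)
  )
  base <- stats::rnorm(n_prot, 0, 2)
  m <- sapply(seq_len(2 * n_per_group), function(j) {
    shift <- if (j <= n_per_group) effect else 0
    base + shift + stats::rnorm(n_prot, 0, sd)
  })
  df <- make_counts(m, genes = paste0("p", seq_len(n_prot)),
                    samples = samples$sample_id)
  list(x = df, samples = samples)
}
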