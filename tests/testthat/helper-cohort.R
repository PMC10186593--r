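# Shared small fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a small but structurally complete cohort
tiny_config <- function(seed = 101L, ...) {
  sim_config(n_cells_per_mouse = 120, n_genes = 700,
             n_signature_genes = 60, seed = seed, ...)
}

tiny_cohort <- function() memo("tiny_cohort", generate_cohort(tiny_config()))

tiny_norm <- function() memo("tiny_norm", {
  normalize_counts(qc_filter(tiny_cohort())$counts)
})

# isotropic Gaussian blobs separated by `sep` SD, for clustering tests
make_blobs <- function(n_per = 150, centers = 3, dims = 5, sep = 10,
                       seed = 42) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(centers), function(k) {
    # centers placed so consecutive blobs are `sep` SD apart (Euclidean)
    mu <- rep((k - 1) * sep / sqrt(dims), dims)
    sweep(matrix(rnorm(n_per * dims), ncol = dims), 2, mu, "+")
  }))
  rownames(x) <- sprintf("cell%03d", seq_len(nrow(x)))
  list(coords = x, labels = rep(seq_len(centers), each = n_per))
}

# adjusted Rand index (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
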