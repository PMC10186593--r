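# hand-built count matrix with controllable per-cell gene detection / mito
make_counts <- function(n_genes_detected, mito_frac = 0, n_genes = 400,
                        n_mito = 20, total = 1000) {
  genes <- c(sprintf("mt-g%02d", seq_len(n_mito)),
             sprintf("g%03d", seq_len(n_genes - n_mito)))
  cols <- lapply(seq_along(n_genes_detected), function(i) {
    v <- numeric(n_genes)
    k <- n_genes_detected[i]
    mito_counts <- round(total * mito_frac[i])
    n_mito_on <- min(n_mito, max(if (mito_counts > 0) 1 else 0, 0))
    body <- total - mito_counts
    on <- (n_mito + 1):(n_mito + k - n_mito_on)
    v[on] <- c(body - (length(on) - 1), rep(1, length(on) - 1))
    if (mito_counts > 0) v[1] <- mito_counts
    v
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(genes, sprintf("c%02d", seq_along(n_genes_detected)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("qc_filter removes low/high-complexity and high-mito cells with
           exclusive bounds", {
  m <- make_counts(n_genes_detected = c(150, 200, 300, 300, 300),
                   mito_frac = c(0, 0, 0.25, 0.20, 0.05))
  out <- qc_filter(m, qc_thresholds())
  kept <- colnames(out)
  expect_false("c01" %in% kept)  # 150 genes < 200
  expect_false("c03" %in% kept)  # mito 0.25 > 0.20
  expect_true("c02" %in% kept)   # exactly 200 genes is kept
  expect_true("c04" %in% kept)   # mito exactly 0.20 is kept
  removed <- attr(out, "removed")
  expect_setequal(removed$cell_id, c("c01", "c03"))
  expect_match(removed$reason[removed$cell_id == "c01"], "low_genes")
  expect_match(removed$reason[removed$cell_id == "c03"], "high_mito")
})

test_that("qc_filter is idempotent and a no-op on clean cohorts", {
  m <- make_counts(n_genes_detected = rep(300, 4), mito_frac = rep(0.05, 4))
  once <- qc_filter(m)
  expect_identical(colnames(once), colnames(m))
  twice <- qc_filter(once)
  expect_equal(as.matrix(twice), as.matrix(once))
  expect_equal(nrow(attr(twice, "removed")), 0)
})

test_that("qc_filter errors when everything would be removed", {
  m <- make_counts(n_genes_detected = c(50, 60), mito_frac = c(0, 0))
  expect_error(qc_filter(m), "review thresholds")
})

test_that("normalization matches the closed form and is scale invariant", {
  m <- methods::as(Matrix::Matrix(matrix(c(2, 0), nrow = 2,
                                         dimnames = list(c("a", "b"), "c1")),
                                  sparse = TRUE), "CsparseMatrix")
  n <- normalize_counts(m)
  expect_equal(n["a", 1], log(10001))
  expect_equal(n["b", 1], 0)
  # doubling a cell's counts leaves normalized values unchanged
  expect_equal(as.matrix(normalize_counts(2 * m)), as.matrix(n))
})

test_that("normalization preserves per-cell gene ranks", {
  set.seed(5)
  m <- matrix(rpois(50, 4), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
  m[1, ] <- m[1, ] + 1  # ensure positive totals
  n <- as.matrix(normalize_counts(Matrix::Matrix(m, sparse = TRUE)))
  for (j in 1:5) expect_identical(order(n[, j]), order(m[, j]))
})

test_that("zero-total cells are rejected by normalization", {
  m <- Matrix::Matrix(matrix(c(1, 0, 0, 0), nrow = 2,
                             dimnames = list(c("a", "b"), c("c1", "c2"))),
                      sparse = TRUE)
  expect_error(normalize_counts(m), "zero total")
})

test_that("embedding is deterministic, sign-fixed and captures planar data", {
  set.seed(11)
  # data on an exact 2-D plane in 30-gene space
  basis <- qr.Q(qr(matrix(rnorm(30 * 2), ncol = 2)))
  scores <- matrix(rnorm(200 * 2, sd = c(4, 2)), ncol = 2, byrow = TRUE)
  x <- scores %*% t(basis)
  m <- t(x) - min(x)  # genes x cells, non-negative
  dimnames(m) <- list(paste0("g", 1:30), paste0("c", 1:200))
  norm <- Matrix::Matrix(m, sparse = TRUE)
  e1 <- embed_cells(norm, n_components = 5, n_hvg = 30)
  e2 <- embed_cells(norm, n_components = 5, n_hvg = 30)
  expect_identical(e1$coords, e2$coords)
  expect_lt(sum(e1$var_share[3:5]), 1e-10)
  expect_gt(sum(e1$var_share[1:2]), 0.999)
  expect_error(embed_cells(norm, n_components = 31), "rank|exceeds")
})

test_that("well-separated blobs are recoverable from the leading PCs", {
  blobs <- make_blobs(n_per = 120, centers = 3, dims = 6, sep = 10)
  m <- t(blobs$coords) - min(blobs$coords)
  dimnames(m) <- list(paste0("g", 1:6), rownames(blobs$coords))
  emb <- embed_cells(Matrix::Matrix(m, sparse = TRUE), n_components = 2,
                     n_hvg = 6)
  cent <- apply(emb$coords, 2, tapply, blobs$labels, mean)
  assign <- apply(emb$coords, 1, function(p)
    which.min(colSums((t(cent) - p)^2)))
  expect_gte(mean(assign == blobs$labels), 0.99)
})

test_that("snn-louvain clustering separates blobs and is seeded", {
  blobs <- make_blobs(n_per = 150, centers = 2, dims = 5, sep = 10)
  cl1 <- cluster_cells(blobs$coords, n_neighbors = 25, seed = 3)
  cl2 <- cluster_cells(blobs$coords, n_neighbors = 25, seed = 3)
  expect_identical(cl1, cl2)
  expect_equal(length(unique(cl1)), 2)
  expect_gte(adjusted_rand(cl1, blobs$labels), 0.99)
  expect_error(cluster_cells(blobs$coords, n_neighbors = 0), "positive")
  one <- cluster_cells(matrix(rnorm(3), nrow = 1,
                              dimnames = list("c1", NULL)))
  expect_identical(unname(one), 0L)
})

test_that("clusters agree with true types on well-separated cohorts", {
  blobs <- make_blobs(n_per = 150, centers = 4, dims = 8, sep = 8)
  cl <- cluster_cells(blobs$coords, n_neighbors = 25, seed = 9)
  expect_gte(adjusted_rand(cl, blobs$labels), 0.9)
})

test_that("marker annotation maps clusters to generating types", {
  co <- tiny_cohort()
  norm <- tiny_norm()
  cof <- qc_filter(co)
  emb <- embed_cells(norm, n_components = 15, n_hvg = 400)
  cl <- cluster_cells(emb, resolution = 1.2, seed = 3)
  ty <- annotate_types(norm, cl, cohort_marker_sets(cof),
                       conditions = cof$cells$condition)
  tc <- cof$truth$cells
  truth_lab <- ifelse(tc$branch == "main", tc$type,
                      sub("side", "Side", tc$branch))
  expect_gte(mean(as.character(ty) == truth_lab), 0.7)
  # side branches essentially perfectly recovered
  side <- tc$branch != "main"
  expect_gte(mean(startsWith(as.character(ty)[side], "Side")), 0.95)
  # per-condition proportions are proper distributions
  prop <- attr(ty, "proportions")
  expect_equal(unname(colSums(prop)), rep(1, ncol(prop)), tolerance = 1e-12)
})

test_that("annotation breaks marker ties lexicographically and validates
           marker presence", {
  m <- Matrix::Matrix(matrix(c(1, 1, 0, 0), nrow = 2,
                             dimnames = list(c("g1", "g2"),
                                             c("c1", "c2"))), sparse = TRUE)
  ty <- annotate_types(m, c(0, 0), list(B = "g1", A = "g2"))
  expect_identical(unname(ty[1]), "A")
  expect_match(attr(ty, "ties"), "A/B")
  expect_error(annotate_types(m, c(0, 0), list(A = "absent")),
               "no marker genes")
})
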