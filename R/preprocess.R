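#' QC thresholds
#'
#' Cells detecting fewer than `min_genes` or more than `max_genes` genes, or
#' with a mitochondrial count fraction above `max_mito_fraction`, are
#' discarded. Bounds are exclusive: a cell at exactly `min_genes`,
#' `max_genes` or `max_mito_fraction` is kept.
#'
#' @param min_genes Minimum detected genes (default 200).
#' @param max_genes Maximum detected genes (default 5000).
#' @param max_mito_fraction Maximum mitochondrial fraction (default 0.20).
#' @return Object of class `stemtraj_qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 5000,
                          max_mito_fraction = 0.20) {
  if (!(min_genes > 0 && min_genes < max_genes))
    stop("need 0 < min_genes < max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "stemtraj_qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param counts Sparse genes x cells count matrix with gene row names.
#' @param mito_prefix Prefix identifying mitochondrial genes (default
#'   `"mt-"`, case-insensitive).
#' @return data.frame with `cell_id`, `n_genes`, `total`, `mito_fraction`.
#' @export
qc_metrics <- function(counts, mito_prefix = "mt-") {
  if (is.null(rownames(counts))) stop("counts must carry gene row names")
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  is_mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  mito <- if (any(is_mito))
    Matrix::colSums(counts[is_mito, , drop = FALSE]) else rep(0, ncol(counts))
  data.frame(cell_id = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             n_genes = as.integer(n_genes), total = as.numeric(total),
             mito_fraction = ifelse(total > 0, mito / total, 0),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' @param counts Sparse genes x cells count matrix (or a `stemtraj_cohort`,
#'   in which case metadata and truth rows are subset alongside).
#' @param thresholds A [qc_thresholds()] object.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @return Filtered object of the input's type; the removal log (cell id and
#'   reason) is attached as attribute `"removed"`.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_prefix = "mt-") {
  if (inherits(counts, "stemtraj_cohort")) {
    filtered <- qc_filter(counts$counts, thresholds, mito_prefix)
    keep <- colnames(filtered)
    out <- counts
    out$counts <- filtered
    out$cells <- counts$cells[match(keep, counts$cells$cell_id), ,
                              drop = FALSE]
    rownames(out$cells) <- NULL
    if (!is.null(counts$truth$cells)) {
      out$truth$cells <-
        counts$truth$cells[match(keep, counts$truth$cells$cell_id), ,
                           drop = FALSE]
      rownames(out$truth$cells) <- NULL
    }
    attr(out, "removed") <- attr(filtered, "removed")
    return(out)
  }
  stopifnot(inherits(thresholds, "stemtraj_qc_thresholds"))
  qc <- qc_metrics(counts, mito_prefix)
  low <- qc$n_genes < thresholds$min_genes
  high <- qc$n_genes > thresholds$max_genes
  mito <- qc$mito_fraction > thresholds$max_mito_fraction
  drop <- low | high | mito
  if (all(drop))
    stop("all cells removed by QC; review thresholds (min_genes=",
         thresholds$min_genes, ", max_genes=", thresholds$max_genes,
         ", max_mito_fraction=", thresholds$max_mito_fraction, ")")
  removed <- if (any(drop)) {
    reason <- apply(cbind(low, high, mito)[drop, , drop = FALSE], 1,
                    function(z) paste(c("low_genes", "high_genes",
                                        "high_mito")[z], collapse = ";"))
    data.frame(cell_id = qc$cell_id[drop], reason = unname(reason),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  out <- counts[, !drop, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Library-size normalize and log-transform counts
#'
#' `log(1 + 1e4 * count / cell_total)` (natural log), the standard
#' counts-per-10k log-normalization. Per-cell gene rank order is preserved
#' and the result is invariant to rescaling a cell's library size.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale_factor Pseudo library size (default 1e4).
#' @return Sparse genes x cells normalized matrix.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  if (!methods::is(counts, "CsparseMatrix"))
    counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(counts)[totals <= 0], 5), collapse = ", "))
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

# Top variable genes by standardized dispersion: genes are binned by mean
# normalized expression and the log dispersion (var/mean) is z-scored
# within bin.
variable_genes <- function(normalized, n = 2000, n_bins = 20) {
  mu <- Matrix::rowMeans(normalized)
  m2 <- Matrix::rowMeans(normalized^2)
  v <- pmax(0, m2 - mu^2) * ncol(normalized) / max(1, ncol(normalized) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- which(mu > 0 & disp > 0)
  if (length(keep) <= n) return(rownames(normalized)[order(-disp)][seq_len(min(n, nrow(normalized)))])
  bins <- cut(rank(mu[keep], ties.method = "first"),
              breaks = min(n_bins, length(keep)), labels = FALSE)
  z <- numeric(length(keep))
  for (ii in split(seq_along(keep), bins)) {
    ld <- log(disp[keep][ii])
    s <- stats::sd(ld)
    z[ii] <- if (is.na(s) || s == 0) 0 else (ld - mean(ld)) / s
  }
  names(z) <- rownames(normalized)[keep]
  names(sort(z, decreasing = TRUE))[seq_len(min(n, length(z)))]
}

#' Principal-component embedding
#'
#' Centers (optionally variance-scales) the top variable genes and computes
#' a truncated SVD. Deterministic: component signs follow the convention
#' that the largest-magnitude gene loading of every component is positive.
#'
#' @param normalized Sparse genes x cells normalized matrix.
#' @param n_components Number of components (default 30).
#' @param n_hvg Number of top-variable genes to use (default 2000).
#' @param scale. Variance-scale genes before the SVD (default FALSE).
#' @return Object of class `stemtraj_embedding`: list with `coords` (cells x
#'   components), `var_share`, `genes_used`, `loadings`.
#' @export
embed_cells <- function(normalized, n_components = 30, n_hvg = 2000,
                        scale. = FALSE) {
  hvg <- variable_genes(normalized, n = n_hvg)
  x <- t(as.matrix(normalized[hvg, , drop = FALSE]))  # cells x genes
  if (n_components > min(dim(x)))
    stop("n_components exceeds the rank of the expression matrix")
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }
  total_var <- sum(colSums(x^2)) / max(1, nrow(x) - 1)
  use_irlba <- requireNamespace("irlba", quietly = TRUE) &&
    n_components < min(dim(x)) / 3 && min(dim(x)) > 100
  if (use_irlba) {
    sv <- with_seed(101L, irlba::irlba(x, nv = n_components))
  } else {
    sv <- svd(x, nu = n_components, nv = n_components)
    sv$d <- sv$d[seq_len(n_components)]
  }
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  coords <- sv$u %*% diag(sv$d, n_components)
  rownames(coords) <- colnames(normalized)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  loadings <- sv$v
  rownames(loadings) <- hvg
  structure(list(
    coords = coords,
    var_share = (sv$d^2 / max(1, nrow(x) - 1)) / total_var,
    genes_used = hvg,
    loadings = loadings,
    center = ctr,
    scaled = scale.
  ), class = "stemtraj_embedding")
}

# Exact k-nearest neighbours in blocks (no n^2 memory blow-up).
knn_blocked <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  idx <- matrix(0L, nrow = n, ncol = k)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    for (r in seq_along(rows)) {
      d2[r, rows[r]] <- Inf
      idx[rows[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  idx
}

#' Shared-nearest-neighbor Louvain clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding coordinates, weights
#' edges by the Jaccard overlap of neighborhoods (shared nearest neighbors,
#' pruning weights below `prune`), and partitions it with the Louvain
#' modularity algorithm.
#'
#' @param embedding A [embed_cells()] object or a cells x dims matrix.
#' @param n_neighbors Neighborhood size (default 15).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed Integer seed (Louvain refinement is randomized).
#' @param prune Minimum SNN Jaccard weight retained (default 1/15).
#' @return Integer vector of cluster labels `0..K-1`, named by cell.
#' @export
cluster_cells <- function(embedding, n_neighbors = 15, resolution = 0.8,
                          seed = 1L, prune = 1 / 15) {
  coords <- if (inherits(embedding, "stemtraj_embedding"))
    embedding$coords else as.matrix(embedding)
  if (n_neighbors <= 0) stop("n_neighbors must be positive")
  n <- nrow(coords)
  if (n == 1L)
    return(stats::setNames(0L, rownames(coords)))
  k <- min(n_neighbors, n - 1L)
  nn <- knn_blocked(coords, k)
  # SNN: Jaccard overlap of (self + neighbors) sets
  nn_self <- cbind(seq_len(n), nn)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = ncol(nn_self)),
    j = as.vector(t(nn_self)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  ksz <- ncol(nn_self)
  snn <- shared
  snn@x <- snn@x / (2 * ksz - snn@x)  # Jaccard: |A&B| / (|A|+|B|-|A&B|)
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::cluster_louvain(
    g, resolution = resolution)$membership)
  # stable relabel: clusters numbered 0.. by decreasing size, ties by first
  # occurrence
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  stats::setNames(as.integer(relab[as.character(memb)]), rownames(coords))
}

#' Annotate clusters with cell types from marker sets
#'
#' Each cluster is assigned the type whose marker genes have the highest
#' mean normalized expression over the cluster's cells; ties are broken
#' lexicographically (and logged in the `"ties"` attribute).
#'
#' @param normalized Genes x cells normalized matrix.
#' @param labels Per-cell cluster labels (vector aligned with columns).
#' @param marker_sets Named list of marker gene vectors.
#' @param conditions Optional per-cell condition labels; when given, the
#'   result carries a per-condition cell-type proportion table (columns sum
#'   to 1) as attribute `"proportions"`.
#' @return Character vector of per-cell types, named by cell; the
#'   cluster-to-type map is attribute `"cluster_types"`.
#' @export
annotate_types <- function(normalized, labels, marker_sets,
                           conditions = NULL) {
  stopifnot(length(labels) == ncol(normalized))
  if (length(marker_sets) == 0 || is.null(names(marker_sets)))
    stop("marker_sets must be a non-empty named list")
  present <- lapply(marker_sets, intersect, y = rownames(normalized))
  empty <- names(present)[vapply(present, length, 1L) == 0]
  if (length(empty))
    stop("no marker genes found in the matrix for type(s): ",
         paste(empty, collapse = ", "))
  types <- sort(names(present))
  clusters <- sort(unique(labels))
  ties <- character(0)
  assign <- vapply(clusters, function(cl) {
    cells <- which(labels == cl)
    score <- vapply(types, function(ty)
      mean(Matrix::rowMeans(normalized[present[[ty]], cells,
                                       drop = FALSE])), numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1)
      ties <<- c(ties, paste0("cluster ", cl, ": ",
                              paste(types[best], collapse = "/")))
    types[best[1]]
  }, character(1))
  names(assign) <- as.character(clusters)
  out <- stats::setNames(assign[as.character(labels)],
                         colnames(normalized))
  attr(out, "cluster_types") <- assign
  if (length(ties)) attr(out, "ties") <- ties
  if (!is.null(conditions)) {
    tab <- table(type = out, condition = conditions)
    attr(out, "proportions") <- prop.table(tab, margin = 2)
  }
  out
}
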