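#' Control-bin module score
#'
#' Per-cell activity score of a gene set relative to expression-matched
#' random control genes: all genes are binned into `n_bins` by their
#' dataset-average expression; for every set gene, `n_ctrl` control genes
#' are drawn with replacement from its bin (the set's own genes are not
#' eligible as controls); the score is
#' `mean(set expression) - mean(pooled control expression)` per cell.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param gene_set Character vector of gene ids.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed (control sampling is random).
#' @return Numeric per-cell score vector, named by cell. Attributes record
#'   the genes used, bin and control counts and the seed.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  genes <- rownames(normalized)
  if (n_bins > length(genes))
    stop("n_bins exceeds the number of genes")
  set <- intersect(gene_set, genes)
  if (length(set) == 0)
    stop("gene_set has no overlap with the expression matrix")
  avg <- Matrix::rowMeans(normalized)
  bins <- if (n_bins == 1) rep(1L, length(genes)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- genes
  bin_members <- split(genes, bins)
  ctrl_counts <- with_seed(seed, {
    counts <- integer(length(genes)); names(counts) <- genes
    for (g in set) {
      # controls are expression-matched genes outside the set itself;
      # if the set saturates a bin, fall back to the whole bin
      pool <- setdiff(bin_members[[as.character(bins[[g]])]], set)
      if (length(pool) == 0)
        pool <- bin_members[[as.character(bins[[g]])]]
      draw <- pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
      tab <- table(draw)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    counts
  })
  set_score <- Matrix::colMeans(normalized[set, , drop = FALSE])
  nz <- ctrl_counts > 0
  ctrl_score <- as.numeric(
    ctrl_counts[nz] %*% normalized[which(nz), , drop = FALSE]) /
    sum(ctrl_counts)
  out <- stats::setNames(as.numeric(set_score - ctrl_score),
                         colnames(normalized))
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                              genes_used = set)
  out
}

#' Score several pathways at once
#'
#' @param normalized Genes x cells normalized matrix.
#' @param gene_sets Named list of gene sets.
#' @param ... Passed to [module_score()]; per-set seeds are derived from
#'   `seed` and the set name so each pathway's control draw is independent
#'   but reproducible.
#' @param seed Integer seed.
#' @return data.frame cells x pathways of scores.
#' @export
module_score_table <- function(normalized, gene_sets, seed = 1L, ...) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  scores <- lapply(names(gene_sets), function(nm)
    as.numeric(module_score(normalized, gene_sets[[nm]],
                            seed = stage_seed(seed, nm), ...)))
  out <- as.data.frame(stats::setNames(scores, names(gene_sets)))
  rownames(out) <- colnames(normalized)
  out
}

#' Mouse-level and condition-level mean module scores
#'
#' The mouse is the experimental unit: per-mouse means are computed first
#' and a condition's mean is the mean of its mice.
#'
#' @param scores Per-cell score vector or cells x pathways data.frame.
#' @param mouse Per-cell mouse ids.
#' @param condition Per-cell condition labels.
#' @return List with `mouse` (mouse x pathway means, with condition column)
#'   and `condition` (condition x pathway means).
#' @export
mean_score_by_mouse <- function(scores, mouse, condition) {
  if (is.null(dim(scores)))
    scores <- data.frame(score = as.numeric(scores))
  stopifnot(nrow(scores) == length(mouse), length(mouse) == length(condition))
  mouse_cond <- tapply(as.character(condition), mouse, function(z) z[1])
  mm <- apply(scores, 2, function(col) tapply(col, mouse, mean))
  mm <- as.data.frame(if (is.null(dim(mm)))
    matrix(mm, nrow = 1, dimnames = list(unique(mouse), colnames(scores)))
    else mm)
  mouse_tab <- data.frame(mouse = rownames(mm),
                          condition = as.character(mouse_cond[rownames(mm)]),
                          mm, row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cond_tab <- stats::aggregate(
    mouse_tab[, colnames(mm), drop = FALSE],
    by = list(condition = mouse_tab$condition), FUN = mean)
  list(mouse = mouse_tab, condition = cond_tab)
}

#' Per-gene mean expression by condition within a cluster
#'
#' Normalized expression is de-logged back to the linear counts-per-10k
#' scale before averaging, so ratios of the resulting means estimate the
#' underlying count-scale condition ratio. Means are computed per mouse
#' over the cluster's cells, then averaged over each condition's mice
#' (mouse = experimental unit). Set `unit = "cell"` to pool cells instead.
#'
#' @param normalized Genes x cells normalized (log) matrix.
#' @param mouse,condition Per-cell metadata vectors.
#' @param scope Logical or index vector selecting the cluster's cells.
#' @param genes Genes to report (default all).
#' @param unit `"mouse"` (default) or `"cell"`.
#' @return Genes x conditions matrix of means; per-mouse means are kept in
#'   the `"mouse_means"` attribute. Mice with no cell in scope are skipped
#'   with a warning.
#' @export
mean_expression_by_condition <- function(normalized, mouse, condition,
                                         scope, genes = NULL,
                                         unit = c("mouse", "cell")) {
  unit <- match.arg(unit)
  stopifnot(ncol(normalized) == length(mouse),
            length(mouse) == length(condition))
  idx <- seq_len(ncol(normalized))[scope]
  if (length(idx) == 0) stop("scope selects no cells")
  if (is.null(genes)) genes <- rownames(normalized)
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "))
  expr <- expm1(normalized[genes, idx, drop = FALSE])
  mo <- as.character(mouse[idx]); co <- as.character(condition)[idx]
  all_mice <- unique(as.character(mouse))
  skipped <- setdiff(all_mice, unique(mo))
  if (length(skipped))
    warning("mice with no cells in scope skipped: ",
            paste(skipped, collapse = ", "))
  if (unit == "cell") {
    conds <- unique(co)
    out <- vapply(conds, function(cn)
      Matrix::rowMeans(expr[, co == cn, drop = FALSE]), numeric(length(genes)))
    rownames(out) <- genes
    return(out)
  }
  mice <- unique(mo)
  mouse_means <- vapply(mice, function(m)
    Matrix::rowMeans(expr[, mo == m, drop = FALSE]), numeric(length(genes)))
  mouse_means <- matrix(mouse_means, nrow = length(genes),
                        dimnames = list(genes, mice))
  mouse_cond <- vapply(mice, function(m) co[match(m, mo)], character(1))
  conds <- unique(mouse_cond)
  out <- vapply(conds, function(cn)
    rowMeans(mouse_means[, mouse_cond == cn, drop = FALSE]),
    numeric(length(genes)))
  out <- matrix(out, nrow = length(genes), dimnames = list(genes, conds))
  attr(out, "mouse_means") <- mouse_means
  attr(out, "mouse_condition") <- mouse_cond
  out
}

#' Per-gene expression ratios with compartment bins
#'
#' `ratio = mean(contrast) / mean(reference)` per gene; genes with zero
#' reference mean are excluded (the signature is restricted to genes
#' expressed in the reference condition) and reported in the `"excluded"`
#' attribute. Compartment bins follow [compartment_edges()] (left-open,
#' right-closed; a ratio of exactly 1 falls in compartment 3).
#'
#' @param means Genes x conditions matrix from
#'   [mean_expression_by_condition()].
#' @param contrasts Condition labels to contrast against the reference
#'   (default: all non-reference columns).
#' @param reference Reference condition (default `"Y"`).
#' @return Long data.frame: `gene`, `contrast`, `ratio`, `compartment`.
#' @export
expression_ratio <- function(means, contrasts = NULL, reference = "Y") {
  if (!reference %in% colnames(means))
    stop("reference condition ", reference, " not present in means")
  if (is.null(contrasts)) contrasts <- setdiff(colnames(means), reference)
  ref <- means[, reference]
  keep <- ref > 0
  excluded <- rownames(means)[!keep]
  if (!any(keep)) stop("no genes expressed in the reference condition")
  edges <- compartment_edges()
  out <- do.call(rbind, lapply(contrasts, function(cn) {
    r <- means[keep, cn] / ref[keep]
    data.frame(gene = rownames(means)[keep], contrast = cn, ratio = r,
               compartment = as.integer(cut(r, breaks = edges, right = TRUE)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "excluded") <- excluded
  attr(out, "reference") <- reference
  out
}

#' Compartment percentages of a ratio table
#'
#' @param ratios Data.frame from [expression_ratio()].
#' @param contrast Contrast to summarize (default: the only one present).
#' @return List with `percent` (named six-bin percentage vector summing to
#'   100), `fraction_below_1` (percent of genes with ratio <= 1, the sum of
#'   compartments 1-3) and `n`.
#' @export
compartment_summary <- function(ratios, contrast = NULL) {
  stopifnot(nrow(ratios) > 0)
  if (is.null(contrast)) {
    contrast <- unique(ratios$contrast)
    if (length(contrast) != 1)
      stop("multiple contrasts present; pick one")
  }
  sub <- ratios[ratios$contrast == contrast, ]
  if (nrow(sub) == 0) stop("no rows for contrast ", contrast)
  counts <- tabulate(sub$compartment, nbins = 6)
  pct <- 100 * counts / sum(counts)
  names(pct) <- c("(0,0.5]", "(0.5,0.8]", "(0.8,1]", "(1,1.2]",
                  "(1.2,1.5]", ">1.5")
  list(percent = pct, fraction_below_1 = sum(pct[1:3]), n = nrow(sub),
       contrast = contrast)
}

#' Bivariate pathway coordination (MANOVA + 95% ellipses)
#'
#' Tests whether mouse-level mean module scores of two pathways differ
#' jointly across conditions (Pillai MANOVA, mice independent) and returns
#' per-condition 95% Gaussian ellipse parameters (mean, covariance
#' eigen-axes scaled to the chi-squared 95% radius on 2 df).
#'
#' @param mouse_means data.frame with columns `condition` and the two
#'   pathway columns named in `pathways` (one row per mouse; the `mouse`
#'   output of [mean_score_by_mouse()]).
#' @param pathways Character vector of two pathway column names.
#' @return List with `test` (a `stemtraj_test`) and `ellipses` (per
#'   condition: center, semi-axes, angle; degenerate ellipses flagged).
#' @export
bivariate_coordination <- function(mouse_means, pathways) {
  stopifnot(length(pathways) == 2,
            all(pathways %in% colnames(mouse_means)),
            "condition" %in% colnames(mouse_means))
  Y <- as.matrix(mouse_means[, pathways])
  groups <- mouse_means$condition
  if (min(table(groups)) < 2) stop("need at least 2 mice per condition")
  test <- manova_two_response(Y, groups)
  radius <- sqrt(stats::qchisq(0.95, df = 2))
  ellipses <- lapply(split(as.data.frame(Y), groups), function(yy) {
    yy <- as.matrix(yy)
    ctr <- colMeans(yy)
    if (nrow(yy) < 3)
      return(list(center = ctr, semi_axes = c(NA, NA), angle = NA,
                  degenerate = TRUE))
    cv <- stats::cov(yy)
    ev <- eigen(cv, symmetric = TRUE)
    degen <- any(ev$values <= 1e-15)
    list(center = ctr,
         semi_axes = radius * sqrt(pmax(0, ev$values)),
         angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
         degenerate = degen)
  })
  list(test = test, ellipses = ellipses)
}
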