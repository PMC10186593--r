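#' Negative-binomial mixed-model differential expression for one gene
#'
#' Fits counts ~ condition with a log link, `offset(log(totals))` for the
#' per-cell library size, a Gaussian random intercept per mouse (Laplace
#' approximation) and a profiled NB dispersion, and reports Wald tests of
#' the condition coefficients against the reference level. The fast
#' `"pseudobulk"` method instead sums counts and totals per mouse and fits
#' a fixed-effect NB regression on the mouse totals.
#'
#' @param counts_g Integer per-cell counts of one gene.
#' @param condition Per-cell condition factor (first level = reference).
#' @param mouse Per-cell mouse ids.
#' @param totals Per-cell total counts (offset).
#' @param gene Gene id carried into the result.
#' @param method `"glmm"` (default) or `"pseudobulk"`.
#' @return data.frame with one row per non-reference condition: `gene`,
#'   `contrast`, `logfc` (natural log), `se`, `p`, `sigma_mouse`,
#'   `converged` flag (`"ok"`, `"non_estimable"`, `"no_convergence"`), and
#'   per-group cell counts in the `"n_cells"` attribute.
#' @export
fit_nb_glmm <- function(counts_g, condition, mouse, totals, gene = "gene",
                        method = c("glmm", "pseudobulk")) {
  method <- match.arg(method)
  condition <- if (is.factor(condition)) droplevels(condition)
    else factor(condition, levels = unique(condition))
  mouse <- factor(mouse)
  stopifnot(length(counts_g) == length(condition),
            length(condition) == length(mouse),
            length(mouse) == length(totals))
  if (nlevels(condition) < 2) stop("need at least two conditions")
  ref <- levels(condition)[1]
  contrasts <- paste0(levels(condition)[-1], ":", ref)
  n_cells <- table(condition)
  empty_row <- function(flag) {
    out <- data.frame(gene = gene, contrast = contrasts, logfc = NA_real_,
                      se = NA_real_, p = NA_real_, sigma_mouse = NA_real_,
                      converged = flag, stringsAsFactors = FALSE)
    attr(out, "n_cells") <- n_cells
    out
  }
  if (all(counts_g == 0)) return(empty_row("non_estimable"))

  extract <- function(coefs, sigma_mouse, flag) {
    idx <- paste0("condition", levels(condition)[-1])
    out <- data.frame(gene = gene, contrast = contrasts,
                      logfc = coefs[idx, 1], se = coefs[idx, 2],
                      p = coefs[idx, 4], sigma_mouse = sigma_mouse,
                      converged = flag, row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(out, "n_cells") <- n_cells
    out
  }

  if (method == "pseudobulk") {
    y <- tapply(counts_g, mouse, sum)
    tt <- tapply(totals, mouse, sum)
    cc <- factor(tapply(as.character(condition), mouse, `[`, 1),
                 levels = levels(condition))
    df <- data.frame(y = as.numeric(y), condition = cc,
                     off = log(as.numeric(tt)))
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ condition + offset(off), data = df)),
      error = function(e) NULL)
    if (is.null(fit)) return(empty_row("no_convergence"))
    co <- summary(fit)$coefficients
    return(extract(co, sigma_mouse = 0,
                   flag = if (fit$converged) "ok" else "no_convergence"))
  }

  df <- data.frame(y = counts_g, condition = condition, mouse = mouse,
                   off = log(totals))
  fit <- tryCatch(suppressWarnings(suppressMessages(
    lme4::glmer.nb(y ~ condition + (1 | mouse) + offset(off), data = df,
                   nb.control = lme4::glmerControl(
                     check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) return(empty_row("no_convergence"))
  co <- summary(fit)$coefficients
  sigma_mouse <- sqrt(as.numeric(lme4::VarCorr(fit)$mouse[1, 1]))
  msgs <- fit@optinfo$conv$lme4$messages
  bad <- !is.null(msgs) && any(grepl("failed to converge", msgs))
  extract(co, sigma_mouse, flag = if (bad) "no_convergence" else "ok")
}

#' Differential expression over many genes
#'
#' Applies [fit_nb_glmm()] gene-by-gene within an optional cell scope and
#' BH-adjusts the Wald p values of converged fits per contrast.
#'
#' @param counts Genes x cells count matrix.
#' @param condition,mouse Per-cell metadata.
#' @param genes Genes to test (default: all with nonzero counts in scope).
#' @param scope Optional logical/index cell selector (e.g. one cluster).
#' @param method Passed to [fit_nb_glmm()]; pseudobulk is the desk-scale
#'   default.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param cluster Optional cluster label recorded in the result.
#' @return data.frame of per-gene per-contrast results with `padj`.
#' @export
run_de <- function(counts, condition, mouse, genes = NULL, scope = NULL,
                   method = c("pseudobulk", "glmm"), adjust = "BH",
                   cluster = NA_character_) {
  method <- match.arg(method)
  if (!is.null(scope)) {
    counts <- counts[, scope, drop = FALSE]
    condition <- condition[scope]
    mouse <- mouse[scope]
  }
  totals <- Matrix::colSums(counts)
  if (is.null(genes)) {
    rs <- Matrix::rowSums(counts)
    genes <- rownames(counts)[rs > 0]
  }
  rows <- lapply(genes, function(g)
    fit_nb_glmm(as.numeric(counts[g, ]), condition, mouse, totals,
                gene = g, method = method))
  out <- do.call(rbind, rows)
  out$cluster <- cluster
  out$padj <- NA_real_
  for (cn in unique(out$contrast)) {
    sel <- out$contrast == cn & out$converged == "ok" & !is.na(out$p)
    out$padj[sel] <- adjust_pvalues(out$p[sel], method = adjust)
  }
  out
}

#' Adjust p values for multiple testing
#'
#' Benjamini-Hochberg (default) or Bonferroni; monotone in the input.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Count differentially expressed genes
#'
#' A gene counts as differentially expressed when `|logFC| >= ln(fc)` and
#' `padj < padj_threshold`. Non-converged genes are excluded from the
#' counts and reported separately.
#'
#' @param results Data.frame from [run_de()] (may span clusters/contrasts).
#' @param fc_threshold Fold-change threshold on the natural scale (1.5).
#' @param padj_threshold Adjusted-p threshold (0.01).
#' @return data.frame with `cluster`, `contrast`, `n_deg`, `n_tested`,
#'   `n_excluded`.
#' @export
count_degs <- function(results, fc_threshold = 1.5, padj_threshold = 0.01) {
  if (nrow(results) == 0) stop("empty results table")
  key <- interaction(results$cluster, results$contrast, drop = TRUE)
  do.call(rbind, lapply(split(results, key), function(sub) {
    ok <- sub$converged == "ok" & !is.na(sub$padj)
    hit <- ok & abs(sub$logfc) >= log(fc_threshold) &
      sub$padj < padj_threshold
    data.frame(cluster = sub$cluster[1], contrast = sub$contrast[1],
               n_deg = sum(hit), n_tested = sum(ok),
               n_excluded = sum(!ok), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
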