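#' Rank genes by a differential-expression metric
#'
#' Orders genes by log fold-change, descending; ties are broken by gene id
#' (ascending) and logged in the `"ties"` attribute.
#'
#' @param de_results Data.frame with one row per gene and columns `gene`
#'   and `logfc` (or a two-column data.frame gene/metric).
#' @return Object of class `stemtraj_ranked`: data.frame `gene`, `metric`
#'   in ranking order.
#' @export
rank_genes <- function(de_results) {
  gene <- de_results$gene
  metric <- de_results$logfc %||% de_results$metric
  if (is.null(gene) || is.null(metric))
    stop("need columns gene and logfc (or metric)")
  if (anyDuplicated(gene))
    stop("duplicate gene ids in the ranking input: ",
         paste(head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  ord <- order(-metric, gene)
  out <- data.frame(gene = gene[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  dup_metric <- metric[duplicated(metric)]
  if (length(dup_metric))
    attr(out, "ties") <- unique(dup_metric)
  class(out) <- c("stemtraj_ranked", "data.frame")
  out
}

# Core running-sum enrichment statistic on hit positions. `metric` is the
# full ranked metric vector, `hits` the integer positions of set genes.
es_from_positions <- function(metric, hits, weight = 1) {
  N <- length(metric)
  n_set <- length(hits)
  if (n_set == N) return(list(es = 1, running = rep(1, N), degenerate = TRUE))
  w <- abs(metric[hits])^weight
  if (sum(w) == 0) w <- rep(1, n_set)  # all-zero metric: unweighted hits
  inc <- numeric(N)
  inc[hits] <- w / sum(w)
  dec <- rep(1 / (N - n_set), N)
  dec[hits] <- 0
  running <- cumsum(inc - dec)
  i <- which.max(abs(running))
  list(es = running[i], running = running, peak = i, degenerate = FALSE)
}

#' Enrichment score of a gene set on a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: the sum gains
#' `|metric|^weight` (normalized over the set's hits) at each set gene and
#' loses `1/(N - n_set)` at each miss; the enrichment score is the signed
#' extremum. A set covering the whole list returns `ES = 1` flagged
#' degenerate.
#'
#' @param ranked A [rank_genes()] object.
#' @param gene_set Character vector of gene ids.
#' @param weight Metric weight (default 1; 0 gives the unweighted
#'   statistic).
#' @return List: `es`, `running` (profile), `leading_edge` (set genes up to
#'   the extremum for positive ES, after it for negative), `degenerate`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "stemtraj_ranked"))
  hits <- which(ranked$gene %in% gene_set)
  if (length(hits) == 0)
    stop("gene set has no overlap with the ranked list: ",
         paste(head(gene_set, 3), collapse = ", "))
  res <- es_from_positions(ranked$metric, hits, weight)
  if (res$degenerate)
    return(list(es = 1, running = res$running, leading_edge = ranked$gene,
                degenerate = TRUE))
  le <- if (res$es >= 0) ranked$gene[hits[hits <= res$peak]]
        else ranked$gene[hits[hits > res$peak]]
  list(es = res$es, running = res$running, leading_edge = le,
       degenerate = FALSE)
}

#' Preranked GSEA with a gene-label permutation null
#'
#' For every set, the null distribution of the enrichment score is obtained
#' by re-drawing the set's positions uniformly among the ranked genes
#' (gene-label permutation preserving set size). `NES = ES / mean(|null ES|
#' of matching sign)`; the nominal p is two-sided on `|ES|` with a +1
#' pseudo-count, and BH adjustment is applied across sets. When the number
#' of distinct position sets `choose(N, n)` does not exceed `n_perm` the
#' null is enumerated exactly (and the p value is the exact two-sided tail
#' fraction, no pseudo-count needed).
#'
#' @param ranked A [rank_genes()] object.
#' @param gene_sets Named list of gene sets.
#' @param n_perm Permutations per set (default 1000; minimum 100).
#' @param weight Metric weight (default 1).
#' @param seed Integer seed.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `padj`,
#'   `leading_edge` (comma-separated), `n_perm`, `exact`.
#' @export
gsea_permutation <- function(ranked, gene_sets, n_perm = 1000, weight = 1,
                             seed = 1L) {
  stopifnot(inherits(ranked, "stemtraj_ranked"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (length(gene_sets) == 0 || is.null(names(gene_sets)))
    stop("gene_sets must be a non-empty named list")
  N <- nrow(ranked)
  rows <- with_seed(seed, lapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    if (length(unique(set)) > N)
      stop("gene set ", nm, " is larger than the ranked list")
    obs <- enrichment_score(ranked, set, weight)
    n_hit <- sum(ranked$gene %in% set)
    exact <- !obs$degenerate && n_hit <= N / 2 &&
      choose(N, n_hit) <= n_perm
    null_es <- if (exact) {
      combs <- utils::combn(N, n_hit)
      apply(combs, 2, function(pos)
        es_from_positions(ranked$metric, pos, weight)$es)
    } else {
      vapply(seq_len(n_perm), function(i)
        es_from_positions(ranked$metric,
                          sort(sample.int(N, n_hit)), weight)$es,
        numeric(1))
    }
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign) == 0) NA_real_ else
      obs$es / mean(abs(same_sign))
    p <- if (exact) mean(abs(null_es) >= abs(obs$es) - 1e-12) else
      (1 + sum(abs(null_es) >= abs(obs$es))) / (length(null_es) + 1)
    data.frame(set = nm, size = n_hit, es = obs$es, nes = nes, p = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               n_perm = length(null_es), exact = exact,
               degenerate = obs$degenerate, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out$padj <- adjust_pvalues(out$p, "BH")
  out[, c("set", "size", "es", "nes", "p", "padj", "leading_edge",
          "n_perm", "exact", "degenerate")]
}
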