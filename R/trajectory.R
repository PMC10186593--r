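#' Learn a principal-graph maturation trajectory
#'
#' A deterministic stand-in for graph-based pseudotime tools: one medoid
#' per cluster, a Euclidean minimum spanning tree over medoids, each cell
#' projected onto the nearest point of the edges incident to its cluster's
#' medoid, and pseudotime defined as the geodesic (along-tree) distance
#' from the root vertex to the projection, min-max normalized to `[0, 1]`.
#'
#' @param embedding A [embed_cells()] object or cells x dims matrix.
#' @param labels Per-cell cluster/type labels (character).
#' @param root Label of the root cluster (e.g. `"Stem"`).
#' @param n_dims Number of leading dimensions used (default: all).
#' @return Object of class `stemtraj_trajectory`: `vertices` (label ->
#'   coordinates), `edges` (data.frame `from`, `to`, `length`), `root`,
#'   `cells` (data.frame `cell_id`, `label`, `edge_from`, `edge_to`, `t`,
#'   `pseudotime`), `graph` (igraph tree).
#' @export
learn_trajectory <- function(embedding, labels, root, n_dims = NULL) {
  coords <- if (inherits(embedding, "stemtraj_embedding"))
    embedding$coords else as.matrix(embedding)
  if (!is.null(n_dims)) coords <- coords[, seq_len(n_dims), drop = FALSE]
  stopifnot(nrow(coords) == length(labels))
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  if (!root %in% labs) stop("root label ", root, " not present")
  if (length(labs) < 2) stop("need at least two clusters")

  medoid <- function(x) {
    if (nrow(x) == 1) return(x[1, ])
    d <- as.matrix(stats::dist(x))
    x[which.min(rowSums(d)), ]
  }
  verts <- t(vapply(labs, function(l)
    medoid(coords[labels == l, , drop = FALSE]), numeric(ncol(coords))))
  rownames(verts) <- labs

  dm <- as.matrix(stats::dist(verts))
  g_full <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                                weighted = TRUE)
  tree <- igraph::mst(g_full)
  el <- igraph::as_edgelist(tree)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length = igraph::E(tree)$weight,
                      stringsAsFactors = FALSE)

  # geodesic vertex distances from root along the tree
  vd <- igraph::distances(tree, v = root)[1, labs]

  # project each cell onto the nearest point of its medoid's incident edges
  n <- nrow(coords)
  proj <- data.frame(cell_id = rownames(coords) %||% as.character(seq_len(n)),
                     label = labels, edge_from = NA_character_,
                     edge_to = NA_character_, t = NA_real_,
                     pseudotime = NA_real_, stringsAsFactors = FALSE)
  for (l in labs) {
    cells <- which(labels == l)
    inc <- which(edges$from == l | edges$to == l)
    best_d <- rep(Inf, length(cells))
    for (e in inc) {
      a <- verts[edges$from[e], ]; b <- verts[edges$to[e], ]
      ab <- b - a
      len2 <- sum(ab^2)
      x <- coords[cells, , drop = FALSE]
      tt <- if (len2 == 0) rep(0, length(cells)) else
        pmin(1, pmax(0, (sweep(x, 2, a) %*% ab)[, 1] / len2))
      p <- outer(tt, ab) + rep(a, each = length(cells))
      d2 <- rowSums((x - p)^2)
      upd <- d2 < best_d
      if (any(upd)) {
        best_d[upd] <- d2[upd]
        proj$edge_from[cells[upd]] <- edges$from[e]
        proj$edge_to[cells[upd]] <- edges$to[e]
        proj$t[cells[upd]] <- tt[upd]
      }
    }
  }
  arc <- proj$t * edges$length[match(paste(proj$edge_from, proj$edge_to),
                                     paste(edges$from, edges$to))]
  pt <- pmin(vd[proj$edge_from] + arc,
             vd[proj$edge_to] +
               edges$length[match(paste(proj$edge_from, proj$edge_to),
                                  paste(edges$from, edges$to))] - arc)
  rng <- range(pt)
  proj$pseudotime <- if (diff(rng) == 0) rep(0, n) else
    (pt - rng[1]) / diff(rng)

  structure(list(vertices = verts, edges = edges, root = root,
                 cells = proj, graph = tree, vertex_dist = vd),
            class = "stemtraj_trajectory")
}

#' @export
print.stemtraj_trajectory <- function(x, ...) {
  cat("stemtraj trajectory:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges, root =", x$root, "\n")
  invisible(x)
}

#' Dichotomize cells into main-path and side-branch cells
#'
#' The main path is the unique tree path from the root to the terminus
#' vertex. Cells projected onto path edges are `main`; cells on subtrees
#' attached at path vertices before the terminus are `side`; cells on the
#' subtree hanging off the terminus itself (the continuation beyond the
#' selected portion) are `excluded`.
#'
#' @param traj A [learn_trajectory()] object.
#' @param terminus Label of the terminus vertex.
#' @return Object of class `stemtraj_selection`: list with `flag` (per-cell
#'   factor main/side/excluded, named by cell), `path` (ordered main-path
#'   vertex labels) and `attachment` (per-cell path vertex its subtree
#'   attaches at).
#' @export
select_and_dichotomize <- function(traj, terminus) {
  labs <- rownames(traj$vertices)
  if (!terminus %in% labs) stop("terminus label ", terminus, " not in graph")
  path <- igraph::shortest_paths(traj$graph, from = traj$root,
                                 to = terminus)$vpath[[1]]$name
  path_edges <- if (length(path) > 1)
    paste(pmin(path[-length(path)], path[-1]),
          pmax(path[-length(path)], path[-1])) else character(0)
  edge_key <- paste(pmin(traj$cells$edge_from, traj$cells$edge_to),
                    pmax(traj$cells$edge_from, traj$cells$edge_to))
  on_path <- edge_key %in% path_edges

  # attachment vertex of every cluster: last main-path vertex on the tree
  # path from the root to the cluster's medoid
  attach_of <- vapply(labs, function(l) {
    vp <- igraph::shortest_paths(traj$graph, from = traj$root,
                                 to = l)$vpath[[1]]$name
    vp[max(which(vp %in% path))]
  }, character(1))

  # a projected cell belongs to the subtree of the farther-from-path end of
  # its edge; for path edges this is irrelevant (main)
  cell_cluster_attach <- attach_of[traj$cells$label]
  flag <- ifelse(on_path, "main",
                 ifelse(cell_cluster_attach == terminus & !on_path,
                        "excluded", "side"))
  # degenerate terminus == root: only cells projected at the root vertex
  if (length(path) == 1) flag <- ifelse(traj$cells$label == traj$root,
                                        "main", "excluded")
  flag <- factor(flag, levels = c("main", "side", "excluded"))
  names(flag) <- traj$cells$cell_id
  structure(list(flag = flag, path = path,
                 attachment = stats::setNames(cell_cluster_attach,
                                              traj$cells$cell_id)),
            class = "stemtraj_selection")
}

#' Tertile (or n-tile) pseudotime compartments
#'
#' Contiguous early/mid/late segments of the main-path pseudotime axis,
#' with boundaries at the main cells' pseudotime n-tiles.
#'
#' @param pseudotime Per-cell pseudotime.
#' @param main Logical per-cell main-path indicator (boundaries are set on
#'   main cells; default all).
#' @param n Number of compartments (default 3).
#' @return Object of class `stemtraj_partition`: list with `breaks`
#'   (length n+1, spanning `[0, max]`) and `labels`.
#' @export
pseudotime_compartments <- function(pseudotime, main = NULL, n = 3) {
  use <- if (is.null(main)) pseudotime else pseudotime[main]
  qs <- stats::quantile(use, probs = seq_len(n - 1) / n, names = FALSE)
  breaks <- c(0, qs, max(pseudotime))
  if (any(diff(breaks) <= 0)) stop("degenerate compartment boundaries")
  labels <- if (n == 3) c("i", "ii", "iii") else as.character(seq_len(n))
  structure(list(breaks = breaks, labels = labels),
            class = "stemtraj_partition")
}

compartment_of <- function(pseudotime, partition) {
  idx <- findInterval(pseudotime, partition$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  factor(partition$labels[idx], levels = partition$labels)
}

#' Cell-type transition test across conditions per pseudotime compartment
#'
#' Builds the cell-type x condition contingency table in each pseudotime
#' compartment and tests it with the Monte-Carlo Pearson chi-squared test;
#' a joint test pools the cells of all compartments.
#'
#' @param types Per-cell cell-type labels.
#' @param pseudotime Per-cell pseudotime.
#' @param partition A [pseudotime_compartments()] object.
#' @param conditions Per-cell condition labels.
#' @param n_sim Monte-Carlo tables per test (default 2000).
#' @param seed Integer seed.
#' @return List with one `stemtraj_test` per compartment plus `joint`; the
#'   contingency tables are attached as `"tables"`.
#' @export
compartment_transition_test <- function(types, pseudotime, partition,
                                        conditions, n_sim = 2000,
                                        seed = 1L) {
  comp <- compartment_of(pseudotime, partition)
  if (any(table(comp, conditions) == 0))
    stop("every compartment x condition must contain at least one cell")
  tests <- list()
  tables <- list()
  for (i in seq_along(partition$labels)) {
    lab <- partition$labels[i]
    sel <- comp == lab
    tab <- table(type = droplevels(factor(types[sel])),
                 condition = conditions[sel])
    tables[[lab]] <- tab
    tests[[lab]] <- chisq_mc(tab, n_sim = n_sim,
                             seed = stage_seed(seed, lab))
  }
  joint_tab <- table(type = factor(types), condition = conditions)
  tables$joint <- joint_tab
  tests$joint <- chisq_mc(joint_tab, n_sim = n_sim,
                          seed = stage_seed(seed, "joint"))
  attr(tests, "tables") <- tables
  tests
}

#' Emergence pseudotime and delay per cell type and condition
#'
#' Emergence of a type in a condition is the `q`-quantile of the type's
#' main-cell pseudotimes ("first detection" operationalized robustly); the
#' delay is the difference to the reference condition.
#'
#' @param types,pseudotime,conditions Per-cell vectors.
#' @param main Logical per-cell main-path indicator.
#' @param reference Reference condition (default `"Y"`).
#' @param q Emergence quantile (default 0.05).
#' @param min_cells Minimum main cells per type x condition (default 20;
#'   groups below it give NA with a warning).
#' @return data.frame: `type`, `condition`, `n`, `emergence`, `delay`.
#' @export
emergence_delay <- function(types, pseudotime, main, conditions,
                            reference = "Y", q = 0.05, min_cells = 20) {
  stopifnot(length(types) == length(pseudotime),
            length(types) == length(conditions))
  ty <- types[main]; pt <- pseudotime[main]; co <- conditions[main]
  out <- expand.grid(type = unique(ty), condition = unique(co),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- mapply(function(t, c) sum(ty == t & co == c),
                  out$type, out$condition)
  out$emergence <- mapply(function(t, c) {
    sel <- ty == t & co == c
    if (sum(sel) < min_cells) NA_real_ else
      stats::quantile(pt[sel], q, names = FALSE)
  }, out$type, out$condition)
  low <- out$n < min_cells
  if (any(low))
    warning("type/condition groups below min_cells skipped: ",
            paste(paste(out$type[low], out$condition[low], sep = "/"),
                  collapse = ", "))
  ref_em <- stats::setNames(
    out$emergence[out$condition == reference],
    out$type[out$condition == reference])
  out$delay <- out$emergence - ref_em[out$type]
  out
}

#' Mean module score per main-path segment per condition
#'
#' Segments are the intervals between consecutive main-path vertices
#' (branch points), ordered by pseudotime. Main cells are assigned to their
#' projected edge's segment; each segment x condition mean score is
#' reported (NA when empty).
#'
#' @param scores Per-cell module scores (vector named by cell).
#' @param traj A [learn_trajectory()] object.
#' @param selection A [select_and_dichotomize()] object.
#' @param conditions Per-cell condition labels (aligned with `traj$cells`).
#' @return data.frame: `segment` (e.g. `"Stem->R"`), `order`, one column
#'   per condition.
#' @export
branchpoint_module_profile <- function(scores, traj, selection, conditions) {
  path <- selection$path
  if (length(path) < 2) stop("main path has no segments")
  segs <- paste(path[-length(path)], path[-1], sep = "->")
  cells <- traj$cells
  is_main <- selection$flag[cells$cell_id] == "main"
  key <- paste(pmin(cells$edge_from, cells$edge_to),
               pmax(cells$edge_from, cells$edge_to))
  seg_key <- paste(pmin(path[-length(path)], path[-1]),
                   pmax(path[-length(path)], path[-1]))
  seg_idx <- match(key, seg_key)
  conds <- sort(unique(as.character(conditions)))
  sc <- scores[cells$cell_id]
  out <- data.frame(segment = segs, order = seq_along(segs),
                    stringsAsFactors = FALSE)
  for (cn in conds) {
    out[[cn]] <- vapply(seq_along(segs), function(i) {
      sel <- is_main & !is.na(seg_idx) & seg_idx == i & conditions == cn
      if (!any(sel)) NA_real_ else mean(sc[sel])
    }, numeric(1))
  }
  out
}

#' Co-expression delay index of an early and a late maturation gene
#'
#' The transcript analog of a dual-stain co-positivity quantification: a
#' cell is positive for a gene when its normalized expression exceeds the
#' gene's `positivity_quantile` within the scoped cells (thresholds set on
#' the pooled scope); the index is
#' `|co-positive| / (|positive early| + |positive late|)`. More
#' intermediate (co-expressing) cells give a larger index, so a maturation
#' delay that piles cells between the two expression waves raises it.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param gene_early,gene_late Gene ids (early / late maturation markers).
#' @param scope Logical or index selector of cells in scope.
#' @param conditions Optional per-cell condition labels (full-length; the
#'   index is then reported per condition).
#' @param positivity_quantile Positivity threshold quantile (default 0.96,
#'   i.e. the top 4% of cells).
#' @return data.frame: `condition` (`"all"` when none given), `n_early`,
#'   `n_late`, `n_co`, `index`.
#' @export
coexpression_index <- function(normalized, gene_early, gene_late, scope,
                               conditions = NULL,
                               positivity_quantile = 0.96) {
  for (g in c(gene_early, gene_late))
    if (!g %in% rownames(normalized)) stop("gene absent: ", g)
  idx <- seq_len(ncol(normalized))[scope]
  if (length(idx) == 0) stop("scope selects no cells")
  e <- as.numeric(normalized[gene_early, idx])
  l <- as.numeric(normalized[gene_late, idx])
  if (stats::var(e) == 0 || stats::var(l) == 0)
    stop("zero-variance gene in scope; positivity threshold undefined")
  th_e <- stats::quantile(e, positivity_quantile, names = FALSE)
  th_l <- stats::quantile(l, positivity_quantile, names = FALSE)
  pos_e <- e > th_e
  pos_l <- l > th_l
  grp <- if (is.null(conditions)) rep("all", length(idx)) else
    as.character(conditions[idx])
  do.call(rbind, lapply(unique(grp), function(cn) {
    s <- grp == cn
    n_e <- sum(pos_e & s); n_l <- sum(pos_l & s)
    n_co <- sum(pos_e & pos_l & s)
    data.frame(condition = cn, n_early = n_e, n_late = n_l, n_co = n_co,
               index = if (n_e + n_l == 0) NA_real_ else n_co / (n_e + n_l),
               stringsAsFactors = FALSE)
  }))
}
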