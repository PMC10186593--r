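#' Expression-ratio compartment bin edges
#'
#' The six fixed intervals of the treated/young per-gene expression ratio
#' used throughout the package: (0,0.5], (0.5,0.8], (0.8,1.0], (1.0,1.2],
#' (1.2,1.5], (1.5,Inf). Intervals are left-open, right-closed, so a ratio
#' of exactly 1 falls in compartment 3.
#'
#' @export
compartment_edges <- function() c(0, 0.5, 0.8, 1.0, 1.2, 1.5, Inf)

#' Default per-condition compartment probabilities for the stem signature
#'
#' The study conditions of the simulator: probability that a signature
#' gene's true condition/young expression ratio falls in each of the six
#' compartments. Young is the reference (all ratios 1). The aged and
#' drug-treated vectors correspond to strong repression partially reversed
#' by metformin and rapamycin.
#'
#' @return 3 x 6 matrix with rows `O`, `O_met`, `O_rap`.
#' @export
default_signature_mixture <- function() {
  m <- rbind(
    O     = c(0.12, 0.38, 0.21, 0.14, 0.10, 0.04),
    O_met = c(0.05, 0.30, 0.37, 0.17, 0.07, 0.04),
    O_rap = c(0.04, 0.33, 0.36, 0.17, 0.07, 0.02)
  )
  # the printed percentages carry rounding (two rows sum to 99%);
  # renormalize to proper probability vectors
  sweep(m, 1, rowSums(m), "/")
}

#' Default per-condition pathway activity multipliers
#'
#' Aging raises OXPHOS and ribosome activity and suppresses Wnt and cell
#' cycle; metformin reverses most shifts, rapamycin reverses them partially
#' (least for OXPHOS).
#'
#' @return Named list of named numeric vectors (pathway -> condition -> x).
#' @export
default_pathway_activity <- function() {
  list(
    Wnt        = c(Y = 1, O = 0.70, O_met = 0.90, O_rap = 0.85),
    cell_cycle = c(Y = 1, O = 0.70, O_met = 0.95, O_rap = 0.90),
    ribosome   = c(Y = 1, O = 1.40, O_met = 1.15, O_rap = 1.20),
    OXPHOS     = c(Y = 1, O = 1.50, O_met = 1.10, O_rap = 1.35)
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. The defaults encode the emulated four-arm design: young (Y),
#' old (O), old + metformin (`O_met`) and old + rapamycin (`O_rap`) mice,
#' three animals per arm, with an Lgr5-like stem signature repressed in O
#' and partially restored by the drugs, pathway programs whose activity
#' shifts with condition, and a maturation delay that postpones the
#' emergence of post-stem cell types in aged animals.
#'
#' @param n_mice_per_condition Mice per experimental arm (default 3).
#' @param n_cells_per_mouse Cells simulated per mouse (default 1000).
#' @param n_genes Total genes (default 2000).
#' @param conditions Ordered condition labels; the first is the reference.
#' @param delay_per_condition Named maturation shift delta in `[0,1)` per
#'   condition: cell-type boundaries move up by delta so each post-stem
#'   type emerges later along the latent maturation coordinate.
#' @param signature_ratio_mixture Matrix (non-reference conditions x 6) of
#'   probabilities over the ratio compartments of [compartment_edges()];
#'   within a compartment the true ratio is drawn uniformly (top bin capped
#'   at `ratio_cap`).
#' @param reversal_epsilon Optional named vector: when set for a condition,
#'   its true ratios are not drawn from the mixture but pulled back toward
#'   young as `1 + eps * (r_O - 1)` (a single "reversal" knob).
#' @param pathway_activity Named list (pathway -> condition -> multiplier).
#' @param n_signature_genes Size of the synthetic stem signature (467, the
#'   size of the Lgr5-high ISC signature gene set it stands in for).
#' @param lgr5_ratio True condition/young ratio of the dedicated `Lgr5`
#'   marker gene (default `c(Y=1, O=0.67, O_met=0.87, O_rap=0.83)`).
#' @param p_side Probability a cell lies on a side branch (default 0.15).
#' @param n_side_branches Number of side-branch programs (default 2).
#' @param mouse_effect_sd Log-scale SD of the per-mouse random intercept.
#' @param nb_dispersion Negative-binomial size parameter (default 10,
#'   i.e. a residual within-cell-type coefficient of variation near 30%).
#' @param library_size_model List with `meanlog`, `sdlog` of the log-normal
#'   per-cell library size (default mean about 3000 counts).
#' @param mito_fraction Expected mitochondrial (`mt-` prefixed) share of a
#'   cell's counts (default 0.05).
#' @param ratio_cap Upper cap of the open top ratio compartment (default 3).
#' @param seed Integer seed; mandatory for reproducible cohorts.
#' @return Object of class `stemtraj_sim_config`.
#' @export
sim_config <- function(n_mice_per_condition = 3,
                       n_cells_per_mouse = 1000,
                       n_genes = 2000,
                       conditions = c("Y", "O", "O_met", "O_rap"),
                       delay_per_condition = c(Y = 0, O = 0.15,
                                               O_met = 0.03, O_rap = 0.06),
                       signature_ratio_mixture = default_signature_mixture(),
                       reversal_epsilon = NULL,
                       pathway_activity = default_pathway_activity(),
                       n_signature_genes = 467,
                       lgr5_ratio = c(Y = 1, O = 0.67,
                                      O_met = 0.87, O_rap = 0.83),
                       p_side = 0.15,
                       n_side_branches = 2,
                       mouse_effect_sd = 0.15,
                       nb_dispersion = 10,
                       library_size_model = list(meanlog = log(3000),
                                                 sdlog = 0.35),
                       mito_fraction = 0.05,
                       ratio_cap = 3,
                       seed = 1L) {
  if (n_mice_per_condition < 1 || n_cells_per_mouse < 1 || n_genes < 1)
    stop("cohort dimensions must be positive")
  if (length(conditions) < 2) stop("need at least two conditions")
  ref <- conditions[1]
  if (!all(conditions %in% names(delay_per_condition)))
    stop("delay_per_condition must name every condition")
  delta <- delay_per_condition[conditions]
  if (any(delta < 0) || any(delta >= 1))
    stop("delay_per_condition values must lie in [0, 1)")
  mix <- signature_ratio_mixture
  non_ref <- setdiff(conditions, ref)
  if (!is.matrix(mix) || ncol(mix) != 6L)
    stop("signature_ratio_mixture must be a (conditions x 6) matrix")
  missing_mix <- setdiff(non_ref, rownames(mix))
  if (length(missing_mix) && is.null(reversal_epsilon))
    stop("no ratio mixture for condition(s): ",
         paste(missing_mix, collapse = ", "))
  ok_rows <- intersect(rownames(mix), non_ref)
  if (any(abs(rowSums(mix[ok_rows, , drop = FALSE]) - 1) > 1e-12))
    stop("each signature_ratio_mixture row must sum to 1")
  if (any(mix < 0)) stop("mixture probabilities must be non-negative")
  for (pw in names(pathway_activity)) {
    act <- pathway_activity[[pw]]
    if (!all(conditions %in% names(act)))
      stop("pathway_activity$", pw, " must name every condition")
    if (any(act[conditions] <= 0))
      stop("pathway_activity multipliers must be positive")
  }
  if (length(pathway_activity) == 0) stop("missing pathway program")
  if (p_side < 0 || p_side >= 1) stop("p_side must lie in [0, 1)")
  if (!all(conditions %in% names(lgr5_ratio)))
    stop("lgr5_ratio must name every condition")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  cfg <- list(
    n_mice_per_condition = as.integer(n_mice_per_condition),
    n_cells_per_mouse = as.integer(n_cells_per_mouse),
    n_genes = as.integer(n_genes),
    conditions = conditions,
    reference = ref,
    delay_per_condition = delta,
    signature_ratio_mixture = mix,
    reversal_epsilon = reversal_epsilon,
    pathway_activity = pathway_activity,
    n_signature_genes = as.integer(n_signature_genes),
    lgr5_ratio = lgr5_ratio[conditions],
    p_side = p_side,
    n_side_branches = as.integer(n_side_branches),
    mouse_effect_sd = mouse_effect_sd,
    nb_dispersion = nb_dispersion,
    library_size_model = library_size_model,
    mito_fraction = mito_fraction,
    ratio_cap = ratio_cap,
    seed = as.integer(seed)
  )
  structure(cfg, class = "stemtraj_sim_config")
}

# ---- internal gene-program layout -----------------------------------------

main_types <- function() c("Stem", "R", "R-Div", "Div1", "Div2", "EC")

# Gaussian bump, peak height 1.
bump <- function(x, center, width) exp(-((x - center)^2) / (2 * width^2))

# Pathway activity profiles along the latent maturation coordinate s.
pathway_profile <- function(pathway, s) {
  switch(pathway,
    Wnt        = exp(-3 * s),
    cell_cycle = bump(s, 0.45, 0.20),
    ribosome   = 1 - 0.6 * s,
    OXPHOS     = bump(s, 0.50, 0.25),
    # unknown pathway names get a flat profile
    rep(1, length(s))
  )
}

# Static description of the gene panel for a config: ids, program labels and
# relative amplitude of every gene. Amplitudes are shares of a unit total;
# background genes absorb the per-cell remainder so that the expected total
# expression is condition-invariant (repression of the signature does not
# change a cell's expected library size).
gene_layout <- function(config) {
  n_pw <- length(config$pathway_activity)
  n_sig <- config$n_signature_genes
  n_mk_per_type <- 15L
  n_side_mk <- 15L
  n_backbone <- 60L
  n_pw_genes <- 40L
  n_mito <- 12L
  ids <- character(0); program <- character(0)
  add <- function(id, prog) {
    ids <<- c(ids, id); program <<- c(program, rep(prog, length(id)))
  }
  add("Lgr5", "lgr5")
  add(c("Uhrf1", "Ccnb1"), "maturation_marker")
  add(sprintf("Sig%03d", seq_len(n_sig)), "signature")
  for (ty in main_types())
    add(sprintf("Mk.%s.%02d", gsub("-", "", ty), seq_len(n_mk_per_type)),
        paste0("stage_marker:", ty))
  if (config$n_side_branches > 0)
    for (k in seq_len(config$n_side_branches))
      add(sprintf("SideMk.%d.%02d", k, seq_len(n_side_mk)),
          paste0("side_marker:", k))
  add(sprintf("Backbone%02d", seq_len(n_backbone)), "backbone")
  for (pw in names(config$pathway_activity))
    add(sprintf("%s.%02d", pw, seq_len(n_pw_genes)),
        paste0("pathway:", pw))
  add(sprintf("mt-Mito%02d", seq_len(n_mito)), "mito")
  n_bg <- config$n_genes - length(ids)
  if (n_bg < 50)
    stop("n_genes too small for the gene panel: need at least ",
         length(ids) + 50, " genes")
  add(sprintf("Bg%04d", seq_len(n_bg)), "background")
  data.frame(gene_id = ids, program = program, stringsAsFactors = FALSE)
}

# Draw true condition/reference ratios for the signature genes: compartment
# by multinomial over the mixture, then uniform within the compartment.
draw_signature_ratios <- function(config, n) {
  edges <- compartment_edges()
  conds <- setdiff(config$conditions, config$reference)
  out <- matrix(1, nrow = n, ncol = length(conds),
                dimnames = list(NULL, conds))
  for (cond in conds) {
    eps <- config$reversal_epsilon[[cond]] %||% NA_real_
    if (!is.na(eps)) next  # filled after the O draw below
    probs <- config$signature_ratio_mixture[cond, ]
    comp <- sample.int(6L, n, replace = TRUE, prob = probs)
    lo <- edges[comp]
    hi <- pmin(edges[comp + 1L], config$ratio_cap)
    out[, cond] <- runif(n, lo, hi)
  }
  for (cond in conds) {
    eps <- config$reversal_epsilon[[cond]] %||% NA_real_
    if (!is.na(eps)) {
      if (!"O" %in% conds) stop("reversal_epsilon requires an O condition")
      out[, cond] <- 1 + eps * (out[, "O"] - 1)
    }
  }
  out
}

#' Generate a ground-truthed synthetic cohort
#'
#' Simulates a genes x cells count matrix with the statistical structure the
#' downstream analyses assume: a latent maturation coordinate `s ~ U(0,1)`
#' per cell along a branching stem-to-enterocyte continuum; cell types
#' assigned from `s` with per-condition boundary shifts (delayed emergence);
#' stage-marker genes following the (delayed) identity coordinate while a
#' condition-independent backbone program follows `s`; a stem signature
#' whose true condition/young ratios are drawn per gene from compartment
#' mixtures; pathway programs with condition multipliers; log-normal library
#' sizes and per-mouse random intercepts; NB-distributed counts.
#'
#' Counts are `NB(mean = libsize * mouse_effect * mu_g(cell), size =
#' nb_dispersion)` where the relative expression `mu_g` sums to 1 in every
#' cell (background genes absorb programmed shifts, so condition effects on
#' individual genes are recoverable from normalized expression).
#'
#' @param config A [sim_config()] object.
#' @return Object of class `stemtraj_cohort`: list with `counts` (sparse
#'   integer dgCMatrix, genes x cells), `cells` (metadata data.frame),
#'   `genes` (gene table with program labels), `truth` (per-cell latent
#'   state, per-gene true ratios) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "stemtraj_sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  genes <- gene_layout(config)
  G <- nrow(genes)
  conds <- config$conditions
  n_mice <- config$n_mice_per_condition
  n_cells <- config$n_cells_per_mouse
  N <- length(conds) * n_mice * n_cells

  # per-gene true condition ratios (reference ratio 1)
  non_ref <- setdiff(conds, config$reference)
  ratio_true <- matrix(1, nrow = G, ncol = length(non_ref),
                       dimnames = list(genes$gene_id, non_ref))
  sig_idx <- which(genes$program == "signature")
  ratio_true[sig_idx, ] <- draw_signature_ratios(config, length(sig_idx))
  ratio_true["Lgr5", ] <- config$lgr5_ratio[non_ref]

  # cell-level latent state
  cell_cond <- rep(conds, each = n_mice * n_cells)
  mouse_num <- rep(rep(seq_len(n_mice), each = n_cells), times = length(conds))
  mouse_id <- paste0(cell_cond, "_m", mouse_num)
  s <- runif(N)
  on_side <- runif(N) < config$p_side & config$n_side_branches > 0
  branch_k <- integer(N)
  branch_k[on_side] <- sample.int(config$n_side_branches, sum(on_side),
                                  replace = TRUE)
  branch <- ifelse(on_side, paste0("side_", branch_k), "main")
  # side-branch cells sit in a narrow maturation window around their
  # branch's attachment locus, so each branch hangs off one point of the
  # main continuum rather than shadowing it; loci are the centers of the
  # intermediate progenitor stages (R, R-Div, ...)
  if (config$n_side_branches > 0) {
    type_centers <- seq(1 / 12, 11 / 12, by = 1 / 6)
    attach_s <- type_centers[1 + (seq_len(config$n_side_branches) - 1) %% 4 +
                               1]
    s[on_side] <- pmin(1, pmax(0, attach_s[branch_k[on_side]] +
                                 runif(sum(on_side), -0.08, 0.08)))
  }
  delta <- config$delay_per_condition[cell_cond]
  d <- pmax(0, s - delta)  # delayed identity coordinate
  bounds <- seq(1 / 6, 5 / 6, by = 1 / 6)
  type_idx <- findInterval(d, bounds) + 1L
  type <- main_types()[type_idx]

  # per-mouse random intercept (log-normal, mean 1)
  mice <- unique(mouse_id)
  m_eff <- stats::setNames(
    exp(rnorm(length(mice), 0, config$mouse_effect_sd) -
          config$mouse_effect_sd^2 / 2), mice)
  libsize <- rlnorm(N, config$library_size_model$meanlog,
                    config$library_size_model$sdlog)

  # relative-expression weight matrix, built per program (genes x cells)
  W <- matrix(0, nrow = G, ncol = N, dimnames = list(genes$gene_id, NULL))
  cond_col <- function(ratios) {
    r <- rep(1, N)
    for (cond in non_ref) r[cell_cond == cond] <- ratios[cond]
    r
  }
  # stage markers dominate the condition-independent backbone so that
  # clusters track (delayed) cell identity while pseudotime tracks overall
  # maturation
  # the backbone (condition-independent maturation program) carries most of
  # the continuum's geometric arc length, so pseudotime tracks overall
  # position; stage markers are strong enough for marker-based typing
  amp <- list(signature = 0.30, marker = 0.06, side = 0.10, backbone = 0.20,
              pathway = 0.05, lgr5 = 0.004, mat = 0.004)

  # Lgr5 and the signature have flat trajectory profiles: their condition
  # ratio is constant along the continuum, so the ratio measured in any
  # cell scope identifies the true r (no composition confounding).
  W["Lgr5", ] <- amp$lgr5 * cond_col(ratio_true["Lgr5", , drop = TRUE])
  # early/late maturation markers with overlapping plateau profiles. The
  # early program (Uhrf1) follows the delayed identity coordinate - in aged
  # animals it persists to later trajectory positions - while the late
  # program (Ccnb1) is triggered by trajectory position, so the
  # co-expression window widens with the maturation delay.
  plateau <- function(x, lo, hi, slope = 0.04)
    stats::plogis((x - lo) / slope) * stats::plogis((hi - x) / slope)
  W["Uhrf1", ] <- amp$mat * plateau(d, 0.12, 0.55)
  W["Ccnb1", ] <- amp$mat * plateau(s, 0.40, 0.80)

  sig_base <- amp$signature / length(sig_idx)
  r_cells <- matrix(1, nrow = length(sig_idx), ncol = N)
  for (cond in non_ref) {
    cc <- cell_cond == cond
    r_cells[, cc] <- ratio_true[sig_idx, cond]
  }
  W[sig_idx, ] <- sig_base * r_cells

  # stage markers are restricted to main-continuum cells; side-branch cells
  # carry their own marker program instead (a distinct transcriptional
  # state, not a delayed copy of the main identity)
  is_main <- branch == "main"
  centers <- seq(1 / 12, 11 / 12, by = 1 / 6)
  for (i in seq_along(main_types())) {
    mk <- which(genes$program == paste0("stage_marker:", main_types()[i]))
    prof <- (amp$marker / length(mk)) * bump(d, centers[i], 0.08) * is_main
    W[mk, ] <- matrix(prof, nrow = length(mk), ncol = N, byrow = TRUE)
  }
  if (config$n_side_branches > 0) {
    for (k in seq_len(config$n_side_branches)) {
      mk <- which(genes$program == paste0("side_marker:", k))
      prof <- (amp$side / length(mk)) * as.numeric(branch == paste0("side_", k))
      W[mk, ] <- matrix(prof, nrow = length(mk), ncol = N, byrow = TRUE)
    }
  }
  bb <- which(genes$program == "backbone")
  bb_centers <- rep(seq(0.05, 0.95, length.out = 10), each = 6)
  for (j in seq_along(bb)) {
    W[bb[j], ] <- (amp$backbone / 15) * bump(s, bb_centers[j], 0.12)
  }
  for (pw in names(config$pathway_activity)) {
    gk <- which(genes$program == paste0("pathway:", pw))
    act <- config$pathway_activity[[pw]][cell_cond]
    prof <- (amp$pathway / length(gk)) * pathway_profile(pw, s) * act
    W[gk, ] <- matrix(prof, nrow = length(gk), ncol = N, byrow = TRUE)
  }
  mito <- which(genes$program == "mito")
  W[mito, ] <- config$mito_fraction / length(mito)

  # background absorbs the remainder so every cell's weights sum to 1
  bg <- which(genes$program == "background")
  used <- colSums(W)
  if (any(used >= 0.98))
    stop("programmed expression exceeds the per-cell budget; ",
         "reduce amplitudes or multipliers")
  W[bg, ] <- matrix((1 - used) / length(bg), nrow = length(bg), ncol = N,
                    byrow = TRUE)

  mu <- W * rep(libsize * m_eff[mouse_id], each = G)
  counts <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                   nrow = G)
  dimnames(counts) <- list(genes$gene_id, sprintf("cell%05d", seq_len(N)))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")

  cells <- data.frame(
    cell_id = colnames(counts),
    mouse = mouse_id,
    condition = cell_cond,
    stringsAsFactors = FALSE
  )
  truth_cells <- data.frame(
    cell_id = cells$cell_id, s = s, identity = d,
    branch = branch, type = type, stringsAsFactors = FALSE
  )
  structure(list(
    counts = counts,
    cells = cells,
    genes = genes,
    truth = list(cells = truth_cells,
                 gene_ratios = data.frame(gene_id = genes$gene_id,
                                          ratio_true,
                                          check.names = FALSE,
                                          stringsAsFactors = FALSE),
                 mouse_effect = m_eff),
    config = config
  ), class = "stemtraj_cohort")
}

#' @export
print.stemtraj_cohort <- function(x, ...) {
  cat("stemtraj cohort:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells\n")
  cat("conditions:", paste(x$config$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Marker gene sets of a synthetic cohort
#'
#' Returns the stage-marker sets (one per main cell type, the Stem set
#' augmented with `Lgr5`) plus one set per side-branch program, suitable for
#' [annotate_types()].
#'
#' @param cohort A `stemtraj_cohort`.
#' @return Named list of character vectors.
#' @export
cohort_marker_sets <- function(cohort) {
  g <- cohort$genes
  sets <- lapply(main_types(), function(ty)
    g$gene_id[g$program == paste0("stage_marker:", ty)])
  names(sets) <- main_types()
  sets$Stem <- c(sets$Stem, "Lgr5")
  if (cohort$config$n_side_branches > 0) {
    for (k in seq_len(cohort$config$n_side_branches))
      sets[[paste0("Side_", k)]] <-
        g$gene_id[g$program == paste0("side_marker:", k)]
  }
  sets
}

#' Pathway gene sets of a synthetic cohort
#'
#' @param cohort A `stemtraj_cohort`.
#' @return Named list of character vectors (one per simulated pathway).
#' @export
cohort_pathway_sets <- function(cohort) {
  g <- cohort$genes
  pws <- names(cohort$config$pathway_activity)
  stats::setNames(lapply(pws, function(pw)
    g$gene_id[g$program == paste0("pathway:", pw)]), pws)
}

#' Signature gene ids of a synthetic cohort
#'
#' @param cohort A `stemtraj_cohort`.
#' @return Character vector of signature gene ids.
#' @export
cohort_signature_genes <- function(cohort) {
  cohort$genes$gene_id[cohort$genes$program == "signature"]
}

# ---- fixture I/O ----------------------------------------------------------

#' Write a cohort to a fixture directory
#'
#' Writes `counts.mtx` (Matrix Market), `genes.tsv`, `cells.tsv`,
#' `truth_cells.tsv`, `truth_gene_ratios.tsv`, `config.json` and GMT files
#' for the simulated marker, pathway and signature sets.
#'
#' @param cohort A `stemtraj_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(cohort$counts, file.path(dir, "counts.mtx"))
  write_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  write_tsv(cohort$cells, file.path(dir, "cells.tsv"))
  write_tsv(cohort$truth$cells, file.path(dir, "truth_cells.tsv"))
  write_tsv(cohort$truth$gene_ratios, file.path(dir, "truth_gene_ratios.tsv"))
  cfg <- cohort$config
  cfg$signature_ratio_mixture <-
    as.data.frame(cfg$signature_ratio_mixture)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_gmt(cohort_marker_sets(cohort), file.path(dir, "markers.gmt"))
  write_gmt(cohort_pathway_sets(cohort), file.path(dir, "pathways.gmt"))
  write_gmt(list(signature = cohort_signature_genes(cohort)),
            file.path(dir, "signature.gmt"))
  invisible(dir)
}

#' Read a cohort fixture directory
#'
#' Round-trips the artifacts of [write_cohort()]; counts, metadata order and
#' truth tables are reproduced exactly.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `stemtraj_cohort` (config restored from the JSON echo).
#' @export
read_cohort <- function(dir) {
  need <- c("counts.mtx", "genes.tsv", "cells.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("fixture file missing: ", file.path(dir, f))
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  if (nrow(genes) != nrow(counts))
    stop("genes.tsv has ", nrow(genes), " rows but counts.mtx has ",
         nrow(counts), " rows")
  if (nrow(cells) != ncol(counts))
    stop("cells.tsv has ", nrow(cells), " rows but counts.mtx has ",
         ncol(counts), " columns")
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  truth <- NULL
  tc <- file.path(dir, "truth_cells.tsv")
  tg <- file.path(dir, "truth_gene_ratios.tsv")
  if (file.exists(tc) && file.exists(tg))
    truth <- list(cells = read_tsv(tc), gene_ratios = read_tsv(tg))
  config <- NULL
  cj <- file.path(dir, "config.json")
  if (file.exists(cj)) config <- jsonlite::read_json(cj, simplifyVector = TRUE)
  structure(list(counts = counts, cells = cells, genes = genes,
                 truth = truth, config = config),
            class = "stemtraj_cohort")
}
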