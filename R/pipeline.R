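#' Default pipeline configuration
#'
#' Stage toggles and parameters for [run_pipeline()]. A single global seed
#' deterministically derives per-stage seeds, so stages are reproducible in
#' isolation.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()] for the simulate stage (its seed is derived
#'   from the global seed when left at `NULL`).
#' @param input_dir Optional fixture directory to read instead of
#'   simulating (disables the simulate stage).
#' @param output_dir Optional directory for artifacts (TSV/JSON/Markdown);
#'   `NULL` keeps everything in memory.
#' @param stages Named logical toggles: simulate, preprocess, diffexpr,
#'   scoring, gsea, trajectory.
#' @param de_method `"pseudobulk"` (desk-scale default) or `"glmm"`.
#' @param de_clusters Clusters to run differential expression in.
#' @param n_components,n_neighbors,resolution Preprocessing parameters.
#' @param gsea_n_perm Permutations for the GSEA stage.
#' @param root,terminus_type Trajectory root type and terminus type.
#' @return Object of class `stemtraj_run_config`.
#' @export
run_config <- function(seed = 1L, sim = NULL, input_dir = NULL,
                       output_dir = NULL,
                       stages = c(simulate = TRUE, preprocess = TRUE,
                                  diffexpr = TRUE, scoring = TRUE,
                                  gsea = TRUE, trajectory = TRUE),
                       de_method = "pseudobulk", de_clusters = "Stem",
                       n_components = 30, n_neighbors = 15,
                       resolution = 1.5, gsea_n_perm = 1000,
                       root = "Stem", terminus_type = "EC") {
  defaults <- c(simulate = TRUE, preprocess = TRUE, diffexpr = TRUE,
                scoring = TRUE, gsea = TRUE, trajectory = TRUE)
  defaults[names(stages)] <- stages
  stages <- defaults
  if (!is.null(input_dir)) stages["simulate"] <- FALSE
  # dependency pre-flight: everything downstream needs preprocess
  downstream <- c("diffexpr", "scoring", "gsea", "trajectory")
  if (!stages["preprocess"] && any(stages[downstream]))
    stop("config error: stage(s) ",
         paste(downstream[stages[downstream]], collapse = ", "),
         " require the preprocess stage")
  if (stages["gsea"] && !stages["diffexpr"])
    stop("config error: gsea requires the diffexpr stage")
  if (!stages["simulate"] && is.null(input_dir))
    stop("config error: no simulate stage and no input_dir")
  if (is.null(sim))
    sim <- sim_config(seed = stage_seed(seed, "simulate"))
  structure(list(seed = as.integer(seed), sim = sim, input_dir = input_dir,
                 output_dir = output_dir, stages = stages,
                 de_method = de_method, de_clusters = de_clusters,
                 n_components = n_components, n_neighbors = n_neighbors,
                 resolution = resolution, gsea_n_perm = gsea_n_perm,
                 root = root, terminus_type = terminus_type),
            class = "stemtraj_run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = 12, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(as.data.frame(x))
  x
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated (or
#' fixture) cohort: QC + normalization + embedding + clustering + type
#' annotation; differential expression and DEG counting; pathway module
#' scores, signature ratio compartments, KS comparisons and bivariate
#' MANOVA; preranked GSEA; trajectory learning, main/side dichotomization,
#' compartment transition tests, emergence delays, branch-point score
#' profiles and the co-expression delay index. Fails fast with
#' stage-tagged errors.
#'
#' @param config A [run_config()] object.
#' @return Object of class `stemtraj_report`: per-stage results plus the
#'   six headline tables (`deg_counts`, `compartments`, `ks`,
#'   `transitions`, `delays`, `coexpression`), the config echo, its hash
#'   and the seed. When `config$output_dir` is set, a machine-readable
#'   `report.json` and a human `report.md` are written alongside TSV
#'   artifacts, every file stamped with the config hash + seed.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "stemtraj_run_config"))
  st <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
  }
  res <- list()

  cohort <- st("simulate", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else generate_cohort(config$sim)
  })
  res$n_cells_input <- ncol(cohort$counts)

  # ---- preprocess ----
  pp <- st("preprocess", {
    cohort_f <- qc_filter(cohort)
    norm <- normalize_counts(cohort_f$counts)
    emb <- embed_cells(norm, n_components = min(config$n_components,
                                                min(dim(norm)) - 1))
    cl <- cluster_cells(emb, n_neighbors = config$n_neighbors,
                        resolution = config$resolution,
                        seed = stage_seed(config$seed, "cluster"))
    markers <- cohort_marker_sets(cohort_f)
    # typing is stratified by condition within clusters: a cluster's cells
    # from different arms are annotated separately, so a maturation delay
    # cannot be voted away by the majority arm of a mixed cluster
    strata <- paste0(cl, "_", cohort_f$cells$condition)
    types <- annotate_types(norm, strata, markers,
                            conditions = cohort_f$cells$condition)
    list(cohort = cohort_f, norm = norm, emb = emb, clusters = cl,
         types = types, removed = attr(cohort_f, "removed"))
  })
  meta <- pp$cohort$cells
  types <- as.character(pp$types)
  res$qc_removed <- nrow(pp$removed)
  res$type_proportions <- attr(pp$types, "proportions")

  # ---- differential expression ----
  de <- st("diffexpr", {
    tabs <- lapply(config$de_clusters, function(cl_name) {
      scope <- types == cl_name
      if (!any(scope)) stop("de cluster ", cl_name, " has no cells")
      conds <- factor(meta$condition,
                      levels = pp$cohort$config$conditions %||%
                        unique(meta$condition))
      run_de(pp$cohort$counts, conds, meta$mouse, scope = scope,
             method = config$de_method, cluster = cl_name)
    })
    do.call(rbind, tabs)
  })
  res$de <- de
  res$deg_counts <- count_degs(de)

  # ---- scoring ----
  sc <- st("scoring", {
    pathways <- cohort_pathway_sets(pp$cohort)
    scores <- module_score_table(pp$norm, pathways,
                                 seed = stage_seed(config$seed, "score"))
    mouse_scores <- mean_score_by_mouse(scores, meta$mouse, meta$condition)
    stem <- types == "Stem"
    sig <- cohort_signature_genes(pp$cohort)
    sig <- intersect(sig, rownames(pp$norm))
    means <- mean_expression_by_condition(pp$norm, meta$mouse,
                                          meta$condition, scope = stem,
                                          genes = c("Lgr5", sig))
    ratios <- expression_ratio(means, reference = "Y")
    comps <- lapply(setdiff(colnames(means), "Y"), function(cn)
      compartment_summary(ratios[ratios$gene %in% sig, ], contrast = cn))
    names(comps) <- setdiff(colnames(means), "Y")
    # cumulative-distribution comparisons of the ratio columns
    r_of <- function(cn) ratios$ratio[ratios$contrast == cn &
                                        ratios$gene %in% sig]
    ks <- list(
      `O_vs_O_met` = ks_two_sample(r_of("O"), r_of("O_met")),
      `O_vs_O_rap` = ks_two_sample(r_of("O"), r_of("O_rap")),
      `O_met_vs_O_rap` = ks_two_sample(r_of("O_met"), r_of("O_rap"))
    )
    biv <- bivariate_coordination(
      mouse_scores$mouse, pathways = c("Wnt", "cell_cycle"))
    list(scores = scores, mouse_scores = mouse_scores, means = means,
         ratios = ratios, compartments = comps, ks = ks, bivariate = biv)
  })
  res$compartments <- lapply(sc$compartments, function(x)
    c(x$percent, below_1 = x$fraction_below_1))
  res$ks <- lapply(sc$ks, function(t) c(D = t$statistic, p = t$p))
  res$manova_p <- sc$bivariate$test$p

  # ---- gsea ----
  gs <- st("gsea", {
    de_stem <- de[de$cluster == config$de_clusters[1] &
                    de$contrast == "O:Y" & de$converged == "ok", ]
    ranked <- rank_genes(de_stem)
    gsea_permutation(ranked, cohort_pathway_sets(pp$cohort),
                     n_perm = config$gsea_n_perm,
                     seed = stage_seed(config$seed, "gsea"))
  })
  res$gsea <- gs

  # ---- trajectory ----
  tr <- st("trajectory", {
    traj <- learn_trajectory(pp$emb, types, root = config$root)
    term_label <- config$terminus_type
    if (!term_label %in% rownames(traj$vertices))
      stop("terminus type ", term_label, " not present among clusters")
    sel <- select_and_dichotomize(traj, term_label)
    pt <- stats::setNames(traj$cells$pseudotime, traj$cells$cell_id)
    main <- sel$flag == "main"
    part <- pseudotime_compartments(pt, main = main)
    keep <- sel$flag != "excluded"
    trans <- compartment_transition_test(
      types[keep], pt[keep], part, meta$condition[keep],
      seed = stage_seed(config$seed, "transition"))
    delays <- emergence_delay(types, pt, main, meta$condition,
                              reference = "Y")
    prof <- lapply(names(sc$scores), function(pw)
      branchpoint_module_profile(
        stats::setNames(sc$scores[[pw]], rownames(sc$scores)),
        traj, sel, meta$condition))
    names(prof) <- names(sc$scores)
    coex <- coexpression_index(pp$norm, "Uhrf1", "Ccnb1",
                               scope = which(keep),
                               conditions = meta$condition)
    list(traj = traj, selection = sel, partition = part,
         transitions = trans, delays = delays, profiles = prof,
         coexpression = coex)
  })
  res$transitions <- lapply(tr$transitions, function(t)
    c(statistic = t$statistic, p = t$p))
  res$delays <- tr$delays
  res$coexpression <- tr$coexpression

  report <- structure(list(
    seed = config$seed,
    config_hash = config_hash(config),
    headline = list(
      deg_counts = res$deg_counts,
      compartments = res$compartments,
      ks = res$ks,
      transitions = res$transitions,
      delays = res$delays,
      coexpression = res$coexpression
    ),
    manova_p = res$manova_p,
    gsea = res$gsea,
    details = list(preprocess = pp, scoring = sc, trajectory = tr, de = de),
    n_cells_input = res$n_cells_input,
    qc_removed = res$qc_removed
  ), class = "stemtraj_report")

  if (!is.null(config$output_dir))
    write_report(report, config)
  report
}

#' @export
print.stemtraj_report <- function(x, ...) {
  cat("stemtraj pipeline report (seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("cells in:", x$n_cells_input, "| removed by QC:", x$qc_removed, "\n")
  cat("\nDEG counts:\n"); print(x$headline$deg_counts)
  cat("\nSignature ratio compartments (%):\n")
  print(do.call(rbind, x$headline$compartments))
  cat("\nTransition tests:\n")
  print(do.call(rbind, x$headline$transitions))
  invisible(x)
}

report_json <- function(report) {
  slim <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    n_cells_input = report$n_cells_input,
    qc_removed = report$qc_removed,
    deg_counts = report$headline$deg_counts,
    compartments = report$headline$compartments,
    ks = report$headline$ks,
    manova_p = report$manova_p,
    gsea = report$gsea,
    transitions = report$headline$transitions,
    delays = report$headline$delays,
    coexpression = report$headline$coexpression
  )
  jsonlite::toJSON(slim, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                   force = TRUE)
}

write_report <- function(report, config) {
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- paste0("# config_hash=", report$config_hash,
                  " seed=", report$seed)
  writeLines(report_json(report), file.path(dir, "report.json"))
  md <- c(paste0("<!-- config_hash=", report$config_hash,
                 " seed=", report$seed, " -->"),
          "# Pipeline report", "",
          paste0("- cells in: ", report$n_cells_input),
          paste0("- removed by QC: ", report$qc_removed),
          "", "## Signature compartments (%)", "```",
          utils::capture.output(print(do.call(rbind,
            report$headline$compartments))), "```",
          "", "## DEG counts", "```",
          utils::capture.output(print(report$headline$deg_counts)), "```",
          "", "## Transition tests", "```",
          utils::capture.output(print(do.call(rbind,
            report$headline$transitions))), "```",
          "", "## Emergence delays", "```",
          utils::capture.output(print(report$headline$delays)), "```",
          "", "## Co-expression index", "```",
          utils::capture.output(print(report$headline$coexpression)), "```")
  writeLines(md, file.path(dir, "report.md"))
  for (nm in c("delays", "coexpression", "deg_counts")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(stamp, f)
    suppressWarnings(utils::write.table(report$headline[[nm]], f,
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  invisible(dir)
}

#' Validate fixture inputs
#'
#' Checks Matrix Market / TSV / GMT conformance, dimension agreement and
#' the condition vocabulary, returning findings instead of erroring.
#'
#' @param dir Fixture directory (as written by [write_cohort()]).
#' @param conditions Expected condition vocabulary.
#' @return data.frame of findings (`file`, `line`, `message`); zero rows
#'   means the inputs validate.
#' @export
validate_inputs <- function(dir,
                            conditions = c("Y", "O", "O_met", "O_rap")) {
  findings <- list()
  note <- function(file, message, line = NA_integer_)
    findings[[length(findings) + 1]] <<-
      data.frame(file = file, line = line, message = message,
                 stringsAsFactors = FALSE)
  mtx <- file.path(dir, "counts.mtx")
  dims <- NULL
  if (!file.exists(mtx)) note("counts.mtx", "missing file") else {
    hdr <- readLines(mtx, n = 1)
    if (!grepl("^%%MatrixMarket\\s+matrix", hdr))
      note("counts.mtx", "malformed Matrix Market header", 1L)
    else dims <- tryCatch(dim(Matrix::readMM(mtx)), error = function(e) {
      note("counts.mtx", paste("unreadable:", conditionMessage(e)))
      NULL
    })
  }
  for (f in c("genes.tsv", "cells.tsv")) {
    p <- file.path(dir, f)
    if (!file.exists(p)) { note(f, "missing file"); next }
    tab <- read_tsv(p)
    if (!is.null(dims)) {
      expected <- if (f == "genes.tsv") dims[1] else dims[2]
      if (nrow(tab) != expected)
        note(f, sprintf("%d rows but counts.mtx implies %d", nrow(tab),
                        expected))
    }
    if (f == "cells.tsv" && "condition" %in% colnames(tab)) {
      bad <- setdiff(unique(tab$condition), conditions)
      if (length(bad))
        note(f, paste0("unknown condition label(s): ",
                       paste(bad, collapse = ", "), "; expected one of ",
                       paste(conditions, collapse = ", ")))
    }
  }
  for (f in list.files(dir, pattern = "\\.gmt$")) {
    lines <- readLines(file.path(dir, f))
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    for (i in which(nf < 3))
      note(f, "GMT line has fewer than 3 tab-separated fields", i)
  }
  if (length(findings) == 0)
    return(data.frame(file = character(0), line = integer(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
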