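# toy geometry: clusters of points around specified centers
toy_embedding <- function(centers, n_per = 60, sd = 0.05, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), ncol = ncol(centers)),
          2, centers[k, ], "+")))
  rownames(coords) <- sprintf("c%04d", seq_len(nrow(coords)))
  list(coords = coords,
       labels = rep(rownames(centers), each = n_per))
}

test_that("collinear clusters give a path graph with monotone pseudotime", {
  centers <- matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE,
                    dimnames = list(c("A", "B", "C"), NULL))
  toy <- toy_embedding(centers)
  traj <- learn_trajectory(toy$coords, toy$labels, root = "A")
  expect_equal(nrow(traj$edges), 2)  # K - 1 edges
  mean_pt <- tapply(traj$cells$pseudotime, toy$labels, mean)
  expect_true(mean_pt["A"] < mean_pt["B"] && mean_pt["B"] < mean_pt["C"])
  # a cell exactly at the root medoid has pseudotime 0
  expect_equal(min(traj$cells$pseudotime[toy$labels == "A"]), 0,
               tolerance = 1e-9)
  expect_error(learn_trajectory(toy$coords, toy$labels, root = "Z"),
               "root")
})

test_that("pseudotime is invariant to rigid rotation of the embedding", {
  centers <- matrix(c(0, 0, 1, 0.2, 2, 0, 1, 1.5), ncol = 2, byrow = TRUE,
                    dimnames = list(c("A", "B", "C", "D"), NULL))
  toy <- toy_embedding(centers, seed = 3)
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  t1 <- learn_trajectory(toy$coords, toy$labels, root = "A")
  t2 <- learn_trajectory(toy$coords %*% rot, toy$labels, root = "A")
  expect_equal(t1$cells$pseudotime, t2$cells$pseudotime, tolerance = 1e-9)
})

test_that("dichotomization separates main-path, side and beyond-terminus
           cells on a constructed topology", {
  # path A-B-C with side branch D off B and continuation E past C
  centers <- matrix(c(0, 0, 1, 0, 2, 0, 1, 1, 3, 0), ncol = 2,
                    byrow = TRUE,
                    dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  toy <- toy_embedding(centers, n_per = 100, seed = 5)
  traj <- learn_trajectory(toy$coords, toy$labels, root = "A")
  sel <- select_and_dichotomize(traj, "C")
  expect_identical(sel$path, c("A", "B", "C"))
  flag <- as.character(sel$flag)
  expect_true(all(flag[toy$labels == "D"] == "side"))
  expect_true(all(flag[toy$labels == "E"] == "excluded"))
  expect_true(all(flag[toy$labels == "A"] == "main"))
  # B cells fall on either the path or the branch edge, never beyond
  expect_true(all(flag[toy$labels == "B"] != "excluded"))
  expect_gte(mean(flag[toy$labels == "B"] == "main"), 0.6)
  # terminus-cluster cells sit on the path or just beyond it, never on a
  # side branch
  expect_true(all(flag[toy$labels == "C"] != "side"))
  expect_error(select_and_dichotomize(traj, "Z"), "terminus")
})

test_that("a pure path has no side cells and terminus = root degenerates", {
  centers <- matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE,
                    dimnames = list(c("A", "B", "C"), NULL))
  toy <- toy_embedding(centers, seed = 7)
  traj <- learn_trajectory(toy$coords, toy$labels, root = "A")
  sel <- select_and_dichotomize(traj, "C")
  expect_true(all(sel$flag != "side"))
  root_only <- select_and_dichotomize(traj, "A")
  expect_true(all(as.character(root_only$flag[toy$labels == "A"]) == "main"))
  expect_true(all(as.character(root_only$flag[toy$labels != "A"]) ==
                    "excluded"))
})

test_that("transition tests return unity p for identical distributions and
           validate compartments", {
  types <- rep(rep(c("Stem", "R"), each = 30), 4)
  conds <- rep(c("Y", "O", "O_met", "O_rap"), each = 60)
  pt <- rep(c(rep(0.2, 20), rep(0.5, 20), rep(0.8, 20)), 4)
  part <- pseudotime_compartments(pt, n = 3)
  out <- compartment_transition_test(types, pt, part, conds, n_sim = 500,
                                     seed = 3)
  expect_equal(out$joint$statistic, 0)
  expect_equal(out$joint$p, 1)
  expect_named(out, c("i", "ii", "iii", "joint"))
})

test_that("emergence delays vanish under the null and track the generator
           shift on ground truth", {
  cfg0 <- sim_config(n_cells_per_mouse = 1000, n_genes = 450,
                     n_signature_genes = 20, seed = 61L,
                     delay_per_condition = c(Y = 0, O = 0, O_met = 0,
                                             O_rap = 0))
  co0 <- generate_cohort(cfg0)
  tc <- co0$truth$cells
  dl0 <- suppressWarnings(
    emergence_delay(tc$type, tc$s, tc$branch == "main",
                    co0$cells$condition))
  post <- dl0$type != "Stem" & dl0$condition != "Y"
  expect_lt(max(abs(dl0$delay[post]), na.rm = TRUE), 0.02)

  cfg1 <- sim_config(n_cells_per_mouse = 1000, n_genes = 450,
                     n_signature_genes = 20, seed = 62L,
                     delay_per_condition = c(Y = 0, O = 0.1, O_met = 0,
                                             O_rap = 0.05))
  co1 <- generate_cohort(cfg1)
  tc1 <- co1$truth$cells
  dl1 <- suppressWarnings(
    emergence_delay(tc1$type, tc1$s, tc1$branch == "main",
                    co1$cells$condition))
  o_rows <- dl1$condition == "O" & dl1$type %in% c("R", "R-Div", "Div1",
                                                   "Div2")
  expect_true(all(dl1$delay[o_rows] > 0.05 & dl1$delay[o_rows] < 0.15))
  # fully reversed arm shows no delay
  met_rows <- dl1$condition == "O_met" & dl1$type != "Stem"
  expect_lt(max(abs(dl1$delay[met_rows]), na.rm = TRUE), 0.03)
})

test_that("the estimated pipeline recovers a positive aged delay", {
  cfg <- sim_config(n_cells_per_mouse = 700, n_genes = 1200,
                    n_signature_genes = 100, seed = 7L,
                    delay_per_condition = c(Y = 0, O = 0.1, O_met = 0.02,
                                            O_rap = 0.05))
  co <- generate_cohort(cfg)
  cof <- qc_filter(co)
  norm <- normalize_counts(cof$counts)
  emb <- embed_cells(norm, n_components = 20)
  cl <- cluster_cells(emb, resolution = 1.5, seed = 3)
  cond <- cof$cells$condition
  ty <- as.character(annotate_types(norm, paste0(cl, "_", cond),
                                    cohort_marker_sets(cof)))
  traj <- learn_trajectory(emb, ty, root = "Stem")
  sel <- select_and_dichotomize(traj, "EC")
  pt <- traj$cells$pseudotime
  # pseudotime orders the true maturation coordinate
  main <- sel$flag == "main"
  expect_gte(cor(pt[main], cof$truth$cells$s[main], method = "spearman"),
             0.8)
  dl <- suppressWarnings(emergence_delay(ty, pt, main, cond))
  post <- c("R", "R-Div", "Div1", "Div2", "EC")
  d_o <- mean(dl$delay[dl$condition == "O" & dl$type %in% post],
              na.rm = TRUE)
  d_met <- mean(dl$delay[dl$condition == "O_met" & dl$type %in% post],
                na.rm = TRUE)
  # simulation-calibrated recovery band for delta = 0.1 at this scale
  expect_gt(d_o, 0.03)
  expect_lt(d_o, 0.30)
  expect_gt(d_o, d_met)
})

test_that("branch-point profiles are constant for constant scores, order
           invariant, and localize the cell-cycle peak", {
  co <- tiny_cohort()
  cof <- qc_filter(co)
  norm <- tiny_norm()
  emb <- embed_cells(norm, n_components = 15, n_hvg = 400)
  cl <- cluster_cells(emb, resolution = 1.2, seed = 3)
  ty <- as.character(annotate_types(norm, cl, cohort_marker_sets(cof)))
  # the fixed-seed cohort always yields both ends of the continuum
  expect_true(all(c("Stem", "EC") %in% ty))
  traj <- learn_trajectory(emb, ty, root = "Stem")
  sel <- select_and_dichotomize(traj, "EC")
  conds <- cof$cells$condition
  const <- stats::setNames(rep(0.4, ncol(norm)), colnames(norm))
  prof <- branchpoint_module_profile(const, traj, sel, conds)
  vals <- unlist(prof[, !(colnames(prof) %in% c("segment", "order"))])
  expect_true(all(abs(vals[!is.na(vals)] - 0.4) < 1e-12))
  # permuting cell order leaves the profile unchanged
  perm <- sample(ncol(norm))
  traj2 <- traj; traj2$cells <- traj$cells[perm, ]
  prof2 <- branchpoint_module_profile(const[perm], traj2, sel, conds[perm])
  expect_equal(prof2, prof)
  # the cell-cycle program peaks mid-trajectory
  cc <- module_score(norm, cohort_pathway_sets(co)$cell_cycle, seed = 5)
  prof_cc <- branchpoint_module_profile(cc, traj, sel, conds)
  y_prof <- prof_cc$Y[!is.na(prof_cc$Y)]
  peak <- which.max(y_prof)
  expect_gt(peak, 1)
  expect_lt(peak, length(y_prof))
})

test_that("co-expression index follows its closed forms and a brute-force
           oracle", {
  # disjoint positive sets
  m <- matrix(0, nrow = 2, ncol = 50,
              dimnames = list(c("e", "l"), paste0("c", 1:50)))
  m["e", 1:25] <- rexp(25) + 1
  m["l", 26:50] <- rexp(25) + 1
  sm <- Matrix::Matrix(m, sparse = TRUE)
  r <- coexpression_index(sm, "e", "l", scope = 1:50,
                          positivity_quantile = 0.5)
  expect_equal(r$index, 0)
  # identical positive sets give 1/2
  m2 <- m; m2["l", ] <- m2["e", ]
  m2["l", 26:50] <- 0; m2["e", 26:50] <- 0
  m2["e", 1:25] <- m2["l", 1:25] <- seq(1, 2, length.out = 25)
  r2 <- coexpression_index(Matrix::Matrix(m2, sparse = TRUE), "e", "l",
                           scope = 1:50, positivity_quantile = 0.9)
  expect_equal(r2$index, 0.5)
  # random toy against explicit enumeration
  set.seed(13)
  m3 <- matrix(rexp(100), nrow = 2,
               dimnames = list(c("e", "l"), paste0("c", 1:50)))
  q <- 0.8
  th_e <- quantile(m3["e", ], q, names = FALSE)
  th_l <- quantile(m3["l", ], q, names = FALSE)
  pos_e <- m3["e", ] > th_e; pos_l <- m3["l", ] > th_l
  expected <- sum(pos_e & pos_l) / (sum(pos_e) + sum(pos_l))
  r3 <- coexpression_index(Matrix::Matrix(m3, sparse = TRUE), "e", "l",
                           scope = 1:50, positivity_quantile = q)
  expect_equal(r3$index, expected)
  # zero-variance gene is rejected
  m4 <- m3; m4["e", ] <- 1
  expect_error(coexpression_index(Matrix::Matrix(m4, sparse = TRUE),
                                  "e", "l", scope = 1:50),
               "zero-variance")
})

test_that("the co-expression index rises with the maturation delay", {
  idx <- vapply(c(0, 0.1, 0.2), function(d) {
    cfg <- sim_config(n_cells_per_mouse = 500, n_genes = 800,
                      n_signature_genes = 60, seed = 4L,
                      delay_per_condition = c(Y = 0, O = d, O_met = 0,
                                              O_rap = 0))
    co <- generate_cohort(cfg)
    norm <- normalize_counts(co$counts)
    coexpression_index(norm, "Uhrf1", "Ccnb1",
                       scope = co$cells$condition == "O",
                       positivity_quantile = 0.9)$index
  }, numeric(1))
  expect_true(all(diff(idx) >= 0))
  expect_gt(idx[3], idx[1])
})
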