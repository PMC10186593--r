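test_that("a gene set drawn from one expression bin scores near zero", {
  norm <- tiny_norm()
  # background genes share a common expression law; pick a random subset
  bg <- rownames(norm)[startsWith(rownames(norm), "Bg")]
  set.seed(4)
  gs <- sample(bg, 30)
  sc <- module_score(norm, gs, seed = 9)
  expect_lt(abs(mean(sc)), 0.02)
})

test_that("module scores shift exactly with an additive construction", {
  set.seed(2)
  n_cells <- 40
  v <- matrix(rexp(10 * n_cells), nrow = 10)
  cc <- 0.7
  m <- rbind(v, v[1:4, ] + cc)
  dimnames(m) <- list(c(paste0("bgg", 1:10), paste0("set", 1:4)),
                      paste0("c", seq_len(n_cells)))
  # single expression bin: controls are the non-set genes
  sc <- module_score(Matrix::Matrix(m, sparse = TRUE),
                     paste0("set", 1:4), n_bins = 1, n_ctrl = 50, seed = 3)
  expect_equal(length(sc), n_cells)
  # the exact additive case: make all background genes identical per cell
  v2 <- matrix(rep(rexp(n_cells), each = 10), nrow = 10)
  m2 <- rbind(v2, v2[1:4, ] + cc)
  dimnames(m2) <- dimnames(m)
  sc2 <- module_score(Matrix::Matrix(m2, sparse = TRUE),
                      paste0("set", 1:4), n_bins = 1, n_ctrl = 50, seed = 3)
  expect_equal(unname(sc2), rep(cc, n_cells), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("module scoring is reproducible under a fixed seed and is
           translation covariant", {
  norm <- tiny_norm()
  gs <- cohort_pathway_sets(tiny_cohort())$Wnt
  s1 <- module_score(norm, gs, seed = 42)
  s2 <- module_score(norm, gs, seed = 42)
  expect_identical(s1, s2)
  # adding c to the set genes raises every score by exactly c when the
  # bin structure is held fixed (single bin)
  m <- as.matrix(norm[1:30, ])
  sA <- module_score(Matrix::Matrix(m, sparse = TRUE), rownames(m)[1:5],
                     n_bins = 1, seed = 7)
  m2 <- m; m2[1:5, ] <- m2[1:5, ] + 0.3
  sB <- module_score(Matrix::Matrix(m2, sparse = TRUE), rownames(m)[1:5],
                     n_bins = 1, seed = 7)
  expect_equal(unname(sB - sA), rep(0.3, ncol(m)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(module_score(norm, c("nope1", "nope2")), "no overlap")
  expect_error(module_score(norm[1:10, ], rownames(norm)[1], n_bins = 50),
               "n_bins")
})

test_that("mouse and condition score means follow the averaging rules", {
  sc <- c(0.1, 0.3, 0.2, 0.4, 0.0, 0.2)
  mouse <- c("m1", "m1", "m2", "m2", "m3", "m3")
  cond <- c("Y", "Y", "Y", "Y", "O", "O")
  out <- mean_score_by_mouse(sc, mouse, cond)
  expect_equal(out$mouse$score[out$mouse$mouse == "m1"], 0.2)
  expect_equal(out$condition$score[out$condition$condition == "Y"],
               mean(c(0.2, 0.3)))
  # order invariance
  perm <- c(3, 1, 5, 2, 6, 4)
  out2 <- mean_score_by_mouse(sc[perm], mouse[perm], cond[perm])
  expect_equal(out2$mouse[order(out2$mouse$mouse), ],
               out$mouse[order(out$mouse$mouse), ], ignore_attr = TRUE)
})

test_that("condition means average per mouse first and skip empty mice", {
  m <- matrix(0, nrow = 1, ncol = 9,
              dimnames = list("g", paste0("c", 1:9)))
  m[1, ] <- c(1, 1, 1, 0, 0, 0, 2, 2, 2)  # normalized values
  norm <- Matrix::Matrix(log1p(expm1(m)), sparse = TRUE)  # identity
  mouse <- rep(c("m1", "m2", "m3"), each = 3)
  cond <- rep("Y", 9)
  mns <- mean_expression_by_condition(norm, mouse, cond,
                                      scope = rep(TRUE, 9), genes = "g")
  # linear-scale means per mouse: expm1 of the stored values
  mm <- expm1(c(1, 0, 2))
  expect_equal(unname(mns["g", "Y"]), mean(mm))
  # a mouse with no cells in scope is skipped with a warning
  expect_warning(
    mean_expression_by_condition(norm, mouse, cond, scope = 1:6,
                                 genes = "g"), "skipped")
  # constant gene: every condition mean equals the constant (linear scale)
  m2 <- Matrix::Matrix(matrix(log1p(5), 1, 9,
                              dimnames = dimnames(m)), sparse = TRUE)
  mns2 <- mean_expression_by_condition(m2, mouse, cond,
                                       scope = rep(TRUE, 9), genes = "g")
  expect_equal(unname(mns2["g", "Y"]), 5)
})

test_that("expression ratios follow the stated bin conventions", {
  means <- matrix(c(1.0, 0.5), ncol = 2,
                  dimnames = list("g1", c("Y", "O")))
  rt <- expression_ratio(means, reference = "Y")
  expect_equal(rt$ratio, 0.5)
  expect_equal(rt$compartment, 1L)  # (0,0.5] is closed on the right

  means2 <- matrix(c(0, 1, 0.3, 1.1), ncol = 2,
                   dimnames = list(c("gz", "g2"), c("Y", "O")))
  rt2 <- expression_ratio(means2, reference = "Y")
  expect_identical(attr(rt2, "excluded"), "gz")
  expect_false("gz" %in% rt2$gene)

  means3 <- matrix(c(rep(1, 6), 0.4, 0.6, 0.9, 1.1, 1.3, 2.0), ncol = 2,
                   dimnames = list(paste0("g", 1:6), c("Y", "O")))
  cs <- compartment_summary(expression_ratio(means3, reference = "Y"))
  expect_equal(unname(cs$percent), rep(100 / 6, 6), tolerance = 1e-9)
  expect_equal(sum(cs$percent), 100, tolerance = 1e-9)
})

test_that("a ratio of exactly one lands in compartment three and the
           below-one fraction sums compartments 1-3", {
  means <- matrix(c(rep(1, 3), rep(1, 3)), ncol = 2,
                  dimnames = list(paste0("g", 1:3), c("Y", "O")))
  cs <- compartment_summary(expression_ratio(means, reference = "Y"))
  expect_equal(unname(cs$percent[3]), 100)
  # the printed compartment distribution implies 71% repressed
  ratios <- data.frame(
    gene = paste0("g", 1:100), contrast = "O",
    ratio = rep(c(0.3, 0.6, 0.9, 1.1, 1.3, 2), c(12, 38, 21, 14, 10, 5)))
  ratios$compartment <- as.integer(cut(ratios$ratio, compartment_edges()))
  cs2 <- compartment_summary(ratios)
  expect_equal(unname(cs2$percent[1:2]), c(12, 38))
  expect_equal(cs2$fraction_below_1, 71)
})

test_that("bivariate coordination flags degeneracy, detects separation and
           has chi-squared-calibrated ellipses", {
  # identical mice: degenerate, p = 1 by convention
  mm <- data.frame(condition = rep(c("Y", "O"), each = 3),
                   A = rep(1, 6), B = rep(2, 6))
  out <- bivariate_coordination(mm, c("A", "B"))
  expect_true(out$test$degenerate)
  expect_equal(out$test$p, 1)

  # 10-SD separated conditions: significant in nearly all draws
  set.seed(6)
  hits <- replicate(30, {
    mm <- data.frame(condition = rep(c("Y", "O"), each = 3),
                     A = rnorm(6, rep(c(0, 10), each = 3)),
                     B = rnorm(6, rep(c(0, 10), each = 3)))
    bivariate_coordination(mm, c("A", "B"))$test$p < 0.05
  })
  expect_gte(mean(hits), 0.9)

  # the 95% ellipse of a unit Gaussian has semi-axes sqrt(qchisq(.95, 2))
  set.seed(7)
  big <- data.frame(condition = rep("Y", 4000),
                    A = rnorm(4000), B = rnorm(4000))
  big2 <- rbind(big, data.frame(condition = rep("O", 4000),
                                A = rnorm(4000, 5), B = rnorm(4000, 5)))
  out <- bivariate_coordination(big2, c("A", "B"))
  ax <- out$ellipses$Y$semi_axes
  expect_equal(unname(ax), rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
})
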