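# deterministic two-type fixture used across engine tests
engine_fixture <- function() {
  types <- c("A", "B")
  genes <- c("L1", "R1", "L2A", "L2B", "R2A", "R2B")
  me <- matrix(c(2, 3, 4, 1, 9, 1,
                 1, 5, 2, 2, 4, 4), 2, byrow = TRUE,
               dimnames = list(types, genes))
  toy_summary(me)
}

lr_db2 <- function() {
  lr_database(list(lr_pair("L1", "R1", "s"),
                   lr_pair("L2A&L2B", "R2A&R2B", "s")))
}

test_that("complex_expression collapses subunits by mode", {
  s <- engine_fixture()
  cx <- gene_complex(c("L2A", "L2B"))
  expect_equal(complex_expression(s, cx, "A", "geometric"), 2)  # sqrt(4*1)
  mn <- toy_summary(matrix(c(0.5, 0.2), 1,
                           dimnames = list("A", c("X", "Y"))))
  expect_equal(complex_expression(mn, gene_complex(c("X", "Y")), "A",
                                  "minimum"), 0.2)
  one <- toy_summary(matrix(3.7, 1, dimnames = list("A", "Z")))
  expect_equal(complex_expression(one, gene_complex("Z"), "A", "geometric"),
               3.7)
  expect_equal(complex_expression(one, gene_complex("Z"), "A", "minimum"),
               3.7)
  expect_error(complex_expression(s, gene_complex("NOPE"), "A"), "NOPE")
  expect_error(complex_expression(s, cx, "C"), "unknown cell type")
})

test_that("scoring kernels implement product / average-of-min rules", {
  s <- engine_fixture()
  db <- lr_db2()
  cc <- score_cellchat_like(s, db)
  expect_equal(dim(cc), c(2, 2, 2))
  # single-subunit pair: ligand mean x receptor mean
  expect_equal(cc["A", "B", "L1_R1"], 2 * 5)
  expect_equal(cc["B", "A", "L1_R1"], 1 * 3)
  # complex pair: geometric means sqrt(4*1)=2 (A), sqrt(9*1)=3 (A)
  expect_equal(cc["A", "A", "L2A&L2B_R2A&R2B"], 2 * 3)

  pdb <- score_cellphonedb_like(s, db)
  expect_equal(pdb["A", "B", "L1_R1"], 0.5 * (2 + 5))
  # min-subunit: ligand min(4,1)=1 in A, receptor min(4,4)=4 in B
  expect_equal(pdb["A", "B", "L2A&L2B_R2A&R2B"], 0.5 * (1 + 4))
  # receptor complex (0.5, 0.2) with ligand 0.8: 0.5 * (0.8 + 0.2)
  s2 <- toy_summary(matrix(c(0.8, 0.5, 0.2), 1,
                           dimnames = list("A", c("L", "RA", "RB"))))
  pdb2 <- score_cellphonedb_like(s2, lr_database(list(
    lr_pair("L", "RA&RB", "s"))))
  expect_equal(pdb2["A", "A", "L_RA&RB"], 0.5)

  # zero ligand mean is absorbing for the product score
  s0 <- toy_summary(matrix(c(0, 2, 1, 3), 2,
                           dimnames = list(c("A", "B"), c("L", "R"))))
  cc0 <- score_cellchat_like(s0, lr_database(list(lr_pair("L", "R", "s"))))
  expect_equal(unname(cc0["A", , "L_R"]), c(0, 0))
})

test_that("celltalker mask follows the expressed-fraction threshold", {
  fr <- matrix(c(0.5, 0.5, 0.05, 0.05), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("L", "R")))
  me <- matrix(1, 2, 2, dimnames = dimnames(fr))
  s <- toy_summary(me, expr_fraction = fr)
  db <- lr_database(list(lr_pair("L", "R", "s")))
  ct <- score_celltalker_like(s, db, min_fraction = 0.1)
  # enumerate the 4 sender-receiver combinations: only (A,A) clears 0.1
  expect_equal(ct$tested[, , "L_R"],
               matrix(c(TRUE, FALSE, FALSE, FALSE), 2, byrow = TRUE,
                      dimnames = list(sender = c("A", "B"),
                                      receiver = c("A", "B"))))
  expect_true(all(score_celltalker_like(s, db, min_fraction = 0)$tested))
  # celltalker scores equal the cellchat product where tested
  expect_equal(ct$scores, score_cellchat_like(s, db))
})

test_that("permutation p-values obey degenerate and extreme cases", {
  # constant matrix: every permuted score equals the observed -> p = 1
  Xc <- as_log_stage(matrix(1, 4, 12,
                            dimnames = list(c("L", "R", "X", "Y"),
                                            sprintf("c%d", 1:12))))
  ann <- cell_annotation(sprintf("c%d", 1:12), rep(c("A", "B"), 6))
  db <- lr_database(list(lr_pair("L", "R", "s")))
  p <- permutation_pvalues(Xc, ann, db, "cellchat_like", n_perm = 25,
                           seed = 3)
  expect_true(all(p == 1))

  # strong separation: type A expresses both genes, B none -> the (A,A)
  # observed product beats every label shuffle, p = 1/(n_perm+1)
  Xs <- as_log_stage(cbind(matrix(5, 4, 10), matrix(0, 4, 10)))
  dimnames(Xs) <- list(c("L", "R", "X", "Y"), sprintf("c%d", 1:20))
  attr(Xs, "stage") <- "log"
  ann2 <- cell_annotation(sprintf("c%d", 1:20), rep(c("A", "B"), each = 10))
  p2 <- permutation_pvalues(Xs, ann2, db, "cellchat_like", n_perm = 60,
                            seed = 5)
  expect_equal(unname(p2["A", "A", "L_R"]), 1 / 61)
  expect_error(permutation_pvalues(Xs, ann2, db, "cellchat_like",
                                   n_perm = 0, seed = 1), "n_perm")
})

test_that("run_engine is deterministic, shaped, and add-one discretised", {
  set.seed(42)
  genes <- sprintf("G%d", 1:8)
  X <- as_log_stage(matrix(rexp(8 * 30), 8, 30,
                           dimnames = list(genes, sprintf("c%d", 1:30))))
  ann <- cell_annotation(sprintf("c%d", 1:30),
                         rep(c("A", "B", "C"), each = 10))
  db <- lr_database(list(lr_pair("G1", "G2", "s"),
                         lr_pair("G3&G4", "G5", "s")))
  r1 <- run_engine("cellchat_like", X, ann, db, n_perm = 40, seed = 9)
  r2 <- run_engine("cellchat_like", X, ann, db, n_perm = 40, seed = 9)
  expect_identical(r1, r2)
  expect_equal(dim(r1$scores), c(3, 3, 2))
  # p-values are multiples of 1/(n_perm+1), in [1/(n_perm+1), 1]
  mult <- r1$pvalues * 41
  expect_equal(mult, round(mult))
  expect_true(all(r1$pvalues >= 1 / 41 & r1$pvalues <= 1))
  expect_error(run_engine("nope", X, ann, db), "unknown engine")

  # min_fraction 1 with a zero for the ligand gene in every type -> no
  # sender clears the threshold, all-untested mask for that pair
  X0 <- X; X0["G1", c("c1", "c11", "c21")] <- 0
  attr(X0, "stage") <- "log"
  rt <- run_engine("celltalker_like", X0, ann, db, n_perm = 5, seed = 1,
                   min_fraction = 1)
  expect_false(any(rt$tested[, , "G1_G2"]))
  expect_true(all(is.na(rt$pvalues[, , "G1_G2"])))
})

test_that("scores are invariant to cell ordering and monotone in expression", {
  set.seed(1)
  X <- as_log_stage(matrix(rexp(6 * 20), 6, 20,
                           dimnames = list(sprintf("G%d", 1:6),
                                           sprintf("c%d", 1:20))))
  ann <- cell_annotation(sprintf("c%d", 1:20), rep(c("A", "B"), 10))
  db <- lr_database(list(lr_pair("G1", "G2", "s"),
                         lr_pair("G3&G4", "G5&G6", "s")))
  perm <- sample(ncol(X))
  Xp <- X[, perm]
  attr(Xp, "stage") <- "log"
  s1 <- summarize_by_type(X, ann)
  s2 <- summarize_by_type(Xp, ann)
  expect_equal(score_cellchat_like(s1, db), score_cellchat_like(s2, db))
  expect_equal(score_cellphonedb_like(s1, db),
               score_cellphonedb_like(s2, db))

  # raising one subunit's mean never lowers cellchat/cellphonedb scores
  bumped <- s1
  bumped$mean_expr["A", "G3"] <- bumped$mean_expr["A", "G3"] + 1
  expect_true(all(score_cellchat_like(bumped, db) >=
                    score_cellchat_like(s1, db)))
  expect_true(all(score_cellphonedb_like(bumped, db) >=
                    score_cellphonedb_like(s1, db)))

  # single-subunit fixtures: geometric == minimum, engines differ only in
  # the combination rule
  db1 <- lr_database(list(lr_pair("G1", "G2", "s")))
  L <- s1$mean_expr[, "G1"]; R <- s1$mean_expr[, "G2"]
  expect_equal(score_cellchat_like(s1, db1)[, , 1], outer(L, R),
               ignore_attr = TRUE)
  expect_equal(score_cellphonedb_like(s1, db1)[, , 1],
               0.5 * outer(L, R, "+"), ignore_attr = TRUE)
})

test_that("per-engine p-values are calibrated on exchangeable null data", {
  # fold-1 dataset: labels carry no signal, so each engine's permutation p
  # should hit <= 0.05 about 5% of the time (add-one discretisation aside)
  spec <- make_planted_spec(n_channels = 0, n_decoys = 30, fold = 1,
                            n_cell_types = 5, cells_per_type = 100,
                            n_genes = 300, seed = 1)
  ds <- generate_dataset(spec)
  pp <- preprocess(ds$counts, ds$annotation, 0, 0)
  db <- filter_to_measured(ds$db, rownames(pp$Xlog))
  res <- run_all_engines(pp$Xlog, pp$ann, db, n_perm = 200, seed = 1)
  for (tag in engine_tags) {
    p <- res[[tag]]$pvalues
    n <- sum(!is.na(p))
    expect_gte(n, 500)
    frac <- mean(p <= 0.05, na.rm = TRUE)
    band <- qbinom(c(0.005, 0.995), n, 10 / 201) / n
    expect_gte(frac, band[1])
    expect_lte(frac, band[2])
  }
})

test_that("each engine recovers fold-8 planted channels at its minimum p", {
  spec <- make_planted_spec(n_channels = 10, n_decoys = 10, fold = 8,
                            n_cell_types = 4, cells_per_type = 60,
                            n_genes = 120, seed = 3)
  ds <- generate_dataset(spec)
  pp <- preprocess(ds$counts, ds$annotation, 0, 0)
  db <- filter_to_measured(ds$db, rownames(pp$Xlog))
  res <- run_all_engines(pp$Xlog, pp$ann, db, n_perm = 200, seed = 3)
  for (tag in engine_tags) {
    r <- res[[tag]]
    pv <- mapply(function(s, rc, p) r$pvalues[s, rc, p],
                 ds$truth$sender, ds$truth$receiver, ds$truth$pair_id)
    expect_gte(mean(pv <= 1 / 201 + 1e-12, na.rm = TRUE), 0.9)
  }
})
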