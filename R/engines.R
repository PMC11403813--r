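# Three ligand-receptor scoring engines over (sender type, receiver type,
# pair), sharing one permutation framework for p-values.
#
#   cellchat_like     product of ligand and receptor expression, complex
#                     subunits collapsed by geometric mean
#   cellphonedb_like  mean of ligand and receptor expression, complex
#                     subunits collapsed by their minimum
#   celltalker_like   same product statistic as cellchat_like, but an entry
#                     is only tested when every subunit is expressed in at
#                     least `min_fraction` of the relevant type's cells
#
# All scores are computed from per-type means of ln(1+x) values.  P-values
# come from shuffling cell-type labels over cells (group sizes preserved)
# with the add-one rule p = (1 + #{perm >= obs}) / (1 + n_perm).

#' Engine tags
#'
#' The three scoring-engine identifiers, in canonical order.
#' @export
engine_tags <- c("cellchat_like", "cellphonedb_like", "celltalker_like")

#' Expression of a (possibly multi-subunit) complex in one cell type
#'
#' @param summary a `type_summary` from [summarize_by_type()].
#' @param cx a [gene_complex()].
#' @param cell_type label present in the summary.
#' @param mode `"geometric"` (geometric mean over subunits) or `"minimum"`
#'   (minimum over subunits); identical for single-subunit complexes.
#' @return scalar mean expression of the complex in that type.
#' @export
complex_expression <- function(summary, cx,
                               cell_type, mode = c("geometric", "minimum")) {
  mode <- match.arg(mode)
  if (!cell_type %in% rownames(summary$mean_expr))
    stop("unknown cell type '", cell_type, "'", call. = FALSE)
  miss <- setdiff(cx$subunits, colnames(summary$mean_expr))
  if (length(miss))
    stop("subunit(s) ", paste(miss, collapse = ", "),
         " of complex ", cx$name, " not measured (cell type '",
         cell_type, "')", call. = FALSE)
  v <- summary$mean_expr[cell_type, cx$subunits]
  if (mode == "geometric") prod(v)^(1 / length(v)) else min(v)
}

# cell-type x pair matrix of collapsed complex expression
unit_type_matrix <- function(mean_expr, sub_lists, mode, pair_names) {
  nT <- nrow(mean_expr)
  cols <- lapply(sub_lists, function(su) {
    miss <- setdiff(su, colnames(mean_expr))
    if (length(miss))
      stop("unmeasured subunit(s): ", paste(miss, collapse = ", "),
           "; filter the database with filter_to_measured() first",
           call. = FALSE)
    sub <- mean_expr[, su, drop = FALSE]
    if (length(su) == 1L) sub[, 1L]
    else if (mode == "geometric")
      apply(sub, 1L, function(v) prod(v)^(1 / length(v)))
    else apply(sub, 1L, min)
  })
  matrix(unlist(cols), nrow = nT,
         dimnames = list(rownames(mean_expr), pair_names))
}

# (sender, receiver, pair) array from per-type unit matrices
pair_score_array <- function(L, R, combine) {
  nT <- nrow(L); nP <- ncol(L)
  arr <- array(0, dim = c(nT, nT, nP),
               dimnames = list(sender = rownames(L), receiver = rownames(L),
                               pair = colnames(L)))
  for (p in seq_len(nP))
    arr[, , p] <- if (combine == "product") outer(L[, p], R[, p])
                  else 0.5 * outer(L[, p], R[, p], "+")
  arr
}

db_subunits <- function(db, side)
  lapply(db$pairs, function(p) p[[side]]$subunits)

observed_scores <- function(summary, db, method, min_fraction) {
  ids <- pair_ids(db)
  lig <- db_subunits(db, "ligand"); rec <- db_subunits(db, "receptor")
  me <- summary$mean_expr
  nT <- nrow(me)
  all_tested <- array(TRUE, dim = c(nT, nT, length(ids)),
                      dimnames = list(sender = rownames(me),
                                      receiver = rownames(me), pair = ids))
  if (method == "cellphonedb_like") {
    scores <- pair_score_array(unit_type_matrix(me, lig, "minimum", ids),
                               unit_type_matrix(me, rec, "minimum", ids),
                               "average")
    return(list(scores = scores, tested = all_tested))
  }
  scores <- pair_score_array(unit_type_matrix(me, lig, "geometric", ids),
                             unit_type_matrix(me, rec, "geometric", ids),
                             "product")
  if (method == "cellchat_like")
    return(list(scores = scores, tested = all_tested))
  # celltalker_like: tested iff every subunit clears the expressed-fraction
  # threshold on its own side
  fr <- summary$expr_fraction
  lig_ok <- unit_type_matrix(fr, lig, "minimum", ids) >= min_fraction
  rec_ok <- unit_type_matrix(fr, rec, "minimum", ids) >= min_fraction
  tested <- all_tested
  for (p in seq_along(ids))
    tested[, , p] <- outer(lig_ok[, p], rec_ok[, p], "&")
  list(scores = scores, tested = tested)
}

#' Engine score arrays from a type summary
#'
#' Pure scoring kernels over a [summarize_by_type()] summary, without
#' permutation testing.  `score_cellchat_like()` multiplies the geometric-
#' mean ligand and receptor expressions; `score_cellphonedb_like()` averages
#' the min-subunit expressions; `score_celltalker_like()` uses the product
#' statistic but masks entries where any subunit is expressed in fewer than
#' `min_fraction` of the sender (ligand) or receiver (receptor) cells.
#'
#' @param summary a `type_summary`.
#' @param db an [lr_database()] pre-filtered to measured genes.
#' @param min_fraction expressed-fraction threshold (celltalker only).
#' @return `score_cellchat_like()` and `score_cellphonedb_like()` return a
#'   (sender, receiver, pair) score array; `score_celltalker_like()` returns
#'   a list with `scores` and the logical `tested` mask.
#' @name engine_scores
NULL

#' @rdname engine_scores
#' @export
score_cellchat_like <- function(summary, db)
  observed_scores(summary, db, "cellchat_like", NA)$scores

#' @rdname engine_scores
#' @export
score_cellphonedb_like <- function(summary, db)
  observed_scores(summary, db, "cellphonedb_like", NA)$scores

#' @rdname engine_scores
#' @export
score_celltalker_like <- function(summary, db, min_fraction = 0.1) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  observed_scores(summary, db, "celltalker_like", min_fraction)
}

# Shared permutation core.  One label-shuffle stream (from `seed`) is reused
# by every engine so that the integrated test compares like with like.
run_engines_core <- function(Xlog, ann, db, methods, n_perm = 100, seed = 0,
                             min_fraction = 0.1) {
  stage <- attr(Xlog, "stage")
  if (is.null(stage) || stage != "log")
    stop("engines expect a log-stage matrix", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  bad <- setdiff(methods, engine_tags)
  if (length(bad))
    stop("unknown engine tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  summary <- summarize_by_type(Xlog, ann)
  ids <- pair_ids(db)
  lig <- db_subunits(db, "ligand"); rec <- db_subunits(db, "receptor")
  need_prod <- any(c("cellchat_like", "celltalker_like") %in% methods)
  need_avg <- "cellphonedb_like" %in% methods

  obs <- lapply(stats::setNames(methods, methods), function(m)
    observed_scores(summary, db, m, min_fraction))
  dims <- dim(obs[[1L]]$scores); dn <- dimnames(obs[[1L]]$scores)
  zero <- array(0L, dims, dn)
  counts_prod <- zero; counts_avg <- zero
  obs_prod <- if (need_prod)
    obs[[intersect(c("cellchat_like", "celltalker_like"), methods)[1L]]]$scores
  obs_avg <- if (need_avg) obs[["cellphonedb_like"]]$scores

  labels <- aligned_labels(Xlog, ann)
  cpt <- table(labels)
  tX <- t(Xlog)
  tol <- 1e-12
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    me <- group_summarize(tX, pl, cpt)
    if (need_prod) {
      sc <- pair_score_array(unit_type_matrix(me, lig, "geometric", ids),
                             unit_type_matrix(me, rec, "geometric", ids),
                             "product")
      counts_prod <- counts_prod + (sc >= obs_prod - tol)
    }
    if (need_avg) {
      sc <- pair_score_array(unit_type_matrix(me, lig, "minimum", ids),
                             unit_type_matrix(me, rec, "minimum", ids),
                             "average")
      counts_avg <- counts_avg + (sc >= obs_avg - tol)
    }
  }
  p_prod <- (1 + counts_prod) / (1 + n_perm)
  p_avg <- (1 + counts_avg) / (1 + n_perm)

  lapply(stats::setNames(methods, methods), function(m) {
    p <- if (m == "cellphonedb_like") p_avg else p_prod
    tested <- obs[[m]]$tested
    p[!tested] <- NA_real_
    sc <- obs[[m]]$scores
    sc[!tested] <- NA_real_
    structure(list(method = m, scores = sc, pvalues = p, tested = tested,
                   n_perm = n_perm, seed = seed,
                   min_fraction = if (m == "celltalker_like") min_fraction
                                  else NA_real_,
                   cells_per_type = summary$cells_per_type),
              class = "method_result")
  })
}

#' Run one scoring engine
#'
#' Computes the engine's observed (sender, receiver, pair) score array, the
#' tested mask, and label-permutation p-values.  Deterministic given `seed`.
#'
#' @param method one of `"cellchat_like"`, `"cellphonedb_like"`,
#'   `"celltalker_like"`.
#' @param Xlog log-stage expression matrix.
#' @param ann [cell_annotation()].
#' @param db [lr_database()] pre-filtered to measured genes.
#' @param n_perm number of label permutations (>= 1); the "maximum
#'   iterations" user parameter.
#' @param seed integer seed for the permutation stream.
#' @param min_fraction expressed-cell fraction threshold for the
#'   celltalker-like tested mask.
#' @return a `method_result` with `scores`, `pvalues`, `tested`, `n_perm`,
#'   `seed`, `cells_per_type`.
#' @export
run_engine <- function(method, Xlog, ann, db, n_perm = 100, seed = 0,
                       min_fraction = 0.1) {
  run_engines_core(Xlog, ann, db, methods = method, n_perm = n_perm,
                   seed = seed, min_fraction = min_fraction)[[method]]
}

#' Run all three engines on one shared permutation stream
#'
#' The same label shuffles are reused across engines, so the engines'
#' p-values are commensurable inputs to the Fisher combination.
#'
#' @inheritParams run_engine
#' @return named list of three `method_result` objects.
#' @export
run_all_engines <- function(Xlog, ann, db, n_perm = 100, seed = 0,
                            min_fraction = 0.1) {
  run_engines_core(Xlog, ann, db, methods = engine_tags, n_perm = n_perm,
                   seed = seed, min_fraction = min_fraction)
}

#' Permutation p-values for one engine
#'
#' @inheritParams run_engine
#' @return (sender, receiver, pair) array of add-one permutation p-values,
#'   `NA` where the engine does not test the entry.
#' @export
permutation_pvalues <- function(Xlog, ann, db, method, n_perm, seed,
                                min_fraction = 0.1) {
  run_engine(method, Xlog, ann, db, n_perm = n_perm, seed = seed,
             min_fraction = min_fraction)$pvalues
}

#' @export
print.method_result <- function(x, ...) {
  d <- dim(x$scores)
  cat("<method_result> ", x$method, ": ", d[1], " x ", d[2],
      " cell types x ", d[3], " pairs; ", sum(x$tested), " tested entries; ",
      "n_perm = ", x$n_perm, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
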