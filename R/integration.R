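# Fisher's combined probability integration of the per-engine p-value
# matrices, the SharedNum-normalised combined communication score, the
# significance filter, and the seven-column result table.

#' Fisher's combined probability test
#'
#' Under k independent nulls, `-2 * sum(log(p_i))` follows a chi-square
#' distribution with `2k` degrees of freedom; the combined p-value is its
#' upper-tail probability.  For k = 1 the combination is the identity.
#'
#' @param p_values numeric vector of p-values, each in (0, 1].
#' @return the combined p-value in (0, 1].
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 1L)
    stop("fisher_combine needs at least one p-value", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stat <- -2 * sum(log(p_values))
  stats::pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
}

check_aligned <- function(results) {
  if (length(results) < 1L) stop("no engine results", call. = FALSE)
  dn <- dimnames(results[[1L]]$scores)
  for (r in results[-1L]) {
    if (!identical(dimnames(r$scores), dn))
      stop("engine results have mismatched (sender, receiver, pair) axes",
           call. = FALSE)
  }
  dn
}

#' Combine per-engine p-value arrays
#'
#' Per entry, `SharedNum` is the number of engines that tested it (k of the
#' Fisher combination); the combined p-value is Fisher's combination of the
#' testing engines' p-values.  Entries tested by no engine are `NA`.
#'
#' @param results list of `method_result` objects on identical axes.
#' @return list with `combined_p` and `shared_num` arrays.
#' @export
combine_pvalue_matrix <- function(results) {
  dn <- check_aligned(results)
  dims <- dim(results[[1L]]$scores)
  shared <- array(0L, dims, dn)
  logsum <- array(0, dims, dn)
  for (r in results) {
    shared <- shared + r$tested
    lp <- log(r$pvalues)
    lp[!r$tested] <- 0
    logsum <- logsum + lp
  }
  combined <- array(NA_real_, dims, dn)
  idx <- shared > 0
  combined[idx] <- stats::pchisq(-2 * logsum[idx], df = 2 * shared[idx],
                                 lower.tail = FALSE)
  list(combined_p = combined, shared_num = shared)
}

#' Combine per-engine score arrays
#'
#' Each engine's score array is first rescaled to `[0, 1]` by its own maximum
#' over tested entries (the engines' raw scales are not comparable), then the
#' testing engines' rescaled scores are summed with the user weights, and
#' finally each L-R pair's slice is normalised over all (sender, receiver)
#' entries so it sums to 1.  A pair whose weighted sums are all zero yields an
#' all-zero slice with a warning.
#'
#' @param results list of `method_result` objects on identical axes.
#' @param weights non-negative per-engine weights, not all zero.
#' @return `combined_score` array, values in `[0, 1]`, `NA` where no engine
#'   tested the entry.
#' @export
combine_score_matrix <- function(results, weights = rep(1, length(results))) {
  dn <- check_aligned(results)
  if (length(weights) != length(results))
    stop("need one weight per engine result", call. = FALSE)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero", call. = FALSE)
  dims <- dim(results[[1L]]$scores)
  num <- array(0, dims, dn)
  shared <- array(0L, dims, dn)
  for (i in seq_along(results)) {
    r <- results[[i]]
    shared <- shared + r$tested
    m <- suppressWarnings(max(r$scores[r$tested], na.rm = TRUE))
    sc <- r$scores
    sc[!r$tested] <- 0
    if (is.finite(m) && m > 0) sc <- sc / m
    num <- num + weights[i] * sc
  }
  combined <- array(NA_real_, dims, dn)
  for (p in seq_len(dims[3L])) {
    slice <- num[, , p]
    mask <- shared[, , p] > 0
    denom <- sum(slice[mask])
    out <- array(NA_real_, dim(slice))
    if (denom > 0) {
      out[mask] <- slice[mask] / denom
    } else {
      if (any(mask))
        warning("all-zero scores for pair '", dn$pair[p],
                "'; combined scores set to 0", call. = FALSE)
      out[mask] <- 0
    }
    combined[, , p] <- out
  }
  combined
}

#' Integrate engine results
#'
#' Convenience wrapper fusing p-values ([combine_pvalue_matrix()]) and scores
#' ([combine_score_matrix()]), then applying the significance filter.
#'
#' @param results list of `method_result` objects (typically from
#'   [run_all_engines()]).
#' @param weights per-engine weights for the score combination (the p-value
#'   combination is unweighted Fisher).
#' @param alpha significance threshold on the combined p-value (strict `<`).
#' @param bh_correct apply Benjamini-Hochberg adjustment to the combined
#'   p-values over tested entries before thresholding (off by default; the
#'   reference workflow thresholds raw p-values).
#' @return an `integrated_result` with arrays `combined_p`, `combined_score`,
#'   `shared_num`, the `significant` mask, and the `ranked` entry table.
#' @export
integrate_results <- function(results, weights = rep(1, length(results)),
                              alpha = 0.05, bh_correct = FALSE) {
  pv <- combine_pvalue_matrix(results)
  combined_p <- pv$combined_p
  if (bh_correct) {
    idx <- which(pv$shared_num > 0)
    combined_p[idx] <- stats::p.adjust(combined_p[idx], method = "BH")
  }
  out <- structure(list(
    combined_p = combined_p,
    combined_score = combine_score_matrix(results, weights),
    shared_num = pv$shared_num,
    weights = weights,
    cells_per_type = results[[1L]]$cells_per_type),
    class = "integrated_result")
  significance_filter(out, alpha = alpha)
}

#' Significance filter and ranking
#'
#' An entry is significant iff at least one engine tested it and its combined
#' p-value is strictly below `alpha`.  Significant entries are ranked by
#' combined p ascending, ties broken by combined score descending, then
#' pair id, sender, receiver lexicographically.
#'
#' @param integrated an `integrated_result`.
#' @param alpha threshold in (0, 1).
#' @return the `integrated_result` with `significant` mask, `ranked` data
#'   frame, and `alpha` set.
#' @export
significance_filter <- function(integrated, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  sig <- !is.na(integrated$combined_p) & integrated$shared_num > 0 &
    integrated$combined_p < alpha
  integrated$significant <- sig
  dn <- dimnames(integrated$combined_p)
  idx <- which(sig, arr.ind = TRUE)
  ranked <- data.frame(
    sender = dn$sender[idx[, 1L]],
    receiver = dn$receiver[idx[, 2L]],
    pair_id = dn$pair[idx[, 3L]],
    combined_score = integrated$combined_score[idx],
    combined_p = integrated$combined_p[idx],
    shared_num = integrated$shared_num[idx],
    stringsAsFactors = FALSE)
  ord <- order(ranked$combined_p, -ranked$combined_score, ranked$pair_id,
               ranked$sender, ranked$receiver)
  integrated$ranked <- ranked[ord, , drop = FALSE]
  rownames(integrated$ranked) <- NULL
  integrated$alpha <- alpha
  integrated
}

#' @export
print.integrated_result <- function(x, ...) {
  d <- dim(x$combined_p)
  cat("<integrated_result> ", d[1], " x ", d[2], " cell types x ", d[3],
      " pairs; ", if (is.null(x$significant)) "unfiltered" else
        paste0(sum(x$significant), " significant at alpha ", x$alpha),
      "\n", sep = "")
  invisible(x)
}

#' Build the result table
#'
#' One row per significant entry and method: the three engines (where each
#' tested the entry, carrying that engine's own score and p-value) plus a
#' `"combined"` row with the integrated score and Fisher p-value.  Columns
#' follow the seven-column download schema -- method, task id, ligand,
#' receptor, L-R pair, communication score, p-value -- plus `sender` and
#' `receiver`.
#'
#' @param integrated an `integrated_result` after [significance_filter()].
#' @param results the list of `method_result` objects that were integrated.
#' @param db the [lr_database()] the engines scored (for ligand/receptor
#'   display names).
#' @param task_id run identifier echoed into every row.
#' @param top_n keep only the `top_n` best-ranked significant entries
#'   (`NULL` = all).
#' @return data frame of result rows, deterministic order.
#' @export
build_result_table <- function(integrated, results, db, task_id = "task",
                               top_n = NULL) {
  if (is.null(integrated$ranked))
    stop("run significance_filter() first", call. = FALSE)
  ranked <- integrated$ranked
  if (!is.null(top_n)) ranked <- utils::head(ranked, top_n)
  ids <- pair_ids(db)
  lig_names <- stats::setNames(
    vapply(db$pairs, function(p) p$ligand$name, character(1)), ids)
  rec_names <- stats::setNames(
    vapply(db$pairs, function(p) p$receptor$name, character(1)), ids)
  empty <- data.frame(method = character(0), task_id = character(0),
                      ligand = character(0), receptor = character(0),
                      lr_pair = character(0),
                      communication_score = numeric(0),
                      p_value = numeric(0), sender = character(0),
                      receiver = character(0), stringsAsFactors = FALSE)
  if (nrow(ranked) == 0L) return(empty)
  rows <- vector("list", nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    e <- ranked[i, ]
    methods <- character(0); scores <- numeric(0); ps <- numeric(0)
    for (r in results) {
      if (r$tested[e$sender, e$receiver, e$pair_id]) {
        methods <- c(methods, r$method)
        scores <- c(scores, r$scores[e$sender, e$receiver, e$pair_id])
        ps <- c(ps, r$pvalues[e$sender, e$receiver, e$pair_id])
      }
    }
    methods <- c(methods, "combined")
    scores <- c(scores, e$combined_score)
    ps <- c(ps, e$combined_p)
    rows[[i]] <- data.frame(
      method = methods, task_id = task_id,
      ligand = unname(lig_names[e$pair_id]),
      receptor = unname(rec_names[e$pair_id]),
      lr_pair = e$pair_id, communication_score = scores, p_value = ps,
      sender = e$sender, receiver = e$receiver, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
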