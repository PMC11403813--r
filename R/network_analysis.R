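# Cell-type communication graph and its topology: PageRank importance,
# largest clique, modularity clustering, and cross-method agreement.

#' Build the cell-type communication network
#'
#' Aggregates significant (sender, receiver, pair) entries into a weighted
#' directed graph over cell types: `weight_count` is the number of
#' significant pairs on the edge, `weight_score` the sum of their scores.
#' Edges with no significant pair are omitted; every cell type remains a
#' node.
#'
#' @param x an `integrated_result` (uses combined p/score) or a
#'   `method_result` (uses that engine's p/score).
#' @param alpha significance threshold (strict `<`).
#' @return a `cell_type_network` with `nodes` (cell type, cell count) and
#'   `edges` data frames.
#' @export
build_network <- function(x, alpha = 0.05) {
  if (inherits(x, "integrated_result")) {
    sig <- !is.na(x$combined_p) & x$shared_num > 0 & x$combined_p < alpha
    scores <- x$combined_score
    mode <- "combined"
  } else if (inherits(x, "method_result")) {
    sig <- x$tested & !is.na(x$pvalues) & x$pvalues < alpha
    scores <- x$scores
    mode <- x$method
  } else stop("x must be an integrated_result or method_result",
              call. = FALSE)
  dn <- dimnames(sig)
  types <- dn$sender
  idx <- which(sig, arr.ind = TRUE)
  edges <- data.frame(sender = character(0), receiver = character(0),
                      weight_count = integer(0), weight_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(idx) > 0L) {
    df <- data.frame(sender = dn$sender[idx[, 1L]],
                     receiver = dn$receiver[idx[, 2L]],
                     score = scores[idx], stringsAsFactors = FALSE)
    agg <- stats::aggregate(score ~ sender + receiver, data = df,
                            FUN = function(v) c(n = length(v), s = sum(v)))
    edges <- data.frame(sender = agg$sender, receiver = agg$receiver,
                        weight_count = as.integer(agg$score[, "n"]),
                        weight_score = as.numeric(agg$score[, "s"]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$sender, edges$receiver), , drop = FALSE]
    rownames(edges) <- NULL
  }
  n_cells <- x$cells_per_type
  nodes <- data.frame(cell_type = types,
                      n_cells = if (!is.null(n_cells))
                        as.integer(n_cells[types]) else NA_integer_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "cell_type_network")
}

#' Assemble a network from explicit node and edge tables
#'
#' @param nodes data frame with `cell_type` (and optionally `n_cells`).
#' @param edges data frame with `sender`, `receiver`, `weight_count`,
#'   `weight_score`.
#' @param mode free-text tag recording which scores built the network.
#' @return a `cell_type_network`.
#' @export
cell_type_network <- function(nodes, edges, mode = "custom") {
  if (!"n_cells" %in% names(nodes)) nodes$n_cells <- NA_integer_
  stopifnot(all(c("sender", "receiver") %in% names(edges)))
  if (!"weight_count" %in% names(edges))
    edges$weight_count <- rep(1L, nrow(edges))
  if (!"weight_score" %in% names(edges))
    edges$weight_score <- rep(1, nrow(edges))
  if (!all(c(edges$sender, edges$receiver) %in% nodes$cell_type))
    stop("edge endpoints must be listed in nodes", call. = FALSE)
  if (any(edges$weight_count < 0) || any(edges$weight_score < 0))
    stop("edge weights must be non-negative", call. = FALSE)
  structure(list(nodes = nodes[, c("cell_type", "n_cells")],
                 edges = edges[, c("sender", "receiver", "weight_count",
                                   "weight_score")], mode = mode),
            class = "cell_type_network")
}

#' @export
print.cell_type_network <- function(x, ...) {
  cat("<cell_type_network> [", x$mode, "] ", nrow(x$nodes), " cell types, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# dense weight matrix, rows = senders, sorted node order
network_matrix <- function(net, weight = c("score", "count")) {
  weight <- match.arg(weight)
  types <- sort(net$nodes$cell_type)
  W <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  if (nrow(net$edges) > 0L) {
    col <- if (weight == "score") net$edges$weight_score else
      net$edges$weight_count
    W[cbind(net$edges$sender, net$edges$receiver)] <- col
  }
  W
}

#' PageRank scores of the cell types
#'
#' Power iteration on the row-normalised transition matrix of the directed
#' weighted communication graph, with uniform teleportation; dangling nodes
#' (no outgoing weight) redistribute uniformly.  Converged when the L1
#' change drops below `tol`.
#'
#' @param net a `cell_type_network`.
#' @param damping damping factor (canonical 0.85).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeded -> error reporting the residual.
#' @param weight edge attribute used: `"score"` (default) or `"count"`.
#' @return named numeric vector summing to 1.
#' @export
pagerank_scores <- function(net, damping = 0.85, tol = 1e-9, max_iter = 500,
                            weight = c("score", "count")) {
  W <- network_matrix(net, weight)
  n <- nrow(W)
  if (n < 1L) stop("network has no nodes", call. = FALSE)
  out <- rowSums(W)
  P <- W
  nz <- out > 0
  P[nz, ] <- W[nz, , drop = FALSE] / out[nz]
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v_new <- damping * (as.vector(crossprod(P, v)) +
                          sum(v[!nz]) / n) + (1 - damping) / n
    if (sum(abs(v_new - v)) < tol)
      return(stats::setNames(v_new / sum(v_new), rownames(W)))
    v <- v_new
  }
  stop(sprintf("PageRank did not converge in %d iterations (residual %.3g)",
               max_iter, sum(abs(v_new - v))), call. = FALSE)
}

undirected_adjacency <- function(net, rule = c("both", "any")) {
  rule <- match.arg(rule)
  W <- network_matrix(net, "count")
  A <- if (rule == "both") (W > 0) & (t(W) > 0) else (W > 0) | (t(W) > 0)
  diag(A) <- FALSE
  A
}

#' Largest communication clique
#'
#' Maximum clique of the undirected presence graph: by default two cell
#' types are adjacent iff significant pairs run in both directions
#' (`rule = "both"`); `rule = "any"` uses either direction.  Exact search
#' (cell-type graphs are small); ties are broken by the lexicographically
#' smallest sorted node list.
#'
#' @param net a `cell_type_network`.
#' @param rule edge presence rule, `"both"` (default) or `"any"`.
#' @return sorted character vector of clique members (empty for an empty
#'   graph; a single smallest-label node for an edgeless one).
#' @export
largest_clique <- function(net, rule = c("both", "any")) {
  A <- undirected_adjacency(net, rule)
  if (nrow(A) == 0L) return(character(0))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cliques <- igraph::largest_cliques(g)
  cands <- lapply(cliques, function(cl) sort(rownames(A)[as.integer(cl)]))
  keys <- vapply(cands, paste, character(1), collapse = "\001")
  cands[[which(keys == min(keys))[1L]]]
}

#' Cluster the communication network
#'
#' Greedy modularity maximisation (fast-greedy agglomeration) on the
#' symmetrised score-weighted graph; deterministic, singleton clusters
#' permitted.
#'
#' @param net a `cell_type_network`.
#' @param weight edge attribute to symmetrise and cluster on.
#' @return named integer vector: cell type -> cluster id (1-based, ordered
#'   by first member).
#' @export
cluster_network <- function(net, weight = c("score", "count")) {
  W <- network_matrix(net, weight)
  if (nrow(W) == 0L) stop("network has no nodes", call. = FALSE)
  S <- W + t(W)
  diag(S) <- 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(nrow(W))
  } else {
    fc <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    # deterministic cut: among cuts whose modularity ties the maximum (to
    # floating tolerance), take the coarsest partition
    n <- nrow(W)
    k_min <- n - nrow(fc$merges)  # merging stops at connected components
    cand <- lapply(seq.int(k_min, n), function(k)
      as.integer(igraph::cut_at(fc, no = k)))
    q <- vapply(cand, function(mm)
      igraph::modularity(g, mm, weights = igraph::E(g)$weight), numeric(1))
    memb <- cand[[which(q >= max(q) - 1e-10)[1L]]]
  }
  relabel <- match(memb, unique(memb))
  stats::setNames(relabel, rownames(W))
}

#' Pearson correlation between two communication networks
#'
#' Correlates the flattened score-weighted (sender, receiver) matrices of
#' two networks over the same cell types, structural zeros included,
#' diagonal self-edges excluded.
#'
#' @param netA,netB `cell_type_network` objects over identical node sets.
#' @param weight edge attribute to correlate (`"score"` or `"count"`).
#' @return Pearson r, or `NA` (with a warning) when either flattening is
#'   constant.
#' @export
network_pcc <- function(netA, netB, weight = c("score", "count")) {
  if (!setequal(netA$nodes$cell_type, netB$nodes$cell_type))
    stop("networks have different node sets", call. = FALSE)
  WA <- network_matrix(netA, weight); WB <- network_matrix(netB, weight)
  off <- row(WA) != col(WA)
  a <- WA[off]; b <- WB[off]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant network weights; PCC undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Cross-method agreement report
#'
#' For every dataset, computes all pairwise network PCCs among the methods
#' (three engines plus `"combined"`).  For each single-method reference m,
#' a one-sided Wilcoxon signed-rank test asks whether PCC(combined, m)
#' exceeds PCC(second, m) across datasets, where `second` is the other
#' single method with the highest median PCC against m (exact distribution
#' for n <= 25 untied pairs).
#'
#' @param networks_by_dataset list (one element per dataset) of named lists
#'   of `cell_type_network` objects; names must include `"combined"` and be
#'   identical across datasets.
#' @param weight edge attribute to correlate.
#' @return an `agreement_report`: `pcc` (method x method x dataset array)
#'   and `wilcoxon` data frame (`reference`, `second`, `n`, `p_value`;
#'   `p_value` is `NA`-flagged when all differences are zero).
#' @export
compare_methods <- function(networks_by_dataset,
                            weight = c("score", "count")) {
  nD <- length(networks_by_dataset)
  if (nD < 2L)
    stop("need networks for at least two datasets", call. = FALSE)
  methods <- names(networks_by_dataset[[1L]])
  if (is.null(methods) || !"combined" %in% methods)
    stop("each dataset needs named networks including 'combined'",
         call. = FALSE)
  for (d in networks_by_dataset)
    if (!identical(sort(names(d)), sort(methods)))
      stop("method names differ across datasets", call. = FALSE)
  ds_names <- names(networks_by_dataset)
  if (is.null(ds_names)) ds_names <- paste0("dataset", seq_len(nD))
  pcc <- array(NA_real_, c(length(methods), length(methods), nD),
               dimnames = list(methods, methods, ds_names))
  for (d in seq_len(nD)) {
    nets <- networks_by_dataset[[d]]
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      pcc[i, j, d] <- if (i == j) 1 else
        suppressWarnings(network_pcc(nets[[methods[i]]], nets[[methods[j]]],
                                     weight = weight))
    }
  }
  singles <- setdiff(methods, "combined")
  wil <- data.frame(reference = character(0), second = character(0),
                    n = integer(0), p_value = numeric(0),
                    stringsAsFactors = FALSE)
  for (m in singles) {
    others <- setdiff(singles, m)
    med <- vapply(others, function(o)
      stats::median(pcc[o, m, ], na.rm = TRUE), numeric(1))
    second <- others[which.max(med)]
    x <- pcc["combined", m, ]; y <- pcc[second, m, ]
    ok <- is.finite(x) & is.finite(y)
    d <- x[ok] - y[ok]
    p <- if (length(d) == 0L || all(d == 0)) NA_real_ else
      suppressWarnings(stats::wilcox.test(
        x[ok], y[ok], paired = TRUE, alternative = "greater",
        exact = sum(ok) <= 25)$p.value)
    wil <- rbind(wil, data.frame(reference = m, second = second,
                                 n = sum(ok), p_value = p,
                                 stringsAsFactors = FALSE))
  }
  structure(list(pcc = pcc, wilcoxon = wil), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", dim(x$pcc)[1], " methods x ", dim(x$pcc)[3],
      " datasets\n", sep = "")
  print(x$wilcoxon)
  invisible(x)
}
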