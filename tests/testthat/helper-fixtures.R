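# Shared fixtures and independent oracles for the test suite.

# mark a plain matrix as log-stage (for tests that state log values directly)
as_log_stage <- function(m) {
  attr(m, "stage") <- "log"
  m
}

# hand-built type summary: mean_expr / expr_fraction are type x gene
toy_summary <- function(mean_expr, expr_fraction = NULL,
                        cells_per_type = NULL) {
  if (is.null(expr_fraction))
    expr_fraction <- (mean_expr > 0) * 1
  if (is.null(cells_per_type))
    cells_per_type <- stats::setNames(rep(10L, nrow(mean_expr)),
                                      rownames(mean_expr))
  structure(list(mean_expr = mean_expr, expr_fraction = expr_fraction,
                 cells_per_type = cells_per_type,
                 cell_types = rownames(mean_expr)),
            class = "type_summary")
}

# minimal method_result for integration tests
fake_result <- function(method, scores, pvalues, tested = NULL,
                        n_perm = 100L, seed = 0L) {
  if (is.null(tested)) tested <- array(TRUE, dim(scores), dimnames(scores))
  p <- pvalues; p[!tested] <- NA_real_
  s <- scores; s[!tested] <- NA_real_
  structure(list(method = method, scores = s, pvalues = p, tested = tested,
                 n_perm = n_perm, seed = seed, min_fraction = NA_real_,
                 cells_per_type = NULL),
            class = "method_result")
}

# named axes helper for 3d arrays
lr_array <- function(values, types, pairs) {
  array(values, dim = c(length(types), length(types), length(pairs)),
        dimnames = list(sender = types, receiver = types, pair = pairs))
}

# --- independent oracles -------------------------------------------------

# chi-square upper tail for even df via the closed-form Poisson sum
# P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!   (df = 2k)
chisq_tail_even_df <- function(x, df) {
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Fisher combination oracle by numerical integration of the chi-square
# density (independent of pchisq's tail path)
fisher_oracle_integrate <- function(p_values) {
  stat <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  if (stat == 0) return(1)
  stats::integrate(function(x) stats::dchisq(x, df = df), lower = stat,
                   upper = Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# dense linear solve of the PageRank fixed point:
# v = (1-d)/n + d * t(P') v, with dangling rows of P' set to 1/n
pagerank_oracle <- function(W, damping = 0.85) {
  n <- nrow(W)
  out <- rowSums(W)
  P <- matrix(1 / n, n, n)
  nz <- out > 0
  P[nz, ] <- W[nz, , drop = FALSE] / out[nz]
  v <- solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
  stats::setNames(v / sum(v), rownames(W))
}

# exhaustive maximum clique over an undirected adjacency matrix; returns the
# lexicographically smallest sorted node set among maximum cliques
clique_oracle <- function(A) {
  n <- nrow(A)
  labels <- rownames(A)
  best <- character(0)
  for (m in 0:(2^n - 1)) {
    members <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < length(best)) next
    ok <- TRUE
    if (length(members) > 1) {
      for (i in members) for (j in members)
        if (i < j && !A[i, j]) { ok <- FALSE; break }
    }
    if (!ok) next
    cand <- sort(labels[members])
    if (length(cand) > length(best) ||
        (length(cand) == length(best) &&
         paste(cand, collapse = "\001") < paste(best, collapse = "\001")))
      best <- cand
  }
  best
}

# exact one-sided (greater) signed-rank p by enumerating all sign vectors;
# differences must be non-zero and tie-free
signed_rank_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  count <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    if (sum(r[signs]) >= w_obs) count <- count + 1L
  }
  count / 2^n
}

# small deterministic random network over given types
random_network <- function(types, p_edge = 0.5) {
  n <- length(types)
  combos <- expand.grid(sender = types, receiver = types,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$sender != combos$receiver, ]
  keep <- stats::runif(nrow(combos)) < p_edge
  edges <- combos[keep, , drop = FALSE]
  edges$weight_count <- sample.int(3L, nrow(edges), replace = TRUE)
  edges$weight_score <- stats::runif(nrow(edges))
  cell_type_network(data.frame(cell_type = types), edges)
}
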