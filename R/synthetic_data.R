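# Negative-binomial scRNA-seq simulator with planted ligand-receptor
# channels, plus the recovery metrics used to evaluate inference on it.
#
# The generator states a world: per-gene baseline means drawn from a gamma
# distribution around `baseline_mean`, per-cell multiplicative library
# factors, NB counts with a common dispersion, and channels planted by
# multiplying the ligand subunits' means by `fold` in the sender type and
# the receptor subunits' means by `fold` in the receiver type.  Decoy pairs
# connect unperturbed genes so false-discovery metrics have a denominator.

#' Specification of a synthetic dataset
#'
#' @param n_cell_types number of cell types (labelled `T1`, `T2`, ...).
#' @param cells_per_type scalar or per-type vector of cell counts.
#' @param n_genes number of genes (labelled `G0001`, ...).
#' @param baseline_mean mean of the per-gene NB baseline rates (counts per
#'   cell at unit library factor).
#' @param dispersion NB dispersion `phi` (variance `mu + phi mu^2`).
#' @param planted_channels list of channels, each a list with `sender`,
#'   `receiver`, `pair` (an [lr_pair()] over simulated gene names) and
#'   `fold >= 1`.
#' @param decoy_pairs list of [lr_pair()]s over unperturbed genes.
#' @param library_size_spread cells' library factors are drawn uniformly
#'   from `[1, library_size_spread]` (>= 1).
#' @param seed integer seed making the dataset fully deterministic.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cell_types = 5, cells_per_type = 100,
                           n_genes = 300, baseline_mean = 0.5,
                           dispersion = 0.5, planted_channels = list(),
                           decoy_pairs = list(), library_size_spread = 2,
                           seed = 1) {
  stopifnot(n_cell_types >= 1, n_genes >= 1, baseline_mean > 0,
            dispersion > 0, library_size_spread >= 1)
  if (length(cells_per_type) == 1L)
    cells_per_type <- rep(cells_per_type, n_cell_types)
  stopifnot(length(cells_per_type) == n_cell_types, all(cells_per_type >= 1))
  types <- sprintf("T%d", seq_len(n_cell_types))
  genes <- sprintf("G%04d", seq_len(n_genes))
  planted_genes <- character(0)
  for (ch in planted_channels) {
    stopifnot(all(c("sender", "receiver", "pair", "fold") %in% names(ch)),
              ch$fold >= 1, ch$sender %in% types, ch$receiver %in% types)
    gs <- c(ch$pair$ligand$subunits, ch$pair$receptor$subunits)
    if (!all(gs %in% genes))
      stop("planted pair ", ch$pair$pair_id,
           " references genes outside the simulated gene set",
           call. = FALSE)
    planted_genes <- union(planted_genes, gs)
  }
  for (dp in decoy_pairs) {
    gs <- c(dp$ligand$subunits, dp$receptor$subunits)
    if (!all(gs %in% genes))
      stop("decoy pair ", dp$pair_id, " references genes outside the ",
           "simulated gene set", call. = FALSE)
    if (any(gs %in% planted_genes))
      stop("decoy pair ", dp$pair_id, " collides with planted genes",
           call. = FALSE)
  }
  structure(list(n_cell_types = n_cell_types,
                 cells_per_type = as.integer(cells_per_type),
                 n_genes = n_genes, baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 planted_channels = planted_channels,
                 decoy_pairs = decoy_pairs,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed), cell_types = types, genes = genes),
            class = "synthetic_spec")
}

#' Standard planted-channel specification
#'
#' Builds a [synthetic_spec()] whose first `2 * n_channels` genes form
#' planted single-subunit ligand-receptor pairs, assigned round-robin to
#' ordered (sender != receiver) type pairs, and whose next `2 * n_decoys`
#' genes form decoy pairs with no planted shift.
#'
#' @inheritParams synthetic_spec
#' @param n_channels number of planted channels.
#' @param n_decoys number of decoy pairs.
#' @param fold common fold change of all planted channels (>= 1).
#' @return a `synthetic_spec`.
#' @export
make_planted_spec <- function(n_channels = 20, n_decoys = 30, fold = 8,
                              n_cell_types = 5, cells_per_type = 200,
                              n_genes = 500, baseline_mean = 0.5,
                              dispersion = 0.5, library_size_spread = 2,
                              seed = 1) {
  stopifnot(2 * (n_channels + n_decoys) <= n_genes)
  types <- sprintf("T%d", seq_len(n_cell_types))
  genes <- sprintf("G%04d", seq_len(n_genes))
  type_pairs <- expand.grid(receiver = types, sender = types,
                            stringsAsFactors = FALSE)
  type_pairs <- type_pairs[type_pairs$sender != type_pairs$receiver,
                           c("sender", "receiver")]
  channels <- lapply(seq_len(n_channels), function(i) {
    tp <- type_pairs[((i - 1L) %% nrow(type_pairs)) + 1L, ]
    list(sender = tp$sender, receiver = tp$receiver,
         pair = lr_pair(genes[2L * i - 1L], genes[2L * i],
                        sources = "planted"),
         fold = fold)
  })
  off <- 2L * n_channels
  decoys <- lapply(seq_len(n_decoys), function(i)
    lr_pair(genes[off + 2L * i - 1L], genes[off + 2L * i],
            sources = "decoy"))
  synthetic_spec(n_cell_types = n_cell_types,
                 cells_per_type = cells_per_type, n_genes = n_genes,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 planted_channels = channels, decoy_pairs = decoys,
                 library_size_spread = library_size_spread, seed = seed)
}

#' Generate a synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (gene x cell matrix), `annotation`
#'   ([cell_annotation()]), `db` ([lr_database()] of planted plus decoy
#'   pairs), and `truth` (a `ground_truth` data frame of planted
#'   (sender, receiver, pair_id) triples).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nC <- sum(spec$cells_per_type)
  nG <- spec$n_genes
  labels <- rep(spec$cell_types, spec$cells_per_type)
  barcodes <- sprintf("cell%05d", seq_len(nC))
  gene_means <- stats::rgamma(nG, shape = 2, rate = 2 / spec$baseline_mean)
  lib <- stats::runif(nC, 1, spec$library_size_spread)
  mu <- outer(gene_means, lib)
  rownames(mu) <- spec$genes
  for (ch in spec$planted_channels) {
    mu[ch$pair$ligand$subunits, labels == ch$sender] <-
      mu[ch$pair$ligand$subunits, labels == ch$sender] * ch$fold
    mu[ch$pair$receptor$subunits, labels == ch$receiver] <-
      mu[ch$pair$receptor$subunits, labels == ch$receiver] * ch$fold
  }
  counts <- matrix(stats::rnbinom(nG * nC, mu = mu,
                                  size = 1 / spec$dispersion),
                   nrow = nG, dimnames = list(spec$genes, barcodes))
  pairs <- c(lapply(spec$planted_channels, `[[`, "pair"), spec$decoy_pairs)
  truth <- data.frame(
    sender = vapply(spec$planted_channels, `[[`, character(1), "sender"),
    receiver = vapply(spec$planted_channels, `[[`, character(1), "receiver"),
    pair_id = vapply(spec$planted_channels,
                     function(ch) ch$pair$pair_id, character(1)),
    stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  list(counts = count_matrix(counts),
       annotation = cell_annotation(barcodes, labels),
       db = if (length(pairs)) merge_databases(lr_database(pairs)) else
         lr_database(list()),
       truth = truth)
}

#' Recovery metrics against the planted truth
#'
#' A significant (sender, receiver, pair) entry is a true positive iff the
#' exact triple was planted.
#'
#' @param significant data frame with columns `sender`, `receiver`,
#'   `pair_id` -- e.g. the `ranked` table of an `integrated_result`, or the
#'   `method == "combined"` rows of a result table.
#' @param truth the `ground_truth` from [generate_dataset()].
#' @return list with `precision` (`NA` when nothing is significant),
#'   `recall`, `fdp` (0 when nothing is significant), and the counts
#'   `tp`, `fp`, `fn`.
#' @export
evaluate_recovery <- function(significant, truth) {
  key <- function(df) paste(df$sender, df$receiver, df$pair_id, sep = "\001")
  sig_keys <- unique(key(significant))
  true_keys <- unique(key(truth))
  tp <- sum(sig_keys %in% true_keys)
  fp <- length(sig_keys) - tp
  fn <- length(true_keys) - tp
  list(precision = if (length(sig_keys) == 0L) NA_real_ else
         tp / length(sig_keys),
       recall = if (length(true_keys) == 0L) NA_real_ else
         tp / length(true_keys),
       fdp = if (length(sig_keys) == 0L) 0 else fp / length(sig_keys),
       tp = tp, fp = fp, fn = fn)
}
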