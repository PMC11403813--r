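# Ligand-receptor knowledge: complexes, pairs, databases.
#
# A ligand or receptor may be a multi-subunit complex ("polymer"); inside a
# table cell subunits are joined by "&" (never "_", which separates ligand
# from receptor in the displayed pair id, e.g. "CD74_MIF").

#' Create a gene complex
#'
#' A ligand or receptor unit made of one or more gene subunits.  Gene symbols
#' are uppercased on construction so that comparisons against expression
#' matrices (whose case conventions vary) are case-insensitive in effect.
#'
#' @param subunits character vector of gene symbols (length >= 1, no
#'   whitespace, no duplicates).
#' @param name display name; defaults to the sole subunit for single-gene
#'   complexes and to the `&`-joined subunit list otherwise.
#' @return an object of class `gene_complex` with fields `name` and
#'   `subunits`.
#' @export
gene_complex <- function(subunits, name = NULL) {
  subunits <- toupper(trimws(as.character(subunits)))
  if (length(subunits) < 1L)
    stop("a gene complex needs at least one subunit", call. = FALSE)
  if (any(!nzchar(subunits)) || any(grepl("[[:space:]]", subunits)))
    stop("subunit symbols must be non-empty and contain no whitespace",
         call. = FALSE)
  if (anyDuplicated(subunits))
    stop("duplicate subunit symbols: ",
         paste(unique(subunits[duplicated(subunits)]), collapse = ", "),
         call. = FALSE)
  if (is.null(name)) {
    name <- if (length(subunits) == 1L) subunits else
      paste(subunits, collapse = "&")
  }
  structure(list(name = name, subunits = subunits), class = "gene_complex")
}

#' @export
print.gene_complex <- function(x, ...) {
  cat("<gene_complex> ", x$name, " [", paste(x$subunits, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

as_gene_complex <- function(x) {
  if (inherits(x, "gene_complex")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(gene_complex(strsplit(x, "&", fixed = TRUE)[[1L]]))
  gene_complex(x)
}

#' Create a ligand-receptor pair
#'
#' @param ligand,receptor a `gene_complex`, or a character scalar with
#'   subunits joined by `"&"`.
#' @param sources character vector of provenance tags (non-empty).
#' @return an `lr_pair` with fields `ligand`, `receptor`, `sources` and the
#'   canonical `pair_id` `"LIGANDNAME_RECEPTORNAME"`.
#' @export
lr_pair <- function(ligand, receptor, sources) {
  ligand <- as_gene_complex(ligand)
  receptor <- as_gene_complex(receptor)
  sources <- unique(as.character(sources))
  if (length(sources) < 1L || any(!nzchar(sources)))
    stop("an lr_pair needs at least one non-empty source tag", call. = FALSE)
  structure(list(ligand = ligand, receptor = receptor,
                 sources = sort(sources),
                 pair_id = paste(ligand$name, receptor$name, sep = "_")),
            class = "lr_pair")
}

# Duplicate rule: two pairs are the same interaction iff their sorted ligand
# subunits and sorted receptor subunits coincide (subunit order in the source
# tables is not meaningful).
pair_dup_key <- function(p) {
  paste(paste(sort(p$ligand$subunits), collapse = "&"),
        paste(sort(p$receptor$subunits), collapse = "&"), sep = "|")
}

#' Create a ligand-receptor database
#'
#' @param pairs list of [lr_pair()] objects; duplicates (by the sorted-subunit
#'   rule) are rejected.
#' @param source_names optional character vector of provenance tags; defaults
#'   to the union of the pairs' sources.
#' @return an `lr_database`.
#' @export
lr_database <- function(pairs, source_names = NULL) {
  stopifnot(is.list(pairs))
  for (p in pairs) {
    if (!inherits(p, "lr_pair")) stop("all pairs must be lr_pair objects",
                                      call. = FALSE)
  }
  keys <- vapply(pairs, pair_dup_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate pairs in database: ",
         paste(unique(vapply(pairs[duplicated(keys)], `[[`, character(1),
                             "pair_id")), collapse = ", "), call. = FALSE)
  ids <- vapply(pairs, `[[`, character(1), "pair_id")
  if (anyDuplicated(ids))
    stop("duplicate pair_id in database: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(source_names))
    source_names <- sort(unique(unlist(lapply(pairs, `[[`, "sources"))))
  structure(list(pairs = pairs, source_names = source_names),
            class = "lr_database")
}

#' @export
length.lr_database <- function(x) length(x$pairs)

#' @export
print.lr_database <- function(x, ...) {
  cat("<lr_database> ", length(x$pairs), " pairs from sources: ",
      paste(x$source_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pair ids of a database
#' @param db an `lr_database`.
#' @return character vector of canonical pair ids.
#' @export
pair_ids <- function(db) vapply(db$pairs, `[[`, character(1), "pair_id")

#' @export
as.data.frame.lr_database <- function(x, ...) {
  data.frame(
    pair_id = pair_ids(x),
    ligand = vapply(x$pairs, function(p)
      paste(p$ligand$subunits, collapse = "&"), character(1)),
    receptor = vapply(x$pairs, function(p)
      paste(p$receptor$subunits, collapse = "&"), character(1)),
    source = vapply(x$pairs, function(p)
      paste(p$sources, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Load a ligand-receptor table
#'
#' Reads the TSV dialect `ligand<TAB>receptor[<TAB>source]`, complex subunits
#' joined by `"&"` within a cell.  Rows that are exact duplicates under the
#' sorted-subunit rule are collapsed (sources unioned).
#'
#' @param path TSV file with header columns `ligand` and `receptor`.
#' @param source_tag provenance tag applied to rows lacking a `source`
#'   column value.
#' @return an [lr_database()].
#' @export
load_lr_table <- function(path, source_tag) {
  if (missing(source_tag) || !nzchar(source_tag))
    stop("source_tag is required", call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  for (col in c("ligand", "receptor")) {
    if (!col %in% names(tab))
      stop(sprintf("malformed L-R table '%s': missing column '%s'",
                   path, col), call. = FALSE)
  }
  has_src <- "source" %in% names(tab)
  pairs <- list()
  keys <- character(0)
  for (i in seq_len(nrow(tab))) {
    lig <- trimws(tab$ligand[i]); rec <- trimws(tab$receptor[i])
    if (!nzchar(lig) || !nzchar(rec))
      stop(sprintf("row %d of '%s': empty ligand or receptor cell",
                   i, path), call. = FALSE)
    src <- if (has_src && nzchar(trimws(tab$source[i])))
      strsplit(trimws(tab$source[i]), ";", fixed = TRUE)[[1L]] else source_tag
    p <- lr_pair(lig, rec, src)
    k <- pair_dup_key(p)
    j <- match(k, keys)
    if (is.na(j)) {
      pairs[[length(pairs) + 1L]] <- p
      keys <- c(keys, k)
    } else {
      pairs[[j]] <- lr_pair(pairs[[j]]$ligand, pairs[[j]]$receptor,
                            union(pairs[[j]]$sources, p$sources))
    }
  }
  lr_database(pairs)
}

#' Write a ligand-receptor table
#'
#' Writes the same TSV dialect read by [load_lr_table()]; re-loading yields an
#' identical pair set.
#'
#' @param db an `lr_database`.
#' @param path output path.
#' @export
write_lr_table <- function(db, path) {
  df <- as.data.frame(db)
  utils::write.table(df[, c("ligand", "receptor", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge ligand-receptor databases
#'
#' Union of pair sets; duplicates (sorted-subunit rule) are collapsed with
#' their sources unioned.  Output is sorted by `pair_id` so the merge result
#' is deterministic and order-independent.
#'
#' @param ... `lr_database` objects, or a single list of them.
#' @return the merged `lr_database`.
#' @export
merge_databases <- function(...) {
  dbs <- list(...)
  if (length(dbs) == 1L && !inherits(dbs[[1L]], "lr_database"))
    dbs <- dbs[[1L]]
  if (length(dbs) < 1L)
    stop("merge_databases needs at least one database", call. = FALSE)
  for (d in dbs) if (!inherits(d, "lr_database"))
    stop("all arguments must be lr_database objects", call. = FALSE)
  pairs <- list(); keys <- character(0)
  for (d in dbs) for (p in d$pairs) {
    k <- pair_dup_key(p)
    j <- match(k, keys)
    if (is.na(j)) {
      pairs[[length(pairs) + 1L]] <- p
      keys <- c(keys, k)
    } else {
      pairs[[j]] <- lr_pair(pairs[[j]]$ligand, pairs[[j]]$receptor,
                            union(pairs[[j]]$sources, p$sources))
    }
  }
  ord <- order(vapply(pairs, `[[`, character(1), "pair_id"))
  lr_database(pairs[ord],
              source_names = sort(unique(unlist(lapply(dbs, `[[`,
                                                       "source_names")))))
}

#' Restrict a database to measured genes
#'
#' Engines can only score a pair when every ligand and receptor subunit is
#' present in the expression matrix; pairs with any unmeasured subunit are
#' dropped.
#'
#' @param db an `lr_database`.
#' @param gene_set character vector of measured gene symbols.
#' @return the filtered `lr_database` (possibly empty).
#' @export
filter_to_measured <- function(db, gene_set) {
  if (length(gene_set) < 1L)
    stop("gene_set must be non-empty", call. = FALSE)
  gene_set <- toupper(gene_set)
  keep <- vapply(db$pairs, function(p)
    all(c(p$ligand$subunits, p$receptor$subunits) %in% gene_set), logical(1))
  lr_database(db$pairs[keep], source_names = db$source_names)
}

#' Summarise a ligand-receptor database
#'
#' @param db an `lr_database`.
#' @return list with `n_pairs` and a named `per_source` count vector (a pair
#'   carrying several provenance tags counts once per tag).
#' @export
lr_summary <- function(db) {
  src <- unlist(lapply(db$pairs, `[[`, "sources"))
  per_source <- if (length(src)) table(src) else table(character(0))
  list(n_pairs = length(db$pairs),
       per_source = as.list(as.integer(per_source)) |>
         stats::setNames(names(per_source)))
}
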