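#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric (upper-tail) test of a DEG list against each
#' gene set of a collection, within a fixed gene universe (all analyzed
#' genes); gene sets are intersected with the universe before testing.
#' P-values are Benjamini-Hochberg adjusted across sets. This is the
#' offline counterpart of web over-representation services, with an
#' explicit, reproducible background.
#'
#' @param deg_list character vector of genes (must be a subset of
#'   `universe`).
#' @param gsc a `gene_set_collection` (see [read_gmt()]).
#' @param universe character vector: the background gene universe.
#' @return data.frame sorted by p-value with columns `set`,
#'   `overlap_count`, `set_size`, `list_size`, `universe_size`, `p_value`,
#'   `adj_p`, `overlap_genes` (comma-separated).
#' @export
ora <- function(deg_list, gsc, universe) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  universe <- unique(universe)
  deg_list <- unique(deg_list)
  if (length(universe) == 0 || length(deg_list) == 0) {
    abort_dsp("deg_list and universe must be non-empty", "dsp_input_error")
  }
  if (!all(deg_list %in% universe)) {
    abort_dsp("deg_list must be a subset of the universe", "dsp_input_error")
  }
  n_univ <- length(universe)
  n_list <- length(deg_list)
  rows <- lapply(names(gsc$sets), function(nm) {
    set_genes <- intersect(gsc$sets[[nm]], universe)
    hit <- intersect(deg_list, set_genes)
    k <- length(hit)
    p <- stats::phyper(k - 1, length(set_genes), n_univ - length(set_genes),
                       n_list, lower.tail = FALSE)
    data.frame(set = nm, overlap_count = k, set_size = length(set_genes),
               list_size = n_list, universe_size = n_univ, p_value = p,
               overlap_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "overlap_count", "set_size", "list_size", "universe_size",
          "p_value", "adj_p", "overlap_genes")]
}

#' Intersect a DEG list with a gene-disease association table
#'
#' Case-insensitive matching (mouse DEG symbols vs human disease-resource
#' symbols differ only in casing).
#'
#' @param deg_list character vector of gene symbols.
#' @param assoc data.frame with columns `gene`, `disease` (see
#'   [read_associations()]).
#' @return A list with `hits` (data.frame `gene`, `disease`; one row per
#'   pair, DEG casing retained) and `counts` (data.frame `disease`,
#'   `n_genes`: distinct DEGs per disease).
#' @export
disease_hits <- function(deg_list, assoc) {
  deg_list <- unique(deg_list)
  idx <- match(toupper(assoc$gene), toupper(deg_list))
  keep <- !is.na(idx)
  hits <- data.frame(gene = deg_list[idx[keep]],
                     disease = assoc$disease[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene, hits$disease), , drop = FALSE]
  rownames(hits) <- NULL
  counts <- if (nrow(hits) > 0) {
    agg <- stats::aggregate(gene ~ disease, data = hits,
                            FUN = function(g) length(unique(g)))
    names(agg) <- c("disease", "n_genes")
    agg[order(-agg$n_genes, agg$disease), , drop = FALSE]
  } else {
    data.frame(disease = character(0), n_genes = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  list(hits = hits, counts = counts)
}
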