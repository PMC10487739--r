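#' Construct a validated AOI count matrix
#'
#' The raw input of the pipeline: deduplicated digital counts for each gene
#' (rows) in each area of illumination (AOI, columns). Counts must be
#' non-negative integers; gene symbols and AOI identifiers must be unique.
#' Normalized values are represented by a distinct class
#' ([q3_normalize()]) and are never written back into a `count_matrix`,
#' which prevents accidental double-normalization.
#'
#' @param counts numeric matrix of non-negative integers, or an object
#'   coercible to one, with genes in rows and AOIs in columns.
#' @param genes character vector of gene symbols (defaults to rownames).
#' @param aois character vector of AOI identifiers (defaults to colnames).
#' @return An object of class `count_matrix` with elements `counts`
#'   (integer-valued matrix with dimnames), `genes` and `aois`.
#' @examples
#' cm <- count_matrix(matrix(c(3, 1, 0, 7), 2,
#'                    dimnames = list(c("A", "B"), c("aoi1", "aoi2"))))
#' cm$counts
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         aois = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(genes) || is.null(aois)) {
    abort_dsp("count matrix needs gene (row) and AOI (column) identifiers",
              "dsp_format_error")
  }
  if (length(genes) != nrow(counts) || length(aois) != ncol(counts)) {
    abort_dsp("gene/AOI identifier lengths do not match matrix dimensions",
              "dsp_format_error")
  }
  if (anyDuplicated(genes)) {
    abort_dsp(sprintf("duplicate gene symbol: '%s'",
                      genes[duplicated(genes)][1]), "dsp_format_error")
  }
  if (anyDuplicated(aois)) {
    abort_dsp(sprintf("duplicate AOI id: '%s'", aois[duplicated(aois)][1]),
              "dsp_format_error")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_dsp(sprintf(
      "counts must be non-negative integers; offending value %s at gene '%s', AOI '%s'",
      format(counts[bad[1, 1], bad[1, 2]]), genes[bad[1, 1]], aois[bad[1, 2]]),
      "dsp_value_error")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(genes, aois)
  structure(list(counts = counts, genes = genes, aois = aois),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d AOIs\n",
              length(x$genes), length(x$aois)))
  invisible(x)
}

#' Read a count matrix and its AOI metadata from TSV files
#'
#' The count file has a header row of AOI ids with gene symbols in the first
#' column; the metadata file has columns `aoi_id`, `region`, `condition`,
#' `treatment`, `replicate`, `mouse_id`. Every AOI in the matrix must have
#' exactly one metadata row; metadata rows are returned in matrix column
#' order.
#'
#' @param path path to the counts TSV.
#' @param metadata_path path to the AOI metadata TSV.
#' @return A list with elements `counts` (a [count_matrix()]) and
#'   `annotations` (a data.frame).
#' @export
read_count_matrix <- function(path, metadata_path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    abort_dsp("counts file must have a gene column plus at least one AOI",
              "dsp_format_error")
  }
  genes <- as.character(raw[[1]])
  aois <- colnames(raw)[-1]
  if (anyDuplicated(aois)) {
    abort_dsp(sprintf("counts file header repeats AOI id '%s'",
                      aois[duplicated(aois)][1]), "dsp_format_error")
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- genes
  cm <- count_matrix(mat, genes = genes, aois = aois)

  ann <- utils::read.delim(metadata_path, header = TRUE,
                           stringsAsFactors = FALSE)
  check_annotations(ann)
  orphan <- setdiff(cm$aois, ann$aoi_id)
  if (length(orphan) > 0) {
    abort_dsp(sprintf("AOI(s) in counts but missing from metadata: %s",
                      paste(orphan, collapse = ", ")), "dsp_linkage_error")
  }
  ann <- ann[match(cm$aois, ann$aoi_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(counts = cm, annotations = ann)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' Inverse of [read_count_matrix()]; `write` then `read` reproduces the
#' matrix exactly.
#'
#' @param cm a [count_matrix()].
#' @param path output path for the counts TSV.
#' @param annotations optional AOI metadata data.frame.
#' @param metadata_path output path for the metadata TSV (required when
#'   `annotations` is given).
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(cm, path, annotations = NULL,
                               metadata_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = cm$genes, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # counts are integral by construction; write them without exponent notation
  df[cm$aois] <- lapply(df[cm$aois], function(x) sprintf("%d", as.integer(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  if (!is.null(annotations)) {
    if (is.null(metadata_path)) {
      abort_dsp("metadata_path required when writing annotations",
                "dsp_io_error")
    }
    write_table(annotations, metadata_path)
  }
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `source` (named character vector
#'   of the per-set description fields).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  src <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort_dsp(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                        i, length(fields)), "dsp_format_error")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort_dsp(sprintf("GMT line %d ('%s') has an empty member list",
                        i, fields[1]), "dsp_format_error")
    }
    nm[i] <- fields[1]
    src[i] <- fields[2]
    sets[[i]] <- members
  }
  if (anyDuplicated(nm)) {
    abort_dsp(sprintf("duplicate gene-set name '%s'", nm[duplicated(nm)][1]),
              "dsp_format_error")
  }
  names(sets) <- nm
  names(src) <- nm
  structure(list(sets = sets, source = src), class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param gsc a `gene_set_collection` as returned by [read_gmt()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$source[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene-disease association table
#'
#' Rows are deduplicated case-insensitively (human resources list symbols in
#' upper case, mouse symbols in title case); the first-seen casing is kept.
#'
#' @param path TSV with columns `gene` and `disease` (header required).
#' @return data.frame with columns `gene`, `disease`.
#' @export
read_associations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "disease") %in% names(df))) {
    abort_dsp("association table needs columns 'gene' and 'disease'",
              "dsp_format_error")
  }
  key <- paste(toupper(df$gene), toupper(df$disease), sep = "\r")
  df <- df[!duplicated(key), c("gene", "disease"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a result table as a deterministic TSV
#'
#' Columns are written in their existing order; double columns use fixed
#' scientific notation with 6 significant digits so that reruns with the
#' same seed produce byte-identical files.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  out <- as.data.frame(lapply(df, format_column), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
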