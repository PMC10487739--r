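#' Per-AOI Q3 scaling factors
#'
#' The third-quartile (Q3) normalization convention for digital spatial
#' profiling: each AOI's factor is its 75th percentile count over all genes,
#' divided by the geometric mean of those percentiles across AOIs. Dividing
#' an AOI's counts by its factor equalizes the per-AOI Q3 at the geometric
#' mean of the raw Q3s. Percentiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param cm a [count_matrix()].
#' @return Named numeric vector of positive per-AOI factors.
#' @examples
#' cm <- count_matrix(matrix(c(0, 1, 2, 3, 0, 4, 8, 12), 4,
#'                    dimnames = list(paste0("g", 1:4), c("a", "b"))))
#' q3_factors(cm)  # Q3s are 2.25 and 9 -> factors 0.5 and 2
#' @export
q3_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  q3 <- apply(cm$counts, 2, stats::quantile, probs = 0.75, names = FALSE,
              type = 7)
  if (any(q3 <= 0)) {
    abort_dsp(sprintf("AOI '%s' has a non-positive 75th percentile; cannot Q3-normalize",
                      cm$aois[which(q3 <= 0)[1]]), "dsp_degenerate_aoi_error")
  }
  f <- q3 / geometric_mean(q3)
  names(f) <- cm$aois
  f
}

#' Q3-normalize a count matrix
#'
#' Divides each AOI's counts by its [q3_factors()] factor and log2-transforms
#' the result with a +1 pseudocount (zeros stay zero). The log2 values are
#' the input to every downstream statistic.
#'
#' @param cm a [count_matrix()].
#' @return An object of class `normalized_matrix`: list with `genes`,
#'   `aois`, `values` (normalized counts), `log2_values`, and `q3_factors`.
#' @export
q3_normalize <- function(cm) {
  f <- q3_factors(cm)
  values <- sweep(cm$counts, 2, f, "/")
  structure(list(genes = cm$genes, aois = cm$aois, values = values,
                 log2_values = log2(values + 1), q3_factors = f),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (Q3): %d genes x %d AOIs\n",
              length(x$genes), length(x$aois)))
  invisible(x)
}
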