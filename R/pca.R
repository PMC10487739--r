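#' Storey q-values
#'
#' FDR-scale adjusted significance measures with the null proportion
#' estimated as `pi0 = min(1, mean(p > lambda) / (1 - lambda))`; q-values
#' are `pi0 * m * p / rank(p)`, made monotone by a running minimum from the
#' largest p downward.
#'
#' @param p vector of p-values.
#' @param lambda tuning point for the null-proportion estimate (fixed at
#'   0.5 by default, for determinism).
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_dsp("p-values must lie in [0, 1]", "dsp_value_error")
  }
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  q <- pmin(pi0 * m * p / rank(p, ties.method = "max"), 1)
  ord <- order(p, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}

#' Per-gene one-way ANOVA screen
#'
#' Fits a one-way ANOVA at each gene on the log2 Q3-normalized values, with
#' the experimental group (region x condition x treatment by default) as
#' the factor, and converts the p-values to [storey_qvalues()]. Genes with
#' q < 0.05 are the input set for [run_pca()]. The F statistics are
#' computed vectorized over genes (between/within sums of squares) and
#' match `stats::aov()` gene by gene.
#'
#' @param norm a `normalized_matrix`.
#' @param grouping per-AOI factor labels, aligned to `norm$aois`; every
#'   level needs at least 2 AOIs and there must be at least 2 levels.
#' @return data.frame with columns `gene`, `F_stat`, `p_value`, `q_value`.
#' @export
anova_filter <- function(norm, grouping) {
  g <- as.factor(grouping)
  if (length(g) != length(norm$aois)) {
    abort_dsp("grouping length must equal the number of AOIs",
              "dsp_design_error")
  }
  tab <- table(g)
  if (length(tab) < 2) {
    abort_dsp("ANOVA needs at least 2 factor levels", "dsp_design_error")
  }
  if (any(tab < 2)) {
    abort_dsp(sprintf("factor level '%s' has fewer than 2 AOIs",
                      names(tab)[which(tab < 2)[1]]), "dsp_design_error")
  }
  x <- norm$log2_values
  n <- ncol(x)
  k <- length(tab)
  mem <- stats::model.matrix(~ g - 1)
  group_sums <- x %*% mem
  group_means <- sweep(group_sums, 2, as.numeric(tab), "/")
  grand_mean <- rowMeans(x)
  ssb <- rowSums(sweep(group_means, 1, grand_mean, "-")^2 %*%
                   diag(as.numeric(tab), k))
  sst <- rowSums(sweep(x, 1, grand_mean, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  f_stat <- (ssb / df1) / pmax(ssw / df2, 1e-300)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  data.frame(gene = norm$genes, F_stat = f_stat, p_value = p,
             q_value = storey_qvalues(p), stringsAsFactors = FALSE)
}

#' Principal component analysis of filtered expression profiles
#'
#' Projects samples (or group centroids, when `average_replicates = TRUE`,
#' matching the replicate-averaged view of the study's figures) onto the
#' principal components of the gene-centered, unscaled log2 matrix
#' restricted to `kept_genes`.
#'
#' @param norm a `normalized_matrix`.
#' @param kept_genes character vector of genes to retain (typically
#'   `q_value < 0.05` from [anova_filter()]).
#' @param annotations AOI metadata; required when `average_replicates`.
#' @param average_replicates average log2 values across replicate AOIs of
#'   each region-by-group cell before the PCA, so each projected point is a
#'   group profile.
#' @return Object of class `pca_result`: list with `coordinates` (rows:
#'   samples or groups), `explained_variance` (fractions, nonincreasing),
#'   `sdev`, `kept_genes`, and `averaged`.
#' @export
run_pca <- function(norm, kept_genes, annotations = NULL,
                    average_replicates = FALSE) {
  kept_genes <- intersect(norm$genes, kept_genes)
  if (length(kept_genes) == 0) {
    abort_dsp("no genes pass the filter; cannot run PCA", "dsp_filter_error")
  }
  x <- norm$log2_values[kept_genes, , drop = FALSE]
  if (average_replicates) {
    if (is.null(annotations)) {
      abort_dsp("annotations required to average replicates",
                "dsp_design_error")
    }
    ann <- annotations[match(norm$aois, annotations$aoi_id), , drop = FALSE]
    grp <- paste(ann$region, ann$condition, ann$treatment, sep = "_")
    levels <- unique(grp)
    x <- vapply(levels, function(l) {
      rowMeans(x[, grp == l, drop = FALSE])
    }, numeric(nrow(x)))
    colnames(x) <- levels
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x, explained_variance = ev,
                 sdev = pc$sdev, kept_genes = kept_genes,
                 averaged = average_replicates),
            class = "pca_result")
}

#' Group-centroid distances in the PC1-PC2 plane
#'
#' For each region, computes the Euclidean distance between the
#' flight-saline and ground-saline centroids (`d_sal`), between the
#' flight-antioxidant and ground-antioxidant centroids (`d_buoe`), and the
#' attenuation ratio `d_buoe / d_sal`. A ratio below 1 means the
#' antioxidant moved the flight transcriptome closer to its matched ground
#' control.
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param annotations AOI metadata (used to map coordinate rows to groups
#'   when replicates were not averaged).
#' @return data.frame with columns `region`, `d_sal`, `d_buoe`,
#'   `attenuation_ratio` (NA when `d_sal` is 0).
#' @export
centroid_distances <- function(pca, annotations) {
  coords <- pca$coordinates[, seq_len(min(2, ncol(pca$coordinates))),
                            drop = FALSE]
  if (pca$averaged) {
    parts <- strsplit(rownames(coords), "_", fixed = TRUE)
    region <- vapply(parts, `[`, character(1), 1)
    grp <- vapply(parts, function(p) paste(p[2], p[3], sep = "-"),
                  character(1))
  } else {
    ann <- annotations[match(rownames(coords), annotations$aoi_id), ,
                       drop = FALSE]
    region <- ann$region
    grp <- group_label(ann)
  }
  centroid <- function(r, g) {
    sel <- region == r & grp == g
    if (!any(sel)) {
      abort_dsp(sprintf("group %s missing in region %s", g, r),
                "dsp_report_error")
    }
    colMeans(coords[sel, , drop = FALSE])
  }
  rows <- lapply(unique(region), function(r) {
    d_sal <- sqrt(sum((centroid(r, "FLT-SAL") - centroid(r, "GC-SAL"))^2))
    d_buoe <- sqrt(sum((centroid(r, "FLT-BuOE") - centroid(r, "GC-BuOE"))^2))
    data.frame(region = r, d_sal = d_sal, d_buoe = d_buoe,
               attenuation_ratio = if (d_sal > 0) d_buoe / d_sal else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
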