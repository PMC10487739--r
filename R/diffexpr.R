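#' Define a differential-expression contrast within one region
#'
#' Groups are named `"COND-TRT"` (e.g. `"FLT-SAL"`). The sign convention is
#' test minus reference, so the flight contrast is
#' `de_contrast(region, test_group = "FLT-SAL", ref_group = "GC-SAL")` and
#' the in-flight antioxidant contrast is
#' `de_contrast(region, "FLT-BuOE", "FLT-SAL")`; with that convention,
#' attenuation of a flight effect shows up as opposite log2 fold-change
#' signs between the two contrasts.
#'
#' @param region one of `"CA"`, `"DG"`, `"FCT"`, `"CT"` (or any region label
#'   present in the annotations).
#' @param test_group,ref_group group labels `"COND-TRT"`; must differ.
#' @return Object of class `de_contrast` with a human-readable `label`.
#' @export
de_contrast <- function(region, test_group, ref_group) {
  if (identical(test_group, ref_group)) {
    abort_dsp("test and reference groups must differ", "dsp_contrast_error")
  }
  structure(list(region = region, test_group = test_group,
                 ref_group = ref_group,
                 label = sprintf("%s: %s vs %s", region, test_group,
                                 ref_group)),
            class = "de_contrast")
}

# Columns (AOI indices) of `norm` belonging to each side of a contrast.
contrast_columns <- function(norm, annotations, contrast) {
  ann <- annotations[match(norm$aois, annotations$aoi_id), , drop = FALSE]
  in_region <- ann$region == contrast$region
  grp <- group_label(ann)
  test <- which(in_region & grp == contrast$test_group)
  ref <- which(in_region & grp == contrast$ref_group)
  if (length(test) == 0 || length(ref) == 0) {
    abort_dsp(sprintf("contrast '%s': group with 0 AOIs", contrast$label),
              "dsp_contrast_error")
  }
  list(test = test, ref = ref)
}

#' Per-gene log2 fold change for a contrast
#'
#' Difference of group means of the log2 Q3-normalized values (test minus
#' reference) — the same scale the t statistic is computed on.
#'
#' @param norm a `normalized_matrix` from [q3_normalize()].
#' @param annotations AOI metadata data.frame.
#' @param contrast a [de_contrast()].
#' @return Named numeric vector (one value per gene).
#' @export
log2_fold_change <- function(norm, annotations, contrast) {
  cols <- contrast_columns(norm, annotations, contrast)
  rowMeans(norm$log2_values[, cols$test, drop = FALSE]) -
    rowMeans(norm$log2_values[, cols$ref, drop = FALSE])
}

# Vectorized two-sided Welch t-test on rows of x (test) vs y (reference).
# A variance floor of 1e-12 keeps zero-variance genes finite: equal constant
# groups give t = 0, p = 1; unequal constant groups give |t| huge, p ~ 0.
welch_t_rows <- function(x, y, var_floor = 1e-12) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- pmax((rowSums(x * x) - n1 * m1^2) / (n1 - 1), var_floor)
  v2 <- pmax((rowSums(y * y) - n2 * m2^2) / (n2 - 1), var_floor)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

#' Unpaired Welch t-test per gene for a contrast
#'
#' Two-sided unequal-variance (Welch) t-test on the log2 Q3-normalized
#' values, vectorized over genes. Each group needs at least 2 AOIs.
#'
#' @inheritParams log2_fold_change
#' @return data.frame with columns `gene`, `t_stat`, `df`, `p_value`.
#' @export
t_test_de <- function(norm, annotations, contrast) {
  cols <- contrast_columns(norm, annotations, contrast)
  if (length(cols$test) < 2 || length(cols$ref) < 2) {
    abort_dsp(sprintf("contrast '%s': each group needs >= 2 AOIs",
                      contrast$label), "dsp_contrast_error")
  }
  w <- welch_t_rows(norm$log2_values[, cols$test, drop = FALSE],
                    norm$log2_values[, cols$ref, drop = FALSE])
  data.frame(gene = norm$genes, t_stat = w$t, df = w$df, p_value = w$p,
             stringsAsFactors = FALSE)
}

# All distinct assignments of `n1` of the pooled columns to the test group,
# as a list of index vectors; used when the exact permutation space is
# smaller than the requested number of permutations. Relabelings equivalent
# to the observed one (the identity split and, for equal group sizes, its
# complement, which yields identical |t|) are excluded: leaving them in
# pools each gene's own observed p-value into the null and imposes a floor
# of (number of equivalent splits) / (number of splits) on every q-value.
all_label_splits <- function(n, n1) {
  cmb <- utils::combn(n, n1)
  splits <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  Filter(function(s) !is_identity_split(s, n, n1), splits)
}

is_identity_split <- function(s, n, n1) {
  identical(sort(s), seq_len(n1)) ||
    (n == 2 * n1 && identical(sort(s), seq.int(n1 + 1, n)))
}

#' Permutation-based q-values for a contrast
#'
#' Group labels are permuted within the contrast's AOIs `n_perm` times; per
#' permutation the per-gene Welch p-values are recomputed, giving a pooled
#' null distribution. The q-value of gene `g` is the plug-in FDR estimate
#' \deqn{q(g) = \frac{\mathrm{mean}_{perm}\,\#\{p_{null} \le p_g\}}{\#\{p_{obs} \le p_g\}}}
#' clipped to `[0, 1]` and made monotone nondecreasing in the p-value rank
#' (running minimum from the largest p downward). Relabelings equivalent to
#' the observed one (identity, and its complement for equal group sizes)
#' are excluded from the null: they would reinsert the observed p-values
#' into the null pool and bound every q-value away from zero in small
#' designs. When the number of distinct label splits is at most `n_perm`,
#' all distinct non-equivalent splits are enumerated instead (with a
#' warning); 3-vs-3 groups, for example, admit only `choose(6, 3) = 20`
#' splits, of which 18 are informative.
#'
#' @inheritParams log2_fold_change
#' @param n_perm number of label permutations (>= 100 unless enumeration
#'   takes over).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with columns `gene`, `p_value`, `q_value`.
#' @export
permutation_qvalues <- function(norm, annotations, contrast, n_perm = 1000,
                                seed = 1L) {
  if (n_perm < 100) {
    abort_dsp("n_perm must be >= 100", "dsp_config_error")
  }
  cols <- contrast_columns(norm, annotations, contrast)
  pooled <- c(cols$test, cols$ref)
  n1 <- length(cols$test)
  x <- norm$log2_values[, pooled, drop = FALSE]
  obs <- welch_t_rows(x[, seq_len(n1), drop = FALSE],
                      x[, -seq_len(n1), drop = FALSE])

  n_distinct <- choose(length(pooled), n1)
  set.seed(seed)
  if (n_distinct <= n_perm) {
    warning(sprintf(
      "only %d distinct label splits (< n_perm = %d); enumerating all of them",
      n_distinct, n_perm))
    splits <- all_label_splits(length(pooled), n1)
  } else {
    splits <- vector("list", n_perm)
    for (i in seq_len(n_perm)) {
      repeat {
        s <- sample.int(length(pooled), n1)
        if (!is_identity_split(s, length(pooled), n1)) break
      }
      splits[[i]] <- s
    }
  }
  null_p <- perm_null_pvalues(x, splits, n1)
  data.frame(gene = norm$genes, p_value = obs$p,
             q_value = plugin_qvalues(obs$p, null_p, length(splits)),
             stringsAsFactors = FALSE)
}

# Null p-values for every split at once via matrix products:
# group sums are X %*% M where M is the 0/1 split membership matrix.
perm_null_pvalues <- function(x, splits, n1, var_floor = 1e-12) {
  n <- ncol(x)
  n2 <- n - n1
  m <- matrix(0, n, length(splits))
  for (j in seq_along(splits)) m[splits[[j]], j] <- 1
  tot <- rowSums(x)
  tot2 <- rowSums(x * x)
  s1 <- x %*% m
  q1 <- (x * x) %*% m
  m1 <- s1 / n1
  m2 <- (tot - s1) / n2
  v1 <- pmax((q1 - n1 * m1^2) / (n1 - 1), var_floor)
  v2 <- pmax(((tot2 - q1) - n2 * m2^2) / (n2 - 1), var_floor)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t_stat), df)
}

# Plug-in FDR: for each observed p, V = mean null exceedances per
# permutation, R = observed exceedances; q = V/R clipped and monotonized.
plugin_qvalues <- function(p_obs, null_p, n_splits) {
  null_sorted <- sort(as.vector(null_p))
  v <- findInterval(p_obs, null_sorted) / n_splits
  r <- rank(p_obs, ties.method = "max")
  q <- pmin(v / r, 1)
  ord <- order(p_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}

#' Call differentially expressed genes at fixed thresholds
#'
#' A gene is a DEG when `q_value < q_threshold` and
#' `|log2FC| > lfc_threshold` (both strict); the defaults, q < 0.05 and
#' |log2 FC| > 0.585 (fold change > 1.5x), are the reference study's
#' criteria. Direction is the sign of the log2 fold change for DEGs and
#' `"none"` otherwise.
#'
#' @param log2fc named per-gene log2 fold changes.
#' @param qvalues data.frame from [permutation_qvalues()] (columns `gene`,
#'   `p_value`, `q_value`), aligned to the same genes.
#' @param t_stats optional data.frame from [t_test_de()] to carry `t_stat`.
#' @param q_threshold,lfc_threshold strict DEG thresholds.
#' @return A DE result table: data.frame with columns `gene`, `log2FC`,
#'   `t_stat`, `p_value`, `q_value`, `is_deg`, `direction`.
#' @export
call_degs <- function(log2fc, qvalues, t_stats = NULL, q_threshold = 0.05,
                      lfc_threshold = 0.585) {
  genes <- qvalues$gene
  if (!identical(names(log2fc), genes)) {
    if (is.null(names(log2fc)) && length(log2fc) == length(genes)) {
      names(log2fc) <- genes
    } else {
      log2fc <- log2fc[genes]
      if (anyNA(log2fc)) {
        abort_dsp("log2fc and qvalues cover different genes",
                  "dsp_alignment_error")
      }
    }
  }
  is_deg <- qvalues$q_value < q_threshold & abs(log2fc) > lfc_threshold
  direction <- ifelse(!is_deg, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(gene = genes, log2FC = unname(log2fc),
             t_stat = if (is.null(t_stats)) NA_real_ else t_stats$t_stat,
             p_value = qvalues$p_value, q_value = qvalues$q_value,
             is_deg = is_deg, direction = direction,
             stringsAsFactors = FALSE)
}

#' Run the full differential-expression analysis for one contrast
#'
#' Convenience wrapper: log2 fold changes, Welch t-tests, permutation
#' q-values and DEG calling in one call.
#'
#' @inheritParams permutation_qvalues
#' @param q_threshold,lfc_threshold strict DEG thresholds (see
#'   [call_degs()]).
#' @return A DE result table (see [call_degs()]) with the contrast label in
#'   attribute `"contrast"`.
#' @export
run_de <- function(norm, annotations, contrast, n_perm = 1000, seed = 1L,
                   q_threshold = 0.05, lfc_threshold = 0.585) {
  lfc <- log2_fold_change(norm, annotations, contrast)
  tt <- t_test_de(norm, annotations, contrast)
  qv <- permutation_qvalues(norm, annotations, contrast, n_perm = n_perm,
                            seed = seed)
  res <- call_degs(lfc, qv, t_stats = tt, q_threshold = q_threshold,
                   lfc_threshold = lfc_threshold)
  attr(res, "contrast") <- contrast$label
  res
}
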