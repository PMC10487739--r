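# Shared fixtures and independent oracles, all built in code.

# Tiny count matrix with annotations for IO tests.
tiny_dataset <- function() {
  counts <- matrix(c(3, 1, 0, 7), 2,
                   dimnames = list(c("GeneA", "GeneB"), c("aoi1", "aoi2")))
  ann <- data.frame(aoi_id = c("aoi1", "aoi2"),
                    region = c("CA", "CA"),
                    condition = c("GC", "FLT"),
                    treatment = c("SAL", "SAL"),
                    replicate = c(1L, 2L),
                    mouse_id = c("GC-SAL-m1", "FLT-SAL-m2"),
                    stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), annotations = ann)
}

# A normalized_matrix built directly from a log2-value matrix (factors 1),
# bypassing Q3 so DE tests control the exact values.
make_norm <- function(log2mat) {
  structure(list(genes = rownames(log2mat), aois = colnames(log2mat),
                 values = 2^log2mat - 1, log2_values = log2mat,
                 q3_factors = stats::setNames(rep(1, ncol(log2mat)),
                                              colnames(log2mat))),
            class = "normalized_matrix")
}

# Annotations for a single region with two groups laid out as the first
# n1 and last n2 columns.
two_group_ann <- function(aois, n1, region = "CA",
                          g1 = c("FLT", "SAL"), g2 = c("GC", "SAL")) {
  n <- length(aois)
  data.frame(aoi_id = aois, region = region,
             condition = c(rep(g1[1], n1), rep(g2[1], n - n1)),
             treatment = c(rep(g1[2], n1), rep(g2[2], n - n1)),
             replicate = c(seq_len(n1), seq_len(n - n1)),
             mouse_id = paste0("m", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Minimal DE result table for the attenuation operations.
make_de_table <- function(genes, deg_genes = character(0), lfc = NULL) {
  if (is.null(lfc)) lfc <- stats::setNames(rep(0, length(genes)), genes)
  data.frame(gene = genes, log2FC = unname(lfc[genes]),
             t_stat = NA_real_, p_value = NA_real_, q_value = NA_real_,
             is_deg = genes %in% deg_genes,
             direction = ifelse(genes %in% deg_genes,
                                ifelse(lfc[genes] > 0, "up", "down"), "none"),
             stringsAsFactors = FALSE)
}

# Brute-force two-sided Fisher oracle: enumerate every table with the
# observed margins via exact log-binomial coefficients and sum the
# probabilities of tables no more probable than the observed one (relative
# tie tolerance 1e-7, the minimum-likelihood convention).
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, m[1, 1]) + lchoose(r2, c1 - m[1, 1]) -
                 lchoose(n, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper-tail oracle for ORA: explicit enumeration of the
# tail via exact log-binomial coefficients.
hyper_tail_oracle <- function(k, set_size, list_size, universe) {
  if (k <= 0) return(1)
  hi <- min(set_size, list_size)
  if (k > hi) return(0)
  xs <- k:hi
  sum(exp(lchoose(set_size, xs) + lchoose(universe - set_size, list_size - xs) -
            lchoose(universe, list_size)))
}

# Cache of heavy planted-effect simulation runs shared by the acceptance
# tests (the attenuation-recovery and the FDR/recall experiments use the
# same study conditions).
.run_cache <- new.env(parent = emptyenv())

planted_run <- function(alpha, seed) {
  key <- sprintf("a%g_s%d", alpha, seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sim <- simulate_dataset(simulation_config(
    n_genes = 5000, regions = "CA", n_replicates = 6,
    n_flight_degs_per_region = 200, flight_effect_size = 2,
    dispersion = 10, attenuation_alpha = alpha, seed = 100000 + seed))
  norm <- q3_normalize(sim$counts)
  space_de <- suppressWarnings(run_de(
    norm, sim$annotations, de_contrast("CA", "FLT-SAL", "GC-SAL"),
    n_perm = 1000, seed = seed))
  buoe_de <- suppressWarnings(run_de(
    norm, sim$annotations, de_contrast("CA", "FLT-BuOE", "FLT-SAL"),
    n_perm = 1000, seed = seed + 500))
  out <- list(truth = sim$truth, space_de = space_de, buoe_de = buoe_de)
  .run_cache[[key]] <- out
  out
}
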