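#' Direction-concordance overlap of two DEG sets
#'
#' Intersects the DEG sets of a flight contrast and an in-flight antioxidant
#' contrast (both over the same gene universe) and partitions the overlap by
#' agreement of the log2 fold-change signs. Opposite signs at a shared DEG
#' are the signature of attenuation: the antioxidant pushes the gene back
#' toward its ground-control level.
#'
#' @param space_de,buoe_de DE result tables (see [call_degs()]) for the
#'   flight-induced and antioxidant-induced contrasts.
#' @return Object of class `overlap_counts`: list with `n_opposite`,
#'   `n_same`, `n_space_degs`, `n_buoe_degs`, `N` (the sum of the last two),
#'   and the gene universe size `G`.
#' @export
overlap_directions <- function(space_de, buoe_de) {
  if (!setequal(space_de$gene, buoe_de$gene)) {
    nd <- length(union(setdiff(space_de$gene, buoe_de$gene),
                       setdiff(buoe_de$gene, space_de$gene)))
    abort_dsp(sprintf(
      "DE tables cover different gene universes (symmetric difference: %d genes)",
      nd), "dsp_alignment_error")
  }
  buoe_de <- buoe_de[match(space_de$gene, buoe_de$gene), , drop = FALSE]
  shared <- space_de$is_deg & buoe_de$is_deg
  opposite <- shared & sign(space_de$log2FC) * sign(buoe_de$log2FC) < 0
  same <- shared & sign(space_de$log2FC) * sign(buoe_de$log2FC) > 0
  structure(list(n_opposite = sum(opposite), n_same = sum(same),
                 n_space_degs = sum(space_de$is_deg),
                 n_buoe_degs = sum(buoe_de$is_deg),
                 N = sum(space_de$is_deg) + sum(buoe_de$is_deg),
                 G = nrow(space_de)),
            class = "overlap_counts")
}

#' Build the direction-concordance contingency matrix
#'
#' With `N` the total number of flight DEGs plus antioxidant DEGs, the 2x2
#' table is
#' \deqn{\begin{pmatrix} X_{11} & N - X_{11} \\ X_{21} & N - X_{21} \end{pmatrix}}
#' where `X11` is the number of flight DEGs changing in the opposite
#' direction as antioxidant DEGs and `X21` the number changing in the same
#' direction. Both row sums equal `N` by construction. Note the off-cells
#' complement against `N`, not against the overlap; this reproduces the
#' reference construction exactly. An orthodox alternative test of the same
#' null is available as the binomial test in [attenuation_test()].
#'
#' @param overlap an `overlap_counts` object from [overlap_directions()].
#' @return 2x2 integer matrix with dimnames
#'   `(opposite/same) x (count/complement)`.
#' @export
build_contingency <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_counts"))
  m <- matrix(c(overlap$n_opposite, overlap$N - overlap$n_opposite,
                overlap$n_same, overlap$N - overlap$n_same),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("opposite", "same"),
                              c("count", "complement")))
  storage.mode(m) <- "integer"
  m
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on all margins, sums the hypergeometric probabilities of
#' every table no more probable than the observed one (the
#' minimum-likelihood two-sided convention, with a relative tie tolerance
#' of 1e-7 as in [stats::fisher.test()]). Implemented by direct enumeration
#' of the hypergeometric support.
#'
#' @param m 2x2 matrix of non-negative counts.
#' @return The two-sided p-value in `(0, 1]`. An all-zero table returns 1
#'   with a warning.
#' @examples
#' fisher_exact(matrix(c(20, 80, 5, 95), 2, byrow = TRUE))
#' @export
fisher_exact <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    abort_dsp("fisher_exact needs a 2x2 matrix of non-negative integers",
              "dsp_value_error")
  }
  if (sum(m) == 0) {
    warning("all-zero contingency matrix; returning p = 1")
    return(1)
  }
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Gene-shuffling permutation null for opposite-direction overlaps
#'
#' Reproduces the shuffling null: in each of `B` iterations the full
#' analyzed gene list is randomly permuted (seeded Fisher-Yates via
#' [sample.int()]); the top `N_up` genes of the shuffled list become
#' pseudo-upregulated antioxidant DEGs and the bottom `N_down` genes
#' pseudo-downregulated ones, where `N_up`/`N_down` are the actual
#' antioxidant DEG direction counts. The number of actual flight DEGs
#' overlapping the pseudo-DEGs in the opposite direction is recorded, and
#' \deqn{p_{emp} = \frac{1 + \#\{null \ge observed\}}{1 + B}.}
#'
#' @param space_de,buoe_de DE result tables over the same gene universe.
#' @param B number of shuffles (default 1000).
#' @param seed integer seed.
#' @return Object of class `permutation_null_result`: list with
#'   `observed_opposite`, `null_counts` (length `B`), `empirical_p`,
#'   `N_up`, `N_down`, and `seed`.
#' @export
permutation_null <- function(space_de, buoe_de, B = 1000, seed = 1L) {
  if (B < 1) abort_dsp("B must be >= 1", "dsp_config_error")
  overlap <- overlap_directions(space_de, buoe_de)
  buoe_de <- buoe_de[match(space_de$gene, buoe_de$gene), , drop = FALSE]
  G <- nrow(space_de)
  n_up <- sum(buoe_de$is_deg & buoe_de$log2FC > 0)
  n_down <- sum(buoe_de$is_deg & buoe_de$log2FC < 0)
  if (n_up + n_down > G) {
    abort_dsp("N_up + N_down exceeds the gene universe size",
              "dsp_config_error")
  }
  space_up <- space_de$is_deg & space_de$log2FC > 0
  space_down <- space_de$is_deg & space_de$log2FC < 0

  set.seed(seed)
  null_counts <- integer(B)
  for (b in seq_len(B)) {
    pos <- sample.int(G)  # pos[g]: position of gene g in the shuffled list
    pseudo_up <- pos <= n_up
    pseudo_down <- pos > G - n_down
    null_counts[b] <- sum(space_down & pseudo_up) +
      sum(space_up & pseudo_down)
  }
  observed <- overlap$n_opposite
  structure(list(observed_opposite = observed, null_counts = null_counts,
                 empirical_p = (1 + sum(null_counts >= observed)) / (1 + B),
                 N_up = n_up, N_down = n_down, seed = seed),
            class = "permutation_null_result")
}

#' Full attenuation analysis for one region
#'
#' Combines [overlap_directions()], [build_contingency()],
#' [fisher_exact()], an exact binomial test of opposite vs same direction
#' among the overlapping DEGs (the orthodox test of the stated null that
#' the two proportions are equal), and the gene-shuffling
#' [permutation_null()].
#'
#' @inheritParams permutation_null
#' @param region label copied into the output row.
#' @return One-row data.frame: `region`, DEG and overlap counts, the four
#'   contingency cells, `fisher_p`, `binomial_p`, `N_up`, `N_down`,
#'   `perm_p`.
#' @export
attenuation_test <- function(space_de, buoe_de, B = 1000, seed = 1L,
                             region = NA_character_) {
  overlap <- overlap_directions(space_de, buoe_de)
  ct <- build_contingency(overlap)
  fisher_p <- fisher_exact(ct)
  n_overlap <- overlap$n_opposite + overlap$n_same
  binom_p <- if (n_overlap > 0) {
    stats::binom.test(overlap$n_opposite, n_overlap, p = 0.5)$p.value
  } else NA_real_
  pn <- permutation_null(space_de, buoe_de, B = B, seed = seed)
  data.frame(region = region,
             n_space_degs = overlap$n_space_degs,
             n_buoe_degs = overlap$n_buoe_degs,
             n_opposite = overlap$n_opposite, n_same = overlap$n_same,
             X11 = ct[1, 1], X12 = ct[1, 2], X21 = ct[2, 1], X22 = ct[2, 2],
             fisher_p = fisher_p, binomial_p = binom_p,
             N_up = pn$N_up, N_down = pn$N_down,
             perm_observed = pn$observed_opposite, perm_p = pn$empirical_p,
             stringsAsFactors = FALSE)
}
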