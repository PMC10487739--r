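test_that("the vectorized ANOVA screen matches stats::aov gene by gene", {
  set.seed(51)
  x <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("a", 1:12)))
  norm <- make_norm(x)
  g <- rep(c("A", "B", "C"), each = 4)
  af <- anova_filter(norm, g)
  for (i in 1:8) {
    sm <- summary(stats::aov(x[i, ] ~ factor(g)))[[1]]
    expect_equal(af$F_stat[i], sm[["F value"]][1], tolerance = 1e-10)
    expect_equal(af$p_value[i], sm[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("ANOVA reduces to the squared pooled t with two groups and is flat under equality", {
  x <- rbind(g1 = c(5, 6, 7, 1, 2, 3), g2 = rep(4, 6))
  colnames(x) <- paste0("a", 1:6)
  af <- anova_filter(make_norm(x), rep(c("A", "B"), each = 3))
  tt <- stats::t.test(c(5, 6, 7), c(1, 2, 3), var.equal = TRUE)
  expect_equal(af$F_stat[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(af$F_stat[2], 0)
  expect_equal(af$p_value[2], 1)

  expect_error(anova_filter(make_norm(x), c("A", "A", "A", "A", "A", "B")),
               class = "dsp_design_error")
  expect_error(anova_filter(make_norm(x), rep("A", 6)),
               class = "dsp_design_error")
})

test_that("Storey q-values are valid, monotone, and conservative under the null", {
  set.seed(52)
  p <- runif(2000)
  q <- storey_qvalues(p)
  expect_true(all(q >= 0 & q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= 0))
  expect_lte(mean(q < 0.05), 0.01)
  expect_error(storey_qvalues(c(0.5, 1.2)), class = "dsp_value_error")
})

test_that("PCA conserves variance and reproduces sample geometry", {
  set.seed(53)
  x <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("g", 1:100), paste0("a", 1:10)))
  x[, 2] <- x[, 1]  # two identical samples
  norm <- make_norm(x)
  pca <- run_pca(norm, rownames(x))
  expect_equal(pca$coordinates["a1", ], pca$coordinates["a2", ],
               tolerance = 1e-9)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-9)

  centered <- scale(t(x), center = TRUE, scale = FALSE)
  expect_equal(sum(pca$coordinates^2), sum(centered^2), tolerance = 1e-9)
  # isometry with all components kept
  expect_equal(as.matrix(dist(pca$coordinates)), as.matrix(dist(centered)),
               tolerance = 1e-8)

  # gene order cannot matter (coordinates fixed up to component sign)
  shuffled <- norm
  ord <- sample(nrow(x))
  shuffled$log2_values <- shuffled$log2_values[ord, ]
  shuffled$values <- shuffled$values[ord, ]
  shuffled$genes <- shuffled$genes[ord]
  pca2 <- run_pca(shuffled, rownames(x))
  for (j in seq_len(ncol(pca$coordinates))) {
    expect_equal(abs(pca$coordinates[, j]), abs(pca2$coordinates[, j]),
                 tolerance = 1e-8)
  }
  expect_error(run_pca(norm, character(0)), class = "dsp_filter_error")
})

test_that("centroid distances capture planted attenuation geometry", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 800, regions = c("CA", "DG"), n_flight_degs_per_region = 80,
    flight_effect_size = 2, attenuation_alpha = 1, seed = 55))
  norm <- q3_normalize(sim$counts)
  grouping <- paste(sim$annotations$region, sim$annotations$condition,
                    sim$annotations$treatment, sep = "_")
  af <- anova_filter(norm, grouping)
  pca <- run_pca(norm, af$gene[af$q_value < 0.05], sim$annotations,
                 average_replicates = TRUE)
  dr <- centroid_distances(pca, sim$annotations)
  expect_setequal(dr$region, c("CA", "DG"))
  expect_true(all(dr$d_sal >= 0 & dr$d_buoe >= 0))
  # full reversal: treated flight centroids sit near treated ground ones
  expect_true(all(dr$attenuation_ratio < 0.5))

  # a missing group is reported by name
  keep <- paste(sim$annotations$condition, sim$annotations$treatment,
                sep = "-") != "GC-BuOE"
  sub <- sim$annotations[keep, ]
  norm_sub <- norm
  norm_sub$aois <- norm$aois[keep]
  norm_sub$values <- norm$values[, keep]
  norm_sub$log2_values <- norm$log2_values[, keep]
  pca_sub <- run_pca(norm_sub, af$gene[af$q_value < 0.05], sub,
                     average_replicates = TRUE)
  expect_error(centroid_distances(pca_sub, sub), class = "dsp_report_error")
})
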