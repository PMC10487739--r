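test_that("log2 fold change is the difference of group means on log2 scale", {
  x <- rbind(gA = c(3, 3, 3, 1, 1, 1), gB = c(2, 2, 2, 2, 2, 2))
  colnames(x) <- paste0("a", 1:6)
  norm <- make_norm(x)
  ann <- two_group_ann(colnames(x), 3)
  lfc <- log2_fold_change(norm, ann, de_contrast("CA", "FLT-SAL", "GC-SAL"))
  expect_equal(unname(lfc), c(2, 0))
  # swapping test and reference negates the fold change
  rev <- log2_fold_change(norm, ann, de_contrast("CA", "GC-SAL", "FLT-SAL"))
  expect_equal(lfc, -rev)
})

test_that("the per-gene t-test matches stats::t.test (Welch) exactly", {
  x <- rbind(g1 = c(5, 6, 7, 1, 2, 3), g2 = c(2, 2, 2, 2, 2, 2))
  colnames(x) <- paste0("a", 1:6)
  norm <- make_norm(x)
  ann <- two_group_ann(colnames(x), 3)
  tt <- t_test_de(norm, ann, de_contrast("CA", "FLT-SAL", "GC-SAL"))
  ref <- stats::t.test(c(5, 6, 7), c(1, 2, 3))
  expect_equal(tt$t_stat[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value[1], ref$p.value, tolerance = 1e-12)
  # no difference and no variance: t = 0, p = 1
  expect_equal(tt$t_stat[2], 0)
  expect_equal(tt$p_value[2], 1)
})

test_that("t statistics are exchangeable under label permutation", {
  set.seed(31)
  x <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("a", 1:6)))
  cmb <- utils::combn(6, 3)
  splits <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  p1 <- dspattenuate:::perm_null_pvalues(x, splits, 3)
  # relabeling the columns permutes the splits but not the p multiset
  x2 <- x[, c(2, 5, 3, 6, 1, 4)]
  p2 <- dspattenuate:::perm_null_pvalues(x2, splits, 3)
  expect_equal(sort(as.vector(p1)), sort(as.vector(p2)), tolerance = 1e-12)
})

test_that("small designs enumerate all informative label splits", {
  splits <- dspattenuate:::all_label_splits(6, 3)
  expect_length(splits, 18)  # choose(6,3) minus identity and complement
  expect_false(any(vapply(splits, function(s)
    dspattenuate:::is_identity_split(s, 6, 3), logical(1))))

  sim <- simulate_dataset(simulation_config(n_genes = 50, regions = "CA",
                                            n_flight_degs_per_region = 5,
                                            seed = 41))
  norm <- q3_normalize(sim$counts)
  expect_warning(
    permutation_qvalues(norm, sim$annotations,
                        de_contrast("CA", "FLT-SAL", "GC-SAL"), seed = 1),
    "20 distinct label splits")
})

test_that("permutation q-values are valid, monotone and seed-stable", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 300, regions = "CA", n_replicates = 4,
    n_flight_degs_per_region = 30, flight_effect_size = 2, seed = 42))
  norm <- q3_normalize(sim$counts)
  ctr <- de_contrast("CA", "FLT-SAL", "GC-SAL")
  qv <- suppressWarnings(permutation_qvalues(norm, sim$annotations, ctr,
                                             seed = 7))
  expect_true(all(qv$q_value >= 0 & qv$q_value <= 1))
  ord <- order(qv$p_value)
  expect_true(all(diff(qv$q_value[ord]) >= 0))
  qv2 <- suppressWarnings(permutation_qvalues(norm, sim$annotations, ctr,
                                              seed = 7))
  expect_identical(qv, qv2)
  expect_error(permutation_qvalues(norm, sim$annotations, ctr, n_perm = 10),
               class = "dsp_config_error")
})

test_that("the plug-in estimator hits its boundary cases", {
  p_obs <- c(0.001, 0.002, 0.003)
  null_p <- matrix(runif(300, 0.5, 1), 3)  # every null p above every observed
  q <- dspattenuate:::plugin_qvalues(p_obs, null_p, 100)
  expect_equal(q, c(0, 0, 0))
})

test_that("DEG calling applies strict thresholds and assigns direction", {
  qv <- data.frame(gene = c("A", "B", "C", "D"),
                   p_value = c(1e-4, 1e-4, 1e-4, 0.5),
                   q_value = c(0.05, 0.01, 0.01, 0.8))
  lfc <- c(A = 2, B = 0.585, C = -1, D = 3)
  res <- call_degs(lfc, qv)
  expect_identical(res$is_deg, c(FALSE, FALSE, TRUE, FALSE))  # strict both
  expect_identical(res$direction, c("none", "none", "down", "none"))
})

test_that("swapping contrast groups leaves p and q unchanged", {
  sim <- simulate_dataset(simulation_config(n_genes = 120, regions = "CA",
                                            n_flight_degs_per_region = 20,
                                            seed = 44))
  norm <- q3_normalize(sim$counts)
  fwd <- suppressWarnings(run_de(norm, sim$annotations,
                                 de_contrast("CA", "FLT-SAL", "GC-SAL"),
                                 seed = 5))
  bwd <- suppressWarnings(run_de(norm, sim$annotations,
                                 de_contrast("CA", "GC-SAL", "FLT-SAL"),
                                 seed = 5))
  expect_equal(fwd$log2FC, -bwd$log2FC)
  expect_equal(fwd$p_value, bwd$p_value, tolerance = 1e-12)
  expect_equal(fwd$q_value, bwd$q_value, tolerance = 1e-12)
  expect_identical(fwd$is_deg, bwd$is_deg)
})
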