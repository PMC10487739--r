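#' Configuration for the digital-spatial-profiling simulator
#'
#' Defines the generative model used by [simulate_dataset()]. The default
#' design mirrors the reference study: four brain regions (CA, DG, FCT, CT),
#' a 2x2 condition-by-treatment layout (ground control vs spaceflight,
#' saline vs the antioxidant BuOE), and three replicate AOIs per
#' region-by-group cell.
#'
#' The expression model for gene `g` in AOI `a` of region `r`, group
#' `(cond, trt)` is negative binomial with mean
#' \deqn{\mu = 2^{\,b_g + [cond=FLT]\,\delta_{g,r} - [cond=FLT,\,trt=BuOE]\,\alpha_g\,\delta_{g,r} + [cond=GC,\,trt=BuOE]\,\epsilon_g} \cdot s_a}
#' where `b_g` is a per-gene baseline (log2 scale, uniform on
#' `baseline_log_mean_range`), `delta_{g,r}` the planted flight effect
#' (zero except at the flight-responsive genes of region `r`), `alpha_g` the
#' fraction of the flight effect reversed by BuOE during flight, `epsilon_g`
#' an optional BuOE effect in ground controls, and `s_a` a log-normal AOI
#' scale factor. A single RNG stream is used, so one seed fixes the whole
#' dataset.
#'
#' @param n_genes number of genes.
#' @param regions character subset of `c("CA","DG","FCT","CT")`.
#' @param n_replicates AOIs per region-by-group cell.
#' @param baseline_log_mean_range length-2 numeric, log2-scale range of
#'   baseline means.
#' @param dispersion negative-binomial size parameter (> 0); variance is
#'   `mu + mu^2 / dispersion`.
#' @param size_factor_sd standard deviation of log-normal AOI scale factors.
#' @param n_flight_degs_per_region planted flight-responsive genes per region.
#' @param flight_effect_size |log2 fold change| of planted flight effects.
#' @param attenuation_alpha fraction in `[0, 1]` of each flight effect
#'   reversed by BuOE during flight.
#' @param buoe_ground_effect |log2 FC| of the BuOE effect in ground-control
#'   animals (default 0: no ground response), applied with alternating sign
#'   to the genes that are planted flight DEGs in at least one region.
#' @param seed integer seed for the shared RNG stream.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 5000,
                              regions = c("CA", "DG", "FCT", "CT"),
                              n_replicates = 3,
                              baseline_log_mean_range = c(2, 9),
                              dispersion = 10,
                              size_factor_sd = 0.3,
                              n_flight_degs_per_region = 200,
                              flight_effect_size = 1.0,
                              attenuation_alpha = 0.5,
                              buoe_ground_effect = 0,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), regions = as.character(regions),
              n_replicates = as.integer(n_replicates),
              baseline_log_mean_range = as.numeric(baseline_log_mean_range),
              dispersion = as.numeric(dispersion),
              size_factor_sd = as.numeric(size_factor_sd),
              n_flight_degs_per_region = as.integer(n_flight_degs_per_region),
              flight_effect_size = as.numeric(flight_effect_size),
              attenuation_alpha = as.numeric(attenuation_alpha),
              buoe_ground_effect = as.numeric(buoe_ground_effect),
              seed = as.integer(seed))
  bad <- function(field, msg) {
    abort_dsp(sprintf("invalid simulation_config field '%s': %s", field, msg),
              "dsp_config_error")
  }
  if (cfg$n_genes < 1) bad("n_genes", "must be >= 1")
  if (length(cfg$regions) < 1 ||
      !all(cfg$regions %in% c("CA", "DG", "FCT", "CT")))
    bad("regions", "must be a non-empty subset of CA, DG, FCT, CT")
  if (anyDuplicated(cfg$regions)) bad("regions", "must be unique")
  if (cfg$n_replicates < 1) bad("n_replicates", "must be >= 1")
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) < 0)
    bad("baseline_log_mean_range", "must be an increasing pair")
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0)
    bad("dispersion", "must be > 0")
  if (cfg$size_factor_sd < 0) bad("size_factor_sd", "must be >= 0")
  if (cfg$n_flight_degs_per_region < 0 ||
      cfg$n_flight_degs_per_region > cfg$n_genes)
    bad("n_flight_degs_per_region", "must be in [0, n_genes]")
  if (cfg$flight_effect_size < 0) bad("flight_effect_size", "must be >= 0")
  if (cfg$attenuation_alpha < 0 || cfg$attenuation_alpha > 1)
    bad("attenuation_alpha", "must be in [0, 1]")
  if (cfg$buoe_ground_effect < 0) bad("buoe_ground_effect", "must be >= 0")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  structure(cfg, class = "simulation_config")
}

#' Simulate a digital-spatial-profiling dataset with known ground truth
#'
#' Draws a gene-by-AOI negative-binomial count matrix under the model of
#' [simulation_config()], together with AOI annotations and the planted
#' ground truth. Planted flight effects alternate in sign (first sampled
#' gene up, second down, ...) for a deterministic 50/50 split.
#'
#' @param config a [simulation_config()].
#' @return A list with elements:
#' \describe{
#'   \item{counts}{a [count_matrix()].}
#'   \item{annotations}{AOI metadata data.frame (`aoi_id`, `region`,
#'     `condition`, `treatment`, `replicate`, `mouse_id`).}
#'   \item{truth}{object of class `ground_truth`: per-region data.frames of
#'     planted genes with signed log2 effects (`flight_degs`), per-gene
#'     attenuation fractions (`alpha`), per-gene ground BuOE effects
#'     (`buoe_ground`), and per-AOI true scale factors (`size_factors`).}
#' }
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 100, regions = "CA",
#'                                           seed = 7))
#' dim(sim$counts$counts)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))

  b <- stats::runif(ng, config$baseline_log_mean_range[1],
                    config$baseline_log_mean_range[2])

  # planted region-specific flight effects, alternating sign
  delta <- matrix(0, ng, length(config$regions),
                  dimnames = list(genes, config$regions))
  flight_degs <- list()
  for (r in config$regions) {
    idx <- sample.int(ng, config$n_flight_degs_per_region)
    sgn <- rep_len(c(1, -1), length(idx))
    delta[idx, r] <- sgn * config$flight_effect_size
    flight_degs[[r]] <- data.frame(gene = genes[idx],
                                   delta = sgn * config$flight_effect_size,
                                   stringsAsFactors = FALSE)
  }
  alpha <- rep(config$attenuation_alpha, ng)
  names(alpha) <- genes
  eps <- numeric(ng)
  names(eps) <- genes
  if (config$buoe_ground_effect > 0) {
    hit <- rowSums(delta != 0) > 0
    eps[hit] <- rep_len(c(1, -1), sum(hit)) * config$buoe_ground_effect
  }

  groups <- expand.grid(replicate = seq_len(config$n_replicates),
                        treatment = c("SAL", "BuOE"),
                        condition = c("GC", "FLT"),
                        region = config$regions,
                        stringsAsFactors = FALSE)
  groups <- groups[, c("region", "condition", "treatment", "replicate")]
  ann <- data.frame(
    aoi_id = paste(groups$region, groups$condition, groups$treatment,
                   groups$replicate, sep = "_"),
    groups,
    mouse_id = paste0(groups$condition, "-", groups$treatment, "-m",
                      groups$replicate),
    stringsAsFactors = FALSE)
  na <- nrow(ann)
  s <- stats::rlnorm(na, 0, config$size_factor_sd)
  names(s) <- ann$aoi_id

  log2mu <- matrix(b, ng, na)
  for (a in seq_len(na)) {
    r <- ann$region[a]
    flt <- ann$condition[a] == "FLT"
    buoe <- ann$treatment[a] == "BuOE"
    if (flt) {
      log2mu[, a] <- log2mu[, a] + delta[, r]
      if (buoe) log2mu[, a] <- log2mu[, a] - alpha * delta[, r]
    } else if (buoe) {
      log2mu[, a] <- log2mu[, a] + eps
    }
  }
  mu <- sweep(2^log2mu, 2, s, "*")
  counts <- matrix(stats::rnbinom(ng * na, mu = mu, size = config$dispersion),
                   ng, na, dimnames = list(genes, ann$aoi_id))

  truth <- structure(list(flight_degs = flight_degs, alpha = alpha,
                          buoe_ground = eps, size_factors = s,
                          config = config),
                     class = "ground_truth")
  list(counts = count_matrix(counts), annotations = ann, truth = truth)
}

#' Summarize planted ground truth
#'
#' @param truth a `ground_truth` object from [simulate_dataset()].
#' @return data.frame with one row per region: counts of planted up/down
#'   flight-responsive genes, mean |log2 effect|, and the mean attenuation
#'   fraction of the planted genes.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- lapply(names(truth$flight_degs), function(r) {
    fd <- truth$flight_degs[[r]]
    data.frame(region = r,
               n_up = sum(fd$delta > 0),
               n_down = sum(fd$delta < 0),
               mean_abs_effect = if (nrow(fd)) mean(abs(fd$delta)) else 0,
               mean_alpha = if (nrow(fd)) mean(truth$alpha[fd$gene]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
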