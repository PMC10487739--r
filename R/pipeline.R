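#' Configure an end-to-end pipeline run
#'
#' Either simulates a dataset ([simulate_dataset()]) or reads counts and
#' metadata from files, then runs Q3 normalization, per-region differential
#' expression for the flight (`FLT-SAL` vs `GC-SAL`), in-flight antioxidant
#' (`FLT-BuOE` vs `FLT-SAL`) and ground antioxidant (`GC-BuOE` vs `GC-SAL`)
#' contrasts, the attenuation statistics, the ANOVA-filtered PCA with
#' centroid distances, and (when a GMT / association file is supplied) the
#' enrichment steps.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param sim a [simulation_config()] (simulate mode).
#' @param counts_path,metadata_path input TSVs (files mode).
#' @param gmt_path optional GMT file for over-representation analysis.
#' @param associations_path optional gene-disease association TSV.
#' @param n_perm permutations for both the DE q-values and the attenuation
#'   null (default 1000, the reference setting).
#' @param q_threshold,lfc_threshold DEG thresholds (defaults q < 0.05,
#'   |log2FC| > 0.585).
#' @param outdir output directory (created if absent).
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            sim = simulation_config(),
                            counts_path = NULL, metadata_path = NULL,
                            gmt_path = NULL, associations_path = NULL,
                            n_perm = 1000, q_threshold = 0.05,
                            lfc_threshold = 0.585,
                            outdir = "dsp_output", seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 1) abort_dsp("n_perm must be >= 1", "dsp_config_error")
  if (q_threshold <= 0 || lfc_threshold <= 0) {
    abort_dsp("DEG thresholds must be positive", "dsp_config_error")
  }
  if (mode == "files") {
    for (p in c(counts_path, metadata_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort_dsp(sprintf("input file not found: %s",
                          if (is.null(p)) "(unset)" else p),
                  "dsp_config_error")
      }
    }
  }
  for (p in c(gmt_path, associations_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort_dsp(sprintf("input file not found: %s", p), "dsp_config_error")
    }
  }
  structure(list(mode = mode, sim = sim, counts_path = counts_path,
                 metadata_path = metadata_path, gmt_path = gmt_path,
                 associations_path = associations_path,
                 n_perm = as.integer(n_perm), q_threshold = q_threshold,
                 lfc_threshold = lfc_threshold, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [simulation_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort_dsp("the 'yaml' package is required to read YAML configs",
              "dsp_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(simulation_config, raw$sim)
  do.call(pipeline_config, raw)
}

# deterministic per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for every region present in the data and writes all
#' intermediate and final tables to `config$outdir` as deterministic TSVs;
#' rerunning with the same config and seed reproduces the output tree
#' byte-for-byte. Stage errors abort with the stage name attached to the
#' condition message.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest data.frame (`file`, `n_rows`), which is
#'   also written to `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note_file <- function(name, n_rows) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = name, n_rows = n_rows, stringsAsFactors = FALSE)
  }
  emit <- function(df, name) {
    write_table(df, file.path(config$outdir, name))
    note_file(name, nrow(df))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_dsp(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "dsp_stage_error")
    })
  }

  if (config$mode == "simulate") {
    dat <- stage("simulate", {
      sim <- simulate_dataset(config$sim)
      write_count_matrix(sim$counts, file.path(config$outdir, "counts.tsv"))
      note_file("counts.tsv", length(sim$counts$genes))
      emit(sim$annotations, "metadata.tsv")
      emit(truth_summary(sim$truth), "truth_summary.tsv")
      sim
    })
  } else {
    dat <- stage("read", read_count_matrix(config$counts_path,
                                           config$metadata_path))
  }
  cm <- dat$counts
  ann <- dat$annotations

  norm <- stage("normalize", q3_normalize(cm))
  emit(data.frame(aoi_id = norm$aois, q3_factor = unname(norm$q3_factors),
                  stringsAsFactors = FALSE), "q3_factors.tsv")
  norm_df <- data.frame(gene = norm$genes, norm$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  emit(norm_df, "normalized.tsv")

  regions <- unique(ann$region)
  atten_rows <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    space_de <- stage(paste0("de_flight_", r), suppressWarnings(
      run_de(norm, ann, de_contrast(r, "FLT-SAL", "GC-SAL"),
             n_perm = config$n_perm, seed = derive_seed(config$seed, i * 10 + 1),
             q_threshold = config$q_threshold,
             lfc_threshold = config$lfc_threshold)))
    buoe_de <- stage(paste0("de_buoe_flight_", r), suppressWarnings(
      run_de(norm, ann, de_contrast(r, "FLT-BuOE", "FLT-SAL"),
             n_perm = config$n_perm, seed = derive_seed(config$seed, i * 10 + 2),
             q_threshold = config$q_threshold,
             lfc_threshold = config$lfc_threshold)))
    gc_buoe_de <- stage(paste0("de_buoe_ground_", r), suppressWarnings(
      run_de(norm, ann, de_contrast(r, "GC-BuOE", "GC-SAL"),
             n_perm = config$n_perm, seed = derive_seed(config$seed, i * 10 + 3),
             q_threshold = config$q_threshold,
             lfc_threshold = config$lfc_threshold)))
    emit(space_de, sprintf("de_%s_flight.tsv", r))
    emit(buoe_de, sprintf("de_%s_buoe_flight.tsv", r))
    emit(gc_buoe_de, sprintf("de_%s_buoe_ground.tsv", r))

    atten_rows[[r]] <- stage(paste0("attenuation_", r),
      attenuation_test(space_de, buoe_de, B = config$n_perm,
                       seed = derive_seed(config$seed, i * 10 + 4),
                       region = r))
    emit(stage(paste0("summarize_", r),
               summarize_attenuation(space_de, buoe_de, gc_buoe_de)),
         sprintf("attenuation_genes_%s.tsv", r))

    if (!is.null(config$gmt_path)) {
      gsc <- read_gmt(config$gmt_path)
      degs <- space_de$gene[space_de$is_deg]
      if (length(degs) > 0) {
        emit(stage(paste0("enrich_", r), ora(degs, gsc, norm$genes)),
             sprintf("enrichment_%s.tsv", r))
      }
    }
    if (!is.null(config$associations_path)) {
      assoc <- read_associations(config$associations_path)
      dh <- stage(paste0("disease_", r),
                  disease_hits(space_de$gene[space_de$is_deg], assoc))
      emit(dh$hits, sprintf("disease_hits_%s.tsv", r))
    }
  }
  emit(do.call(rbind, atten_rows), "attenuation_summary.tsv")

  pca_out <- stage("pca", {
    grouping <- paste(ann$region, ann$condition, ann$treatment, sep = "_")
    aq <- anova_filter(norm, grouping)
    kept <- aq$gene[aq$q_value < 0.05]
    if (length(kept) == 0) kept <- aq$gene[order(aq$p_value)][1:50]
    pca <- run_pca(norm, kept, annotations = ann,
                   average_replicates = TRUE)
    list(aq = aq, pca = pca)
  })
  emit(pca_out$aq, "anova_qvalues.tsv")
  coords <- data.frame(sample = rownames(pca_out$pca$coordinates),
                       pca_out$pca$coordinates, check.names = FALSE,
                       stringsAsFactors = FALSE)
  emit(coords, "pca_coordinates.tsv")
  emit(stage("distances", centroid_distances(pca_out$pca, ann)),
       "distance_report.tsv")

  manifest_df <- do.call(rbind, manifest)
  write_table(manifest_df, file.path(config$outdir, "manifest.tsv"))
  invisible(manifest_df)
}

#' Per-gene attenuation summary across the three contrasts
#'
#' For every flight-induced DEG, juxtaposes its log2 fold changes in the
#' flight contrast, the in-flight antioxidant contrast and the ground
#' antioxidant contrast; flags genes whose antioxidant response during
#' flight goes in the opposite direction to the flight effect (regardless
#' of significance), and genes whose antioxidant response is
#' flight-specific (an antioxidant DEG in flight but not in ground
#' controls).
#'
#' @param space_de,buoe_de,gc_buoe_de aligned DE result tables for the
#'   flight, in-flight antioxidant and ground antioxidant contrasts.
#' @return data.frame with one row per flight DEG: `gene`, `log2FC_flight`,
#'   `log2FC_buoe_flight`, `log2FC_buoe_ground`, `opposite`,
#'   `flight_specific_buoe`.
#' @export
summarize_attenuation <- function(space_de, buoe_de, gc_buoe_de) {
  if (!setequal(space_de$gene, buoe_de$gene) ||
      !setequal(space_de$gene, gc_buoe_de$gene)) {
    abort_dsp("the three DE tables must cover the same gene universe",
              "dsp_alignment_error")
  }
  buoe_de <- buoe_de[match(space_de$gene, buoe_de$gene), , drop = FALSE]
  gc_buoe_de <- gc_buoe_de[match(space_de$gene, gc_buoe_de$gene), ,
                           drop = FALSE]
  sel <- space_de$is_deg
  data.frame(gene = space_de$gene[sel],
             log2FC_flight = space_de$log2FC[sel],
             log2FC_buoe_flight = buoe_de$log2FC[sel],
             log2FC_buoe_ground = gc_buoe_de$log2FC[sel],
             opposite = sign(space_de$log2FC[sel]) *
               sign(buoe_de$log2FC[sel]) < 0,
             flight_specific_buoe = buoe_de$is_deg[sel] &
               !gc_buoe_de$is_deg[sel],
             stringsAsFactors = FALSE)
}
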