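# End-to-end pipeline driver: one config document, staged execution with
# per-stage attrition logging, a manifest with input hashes, and a markdown
# run report.

#' Default run configuration
#'
#' A single document holding every tunable of the pipeline. `sim` entries
#' are forwarded to [sim_config()] when no input paths are given.
#'
#' @param ... Overrides, as `name = value`; nested lists (`thresholds`,
#'   `flags`, `paths`, `sim`) are replaced element-wise.
#' @return A `md_run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    thresholds = list(alpha = 0.05, rsd_max = 50, missing_max = 0.70,
                      prevalence_min = 0.30, min_cluster_size = 3,
                      min_corr_n = 15),
    flags = list(fdr = FALSE, adjust_weight = FALSE,
                 variance_mode = "per-sex", welch = FALSE,
                 gate_genotype = FALSE, gc_noise_floor = FALSE,
                 normalize_platforms = "HILIC"),
    paths = list(abundance = NULL, meta = NULL, annotation = NULL,
                 phenotypes = NULL),
    sim = list())
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("thresholds", "flags", "paths", "sim") && is.list(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  structure(cfg, class = "md_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A `md_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw)
}

#' Write a run configuration
#'
#' @param config A `md_run_config`.
#' @param path Output file (`.yaml` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

.fmt_tbl <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  body <- apply(df, 1, function(r) paste(r, collapse = " | "))
  paste(c(paste("|", header, "|"), paste("|", sep, "|"),
          paste("|", body, "|")), collapse = "\n")
}

#' Run the full dimorphism pipeline
#'
#' Executes, in order: cohort input (read from `config$paths`, or simulated
#' via [simulate_cohort()] when paths are absent), QC statistics and
#' feature filtering, median batch normalization, half-minimum imputation,
#' WT sex-effect testing with cluster enrichment, per-line KO dimorphism
#' testing with global and per-line summaries, phenotype imputation and
#' per-sex metabolite-phenotype correlation with the cluster-association
#' matrix. Every stage writes its TSV outputs under `out_dir`, attrition
#' counts are logged, and `manifest.json` plus a markdown `report.md`
#' aggregate the run. Fully deterministic given the config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "md_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds; fl <- config$flags
  stage <- "input"
  res <- tryCatch({
    ## ---- input ----
    if (!is.null(config$paths$abundance)) {
      inp <- read_abundance(config$paths$abundance, config$paths$meta,
                            config$paths$annotation)
      cohort <- list(abundance = inp$abundance, meta = inp$meta,
                     annotation = inp$annotation,
                     phenotypes = if (!is.null(config$paths$phenotypes))
                       read_phenotypes(config$paths$phenotypes) else NULL,
                     truth = NULL)
    } else {
      cohort <- simulate_cohort(do.call(
        sim_config, c(list(seed = config$seed), config$sim)))
    }
    in_dir <- file.path(out_dir, "input")
    write_cohort(cohort, in_dir)
    n0 <- ncol(cohort$abundance$values)

    ## ---- preprocess ----
    stage <- "preprocess"
    qc <- compute_qc_stats(cohort$abundance, cohort$meta)
    write_table(qc, file.path(out_dir, "qc_stats.tsv"))
    filt <- filter_features(cohort$abundance, qc,
                            rsd_max = th$rsd_max, missing_max = th$missing_max,
                            prevalence_min = th$prevalence_min,
                            annotation = cohort$annotation)
    write_table(filt$log, file.path(out_dir, "feature_removal_log.tsv"))
    tbl <- median_batch_normalize(filt$table, cohort$meta,
                                  platforms = fl$normalize_platforms)
    tbl <- impute_half_min(tbl, cohort$meta,
                           gc_noise_floor = isTRUE(fl$gc_noise_floor),
                           seed = config$seed + 1L)
    n1 <- ncol(tbl$values)

    ## ---- WT sex effects ----
    stage <- "wt-sex"
    wt_res <- wt_sex_test(tbl, cohort$meta,
                          adjust_weight = isTRUE(fl$adjust_weight),
                          variance_mode = fl$variance_mode,
                          alpha = th$alpha, use_fdr = isTRUE(fl$fdr))
    write_table(wt_res, file.path(out_dir, "wt_sex.tsv"))
    wt_sum <- summarize_sex_effects(wt_res, alpha = th$alpha,
                                    use_fdr = isTRUE(fl$fdr))
    write_table(wt_sum, file.path(out_dir, "wt_sex_summary.tsv"))

    stage <- "enrich"
    clusters <- stats::setNames(cohort$annotation$chemical_cluster,
                                cohort$annotation$feature_id)
    p <- stats::setNames(wt_res$p_value, wt_res$feature_id)
    d <- stats::setNames(sign(wt_res$estimate), wt_res$feature_id)
    enr <- enrich_clusters(p, d, clusters, alpha = th$alpha,
                           min_size = th$min_cluster_size)
    write_table(enr, file.path(out_dir, "wt_sex_enrichment.tsv"))

    ## ---- KO dimorphism ----
    stage <- "ko-test"
    ko_res <- test_all_lines(tbl, cohort$meta, alpha = th$alpha,
                             welch = isTRUE(fl$welch),
                             gate_genotype = isTRUE(fl$gate_genotype))
    write_table(ko_res, file.path(out_dir, "ko_dimorphism.tsv"))
    ko_sum <- if (nrow(ko_res)) summarize_ko(ko_res, alpha = th$alpha) else NULL
    if (!is.null(ko_sum)) {
      write_table(ko_sum$global, file.path(out_dir, "ko_summary_global.tsv"))
      write_table(ko_sum$per_line, file.path(out_dir, "ko_summary_per_line.tsv"))
    }

    ## ---- phenotype associations ----
    stage <- "pheno-corr"
    corr <- NULL; corr_sum <- NULL; heat <- NULL
    if (!is.null(cohort$phenotypes)) {
      ph <- impute_phenotype_min(cohort$phenotypes, cohort$meta,
                                 missing_max = th$missing_max)
      corr <- spearman_by_sex(tbl, ph$pheno, cohort$meta,
                              alpha = th$alpha, min_n = th$min_corr_n)
      write_table(corr, file.path(out_dir, "phenotype_correlations.tsv"))
      corr_sum <- categorize_summary(corr)
      write_table(corr_sum, file.path(out_dir, "phenotype_corr_summary.tsv"))
      heat <- cluster_phenotype_matrix(corr, clusters, alpha = th$alpha,
                                       min_size = th$min_cluster_size)
      write_table(heat, file.path(out_dir, "cluster_phenotype_heatmap.tsv"))
    }

    ## ---- manifest and report ----
    stage <- "report"
    inputs <- list.files(in_dir, full.names = TRUE)
    manifest <- list(
      config = unclass(config),
      inputs = as.list(tools::md5sum(inputs)),
      attrition = list(features_in = n0,
                       features_removed = nrow(filt$log),
                       features_tested = n1,
                       phenotypes_dropped =
                         if (!is.null(corr)) length(
                           setdiff(colnames(cohort$phenotypes),
                                   unique(corr$phenotype_id))) else NA))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
    rpt <- c(
      "# Dimorphism pipeline report", "",
      sprintf("Features: %d in, %d removed, %d tested.", n0, nrow(filt$log), n1),
      "", "## Wildtype sex effects", .fmt_tbl(wt_sum),
      "", "## Enriched chemical clusters (WT sex effect)",
      .fmt_tbl(utils::head(enr, 15)),
      "", "## KO genotype and genotype-sex interaction effects",
      if (!is.null(ko_sum)) .fmt_tbl(ko_sum$global) else "(no KO lines)",
      "", "## Per-line dimorphism",
      if (!is.null(ko_sum)) .fmt_tbl(ko_sum$per_line) else "(no KO lines)",
      "", "## Metabolite-phenotype correlations (WT)",
      if (!is.null(corr_sum)) .fmt_tbl(corr_sum) else "(no phenotypes)")
    writeLines(rpt, file.path(out_dir, "report.md"))
    list(cohort = cohort, qc = qc, removal_log = filt$log, table = tbl,
         wt = wt_res, wt_summary = wt_sum, enrichment = enr,
         ko = ko_res, ko_summary = ko_sum,
         correlations = corr, corr_summary = corr_sum, heatmap = heat)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
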