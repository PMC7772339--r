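#' Run the full analysis pipeline
#'
#' Config-driven orchestration of the downstream stages: taxonomy and rare
#' filtering, per-sample diversity with pairwise group tests, Spearman
#' community dendrogram with the agglomerative coefficient, CCA variance
#' partitioning, core-microbiome profiles, and the paired endophyte screen.
#' Inputs are either TSV paths (`table`, `metadata`) or a synthetic
#' [studyConfig()]. Every stage can be toggled; all stage parameters and the
#' seed are echoed into a machine-readable JSON run report, and identical
#' config plus seed yields identical numerical outputs.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `input` (either `table`/`metadata` TSV paths or `synthetic = TRUE` plus
#'   optional [studyConfig()] arguments under `study`), `stages` (logical
#'   toggles: `filter`, `diversity`, `clustering`, `ordination`, `core`,
#'   `endophyte`), `params` (per-stage parameter overrides), `seed`,
#'   `out_dir`.
#' @return the run report (list), invisibly; outputs and `run_report.json`
#'   are written to `out_dir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  outDir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- utils::modifyList(
    list(filter = TRUE, diversity = TRUE, clustering = TRUE,
         ordination = TRUE, core = TRUE, endophyte = TRUE),
    config$stages %||% list())
  params <- utils::modifyList(
    list(exclude_patterns = "chloroplast", min_fraction = 1e-4,
         diversity_group = "system", core_thresholds = c(0.66, 0.75),
         partition_variables = c("plant_label", "hydrology", "fraction",
                                 "pH", "temperature", "ch4"),
         n_perm = 999, alpha = 0.001, min_relabund = 0.005,
         min_samples = 4L, n_rep = 5000),
    config$params %||% list())
  t0 <- Sys.time()
  report <- list(package_version = as.character(utils::packageVersion("mossmicrobiota")),
                 seed = seed, stages = stages, params = params,
                 outputs = list(), stage_results = list())

  ## ---- input ----------------------------------------------------------
  if (isTRUE(config$input$synthetic)) {
    studyArgs <- config$input$study %||% list()
    studyArgs$seed <- studyArgs$seed %||% seed
    study <- generateStudy(do.call(studyConfig, studyArgs))
    tab <- study$table
    md <- study$metadata
    report$input <- list(synthetic = TRUE, study = studyArgs,
                         n_otus = nrow(tab), n_samples = ncol(tab))
  } else {
    tab <- readOtuTable(config$input$table)
    md <- readSampleMetadata(config$input$metadata)
    tab <- attachSampleData(tab, md)
    report$input <- list(synthetic = FALSE, table = config$input$table,
                         metadata = config$input$metadata,
                         n_otus = nrow(tab), n_samples = ncol(tab))
  }

  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    report$outputs[[name]] <<- name
    path
  }

  if (stages$filter) {
    tab <- filterTaxa(tab, exclude_patterns = params$exclude_patterns)
    tab <- filterRare(tab, min_fraction = params$min_fraction)
    rep_ <- S4Vectors::metadata(tab)$rareFilter
    report$stage_results$filter <- list(
      n_otus_after = nrow(tab),
      entries_zeroed = rep_$entries_zeroed,
      otus_dropped = length(rep_$otus_dropped))
    emit("filtered_table.tsv", function(p) writeOtuTable(tab, p))
  }

  if (stages$diversity) {
    div <- sampleDiversity(tab, "invsimpson")
    rich <- sampleDiversity(tab, "richness")
    g <- md[[params$diversity_group]][match(sampleIds(tab), md$sample_id)]
    gt <- pairwiseWilcoxon(div, g)
    report$stage_results$diversity <- list(
      group = params$diversity_group,
      letters = as.list(groupLetters(gt)),
      median_invsimpson = stats::median(div))
    emit("diversity.tsv", function(p) utils::write.table(
      data.frame(sample_id = sampleIds(tab), invsimpson = div, richness = rich),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (stages$clustering) {
    dend <- agnesCluster(corToDissimilarity(
      correlationMatrix(tab, method = "spearman")))
    report$stage_results$clustering <- list(
      agglomerative_coefficient = agCoefficient(dend))
    emit("dendrogram.nwk", function(p) writeLines(exportNewick(dend), p))
  }

  if (stages$ordination) {
    vp <- variancePartition(tab, md, params$partition_variables,
                            n_perm = params$n_perm, seed = seed)
    report$stage_results$ordination <- list(
      total_inertia = attr(vp, "total_inertia"),
      joint_share_pct = attr(vp, "joint_share_pct"),
      shares = stats::setNames(as.list(vp$share_pct), vp$variable))
    emit("variance_partition.tsv", function(p) utils::write.table(
      vp, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (stages$core) {
    cores <- c(coreProfiles("total", tab, md),
               coreProfiles("per_system", tab, md))
    report$stage_results$core <- lapply(cores, function(cr)
      list(n_core = length(coreIds(cr)),
           contribution = as.list(as.data.frame(t(cr@contribution)))))
    emit("core_otus.tsv", function(p) utils::write.table(
      do.call(rbind, lapply(names(cores), function(nm) data.frame(
        core = nm, otu_id = coreIds(cores[[nm]])))),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (stages$endophyte) {
    scr <- classifyEndophytes(tab, md, alpha = params$alpha,
                              min_relabund = params$min_relabund,
                              min_samples = params$min_samples,
                              n_rep = params$n_rep, seed = seed)
    nQual <- sum(scr$calls$qualifies)
    report$stage_results$endophyte <- list(
      n_tested = nrow(scr$calls), n_qualifying = nQual)
    emit("endophyte_calls.tsv", function(p) utils::write.table(
      scr$calls, p, sep = "\t", quote = FALSE, row.names = FALSE))
    if (nQual > 0) {
      hm <- heatmapMatrix(scr)
      emit("endophyte_heatmap.tsv", function(p) utils::write.table(
        data.frame(otu_id = rownames(hm$matrix), hm$matrix, check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    }
  }

  report$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
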