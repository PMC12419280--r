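#' Pipeline configuration
#'
#' A single document describing an end-to-end run: either file paths for a
#' real cohort (phenotype CSV, VCF, annotation TSV, optional quality matrix,
#' gene scores and database lookup) or a [simulation_config()] to generate a
#' synthetic cohort in memory, plus the cohort-selection parameters, the
#' [filter_config()] and the report size.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest; when simulating it
#'   overrides the simulation config's root seed.
#' @param simulate Optional [simulation_config()].
#' @param pheno_csv,vcf,annotation_tsv,quals_tsv,gene_scores_tsv,hgmd_tsv
#'   Input paths (used when `simulate` is `NULL`; score/lookup paths are
#'   optional either way).
#' @param tg_threshold,n_extreme,n_control,matching Cohort selection, see
#'   [select_extremes()]. Group sizes default to the simulation's when
#'   simulating.
#' @param filter A [filter_config()].
#' @param top_k Genes reported in the ranked table.
#' @param convention Exact-test convention, see [fisher_two_sided()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            pheno_csv = NULL, vcf = NULL,
                            annotation_tsv = NULL, quals_tsv = NULL,
                            gene_scores_tsv = NULL, hgmd_tsv = NULL,
                            tg_threshold = 0.45, n_extreme = NULL,
                            n_control = NULL, matching = TRUE,
                            filter = filter_config(), top_k = 10,
                            convention = "doubling") {
  if (is.null(simulate)) {
    for (p in c(pheno_csv, vcf, annotation_tsv, quals_tsv,
                gene_scores_tsv, hgmd_tsv))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    if (is.null(pheno_csv) || is.null(vcf) || is.null(annotation_tsv))
      stop("either `simulate` or pheno_csv + vcf + annotation_tsv required")
    if (is.null(n_extreme) || is.null(n_control))
      stop("n_extreme and n_control are required with file inputs")
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
    simulate$seed <- as.integer(seed)
    if (is.null(n_extreme)) n_extreme <- simulate$n_extreme
    if (is.null(n_control)) n_control <- simulate$n_control
    tg_threshold <- simulate$tg_threshold
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, pheno_csv = pheno_csv, vcf = vcf,
                 annotation_tsv = annotation_tsv, quals_tsv = quals_tsv,
                 gene_scores_tsv = gene_scores_tsv, hgmd_tsv = hgmd_tsv,
                 tg_threshold = tg_threshold, n_extreme = n_extreme,
                 n_control = n_control, matching = matching, filter = filter,
                 top_k = top_k, convention = convention),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML document mirrors [pipeline_config()]; a `simulate:` block mirrors
#' [simulation_config()] (with `planted_genes` as a list of records) and a
#' `filter:` block mirrors [filter_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$planted_genes))
      sim$planted_genes <- do.call(rbind, lapply(sim$planted_genes,
                                                 as.data.frame))
    y$simulate <- do.call(simulation_config, sim)
  }
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  do.call(pipeline_config, y)
}

.write_report_tsv <- function(x, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# extremoseq %s seed=%d",
                     utils::packageVersion("extremoseq"), seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Loads (or simulates) the cohort, selects the extreme and control groups,
#' computes the baseline comparison table, runs the prioritization cascade,
#' collapses prioritized genotypes per gene and ranks genes by the exact
#' test. Writes `baseline.tsv`, `cascade_report.tsv`, `cascade_report.json`,
#' `ranked_genes.tsv` and `manifest.json` into the output directory; every
#' TSV header records the seed, and the manifest (seed, package and R
#' versions, full configuration) makes any output reproducible from
#' configuration plus seed alone.
#'
#' @param config A [pipeline_config()] or the path to its YAML document.
#' @return Invisibly, a list with `design`, `baseline`, `cascade`, `burden`,
#'   `ranked` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    phenotypes <- cohort$phenotypes
    variants <- cohort$variants
    genotypes <- cohort$genotypes
    quals <- cohort$quals
  } else {
    phenotypes <- read_phenotypes(config$pheno_csv)
    variants <- read_annotation_table(config$annotation_tsv)
    genotypes <- read_vcf_genotypes(config$vcf)
    quals <- if (!is.null(config$quals_tsv)) read_quals(config$quals_tsv)
  }
  scores <- if (!is.null(config$gene_scores_tsv))
    read_gene_scores(config$gene_scores_tsv)
  hgmd <- if (!is.null(config$hgmd_tsv))
    utils::read.delim(config$hgmd_tsv, stringsAsFactors = FALSE)
  fcfg <- config$filter
  if (is.null(quals) && "quality" %in% fcfg$gates)
    fcfg$gates <- setdiff(fcfg$gates, "quality")

  design <- select_extremes(phenotypes, config$tg_threshold,
                            config$n_extreme, config$n_control,
                            config$matching)
  baseline <- baseline_table(phenotypes, design)
  cascade <- run_cascade(variants, quals, fcfg, hgmd)
  burden <- gene_burden_table(genotypes, cascade$variants, design,
                              scores, config$convention)
  ranked <- rank_genes(burden, config$top_k, scores)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    baseline = file.path(config$out_dir, "baseline.tsv"),
    cascade_tsv = file.path(config$out_dir, "cascade_report.tsv"),
    cascade_json = file.path(config$out_dir, "cascade_report.json"),
    ranked = file.path(config$out_dir, "ranked_genes.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  .write_report_tsv(baseline, paths$baseline, config$seed)
  .write_report_tsv(cascade$report, paths$cascade_tsv, config$seed)
  jsonlite::write_json(cascade$report, paths$cascade_json,
                       dataframe = "rows", digits = NA)
  .write_report_tsv(ranked, paths$ranked, config$seed)
  manifest <- list(
    package = "extremoseq",
    version = as.character(utils::packageVersion("extremoseq")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_extreme = config$n_extreme, n_control = config$n_control,
    tg_threshold = config$tg_threshold, top_k = config$top_k,
    convention = config$convention,
    filter = unclass(config$filter),
    simulated = !is.null(config$simulate))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(design = design, baseline = baseline, cascade = cascade,
                 burden = burden, ranked = ranked, paths = paths))
}
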