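#' Prioritization cascade configuration
#'
#' Every threshold of the low-frequency functional-variant prioritization
#' cascade. Defaults are the published rules: keep variants strictly below
#' 0.001 in 1000 Genomes, below 0.01 in self-controls and ESP6500, below
#' 0.005 in the internal (Tianhao-style) database; require an exonic or
#' splice-affecting region with at least one damaging predictor call; keep
#' sites where at most 50% of samples have call quality below Phred 20, the
#' quality letter grade is not "L", and the homology flag equals 1.
#'
#' @param max_freq_1kg,max_freq_selfctrl,max_freq_esp6500,max_freq_tianhao
#'   Frequency caps (strict `<`), each in \[0, 1\].
#' @param min_predictors_damaging Minimum number of damaging predictor calls.
#' @param require_region Gate on exonic/splice-affecting region in the
#'   deleteriousness stage.
#' @param qual_threshold Phred threshold below which a per-sample call counts
#'   as low quality.
#' @param max_lowqual_sample_fraction Maximum tolerated fraction of
#'   low-quality samples per site (inclusive `<=`).
#' @param exclude_qual_class Quality letter grade that disqualifies a site
#'   (`NA` to disable).
#' @param require_homology Required value of the integer homology annotation
#'   (`NULL` to disable).
#' @param treat_missing_freq_as_rare Whether an absent frequency passes its
#'   cap.
#' @param gates Character vector of active stages, in execution order, from
#'   `"hgmd"`, `"deleterious"`, `"frequency"`, `"quality"`. The HGMD stage
#'   only flags; it never removes.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(max_freq_1kg = 0.001,
                          max_freq_selfctrl = 0.01,
                          max_freq_esp6500 = 0.01,
                          max_freq_tianhao = 0.005,
                          min_predictors_damaging = 1L,
                          require_region = TRUE,
                          qual_threshold = 20,
                          max_lowqual_sample_fraction = 0.5,
                          exclude_qual_class = "L",
                          require_homology = 1L,
                          treat_missing_freq_as_rare = TRUE,
                          gates = c("hgmd", "deleterious", "frequency",
                                    "quality")) {
  caps <- c(max_freq_1kg, max_freq_selfctrl, max_freq_esp6500,
            max_freq_tianhao)
  if (any(caps < 0 | caps > 1)) stop("frequency caps must lie in [0,1]")
  if (max_lowqual_sample_fraction < 0 || max_lowqual_sample_fraction > 1)
    stop("max_lowqual_sample_fraction must lie in [0,1]")
  gates <- match.arg(gates, several.ok = TRUE)
  structure(list(max_freq_1kg = max_freq_1kg,
                 max_freq_selfctrl = max_freq_selfctrl,
                 max_freq_esp6500 = max_freq_esp6500,
                 max_freq_tianhao = max_freq_tianhao,
                 min_predictors_damaging = as.integer(min_predictors_damaging),
                 require_region = isTRUE(require_region),
                 qual_threshold = qual_threshold,
                 max_lowqual_sample_fraction = max_lowqual_sample_fraction,
                 exclude_qual_class = exclude_qual_class,
                 require_homology = require_homology,
                 treat_missing_freq_as_rare = isTRUE(treat_missing_freq_as_rare),
                 gates = gates),
            class = "filter_config")
}

#' Canonical variant identifiers
#'
#' @param variants Variant data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_ids <- function(variants)
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")

#' Flag variants known to a mutation database
#'
#' Adds a logical `hgmd_known` column: `TRUE` when the site carries a database
#' identifier in its annotation or matches a `(chrom, pos, ref, alt)` row of
#' the lookup table. Membership never removes a variant.
#'
#' @param variants Annotated variant data.frame.
#' @param hgmd_table Optional lookup data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`. Malformed rows (missing fields) are skipped with a warning.
#' @return `variants` with the `hgmd_known` column added.
#' @export
flag_hgmd <- function(variants, hgmd_table = NULL) {
  known <- if ("hgmd_id" %in% names(variants))
    !is.na(variants$hgmd_id) & variants$hgmd_id != "" else
      rep(FALSE, nrow(variants))
  if (!is.null(hgmd_table) && nrow(hgmd_table) > 0) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(hgmd_table)))
      stop("hgmd_table must have columns ", paste(need, collapse = ", "))
    ok <- stats::complete.cases(hgmd_table[need])
    if (any(!ok))
      warning(sum(!ok), " malformed lookup row(s) skipped")
    keys <- variant_ids(hgmd_table[ok, , drop = FALSE])
    known <- known | variant_ids(variants) %in% keys
  }
  variants$hgmd_known <- known
  variants
}

.PREDICTOR_COLS <- c("sift", "polyphen2", "mutation_taster", "cadd", "dann")
.SPLICE_REGIONS <- c("splicing", "exonic/splicing", "splicing/ncRNA_exonic",
                     "ncRNA_splicing")
.EXONIC_OR_SPLICE <- c("exonic", .SPLICE_REGIONS)

damaging_count <- function(variants) {
  n <- Reduce(`+`, lapply(.PREDICTOR_COLS, function(col)
    as.integer(!is.na(variants[[col]]) & variants[[col]] == "damaging")))
  # dbscSNV is a splice predictor: damaging calls count only at
  # splice-affecting sites
  splice <- variants$region %in% .SPLICE_REGIONS
  n + as.integer(splice & !is.na(variants$dbscsnv) &
                   variants$dbscsnv == "damaging")
}

#' Deleteriousness and region gate
#'
#' Keeps variants in an exonic or splice-affecting region whose number of
#' damaging predictor calls meets the configured minimum.
#'
#' @param variants Annotated variant data.frame.
#' @param config A [filter_config()].
#' @return Filtered data.frame.
#' @export
deleteriousness_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  keep <- damaging_count(variants) >= config$min_predictors_damaging
  if (config$require_region)
    keep <- keep & variants$region %in% .EXONIC_OR_SPLICE
  variants[keep, , drop = FALSE]
}

#' Population-frequency gate
#'
#' Keeps variants strictly below every configured frequency cap; an absent
#' frequency passes its cap iff `treat_missing_freq_as_rare`.
#'
#' @inheritParams deleteriousness_filter
#' @return Filtered data.frame.
#' @export
frequency_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  caps <- c(freq_1kg = config$max_freq_1kg,
            freq_selfctrl = config$max_freq_selfctrl,
            freq_esp6500 = config$max_freq_esp6500,
            freq_tianhao = config$max_freq_tianhao)
  keep <- rep(TRUE, nrow(variants))
  for (col in names(caps)) {
    f <- variants[[col]]
    bad <- !is.na(f) & (f < 0 | f > 1)
    if (any(bad))
      stop("frequency ", col, " outside [0,1] in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    pass <- ifelse(is.na(f), config$treat_missing_freq_as_rare, f < caps[[col]])
    keep <- keep & pass
  }
  variants[keep, , drop = FALSE]
}

#' Site-quality gate
#'
#' Keeps sites where the fraction of samples with per-call quality below the
#' Phred threshold does not exceed the configured maximum, the quality letter
#' grade is not the excluded one, and (when configured) the homology flag
#' equals the required value.
#'
#' @inheritParams deleteriousness_filter
#' @param genotype_quals Numeric matrix of per-call Phred qualities, samples
#'   in rows, sites in columns named by [variant_ids()].
#' @return Filtered data.frame.
#' @export
quality_filter <- function(variants, genotype_quals,
                           config = filter_config()) {
  if (is.null(genotype_quals))
    stop("quality gate requires a per-sample quality matrix")
  if (nrow(variants) == 0) return(variants)
  vid <- variant_ids(variants)
  missing <- setdiff(vid, colnames(genotype_quals))
  if (length(missing))
    stop("quality matrix lacks ", length(missing), " site(s), e.g. ",
         missing[1])
  frac_low <- colMeans(genotype_quals[, vid, drop = FALSE] <
                         config$qual_threshold, na.rm = TRUE)
  keep <- frac_low <= config$max_lowqual_sample_fraction
  if (!is.na(config$exclude_qual_class) && "qual_class" %in% names(variants))
    keep <- keep & (is.na(variants$qual_class) |
                      variants$qual_class != config$exclude_qual_class)
  if (!is.null(config$require_homology) && "homology" %in% names(variants))
    keep <- keep & !is.na(variants$homology) &
      variants$homology == config$require_homology
  variants[keep, , drop = FALSE]
}

#' Run the full prioritization cascade
#'
#' Executes the configured stages in order (HGMD flagging, deleteriousness,
#' frequency, quality) and records per-stage attrition. The HGMD stage only
#' annotates known/novel status.
#'
#' @inheritParams quality_filter
#' @param hgmd_table Optional database lookup table for [flag_hgmd()].
#' @return Object of class `cascade_report`: list with `report` (stage,
#'   n_in, n_out, removed), `variants` (survivors), `hgmd_known` (survivors
#'   flagged known) and `config`.
#' @export
run_cascade <- function(variants, genotype_quals = NULL,
                        config = filter_config(), hgmd_table = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if ("quality" %in% config$gates && is.null(genotype_quals))
    stop("quality gate is active but no genotype quality matrix was supplied")
  current <- variants
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), removed = integer(0),
                       stringsAsFactors = FALSE)
  for (stage in config$gates) {
    n_in <- nrow(current)
    current <- switch(stage,
      hgmd = flag_hgmd(current, hgmd_table),
      deleterious = deleteriousness_filter(current, config),
      frequency = frequency_filter(current, config),
      quality = quality_filter(current, genotype_quals, config))
    report <- rbind(report, data.frame(
      stage = stage, n_in = n_in, n_out = nrow(current),
      removed = n_in - nrow(current), stringsAsFactors = FALSE))
  }
  if (!"hgmd_known" %in% names(current))
    current <- flag_hgmd(current, hgmd_table)
  structure(list(report = report, variants = current,
                 hgmd_known = current[current$hgmd_known, , drop = FALSE],
                 config = config),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report:\n")
  print(x$report, row.names = FALSE)
  cat(nrow(x$variants), "variant(s) retained;",
      nrow(x$hgmd_known), "database-known\n")
  invisible(x)
}
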