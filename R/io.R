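#' Annotation table column contract
#'
#' Required columns of the per-variant annotation TSV: coordinates and
#' alleles, gene symbol, region and functional class, six deleteriousness
#' predictions, four population/database frequencies, database id, site
#' quality, quality letter grade and homology flag.
#'
#' @export
ANNOTATION_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "gene", "region", "func_class",
  "sift", "polyphen2", "mutation_taster", "cadd", "dann", "dbscsnv",
  "freq_1kg", "freq_esp6500", "freq_selfctrl", "freq_tianhao",
  "hgmd_id", "site_qual", "qual_class", "homology")

.FREQ_COLS <- c("freq_1kg", "freq_esp6500", "freq_selfctrl", "freq_tianhao")

#' Read a per-variant annotation table
#'
#' Reads the documented TSV layout (see [ANNOTATION_COLUMNS]), mapping empty
#' strings to absent values and validating that frequencies lie in \[0, 1\].
#'
#' @param path TSV file path.
#' @return Data frame of annotated variants.
#' @export
read_annotation_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing <- setdiff(ANNOTATION_COLUMNS, names(x))
  if (length(missing))
    stop("annotation table lacks required column(s): ",
         paste(missing, collapse = ", "))
  x$pos <- as.integer(x$pos)
  x$homology <- as.integer(x$homology)
  for (col in c(.FREQ_COLS, "site_qual")) {
    x[[col]] <- as.numeric(x[[col]])
    if (col %in% .FREQ_COLS) {
      bad <- !is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1)
      if (any(bad))
        stop("frequency ", col, " outside [0,1] in row(s) ",
             paste(utils::head(which(bad), 5), collapse = ", "))
    }
  }
  x
}

#' Write a per-variant annotation table
#'
#' @param variants Annotated variant data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(variants, path) {
  utils::write.table(variants[ANNOTATION_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a phenotype table (CSV)
#'
#' @param path CSV with at least `sample_id` plus trait columns.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x))
    stop("phenotype table lacks a sample_id column")
  x
}

#' Write a phenotype table (CSV)
#'
#' @param phenotypes Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a GT-only-FORMAT VCF with one biallelic record per site, in the
#' column order of the matrix.
#'
#' @param genotypes Integer matrix (samples x sites; 0/1/2/`NA`), colnames
#'   equal to [variant_ids()] of `variants`.
#' @param variants Variant data.frame supplying coordinates, alleles and site
#'   quality.
#' @param path Output `.vcf` path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  vid <- variant_ids(variants)
  stopifnot(identical(colnames(genotypes), vid))
  gt <- matrix("./.", nrow(variants), nrow(genotypes))
  for (code in 0:2)
    gt[t(genotypes) == code] <- .GT_STRINGS[code + 1]
  qual <- if ("site_qual" %in% names(variants))
    format(variants$site_qual, trim = TRUE) else "."
  body <- paste(variants$chrom, variants$pos, vid, variants$ref,
                variants$alt, qual, "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=extremoseq-", utils::packageVersion("extremoseq")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

.gt_code <- function(g, allele) {
  if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
  alleles <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
  if (anyNA(alleles)) return(NA_integer_)
  sum(alleles == allele)
}

#' Read genotypes from a VCF into a samples-by-sites matrix
#'
#' Diploid GT fields map to 0 (wild-type), 1 (het), 2 (hom); any genotype
#' containing `.` is missing. Multi-allelic records are split into one
#' biallelic site per alternate allele.
#'
#' @param path VCF 4.x path (plain or bgzipped).
#' @param sample_subset Optional character vector restricting (and ordering)
#'   the samples; an unknown sample is an error naming it.
#' @return Integer matrix, samples in rows (VCF header order or
#'   `sample_subset`), sites in columns named `chrom:pos:ref:alt`.
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2)
    stop("VCF carries no genotype columns: ", path)
  if (!all(grepl("(^|:)GT($|:)", v@gt[, "FORMAT"])))
    stop("VCF record(s) without GT in FORMAT: ", path)
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    absent <- setdiff(sample_subset, samples)
    if (length(absent))
      stop("sample(s) not in VCF header: ", paste(absent, collapse = ", "))
    samples <- sample_subset
  }
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  cols <- list()
  ids <- character(0)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      ids <- c(ids, paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                          alts[a], sep = ":"))
      cols[[length(cols) + 1L]] <-
        vapply(gt[i, samples], .gt_code, integer(1), allele = a)
    }
  }
  out <- do.call(cbind, cols)
  dimnames(out) <- list(samples, ids)
  out
}

#' Read/write a per-call quality matrix (TSV)
#'
#' @param quals Numeric matrix, samples x sites.
#' @param path TSV path.
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
write_quals <- function(quals, path) {
  utils::write.table(quals, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_quals
#' @export
read_quals <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' Read an external gene-score table
#'
#' Two-column TSV (`gene`, `score`), scores in \[0, 1\], as produced by
#' phenotype-relevance scorers.
#'
#' @param path TSV path.
#' @return Data frame with `gene` and `score`.
#' @export
read_gene_scores <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(x)))
    stop("gene-score table needs columns gene, score")
  if (any(!is.na(x$score) & (x$score < 0 | x$score > 1)))
    stop("gene scores must lie in [0,1]")
  x
}

#' Write a synthetic cohort to interchange files
#'
#' Writes `phenotypes.csv`, `variants.tsv`, `genotypes.vcf`, `quals.tsv` and
#' `truth.json` into a directory, so a cohort can be round-tripped through
#' the package's readers.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  write_annotation_table(cohort$variants, file.path(dir, "variants.tsv"))
  write_vcf(cohort$genotypes, cohort$variants, file.path(dir, "genotypes.vcf"))
  write_quals(cohort$quals, file.path(dir, "quals.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
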