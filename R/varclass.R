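#' Region and functional-class taxonomies
#'
#' The fifteen closed region categories (eleven single labels plus the four
#' compound cross-gene categories) and the nine functional classes used by
#' the classifier.
#'
#' @format Character vectors.
#' @name taxonomies
NULL

#' @rdname taxonomies
#' @export
REGION_CATEGORIES <- c(
  "exonic", "splicing", "ncRNA_splicing", "ncRNA_exonic", "UTR5", "UTR3",
  "intronic", "ncRNA_intronic", "upstream", "downstream", "intergenic",
  "UTR5/UTR3", "exonic/splicing", "splicing/ncRNA_exonic",
  "upstream/downstream")

#' @rdname taxonomies
#' @export
FUNC_CLASSES <- c(
  "stoploss", "frameshift insertion", "nonframeshift insertion",
  "frameshift deletion", "stopgain", "nonframeshift deletion",
  "synonymous", "nonsynonymous", "unknown")

# Single-label precedence, most severe first. ncRNA_splicing is slotted
# directly after splicing (it is not part of the stated order).
.REGION_PRECEDENCE <- c(
  "exonic", "splicing", "ncRNA_splicing", "ncRNA_exonic", "UTR5", "UTR3",
  "intronic", "ncRNA_intronic", "upstream", "downstream")

.COMPOUNDS <- list(
  "UTR5/UTR3"             = c("UTR3", "UTR5"),
  "exonic/splicing"       = c("exonic", "splicing"),
  "splicing/ncRNA_exonic" = c("ncRNA_exonic", "splicing"),
  "upstream/downstream"   = c("downstream", "upstream"))

#' Construct a gene model
#'
#' A minimal transcript model: sorted non-overlapping exons and an optional
#' CDS span, all as 0-based half-open intervals on the genome. Coding genes
#' may carry the spliced CDS sequence (coding orientation) so substitutions
#' can be translated.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon `(start, end)` intervals, 0-based
#'   half-open, sorted and non-overlapping.
#' @param cds `NULL` for a noncoding gene, else `c(start, end)` (0-based
#'   half-open genomic span of the CDS, contained in the exon span).
#' @param cds_seq Optional spliced CDS sequence (character, coding strand).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand = c("+", "-"), exons, cds = NULL,
                       cds_seq = NULL) {
  strand <- match.arg(strand)
  exons <- matrix(as.integer(exons), ncol = 2)
  if (any(exons[, 1] >= exons[, 2])) stop("exon start must precede exon end")
  if (is.unsorted(exons[, 1], strictly = TRUE) ||
      any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exons must be sorted and non-overlapping")
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (cds[1] >= cds[2] || cds[1] < exons[1, 1] || cds[2] > exons[nrow(exons), 2])
      stop("CDS must be a non-empty span within the exon span")
  }
  if (!is.null(cds_seq)) cds_seq <- toupper(cds_seq)
  structure(list(gene = gene, chrom = chrom, strand = strand, exons = exons,
                 cds = cds, coding = !is.null(cds), cds_seq = cds_seq),
            class = "gene_model")
}

#' Bundle gene models into an indexed set
#'
#' @param ... `gene_model` objects (or a single list of them).
#' @return Object of class `gene_model_set`.
#' @export
gene_model_set <- function(...) {
  models <- list(...)
  if (length(models) == 1 && !inherits(models[[1]], "gene_model"))
    models <- models[[1]]
  stopifnot(all(vapply(models, inherits, logical(1), "gene_model")))
  names(models) <- vapply(models, `[[`, character(1), "gene")
  index <- data.frame(
    gene = names(models),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, function(m) m$exons[1, 1], integer(1)),
    end = vapply(models, function(m) m$exons[nrow(m$exons), 2], integer(1)),
    stringsAsFactors = FALSE)
  structure(list(models = models, index = index), class = "gene_model_set")
}

# Region label of pos0 (0-based) with respect to one gene model; NA when the
# position is outside the transcript +/- flank.
.region_for_gene <- function(pos0, m, splice_window, flank) {
  tx_start <- m$exons[1, 1]
  tx_end <- m$exons[nrow(m$exons), 2]
  if (pos0 >= tx_start && pos0 < tx_end) {
    if (any(pos0 >= m$exons[, 1] & pos0 < m$exons[, 2])) {
      if (!m$coding) return("ncRNA_exonic")
      if (pos0 >= m$cds[1] && pos0 < m$cds[2]) return("exonic")
      before <- pos0 < m$cds[1]
      if (m$strand == "+") return(if (before) "UTR5" else "UTR3")
      return(if (before) "UTR3" else "UTR5")
    }
    near <- any((pos0 >= m$exons[, 2] & pos0 < m$exons[, 2] + splice_window) |
                (pos0 < m$exons[, 1] & pos0 >= m$exons[, 1] - splice_window))
    if (near) return(if (m$coding) "splicing" else "ncRNA_splicing")
    return(if (m$coding) "intronic" else "ncRNA_intronic")
  }
  if (pos0 < tx_start && pos0 >= tx_start - flank)
    return(if (m$strand == "+") "upstream" else "downstream")
  if (pos0 >= tx_end && pos0 < tx_end + flank)
    return(if (m$strand == "+") "downstream" else "upstream")
  NA_character_
}

#' Classify variants into the fifteen region categories
#'
#' Each overlapping gene contributes its most severe label under the
#' precedence exonic > splicing > (ncRNA_splicing) > ncRNA_exonic > UTR5 >
#' UTR3 > intronic > ncRNA_intronic > upstream > downstream. A variant whose
#' per-gene labels form one of the four closed compound pairs gets the
#' compound category; any other cross-gene conflict resolves to the
#' higher-precedence single label. A position with no gene within the flank
#' is intergenic.
#'
#' @param variants Data frame with `chrom` and `pos` (1-based) columns.
#' @param gene_models A [gene_model_set()].
#' @param splice_window Intronic bases adjoining an exon boundary that count
#'   as splice-region (default 2).
#' @param flank Upstream/downstream flank in bases (default 1000).
#' @return Character vector of region categories, one per variant.
#' @export
classify_region <- function(variants, gene_models, splice_window = 2L,
                            flank = 1000L) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  idx <- gene_models$index
  known_chroms <- unique(idx$chrom)
  vapply(seq_len(nrow(variants)), function(i) {
    chrom <- variants$chrom[i]
    if (!chrom %in% known_chroms)
      stop("unknown chromosome in variant ", i, ": ", chrom)
    pos0 <- variants$pos[i] - 1L
    hit <- idx$chrom == chrom & pos0 >= idx$start - flank &
      pos0 < idx$end + flank
    if (!any(hit)) return("intergenic")
    labels <- vapply(idx$gene[hit], function(g)
      .region_for_gene(pos0, gene_models$models[[g]], splice_window, flank),
      character(1))
    labels <- unique(labels[!is.na(labels)])
    if (length(labels) == 0) return("intergenic")
    if (length(labels) == 2) {
      key <- sort(labels)
      for (comp in names(.COMPOUNDS))
        if (identical(key, .COMPOUNDS[[comp]])) return(comp)
    }
    labels[which.min(match(labels, .REGION_PRECEDENCE))]
  }, character(1))
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

# 0-based offset of a genomic position within the spliced CDS (coding
# orientation), or NA when outside the CDS exons.
.cds_offset <- function(pos0, m) {
  iv <- cbind(pmax(m$exons[, 1], m$cds[1]), pmin(m$exons[, 2], m$cds[2]))
  iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
  widths <- iv[, 2] - iv[, 1]
  total <- sum(widths)
  k <- which(pos0 >= iv[, 1] & pos0 < iv[, 2])
  if (length(k) != 1) return(NA_integer_)
  off_plus <- sum(widths[seq_len(k - 1)]) + (pos0 - iv[k, 1])
  if (m$strand == "+") off_plus else total - 1L - off_plus
}

#' Classify exonic variants into the nine functional classes
#'
#' Substitutions are translated against the gene's spliced CDS sequence and
#' called synonymous, nonsynonymous, stopgain or stoploss; insertions and
#' deletions are frameshift when the allele length difference is not a
#' multiple of three, else nonframeshift. Untranslatable contexts (no CDS
#' sequence, reference mismatch, position outside the CDS, multi-base
#' substitution) are `"unknown"` rather than an error.
#'
#' @param variants Data frame with `pos` (1-based), `ref`, `alt`, `gene`.
#' @param gene_models A [gene_model_set()].
#' @return Character vector of functional classes, one per variant.
#' @export
classify_function <- function(variants, gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  code <- Biostrings::GENETIC_CODE
  vapply(seq_len(nrow(variants)), function(i) {
    m <- gene_models$models[[variants$gene[i]]]
    if (is.null(m) || !m$coding) return("unknown")
    ref <- toupper(variants$ref[i]); alt <- toupper(variants$alt[i])
    dl <- nchar(alt) - nchar(ref)
    if (dl > 0)
      return(if (dl %% 3 != 0) "frameshift insertion"
             else "nonframeshift insertion")
    if (dl < 0)
      return(if ((-dl) %% 3 != 0) "frameshift deletion"
             else "nonframeshift deletion")
    if (nchar(ref) != 1 || is.null(m$cds_seq)) return("unknown")
    pos0 <- variants$pos[i] - 1L
    off <- .cds_offset(pos0, m)
    if (is.na(off)) return("unknown")
    ref_c <- if (m$strand == "-") .complement(ref) else ref
    alt_c <- if (m$strand == "-") .complement(alt) else alt
    if (substr(m$cds_seq, off + 1, off + 1) != ref_c) return("unknown")
    ci <- off %/% 3L
    codon <- substr(m$cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    if (nchar(codon) < 3) return("unknown")
    codon_alt <- codon
    substr(codon_alt, off %% 3L + 1L, off %% 3L + 1L) <- alt_c
    aa_ref <- unname(code[codon]); aa_alt <- unname(code[codon_alt])
    if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
    if (aa_ref == aa_alt) return("synonymous")
    if (aa_ref == "*") return("stoploss")
    if (aa_alt == "*") return("stopgain")
    "nonsynonymous"
  }, character(1))
}

.INDEL_BINS <- c("1-5", "6-10", "11-15", "16-20", ">20",
                 "-5 to -1", "-10 to -6", "-15 to -11", "-20 to -16", "<-20")

.indel_bin <- function(len) {
  if (len > 0) {
    if (len <= 5) "1-5" else if (len <= 10) "6-10"
    else if (len <= 15) "11-15" else if (len <= 20) "16-20" else ">20"
  } else {
    if (len >= -5) "-5 to -1" else if (len >= -10) "-10 to -6"
    else if (len >= -15) "-15 to -11" else if (len >= -20) "-20 to -16"
    else "<-20"
  }
}

#' InDel length distribution table
#'
#' Bins signed InDel lengths (`nchar(alt) - nchar(ref)`, i.e. insertions
#' positive) into the ten conventional bins and reports counts and
#' percentages (two decimals). Zero-length rows (substitutions) are excluded
#' from the table and counted in the `n_snv_excluded` attribute.
#'
#' @param x Either a variant data.frame with `ref`/`alt` columns, or a
#'   numeric vector of signed lengths.
#' @return Data frame with columns `bin`, `count`, `percent`, with attributes
#'   `n_total` (InDels binned) and `n_snv_excluded`.
#' @export
indel_length_table <- function(x) {
  lens <- if (is.data.frame(x)) nchar(x$alt) - nchar(x$ref) else as.numeric(x)
  snv <- sum(lens == 0)
  lens <- lens[lens != 0]
  bins <- vapply(lens, .indel_bin, character(1))
  counts <- table(factor(bins, levels = .INDEL_BINS))
  total <- length(lens)
  out <- data.frame(bin = .INDEL_BINS, count = as.integer(counts),
                    percent = if (total > 0)
                      round(100 * as.integer(counts) / total, 2)
                    else rep(NA_real_, length(.INDEL_BINS)),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- total
  attr(out, "n_snv_excluded") <- snv
  out
}
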