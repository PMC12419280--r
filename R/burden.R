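#' Collapse a gene's genotypes into per-group wild/het/hom counts
#'
#' Per sample over the gene's prioritized sites: homozygous at any site puts
#' the sample in C; else heterozygous at any site puts it in B; a sample whose
#' calls are all missing is excluded from the gene's table; otherwise A.
#'
#' @param genotypes Integer genotype matrix (samples x sites; 0 wild, 1 het,
#'   2 hom, `NA` missing) with sample-id rownames and [variant_ids()]
#'   colnames.
#' @param design A [select_extremes()] cohort design.
#' @param gene_sites Character vector of the gene's site ids (columns).
#' @return List with `extreme` and `control` (each a named `c(A, B, C)`
#'   integer triple), plus `excluded_extreme`/`excluded_control` counts of
#'   all-missing samples.
#' @export
collapse_gene <- function(genotypes, design, gene_sites) {
  stopifnot(inherits(design, "cohort_design"), length(gene_sites) >= 1)
  missing_sites <- setdiff(gene_sites, colnames(genotypes))
  if (length(missing_sites))
    stop("site(s) absent from genotype matrix: ",
         paste(utils::head(missing_sites, 3), collapse = ", "))
  one_group <- function(ids) {
    absent <- setdiff(ids, rownames(genotypes))
    if (length(absent))
      stop("sample(s) in design absent from genotype matrix: ",
           paste(utils::head(absent, 3), collapse = ", "))
    sub <- genotypes[ids, gene_sites, drop = FALSE]
    status <- apply(sub, 1, function(r)
      if (all(is.na(r))) -1L else max(r, na.rm = TRUE))
    list(abc = c(A = sum(status == 0L), B = sum(status == 1L),
                 C = sum(status == 2L)),
         excluded = sum(status == -1L))
  }
  e <- one_group(design$extreme_ids)
  c_ <- one_group(design$control_ids)
  list(extreme = e$abc, control = c_$abc,
       excluded_extreme = e$excluded, excluded_control = c_$excluded)
}

#' Carrier-rate ratio statistic
#'
#' Carriers are het + hom samples per group. With control carriers present,
#' the statistic is the ratio of per-group carrier frequencies,
#' `(carriers_e / n_e) / (carriers_c / n_c)`, truncated (floored, not
#' rounded) to three decimals. When the control group has zero carriers the
#' conventional report is the extreme-group carrier count itself.
#'
#' @param extreme,control `(A, B, C)` triples of wild-type, heterozygous and
#'   homozygous sample counts.
#' @return The rate statistic (0 when neither group has carriers).
#' @export
#' @examples
#' carrier_rate_statistic(c(97, 11, 0), c(100, 1, 0))  # 10.287
#' carrier_rate_statistic(c(98, 9, 1), c(101, 0, 0))   # 10
carrier_rate_statistic <- function(extreme, control) {
  if (any(c(extreme, control) < 0)) stop("counts must be non-negative")
  n_e <- sum(extreme); n_c <- sum(control)
  if (n_e == 0 || n_c == 0) stop("group totals must be positive")
  carriers_e <- extreme[2] + extreme[3]
  carriers_c <- control[2] + control[3]
  if (carriers_c == 0) return(as.numeric(carriers_e))
  r <- (carriers_e / n_e) / (carriers_c / n_c)
  floor(r * 1000 + 1e-9) / 1000
}

#' Two-sided exact test on a 2x2 carrier table
#'
#' Exact hypergeometric test of carrier counts between groups. The default
#' doubling convention takes twice the smaller one-sided tail of the observed
#' or more extreme carrier split, capped at 1; the minimum-likelihood
#' convention (the `fisher.test` definition) sums all outcomes no more likely
#' than the observed one.
#'
#' @param extreme,control `c(carriers, non_carriers)` per group.
#' @param convention `"doubling"` (default) or `"minlik"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
#' @examples
#' fisher_two_sided(c(10, 98), c(0, 101))  # ~ 0.0022
fisher_two_sided <- function(extreme, control,
                             convention = c("doubling", "minlik")) {
  convention <- match.arg(convention)
  if (any(c(extreme, control) < 0)) stop("cells must be non-negative")
  k_e <- extreme[1]; n_e <- sum(extreme); n_c <- sum(control)
  if (n_e == 0 || n_c == 0) stop("degenerate table: empty group")
  N <- n_e + n_c
  K <- k_e + control[1]
  if (K == 0 || K == N) return(1)
  supp <- max(0, K - n_c):min(K, n_e)
  pr <- stats::dhyper(supp, K, N - K, n_e)
  if (convention == "doubling") {
    lower <- sum(pr[supp <= k_e])
    upper <- sum(pr[supp >= k_e])
    min(1, 2 * min(lower, upper))
  } else {
    min(1, sum(pr[pr <= pr[supp == k_e] * (1 + 1e-7)]))
  }
}

#' Per-gene burden table
#'
#' Collapses every gene with prioritized sites into two-group (A, B, C)
#' tables, and computes the carrier-rate statistic and the exact-test
#' p-value per gene.
#'
#' @param genotypes Genotype matrix as in [collapse_gene()].
#' @param variants Prioritized variant data.frame (typically the survivors of
#'   [run_cascade()]).
#' @param design A [select_extremes()] design.
#' @param gene_scores Optional data.frame with columns `gene`, `score`
#'   (external phenotype-relevance scores in \[0, 1\]).
#' @param convention Exact-test convention, see [fisher_two_sided()].
#' @return Data frame with one row per gene: `gene`, `snv_count`,
#'   `carrier_samples`, the total/extreme/control A-B-C triples, `rate`, `p`
#'   and `gene_score`.
#' @export
gene_burden_table <- function(genotypes, variants, design,
                              gene_scores = NULL, convention = "doubling") {
  stopifnot(inherits(design, "cohort_design"))
  if (nrow(variants) == 0)
    return(data.frame(gene = character(0)))
  vid <- variant_ids(variants)
  genes <- unique(variants$gene)
  rows <- lapply(genes, function(g) {
    sites <- vid[variants$gene == g]
    cc <- collapse_gene(genotypes, design, sites)
    tot <- cc$extreme + cc$control
    data.frame(
      gene = g, snv_count = length(sites),
      carrier_samples = unname(tot[2] + tot[3]),
      a_total = unname(tot[1]), b_total = unname(tot[2]),
      c_total = unname(tot[3]),
      a_extreme = unname(cc$extreme[1]), b_extreme = unname(cc$extreme[2]),
      c_extreme = unname(cc$extreme[3]),
      a_control = unname(cc$control[1]), b_control = unname(cc$control[2]),
      c_control = unname(cc$control[3]),
      rate = carrier_rate_statistic(cc$extreme, cc$control),
      p = fisher_two_sided(
        c(cc$extreme[2] + cc$extreme[3], cc$extreme[1]),
        c(cc$control[2] + cc$control[3], cc$control[1]),
        convention = convention),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gene_score <- if (!is.null(gene_scores))
    gene_scores$score[match(out$gene, gene_scores$gene)] else NA_real_
  rownames(out) <- NULL
  out
}

#' Rank genes by exact-test p-value
#'
#' Sorts ascending by p, breaking ties by descending rate, then descending
#' external gene score (when supplied), then gene symbol, and returns the top
#' rows in report layout.
#'
#' @param rows Output of [gene_burden_table()].
#' @param top_k Number of genes to report (positive).
#' @param gene_scores Optional score table (columns `gene`, `score`) merged
#'   before ranking.
#' @return The top `top_k` rows, re-ranked.
#' @export
rank_genes <- function(rows, top_k = 10, gene_scores = NULL) {
  if (top_k <= 0) stop("top_k must be positive")
  if (!is.null(gene_scores))
    rows$gene_score <- gene_scores$score[match(rows$gene, gene_scores$gene)]
  if (is.null(rows$gene_score)) rows$gene_score <- NA_real_
  score <- ifelse(is.na(rows$gene_score), -Inf, rows$gene_score)
  ord <- order(rows$p, -rows$rate, -score, rows$gene)
  out <- rows[utils::head(ord, top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
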