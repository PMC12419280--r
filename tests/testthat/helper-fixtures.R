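# Shared fixture builders: everything is generated in code at test time.

design_fixture <- function(extreme_ids, control_ids) {
  structure(list(tg_threshold = 0.45, extreme_ids = extreme_ids,
                 control_ids = control_ids, matching = FALSE, trait = "tg"),
            class = "cohort_design")
}

# One fully-populated annotation row; override any field.
variant_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                        gene = "G1", region = "exonic",
                        func_class = "nonsynonymous",
                        sift = "damaging", polyphen2 = "tolerated",
                        mutation_taster = NA_character_,
                        cadd = NA_character_, dann = NA_character_,
                        dbscsnv = NA_character_,
                        freq_1kg = 0, freq_esp6500 = 0, freq_selfctrl = 0,
                        freq_tianhao = 0, hgmd_id = NA_character_,
                        site_qual = 60, qual_class = "H", homology = 1L) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, region = region, func_class = func_class,
             sift = sift, polyphen2 = polyphen2,
             mutation_taster = mutation_taster, cadd = cadd, dann = dann,
             dbscsnv = dbscsnv, freq_1kg = freq_1kg,
             freq_esp6500 = freq_esp6500, freq_selfctrl = freq_selfctrl,
             freq_tianhao = freq_tianhao, hgmd_id = hgmd_id,
             site_qual = site_qual, qual_class = qual_class,
             homology = homology, stringsAsFactors = FALSE)
}

# Genotype matrix for one gene: first n_e rows are extreme samples. The
# requested numbers of het/hom carriers are placed at the gene's first site.
geno_fixture <- function(n_e, n_c, sites = 1, het_e = 0, hom_e = 0,
                         het_c = 0, hom_c = 0,
                         site_ids = paste0("chr1:", 1000 + seq_len(sites),
                                           ":A:G")) {
  ids <- c(sprintf("E%03d", seq_len(n_e)), sprintf("C%03d", seq_len(n_c)))
  g <- matrix(0L, n_e + n_c, sites, dimnames = list(ids, site_ids))
  g[seq_len(het_e), 1] <- 1L
  if (hom_e > 0) g[het_e + seq_len(hom_e), 1] <- 2L
  g[n_e + seq_len(het_c), 1] <- if (het_c > 0) 1L else integer(0)
  if (hom_c > 0) g[n_e + het_c + seq_len(hom_c), 1] <- 2L
  g
}

# A coding gene whose CDS starts ATG TAC GCT GCT ... TAA; exon (100,400),
# CDS (130, 367), 237 coding bases. Codon 2 third base (genomic pos0 135,
# 1-based 136) is C; C->A makes TAC->TAA (stopgain).
coding_gene_fixture <- function(gene = "CODA", strand = "+") {
  cds_seq <- paste0("ATG", "TAC", strrep("GCT", 76), "TAA")
  gene_model(gene, "chr1", strand, exons = cbind(100L, 400L),
             cds = c(130L, 367L), cds_seq = cds_seq)
}

# Two-exon coding gene for splice fixtures: exons (100,200) and (300,400).
split_gene_fixture <- function(gene = "SPLIT") {
  cds_seq <- strrep("GCT", 66)  # 198 bases = (200-130) + (300..428? unused)
  gene_model(gene, "chr1", "+", exons = rbind(c(100L, 200L), c(300L, 400L)),
             cds = c(130L, 370L), cds_seq = NULL)
}

# Brute-force two-sided exact test by explicit enumeration of the
# hypergeometric support with binomial coefficients (independent of dhyper).
fisher_oracle <- function(k_e, n_e, k_c, n_c,
                          convention = c("doubling", "minlik")) {
  convention <- match.arg(convention)
  N <- n_e + n_c; K <- k_e + k_c
  if (K == 0 || K == N) return(1)
  ks <- max(0, K - n_c):min(K, n_e)
  pr <- exp(lchoose(K, ks) + lchoose(N - K, n_e - ks) - lchoose(N, n_e))
  if (convention == "doubling") {
    min(1, 2 * min(sum(pr[ks <= k_e]), sum(pr[ks >= k_e])))
  } else {
    min(1, sum(pr[pr <= pr[ks == k_e] * (1 + 1e-7)]))
  }
}

tiny_config <- function(...) {
  defaults <- list(n_extreme = 12L, n_control = 10L, n_genes = 4L,
                   sites_per_gene = 2L, missing_rate = 0, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
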