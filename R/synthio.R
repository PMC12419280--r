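#' Simulation configuration for a synthetic extreme-phenotype cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: group sizes,
#' per-group lipid/biochemistry distributions, variant annotation proportions,
#' and the gene-level carrier enrichment planted into the genotype matrix.
#' Defaults emulate the study design the package targets: an extreme-low
#' triglyceride group (TG <= 0.45 mmol/L) of 111 samples versus a normal-TG
#' control group of 102 samples, with trait means/SDs per group matching the
#' published baseline table.
#'
#' @param n_extreme,n_control Number of samples in the extreme-low and control
#'   groups. Must be positive.
#' @param lipid_params Named list of traits; each element is a list with
#'   `extreme = c(mean, sd)`, `control = c(mean, sd)` and optionally `lower`
#'   (truncation bound, exclusive; defaults to 0). Units follow clinical
#'   convention (mmol/L for lipids/glucose, umol/L-scale creatinine values as
#'   printed, U/L for transaminases, years for age).
#' @param male_fraction Target male fraction in each group.
#' @param tg_threshold TG threshold (mmol/L) separating the extreme stratum
#'   (TG in (0, threshold]) from the control stratum (TG > threshold).
#' @param n_genes,sites_per_gene Number of genes and variant sites per gene.
#' @param planted_genes `NULL`, or a data.frame with columns `gene`,
#'   `p_extreme`, `p_control`, `hom_fraction`: per-group per-sample carrier
#'   probabilities and the fraction of carriers made homozygous.
#' @param p_background Per-sample carrier probability for non-planted genes,
#'   identical in both groups.
#' @param hom_fraction_background Fraction of background carriers that are
#'   homozygous.
#' @param rare_fraction Proportion of sites whose four population frequencies
#'   all fall below the default cascade caps.
#' @param deleterious_fraction Proportion of sites that are exonic with at
#'   least one damaging predictor call.
#' @param hgmd_fraction Proportion of sites assigned a database identifier.
#' @param missing_rate Independent per-call missingness probability.
#' @param lowqual_fraction Proportion of per-call quality values drawn below
#'   Phred 20 (the cascade's low-quality threshold).
#' @param multi_site_carriers If `TRUE`, a planted carrier may carry mutations
#'   at additional sites of the gene; by default each carrier gets exactly one
#'   mutated site.
#' @param seed Integer root seed. Child streams for the three generators are
#'   derived from it (stream order: phenotypes, variants, genotypes), so equal
#'   seed and configuration give byte-identical output.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_extreme = 20, n_control = 20, n_genes = 5,
#'                          sites_per_gene = 2, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$genotypes)
simulation_config <- function(n_extreme = 111L,
                              n_control = 102L,
                              lipid_params = default_lipid_params(),
                              male_fraction = 102 / 213,
                              tg_threshold = 0.45,
                              n_genes = 100L,
                              sites_per_gene = 3L,
                              planted_genes = NULL,
                              p_background = 0.005,
                              hom_fraction_background = 0.03,
                              rare_fraction = 1,
                              deleterious_fraction = 1,
                              hgmd_fraction = 0.02,
                              missing_rate = 0.02,
                              lowqual_fraction = 0,
                              multi_site_carriers = FALSE,
                              seed = 1L) {
  if (n_extreme <= 0 || n_control <= 0)
    stop("group sizes must be positive (got n_extreme = ", n_extreme,
         ", n_control = ", n_control, ")")
  if (n_genes <= 0 || sites_per_gene <= 0)
    stop("n_genes and sites_per_gene must be positive")
  probs <- c(male_fraction = male_fraction, p_background = p_background,
             rare_fraction = rare_fraction,
             deleterious_fraction = deleterious_fraction,
             hgmd_fraction = hgmd_fraction, missing_rate = missing_rate,
             lowqual_fraction = lowqual_fraction,
             hom_fraction_background = hom_fraction_background)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  for (tr in names(lipid_params)) {
    p <- lipid_params[[tr]]
    if (any(c(p$extreme[2], p$control[2]) < 0))
      stop("negative SD for trait ", tr)
  }
  if (!is.null(planted_genes)) {
    planted_genes <- as.data.frame(planted_genes)
    need <- c("gene", "p_extreme", "p_control", "hom_fraction")
    if (!all(need %in% names(planted_genes)))
      stop("planted_genes must have columns ", paste(need, collapse = ", "))
    pv <- unlist(planted_genes[c("p_extreme", "p_control", "hom_fraction")])
    if (any(pv < 0 | pv > 1))
      stop("planted carrier probabilities must lie in [0,1]")
    known <- gene_names(n_genes)
    missing <- setdiff(planted_genes$gene, known)
    if (length(missing))
      stop("planted genes not among generated genes: ",
           paste(missing, collapse = ", "))
  }
  structure(list(
    n_extreme = as.integer(n_extreme), n_control = as.integer(n_control),
    lipid_params = lipid_params, male_fraction = male_fraction,
    tg_threshold = tg_threshold, n_genes = as.integer(n_genes),
    sites_per_gene = as.integer(sites_per_gene),
    planted_genes = planted_genes, p_background = p_background,
    hom_fraction_background = hom_fraction_background,
    rare_fraction = rare_fraction,
    deleterious_fraction = deleterious_fraction,
    hgmd_fraction = hgmd_fraction, missing_rate = missing_rate,
    lowqual_fraction = lowqual_fraction,
    multi_site_carriers = isTRUE(multi_site_carriers),
    seed = as.integer(seed)), class = "simulation_config")
}

#' Default per-group trait distributions
#'
#' Group means/SDs for every baseline trait of the emulated design: TG, TC,
#' HDL-C, LDL-C (mmol/L), glucose (mmol/L), creatinine, BUN, AST, ALT and age.
#' The `extreme` entry describes the extreme-low TG group, `control` the
#' normal-TG group.
#'
#' @return Named list suitable for the `lipid_params` argument of
#'   [simulation_config()].
#' @export
default_lipid_params <- function() {
  tr <- function(e_mean, e_sd, c_mean, c_sd, lower = 0)
    list(extreme = c(e_mean, e_sd), control = c(c_mean, c_sd), lower = lower)
  list(
    age        = tr(20.76, 1.48, 20.91, 1.36, lower = 16),
    tg         = tr(0.40, 0.04, 1.43, 0.13),
    tc         = tr(3.59, 0.59, 4.71, 0.38),
    hdl_c      = tr(1.56, 0.26, 1.28, 0.25),
    ldl_c      = tr(1.79, 0.44, 2.93, 0.23),
    glucose    = tr(4.88, 0.50, 4.95, 0.50),
    creatinine = tr(73.90, 13.44, 75.11, 13.47),
    bun        = tr(4.64, 1.12, 4.40, 1.05),
    ast        = tr(18.69, 4.44, 20.66, 11.08),
    alt        = tr(15.90, 9.17, 26.27, 25.80)
  )
}

gene_names <- function(n) sprintf("GENE%04d", seq_len(n))

# Child seeds: one root seed spawns one stream per generator, in documented
# order (1 = phenotypes, 2 = variants, 3 = genotypes), so regenerating a single
# component is stable.
child_seed <- function(seed, stream) {
  stopifnot(stream %in% 1:3)
  set.seed(seed)
  sample.int(2147483646L, 3L)[stream]
}

# Truncated normal by rejection; lower bound exclusive, upper inclusive,
# matching the TG strata (0, 0.45] and (0.45, Inf). sd = 0 degenerates to the
# mean (which must satisfy the bounds).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= lower || mean > upper)
      stop("degenerate distribution at ", mean, " violates bounds (",
           lower, ", ", upper, "]")
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (i in 1:10000) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > lower & x <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated-normal rejection sampling failed for mean ", mean,
       ", sd ", sd, " on (", lower, ", ", upper, "]")
}

#' Generate a synthetic phenotype table
#'
#' Draws each trait independently per group from truncated normal
#' distributions. TG is truncated to (0, tg_threshold] for the extreme group
#' and to (tg_threshold, Inf) for the control group, so group membership is
#' recoverable from the trait alone; sex is assigned to match the configured
#' male fraction exactly (up to rounding) in each group.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `sample_id`, `group`
#'   (`"extreme"`/`"control"`), `sex` (`"male"`/`"female"`) and one numeric
#'   column per configured trait.
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 1L))
  n_e <- config$n_extreme; n_c <- config$n_control
  group <- rep(c("extreme", "control"), c(n_e, n_c))
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_e + n_c)),
    group = group, stringsAsFactors = FALSE)
  draw_sex <- function(n) {
    males <- round(n * config$male_fraction)
    sample(rep(c("male", "female"), c(males, n - males)))
  }
  out$sex <- c(draw_sex(n_e), draw_sex(n_c))
  for (tr in names(config$lipid_params)) {
    p <- config$lipid_params[[tr]]
    lower <- if (is.null(p$lower)) 0 else p$lower
    if (tr == "tg") {
      e <- rnorm_trunc(n_e, p$extreme[1], p$extreme[2],
                       lower = 0, upper = config$tg_threshold)
      c_ <- rnorm_trunc(n_c, p$control[1], p$control[2],
                        lower = config$tg_threshold, upper = Inf)
    } else {
      e <- rnorm_trunc(n_e, p$extreme[1], p$extreme[2], lower = lower)
      c_ <- rnorm_trunc(n_c, p$control[1], p$control[2], lower = lower)
    }
    out[[tr]] <- c(e, c_)
  }
  out
}

#' Generate synthetic annotated variant sites
#'
#' Produces `n_genes * sites_per_gene` annotated sites. A site is "rare" with
#' probability `rare_fraction`, in which case all four population frequencies
#' fall below the default cascade caps (1000 Genomes 0.001, self-control 0.01,
#' ESP6500 0.01, internal database 0.005); otherwise every frequency lies above
#' its cap. A site is "deleterious" with probability `deleterious_fraction`:
#' exonic region with 1-5 damaging predictor calls; otherwise all predictors
#' are tolerated. Site quality, quality class and the homology flag default to
#' passing values so that cascade attrition is controlled by the rare and
#' deleterious proportions.
#'
#' @param config A [simulation_config()].
#' @return Data frame of annotated variants (one row per site) with the
#'   documented annotation columns; see [read_annotation_table()].
#' @export
generate_variants <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 2L))
  genes <- gene_names(config$n_genes)
  spg <- config$sites_per_gene
  n <- config$n_genes * spg
  gene <- rep(genes, each = spg)
  pos <- rep(seq_len(config$n_genes) * 100000L, each = spg) +
    seq_len(spg) * 150L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  rare <- stats::runif(n) < config$rare_fraction
  caps <- c(freq_1kg = 0.001, freq_esp6500 = 0.01,
            freq_selfctrl = 0.01, freq_tianhao = 0.005)
  freqs <- sapply(caps, function(cap)
    ifelse(rare, stats::runif(n, 0, 0.8 * cap),
           stats::runif(n, pmax(2 * cap, 0.02), 0.5)))
  deleterious <- stats::runif(n) < config$deleterious_fraction
  region <- ifelse(deleterious, "exonic",
                   sample(c("exonic", "intronic", "UTR5", "UTR3", "intergenic"),
                          n, replace = TRUE))
  func_class <- ifelse(deleterious, "nonsynonymous",
                       sample(c("synonymous", "nonsynonymous", "unknown"),
                              n, replace = TRUE, prob = c(0.6, 0.35, 0.05)))
  predictors <- c("sift", "polyphen2", "mutation_taster", "cadd", "dann")
  pred <- matrix("tolerated", n, length(predictors),
                 dimnames = list(NULL, predictors))
  n_dmg <- ifelse(deleterious, sample(seq_along(predictors), n, replace = TRUE), 0L)
  for (i in which(deleterious))
    pred[i, sample(predictors, n_dmg[i])] <- "damaging"
  hgmd_id <- ifelse(stats::runif(n) < config$hgmd_fraction,
                    sprintf("CM%06d", sample.int(999999L, n, replace = TRUE)),
                    NA_character_)
  out <- data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt, gene = gene,
    region = region, func_class = func_class,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pred, stringsAsFactors = FALSE))
  out$dbscsnv <- NA_character_
  out <- cbind(out, as.data.frame(freqs))
  out$hgmd_id <- hgmd_id
  out$site_qual <- round(pmax(30, stats::rnorm(n, 60, 10)), 1)
  out$qual_class <- "H"
  out$homology <- 1L
  rownames(out) <- NULL
  out
}

#' Generate a synthetic genotype matrix with planted carrier enrichment
#'
#' For every planted gene, each sample becomes a carrier with its group's
#' probability; a carrier is homozygous with the gene's `hom_fraction`, else
#' heterozygous, at one uniformly chosen site of the gene (optionally extra
#' sites when `multi_site_carriers` is on). Non-planted genes use the
#' background carrier probability, identical in both groups. Missing calls are
#' inserted independently per call at `missing_rate`. A per-call Phred quality
#' matrix of identical shape is generated alongside, with `lowqual_fraction`
#' of entries below 20.
#'
#' @param config A [simulation_config()].
#' @param variants Variant table from [generate_variants()].
#' @param phenotypes Phenotype table from [generate_phenotypes()].
#' @return List with `genotypes` (integer matrix, samples x sites; 0 wild,
#'   1 het, 2 hom, `NA` missing), `quals` (numeric matrix, same shape) and
#'   `truth` (data.frame of per-gene planted probabilities and realized carrier
#'   counts per group).
#' @export
generate_genotypes <- function(config, variants, phenotypes) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 3L))
  samples <- phenotypes$sample_id
  is_extreme <- phenotypes$group == "extreme"
  vid <- variant_ids(variants)
  n_s <- length(samples); n_v <- nrow(variants)
  G <- matrix(0L, n_s, n_v, dimnames = list(samples, vid))
  genes <- unique(variants$gene)
  planted <- config$planted_genes
  if (!is.null(planted)) {
    absent <- setdiff(planted$gene, genes)
    if (length(absent))
      stop("planted gene(s) absent from variants: ",
           paste(absent, collapse = ", "))
  }
  truth <- data.frame(gene = genes,
                      p_extreme = config$p_background,
                      p_control = config$p_background,
                      hom_fraction = config$hom_fraction_background,
                      planted = FALSE,
                      carriers_extreme = 0L, carriers_control = 0L,
                      stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    gn <- genes[g]
    if (!is.null(planted) && gn %in% planted$gene) {
      row <- planted[planted$gene == gn, ]
      truth[g, c("p_extreme", "p_control", "hom_fraction")] <-
        row[c("p_extreme", "p_control", "hom_fraction")]
      truth$planted[g] <- TRUE
    }
    p <- ifelse(is_extreme, truth$p_extreme[g], truth$p_control[g])
    carrier <- stats::rbinom(n_s, 1L, p) == 1L
    truth$carriers_extreme[g] <- sum(carrier & is_extreme)
    truth$carriers_control[g] <- sum(carrier & !is_extreme)
    sites <- which(variants$gene == gn)
    for (s in which(carrier)) {
      call <- if (stats::runif(1) < truth$hom_fraction[g]) 2L else 1L
      at <- sites[sample.int(length(sites), 1L)]
      G[s, at] <- call
      if (config$multi_site_carriers && length(sites) > 1L) {
        extra <- setdiff(sites, at)
        extra <- extra[stats::runif(length(extra)) < 0.15]
        if (length(extra)) G[s, extra] <- 1L
      }
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n_s * n_v) < config$missing_rate, n_s, n_v)
    G[miss] <- NA_integer_
  }
  quals <- matrix(round(pmax(21, stats::rnorm(n_s * n_v, 60, 8)), 1),
                  n_s, n_v, dimnames = list(samples, vid))
  if (config$lowqual_fraction > 0) {
    low <- matrix(stats::runif(n_s * n_v) < config$lowqual_fraction, n_s, n_v)
    quals[low] <- round(stats::runif(sum(low), 5, 19), 1)
  }
  list(genotypes = G, quals = quals, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the three generators under documented child-seed streams of the root
#' seed and assembles a `synthetic_cohort`: phenotype table, annotated variant
#' table, genotype and per-call quality matrices, and the planted-enrichment
#' truth record for parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: list with elements `config`,
#'   `phenotypes`, `variants`, `genotypes`, `quals`, `truth`.
#' @export
simulate_cohort <- function(config) {
  phenotypes <- generate_phenotypes(config)
  variants <- generate_variants(config)
  gt <- generate_genotypes(config, variants, phenotypes)
  structure(list(config = config, phenotypes = phenotypes, variants = variants,
                 genotypes = gt$genotypes, quals = gt$quals, truth = gt$truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:",
      nrow(x$phenotypes), "samples (",
      sum(x$phenotypes$group == "extreme"), "extreme /",
      sum(x$phenotypes$group == "control"), "control ),",
      nrow(x$variants), "sites in",
      length(unique(x$variants$gene)), "genes;",
      sum(x$truth$planted), "planted gene(s)\n")
  invisible(x)
}
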