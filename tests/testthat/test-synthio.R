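test_that("generators are deterministic given seed and config", {
  cfg <- tiny_config(missing_rate = 0.05)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$variants, b$variants)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$quals, b$quals)
  c_ <- simulate_cohort(tiny_config(missing_rate = 0.05, seed = 43L))
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("config validation rejects bad probabilities, sizes and genes", {
  expect_error(simulation_config(n_extreme = 0), "positive")
  expect_error(simulation_config(missing_rate = 1.2), "\\[0,1\\]")
  expect_error(tiny_config(planted_genes = data.frame(
    gene = "NOPE", p_extreme = 0.5, p_control = 0.1, hom_fraction = 0)),
    "not among generated genes")
  expect_error(tiny_config(planted_genes = data.frame(
    gene = "GENE0001", p_extreme = 1.5, p_control = 0.1, hom_fraction = 0)),
    "\\[0,1\\]")
})

test_that("phenotypes honour group sizes, TG truncation and sex targets", {
  cfg <- simulation_config(n_extreme = 111, n_control = 102, seed = 7)
  ph <- generate_phenotypes(cfg)
  expect_equal(nrow(ph), 213)
  expect_equal(sum(ph$group == "extreme"), 111)
  e_tg <- ph$tg[ph$group == "extreme"]
  c_tg <- ph$tg[ph$group == "control"]
  expect_true(all(e_tg > 0 & e_tg <= 0.45))
  expect_true(all(c_tg > 0.45))
  expect_equal(sum(ph$sex[ph$group == "extreme"] == "male"),
               round(111 * 102 / 213))
})

test_that("degenerate SD = 0 collapses every trait onto its mean", {
  lp <- default_lipid_params()
  for (tr in names(lp)) {
    lp[[tr]]$extreme[2] <- 0
    lp[[tr]]$control[2] <- 0
  }
  ph <- generate_phenotypes(tiny_config(lipid_params = lp))
  expect_true(all(ph$tg[ph$group == "extreme"] == 0.40))
  expect_true(all(ph$tc[ph$group == "control"] == 4.71))
})

test_that("extreme-group TG mean matches the configured distribution", {
  cfg <- simulation_config(n_extreme = 111, n_control = 102, seed = 1)
  e_tg <- generate_phenotypes(cfg)$tg[1:111]
  # reference: mean of N(0.40, 0.04) truncated above at the 0.45 threshold
  a <- (0 - 0.40) / 0.04; b <- (0.45 - 0.40) / 0.04
  trunc_mean <- 0.40 - 0.04 * (dnorm(b) - dnorm(a)) / (pnorm(b) - pnorm(a))
  se <- 0.04 / sqrt(111)
  expect_lt(abs(mean(e_tg) - trunc_mean), 3 * se)
  expect_lt(abs(mean(e_tg) - 0.40), 0.02)
})

test_that("variant generation counts, gene partition and rare fractions hold", {
  cfg <- tiny_config(n_genes = 10L, sites_per_gene = 5L)
  v <- generate_variants(cfg)
  expect_equal(nrow(v), 50)
  expect_true(all(table(v$gene) == 5))
  # rare_fraction = 1 and deleterious_fraction = 1 force a full cascade pass
  co <- simulate_cohort(tiny_config(rare_fraction = 1,
                                    deleterious_fraction = 1))
  rep_all <- run_cascade(co$variants, co$quals)
  expect_equal(nrow(rep_all$variants), nrow(co$variants))
  # rare_fraction = 0: nothing survives the frequency gate
  co0 <- simulate_cohort(tiny_config(rare_fraction = 0))
  expect_equal(nrow(run_cascade(co0$variants, co0$quals)$variants), 0)
})

test_that("survivor count of the frequency gate is binomial in rare_fraction", {
  cfg <- simulation_config(n_extreme = 4, n_control = 4, n_genes = 200,
                           sites_per_gene = 5, rare_fraction = 0.3, seed = 9)
  v <- generate_variants(cfg)
  n <- nrow(v)
  surv <- nrow(frequency_filter(v))
  expect_lt(abs(surv - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("deterministic planting yields the exact collapsed pattern", {
  cfg <- tiny_config(
    n_extreme = 9L, n_control = 7L, missing_rate = 0,
    planted_genes = data.frame(gene = "GENE0001", p_extreme = 1,
                               p_control = 0, hom_fraction = 0),
    p_background = 0)
  co <- simulate_cohort(cfg)
  design <- design_fixture(co$phenotypes$sample_id[1:9],
                           co$phenotypes$sample_id[10:16])
  sites <- variant_ids(co$variants)[co$variants$gene == "GENE0001"]
  cc <- collapse_gene(co$genotypes, design, sites)
  expect_equal(unname(cc$extreme), c(0, 9, 0))
  expect_equal(unname(cc$control), c(7, 0, 0))
  # no carriers anywhere: rate 0 downstream
  g2 <- variant_ids(co$variants)[co$variants$gene == "GENE0002"]
  cc2 <- collapse_gene(co$genotypes, design, g2)
  expect_equal(carrier_rate_statistic(cc2$extreme, cc2$control), 0)
})

test_that("planted carrier counts follow the binomial expectation", {
  base <- simulation_config(
    n_extreme = 108, n_control = 101, n_genes = 2, sites_per_gene = 2,
    missing_rate = 0, p_background = 0,
    planted_genes = data.frame(gene = "GENE0001", p_extreme = 0.10,
                               p_control = 0.01, hom_fraction = 0),
    seed = 1)
  ph <- generate_phenotypes(base)
  v <- generate_variants(base)
  counts <- vapply(seq_len(300), function(s) {
    cfg <- base; cfg$seed <- 1000L + s
    generate_genotypes(cfg, v, ph)$truth$carriers_extreme[1]
  }, numeric(1))
  se_mean <- sqrt(108 * 0.10 * 0.90 / 300)
  expect_lt(abs(mean(counts) - 10.8), 3 * se_mean)
})

test_that("genotype matrix dimensions and quality matrix agree", {
  cfg <- tiny_config(lowqual_fraction = 0.1, missing_rate = 0.03)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$genotypes), c(22, 8))
  expect_identical(dimnames(co$genotypes), dimnames(co$quals))
  expect_identical(rownames(co$genotypes), co$phenotypes$sample_id)
  expect_identical(colnames(co$genotypes), variant_ids(co$variants))
  expect_true(anyNA(co$genotypes))
  expect_true(any(co$quals < 20))
})

test_that("planting a gene missing from the variant table errors", {
  cfg <- tiny_config()
  co <- simulate_cohort(cfg)
  bad <- cfg
  bad$planted_genes <- data.frame(gene = "GENE0099", p_extreme = 1,
                                  p_control = 0, hom_fraction = 0)
  expect_error(generate_genotypes(bad, co$variants, co$phenotypes),
               "absent from variants")
})
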