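test_that("gene collapse reproduces the wild/het/hom pattern", {
  g <- geno_fixture(108, 101, sites = 2, het_e = 9, hom_e = 1)
  design <- design_fixture(rownames(g)[1:108], rownames(g)[109:209])
  cc <- collapse_gene(g, design, colnames(g))
  expect_equal(unname(cc$extreme), c(98, 9, 1))
  expect_equal(unname(cc$control), c(101, 0, 0))
  expect_equal(cc$extreme + cc$control, c(A = 199, B = 9, C = 1))
})

test_that("all-missing samples are excluded and multi-site hets count once", {
  g <- geno_fixture(10, 10, sites = 2, het_e = 2)
  g[1, ] <- NA_integer_           # het sample with both calls missing
  g[4, 1] <- NA_integer_          # partially missing wild-type stays A
  g[5, 1] <- 1L; g[5, 2] <- 1L    # het at two sites: one B
  design <- design_fixture(rownames(g)[1:10], rownames(g)[11:20])
  cc <- collapse_gene(g, design, colnames(g))
  expect_equal(cc$excluded_extreme, 1)
  expect_equal(sum(cc$extreme), 9)
  expect_equal(unname(cc$extreme), c(7, 2, 0))
  expect_error(collapse_gene(g, design_fixture("NOPE", rownames(g)[11:20]),
                             colnames(g)), "absent")
})

test_that("carrier-rate statistic matches the published rate column", {
  expect_equal(carrier_rate_statistic(c(97, 11, 0), c(100, 1, 0)), 10.287)
  expect_equal(carrier_rate_statistic(c(97, 11, 0), c(99, 1, 1)), 5.143)
  expect_equal(carrier_rate_statistic(c(98, 10, 0), c(100, 1, 0)), 9.351)
  expect_equal(carrier_rate_statistic(c(97, 10, 1), c(100, 1, 0)), 10.287)
  expect_equal(carrier_rate_statistic(c(100, 8, 0), c(101, 0, 0)), 8)
  expect_equal(carrier_rate_statistic(c(98, 9, 1), c(101, 0, 0)), 10)
  expect_equal(carrier_rate_statistic(c(108, 0, 0), c(101, 0, 0)), 0)
  expect_error(carrier_rate_statistic(c(0, 0, 0), c(1, 0, 0)), "positive")
})

test_that("truncation, not rounding, is applied to the rate", {
  # 1111/216 = 5.14351...: rounding would give 5.144
  expect_equal(carrier_rate_statistic(c(97, 11, 0), c(99, 1, 1)), 5.143)
  # 1010/108 = 9.35185...: rounding would give 9.352
  expect_equal(carrier_rate_statistic(c(98, 10, 0), c(100, 1, 0)), 9.351)
})

test_that("rate is invariant to scaling both groups before truncation", {
  for (k in c(2, 5)) {
    expect_equal(carrier_rate_statistic(c(97, 11, 0) * k, c(100, 1, 0) * k),
                 10.287)
    expect_equal(carrier_rate_statistic(c(98, 10, 0) * k, c(100, 1, 0) * k),
                 9.351)
  }
})

test_that("exact test agrees with full-support enumeration on random tables", {
  expect_equal(fisher_two_sided(c(10, 98), c(0, 101)),
               fisher_oracle(10, 108, 0, 101), tolerance = 1e-12)
  expect_equal(round(fisher_two_sided(c(10, 98), c(0, 101)), 5), 0.0022)
  expect_equal(fisher_two_sided(c(1, 0), c(0, 1)), 1.0)
  expect_equal(fisher_two_sided(c(5, 45), c(5, 45)), 1.0)
  set.seed(99)
  for (i in 1:200) {
    n_e <- sample(2:200, 1)
    n_c <- sample(2:(300 - n_e), 1)
    k_e <- sample(0:n_e, 1)
    k_c <- sample(0:n_c, 1)
    expect_equal(fisher_two_sided(c(k_e, n_e - k_e), c(k_c, n_c - k_c)),
                 fisher_oracle(k_e, n_e, k_c, n_c), tolerance = 1e-9)
    expect_equal(
      fisher_two_sided(c(k_e, n_e - k_e), c(k_c, n_c - k_c), "minlik"),
      fisher_oracle(k_e, n_e, k_c, n_c, "minlik"), tolerance = 1e-9)
  }
})

test_that("minimum-likelihood convention matches fisher.test", {
  set.seed(123)
  for (i in 1:50) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0)) next
    expect_equal(fisher_two_sided(tab[1, ], tab[2, ], "minlik"),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("burden table satisfies componentwise group additivity", {
  cfg <- tiny_config(n_extreme = 30L, n_control = 25L, n_genes = 8L,
                     p_background = 0.2, missing_rate = 0.05)
  co <- simulate_cohort(cfg)
  design <- select_extremes(co$phenotypes, 0.45, 30, 25, matching = FALSE)
  tab <- gene_burden_table(co$genotypes, co$variants, design)
  expect_equal(tab$a_extreme + tab$a_control, tab$a_total)
  expect_equal(tab$b_extreme + tab$b_control, tab$b_total)
  expect_equal(tab$c_extreme + tab$c_control, tab$c_total)
  expect_equal(tab$carrier_samples, tab$b_total + tab$c_total)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$rate >= 0))
})

test_that("gene ranking orders by p, then rate, then score, then symbol", {
  rows <- data.frame(gene = c("B", "A", "C", "D"),
                     rate = c(8, 10.287, 10.287, 5),
                     p = c(0.01, 0.002, 0.002, 0.002),
                     gene_score = NA_real_, stringsAsFactors = FALSE)
  ranked <- rank_genes(rows, top_k = 4)
  expect_equal(ranked$gene, c("A", "C", "D", "B"))
  scores <- data.frame(gene = c("A", "C"), score = c(0.2, 0.9))
  ranked2 <- rank_genes(rows, top_k = 4, gene_scores = scores)
  expect_equal(ranked2$gene, c("C", "A", "D", "B"))
  expect_error(rank_genes(rows, top_k = 0), "positive")
  expect_equal(nrow(rank_genes(rows, top_k = 2)), 2)
})

test_that("the rate statistic recovers the planted carrier-probability ratio", {
  base <- simulation_config(
    n_extreme = 108, n_control = 101, n_genes = 1, sites_per_gene = 2,
    missing_rate = 0,
    planted_genes = data.frame(gene = "GENE0001", p_extreme = 0.30,
                               p_control = 0.10, hom_fraction = 0),
    seed = 1)
  ph <- generate_phenotypes(base)
  v <- generate_variants(base)
  design <- design_fixture(ph$sample_id[1:108], ph$sample_id[109:209])
  sites <- variant_ids(v)
  rates <- vapply(seq_len(500), function(s) {
    cfg <- base; cfg$seed <- 50000L + s
    g <- generate_genotypes(cfg, v, ph)$genotypes
    cc <- collapse_gene(g, design, sites)
    carrier_rate_statistic(cc$extreme, cc$control)
  }, numeric(1))
  # keep replicates where the control group has carriers (zero-control
  # convention switches scale); that event has probability ~1e-5 here
  rates <- rates[rates < 50]
  expect_lt(abs(mean(rates) - 3) / 3, 0.15)
})
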