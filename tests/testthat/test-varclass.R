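test_that("single-gene positions get the expected region labels", {
  gm <- gene_model_set(coding_gene_fixture())
  v <- data.frame(chrom = "chr1",
                  pos = c(150, 110, 380, 250, 50, 410, 5000))
  expect_equal(classify_region(v, gm),
               c("exonic",      # inside CDS
                 "UTR5",        # exon before CDS start (+ strand)
                 "UTR3",        # exon after CDS end
                 "exonic",      # still CDS
                 "upstream",    # within 1 kb before tx start
                 "downstream",  # within 1 kb after tx end
                 "intergenic")) # beyond the flank
  expect_error(classify_region(data.frame(chrom = "chrX", pos = 1), gm),
               "unknown chromosome")
})

test_that("splice windows and intron labels follow the 2-base convention", {
  gm <- gene_model_set(split_gene_fixture())
  # exon1 ends at pos0 200 (1-based 200); first two intron bases are
  # 1-based 201, 202; third is intronic
  v <- data.frame(chrom = "chr1", pos = c(201, 202, 203, 299, 300, 250))
  expect_equal(classify_region(v, gm),
               c("splicing", "splicing", "intronic",
                 "splicing",   # 2 bases before exon2 start
                 "splicing",   # 1 base before exon2 start (pos0 299)
                 "intronic"))
})

test_that("cross-gene conflicts resolve to compounds or precedence", {
  coding <- split_gene_fixture()
  nc <- gene_model("NCRNA", "chr1", "+", exons = cbind(150L, 250L))
  gm <- gene_model_set(coding, nc)
  # 1-based 202 = pos0 201: 2nd intron base of the coding gene (splicing)
  # and inside the noncoding exon -> closed compound
  expect_equal(classify_region(data.frame(chrom = "chr1", pos = 202), gm),
               "splicing/ncRNA_exonic")
  # 1-based 150 = exonic (CDS) for coding, ncRNA_exonic for nc: not one of
  # the closed compounds -> precedence picks exonic
  expect_equal(classify_region(data.frame(chrom = "chr1", pos = 151), gm),
               "exonic")
  # UTR5 of a + gene and UTR3 of a - gene -> UTR5/UTR3 compound
  plus <- coding_gene_fixture("PLUS")
  minus <- gene_model("MINUS", "chr1", "-", exons = cbind(100L, 400L),
                      cds = c(130L, 367L))
  gm2 <- gene_model_set(plus, minus)
  expect_equal(classify_region(data.frame(chrom = "chr1", pos = 110), gm2),
               "UTR5/UTR3")
  # between two + genes: upstream of the right one, downstream of the left
  gm3 <- gene_model_set(
    gene_model("A", "chr1", "+", exons = cbind(2000L, 2500L)),
    gene_model("B", "chr1", "+", exons = cbind(500L, 900L)))
  expect_equal(classify_region(data.frame(chrom = "chr1", pos = 1500), gm3),
               "upstream/downstream")
})

test_that("region categories partition any classified input", {
  gm <- gene_model_set(
    coding_gene_fixture("A"),
    gene_model("NC", "chr1", "+", exons = rbind(c(600L, 700L),
                                                c(800L, 900L))),
    split_gene_fixture("S"))
  set.seed(31)
  v <- data.frame(chrom = "chr1", pos = sample.int(5000, 400, replace = TRUE))
  regions <- classify_region(v, gm)
  expect_true(all(regions %in% REGION_CATEGORIES))
  counts <- table(regions)
  expect_equal(sum(counts), nrow(v))
})

test_that("functional classes follow codon translation and frame arithmetic", {
  gm <- gene_model_set(coding_gene_fixture())
  sub <- function(pos, ref, alt)
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               gene = "CODA", stringsAsFactors = FALSE)
  # codon 2 TAC: third base C (1-based 136); C->A gives TAA (stopgain),
  # C->T gives TAT (nonsynonymous Tyr stays Tyr? TAC and TAT are both Tyr)
  expect_equal(classify_function(sub(136, "C", "A"), gm), "stopgain")
  expect_equal(classify_function(sub(136, "C", "T"), gm), "synonymous")
  # codon 2 first base (1-based 134) T->C: TAC -> CAC, His: nonsynonymous
  expect_equal(classify_function(sub(134, "T", "C"), gm), "nonsynonymous")
  # final stop codon TAA (offsets 234..236): A->C at its second base gives
  # TCA (Ser) -> stoploss
  expect_equal(classify_function(sub(366, "A", "C"), gm), "stoploss")
  # indels: anchor-base VCF representation
  expect_equal(classify_function(sub(140, "CG", "C"), gm),
               "frameshift deletion")
  expect_equal(classify_function(sub(140, "C", "CAGT"), gm),
               "nonframeshift insertion")
  expect_equal(classify_function(sub(140, "CAGTA", "C"), gm),
               "frameshift deletion")
  # reference mismatch and non-CDS positions are unknown, not errors
  expect_equal(classify_function(sub(136, "G", "A"), gm), "unknown")
  expect_equal(classify_function(sub(110, "A", "G"), gm), "unknown")
})

test_that("functional classification is invariant to strand representation", {
  plus <- coding_gene_fixture("P", strand = "+")
  minus <- coding_gene_fixture("M", strand = "-")
  gm <- gene_model_set(plus, minus)
  # same coding event (codon 2 TAC->TAA) seen from each strand: on the minus
  # gene the coding offset 5 maps to genomic pos0 130 + (237-1-5) = 361,
  # and the alleles are complemented
  v_plus <- data.frame(chrom = "chr1", pos = 136, ref = "C", alt = "A",
                       gene = "P", stringsAsFactors = FALSE)
  v_minus <- data.frame(chrom = "chr1", pos = 362, ref = "G", alt = "T",
                        gene = "M", stringsAsFactors = FALSE)
  expect_equal(classify_function(v_plus, gm), "stopgain")
  expect_equal(classify_function(v_minus, gm), "stopgain")
})

test_that("InDel length binning reproduces reference percentages", {
  counts <- c("1-5" = 37442, "6-10" = 3123, "11-15" = 1010, "16-20" = 617,
              ">20" = 852, "-5 to -1" = 51494, "-10 to -6" = 4468,
              "-15 to -11" = 1953, "-20 to -16" = 967, "<-20" = 2084)
  reps <- c(3, 8, 13, 18, 25, -3, -8, -13, -18, -25)
  lens <- rep(reps, counts)
  tab <- indel_length_table(lens)
  expect_equal(tab$count[match(names(counts), tab$bin)], unname(counts))
  expect_equal(tab$percent[tab$bin == "1-5"], 36.00)
  expect_equal(tab$percent[tab$bin == "-5 to -1"], 49.51)
  expect_lt(abs(sum(tab$percent) - 100), 0.05)
})

test_that("InDel table handles degenerate inputs and excludes substitutions", {
  tab <- indel_length_table(c(2, 2, 0, 0, 0))
  expect_equal(attr(tab, "n_snv_excluded"), 3)
  expect_equal(attr(tab, "n_total"), 2)
  expect_equal(tab$percent[tab$bin == "1-5"], 100.00)
  v <- rbind(variant_row(ref = "A", alt = "AT"),
             variant_row(ref = "ACGT", alt = "A"))
  tab2 <- indel_length_table(v)
  expect_equal(tab2$count[tab2$bin == "1-5"], 1)
  expect_equal(tab2$count[tab2$bin == "-5 to -1"], 1)
})
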