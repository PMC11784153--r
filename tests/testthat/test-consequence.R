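# toy gene: CDS "ATGGAATAA" = Met-Glu-Stop on the plus strand
toy_gene_genome <- function() {
  g <- toy_genome(paste0("TTTT", "ATGGAATAA", "TTTT"))
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "c1",
                                  start = 4L, end = 13L, strand = "+",
                                  phase = 0L))
  list(genome = g, genes = genes)
}

test_that("SNV consequences follow the codon table", {
  fx <- toy_gene_genome()
  # codon 2 GAA(Glu) -> GAG(Glu): synonymous (position 9 0-based)
  v <- make_variants(fx$genome, "L1", "c1", 9L, "A", "G")
  ann <- annotate_consequences(v, fx$genes, fx$genome)
  expect_equal(ann$consequence, "synonymous")
  # codon 2 GAA -> AAA: missense Glu->Lys
  v2 <- make_variants(fx$genome, "L1", "c1", 7L, "G", "A")
  expect_equal(annotate_consequences(v2, fx$genes,
                                     fx$genome)$consequence, "missense")
  # stop codon TAA -> CAA: stop_lost
  v3 <- make_variants(fx$genome, "L1", "c1", 10L, "T", "C")
  expect_equal(annotate_consequences(v3, fx$genes,
                                     fx$genome)$consequence, "stop_lost")
  # start codon ATG -> TTG: start_lost
  v4 <- make_variants(fx$genome, "L1", "c1", 4L, "A", "T")
  expect_equal(annotate_consequences(v4, fx$genes,
                                     fx$genome)$consequence, "start_lost")
  # missense -> stop: stop_gained (GAA -> TAA at codon 2)
  v5 <- make_variants(fx$genome, "L1", "c1", 7L, "G", "T")
  expect_equal(annotate_consequences(v5, fx$genes,
                                     fx$genome)$consequence, "stop_gained")
  # outside any CDS: noncoding
  v6 <- make_variants(fx$genome, "L1", "c1", 1L, "T", "A")
  expect_equal(annotate_consequences(v6, fx$genes,
                                     fx$genome)$consequence, "noncoding")
})

test_that("CDS indel consequences depend on length mod 3", {
  fx <- toy_gene_genome()
  # 2 bp deletion inside the CDS: frameshift
  v <- make_variants(fx$genome, "L1", "c1", 6L, "GGA", "G")
  expect_equal(annotate_consequences(v, fx$genes,
                                     fx$genome)$consequence, "frameshift")
  # 3 bp deletion: in-frame
  v2 <- make_variants(fx$genome, "L1", "c1", 6L, "GGAA", "G")
  expect_equal(annotate_consequences(v2, fx$genes,
                                     fx$genome)$consequence,
               "inframe_indel")
  # SNVs never frameshift; CDS indels with len %% 3 != 0 always do
  expect_false(any(annotate_consequences(
    make_variants(fx$genome, "L1", "c1", 9L, "A", "G"),
    fx$genes, fx$genome)$consequence == "frameshift"))
})

test_that("minus-strand genes give the same consequences (metamorphic)", {
  fx <- toy_gene_genome()
  fwd <- fx$genome$seq[["c1"]]
  rev <- oracle_revcomp(fwd)
  g_rev <- toy_genome(rev)
  L <- nchar(fwd)
  genes_rev <- gene_models(data.frame(gene_id = "g1", chrom = "c1",
                                      start = L - 13L, end = L - 4L,
                                      strand = "-", phase = 0L))
  # mirror each SNV: position p -> L-1-p, alleles complemented
  cases <- list(c(9L, "A", "G"), c(7L, "G", "A"), c(10L, "T", "C"),
                c(4L, "A", "T"))
  for (cs in cases) {
    p <- as.integer(cs[1])
    v_fwd <- make_variants(fx$genome, "L1", "c1", p, cs[2], cs[3])
    v_rev <- make_variants(g_rev, "L1", "c1", L - 1L - p,
                           chartr("ACGT", "TGCA", cs[2]),
                           chartr("ACGT", "TGCA", cs[3]))
    expect_equal(
      annotate_consequences(v_rev, genes_rev, g_rev)$consequence,
      annotate_consequences(v_fwd, fx$genes, fx$genome)$consequence)
  }
})

test_that("coding fraction test matches the hand chi-squared formula", {
  fx <- toy_gene_genome()
  # genome 17 bp, CDS 9 bp
  expect_equal(coding_fraction(fx$genes, fx$genome), 9 / 17)
  # all variants coding with coding fraction 0.5, n = 100 -> X2 = 100
  g <- toy_genome(paste0(strrep("A", 50), strrep("C", 50)))
  genes <- gene_models(data.frame(gene_id = "g", chrom = "c1",
                                  start = 0L, end = 51L, strand = "+",
                                  phase = 0L))
  # put 100 SNVs at coding positions (fraction 0.51; use exact 0.5 math)
  ann <- data.frame(consequence = rep("missense", 100))
  f <- coding_fraction(genes, g)
  res <- coding_fraction_test(ann, genes, g)
  oracle <- (100 - 100 * f)^2 / (100 * f) +
    (0 - 100 * (1 - f))^2 / (100 * (1 - f))
  expect_equal(res$statistic, oracle)
  expect_equal(res$n_coding + res$n_noncoding, 100)
  # observed proportions equal to the genomic fraction -> statistic 0
  g2 <- toy_genome(strrep("ACGT", 25))
  genes2 <- gene_models(data.frame(gene_id = "g", chrom = "c1",
                                   start = 0L, end = 51L, strand = "+",
                                   phase = 0L))
  ann2 <- data.frame(consequence = c(rep("missense", 51),
                                     rep("noncoding", 49)))
  expect_equal(coding_fraction_test(ann2, genes2, g2)$statistic, 0)
})

test_that("annotation on simulated genes partitions all variants", {
  gg <- generate_genome(40000, seed = 19)
  pr <- condition_profile("spontaneous")
  pr$snv_rates <- pr$snv_rates * 5e3   # scale up for a small genome
  pr$indel_rates <- pr$indel_rates * 5e3
  sim <- simulate_lines(gg$genome, pr, n_lines = 2, n_cycles = 50L,
                        t = 25L, seed = 23)
  ann <- annotate_consequences(sim$variants, gg$genes, gg$genome)
  expect_equal(nrow(ann), nrow(sim$variants))
  expect_true(all(ann$consequence %in%
                    c("missense", "synonymous", "stop_gained",
                      "stop_lost", "start_lost", "frameshift",
                      "inframe_indel", "noncoding", "unannotatable")))
  n_cod <- sum(!ann$consequence %in% c("noncoding", "unannotatable"))
  expect_equal(n_cod + sum(ann$consequence %in%
                             c("noncoding", "unannotatable")),
               nrow(ann))
})
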