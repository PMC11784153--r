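test_that("read_genome parses FASTA, uppercases and totals lengths", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), fa)
  g <- read_genome(fa)
  expect_equal(g$seq[["c1"]], "ACGT")
  expect_equal(g$total_length, 4L)

  writeLines(c(">c1", "ACGTACGTAC", ">c2", "acgtn"), fa)
  g <- read_genome(fa)
  expect_equal(g$total_length, 15L)
  expect_equal(g$seq[["c2"]], "ACGTN")  # soft-mask uppercased, N kept
})

test_that("read_genome rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACXT"), fa)
  expect_error(read_genome(fa), "non-nucleotide")
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(read_genome(fa), "duplicate")
  expect_error(mae_genome(character(0)), "no sequences")
})

test_that("gc_content matches brute-force tally and handles N", {
  expect_equal(gc_content(toy_genome("GGCC")), 1.0)
  expect_equal(gc_content(toy_genome("ATAT")), 0.0)
  expect_equal(gc_content(toy_genome("ATGCNN")), 0.5)
  expect_error(gc_content(toy_genome("NNNN")), "no A/C/G/T")

  s <- random_seq(10000, seed = 42, gc = 0.6)
  tab <- table(strsplit(s, "")[[1]])
  oracle <- (tab[["G"]] + tab[["C"]]) / sum(tab)
  expect_equal(gc_content(toy_genome(s)), unname(oracle))
})

test_that("variant normalization left-aligns against exhaustive oracle", {
  # run "CAAAA": a 1 bp A-deletion must shift to the run's left edge
  g <- toy_genome("GCAAAAT")
  nv <- normalize_variant(g, "c1", 1L, "CAA", "CA")
  expect_equal(nv, list(pos = 1L, ref = "CA", alt = "C"))

  # oracle: enumerate every anchored representation of deleting one A
  # from the run and check all normalize to the same leftmost form
  s <- "GCAAAAT"
  for (p in 1:4) {
    ref_p <- substr(s, p + 1, p + 2)  # anchor base + one run base
    alt_p <- substr(s, p + 1, p + 1)
    nv2 <- normalize_variant(g, "c1", p, ref_p, alt_p)
    expect_equal(nv2, list(pos = 1L, ref = "CA", alt = "C"))
  }

  # parsimony trimming: "AT" > "A" is a 1 bp deletion
  g2 <- toy_genome("GATTC")
  nv3 <- normalize_variant(g2, "c1", 1L, "AT", "A")
  expect_equal(nchar(nv3$ref) - nchar(nv3$alt), 1L)

  # idempotence: normalizing twice equals normalizing once
  nv4 <- normalize_variant(g, "c1", nv$pos, nv$ref, nv$alt)
  expect_equal(nv4, nv)
})

test_that("make_variants validates ref, classifies, rejects MNVs", {
  g <- toy_genome("ACGTA")
  v <- make_variants(g, "L1", "c1", 2L, "G", "T")
  expect_equal(v$vclass, "SNV")
  expect_error(make_variants(g, "L1", "c1", 2L, "A", "T"),
               "ref allele mismatch")
  expect_warning(v2 <- make_variants(g, "L1", "c1", 1L, "CG", "GA"),
                 "multi-nucleotide")
  expect_equal(nrow(v2), 0L)
})

test_that("read_variants converts VCF coordinates and splits alleles", {
  g <- toy_genome("ACGTA")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               "c1\t3\t.\tG\tT\t.\tPASS\t.",
               "c1\t4\t.\tT\tA,C\t.\tPASS\t."), vcf)
  v <- read_variants(vcf, g, "L1")
  expect_equal(nrow(v), 3L)           # multi-allelic split
  expect_equal(v$pos[1], 2L)          # 1-based -> 0-based
  expect_true(all(v$vclass == "SNV"))

  # TSV dialect
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos_1based\tref\talt", "c1\t3\tGT\tG"), tsv)
  v2 <- read_variants(tsv, g, "L2")
  expect_equal(v2$vclass, "deletion")
  expect_equal(v2$indel_len, 1L)
})

test_that("variant round trip preserves alleles and 1-based positions", {
  g <- toy_genome("ACGTACGTAC")
  v <- make_variants(g, "L1", rep("c1", 3), c(1L, 4L, 6L),
                     c("C", "AC", "G"), c("A", "A", "GTT"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v, f, g)
  v2 <- read_variants(f, g, "L1")
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$ref, v$ref)
  expect_equal(v2$alt, v$alt)
})

test_that("gene models read from GFF3 and get validated", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("c1", "test", "gene", "11", "19", ".", "+", ".",
                     "ID=g1", sep = "\t"),
               paste("c1", "test", "CDS", "11", "19", ".", "+", "0",
                     "ID=g1.c;Parent=g1", sep = "\t")), gff)
  genes <- read_genes(gff)
  expect_equal(genes$start, 10L)  # 0-based
  expect_equal(genes$end, 19L)
  expect_equal(attr(genes, "flagged"), character(0))

  # CDS length not a codon multiple -> flagged, not fatal
  bad <- gene_models(data.frame(gene_id = "gX", chrom = "c1",
                                start = 0L, end = 10L, strand = "+",
                                phase = 0L))
  expect_equal(attr(bad, "flagged"), "gX")
})
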