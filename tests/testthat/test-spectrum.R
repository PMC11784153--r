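test_that("SNV classification follows the pyrimidine convention", {
  expect_equal(classify_snv("C", "T")$class, "C>T")
  expect_equal(classify_snv("C", "T")$type, "transition")
  g2a <- classify_snv("G", "A")   # purine call reflects C>T
  expect_equal(g2a$class, "C>T")
  expect_true(g2a$purine_ref)
  expect_equal(classify_snv("A", "C")$class, "T>G")
  expect_equal(classify_snv("A", "C")$type, "transversion")
  expect_error(classify_snv("AT", "A"), "single-base")
  # double reverse-complement normalization is the identity
  for (r in c("C", "T")) for (a in setdiff(c("A", "C", "G", "T"), r)) {
    direct <- classify_snv(r, a)$class
    back <- classify_snv(chartr("ACGT", "TGCA", r),
                         chartr("ACGT", "TGCA", a))$class
    expect_equal(back, direct)
  }
})

test_that("snv_context orients to the pyrimidine strand", {
  g <- toy_genome("AAGTA")
  v <- one_variant(g, "c1", 2L, "G", "A")
  # plus-strand "AGT" reverse-complemented = "ACT": center C, class C>T
  expect_equal(as.vector(snv_context(g, v, k = 1)), "ACT")
  expect_equal(oracle_revcomp("AGT"), "ACT")  # independent check
  # pyrimidine center returned unmodified
  v2 <- one_variant(g, "c1", 3L, "T", "C")
  expect_equal(as.vector(snv_context(g, v2, k = 1)), "GTA")
  # chromosome-end SNV excluded and counted
  v3 <- one_variant(g, "c1", 0L, "A", "G")
  ctx <- snv_context(g, v3, k = 1)
  expect_true(is.na(ctx[1]))
  expect_equal(attr(ctx, "n_excluded"), 1L)
})

test_that("sbs96 counts conserve totals and match brute-force tally", {
  g <- toy_genome("AAGTA")
  v <- one_variant(g, "c1", 2L, "G", "A")
  cnt <- sbs96_counts(v, g)
  expect_equal(sum(cnt), 1L)
  expect_equal(unname(cnt[["A[C>T]T"]]), 1L)

  # 500 uniform SNVs on a random genome: independent re-count
  s <- random_seq(20000, seed = 13)
  g2 <- toy_genome(s)
  set.seed(99)
  pos <- sample(1:(nchar(s) - 2), 500)
  ref <- substr(rep(s, 500), pos + 1, pos + 1)
  ref <- vapply(seq_along(pos), function(i) substr(s, pos[i] + 1, pos[i] + 1),
                character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  v2 <- make_variants(g2, "L1", rep("c1", 500), pos, ref, alt)
  cnt2 <- sbs96_counts(v2, g2)
  expect_equal(sum(cnt2), 500L)
  # oracle: per-variant string operations, no package internals
  oracle <- integer(0)
  for (i in seq_along(pos)) {
    tri <- substr(s, pos[i], pos[i] + 2)
    r <- ref[i]; a <- alt[i]
    if (r %in% c("A", "G")) {
      tri <- oracle_revcomp(tri)
      r <- chartr("ACGT", "TGCA", r); a <- chartr("ACGT", "TGCA", a)
    }
    key <- paste0(substr(tri, 1, 1), "[", r, ">", a, "]",
                  substr(tri, 3, 3))
    oracle[key] <- (if (is.na(oracle[key])) 0L else oracle[key]) + 1L
  }
  for (key in names(oracle))
    expect_equal(unname(cnt2[[key]]), unname(oracle[[key]]))
  # six-class collapse equals direct six-class counting
  cls <- classify_snv(v2$ref, v2$alt)$class
  direct <- table(factor(cls, levels = SUB_CLASSES))
  expect_equal(unname(collapse_to_classes(cnt2)),
               unname(as.integer(direct)))
})

test_that("genome context expectation matches hand enumeration", {
  g <- toy_genome(strrep("C", 50))
  e <- genome_context_expectation(g)
  expect_equal(unname(e[["CCC"]]), 1)
  # periodic genome ACGTACGT...: plus-strand trinucs cycle through
  # ACG, CGT, GTA, TAC; normalized: CGT(ACG), CGT? -> enumerate by hand
  g2 <- toy_genome(strrep("ACGT", 25))
  e2 <- genome_context_expectation(g2)
  s <- strrep("ACGT", 25)
  tally <- table(vapply(1:(nchar(s) - 2), function(i) {
    tri <- substr(s, i, i + 2)
    if (substr(tri, 2, 2) %in% c("A", "G")) oracle_revcomp(tri) else tri
  }, character(1)))
  for (ctr in c("C", "T")) {
    sel <- names(tally)[substr(names(tally), 2, 2) == ctr]
    for (k in sel)
      expect_equal(unname(e2[[k]]), unname(tally[[k]] / sum(tally[sel])))
  }
  # frequencies conditioned on each center base sum to 1
  expect_equal(sum(e2[substr(names(e2), 2, 2) == "C"]), 1)
  expect_equal(sum(e2[substr(names(e2), 2, 2) == "T"]), 1)
})

test_that("context enrichment chi-squared equals the hand formula", {
  # one class with 40 SNVs, 30 in a context of expected frequency 0.25
  counts <- stats::setNames(integer(96), sbs96_categories())
  counts[["A[C>T]A"]] <- 30L
  others <- setdiff(grep("C>T", sbs96_categories(), fixed = TRUE,
                         value = TRUE), "A[C>T]A")
  counts[others[1:10]] <- 1L   # class total 40
  expectation <- stats::setNames(rep(0.75 / 15, 32),
                                 names(genome_context_expectation(
                                   toy_genome(random_seq(3000, 1)))))
  expectation[["ACA"]] <- 0.25
  res <- suppressWarnings(context_enrichment(counts, expectation,
                                             min_class_count = 10))
  row <- res[res$class == "C>T" & res$trinuc == "ACA", ]
  expect_equal(row$statistic,
               (30 - 10)^2 / 10 + (10 - 30)^2 / 30)
  expect_equal(row$p,
               stats::pchisq((30 - 10)^2 / 10 + (10 - 30)^2 / 30, 1,
                             lower.tail = FALSE))
  expect_true(row$enriched)
})

test_that("counts proportional to expectation are not flagged", {
  g <- toy_genome(random_seq(50000, seed = 21))
  e <- genome_context_expectation(g)
  counts <- stats::setNames(integer(96), sbs96_categories())
  # build counts exactly proportional to expectation (rounded)
  for (cl in SUB_CLASSES) {
    ctr <- substr(cl, 1, 1)
    for (p5 in c("A", "C", "G", "T")) for (p3 in c("A", "C", "G", "T")) {
      key <- paste0(p5, "[", cl, "]", p3)
      counts[[key]] <- round(400 * e[[paste0(p5, ctr, p3)]])
    }
  }
  res <- suppressWarnings(context_enrichment(counts, e))
  expect_true(all(res$p_adj[res$enriched] > 0.01))
})

test_that("flank matrices report frequencies and information in bits", {
  # constructed fixture: C>T SNVs placed only after a 5' T
  s <- paste0(strrep("A", 10), strrep("TC", 50), strrep("A", 10))
  g <- toy_genome(s)
  pos <- seq(11L, 108L, by = 2L)  # every C, 0-based, 5' base is T
  v <- make_variants(g, "L1", rep("c1", length(pos)), pos,
                     rep("C", length(pos)), rep("T", length(pos)))
  fm <- flank_matrix(v, g, window = 1)
  expect_equal(unname(fm$freq["T", "-1"]), 1)
  expect_true(all(abs(colSums(fm$freq) - 1) < 1e-12))
  expect_equal(unname(fm$info[["-1"]]), 2)   # fully determined: 2 bits
  expect_true(all(fm$info >= 0 & fm$info <= 2))

  # identical flanks everywhere -> 2 bits at every position
  s2 <- strrep("GACTG", 30)
  g2 <- toy_genome(s2)
  pos2 <- seq(2L, 140L, by = 5L)  # every central C in GACTG
  v2 <- make_variants(g2, "L1", rep("c1", length(pos2)), pos2,
                      rep("C", length(pos2)), rep("A", length(pos2)))
  fm2 <- flank_matrix(v2, g2, window = 2)
  expect_true(all(abs(fm2$info - 2) < 1e-12))
})

test_that("G/C site composition test matches exact binomial oracle", {
  g <- toy_genome(random_seq(1000, 3))
  v <- data.frame(line_id = "L", chrom = "c1", pos = 0L,
                  ref = rep("C", 100), alt = "T", vclass = "SNV",
                  indel_len = 0L)
  r <- site_composition_test(v, 0.5)
  expect_equal(r$fraction_gc, 1)
  expect_lt(r$p_value, 1e-20)

  # 160 of 247 at G/C vs genomic 0.494: brute-force two-sided sum
  v2 <- data.frame(line_id = "L", chrom = "c1", pos = 0L,
                   ref = c(rep("G", 80), rep("C", 80), rep("A", 50),
                           rep("T", 37)),
                   alt = "N", vclass = "SNV", indel_len = 0L)
  v2$alt <- ifelse(v2$ref == "A", "G", "A")
  r2 <- site_composition_test(v2, 0.494)
  dens <- stats::dbinom(0:247, 247, 0.494)
  p_oracle <- sum(dens[dens <= stats::dbinom(160, 247, 0.494) *
                         (1 + 1e-7)])
  expect_equal(r2$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(r2$fraction_gc + mean(v2$ref %in% c("A", "T")), 1)
})
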