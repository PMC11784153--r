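# Pyrimidine-normalized substitution classes and the SBS96
# trinucleotide classification (COSMIC convention).

#' The six pyrimidine-referenced substitution classes
#' @export
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# 32 pyrimidine-centered trinucleotides, and 96 SBS category names in
# COSMIC order (class-major, then 5' base, then 3' base).
#' @noRd
pyr_trinucs <- function(center) {
  as.vector(outer(DNA_BASES, DNA_BASES,
                  function(a, b) paste0(a, center, b)))
}

#' SBS96 category names in COSMIC order, e.g. "A[C>A]A"
#' @export
sbs96_categories <- function() {
  out <- character(0)
  for (cl in SUB_CLASSES) {
    ctr <- substr(cl, 1, 1)
    for (p5 in DNA_BASES) for (p3 in DNA_BASES)
      out <- c(out, paste0(p5, "[", cl, "]", p3))
  }
  out
}

#' Classify SNVs into pyrimidine-normalized substitution classes
#'
#' Substitutions called on the purine strand are mapped to their
#' reverse-complement class (G>A becomes C>T, etc.), the COSMIC SBS
#' convention.
#'
#' @param ref,alt single-base allele vectors.
#' @return data.frame with `class` (one of `C>A, C>G, C>T, T>A, T>C,
#'   T>G`), `type` (`transition`/`transversion`) and `purine_ref`
#'   (whether the original call was on a purine base).
#' @export
classify_snv <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L | ref == alt))
    stopf("classify_snv expects single-base substitutions")
  purine <- is_purine(ref)
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  cls <- paste0(r, ">", a)
  stopifnot(all(cls %in% SUB_CLASSES))
  data.frame(class = cls,
             type = ifelse(cls %in% c("C>T", "T>C"),
                           "transition", "transversion"),
             purine_ref = purine, stringsAsFactors = FALSE)
}

#' Oriented flanking context of SNVs
#'
#' Extracts the `2k+1`-mer centered on each SNV and reverse-complements
#' it when the reference base is a purine, so the center is always a
#' pyrimidine. SNVs within `k` bases of a chromosome end, or whose
#' context contains `N`, are excluded (returned as `NA`) and counted in
#' the `n_excluded` attribute.
#'
#' @param genome an `mae_genome`.
#' @param variants variant table (non-SNVs are an error).
#' @param k flank length on each side (default 1: trinucleotides).
#' @return character vector of oriented contexts with attribute
#'   `n_excluded`.
#' @export
snv_context <- function(genome, variants, k = 1L) {
  if (nrow(variants) > 0L && any(variants$vclass != "SNV"))
    stopf("snv_context expects SNVs only")
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  if (n > 0L) {
    lens <- genome$lengths[variants$chrom]
    ok <- variants$pos >= k & variants$pos + k < lens
    ctx <- character(sum(ok))
    idx <- which(ok)
    for (j in seq_along(idx)) {
      i <- idx[j]
      ctx[j] <- subseq0(genome$seq[[variants$chrom[i]]],
                        variants$pos[i] - k, variants$pos[i] + k + 1L)
    }
    hasN <- grepl("N", ctx, fixed = TRUE)
    ctx[hasN] <- NA_character_
    purine <- is_purine(variants$ref[idx])
    ctx[purine & !hasN] <- revcomp(ctx[purine & !hasN])
    out[idx] <- ctx
  }
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' SBS96 category counts
#'
#' Counts SNVs in the 96 trinucleotide substitution categories
#' (pyrimidine-normalized center, COSMIC ordering). The vector sums to
#' the number of SNVs minus context exclusions.
#'
#' @param variants variant table; non-SNV rows are ignored.
#' @param genome an `mae_genome`.
#' @return named integer vector of length 96 with attribute
#'   `n_excluded`.
#' @export
sbs96_counts <- function(variants, genome) {
  snvs <- variants[variants$vclass == "SNV", , drop = FALSE]
  cats <- factor(character(0), levels = sbs96_categories())
  excl <- 0L
  if (nrow(snvs) > 0L) {
    ctx <- snv_context(genome, snvs, k = 1L)
    cls <- classify_snv(snvs$ref, snvs$alt)$class
    keep <- !is.na(ctx)
    excl <- sum(!keep)
    cats <- factor(paste0(substr(ctx[keep], 1, 1), "[", cls[keep], "]",
                          substr(ctx[keep], 3, 3)),
                   levels = sbs96_categories())
  }
  out <- table(cats)
  res <- stats::setNames(as.integer(out), names(out))
  attr(res, "n_excluded") <- excl
  res
}

#' Collapse SBS96 counts to the six substitution classes
#'
#' @param counts96 named 96-vector from [sbs96_counts()].
#' @return named integer vector over the six classes.
#' @export
collapse_to_classes <- function(counts96) {
  cls <- sub("^.\\[(.+)\\].$", "\\1", names(counts96))
  tab <- tapply(as.integer(counts96), factor(cls, levels = SUB_CLASSES),
                sum)
  stats::setNames(as.integer(tab), SUB_CLASSES)
}

#' Expected trinucleotide frequencies from genome composition
#'
#' For each pyrimidine-normalized trinucleotide, its frequency among
#' genome positions whose normalized center base matches. Both strands
#' are counted via the normalization (a purine-centered trinucleotide
#' contributes to its reverse complement). Frequencies sum to 1 within
#' each center base (C and T).
#'
#' @param genome an `mae_genome`.
#' @return named numeric vector over the 32 pyrimidine-centered
#'   trinucleotides.
#' @export
genome_context_expectation <- function(genome) {
  dss <- Biostrings::DNAStringSet(genome$seq)
  tf <- colSums(Biostrings::trinucleotideFrequency(dss, step = 1))
  tf <- tf[!grepl("N", names(tf))]
  keys <- names(tf)
  ctr <- substr(keys, 2, 2)
  norm <- ifelse(ctr %in% PYRIMIDINES, keys, revcomp(keys))
  counts <- tapply(tf, norm, sum)
  out <- stats::setNames(numeric(32),
                         c(pyr_trinucs("C"), pyr_trinucs("T")))
  out[names(counts)] <- counts
  for (ctr in PYRIMIDINES) {
    sel <- substr(names(out), 2, 2) == ctr
    s <- sum(out[sel])
    if (s > 0) out[sel] <- out[sel] / s
  }
  out
}

#' Trinucleotide-context enrichment tests
#'
#' Within each substitution-class family, each trinucleotide's observed
#' count is compared to its expectation under the genome composition
#' (class total x genome frequency of that context) with a 1-df
#' chi-squared goodness-of-fit test against the complement. Categories
#' with expected counts below 5 fall back to an exact binomial test.
#' P values are adjusted within each class family.
#'
#' @param counts96 named 96-vector from [sbs96_counts()].
#' @param expectation 32-vector from [genome_context_expectation()].
#' @param min_class_count families with fewer SNVs are skipped with a
#'   warning.
#' @param adjust multiple-testing adjustment within family:
#'   `"bonferroni"` (default, conservative) or `"BH"`.
#' @return data.frame with one row per tested category: `class`,
#'   `trinuc`, `observed`, `expected`, `statistic`, `p`, `p_adj`,
#'   `enriched` (observed > expected), `method`.
#' @export
context_enrichment <- function(counts96, expectation,
                               min_class_count = 10L,
                               adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  res <- list()
  for (cl in SUB_CLASSES) {
    ctr <- substr(cl, 1, 1)
    cats <- paste0(rep(DNA_BASES, each = 4), "[", cl, "]", DNA_BASES)
    obs <- as.integer(counts96[cats])
    n <- sum(obs)
    if (n < min_class_count) {
      warnf("class %s has %d SNVs (< %d); enrichment family skipped",
            cl, n, min_class_count)
      next
    }
    trinuc <- paste0(substr(cats, 1, 1), ctr, substr(cats, 7, 7))
    ef <- expectation[trinuc]
    expd <- n * ef
    stat <- p <- numeric(length(obs))
    method <- character(length(obs))
    for (i in seq_along(obs)) {
      if (expd[i] >= 5 && (n - expd[i]) >= 5) {
        stat[i] <- (obs[i] - expd[i])^2 / expd[i] +
          ((n - obs[i]) - (n - expd[i]))^2 / (n - expd[i])
        p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
        method[i] <- "chisq"
      } else {
        stat[i] <- NA_real_
        p[i] <- stats::binom.test(obs[i], n, ef[i])$p.value
        method[i] <- "binomial"
      }
    }
    res[[cl]] <- data.frame(
      class = cl, trinuc = trinuc, observed = obs,
      expected = as.numeric(expd), statistic = stat, p = p,
      p_adj = stats::p.adjust(p, method = adjust),
      enriched = obs > expd, method = method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Position frequency and information matrix of SNV flanks
#'
#' Base frequencies at each flanking position on the
#' pyrimidine-normalized strand, plus the per-position information
#' content `2 - H` (bits), the quantity sequence-logo tools draw. No
#' small-sample correction is applied.
#'
#' @param variants SNV table, typically restricted to one substitution
#'   class.
#' @param genome an `mae_genome`.
#' @param window flank length on each side (default 4).
#' @return object of class `flank_matrix`: list with `freq` (4 x 2*window
#'   matrix, rows A/C/G/T, columns -window..-1, +1..+window), `info`
#'   (bits per position), `n` (SNVs used).
#' @export
flank_matrix <- function(variants, genome, window = 4L) {
  snvs <- variants[variants$vclass == "SNV", , drop = FALSE]
  if (nrow(snvs) == 0L) stopf("no SNVs to build a flank matrix from")
  ctx <- snv_context(genome, snvs, k = window)
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx) == 0L)
    stopf("all SNVs excluded (chromosome ends / N contexts)")
  m <- do.call(rbind, strsplit(ctx, "", fixed = TRUE))
  m <- m[, -(window + 1L), drop = FALSE]  # drop the mutated center
  pos_labels <- c(-(window:1), 1:window)
  freq <- apply(m, 2, function(col)
    table(factor(col, levels = DNA_BASES)) / length(col))
  dimnames(freq) <- list(DNA_BASES, pos_labels)
  ent <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(freq = freq, info = 2 - ent, n = length(ctx)),
            class = "flank_matrix")
}

#' @export
print.flank_matrix <- function(x, ...) {
  cat(sprintf("<flank_matrix> %d SNVs\n", x$n))
  print(round(x$freq, 3))
  cat("information (bits):\n")
  print(round(x$info, 3))
  invisible(x)
}

#' Test SNV composition at G/C sites against genome GC content
#'
#' Fraction of SNVs whose original reference base is G or C, compared
#' to the genomic GC fraction with a two-sided exact binomial test.
#'
#' @param variants SNV table.
#' @param genome_gc genomic GC fraction (see [gc_content()]).
#' @return list with `fraction_gc`, `n_gc`, `n`, `p_value`.
#' @export
site_composition_test <- function(variants, genome_gc) {
  snvs <- variants[variants$vclass == "SNV", , drop = FALSE]
  if (nrow(snvs) == 0L) stopf("no SNVs")
  x <- sum(snvs$ref %in% c("G", "C"))
  n <- nrow(snvs)
  bt <- stats::binom.test(x, n, genome_gc, alternative = "two.sided")
  list(fraction_gc = x / n, n_gc = x, n = n, p_value = bt$p.value)
}
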