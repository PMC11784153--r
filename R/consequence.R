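# Coding/non-coding partition and lightweight consequence classes.

# severity order, most severe first, used when a variant hits several
# genes
CONSEQ_SEVERITY <- c("frameshift", "stop_gained", "stop_lost",
                     "start_lost", "missense", "inframe_indel",
                     "synonymous", "noncoding", "unannotatable")

# Spliced CDS sequence of one gene in transcription direction, with the
# genomic coordinate of each CDS base.
#' @noRd
gene_cds_sequence <- function(genome, cds) {
  seq <- genome$seq[[cds$chrom[1]]]
  minus <- cds$strand[1] == "-"
  pieces <- character(nrow(cds))
  coords <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    s <- subseq0(seq, cds$start[i], cds$end[i])
    if (minus) {
      pieces[i] <- revcomp(s)
      coords[[i]] <- seq.int(cds$end[i] - 1L, cds$start[i])
    } else {
      pieces[i] <- s
      coords[[i]] <- seq.int(cds$start[i], cds$end[i] - 1L)
    }
  }
  phase <- cds$phase[1]
  cds_seq <- paste(pieces, collapse = "")
  pos_map <- unlist(coords)
  if (phase > 0L) {
    cds_seq <- substr(cds_seq, phase + 1L, nchar(cds_seq))
    pos_map <- pos_map[-seq_len(phase)]
  }
  list(seq = cds_seq, pos_map = pos_map, minus = minus)
}

#' @noRd
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Consequence of one SNV inside one gene.
#' @noRd
snv_consequence <- function(genome, gene_cds, v) {
  g <- gene_cds_sequence(genome, gene_cds)
  cds_idx <- match(v$pos, g$pos_map)
  if (is.na(cds_idx)) return("noncoding")
  codon_i <- (cds_idx - 1L) %/% 3L
  off <- (cds_idx - 1L) %% 3L
  codon <- substr(g$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return("unannotatable")
  alt_base <- if (g$minus) complement_base(v$alt) else v$alt
  alt_codon <- codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_base
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unannotatable")
  if (codon_i == 0L && codon == "ATG" && alt_codon != "ATG")
    return("start_lost")
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_ref == "*") return("stop_lost")
  if (aa_alt == "*") return("stop_gained")
  "missense"
}

#' Annotate variants with coding consequences
#'
#' Partitions variants into coding (overlapping any CDS interval) and
#' non-coding, and assigns a consequence class. SNV consequences come
#' from codon comparison on the gene strand using the standard nuclear
#' code; CDS InDels are `frameshift` when their length is not a multiple
#' of 3 and `inframe_indel` otherwise. Variants hitting several genes
#' get the most severe consequence with all genes listed; InDels
#' spanning a CDS boundary are counted coding and flagged.
#'
#' @param variants variant table.
#' @param genes CDS table from [read_genes()] / [gene_models()].
#' @param genome an `mae_genome`.
#' @return the variant table with added columns `consequence`,
#'   `gene_id` (comma-separated when several) and `boundary_spanning`.
#' @export
annotate_consequences <- function(variants, genes, genome) {
  n <- nrow(variants)
  conseq <- rep("noncoding", n)
  gene_id <- rep(NA_character_, n)
  boundary <- rep(FALSE, n)
  flagged <- attr(genes, "flagged") %||% character(0)
  cds_by_gene <- split(genes, genes$gene_id)
  cds_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    gene_id = genes$gene_id)
  if (n == 0L) {
    variants$consequence <- character(0)
    variants$gene_id <- character(0)
    variants$boundary_spanning <- logical(0)
    return(variants)
  }
  # affected reference span: SNV = 1 bp; indel = bases after the anchor
  # (insertions get the 2 bp around the insertion point)
  sp_start <- ifelse(variants$vclass == "SNV", variants$pos + 1L,
                     variants$pos + 2L)
  sp_end <- ifelse(variants$vclass == "SNV", variants$pos + 1L,
                   ifelse(variants$vclass == "deletion",
                          variants$pos + 1L + variants$indel_len,
                          variants$pos + 2L))
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(sp_start, sp_end))
  hits <- GenomicRanges::findOverlaps(v_gr, cds_gr)
  hit_list <- split(S4Vectors::subjectHits(hits),
                    S4Vectors::queryHits(hits))
  for (qi in names(hit_list)) {
    i <- as.integer(qi)
    v <- variants[i, ]
    gids <- unique(genes$gene_id[hit_list[[qi]]])
    per_gene <- vapply(gids, function(g) {
      if (g %in% flagged) return("unannotatable")
      cdsg <- cds_by_gene[[g]]
      if (v$vclass == "SNV") {
        snv_consequence(genome, cdsg, v)
      } else {
        # boundary check: does the affected span leave the CDS?
        inside <- any(sp_start[i] - 1L >= cdsg$start &
                        sp_end[i] <= cdsg$end)
        if (!inside) boundary[i] <<- TRUE
        if (v$indel_len %% 3L != 0L) "frameshift" else "inframe_indel"
      }
    }, character(1))
    best <- per_gene[order(match(per_gene, CONSEQ_SEVERITY))][1]
    conseq[i] <- best
    gene_id[i] <- paste(gids, collapse = ",")
  }
  variants$consequence <- conseq
  variants$gene_id <- gene_id
  variants$boundary_spanning <- boundary
  variants
}

#' Genomic coding fraction from a CDS table
#'
#' Fraction of the genome covered by the union of CDS intervals.
#'
#' @param genes CDS table.
#' @param genome an `mae_genome`.
#' @return fraction in `[0, 1]`.
#' @export
coding_fraction <- function(genes, genome) {
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)))
  sum(GenomicRanges::width(gr)) / genome$total_length
}

#' Test the coding/non-coding distribution of variants
#'
#' Compares observed coding vs non-coding counts to the expectation
#' under the genomic CDS footprint with a 1-df chi-squared
#' goodness-of-fit test.
#'
#' @param annotated output of [annotate_consequences()].
#' @param genes CDS table.
#' @param genome an `mae_genome`.
#' @return list with `n_coding`, `n_noncoding`, `coding_fraction_genome`,
#'   `expected_coding`, `statistic`, `p_value`.
#' @export
coding_fraction_test <- function(annotated, genes, genome) {
  if (nrow(annotated) == 0L) stopf("no variants")
  n <- nrow(annotated)
  n_cod <- sum(!annotated$consequence %in% c("noncoding",
                                             "unannotatable"))
  n_non <- n - n_cod
  f <- coding_fraction(genes, genome)
  e_cod <- n * f
  e_non <- n * (1 - f)
  stat <- (n_cod - e_cod)^2 / e_cod + (n_non - e_non)^2 / e_non
  list(n_coding = n_cod, n_noncoding = n_non,
       coding_fraction_genome = f, expected_coding = e_cod,
       statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
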