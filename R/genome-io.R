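#' Build a genome object from named sequences
#'
#' Internal constructor shared by [read_genome()] and the synthetic
#' generator. Sequences are uppercased and validated against the
#' A/C/G/T/N alphabet.
#'
#' @param sequences named character vector, one chromosome per element.
#' @return An object of class `mae_genome`: a list with elements
#'   `seq` (named uppercase character vector), `lengths` and
#'   `total_length`.
#' @export
mae_genome <- function(sequences) {
  if (length(sequences) == 0L)
    stopf("genome has no sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("all genome sequences must be named")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate chromosome names: %s",
          paste(unique(names(sequences)[duplicated(names(sequences))]),
                collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stopf("non-nucleotide characters in sequence(s): %s",
          paste(names(sequences)[bad], collapse = ", "))
  lens <- nchar(sequences)
  structure(list(seq = sequences, lengths = lens,
                 total_length = sum(lens)),
            class = "mae_genome")
}

#' Read a reference genome from FASTA
#'
#' Soft-masked (lowercase) bases are uppercased and retained; `N` is
#' allowed. Duplicate record names and non-nucleotide characters are
#' errors.
#'
#' @param path path to a (multi-)FASTA file.
#' @return An `mae_genome` object.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT"), fa)
#' g <- read_genome(fa)
#' g$total_length
#' @export
read_genome <- function(path) {
  # read as raw strings so alphabet violations surface as this
  # package's own validation error rather than a parser failure
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stopf("no FASTA records in %s", path)
  # drop description after first whitespace, as aligners do
  names(dss) <- sub("\\s.*$", "", names(dss))
  mae_genome(stats::setNames(as.character(dss), names(dss)))
}

#' @export
print.mae_genome <- function(x, ...) {
  cat(sprintf("<mae_genome> %d sequence(s), %s bp total\n",
              length(x$seq), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome an `mae_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Genomic GC content
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param genome an `mae_genome`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(genome) {
  dss <- Biostrings::DNAStringSet(genome$seq)
  counts <- colSums(Biostrings::letterFrequency(dss, DNA_BASES))
  tot <- sum(counts)
  if (tot == 0L) stopf("genome contains no A/C/G/T bases")
  unname((counts[["G"]] + counts[["C"]]) / tot)
}

# ---- variant normalization ----------------------------------------------

#' Normalize one variant to minimal left-aligned form
#'
#' Implements the standard VCF normalization algorithm: shared suffix
#' bases are trimmed (extending left over the reference when an allele
#' empties), then shared prefix bases are trimmed. SNVs pass through
#' unchanged; InDels end up left-aligned and anchored (first base of
#' `ref` and `alt` shared).
#'
#' @param genome an `mae_genome`.
#' @param chrom chromosome name.
#' @param pos 0-based position of the first `ref` base.
#' @param ref,alt alleles as called.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(genome, chrom, pos, ref, alt) {
  seq <- genome$seq[[chrom]]
  if (is.null(seq)) stopf("unknown chromosome '%s'", chrom)
  if (subseq0(seq, pos, pos + nchar(ref)) != ref)
    stopf("ref allele mismatch at %s:%d (expected '%s', genome has '%s')",
          chrom, pos + 1L, ref, subseq0(seq, pos, pos + nchar(ref)))
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos == 0L)
        stopf("cannot left-extend variant at %s:1", chrom)
      b <- subseq0(seq, pos - 1L, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Classify a normalized (ref, alt) pair. Multi-nucleotide substitutions
# return NA and are handled by the caller.
#' @noRd
variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SNV")
  if (nr < na && ref == substr(alt, 1L, nr)) return("insertion")
  if (na < nr && alt == substr(ref, 1L, na)) return("deletion")
  NA_character_
}

#' Assemble a validated variant table
#'
#' Normalizes every record against the genome, classifies it as SNV,
#' insertion or deletion, and rejects multi-nucleotide substitutions
#' with a warning (they are dropped, not split).
#'
#' @param genome an `mae_genome`.
#' @param line_id line identifier attached to every record.
#' @param chrom,pos,ref,alt parallel vectors; `pos` 0-based.
#' @return data.frame with columns `line_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `vclass`, `indel_len` (0 for SNVs).
#' @export
make_variants <- function(genome, line_id, chrom, pos, ref, alt) {
  n <- length(chrom)
  if (n == 0L) return(empty_variants())
  out <- vector("list", n)
  dropped <- 0L
  for (i in seq_len(n)) {
    nv <- normalize_variant(genome, chrom[i], pos[i], ref[i], alt[i])
    cl <- variant_class(nv$ref, nv$alt)
    if (is.na(cl)) { dropped <- dropped + 1L; next }
    out[[i]] <- data.frame(
      line_id = line_id, chrom = chrom[i], pos = nv$pos,
      ref = nv$ref, alt = nv$alt, vclass = cl,
      indel_len = abs(nchar(nv$ref) - nchar(nv$alt)),
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    warnf("%d multi-nucleotide substitution(s) rejected", dropped)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty_variants() else res
}

#' Read per-line variant calls from VCF or TSV
#'
#' VCF v4.x files are parsed with \pkg{vcfR}; multi-allelic records are
#' split into one record per alternate allele. The TSV dialect has
#' columns `chrom`, `pos_1based`, `ref`, `alt` (header required).
#' All records are ref-checked against the genome, left-aligned and
#' converted to 0-based coordinates.
#'
#' @param path variant file; format chosen by extension (`.vcf` /
#'   `.vcf.gz` vs anything else) unless `format` is given.
#' @param genome an `mae_genome`.
#' @param line_id identifier for the line the calls belong to.
#' @param format `"vcf"`, `"tsv"` or `"auto"`.
#' @return variant data.frame as in [make_variants()].
#' @export
read_variants <- function(path, genome, line_id,
                          format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                       dimnames = list(NULL, names(fx)))
    if (nrow(fx) == 0L) return(empty_variants())
    alts <- strsplit(fx[, "ALT"], ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fx)), lengths(alts))
    chrom <- fx[idx, "CHROM"]
    pos <- as.integer(fx[idx, "POS"]) - 1L
    ref <- fx[idx, "REF"]
    alt <- unlist(alts)
    keep <- alt != "." & !is.na(alt)
    make_variants(genome, line_id, chrom[keep], pos[keep],
                  ref[keep], alt[keep])
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos_1based", "ref", "alt")
    if (!all(need %in% names(tb)))
      stopf("TSV variant file must have columns: %s",
            paste(need, collapse = ", "))
    if (nrow(tb) == 0L) return(empty_variants())
    make_variants(genome, line_id, tb$chrom,
                  as.integer(tb$pos_1based) - 1L, tb$ref, tb$alt)
  }
}

#' Write a variant table as single-sample VCF
#'
#' Positions are converted back to the 1-based VCF convention.
#'
#' @param variants variant data.frame.
#' @param path output path.
#' @param genome optional `mae_genome` used to emit contig header lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=mutacc")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$seq), genome$lengths))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                        "QUAL", "FILTER", "INFO"), collapse = "\t"))
  body <- if (nrow(variants) == 0L) character(0) else
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            variants$chrom, variants$pos + 1L,
            variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- gene models ---------------------------------------------------------

#' Read CDS gene models from GFF3
#'
#' Extracts `CDS` features, keyed by their `Parent` attribute (falling
#' back to `ID`). Genes whose total CDS length (after phase adjustment)
#' is not divisible by 3, or whose CDS intervals overlap, are flagged in
#' the `flagged` attribute but kept.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, `phase`; CDS rows ordered in
#'   transcription direction within gene. Attribute `flagged` lists gene
#'   ids with suspect models.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L)
    stopf("no CDS features in %s", path)
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  if (all(!nzchar(parent)) || all(is.na(parent)))
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  phase <- S4Vectors::mcols(cds)$phase
  if (is.null(phase)) phase <- rep(0L, length(cds))
  phase[is.na(phase)] <- 0L
  df <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    phase = as.integer(phase),
    stringsAsFactors = FALSE)
  gene_models(df)
}

#' Validate a CDS table as gene models
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `phase` (0-based half-open intervals).
#' @return the table, CDS rows ordered in transcription direction within
#'   each gene, with attribute `flagged` (character vector of gene ids
#'   whose CDS overlap or whose length is not a codon multiple).
#' @export
gene_models <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "phase") %in% names(df)))
  flagged <- character(0)
  parts <- split(seq_len(nrow(df)), df$gene_id)
  ord <- integer(0)
  for (g in names(parts)) {
    i <- parts[[g]]
    minus <- df$strand[i][1] == "-"
    i <- i[order(df$start[i], decreasing = minus)]
    ord <- c(ord, i)
    s <- df$start[i][order(df$start[i])]
    e <- df$end[i][order(df$start[i])]
    if (length(i) > 1L && any(s[-1] < e[-length(e)]))
      flagged <- c(flagged, g)
    len <- sum(df$end[i] - df$start[i]) - df$phase[i][1]
    if (len %% 3L != 0L) flagged <- c(flagged, g)
  }
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- unique(flagged)
  out
}
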