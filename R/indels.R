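# InDel size classification, tandem-repeat (slippage) context, and a
# genome-wide mononucleotide-repeat census.

#' Classify InDels by direction and size bin
#'
#' Bins are 1 bp, 2 bp and >= 3 bp, separately for insertions and
#' deletions; the exact length is retained.
#'
#' @param variants variant table (SNV rows are an error).
#' @return data.frame with `direction`, `length`, `size_bin` (one of
#'   `"1bp"`, `"2bp"`, `"3bp+"`) and `class` (e.g. `"deletion_1bp"`).
#' @export
classify_indel <- function(variants) {
  if (any(variants$vclass == "SNV"))
    stopf("classify_indel expects InDels only")
  len <- variants$indel_len
  bin <- ifelse(len == 1L, "1bp", ifelse(len == 2L, "2bp", "3bp+"))
  data.frame(direction = variants$vclass, length = len, size_bin = bin,
             class = paste0(variants$vclass, "_", bin),
             stringsAsFactors = FALSE)
}

#' The six InDel classes in reporting order
#' @export
INDEL_CLASSES <- c("deletion_1bp", "insertion_1bp", "deletion_2bp",
                   "insertion_2bp", "deletion_3bp+", "insertion_3bp+")

# Count tandem copies of unit `u` in `seq` around 0-based position
# `event_start`, scanning at most `window` bp each side.
#' @noRd
count_tandem_copies <- function(seq, event_start, u, window) {
  d <- nchar(u)
  len <- nchar(seq)
  copies <- 0L
  truncated <- FALSE
  # rightward, including the event site itself
  j <- event_start
  while (j + d <= len && subseq0(seq, j, j + d) == u) {
    copies <- copies + 1L
    j <- j + d
    if (j - event_start >= window) { truncated <- TRUE; break }
  }
  # leftward
  j <- event_start
  while (j - d >= 0L && subseq0(seq, j - d, j) == u) {
    copies <- copies + 1L
    j <- j - d
    if (event_start - j >= window) { truncated <- TRUE; break }
  }
  list(copies = copies, truncated = truncated)
}

#' Tandem-repeat context of one InDel
#'
#' Tests whether the inserted/deleted sequence consists of one or more
#' copies of a unit `u` (all divisors of the event length are tried,
#' shortest qualifying unit wins) and whether the reference around the
#' event carries at least `min_copies` tandem copies of `u` including or
#' adjacent to the event site. Such events are candidate replication
#' (template) slippage errors.
#'
#' @param genome an `mae_genome`.
#' @param variants left-aligned InDel table (SNVs are an error).
#' @param min_copies minimum reference copies of the unit for the locus
#'   to count as a tandem repeat (default 2).
#' @param window maximum scan distance each side of the event (bp);
#'   longer arrays are truncated and flagged.
#' @return data.frame with `in_tandem_repeat`, `unit`, `unit_len`,
#'   `ref_copies`, `repeat_type` (`mononucleotide` / `multinucleotide` /
#'   `none`), `truncated`.
#' @export
repeat_context <- function(genome, variants, min_copies = 2L,
                           window = 50L) {
  if (any(variants$vclass == "SNV"))
    stopf("repeat_context expects InDels only")
  n <- nrow(variants)
  out <- data.frame(in_tandem_repeat = logical(n),
                    unit = NA_character_, unit_len = NA_integer_,
                    ref_copies = NA_integer_,
                    repeat_type = "none", truncated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    seq <- genome$seq[[v$chrom]]
    longer <- if (v$vclass == "deletion") v$ref else v$alt
    indel_seq <- substr(longer, 2L, nchar(longer))
    L <- nchar(indel_seq)
    event_start <- v$pos + 1L
    divisors <- seq_len(L)[L %% seq_len(L) == 0L]
    for (d in divisors) {
      u <- substr(indel_seq, 1L, d)
      if (strrep(u, L / d) != indel_seq) next
      tc <- count_tandem_copies(seq, event_start, u, window)
      if (tc$copies >= min_copies) {
        out$in_tandem_repeat[i] <- TRUE
        out$unit[i] <- u
        out$unit_len[i] <- d
        out$ref_copies[i] <- tc$copies
        out$repeat_type[i] <- if (d == 1L) "mononucleotide"
                              else "multinucleotide"
        out$truncated[i] <- tc$truncated
        break
      }
      if (d == min(divisors)) {
        # record the shortest-unit copy count even when not qualifying
        out$unit[i] <- u
        out$unit_len[i] <- d
        out$ref_copies[i] <- tc$copies
      }
    }
  }
  out
}

#' Fraction of InDels in tandem repeats
#'
#' Counts and fraction of InDels annotated as lying within a tandem
#' repeat, overall and per size class.
#'
#' @inheritParams repeat_context
#' @return list with `n`, `n_in_repeat`, `fraction`, and `by_class`
#'   (data.frame per InDel class, including the mononucleotide-repeat
#'   fraction among 1 bp events).
#' @export
repeat_fraction <- function(genome, variants, min_copies = 2L,
                            window = 50L) {
  ind <- variants[variants$vclass != "SNV", , drop = FALSE]
  if (nrow(ind) == 0L) stopf("no InDels")
  ann <- repeat_context(genome, ind, min_copies, window)
  cls <- classify_indel(ind)$class
  by_class <- do.call(rbind, lapply(INDEL_CLASSES, function(cl) {
    sel <- cls == cl
    data.frame(class = cl, n = sum(sel),
               n_in_repeat = sum(ann$in_tandem_repeat[sel]),
               n_mononucleotide = sum(ann$repeat_type[sel] ==
                                        "mononucleotide"),
               fraction = if (sum(sel)) mean(ann$in_tandem_repeat[sel])
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(n = nrow(ind), n_in_repeat = sum(ann$in_tandem_repeat),
       fraction = mean(ann$in_tandem_repeat), by_class = by_class)
}

#' Census of mononucleotide repeats in a genome
#'
#' Tabulates all maximal single-base runs of length >= `min_run`
#' (flanked by a different base or a chromosome end). Runs of `N` are
#' ignored. Mononucleotide runs are strand-symmetric, so each array is
#' counted once.
#'
#' @param genome an `mae_genome`.
#' @param min_run minimum run length (>= 2).
#' @return data.frame with `base`, `length`, `count`; attributes
#'   `total_runs` and `total_bases` give summary totals.
#' @export
mononucleotide_census <- function(genome, min_run = 2L) {
  if (min_run < 2L) stopf("min_run must be >= 2")
  acc <- list()
  for (chrom in names(genome$seq)) {
    r <- rle(strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1]])
    keep <- r$lengths >= min_run & r$values != "N"
    if (!any(keep)) next
    acc[[chrom]] <- data.frame(base = r$values[keep],
                               length = r$lengths[keep])
  }
  runs <- do.call(rbind, acc)
  if (is.null(runs))
    runs <- data.frame(base = character(0), length = integer(0))
  tab <- stats::aggregate(list(count = rep(1L, nrow(runs))),
                          by = list(base = runs$base,
                                    length = runs$length), FUN = sum)
  tab <- tab[order(tab$base, tab$length), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "total_runs") <- nrow(runs)
  attr(tab, "total_bases") <- sum(runs$length)
  tab
}
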