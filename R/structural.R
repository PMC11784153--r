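# Relative-coverage tracks and coverage-based CNV / aneuploidy calls.

#' Read a windowed depth track
#'
#' Expects a TSV/BED-like file with columns `chrom`, `start`, `end`,
#' `depth` (0-based half-open windows).
#'
#' @param path input file (header required).
#' @return data.frame with those columns.
#' @export
read_depth_track <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(tb)))
    stopf("depth track must have columns: %s", paste(need, collapse = ", "))
  if (any(tb$depth < 0)) stopf("negative depths")
  tb
}

#' Relative coverage from windowed depth
#'
#' Divides each window's depth by the genome-wide median window depth.
#' On a balanced haploid genome the result is centered at 1; values near
#' 0 and 2 indicate deleted and duplicated DNA. The median normalizer is
#' robust to CNVs occupying less than half the genome.
#'
#' @param depth data.frame with `chrom`, `start`, `end`, `depth`.
#' @return the input with an added `rc` column.
#' @export
relative_coverage <- function(depth) {
  if (nrow(depth) == 0L) stopf("no depth windows")
  med <- stats::median(depth$depth)
  if (med == 0) stopf("genome-wide median depth is zero")
  depth$rc <- depth$depth / med
  depth
}

#' Call CNVs from a relative-coverage track
#'
#' Scans each chromosome for maximal runs of at least `min_windows`
#' consecutive windows with RC at or below `low_thr` (deletion, copy
#' state 0) or at or above `high_thr` (duplication, copy state 2). Runs
#' covering at least `whole_chr_fraction` of a chromosome are labelled
#' whole-chromosome (aneuploidy); runs touching a chromosome end are
#' terminal; the rest interstitial.
#'
#' @param rc data.frame from [relative_coverage()].
#' @param low_thr,high_thr RC thresholds, `0 < low_thr < 1 < high_thr`.
#' @param min_windows minimum run length in windows.
#' @param whole_chr_fraction chromosome fraction above which a run is an
#'   aneuploidy call.
#' @return data.frame of calls: `chrom`, `start`, `end` (0-based
#'   half-open), `copy_state` (0 or 2), `scope` (`whole_chromosome` /
#'   `terminal` / `interstitial`), `n_windows`, `mean_rc`.
#' @export
call_cnvs <- function(rc, low_thr = 0.5, high_thr = 1.5,
                      min_windows = 10L, whole_chr_fraction = 0.9) {
  if (!(low_thr > 0 && low_thr < 1 && high_thr > 1))
    stopf("need 0 < low_thr < 1 < high_thr")
  calls <- list()
  for (chrom in unique(rc$chrom)) {
    w <- rc[rc$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    state <- ifelse(w$rc <= low_thr, -1L, ifelse(w$rc >= high_thr, 1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    span <- max(w$end) - min(w$start)
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L || r$lengths[k] < min_windows) next
      i0 <- starts[k]; i1 <- ends[k]
      seg_start <- w$start[i0]; seg_end <- w$end[i1]
      scope <- if ((seg_end - seg_start) / span >= whole_chr_fraction)
        "whole_chromosome"
      else if (i0 == 1L || i1 == nrow(w)) "terminal"
      else "interstitial"
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom, start = seg_start, end = seg_end,
        copy_state = if (r$values[k] == 1L) 2L else 0L,
        scope = scope, n_windows = r$lengths[k],
        mean_rc = mean(w$rc[i0:i1]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), copy_state = integer(0),
                      scope = character(0), n_windows = integer(0),
                      mean_rc = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Summarize structural events into per-division rates
#'
#' Whole-chromosome calls are counted as aneuploidies; terminal and
#' interstitial calls as chromosomal rearrangements. Rates come from
#' [structural_rate()] on the design's total divisions.
#'
#' @param calls CNV call table with a `line_id` column (calls should be
#'   deduplicated per line beforehand).
#' @param design an `experiment_design`.
#' @return list with `n_aneuploidy`, `n_rearrangement`,
#'   `aneuploidy_rate` and `rearrangement_rate` (`rate_estimate`s).
#' @export
structural_event_summary <- function(calls, design) {
  n_aneu <- sum(calls$scope == "whole_chromosome")
  n_rearr <- sum(calls$scope != "whole_chromosome")
  list(n_aneuploidy = n_aneu, n_rearrangement = n_rearr,
       aneuploidy_rate = structural_rate(n_aneu, design),
       rearrangement_rate = structural_rate(n_rearr, design))
}

#' Write CNV calls as BED3+
#'
#' Columns: chrom, start, end, name (scope), score (copy state), mean RC.
#'
#' @param calls CNV call table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%.4f",
                   calls$chrom, calls$start, calls$end, calls$scope,
                   calls$copy_state, calls$mean_rc)
  writeLines(lines, path)
  invisible(path)
}
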