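#' Describe an experiment's denominator model
#'
#' A mutation accumulation experiment is summarized by its line table
#' (one row per independently subcultured isolate), the assumed number
#' of cell divisions from a single cell to a picked colony (`t`,
#' approximately 25 for yeast on plates), and the genome size used for
#' per-base rates.
#'
#' @param lines data.frame with columns `line_id`, `condition`,
#'   `n_cycles` (subculture streaking cycles, i.e. colony generations).
#' @param t divisions per colony (default 25).
#' @param genome_size genome length in bp, or an `mae_genome` from which
#'   it is taken. Can be overridden by a constant to reproduce published
#'   arithmetic.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(lines, t = 25L, genome_size) {
  stopifnot(all(c("line_id", "n_cycles") %in% names(lines)))
  if (t < 1L) stopf("t must be >= 1")
  if (any(lines$n_cycles < 1L)) stopf("all n_cycles must be >= 1")
  if (inherits(genome_size, "mae_genome"))
    genome_size <- genome_size$total_length
  if (genome_size <= 0) stopf("genome_size must be positive")
  if (is.null(lines$condition)) lines$condition <- "unspecified"
  structure(list(lines = lines, t = as.integer(t),
                 genome_size = as.numeric(genome_size)),
            class = "experiment_design")
}

#' Total cell divisions represented by a set of lines
#'
#' The denominator of all rate estimates: the summed subculture cycles
#' across lines times the divisions per colony, i.e. `sum(n_cycles) * t`.
#'
#' @param lines line table (see [experiment_design()]) or an
#'   `experiment_design`.
#' @param t divisions per colony; ignored when `lines` is a design.
#' @return total division count.
#' @examples
#' li <- data.frame(line_id = paste0("L", 1:21),
#'                  n_cycles = rep(c(103, 120), c(11, 10)))
#' total_divisions(li, t = 25)  # 58325
#' @export
total_divisions <- function(lines, t = 25L) {
  if (inherits(lines, "experiment_design")) {
    t <- lines$t
    lines <- lines$lines
  }
  if (nrow(lines) == 0L) stopf("no lines")
  if (t < 1L) stopf("t must be >= 1")
  sum(lines$n_cycles) * t
}

#' @noRd
new_rate_estimate <- function(point, ci_low, ci_high, n_events,
                              n_divisions, genome_size = NA_real_,
                              ci_method = "none") {
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 n_events = n_events, n_divisions = n_divisions,
                 genome_size = genome_size, ci_method = ci_method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  unit <- if (is.na(x$genome_size)) "per cell division"
          else "per base per cell division"
  ci <- if (x$ci_method == "none") ""
        else sprintf(" (95%% CI %.3g-%.3g, %s)",
                     x$ci_low, x$ci_high, x$ci_method)
  cat(sprintf("rate %.3g %s%s; %d events / %s divisions\n",
              x$point, unit, ci, x$n_events,
              format(x$n_divisions, big.mark = ",")))
  invisible(x)
}

# Exact Poisson CI on a count, via the gamma quantile identity.
#' @noRd
poisson_count_ci <- function(n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (n == 0) 0 else stats::qgamma(a, n)
  high <- stats::qgamma(1 - a, n + 1)
  c(low, high)
}

#' Per-base mutation rate
#'
#' Point estimate `n_events / (genome_size * total_divisions)`, in
#' events per base per cell division. The default confidence interval is
#' Poisson-exact on the event count; for the line-resampling bootstrap
#' interval use [bootstrap_ci()].
#'
#' @param n_events number of observed events of the class of interest.
#' @param design an `experiment_design`.
#' @param ci_method `"poisson"` or `"none"`.
#' @return a `rate_estimate`.
#' @examples
#' li <- data.frame(line_id = paste0("L", 1:21),
#'                  n_cycles = rep(c(103, 120), c(11, 10)))
#' d <- experiment_design(li, t = 25, genome_size = 20500000)
#' per_base_rate(247, d)  # 2.07e-10
#' @export
per_base_rate <- function(n_events, design,
                          ci_method = c("poisson", "none")) {
  ci_method <- match.arg(ci_method)
  if (n_events < 0) stopf("n_events must be >= 0")
  div <- total_divisions(design)
  denom <- design$genome_size * div
  if (denom <= 0) stopf("zero denominator")
  point <- n_events / denom
  if (ci_method == "none" || n_events == 0) {
    method <- if (n_events == 0) "no events observed" else "none"
    ci <- if (n_events == 0) c(0, poisson_count_ci(0)[2] / denom)
          else c(NA_real_, NA_real_)
    return(new_rate_estimate(point, ci[1], ci[2], n_events, div,
                             design$genome_size, method))
  }
  ci <- poisson_count_ci(n_events) / denom
  new_rate_estimate(point, ci[1], ci[2], n_events, div,
                    design$genome_size, "poisson")
}

#' Structural event rate per cell division
#'
#' Rate of aneuploidies or chromosomal rearrangements:
#' `n_events / total_divisions`; the genome size does not enter.
#'
#' @inheritParams per_base_rate
#' @return a `rate_estimate` with `genome_size = NA`.
#' @export
structural_rate <- function(n_events, design,
                            ci_method = c("poisson", "none")) {
  ci_method <- match.arg(ci_method)
  if (n_events < 0) stopf("n_events must be >= 0")
  div <- total_divisions(design)
  if (div <= 0) stopf("zero denominator")
  point <- n_events / div
  if (ci_method == "none" || n_events == 0) {
    method <- if (n_events == 0) "no events observed" else "none"
    ci <- if (n_events == 0) c(0, poisson_count_ci(0)[2] / div)
          else c(NA_real_, NA_real_)
    return(new_rate_estimate(point, ci[1], ci[2], n_events, div,
                             NA_real_, method))
  }
  ci <- poisson_count_ci(n_events) / div
  new_rate_estimate(point, ci[1], ci[2], n_events, div, NA_real_,
                    "poisson")
}

# Per-line event counts under a selector.
#' @noRd
line_event_counts <- function(variants, lines, selector = NULL) {
  if (!is.null(selector) && nrow(variants) > 0L)
    variants <- variants[selector(variants), , drop = FALSE]
  counts <- table(factor(variants$line_id, levels = lines$line_id))
  as.integer(counts)
}

#' Bootstrap confidence interval for a per-base rate
#'
#' Nonparametric bootstrap over whole lines: lines are resampled with
#' replacement, the rate is recomputed on each resample (numerator and
#' denominator together), and the percentile 2.5/97.5 bounds are
#' returned. Deterministic for a given seed.
#'
#' @param variants variant table covering all lines.
#' @param design an `experiment_design` whose line table defines the
#'   resampling units.
#' @param selector optional predicate `function(variants) -> logical`
#'   restricting which events are counted (e.g. only SNVs).
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param per_base if `FALSE`, compute a per-division (structural) rate.
#' @return a `rate_estimate` with `ci_method = "bootstrap"`. With a
#'   single line the interval is undefined and flagged. Note the
#'   percentile interval is not guaranteed to contain the full-data
#'   point estimate.
#' @export
bootstrap_ci <- function(variants, design, selector = NULL,
                         n_boot = 10000L, seed = 1L, per_base = TRUE) {
  if (n_boot < 100L) stopf("n_boot must be >= 100")
  lines <- design$lines
  counts <- line_event_counts(variants, lines, selector)
  cycles <- lines$n_cycles
  nl <- length(counts)
  gs <- if (per_base) design$genome_size else 1
  div <- sum(cycles) * design$t
  point <- sum(counts) / (gs * div)
  if (nl < 2L) {
    warnf("confidence interval undefined with a single line")
    return(new_rate_estimate(point, NA_real_, NA_real_, sum(counts),
                             div, if (per_base) gs else NA_real_,
                             "bootstrap (undefined: single line)"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(nl, nl * n_boot, replace = TRUE), nrow = nl)
  num <- colSums(matrix(counts[idx], nrow = nl))
  den <- colSums(matrix(cycles[idx], nrow = nl)) * design$t * gs
  rates <- num / den
  ci <- unname(stats::quantile(rates, c(0.025, 0.975), type = 7))
  new_rate_estimate(point, ci[1], ci[2], sum(counts), div,
                    if (per_base) gs else NA_real_, "bootstrap")
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Ratio of two rate estimates
#'
#' @param numerator,denominator `rate_estimate` objects.
#' @return the ratio of point estimates. A zero denominator rate yields
#'   `Inf` with a warning carrying the event-count context.
#' @export
fold_change <- function(numerator, denominator) {
  if (denominator$point == 0) {
    warnf("denominator rate is zero (%d events); fold change infinite",
          denominator$n_events)
    return(Inf)
  }
  numerator$point / denominator$point
}

#' Per-line mutation rates
#'
#' Each line's own rate: its event count divided by its own denominator
#' `genome_size * n_cycles * t`.
#'
#' @inheritParams bootstrap_ci
#' @return named numeric vector, one rate per line.
#' @export
per_line_rates <- function(variants, design, selector = NULL) {
  lines <- design$lines
  counts <- line_event_counts(variants, lines, selector)
  stats::setNames(
    counts / (design$genome_size * lines$n_cycles * design$t),
    lines$line_id)
}

#' Compare per-line rates between two groups
#'
#' Two-sided Wilcoxon rank-sum test on per-line rates, each line using
#' its own denominator. The exact null distribution is used for small
#' samples without ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param rates_a,rates_b numeric vectors of per-line rates (from
#'   [per_line_rates()]), one value per line; each group needs >= 2
#'   lines.
#' @return list with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
compare_line_rates <- function(rates_a, rates_b) {
  if (length(rates_a) < 2L || length(rates_b) < 2L)
    stopf("need at least two lines per group")
  if (length(unique(c(rates_a, rates_b))) == 1L) {
    warnf("all per-line rates identical; comparison degenerate")
    return(list(statistic = length(rates_a) * length(rates_b) / 2,
                p_value = 1, method = "degenerate (all values equal)"))
  }
  ties <- any(duplicated(c(rates_a, rates_b)))
  wt <- suppressWarnings(
    stats::wilcox.test(rates_a, rates_b, alternative = "two.sided",
                       exact = !ties, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}
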