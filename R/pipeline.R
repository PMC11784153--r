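# End-to-end orchestration: config validation and the full analysis
# over a set of lines, producing tables mirroring a MAE study report.

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list and returns the full list of
#' problems (not just the first). A valid config has zero errors.
#'
#' Recognized fields: `genome` (FASTA path, required), `lines_table`
#' (TSV path with columns `line_id`, `condition`, `n_cycles`,
#' `variant_file`, optional `depth_file`; required), `gff` (optional
#' GFF3), `t` (default 25), `genome_size_override` (optional), `n_boot`
#' (default 1000), `seed` (default 1), `out_dir` (optional), plus the
#' module threshold blocks `spectrum` (`window`, `adjust`,
#' `min_class_count`), `indel` (`min_copies`, `window`) and `cnv`
#' (`low_thr`, `high_thr`, `min_windows`, `whole_chr_fraction`).
#'
#' @param config path to a YAML file, or a list.
#' @return list with `config` (normalized, defaults filled) and
#'   `errors` (character vector; empty when valid).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(config = NULL,
                  errors = sprintf("config file not found: %s", config)))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    return(list(config = NULL, errors = "config must be a list"))
  defaults <- list(t = 25L, n_boot = 1000L, seed = 1L,
                   genome_size_override = NULL, gff = NULL,
                   out_dir = NULL,
                   spectrum = list(window = 4L, adjust = "bonferroni",
                                   min_class_count = 10L),
                   indel = list(min_copies = 2L, window = 50L),
                   cnv = list(low_thr = 0.5, high_thr = 1.5,
                              min_windows = 10L,
                              whole_chr_fraction = 0.9))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]]))
        if (is.null(config[[nm]][[sub]]))
          config[[nm]][[sub]] <- defaults[[nm]][[sub]]
    }
  }
  for (req in c("genome", "lines_table")) {
    if (is.null(config[[req]]))
      errors <- c(errors, sprintf("missing required field: %s", req))
    else if (!file.exists(config[[req]]))
      errors <- c(errors, sprintf("%s: file not found: %s", req,
                                  config[[req]]))
  }
  if (!is.null(config$gff) && !file.exists(config$gff))
    errors <- c(errors, sprintf("gff: file not found: %s", config$gff))
  if (config$t < 1)
    errors <- c(errors, "t must be >= 1")
  if (config$n_boot < 100)
    errors <- c(errors, "n_boot must be >= 100")
  cnv <- config$cnv
  if (!(cnv$low_thr > 0 && cnv$low_thr < 1 && cnv$high_thr > 1))
    errors <- c(errors, "cnv thresholds need 0 < low_thr < 1 < high_thr")
  if (length(errors) == 0 && !is.null(config$lines_table)) {
    lt <- utils::read.delim(config$lines_table, stringsAsFactors = FALSE)
    need <- c("line_id", "condition", "n_cycles", "variant_file")
    miss <- setdiff(need, names(lt))
    if (length(miss) > 0)
      errors <- c(errors, sprintf("lines_table missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  }
  list(config = config, errors = errors)
}

#' Run the full MAE analysis pipeline
#'
#' Reads the genome, annotation and per-line variant calls, then per
#' condition computes: SNV/InDel rates with bootstrap confidence
#' intervals, the per-class InDel rate table, six-class and 96-category
#' substitution spectra, trinucleotide context-enrichment tests, the
#' tandem-repeat fraction of InDels, the G/C site-composition test,
#' coding/non-coding partition (when a GFF3 is given) and CNV calls
#' with structural rates (when depth files are given). Relative paths
#' in the lines table are resolved against its own directory.
#'
#' @param config YAML path or list (see [validate_config()]).
#' @return the report as a nested list, invisibly when written to
#'   `out_dir` (as `report.json`, stamped with seed and config hash).
#' @export
run_pipeline <- function(config) {
  vc <- validate_config(config)
  if (length(vc$errors) > 0)
    stopf("invalid config:\n  %s", paste(vc$errors, collapse = "\n  "))
  config <- vc$config
  genome <- read_genome(config$genome)
  genome_size <- config$genome_size_override %||% genome$total_length
  genes <- if (!is.null(config$gff)) read_genes(config$gff) else NULL
  lt <- utils::read.delim(config$lines_table, stringsAsFactors = FALSE)
  base_dir <- dirname(config$lines_table)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  vars <- list()
  for (i in seq_len(nrow(lt))) {
    vars[[i]] <- read_variants(resolve(lt$variant_file[i]), genome,
                               lt$line_id[i])
  }
  variants <- do.call(rbind, vars) %||% empty_variants()
  expectation <- genome_context_expectation(genome)
  genome_gc <- gc_content(genome)
  report <- list(
    seed = config$seed,
    genome_size = genome_size,
    t = config$t,
    config_hash = config_hash(config),
    conditions = list())
  is_snv <- function(v) v$vclass == "SNV"
  is_indel <- function(v) v$vclass != "SNV"
  for (cond in unique(lt$condition)) {
    li <- lt[lt$condition == cond, , drop = FALSE]
    design <- experiment_design(li, t = config$t,
                                genome_size = genome_size)
    cv <- variants[variants$line_id %in% li$line_id, , drop = FALSE]
    snv_rate <- bootstrap_ci(cv, design, is_snv,
                             n_boot = config$n_boot,
                             seed = config$seed)
    indel_rate <- bootstrap_ci(cv, design, is_indel,
                               n_boot = config$n_boot,
                               seed = config$seed)
    # per-class InDel rates (Table-2-style)
    ind <- cv[cv$vclass != "SNV", , drop = FALSE]
    icls <- if (nrow(ind) > 0) classify_indel(ind)$class else character(0)
    indel_table <- lapply(stats::setNames(INDEL_CLASSES, INDEL_CLASSES),
      function(cl) {
        n <- sum(icls == cl)
        r <- per_base_rate(n, design)
        list(n_events = n, rate = r$point,
             zero_events = n == 0L)
      })
    counts96 <- sbs96_counts(cv, genome)
    spectrum6 <- collapse_to_classes(counts96)
    enr <- if (sum(counts96) >= config$spectrum$min_class_count) {
      suppressWarnings(context_enrichment(
        counts96, expectation,
        min_class_count = config$spectrum$min_class_count,
        adjust = config$spectrum$adjust))
    } else NULL
    rep_frac <- if (nrow(ind) > 0)
      repeat_fraction(genome, ind, config$indel$min_copies,
                      config$indel$window) else NULL
    site_comp <- if (sum(cv$vclass == "SNV") > 0)
      site_composition_test(cv, genome_gc) else NULL
    coding <- NULL
    if (!is.null(genes) && nrow(cv) > 0) {
      ann <- annotate_consequences(cv, genes, genome)
      coding <- list(
        consequences = as.list(table(ann$consequence)),
        test = coding_fraction_test(ann, genes, genome))
    }
    structural <- NULL
    if ("depth_file" %in% names(lt)) {
      calls <- list()
      for (i in which(lt$condition == cond)) {
        if (is.na(lt$depth_file[i]) || !nzchar(lt$depth_file[i])) next
        d <- read_depth_track(resolve(lt$depth_file[i]))
        rc <- relative_coverage(d)
        cc <- call_cnvs(rc, config$cnv$low_thr, config$cnv$high_thr,
                        config$cnv$min_windows,
                        config$cnv$whole_chr_fraction)
        if (nrow(cc) > 0) {
          cc$line_id <- lt$line_id[i]
          calls[[length(calls) + 1]] <- cc
        }
      }
      calls <- do.call(rbind, calls)
      if (!is.null(calls))
        structural <- structural_event_summary(calls, design)
      else
        structural <- structural_event_summary(
          data.frame(scope = character(0)), design)
      structural$calls <- calls
    }
    report$conditions[[cond]] <- list(
      n_lines = nrow(li),
      total_divisions = total_divisions(design),
      snv_rate = unclass(snv_rate),
      indel_rate = unclass(indel_rate),
      indel_class_rates = indel_table,
      spectrum6 = as.list(spectrum6),
      spectrum96 = stats::setNames(as.integer(counts96),
                                   names(counts96)),
      enrichment = enr,
      repeat_fraction = rep_frac,
      site_composition = site_comp,
      coding = coding,
      structural = if (is.null(structural)) NULL else
        list(n_aneuploidy = structural$n_aneuploidy,
             n_rearrangement = structural$n_rearrangement,
             aneuploidy_rate = structural$aneuploidy_rate$point,
             rearrangement_rate = structural$rearrangement_rate$point))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report, file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    return(invisible(report))
  }
  report
}

# Stable fingerprint of the (normalized) config, for report stamping.
#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}
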