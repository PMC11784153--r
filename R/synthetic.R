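# Synthetic mutation-accumulation datasets with known ground truth:
# genome + gene models, per-line variants, depth tracks.

# trinucleotide -> pyrimidine-normalized trinucleotide lookup
#' @noRd
trinuc_normalizer <- function() {
  all3 <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                          DNA_BASES, paste0))
  all3 <- all3[order(all3)]
  norm <- ifelse(substr(all3, 2, 2) %in% PYRIMIDINES, all3, revcomp(all3))
  stats::setNames(norm, all3)
}

# Markov-chain nucleotide simulation; boost > 1 inflates the
# self-transition probability, lengthening homopolymer runs.
#' @noRd
markov_chain_seq <- function(n, p, boost) {
  if (boost == 1) {
    return(paste(sample(DNA_BASES, n, replace = TRUE, prob = p),
                 collapse = ""))
  }
  trans <- matrix(rep(p, 4), nrow = 4, byrow = TRUE,
                  dimnames = list(DNA_BASES, DNA_BASES))
  diag(trans) <- diag(trans) * boost
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  out <- integer(n)
  out[1] <- sample.int(4, 1, prob = p)
  u <- stats::runif(n)
  for (i in 2:n) {
    out[i] <- findInterval(u[i], cum[out[i - 1], ]) + 1L
  }
  paste(DNA_BASES[out], collapse = "")
}

#' Generate a synthetic genome with gene models
#'
#' Nucleotides are drawn from a first-order Markov chain whose
#' stationary composition matches the requested GC content;
#' `homopolymer_boost > 1` multiplies the self-transition probability,
#' inflating mononucleotide-run frequency the way real genomes are
#' enriched relative to an i.i.d. model. Non-overlapping single-CDS
#' genes (ATG + non-stop codons + stop, on either strand) are written
#' into the sequence so that consequence annotation on simulated
#' variants is meaningful.
#'
#' @param length total genome length in bp (>= 10 kb recommended).
#' @param gc target GC fraction.
#' @param homopolymer_boost self-transition multiplier (1 = i.i.d.).
#' @param coding_target approximate fraction of the genome to cover
#'   with CDS (0 disables gene placement).
#' @param n_chrom number of chromosomes (length split evenly).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `genome` (an `mae_genome`) and `genes` (CDS table
#'   as from [gene_models()]; `NULL` when `coding_target = 0`).
#' @export
generate_genome <- function(length, gc = 0.49, homopolymer_boost = 1,
                            coding_target = 0.45, n_chrom = 3L,
                            seed = 1L) {
  if (length < 1000L) stopf("genome length must be >= 1000")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- diff(round(seq(0, length, length.out = n_chrom + 1L)))
  seqs <- stats::setNames(
    vapply(lens, markov_chain_seq, character(1), p = p,
           boost = homopolymer_boost),
    sprintf("chr%s", LETTERS[seq_len(n_chrom)]))
  genes <- NULL
  if (coding_target > 0) {
    rows <- list()
    gi <- 0L
    for (ci in seq_along(seqs)) {
      chrom <- names(seqs)[ci]
      L <- nchar(seqs[[ci]])
      pos <- sample(50:250, 1)
      budget <- coding_target * L
      used <- 0
      while (used < budget) {
        n_codons <- sample(100:400, 1)
        glen <- 3L * (n_codons + 2L)  # incl. start + stop
        if (pos + glen + 50L > L) break
        strand <- sample(c("+", "-"), 1)
        codons <- names(Biostrings::GENETIC_CODE)
        codons <- codons[Biostrings::GENETIC_CODE != "*"]
        orf <- paste0("ATG",
                      paste(sample(codons, n_codons, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1))
        ins <- if (strand == "+") orf else revcomp(orf)
        substr(seqs[[ci]], pos + 1L, pos + glen) <- ins
        gi <- gi + 1L
        rows[[gi]] <- data.frame(
          gene_id = sprintf("g%04d", gi), chrom = chrom,
          start = pos, end = pos + glen, strand = strand,
          phase = 0L, stringsAsFactors = FALSE)
        used <- used + glen
        pos <- pos + glen + sample(50:300, 1)
      }
    }
    genes <- gene_models(do.call(rbind, rows))
  }
  list(genome = mae_genome(seqs), genes = genes)
}

#' Condition profiles for the synthetic generator
#'
#' Event-rate presets emulating the magnitudes measured for spontaneous
#' growth and for UV, MMS and Zeocin mutagenesis in a haploid yeast MAE:
#' per-class SNV rates (per base per division) summing to the headline
#' total for the condition, per-class InDel rates, trinucleotide
#' context-bias weights (e.g. the 5'-G-pyrimidine preference of
#' bleomycin-family mutagens in the Zeocin preset), the fraction of
#' InDels arising by replication slippage in tandem repeats, and
#' per-division aneuploidy/rearrangement rates. All values are config
#' data and can be overridden.
#'
#' @param label one of `"spontaneous"`, `"uv"`, `"mms"`, `"zeocin"`, or
#'   `"custom"`.
#' @param ... fields overriding the preset (any of `snv_rates`,
#'   `indel_rates`, `context_weights`, `slippage_fraction`,
#'   `aneuploidy_rate`, `rearrangement_rate`, `indel_len_sampler`).
#' @return object of class `condition_profile`.
#' @export
condition_profile <- function(label = c("spontaneous", "uv", "mms",
                                        "zeocin", "custom"), ...) {
  label <- match.arg(label)
  w5 <- function(prefixes, weight) {
    # weight all 32 normalized trinucs starting with given 5' bases
    tn <- c(pyr_trinucs("C"), pyr_trinucs("T"))
    w <- stats::setNames(rep(1, 32), tn)
    w[substr(tn, 1, 1) %in% prefixes] <- weight
    w
  }
  base <- switch(label,
    spontaneous = list(
      snv_rates = 2.07e-10 * c("C>A" = 0.19, "C>G" = 0.06, "C>T" = 0.43,
                               "T>A" = 0.08, "T>C" = 0.16, "T>G" = 0.08),
      indel_rates = 1e-11 * c(deletion_1bp = 8.36, insertion_1bp = 4.27,
                              deletion_2bp = 0.59, insertion_2bp = 1.25,
                              "deletion_3bp+" = 0.92,
                              "insertion_3bp+" = 0.67),
      context_weights = NULL,
      slippage_fraction = 0.82,
      aneuploidy_rate = 1.71e-5, rearrangement_rate = 5.14e-5),
    uv = list(
      snv_rates = 1.104e-8 * c("C>A" = 0.10, "C>G" = 0.05, "C>T" = 0.60,
                               "T>A" = 0.10, "T>C" = 0.10, "T>G" = 0.05),
      indel_rates = 1e-11 * c(deletion_1bp = 29.08,
                              insertion_1bp = 20.64,
                              deletion_2bp = 4.69, insertion_2bp = 5.63,
                              "deletion_3bp+" = 5.63,
                              "insertion_3bp+" = 1.88),
      context_weights = list("C>T" = w5(c("C", "T"), 5),
                             "T>A" = w5("T", 3), "T>C" = w5("T", 3)),
      slippage_fraction = 0.7,
      aneuploidy_rate = 1.71e-5, rearrangement_rate = 5.77e-4),
    mms = list(
      snv_rates = 6.91e-9 * c("C>A" = 0.07, "C>G" = 0.03, "C>T" = 0.33,
                              "T>A" = 0.25, "T>C" = 0.07, "T>G" = 0.25),
      indel_rates = 1e-11 * c(deletion_1bp = 11.58,
                              insertion_1bp = 11.58,
                              deletion_2bp = 0, insertion_2bp = 0,
                              "deletion_3bp+" = 0,
                              "insertion_3bp+" = 0),
      context_weights = list("T>G" = w5(c("C", "G"), 5),
                             "T>A" = w5("G", 5), "T>C" = w5("G", 5)),
      slippage_fraction = 0.8,
      aneuploidy_rate = 1.71e-5, rearrangement_rate = 3.39e-4),
    zeocin = list(
      snv_rates = 5.32e-9 * c("C>A" = 0.20, "C>G" = 0.04, "C>T" = 0.12,
                              "T>A" = 0.33, "T>C" = 0.15, "T>G" = 0.16),
      indel_rates = 1e-11 * c(deletion_1bp = 149.54,
                              insertion_1bp = 36.78,
                              deletion_2bp = 27.99, insertion_2bp = 7.20,
                              "deletion_3bp+" = 173.53,
                              "insertion_3bp+" = 5.60),
      context_weights = list("T>A" = w5("G", 5), "T>C" = w5("G", 5),
                             "T>G" = w5("G", 5), "C>A" = w5("G", 5),
                             "C>T" = w5("G", 5)),
      slippage_fraction = 0.5,
      aneuploidy_rate = 1.71e-5, rearrangement_rate = 1.64e-4),
    custom = list(
      snv_rates = stats::setNames(rep(0, 6), SUB_CLASSES),
      indel_rates = stats::setNames(rep(0, 6), INDEL_CLASSES),
      context_weights = NULL, slippage_fraction = 0,
      aneuploidy_rate = 0, rearrangement_rate = 0))
  base$indel_len_sampler <- function(n) sample(3:8, n, replace = TRUE)
  base$label <- label
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  stopifnot(all(base$snv_rates >= 0), all(base$indel_rates >= 0),
            base$slippage_fraction >= 0, base$slippage_fraction <= 1)
  structure(base, class = "condition_profile")
}

# Precomputed per-genome indices used by the line simulator.
#' @noRd
genome_site_index <- function(genome) {
  normalizer <- trinuc_normalizer()
  # normalized-context lookup by integer trinucleotide code (fast path
  # for megabase genomes)
  eg <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                    stringsAsFactors = FALSE)
  code_tbl <- unname(normalizer[paste0(eg$b1, eg$b2, eg$b3)])
  sites <- list()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    if (L < 3L) next
    b <- match(strsplit(s, "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
    b1 <- b[1:(L - 2L)]; b2 <- b[2:(L - 1L)]; b3 <- b[3:L]
    ok <- b1 < 5L & b2 < 5L & b3 < 5L
    code <- 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3
    pos <- which(ok)
    sites[[chrom]] <- data.frame(
      chrom = rep(chrom, length(pos)),
      pos = pos,  # 0-based position of the center base
      ctx = code_tbl[code[ok]],
      center = c("T", "C", "C", "T")[b2[ok]],  # pyrimidine-normalized
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, sites)
  rownames(df) <- NULL
  # mononucleotide runs (>= 2) with positions, for slippage placement
  runs <- list()
  for (chrom in names(genome$seq)) {
    r <- rle(strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= 2L & r$values != "N" & starts > 1L
    if (any(keep))
      runs[[chrom]] <- data.frame(
        chrom = chrom, start = starts[keep] - 1L,  # 0-based
        length = r$lengths[keep], base = r$values[keep],
        stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs)
  # dinucleotide tandem arrays (>= 2 unit copies)
  dins <- list()
  for (chrom in names(genome$seq)) {
    m <- gregexpr("([ACGT]{2})\\1+", genome$seq[[chrom]], perl = TRUE)[[1]]
    if (m[1] != -1L) {
      len <- attr(m, "match.length")
      keep <- as.integer(m) > 1L
      if (any(keep))
        dins[[chrom]] <- data.frame(
          chrom = chrom, start = as.integer(m)[keep] - 1L,
          length = len[keep], stringsAsFactors = FALSE)
    }
  }
  dins <- do.call(rbind, dins)
  list(sites = df, mono_runs = runs, dinuc_runs = dins)
}

# Draw one slippage InDel (unit copy change) inside a repeat run.
#' @noRd
draw_slippage_indel <- function(genome, index, unit_len, direction) {
  runs <- if (unit_len == 1L) index$mono_runs else index$dinuc_runs
  if (is.null(runs) || nrow(runs) == 0L) return(NULL)
  if (direction == "deletion")  # need >= 2 units present to delete one
    runs <- runs[runs$length >= 2L * unit_len, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  k <- sample.int(nrow(runs), 1, prob = runs$length)
  run <- runs[k, ]
  seq <- genome$seq[[run$chrom]]
  anchor <- run$start - 1L
  unit <- subseq0(seq, run$start, run$start + unit_len)
  a <- subseq0(seq, anchor, anchor + 1L)
  if (direction == "deletion") {
    list(chrom = run$chrom, pos = anchor,
         ref = paste0(a, unit), alt = a)
  } else {
    list(chrom = run$chrom, pos = anchor,
         ref = a, alt = paste0(a, unit))
  }
}

# Draw one non-slippage InDel at a uniform position. Positions where
# the event would sit in a tandem repeat of its own unit (and thus be
# indistinguishable from slippage) are rejected so that truth labels
# and repeat annotation stay consistent.
#' @noRd
draw_random_indel <- function(genome, len, direction, max_tries = 50L) {
  ev <- NULL
  for (try in seq_len(max_tries)) {
    chrom <- sample(names(genome$seq), 1,
                    prob = genome$lengths / genome$total_length)
    L <- genome$lengths[[chrom]]
    pos <- sample.int(L - len - 2L, 1)  # 0-based anchor, room rightward
    seq <- genome$seq[[chrom]]
    a <- subseq0(seq, pos, pos + 1L)
    ev <- if (direction == "deletion") {
      list(chrom = chrom, pos = pos,
           ref = subseq0(seq, pos, pos + len + 1L), alt = a)
    } else {
      list(chrom = chrom, pos = pos, ref = a,
           alt = paste0(a, paste(sample(DNA_BASES, len, replace = TRUE),
                                 collapse = "")))
    }
    longer <- if (direction == "deletion") ev$ref else ev$alt
    indel_seq <- substr(longer, 2L, nchar(longer))
    Ls <- nchar(indel_seq)
    in_repeat <- FALSE
    for (d in seq_len(Ls)[Ls %% seq_len(Ls) == 0L]) {
      u <- substr(indel_seq, 1L, d)
      if (strrep(u, Ls / d) != indel_seq) next
      if (count_tandem_copies(seq, pos + 1L, u, 50L)$copies >= 2L) {
        in_repeat <- TRUE
        break
      }
    }
    if (!in_repeat) return(ev)
  }
  ev
}

#' Simulate mutation-accumulation lines
#'
#' For each line, per-class event counts are drawn as Poisson with mean
#' `rate * genome_size * n_cycles * t` (SNVs, InDels) or
#' `rate * n_cycles * t` (structural events), matching the independent-
#' divisions, minimal-selection MAE model. SNV positions are sampled
#' proportional to the profile's trinucleotide context weights over
#' eligible sites; slippage InDels change one unit copy inside a
#' sampled tandem run; remaining InDels are placed uniformly. CNVs are
#' placed as whole-chromosome duplications (aneuploidy) or segmental
#' duplications/deletions. All emitted variants are left-aligned and
#' ref-checked; the truth tables record the generating mechanism.
#'
#' @param genome an `mae_genome` (from [generate_genome()] or real).
#' @param profile a [condition_profile()].
#' @param n_lines number of independent lines.
#' @param n_cycles subculture cycles per line (recycled).
#' @param t divisions per colony.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, per-line VCFs and a
#'   `lines.tsv` metadata table are written there.
#' @return list with `lines` (metadata data.frame), `variants`
#'   (canonical variant table over all lines), and `truth` (list:
#'   `variants` with `class` and `slippage` columns; `cnvs` with
#'   `line_id`, `chrom`, `start`, `end`, `copy_state`, `scope`).
#' @export
simulate_lines <- function(genome, profile, n_lines, n_cycles,
                           t = 25L, seed = 1L, out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_cycles <- rep_len(n_cycles, n_lines)
  index <- genome_site_index(genome)
  N <- genome$total_length
  lines <- data.frame(
    line_id = sprintf("%s%02d", toupper(substr(profile$label, 1, 1)),
                      seq_len(n_lines)),
    condition = profile$label, n_cycles = n_cycles,
    stringsAsFactors = FALSE)
  all_var <- list(); all_truth <- list(); all_cnv <- list()
  for (li in seq_len(n_lines)) {
    divisions <- n_cycles[li] * t
    raw <- list()
    # --- SNVs per class
    for (cl in SUB_CLASSES) {
      lambda <- profile$snv_rates[[cl]] * N * divisions
      n_ev <- stats::rpois(1, lambda)
      if (n_ev == 0L) next
      ctr <- substr(cl, 1, 1)
      el <- index$sites[index$sites$center == ctr, , drop = FALSE]
      if (nrow(el) == 0L) stopf("no eligible sites for class %s", cl)
      w <- rep(1, nrow(el))
      cw <- profile$context_weights[[cl]]
      if (!is.null(cw)) w <- unname(cw[el$ctx])
      pick <- el[sample.int(nrow(el), min(n_ev, nrow(el)), prob = w), ]
      for (j in seq_len(nrow(pick))) {
        chrom <- pick$chrom[j]; pos <- pick$pos[j]
        ref <- subseq0(genome$seq[[chrom]], pos, pos + 1L)
        alt_pyr <- substr(cl, 3, 3)
        alt <- if (is_purine(ref)) complement_base(alt_pyr) else alt_pyr
        raw[[length(raw) + 1L]] <- list(chrom = chrom, pos = pos,
                                        ref = ref, alt = alt,
                                        class = cl, slippage = FALSE)
      }
    }
    # --- InDels per class
    for (cl in INDEL_CLASSES) {
      lambda <- profile$indel_rates[[cl]] * N * divisions
      n_ev <- stats::rpois(1, lambda)
      if (n_ev == 0L) next
      direction <- sub("_.*$", "", cl)
      bin <- sub("^.*_", "", cl)
      for (j in seq_len(n_ev)) {
        slip <- bin %in% c("1bp", "2bp") &&
          stats::runif(1) < profile$slippage_fraction
        ev <- if (slip) {
          draw_slippage_indel(genome, index,
                              if (bin == "1bp") 1L else 2L, direction)
        } else NULL
        if (is.null(ev)) {
          slip <- FALSE
          len <- switch(bin, "1bp" = 1L, "2bp" = 2L,
                        "3bp+" = profile$indel_len_sampler(1))
          ev <- draw_random_indel(genome, len, direction)
        }
        ev$class <- cl; ev$slippage <- slip
        raw[[length(raw) + 1L]] <- ev
      }
    }
    if (length(raw) > 0L) {
      rawdf <- do.call(rbind, lapply(raw, as.data.frame))
      v <- make_variants(genome, lines$line_id[li], rawdf$chrom,
                         rawdf$pos, rawdf$ref, rawdf$alt)
      all_var[[li]] <- v
      all_truth[[li]] <- cbind(v, class = rawdf$class,
                               slippage = rawdf$slippage)
    }
    # --- structural events
    n_aneu <- stats::rpois(1, profile$aneuploidy_rate * divisions)
    n_rearr <- stats::rpois(1, profile$rearrangement_rate * divisions)
    cnvs <- list()
    for (j in seq_len(n_aneu)) {
      chrom <- sample(names(genome$seq), 1)
      cnvs[[length(cnvs) + 1L]] <- data.frame(
        line_id = lines$line_id[li], chrom = chrom, start = 0L,
        end = genome$lengths[[chrom]], copy_state = 2L,
        scope = "whole_chromosome", stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_rearr)) {
      chrom <- sample(names(genome$seq), 1)
      L <- genome$lengths[[chrom]]
      width <- round(stats::runif(1, 0.05, 0.3) * L)
      terminal <- stats::runif(1) < 0.5
      if (terminal) {
        at_start <- stats::runif(1) < 0.5
        start <- if (at_start) 0L else L - width
      } else {
        start <- sample.int(L - width - 1L, 1)
      }
      cnvs[[length(cnvs) + 1L]] <- data.frame(
        line_id = lines$line_id[li], chrom = chrom, start = start,
        end = start + width,
        copy_state = sample(c(0L, 2L), 1),
        scope = if (terminal) "terminal" else "interstitial",
        stringsAsFactors = FALSE)
    }
    if (length(cnvs) > 0L) all_cnv[[li]] <- do.call(rbind, cnvs)
  }
  variants <- do.call(rbind, all_var) %||% empty_variants()
  if (is.null(variants)) variants <- empty_variants()
  truth_var <- do.call(rbind, all_truth)
  if (is.null(truth_var))
    truth_var <- cbind(empty_variants(), class = character(0),
                       slippage = logical(0))
  cnvs <- do.call(rbind, all_cnv)
  if (is.null(cnvs))
    cnvs <- data.frame(line_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       copy_state = integer(0), scope = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vf <- character(nrow(lines))
    for (li in seq_len(nrow(lines))) {
      vf[li] <- file.path(out_dir,
                          paste0(lines$line_id[li], ".vcf"))
      write_variants(
        variants[variants$line_id == lines$line_id[li], , drop = FALSE],
        vf[li], genome)
    }
    meta <- cbind(lines, variant_file = vf)
    utils::write.table(meta, file.path(out_dir, "lines.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(lines = lines, variants = variants,
       truth = list(variants = truth_var, cnvs = cnvs))
}

#' Simulate a windowed depth track
#'
#' Tiles each chromosome with half-open windows and draws per-window
#' depth as Poisson with mean `mean_depth * copy_state`, where the copy
#' state (0/1/2) comes from the CNV truth for one line (1 where
#' unaffected). A window takes the state of the CNV containing its
#' midpoint.
#'
#' @param genome an `mae_genome`.
#' @param cnvs CNV truth rows for one line (may be empty).
#' @param mean_depth expected depth at copy state 1 (default 100, a
#'   typical whole-genome coverage for a small eukaryote).
#' @param window window size in bp.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `depth`.
#' @export
simulate_depth <- function(genome, cnvs = NULL, mean_depth = 100,
                           window = 1000L, seed = 1L) {
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- list()
  for (chrom in names(genome$seq)) {
    L <- genome$lengths[[chrom]]
    starts <- seq.int(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    copy <- rep(1, length(starts))
    if (!is.null(cnvs) && nrow(cnvs) > 0L) {
      cc <- cnvs[cnvs$chrom == chrom, , drop = FALSE]
      mid <- (starts + ends) / 2
      for (k in seq_len(nrow(cc))) {
        hit <- mid >= cc$start[k] & mid < cc$end[k]
        copy[hit] <- cc$copy_state[k]
      }
    }
    out[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = ends,
      depth = stats::rpois(length(starts), mean_depth * copy),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
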