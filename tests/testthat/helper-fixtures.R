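# Shared fixtures, all built in code at test time.

# the 21-line spontaneous design: 11 lines x 103 cycles + 10 x 120,
# t = 25, genome size 20.5 Mb
spontaneous_design <- function() {
  li <- data.frame(line_id = sprintf("WY%02d", 1:21),
                   condition = "spontaneous",
                   n_cycles = rep(c(103L, 120L), c(11L, 10L)))
  experiment_design(li, t = 25L, genome_size = 20500000)
}

# the 8-line Zeocin design: 4 x 22 + 4 x 39 cycles
zeocin_design <- function() {
  li <- data.frame(line_id = sprintf("WZ%02d", 1:8),
                   condition = "zeocin",
                   n_cycles = rep(c(22L, 39L), each = 4L))
  experiment_design(li, t = 25L, genome_size = 20500000)
}

# small single-chromosome genome from an explicit sequence
toy_genome <- function(seq, name = "c1") {
  mae_genome(stats::setNames(seq, name))
}

# random i.i.d. genome as a plain string (independent of the package's
# Markov generator) for oracle comparisons
random_seq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# independent reverse complement used by oracles
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# a tiny variant table row
one_variant <- function(genome, chrom, pos, ref, alt, line = "L1") {
  make_variants(genome, line, chrom, pos, ref, alt)
}
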