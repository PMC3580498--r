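# Shared fixtures and independent oracles.  Everything is generated in code;
# no fixture files.

# a small scenario that keeps unit tests fast
small_config <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         n_genes = c(hog1_dependent = 10, hog1_independent = 10,
                     housekeeping = 10, down_regulated = 10,
                     unchanged = 60),
         chip_depth = 5e4, mnase_depth = 5e4),
    list(...))
  do.call(scenario_config, args)
}

# multiplier table with a single value everywhere (null scenarios)
flat_multipliers <- function(value = 1) {
  g <- default_chip_multipliers()
  g$multiplier <- value
  g
}

no_eviction <- function() {
  g <- default_eviction()
  g$fraction <- 0
  g
}

make_reads <- function(chrom, start, end, strand, name = NULL) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             name = if (is.null(name)) sprintf("r%d", seq_len(n)) else name,
             score = rep(0, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chrom_len, max_width = 300) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  make_reads("chrT", start, start + width, sample(c("+", "-"), n, TRUE))
}

# O(n*m) brute-force midpoint counting oracle
oracle_count_midpoint <- function(intervals, regions) {
  mid <- floor((intervals$start + intervals$end) / 2)
  vapply(seq_len(nrow(regions)), function(i) {
    sum(intervals$chrom == regions$chrom[i] &
          mid >= regions$start[i] & mid < regions$end[i])
  }, 0)
}

oracle_count_overlap <- function(intervals, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(intervals$chrom == regions$chrom[i] &
          intervals$start < regions$end[i] & intervals$end > regions$start[i])
  }, 0)
}

# brute-force doubly-trimmed mean-of-M factor, written independently of the
# package implementation (logical subsetting on rank thresholds)
oracle_tmm <- function(s, r, trim_m = 0.30, trim_a = 0.05) {
  pos <- s > 0 & r > 0
  s <- s[pos]; r <- r[pos]
  M <- log2(s / r)
  A <- (log2(s) + log2(r)) / 2
  n <- length(M)
  dm_rank <- rank(-abs(M - median(M)), ties.method = "first")
  da_rank <- rank(-abs(A - median(A)), ties.method = "first")
  keep <- dm_rank > floor(trim_m * n) & da_rank > floor(trim_a * n)
  2^mean(M[keep])
}

# bitmask membership-table oracle for three-set Venn cells
oracle_venn <- function(a, b, c) {
  u <- unique(c(a, b, c))
  mask <- (u %in% a) + 2 * (u %in% b) + 4 * (u %in% c)
  counts <- tabulate(mask, nbins = 7)
  # order: A_only, B_only, C_only, AB, AC, BC, ABC
  counts[c(1, 2, 4, 3, 5, 6, 7)]
}
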