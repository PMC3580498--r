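#' Remove over-represented reads (PCR amplification artifacts)
#'
#' Retains at most `max_per_position` reads per identical
#' `(chrom, start, strand)` key, keeping the first occurrences in input
#' order.  Idempotent.
#'
#' @param reads BED-style data.frame of reads.
#' @param max_per_position cap per key (>= 1); default 10, suited to the
#'   simulator's toy depths.
#' @return the filtered data.frame, original order preserved.
#' @export
dedup_reads <- function(reads, max_per_position = 10) {
  if (max_per_position < 1) stop("max_per_position must be >= 1")
  n <- nrow(reads)
  if (n == 0) return(reads)
  key <- paste(reads$chrom, reads$start, reads$strand, sep = "\r")
  ord <- order(factor(key, levels = unique(key)))  # stable: groups in first-seen order
  r <- rle(key[ord])
  occurrence <- integer(n)
  occurrence[ord] <- sequence(r$lengths)
  reads[occurrence <= max_per_position, , drop = FALSE]
}

#' Extend reads to a fixed fragment length from their 5' end
#'
#' Each read becomes a `target_length` bp interval anchored at its 5' end
#' and extended 3'-ward on its own strand (the standard fragment-size proxy
#' for single-end ChIP reads), clipped at chromosome edges.
#'
#' @param reads BED-style data.frame; strand must be `+` or `-`.
#' @param target_length fragment length in bp (default 250); must be at
#'   least the read length.
#' @param genome optional [genome_build()] used for right-edge clipping.
#' @return data.frame of extended intervals.
#' @export
extend_reads <- function(reads, target_length = 250, genome = NULL) {
  if (nrow(reads) == 0) return(reads)
  if (any(!reads$strand %in% c("+", "-")))
    stop("extend_reads() requires stranded reads")
  if (any(reads$end - reads$start > target_length))
    stop("target_length is shorter than some reads")
  out <- reads
  plus <- reads$strand == "+"
  out$end[plus] <- reads$start[plus] + target_length
  out$start[!plus] <- pmax(reads$end[!plus] - target_length, 0)
  if (!is.null(genome))
    out$end <- pmin(out$end, chrom_len(genome, out$chrom))
  out
}

#' Per-base coverage of a set of intervals
#'
#' `track[p]` is the number of intervals covering position `p`; the total
#' coverage mass equals the summed interval lengths.
#'
#' @param intervals BED-style data.frame.
#' @param genome a [genome_build()].
#' @return an object of class `"coverage_track"`: a list with `tracks` (one
#'   numeric vector per chromosome, index `p + 1` holds position `p`),
#'   `norm` (`"raw"` or `"rpm"`) and `n_reads`.
#' @export
pileup <- function(intervals, genome) {
  validate_intervals(intervals, genome)
  tracks <- lapply(names(genome), function(ch) {
    len <- chrom_len(genome, ch)
    sel <- intervals$chrom == ch
    d <- numeric(len + 1)
    if (any(sel)) {
      d <- tabulate(intervals$start[sel] + 1L, nbins = len + 1) -
        tabulate(intervals$end[sel] + 1L, nbins = len + 1)
    }
    cumsum(d)[seq_len(len)]
  })
  names(tracks) <- names(genome)
  structure(list(tracks = tracks, norm = "raw", n_reads = nrow(intervals)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", length(x$tracks), " chromosome(s), ",
      x$n_reads, " intervals, normalization: ", x$norm, "\n", sep = "")
  invisible(x)
}

#' Convert a raw coverage track to reads per million
#'
#' Each value is scaled by `1e6 / n_reads`, so the track is invariant to
#' global sequencing depth.
#'
#' @param track a `coverage_track` from [pileup()].
#' @param n_reads read count of the sample; defaults to the interval count
#'   recorded in the track.
#' @return the normalized `coverage_track` (norm `"rpm"`).
#' @export
to_rpm <- function(track, n_reads = track$n_reads) {
  if (track$norm == "rpm") return(track)
  if (n_reads <= 0) stop("n_reads must be positive")
  track$tracks <- lapply(track$tracks, function(v) v * 1e6 / n_reads)
  track$norm <- "rpm"
  track
}

#' Export a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed into intervals; zero runs are
#' omitted.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$tracks)) {
    v <- track$tracks[[ch]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(paste(ch, format_coord(start[keep]), format_coord(end[keep]),
                       format(r$values[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Count fragments per region and derive reads-per-kilobase
#'
#' A fragment is assigned to a region when its midpoint
#' (`floor((start+end)/2)`) falls inside the region's half-open span —
#' an unambiguous single assignment.  `method = "overlap"` instead counts
#' every fragment overlapping the region by at least one base.
#'
#' @param intervals BED-style data.frame of (extended) fragments.
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @param method `"midpoint"` (default) or `"overlap"`.
#' @return data.frame of class `"region_counts"`: `region_id`, `chrom`,
#'   `start`, `end`, `length`, `count`, `rpk`.
#' @export
count_regions <- function(intervals, regions, method = c("midpoint", "overlap")) {
  method <- match.arg(method)
  if (any(regions$end <= regions$start))
    stop("zero- or negative-length region: ",
         regions$region_id[which(regions$end <= regions$start)[1]])
  count <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    rsel <- which(regions$chrom == ch)
    isel <- intervals$chrom == ch
    if (method == "midpoint") {
      mids <- sort(floor((intervals$start[isel] + intervals$end[isel]) / 2))
      count[rsel] <- findInterval(regions$end[rsel] - 0.5, mids) -
        findInterval(regions$start[rsel] - 0.5, mids)
    } else {
      starts <- sort(intervals$start[isel])
      ends <- sort(intervals$end[isel])
      ## overlapping = total - entirely left (end <= region start)
      ##                     - entirely right (start >= region end)
      n <- length(starts)
      count[rsel] <- n - findInterval(regions$start[rsel] + 0.5, ends) -
        (n - findInterval(regions$end[rsel] - 0.5, starts))
    }
  }
  out <- data.frame(region_id = regions$region_id, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    length = regions$end - regions$start, count = count,
                    stringsAsFactors = FALSE)
  out$rpk <- out$count / (out$length / 1000)
  class(out) <- c("region_counts", "data.frame")
  out
}

#' Trimmed-mean-of-M-values (TMM) scaling factor between two samples
#'
#' Computes `factor = 2^mean(M)` over the regions surviving a double trim,
#' where `M = log2(sample/reference)` per region: regions with a zero in
#' either sample are excluded, then the `trim_m` fraction most extreme by
#' `|M - median(M)|` and the `trim_a` fraction most extreme by
#' `|A - median(A)|` are dropped.  A sample that is a pure multiple `c` of
#' the reference yields exactly `c`.
#'
#' @param sample_rpk,reference_rpk `region_counts` tables over identical
#'   regions, or plain numeric vectors aligned by position.
#' @param trim_m,trim_a trim fractions for M and A (defaults 0.30 / 0.05,
#'   the method's canonical values).
#' @return the positive scaling factor (divide RPK by it to obtain TRPK).
#' @export
tmm_factor <- function(sample_rpk, reference_rpk, trim_m = 0.30, trim_a = 0.05) {
  s <- region_values(sample_rpk, "rpk")
  r <- region_values(reference_rpk, "rpk")
  if (inherits(sample_rpk, "region_counts") && inherits(reference_rpk, "region_counts")) {
    if (!identical(sample_rpk$region_id, reference_rpk$region_id))
      stop("tmm_factor(): region sets differ between sample and reference")
  }
  if (length(s) != length(r)) stop("tmm_factor(): tables have different sizes")
  keep <- s > 0 & r > 0
  if (sum(keep) < 10)
    stop("tmm_factor(): fewer than 10 regions with positive signal in both samples")
  s <- s[keep]; r <- r[keep]
  M <- log2(s / r)
  A <- 0.5 * (log2(s) + log2(r))
  n <- length(M)
  drop_m <- utils::head(order(abs(M - stats::median(M)), decreasing = TRUE),
                        floor(trim_m * n))
  drop_a <- utils::head(order(abs(A - stats::median(A)), decreasing = TRUE),
                        floor(trim_a * n))
  surv <- setdiff(seq_len(n), union(drop_m, drop_a))
  if (length(surv) < 3)
    stop("tmm_factor(): too few regions survive trimming")
  2^mean(M[surv])
}

region_values <- function(x, column) {
  if (is.numeric(x)) return(x)
  if (column == "trpk_or_rpk") {
    for (col in c("trpk", "rpk", "count"))
      if (!is.null(x[[col]])) return(x[[col]])
  } else if (!is.null(x[[column]])) {
    return(x[[column]])
  }
  stop("expected a numeric vector or a table with a '", column, "' column")
}

#' TMM-normalized reads per kilobase (TRPK)
#'
#' Divides each region's RPK by the sample's TMM scaling factor; TRPK is
#' thereby invariant to global sequencing depth.
#'
#' @param table a `region_counts` table with an `rpk` column.
#' @param factor a positive scaling factor from [tmm_factor()].
#' @return the table with a `trpk` column added (`trpk = rpk / factor`).
#' @export
trpk <- function(table, factor) {
  if (!is.finite(factor) || factor <= 0) stop("scaling factor must be positive")
  table$trpk <- table$rpk / factor
  attr(table, "tmm_factor") <- factor
  table
}
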