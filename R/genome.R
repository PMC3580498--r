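#' hogseq: osmostress chromatin analysis on ChIP-Seq and MNase-Seq data
#'
#' Implements a reusable pipeline for the genome-wide analysis of RNA Pol II
#' redistribution, Hog1 chromatin association and Hog1-dependent nucleosome
#' eviction upon hyperosmotic stress in budding yeast, together with a
#' synthetic-data generator that produces inputs with known ground truth.
#'
#' All genomic coordinates are 0-based, half-open (BED convention) throughout
#' the package.  Gene tables supplied in 1-based inclusive coordinates are
#' converted once, at the reader, via `one_based = TRUE`.
#'
#' @name hogseq-package
#' @keywords internal
"_PACKAGE"

STRANDS <- c("+", "-", ".")

#' Construct a genome build
#'
#' A genome build is the set of chromosome names and lengths against which
#' every interval is validated.
#'
#' @param lengths named numeric vector of chromosome lengths in base pairs;
#'   names are chromosome identifiers.
#' @return an integer vector of class `"genome_build"`.
#' @examples
#' genome_build(c(chrI = 230218, chrII = 813184))
#' @export
genome_build <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(stats::setNames(as.numeric(lengths), names(lengths)),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

chrom_len <- function(genome, chrom) {
  i <- match(chrom, names(genome))
  if (anyNA(i)) stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  unname(unclass(genome)[i])
}

## internal: validate an interval data.frame (chrom/start/end/strand)
validate_intervals <- function(x, genome = NULL, where = "interval") {
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(where, " ", bad[1], ": invalid coordinates (need 0 <= start < end), got [",
         x$start[bad[1]], ",", x$end[bad[1]], ")")
  if (!is.null(x$strand)) {
    bad <- which(!x$strand %in% STRANDS)
    if (length(bad)) stop(where, " ", bad[1], ": invalid strand '", x$strand[bad[1]], "'")
  }
  if (!is.null(genome)) {
    len <- chrom_len(genome, x$chrom)
    bad <- which(x$end > len)
    if (length(bad))
      stop(where, " ", bad[1], ": interval ends at ", x$end[bad[1]],
           " beyond chromosome ", x$chrom[bad[1]], " (length ", len[bad[1]], ")")
  }
  invisible(x)
}

#' Read aligned reads from a BED file
#'
#' Accepts BED6 (`chrom start end name score strand`) or the minimal
#' BED3+strand layout (`chrom start end strand`).  Coordinates are taken
#' verbatim as 0-based half-open.  Line order is preserved.
#'
#' @param path path to a tab-separated BED file.
#' @param genome optional [genome_build()]; when supplied every interval is
#'   validated against the chromosome lengths.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.  An empty file yields a zero-row frame.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0 || is.null(nf))
    return(empty_reads())
  bad <- which(nf < 3 | nf == 5 | nf > 12)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": ", nf[bad[1]], " field(s)")
  if (length(unique(nf)) > 1)
    stop("malformed BED file ", path, ": inconsistent field count at line ",
         which(nf != nf[1])[1])
  x <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                         colClasses = "character", stringsAsFactors = FALSE)
  out <- data.frame(chrom = x[[1]],
                    start = suppressWarnings(as.numeric(x[[2]])),
                    end   = suppressWarnings(as.numeric(x[[3]])),
                    name = ".", score = 0, strand = ".",
                    stringsAsFactors = FALSE)
  if (ncol(x) == 4) {
    out$strand <- x[[4]]
  } else if (ncol(x) >= 6) {
    out$name <- x[[4]]
    out$score <- suppressWarnings(as.numeric(x[[5]]))
    out$strand <- x[[6]]
  }
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path, ": non-numeric coordinate")
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": need 0 <= start < end, got [",
         out$start[bad[1]], ",", out$end[bad[1]], ")")
  bad <- which(!out$strand %in% STRANDS)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path,
                        ": invalid strand '", out$strand[bad[1]], "'")
  if (!is.null(genome)) validate_intervals(out, genome, where = paste0(path, " line"))
  out
}

empty_reads <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Write intervals to a BED6 file
#'
#' Inverse of [read_bed()]: `write_bed(read_bed(f), f2)` reproduces a
#' canonical BED6 file byte-wise.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (defaults `"."`, `0`, `"."`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  name <- if (is.null(x$name)) rep(".", n) else x$name
  score <- if (is.null(x$score)) rep(0, n) else x$score
  strand <- if (is.null(x$strand)) rep(".", n) else x$strand
  lines <- paste(x$chrom, format_coord(x$start), format_coord(x$end),
                 name, format_coord(score), strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene-model table
#'
#' The table is tab-separated with a header row and columns `gene_id`,
#' `chrom`, `strand`, `orf_start`, `orf_end`, `tss`.  Internally all
#' coordinates are 0-based half-open; supply `one_based = TRUE` for tables in
#' the 1-based inclusive convention (converted once here, nowhere else).
#'
#' The TSS must lie on the gene's strand side of the ORF: `tss <= orf_start`
#' for `+` genes and `tss >= orf_end - 1` for `-` genes.
#'
#' @param path path to the gene table.
#' @param one_based logical; is the table 1-based inclusive?
#' @param genome optional [genome_build()] for coordinate validation.
#' @return a `data.frame` of class `"gene_model"`.
#' @export
read_gene_table <- function(path, one_based = FALSE, genome = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "orf_start", "orf_end", "tss")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (one_based) {
    x$orf_start <- x$orf_start - 1  # inclusive start -> 0-based
    x$tss <- x$tss - 1
  }
  as_gene_model(x[need], genome)
}

#' Assemble a gene-model table from vectors or a data.frame
#'
#' @param x data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `orf_start`, `orf_end`, `tss` in 0-based half-open coordinates.
#' @param genome optional [genome_build()] for validation.
#' @return `x` with class `"gene_model"` prepended.
#' @export
as_gene_model <- function(x, genome = NULL) {
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in gene table")
  if (any(!x$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  ok <- ifelse(x$strand == "+", x$tss <= x$orf_start, x$tss >= x$orf_end - 1)
  if (any(!ok))
    stop("TSS on the wrong side of the ORF for gene(s): ",
         paste(utils::head(x$gene_id[!ok], 5), collapse = ", "))
  validate_intervals(data.frame(chrom = x$chrom, start = x$orf_start,
                                end = x$orf_end, strand = x$strand),
                     genome, where = "gene")
  class(x) <- c("gene_model", "data.frame")
  x
}

#' Write a gene-model table (0-based half-open)
#' @param x a `gene_model` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression fold-change table
#'
#' Tab-separated with header `gene_id`, `fc_wt`, `fc_hog1`: linear fold
#' changes (stressed over unstressed) in the wild-type and the hog1 deletion
#' strain.  Fold changes must be positive.
#'
#' @param path path to the table.
#' @return a `data.frame` with the three columns.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "fc_wt", "fc_hog1")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(x$fc_wt)) || any(!is.finite(x$fc_hog1)) ||
      any(x$fc_wt <= 0) || any(x$fc_hog1 <= 0))
    stop("fold changes must be positive and finite")
  x[need]
}

#' Promoter window of each gene
#'
#' The promoter spans the 500 bp (by default) immediately upstream of the
#' TSS: `[tss - 500, tss)` for `+` genes, `[tss + 1, tss + 501)` for `-`
#' genes, clipped to chromosome bounds when a genome is given.
#'
#' @param genes a `gene_model` data.frame.
#' @param genome optional [genome_build()] used for clipping.
#' @param upstream promoter length in bp (default 500).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_of <- function(genes, genome = NULL, upstream = 500) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss + 1)
  end <- ifelse(plus, genes$tss, genes$tss + 1 + upstream)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(start, 0), end = end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if (!is.null(genome)) out$end <- pmin(out$end, chrom_len(genome, out$chrom))
  out
}

#' ORF interval of each gene
#' @inheritParams promoter_of
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
orf_of <- function(genes) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$orf_start, end = genes$orf_end,
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Window immediately downstream of the TSS
#'
#' The `[TSS, TSS + width)` window on the gene's own strand; it encompasses
#' the +1 nucleosome and is the region over which nucleosome occupancy is
#' quantified.
#'
#' @inheritParams promoter_of
#' @param width window width in bp (default 200).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
tss_window <- function(genes, genome = NULL, width = 200) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss, genes$tss - width + 1)
  end <- ifelse(plus, genes$tss + width, genes$tss + 1)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(start, 0), end = end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if (!is.null(genome)) out$end <- pmin(out$end, chrom_len(genome, out$chrom))
  out
}

#' Strand-aware TSS-relative offset of genomic positions
#'
#' Offset 0 is the TSS base itself; positive offsets run in the direction of
#' transcription.  For a `+` gene the offset is `position - tss`, for a `-`
#' gene `tss - position`, so flipping the strand negates nonzero offsets.
#'
#' @param position numeric vector of 0-based genomic positions on the gene's
#'   chromosome.
#' @param gene one row of a `gene_model` data.frame (or a list with `tss` and
#'   `strand`).
#' @return numeric vector of signed offsets.
#' @export
tss_relative <- function(position, gene) {
  if (gene$strand[1] == "+") position - gene$tss[1] else gene$tss[1] - position
}
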