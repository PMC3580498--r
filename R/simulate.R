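GENE_CLASSES <- c("hog1_dependent", "hog1_independent", "housekeeping",
                  "down_regulated", "unchanged")
CHIP_FACTORS <- c("Hog1", "PolII")
STRAINS <- c("wt", "hog1")
CONDITIONS <- c("t0", "stress")

#' Default ChIP enrichment multipliers
#'
#' Foreground read density over promoter+ORF relative to the genomic
#' background (density 1), per gene class, immunoprecipitated factor, strain
#' and condition.  The defaults encode the study conditions the pipeline is
#' meant to recover:
#'
#' * Pol II is recruited strongly upon stress to osmoresponsive genes; in
#'   Hog1-dependent genes that recruitment collapses in the hog1 strain,
#'   in Hog1-independent genes it is strain-independent.
#' * Housekeeping and down-regulated genes lose Pol II upon stress equally in
#'   both strains (Hog1 plays no role in non-stress-dependent genes).
#' * Hog1 itself binds Hog1-dependent genes strongly upon stress and
#'   Hog1-independent genes only marginally; in the hog1 deletion strain the
#'   Hog1 track is pure background.
#'
#' @return data.frame with columns `class`, `factor`, `strain`, `condition`,
#'   `multiplier`.
#' @export
default_chip_multipliers <- function() {
  g <- expand.grid(class = GENE_CLASSES, factor = CHIP_FACTORS,
                   strain = STRAINS, condition = CONDITIONS,
                   stringsAsFactors = FALSE)
  g$multiplier <- 1
  set_mult <- function(g, class, factor, strain, condition, value) {
    i <- g$class %in% class & g$factor %in% factor &
      g$strain %in% strain & g$condition %in% condition
    g$multiplier[i] <- value
    g
  }
  ## Pol II basal occupancy: housekeeping/down-regulated genes are well
  ## transcribed before stress, 'unchanged' genes modestly so.
  g <- set_mult(g, c("housekeeping", "down_regulated"), "PolII", STRAINS, "t0", 4)
  g <- set_mult(g, "unchanged", "PolII", STRAINS, CONDITIONS, 2)
  ## Pol II upon stress.
  g <- set_mult(g, "hog1_dependent", "PolII", "wt", "stress", 8)
  g <- set_mult(g, "hog1_dependent", "PolII", "hog1", "stress", 1)
  g <- set_mult(g, "hog1_independent", "PolII", STRAINS, "stress", 8)
  g <- set_mult(g, "housekeeping", "PolII", STRAINS, "stress", 2)
  g <- set_mult(g, "down_regulated", "PolII", STRAINS, "stress", 1)
  ## Hog1 binding (wild type; the hog1 strain is forced to background).
  g <- set_mult(g, "hog1_dependent", "Hog1", "wt", "stress", 8)
  g <- set_mult(g, "hog1_independent", "Hog1", "wt", "stress", 1.25)
  g
}

#' Default nucleosome eviction fractions
#'
#' Fraction of nucleosome signal lost upon stress over each gene of a class,
#' by strain.  Hog1-dependent genes are strongly remodeled in wild type and
#' not at all in the hog1 strain; Hog1-independent genes lose a smaller
#' fraction equally in both strains; the remaining classes are untouched.
#'
#' @return data.frame with columns `class`, `strain`, `fraction`.
#' @export
default_eviction <- function() {
  g <- expand.grid(class = GENE_CLASSES, strain = STRAINS,
                   stringsAsFactors = FALSE)
  g$fraction <- 0
  g$fraction[g$class == "hog1_dependent" & g$strain == "wt"] <- 0.51
  g$fraction[g$class == "hog1_independent"] <- 0.25
  g
}

#' Default expression fold-change class means
#'
#' Linear fold changes (stress over basal) around which the simulated
#' expression table is drawn.  Chosen so that at zero noise the downstream
#' classifier rules recover each class exactly: Hog1-dependent genes are
#' strongly induced with most induction lost in the hog1 strain
#' (ratio 0.25), Hog1-independent genes are induced nearly equally in both
#' strains (ratio ~0.95), housekeeping genes sit inside [1, 1.1],
#' down-regulated genes at 0.4, and 'unchanged' genes at a fold change that
#' triggers none of the rules.
#'
#' @return data.frame with columns `class`, `fc_wt`, `fc_hog1`.
#' @export
default_expression_means <- function() {
  data.frame(class = GENE_CLASSES,
             fc_wt = c(8, 2.2, 1.05, 0.4, 1.3),
             fc_hog1 = c(2, 2.1, 1.05, 0.4, 1.3),
             stringsAsFactors = FALSE)
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator.  The defaults are the package's
#' study conditions (documented in the methods vignette) and define the
#' default scenario used by the acceptance checks: 500 genes in five classes
#' (50 Hog1-dependent, 50 Hog1-independent, 50 housekeeping, 50
#' down-regulated, 300 unchanged), 5e5 reads per sample, 250-bp ChIP
#' fragments sequenced as 36-nt reads, 147-bp mononucleosome fragments on a
#' canonical TSS-relative grid with the +1 nucleosome at +50 bp.
#'
#' @param seed integer random seed; mandatory, every simulator output is an
#'   exact function of `(config, seed)`.
#' @param n_genes named integer vector of genes per class.
#' @param orf_length,spacing,tss_offset,promoter_length,profile_flank gene
#'   geometry in bp: ORF length, distance between consecutive gene anchors,
#'   TSS-to-ORF-start distance, promoter length, and the profile flank that
#'   must fit between genes.
#' @param chip_depth,mnase_depth reads emitted per ChIP / MNase sample.
#' @param chip_fragment,chip_read_length,mnase_fragment fragment and read
#'   geometry in bp.
#' @param nuc_offsets TSS-relative nucleosome centre grid in bp.
#' @param jitter_sd Gaussian jitter of nucleosome fragment centres, bp.
#' @param plus1_shift_dependent optional shift of the +1 nucleosome of
#'   Hog1-dependent genes, bp (default 0).
#' @param baseline_sd per-gene baseline binding spread, in log2 units; one
#'   lognormal factor per gene multiplies its foreground weight in every
#'   ChIP sample (it cancels from M but spreads A, as real per-gene
#'   expression levels do).
#' @param response_sd per-sample multiplier noise in log2 units.
#' @param chip_multipliers,eviction,expression_means class-level parameter
#'   tables; see [default_chip_multipliers()], [default_eviction()],
#'   [default_expression_means()].
#' @param expr_sdlog lognormal noise (sdlog) of the expression fold changes.
#' @param promoter_bias relative foreground density of promoter vs ORF
#'   (1 = uniform over promoter and ORF).
#' @param dup_rate,dup_geom_prob optional PCR-duplication artifact: fraction
#'   of reads re-emitted with geometric multiplicity (default off).
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed,
                            n_genes = c(hog1_dependent = 50,
                                        hog1_independent = 50,
                                        housekeeping = 50,
                                        down_regulated = 50,
                                        unchanged = 300),
                            orf_length = 1000, spacing = 4000,
                            tss_offset = 50, promoter_length = 500,
                            profile_flank = 1000,
                            chip_depth = 5e5, mnase_depth = 5e5,
                            chip_fragment = 250, chip_read_length = 36,
                            mnase_fragment = 147,
                            nuc_offsets = c(-200, 50, 215, 380, 545),
                            jitter_sd = 20,
                            plus1_shift_dependent = 0,
                            baseline_sd = 1, response_sd = 0.1,
                            chip_multipliers = default_chip_multipliers(),
                            eviction = default_eviction(),
                            expression_means = default_expression_means(),
                            expr_sdlog = 0.15,
                            promoter_bias = 1,
                            dup_rate = 0, dup_geom_prob = 0.5) {
  if (missing(seed)) stop("scenario_config(): 'seed' is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              orf_length = orf_length, spacing = spacing,
              tss_offset = tss_offset, promoter_length = promoter_length,
              profile_flank = profile_flank,
              chip_depth = chip_depth, mnase_depth = mnase_depth,
              chip_fragment = chip_fragment,
              chip_read_length = chip_read_length,
              mnase_fragment = mnase_fragment,
              nuc_offsets = nuc_offsets, jitter_sd = jitter_sd,
              plus1_shift_dependent = plus1_shift_dependent,
              baseline_sd = baseline_sd, response_sd = response_sd,
              chip_multipliers = chip_multipliers, eviction = eviction,
              expression_means = expression_means, expr_sdlog = expr_sdlog,
              promoter_bias = promoter_bias,
              dup_rate = dup_rate, dup_geom_prob = dup_geom_prob)
  class(cfg) <- "scenario_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (is.null(names(cfg$n_genes)) || !setequal(names(cfg$n_genes), GENE_CLASSES))
    stop("n_genes must be named with the five gene classes")
  if (any(cfg$n_genes < 0)) stop("n_genes must be non-negative")
  if (cfg$chip_depth <= 0 || cfg$mnase_depth <= 0) stop("read depth must be positive")
  if (cfg$spacing < cfg$orf_length + 2 * cfg$profile_flank)
    stop("spacing (", cfg$spacing, ") must be at least orf_length + 2*profile_flank (",
         cfg$orf_length + 2 * cfg$profile_flank, ")")
  if (any(cfg$eviction$fraction < 0 | cfg$eviction$fraction > 1))
    stop("eviction fractions must lie in [0, 1]")
  if (any(cfg$chip_multipliers$multiplier <= 0))
    stop("ChIP multipliers must be positive")
  if (any(cfg$expression_means$fc_wt <= 0) || any(cfg$expression_means$fc_hog1 <= 0))
    stop("expression fold-change means must be positive")
  if (cfg$dup_rate < 0 || cfg$dup_rate >= 1) stop("dup_rate must lie in [0, 1)")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> seed ", x$seed, ", ", sum(x$n_genes), " genes (",
      paste(names(x$n_genes), x$n_genes, sep = ":", collapse = ", "),
      "), chip depth ", format(x$chip_depth, scientific = FALSE),
      ", mnase depth ", format(x$mnase_depth, scientific = FALSE), "\n", sep = "")
  invisible(x)
}

#' Write / read a scenario configuration as YAML
#'
#' @param cfg a `scenario_config`.
#' @param path file path.
#' @return `path` invisibly, or the configuration.
#' @export
write_scenario_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$n_genes <- as.list(x$n_genes)
  for (tab in c("chip_multipliers", "eviction", "expression_means"))
    x[[tab]] <- lapply(x[[tab]], as.vector)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (tab in c("chip_multipliers", "eviction", "expression_means"))
    x[[tab]] <- as.data.frame(x[[tab]], stringsAsFactors = FALSE)
  args <- x
  args$n_genes <- unlist(x$n_genes)
  args$nuc_offsets <- as.numeric(x$nuc_offsets)
  do.call(scenario_config, args)
}

## deterministic per-stream seed: Horner hash of the tag folded into the
## user seed, kept below 2^31
derive_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a toy genome and gene models from a scenario configuration
#'
#' Genes are tiled on one chromosome with fixed spacing and alternating
#' strands; the chromosome length is `(n_genes + 1) * spacing` so every gene
#' keeps full profile flanks.  The TSS is placed `tss_offset` bp upstream of
#' the ORF start on each gene's strand.  Deterministic for a given config.
#'
#' @param config a [scenario_config()].
#' @return list with elements `genome` ([genome_build()]) and `genes`
#'   (`gene_model` data.frame).
#' @export
build_toy_genome <- function(config) {
  n <- sum(config$n_genes)
  len <- (n + 1) * config$spacing
  genome <- genome_build(c(chrS = len))
  if (n == 0)
    return(list(genome = genome,
                genes = as_gene_model(data.frame(gene_id = character(0),
                                                 chrom = character(0), strand = character(0),
                                                 orf_start = numeric(0), orf_end = numeric(0),
                                                 tss = numeric(0)))))
  i <- seq_len(n)
  anchor <- i * config$spacing
  strand <- ifelse(i %% 2 == 1, "+", "-")
  orf_start <- anchor
  orf_end <- anchor + config$orf_length
  tss <- ifelse(strand == "+", orf_start - config$tss_offset,
                orf_end - 1 + config$tss_offset)
  genes <- data.frame(gene_id = sprintf("g%04d", i), chrom = "chrS",
                      strand = strand, orf_start = orf_start,
                      orf_end = orf_end, tss = tss,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = as_gene_model(genes, genome))
}

#' Simulate the ground-truth manifest
#'
#' Assigns each gene a class (shuffled deterministically so class and
#' genomic position are not confounded), a per-gene baseline binding factor,
#' realised ChIP multipliers per factor/strain/condition, eviction fractions
#' per strain, and the true nucleosome centre offsets.
#'
#' @param genes `gene_model` data.frame.
#' @param config a [scenario_config()].
#' @return data.frame of class `"ground_truth"`, one row per gene; the
#'   nucleosome grid is stored in `attr(, "nuc_offsets")` and per-gene +1
#'   shifts in column `plus1_shift`.
#' @export
simulate_ground_truth <- function(genes, config) {
  n <- nrow(genes)
  stopifnot(n == sum(config$n_genes))
  with_seed(derive_seed(config$seed, "ground_truth"), {
    cls <- sample(rep(names(config$n_genes), times = config$n_genes))
    baseline <- 2^stats::rnorm(n, 0, config$baseline_sd)
    truth <- data.frame(gene_id = genes$gene_id, class = cls,
                        baseline = baseline, stringsAsFactors = FALSE)
    mt <- config$chip_multipliers
    for (f in CHIP_FACTORS) for (s in STRAINS) for (co in CONDITIONS) {
      key <- mt$factor == f & mt$strain == s & mt$condition == co
      m <- mt$multiplier[key][match(cls, mt$class[key])]
      m <- m * 2^stats::rnorm(n, 0, config$response_sd)
      if (f == "Hog1" && s == "hog1") m <- rep(1, n)  # knockout: pure background
      truth[[paste("mult", f, s, co, sep = "_")]] <- m
    }
    ev <- config$eviction
    for (s in STRAINS) {
      key <- ev$strain == s
      truth[[paste0("evict_", s)]] <- ev$fraction[key][match(cls, ev$class[key])]
    }
    truth$plus1_shift <- ifelse(cls == "hog1_dependent",
                                config$plus1_shift_dependent, 0)
    attr(truth, "nuc_offsets") <- config$nuc_offsets
    class(truth) <- c("ground_truth", "data.frame")
    truth
  })
}

## foreground segments (promoter and ORF per gene) with per-bp weights,
## plus the background complement at weight 1; returns a partition of the
## chromosome usable for piecewise-uniform sampling
chip_segments <- function(genes, genome, weights, promoter_bias = 1,
                          promoter_length = 500) {
  prom <- promoter_of(genes, genome, upstream = promoter_length)
  orf <- orf_of(genes)
  fg <- rbind(data.frame(start = prom$start, end = prom$end,
                         w = weights * promoter_bias),
              data.frame(start = orf$start, end = orf$end, w = weights))
  fg <- fg[order(fg$start), ]
  len <- unname(chrom_len(genome, "chrS"))
  ## complement gaps at weight 1
  gap_start <- c(0, fg$end)
  gap_end <- c(fg$start, len)
  keep <- gap_end > gap_start
  seg <- rbind(fg, data.frame(start = gap_start[keep], end = gap_end[keep], w = 1))
  seg <- seg[order(seg$start), ]
  seg$len <- seg$end - seg$start
  seg
}

## sample n integer positions from a piecewise-constant density
sample_positions <- function(seg, n) {
  counts <- as.vector(stats::rmultinom(1, n, prob = seg$w * seg$len))
  pos <- floor(rep(seg$start, counts) + stats::runif(n) * rep(seg$len, counts))
  pos
}

pcr_duplicate <- function(idx, dup_rate, geom_prob) {
  if (dup_rate <= 0) return(idx)
  n <- length(idx)
  pick <- stats::runif(n) < dup_rate
  extra <- stats::rgeom(sum(pick), geom_prob) + 1
  c(idx, rep(idx[pick], extra))
}

#' Simulate ChIP-Seq reads for one sample
#'
#' Fragment midpoints are drawn from a mixture of a uniform genomic
#' background (density 1) and per-gene foreground over promoter+ORF with
#' density equal to that gene's realised multiplier.  Each fragment is
#' `chip_fragment` bp; the emitted read is `chip_read_length` nt anchored at
#' the fragment's 5' end on a random strand, so strand-aware extension back
#' to the fragment length reconstitutes the fragment.  Exactly `chip_depth`
#' reads are emitted (multinomial allocation).
#'
#' @param factor `"Hog1"` or `"PolII"`.
#' @param strain `"wt"` or `"hog1"`.
#' @param condition `"t0"` or `"stress"`.
#' @param genes,truth,config,genome scenario objects from
#'   [build_toy_genome()] and [simulate_ground_truth()].
#' @return a BED-style `data.frame` of aligned reads.
#' @export
simulate_chip_reads <- function(factor, strain, condition, genes, truth,
                                config, genome) {
  if (!factor %in% CHIP_FACTORS) stop("unknown factor: ", factor)
  if (!strain %in% STRAINS) stop("unknown strain: ", strain)
  if (!condition %in% CONDITIONS) stop("unknown condition: ", condition)
  mcol <- paste("mult", factor, strain, condition, sep = "_")
  w <- truth[[mcol]] * truth$baseline
  if (factor == "Hog1" && strain == "hog1") w <- rep(1, nrow(truth))
  tag <- paste("chip", factor, strain, condition, sep = "_")
  with_seed(derive_seed(config$seed, tag), {
    seg <- chip_segments(genes, genome, w, config$promoter_bias,
                         config$promoter_length)
    mid <- sample_positions(seg, config$chip_depth)
    mid <- pcr_duplicate(mid, config$dup_rate, config$dup_geom_prob)
    n <- length(mid)
    len <- unname(chrom_len(genome, "chrS"))
    flen <- config$chip_fragment
    fstart <- pmax(mid - flen %/% 2, 0)
    fend <- pmin(fstart + flen, len)
    fstart <- pmax(fend - flen, 0)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rl <- min(config$chip_read_length, flen)
    rstart <- ifelse(strand == "+", fstart, pmax(fend - rl, fstart))
    rend <- ifelse(strand == "+", pmin(fstart + rl, fend), fend)
    data.frame(chrom = "chrS", start = rstart, end = rend,
               name = paste0("r", seq_len(n)), score = 0, strand = strand,
               stringsAsFactors = FALSE)
  })
}

#' Simulate MNase-Seq mononucleosome fragments for one sample
#'
#' Fragment centres sit on the TSS-relative nucleosome grid (strand-aware)
#' plus Gaussian jitter.  Under stress the sampling weight of every
#' nucleosome of a gene is multiplied by `1 - eviction fraction` for that
#' gene's class and strain, which emulates Hog1-dependent chromatin
#' remodeling as proportional thinning.  Fragments are `mnase_fragment` bp
#' centred on the sampled centre; exactly `mnase_depth` fragments are
#' emitted.
#'
#' @inheritParams simulate_chip_reads
#' @return a BED-style `data.frame` of aligned fragments.
#' @export
simulate_mnase_fragments <- function(strain, condition, genes, truth,
                                     config, genome) {
  if (!strain %in% STRAINS) stop("unknown strain: ", strain)
  if (!condition %in% CONDITIONS) stop("unknown condition: ", condition)
  offs <- attr(truth, "nuc_offsets")
  if (is.null(offs)) offs <- config$nuc_offsets
  nnuc <- length(offs)
  n_genes <- nrow(genes)
  tag <- paste("mnase", strain, condition, sep = "_")
  with_seed(derive_seed(config$seed, tag), {
    ## gene x nucleosome weight table
    w <- matrix(1, nrow = n_genes, ncol = nnuc)
    if (condition == "stress") {
      ev <- truth[[paste0("evict_", strain)]]
      w <- w * (1 - ev)
    }
    ## strand-aware genomic centres; +1 nucleosome (offset index of +50)
    ## optionally shifted for hog1_dependent genes
    shift <- truth$plus1_shift
    centre <- matrix(0, nrow = n_genes, ncol = nnuc)
    plus1 <- which.min(abs(offs - 50))
    for (k in seq_len(nnuc)) {
      o <- offs[k] + if (k == plus1) shift else 0
      centre[, k] <- ifelse(genes$strand == "+", genes$tss + o, genes$tss - o)
    }
    counts <- as.vector(stats::rmultinom(1, config$mnase_depth, prob = as.vector(w)))
    mid <- rep(as.vector(centre), counts) +
      round(stats::rnorm(config$mnase_depth, 0, config$jitter_sd))
    mid <- pcr_duplicate(mid, config$dup_rate, config$dup_geom_prob)
    n <- length(mid)
    len <- unname(chrom_len(genome, "chrS"))
    flen <- config$mnase_fragment
    fstart <- pmax(mid - flen %/% 2, 0)
    fend <- pmin(fstart + flen, len)
    fstart <- pmax(fend - flen, 0)
    data.frame(chrom = "chrS", start = fstart, end = fend,
               name = paste0("f", seq_len(n)), score = 0,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a per-gene expression fold-change table
#'
#' Fold changes are drawn lognormally around the class means of the
#' configuration; at `expr_sdlog = 0` the table equals the class means and
#' the downstream classifier recovers every class exactly.
#'
#' @inheritParams simulate_chip_reads
#' @return data.frame `gene_id`, `fc_wt`, `fc_hog1`.
#' @export
simulate_expression_table <- function(genes, truth, config) {
  n <- nrow(genes)
  em <- config$expression_means
  i <- match(truth$class, em$class)
  with_seed(derive_seed(config$seed, "expression"), {
    data.frame(gene_id = genes$gene_id,
               fc_wt = em$fc_wt[i] * exp(stats::rnorm(n, 0, config$expr_sdlog)),
               fc_hog1 = em$fc_hog1[i] * exp(stats::rnorm(n, 0, config$expr_sdlog)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete experiment to disk
#'
#' Emits, under `outdir`: one BED6 file per sample named
#' `{factor}_{strain}_{condition}.bed` (factors `Hog1`, `PolII`, `MNase`),
#' the gene table (`genes.tsv`), expression table (`expression.tsv`),
#' ground-truth manifest (`ground_truth.tsv`), genome table (`genome.tsv`)
#' and the configuration (`config.yaml`).
#'
#' @param config a [scenario_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
simulate_experiment <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tg <- build_toy_genome(config)
  truth <- simulate_ground_truth(tg$genes, config)
  paths <- list()
  for (f in CHIP_FACTORS) for (s in STRAINS) for (co in CONDITIONS) {
    p <- file.path(outdir, paste0(f, "_", s, "_", co, ".bed"))
    write_bed(simulate_chip_reads(f, s, co, tg$genes, truth, config, tg$genome), p)
    paths[[paste(f, s, co, sep = "_")]] <- p
  }
  for (s in STRAINS) for (co in CONDITIONS) {
    p <- file.path(outdir, paste0("MNase_", s, "_", co, ".bed"))
    write_bed(simulate_mnase_fragments(s, co, tg$genes, truth, config, tg$genome), p)
    paths[[paste("MNase", s, co, sep = "_")]] <- p
  }
  paths$genes <- write_gene_table(tg$genes, file.path(outdir, "genes.tsv"))
  expr <- simulate_expression_table(tg$genes, truth, config)
  utils::write.table(expr, file.path(outdir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$expression <- file.path(outdir, "expression.tsv")
  utils::write.table(truth, file.path(outdir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$ground_truth <- file.path(outdir, "ground_truth.tsv")
  utils::write.table(data.frame(chrom = names(tg$genome),
                                length = as.numeric(tg$genome)),
                     file.path(outdir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$genome <- file.path(outdir, "genome.tsv")
  paths$config <- write_scenario_config(config, file.path(outdir, "config.yaml"))
  invisible(paths)
}
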