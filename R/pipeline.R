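Z_HOG1 <- 4
Z_POLII <- 6
Z_DIFFERENTIAL <- 4

## promoters and ORFs of all genes as one region table; region ids carry the
## region kind so promoter- and ORF-level calls can be separated again
analysis_regions <- function(genes, genome, promoter_length = 500) {
  prom <- promoter_of(genes, genome, upstream = promoter_length)
  orf <- orf_of(genes)
  prom$region_id <- paste0(prom$gene_id, ":promoter")
  orf$region_id <- paste0(orf$gene_id, ":orf")
  prom$kind <- "promoter"; orf$kind <- "orf"
  rbind(prom, orf)
}

split_calls <- function(calls) {
  kind <- sub("^.*:", "", calls$region_id)
  gene <- sub(":[^:]*$", "", calls$region_id)
  calls$region_id <- gene
  list(promoter = calls[kind == "promoter", , drop = FALSE],
       orf = calls[kind == "orf", , drop = FALSE])
}

## gene-level booleans and max Z from promoter+ORF calls
gene_level <- function(calls) {
  sp <- split_calls(calls)
  orf <- sp$orf[match(sp$promoter$region_id, sp$orf$region_id), ]
  data.frame(gene_id = sp$promoter$region_id,
             significant = sp$promoter$significant | orf$significant,
             z_max = pmax(sp$promoter$Z, orf$Z),
             stringsAsFactors = FALSE)
}

## counts -> TRPK for one factor's four samples, TMM-referenced to wt t0
chip_quantify <- function(factor, samples, regions, config, genome) {
  counts <- lapply(samples, function(reads) {
    frags <- extend_reads(dedup_reads(reads), config$chip_fragment, genome)
    count_regions(frags, regions)
  })
  ref <- counts[[paste(factor, "wt", "t0", sep = "_")]]
  lapply(counts, function(ct) trpk(ct, tmm_factor(ct, ref)))
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Simulates every sample of the default experiment (two ChIP factors and
#' MNase, in two strains and two conditions, plus the expression table),
#' then runs the complete analysis: deduplication, extension, per-region
#' TRPK quantification, stress-vs-basal enrichment Z-scores for the kinase
#' (threshold 4) and Pol II (threshold 6), wt-vs-hog1 differential
#' recruitment (threshold 4), promoter/ORF binding assignment, gene
#' classification from expression, Venn overlaps, colocalization
#' statistics, TSS-aligned nucleosome profiles, per-strain occupancy /
#' eviction and the paired wt-vs-hog1 eviction test.
#'
#' @param config a [scenario_config()]; the seed inside it drives every
#'   random draw.
#' @return object of class `"hog1_run"` with components `config`, `genome`,
#'   `genes`, `truth`, `expression`, `classes`, `chip` (per-factor TRPK
#'   tables and calls), `binding`, `venn`, `colocalization`, `profiles`,
#'   `nucleosome_calls`, `occupancy` (per strain), `eviction_test` and
#'   `report`.
#' @export
run_pipeline <- function(config) {
  tg <- build_toy_genome(config)
  genome <- tg$genome; genes <- tg$genes
  truth <- simulate_ground_truth(genes, config)
  expression <- simulate_expression_table(genes, truth, config)
  classes <- classify_genes(expression)
  regions <- analysis_regions(genes, genome, config$promoter_length)

  ## --- ChIP branch -------------------------------------------------------
  chip <- list()
  for (f in CHIP_FACTORS) {
    samples <- list()
    for (s in STRAINS) for (co in CONDITIONS)
      samples[[paste(f, s, co, sep = "_")]] <-
        simulate_chip_reads(f, s, co, genes, truth, config, genome)
    quant <- chip_quantify(f, samples, regions, config, genome)
    thr <- if (f == "Hog1") Z_HOG1 else Z_POLII
    enr <- ma_transform(quant[[paste(f, "wt", "t0", sep = "_")]],
                        quant[[paste(f, "wt", "stress", sep = "_")]])
    enr <- zscore_stratified(enr)
    enrichment <- call_enriched(enr, thr)
    differential <- differential_recruitment(
      quant[[paste(f, "wt", "stress", sep = "_")]],
      quant[[paste(f, "hog1", "stress", sep = "_")]],
      z_threshold = Z_DIFFERENTIAL)
    chip[[f]] <- list(trpk = quant, enrichment = enrichment,
                      differential = differential,
                      gene_enrichment = gene_level(enrichment),
                      gene_differential = gene_level(differential),
                      z_threshold = thr)
  }
  hog1_bound <- chip$Hog1$gene_enrichment
  polii_recruited <- chip$PolII$gene_enrichment
  sp <- split_calls(chip$Hog1$enrichment)
  binding <- binding_assignment(sp$promoter, sp$orf,
                                polii_recruited$gene_id[polii_recruited$significant])

  ## --- overlaps and colocalization --------------------------------------
  venn <- venn_counts(hog1_bound$gene_id[hog1_bound$significant],
                      polii_recruited$gene_id[polii_recruited$significant],
                      classes$gene_id[classes$nacl_group],
                      labels = c("hog1", "polii", "upregulated"))
  osmo <- classes$gene_id[classes$osmoresponsive]
  io <- match(osmo, hog1_bound$gene_id)
  colocalization <- colocalization_stats(
    hog1_bound$z_max[io], polii_recruited$z_max[io],
    classes$fc_wt[match(osmo, classes$gene_id)])

  ## --- MNase branch ------------------------------------------------------
  mnase <- list()
  for (s in STRAINS) for (co in CONDITIONS)
    mnase[[paste(s, co, sep = "_")]] <-
      dedup_reads(simulate_mnase_fragments(s, co, genes, truth, config, genome))
  group_of <- stats::setNames(classes$label, classes$gene_id)
  tracks <- lapply(mnase, function(fr) to_rpm(pileup(fr, genome)))
  profiles <- list()
  nuc_calls <- list()
  for (cl in GENE_CLASSES) {
    gsel <- genes[genes$gene_id %in% classes$gene_id[classes$label == cl], ,
                  drop = FALSE]
    if (nrow(gsel) == 0) next
    for (nm in names(mnase))
      profiles[[paste(cl, nm, sep = "|")]] <-
        tss_profile(tracks[[nm]], gsel, flank = config$profile_flank,
                    group = paste(cl, nm))
    nuc_calls[[cl]] <- call_nucleosomes(profiles[[paste(cl, "wt_t0", sep = "|")]])
  }
  occupancy <- list()
  for (s in STRAINS)
    occupancy[[s]] <- occupancy_percent(mnase[[paste0(s, "_stress")]],
                                        mnase[[paste0(s, "_t0")]],
                                        genes, genome, groups = group_of)
  dep_genes <- classes$gene_id[classes$label == "hog1_dependent"]
  eviction_test <- if (length(dep_genes) >= 3)
    compare_eviction(occupancy$wt, occupancy$hog1, genes = dep_genes)
  else NULL

  run <- structure(list(config = config, genome = genome, genes = genes,
                        truth = truth, expression = expression,
                        classes = classes, chip = chip, binding = binding,
                        venn = venn, colocalization = colocalization,
                        profiles = profiles, nucleosome_calls = nuc_calls,
                        occupancy = occupancy, eviction_test = eviction_test),
                   class = "hog1_run")
  run$report <- run_report(run)
  run
}

## fraction of `genes` flagged significant in a gene-level call table
called_fraction <- function(gene_calls, genes) {
  i <- match(genes, gene_calls$gene_id)
  if (length(i) == 0) return(NA_real_)
  mean(gene_calls$significant[i])
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble the machine-readable run report
#'
#' Summarises a pipeline run: group sizes (classified and true), binding
#' fractions per dependency class, differential-recruitment recovery
#' against ground truth, Venn cells, per-group occupancy and eviction per
#' strain, the paired eviction test, colocalization correlations, the
#' thresholds used, the seed and a configuration hash.  Two runs with the
#' same configuration produce identical reports.
#'
#' @param run a `hog1_run` object.
#' @return a nested list of class `"hog1_report"`.
#' @export
run_report <- function(run) {
  for (part in c("classes", "chip", "venn", "occupancy"))
    if (is.null(run[[part]]))
      stop("run_report(): missing upstream output '", part, "'")
  classes <- run$classes
  truth <- run$truth
  by_class <- function(genes_of) {
    stats::setNames(lapply(GENE_CLASSES, genes_of), GENE_CLASSES)
  }
  class_sizes <- table(factor(classes$label, levels = GENE_CLASSES))
  truth_sizes <- table(factor(truth$class, levels = GENE_CLASSES))
  truth_genes <- function(cl) truth$gene_id[truth$class == cl]
  hog1_bound <- run$chip$Hog1$gene_enrichment
  polii_diff <- run$chip$PolII$gene_differential
  polii_enr <- run$chip$PolII$gene_enrichment
  binding_pct <- by_class(function(cl)
    100 * called_fraction(hog1_bound, truth_genes(cl)))
  polii_recruited_pct <- by_class(function(cl)
    100 * called_fraction(polii_enr, truth_genes(cl)))
  differential_pct <- by_class(function(cl)
    100 * called_fraction(polii_diff, truth_genes(cl)))
  occ_groups <- lapply(run$occupancy, function(o) o$groups)
  ev <- run$eviction_test
  accuracy <- 100 * mean(classes$label[match(truth$gene_id, classes$gene_id)] ==
                           truth$class)
  structure(list(
    seed = run$config$seed,
    config_hash = config_hash(run$config),
    thresholds = list(hog1_z = Z_HOG1, polii_z = Z_POLII,
                      differential_z = Z_DIFFERENTIAL),
    class_sizes = as.list(class_sizes),
    true_class_sizes = as.list(truth_sizes),
    class_label_accuracy_pct = accuracy,
    mean_fc = list(
      osmoresponsive = group_mean_fc(classes,
        classes$gene_id[classes$osmoresponsive]),
      non_osmoresponsive = group_mean_fc(classes,
        classes$gene_id[!classes$osmoresponsive])),
    hog1_bound_pct = binding_pct,
    polii_recruited_pct = polii_recruited_pct,
    polii_differential_pct = differential_pct,
    binding_categories = as.list(table(run$binding$category)),
    venn = c(as.list(run$venn), list(union = attr(run$venn, "union"))),
    colocalization = run$colocalization,
    occupancy_groups = occ_groups,
    eviction_test = if (is.null(ev)) NULL else unclass(ev)
  ), class = "hog1_report")
}

#' Write a run report as JSON plus a plain-text summary
#'
#' @param report a `hog1_report` (or a `hog1_run`, whose report is used).
#' @param dir output directory; `report.json` and `report.txt` are written
#'   there.  Report bodies are byte-identical across runs with the same
#'   configuration and seed.
#' @return invisibly, the two paths.
#' @export
write_report <- function(report, dir) {
  if (inherits(report, "hog1_run")) report <- report$report
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  txt_path <- file.path(dir, "report.txt")
  writeLines(format_report(report), txt_path)
  invisible(c(json = json_path, text = txt_path))
}

format_report <- function(report) {
  num <- function(x) formatC(x, digits = 4, format = "fg")
  lines <- c(
    "Osmostress chromatin pipeline report",
    paste0("seed ", report$seed, ", config ", report$config_hash),
    "",
    "Gene classes (classified / true):",
    vapply(GENE_CLASSES, function(cl)
      sprintf("  %-18s %4d / %4d", cl, report$class_sizes[[cl]],
              report$true_class_sizes[[cl]]), ""),
    sprintf("Label accuracy vs ground truth: %s%%",
            num(report$class_label_accuracy_pct)),
    sprintf("Mean FC, osmoresponsive: %s; rest: %s",
            num(report$mean_fc$osmoresponsive),
            num(report$mean_fc$non_osmoresponsive)),
    "",
    sprintf("Hog1-bound (Z>%d): dependent %s%%, independent %s%%",
            report$thresholds$hog1_z,
            num(report$hog1_bound_pct$hog1_dependent),
            num(report$hog1_bound_pct$hog1_independent)),
    sprintf("Pol II recruited (Z>%d): dependent %s%%, independent %s%%",
            report$thresholds$polii_z,
            num(report$polii_recruited_pct$hog1_dependent),
            num(report$polii_recruited_pct$hog1_independent)),
    sprintf("Differential recruitment (Z>%d): dependent %s%%, independent %s%%",
            report$thresholds$differential_z,
            num(report$polii_differential_pct$hog1_dependent),
            num(report$polii_differential_pct$hog1_independent)),
    "",
    "Venn cells (hog1 / polii / upregulated):",
    vapply(setdiff(names(report$venn), "union"), function(nm)
      sprintf("  %-28s %d", nm, report$venn[[nm]]), ""),
    ""
  )
  for (s in names(report$occupancy_groups)) {
    g <- report$occupancy_groups[[s]]
    lines <- c(lines, sprintf("Occupancy, %s stress vs t0:", s),
               vapply(seq_len(nrow(g)), function(i)
                 sprintf("  %-18s occ %s%%  evict %s%%  (n=%d)", g$group[i],
                         num(g$mean_occupancy_pct[i]),
                         num(g$mean_eviction_pct[i]), g$n[i]), ""))
  }
  if (!is.null(report$eviction_test))
    lines <- c(lines, "",
               sprintf("Paired eviction test (wt vs hog1, dependent genes): t=%s, p=%s",
                       num(report$eviction_test$t),
                       format.pval(report$eviction_test$p_value, digits = 3)))
  lines
}

#' @export
print.hog1_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.hog1_run <- function(x, ...) {
  cat("<hog1_run> ", nrow(x$genes), " genes, seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.hog1_run <- function(object, ...) {
  print(object$report)
  invisible(object$report)
}
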