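test_that("toy genome geometry follows the configuration arithmetic", {
  cfg <- scenario_config(seed = 1,
                         n_genes = c(hog1_dependent = 2, hog1_independent = 2,
                                     housekeeping = 2, down_regulated = 2,
                                     unchanged = 2),
                         orf_length = 2000, spacing = 4000,
                         profile_flank = 1000)
  tg <- build_toy_genome(cfg)
  expect_equal(unname(unclass(tg$genome)), 44000)  # (10 + 1) * 4000
  expect_equal(nrow(tg$genes), 10)
  expect_equal(tg$genes$orf_start, (1:10) * 4000)
  expect_equal(tg$genes$strand, rep(c("+", "-"), 5))

  empty <- scenario_config(seed = 1,
                           n_genes = c(hog1_dependent = 0, hog1_independent = 0,
                                       housekeeping = 0, down_regulated = 0,
                                       unchanged = 0))
  expect_equal(nrow(build_toy_genome(empty)$genes), 0)

  expect_error(scenario_config(seed = 1, spacing = 2500),
               "spacing")
})

test_that("simulators are exact functions of (config, seed)", {
  cfg <- small_config(seed = 7)
  tg <- build_toy_genome(cfg)
  t1 <- simulate_ground_truth(tg$genes, cfg)
  t2 <- simulate_ground_truth(tg$genes, cfg)
  expect_identical(t1, t2)
  r1 <- simulate_chip_reads("PolII", "wt", "stress", tg$genes, t1, cfg, tg$genome)
  r2 <- simulate_chip_reads("PolII", "wt", "stress", tg$genes, t1, cfg, tg$genome)
  expect_identical(r1, r2)
  e1 <- simulate_expression_table(tg$genes, t1, cfg)
  e2 <- simulate_expression_table(tg$genes, t1, cfg)
  expect_identical(e1, e2)
  # different seeds decouple
  cfg2 <- small_config(seed = 8)
  t3 <- simulate_ground_truth(tg$genes, cfg2)
  expect_false(identical(t1$baseline, t3$baseline))
})

test_that("emitted reads per sample equal the configured depth", {
  cfg <- small_config(seed = 3)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  reads <- simulate_chip_reads("Hog1", "wt", "stress", tg$genes, truth, cfg, tg$genome)
  expect_equal(nrow(reads), cfg$chip_depth)
  frags <- simulate_mnase_fragments("wt", "stress", tg$genes, truth, cfg, tg$genome)
  expect_equal(nrow(frags), cfg$mnase_depth)
})

test_that("flat multipliers give uniform read density (chi-square GOF)", {
  cfg <- small_config(seed = 11, chip_depth = 1e5,
                      chip_multipliers = flat_multipliers(1),
                      baseline_sd = 0, response_sd = 0)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  reads <- simulate_chip_reads("PolII", "wt", "t0", tg$genes, truth, cfg, tg$genome)
  mid <- floor((reads$start + reads$end) / 2)
  len <- unname(unclass(tg$genome))
  interior <- mid[mid >= 500 & mid < len - 500]
  bins <- cut(interior, breaks = seq(500, len - 500, length.out = 41))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})

test_that("foreground read mass matches the closed-form mixture expectation", {
  cfg <- small_config(seed = 13, chip_depth = 2e5,
                      chip_multipliers = flat_multipliers(16),
                      baseline_sd = 0, response_sd = 0)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  reads <- simulate_chip_reads("PolII", "wt", "stress", tg$genes, truth, cfg, tg$genome)
  frags <- extend_reads(reads, cfg$chip_fragment, tg$genome)
  prom <- promoter_of(tg$genes, tg$genome)
  orf <- orf_of(tg$genes)
  fg_len <- sum(prom$end - prom$start) + sum(orf$end - orf$start)
  total_len <- sum(unclass(tg$genome))
  expected_frac <- 16 * fg_len / (16 * fg_len + (total_len - fg_len))
  regions <- rbind(cbind(prom, region_id = paste0(prom$gene_id, "p")),
                   cbind(orf, region_id = paste0(orf$gene_id, "o")))
  observed <- sum(count_regions(frags, regions)$count) / nrow(frags)
  se <- sqrt(expected_frac * (1 - expected_frac) / nrow(frags))
  expect_lt(abs(observed - expected_frac), 4 * se)
})

test_that("the Hog1 track in the hog1 strain shows no gene-localized excess", {
  cfg <- small_config(seed = 17, chip_depth = 1e5)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  reads <- simulate_chip_reads("Hog1", "hog1", "stress", tg$genes, truth, cfg, tg$genome)
  frags <- extend_reads(reads, cfg$chip_fragment, tg$genome)
  prom <- promoter_of(tg$genes, tg$genome)
  orf <- orf_of(tg$genes)
  fg_len <- sum(prom$end - prom$start) + sum(orf$end - orf$start)
  expected_frac <- fg_len / sum(unclass(tg$genome))
  regions <- rbind(cbind(prom, region_id = paste0(prom$gene_id, "p")),
                   cbind(orf, region_id = paste0(orf$gene_id, "o")))
  observed <- sum(count_regions(frags, regions)$count) / nrow(frags)
  se <- sqrt(expected_frac * (1 - expected_frac) / nrow(frags))
  expect_lt(abs(observed - expected_frac), 4 * se)
})

test_that("zero jitter and zero eviction put fragment centres exactly on the grid", {
  cfg <- small_config(seed = 19, jitter_sd = 0, eviction = no_eviction(),
                      mnase_depth = 2e4)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  frags <- simulate_mnase_fragments("wt", "stress", tg$genes, truth, cfg, tg$genome)
  mid <- floor((frags$start + frags$end) / 2)
  centres <- unlist(lapply(seq_len(nrow(tg$genes)), function(i) {
    g <- tg$genes[i, ]
    if (g$strand == "+") g$tss + cfg$nuc_offsets else g$tss - cfg$nuc_offsets
  }))
  expect_true(all(mid %in% centres))
})

test_that("eviction thins nucleosome fragment mass proportionally", {
  ev <- no_eviction()
  ev$fraction[ev$class == "hog1_dependent" & ev$strain == "wt"] <- 0.5
  cfg <- scenario_config(seed = 23,
                         n_genes = c(hog1_dependent = 5, hog1_independent = 0,
                                     housekeeping = 0, down_regulated = 0,
                                     unchanged = 95),
                         mnase_depth = 2e5, eviction = ev)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  f0 <- simulate_mnase_fragments("wt", "t0", tg$genes, truth, cfg, tg$genome)
  f1 <- simulate_mnase_fragments("wt", "stress", tg$genes, truth, cfg, tg$genome)
  dep <- tg$genes[tg$genes$gene_id %in% truth$gene_id[truth$class == "hog1_dependent"], ]
  win <- tss_window(dep, tg$genome)
  win$region_id <- win$gene_id
  c0 <- sum(count_regions(f0, win)$count)
  c1 <- sum(count_regions(f1, win)$count)
  # thinning expectation: weight ratio times the fixed-depth renormalization
  w0 <- 100 * 5
  w1 <- 95 * 5 + 5 * 5 * 0.5
  expected <- 0.5 * w0 / w1
  se <- sqrt(1 / c0 + 1 / c1) * expected
  expect_lt(abs(c1 / c0 - expected), 4 * se)
})

test_that("knockout strain keeps nucleosomes of dependent genes upon stress", {
  cfg <- small_config(seed = 29, mnase_depth = 1e5)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  f0 <- simulate_mnase_fragments("hog1", "t0", tg$genes, truth, cfg, tg$genome)
  f1 <- simulate_mnase_fragments("hog1", "stress", tg$genes, truth, cfg, tg$genome)
  dep <- tg$genes[tg$genes$gene_id %in% truth$gene_id[truth$class == "hog1_dependent"], ]
  win <- tss_window(dep, tg$genome)
  win$region_id <- win$gene_id
  c0 <- sum(count_regions(f0, win)$count)
  c1 <- sum(count_regions(f1, win)$count)
  pt <- stats::prop.test(c(c0, c1), c(nrow(f0), nrow(f1)))
  expect_gt(pt$p.value, 0.01)
})

test_that("noiseless expression tables sit on the class means and classify exactly", {
  cfg <- small_config(seed = 31, expr_sdlog = 0)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  expr <- simulate_expression_table(tg$genes, truth, cfg)
  em <- cfg$expression_means
  i <- match(truth$class, em$class)
  expect_equal(expr$fc_wt, em$fc_wt[i])
  expect_equal(expr$fc_hog1, em$fc_hog1[i])
  labels <- classify_genes(expr)
  expect_equal(labels$label, truth$class)
})

test_that("a simulated experiment round-trips through its on-disk formats", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(seed = 37,
                         n_genes = c(hog1_dependent = 2, hog1_independent = 2,
                                     housekeeping = 2, down_regulated = 2,
                                     unchanged = 12),
                         chip_depth = 2000, mnase_depth = 2000)
  paths <- simulate_experiment(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  genome_tab <- read.table(paths$genome, header = TRUE, sep = "\t")
  genome <- genome_build(setNames(genome_tab$length, genome_tab$chrom))
  reads <- read_bed(paths$PolII_wt_stress, genome)
  expect_equal(nrow(reads), 2000)
  genes <- read_gene_table(paths$genes, genome = genome)
  expect_equal(nrow(genes), 20)
  expr <- read_expression_table(paths$expression)
  expect_equal(nrow(expr), 20)
  cfg2 <- read_scenario_config(paths$config)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$n_genes, cfg$n_genes)
  reads2 <- simulate_chip_reads("PolII", "wt", "stress",
                                build_toy_genome(cfg2)$genes,
                                simulate_ground_truth(build_toy_genome(cfg2)$genes, cfg2),
                                cfg2, genome)
  expect_equal(reads2[c("chrom", "start", "end", "strand")],
               reads[c("chrom", "start", "end", "strand")])
})
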