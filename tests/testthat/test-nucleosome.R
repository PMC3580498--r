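toy_profile_genes <- function(n = 4, spacing = 5000, strand = rep("+", n)) {
  anchor <- (1:n) * spacing
  as_gene_model(data.frame(
    gene_id = paste0("g", 1:n), chrom = "chrT", strand = strand,
    orf_start = anchor, orf_end = anchor + 1000,
    tss = ifelse(strand == "+", anchor - 50, anchor + 1049)))
}

test_that("TSS profiles are flat on uniform tracks and strand-aware", {
  genes <- toy_profile_genes(4)
  genome <- genome_build(c(chrT = 30000))
  track <- pileup(make_reads("chrT", 0, 30000, "+"), genome)  # uniform value 1
  prof <- tss_profile(track, genes, flank = 500)
  expect_true(all(prof$mean == 1))

  # delta of coverage exactly at the TSS of a minus-strand gene -> offset 0
  mgenes <- toy_profile_genes(2, strand = c("-", "-"))
  delta <- make_reads("chrT", mgenes$tss[1], mgenes$tss[1] + 1, "+")
  prof2 <- tss_profile(pileup(delta, genome), mgenes[1, ], flank = 200)
  expect_equal(unname(prof2$matrix[1, "0"]), 1)
  expect_equal(sum(prof2$matrix), 1)

  # edge genes are dropped with a warning
  edge <- toy_profile_genes(1)
  edge$tss <- 100
  expect_warning(expect_error(tss_profile(pileup(delta, genome), edge, flank = 500),
                              "no eligible genes"),
                 "dropped")
})

test_that("minus-strand profile rows run in the direction of transcription", {
  genome <- genome_build(c(chrT = 30000))
  g <- toy_profile_genes(2, strand = c("-", "-"))[1, ]
  downstream <- make_reads("chrT", g$tss - 100, g$tss - 90, "+")  # 10 bp at offset +91..+100
  prof <- tss_profile(pileup(downstream, genome), g, flank = 200)
  expect_equal(sum(prof$matrix[1, as.character(91:100)]), 10)
})

test_that("the peak caller finds a Gaussian bump, ignores flat profiles, merges close maxima", {
  offs <- -1000:1000
  bump <- function(c0) exp(-(offs - c0)^2 / (2 * 30^2))
  calls <- call_nucleosomes(bump(50), offsets = offs)
  expect_equal(nrow(calls), 1)
  expect_lt(abs(calls$center - 50), 5)

  expect_equal(nrow(call_nucleosomes(rep(2, 2001), offsets = offs)), 0)

  two_far <- bump(-150) + bump(150)
  expect_equal(nrow(call_nucleosomes(two_far, offsets = offs)), 2)
  two_close <- bump(-30) + 1.2 * bump(30)
  merged <- call_nucleosomes(two_close, offsets = offs)
  expect_equal(nrow(merged), 1)
  expect_gt(merged$center, -30)  # the higher of the pair wins
})

test_that("simulated phased nucleosomes are recovered near the grid offsets", {
  cfg <- small_config(seed = 41, mnase_depth = 2e5, eviction = no_eviction())
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  frags <- simulate_mnase_fragments("wt", "t0", tg$genes, truth, cfg, tg$genome)
  prof <- tss_profile(to_rpm(pileup(frags, tg$genome)), tg$genes)
  calls <- call_nucleosomes(prof)
  expect_equal(nrow(calls), length(cfg$nuc_offsets))
  err <- abs(calls$center - cfg$nuc_offsets)
  expect_true(all(err <= 20))
})

test_that("occupancy is 100% on identical samples and tracks in-window thinning", {
  cfg <- small_config(seed = 47, mnase_depth = 5e4)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  frags <- simulate_mnase_fragments("wt", "t0", tg$genes, truth, cfg, tg$genome)
  same <- occupancy_percent(frags, frags, tg$genes, tg$genome)
  expect_equal(same$per_gene$occupancy_pct, rep(100, nrow(same$per_gene)))
  expect_equal(same$per_gene$eviction_pct, rep(0, nrow(same$per_gene)))
  expect_equal(same$tmm_factor, 1)

  # halve the fragments overlapping two genes' windows: ~50% occupancy there
  win <- tss_window(tg$genes[1:2, ], tg$genome)
  mid <- floor((frags$start + frags$end) / 2)
  inwin <- (mid >= win$start[1] & mid < win$end[1]) |
    (mid >= win$start[2] & mid < win$end[2])
  thin <- frags[!(inwin & seq_len(nrow(frags)) %% 2 == 0), ]
  occ <- occupancy_percent(thin, frags, tg$genes, tg$genome)
  thinned <- occ$per_gene$occupancy_pct[match(tg$genes$gene_id[1:2],
                                              occ$per_gene$gene_id)]
  expect_true(all(abs(thinned - 50) < 6))
  rest <- occ$per_gene$occupancy_pct[!occ$per_gene$gene_id %in% tg$genes$gene_id[1:2]]
  expect_lt(abs(mean(rest) - 100), 2)
})

test_that("the paired eviction test matches the closed-form and t.test oracles", {
  wt <- data.frame(gene_id = c("a", "b", "c"), eviction_pct = c(10, 20, 30))
  hog1 <- data.frame(gene_id = c("a", "b", "c"), eviction_pct = c(5, 10, 15))
  res <- compare_eviction(wt, hog1)
  expect_equal(res$t, 10 / (5 / sqrt(3)), tolerance = 1e-6)  # 3.4641
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  tt <- t.test(wt$eviction_pct, hog1$eviction_pct, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)

  same <- compare_eviction(wt, wt)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  set.seed(51)
  w2 <- data.frame(gene_id = paste0("g", 1:20), eviction_pct = rnorm(20, 40, 10))
  h2 <- data.frame(gene_id = paste0("g", 1:20), eviction_pct = rnorm(20, 5, 10))
  r2 <- compare_eviction(w2, h2)
  t2 <- t.test(w2$eviction_pct, h2$eviction_pct, paired = TRUE)
  expect_equal(r2$t, unname(t2$statistic))
  expect_equal(r2$p_value, t2$p.value)
  expect_error(compare_eviction(wt, hog1[1:2, ]), "differ")
})

test_that("wt-vs-hog1 eviction difference is detected on simulated genes", {
  cfg <- small_config(seed = 53, mnase_depth = 2e5)
  tg <- build_toy_genome(cfg)
  truth <- simulate_ground_truth(tg$genes, cfg)
  occ <- lapply(c(wt = "wt", hog1 = "hog1"), function(s) {
    occupancy_percent(
      simulate_mnase_fragments(s, "stress", tg$genes, truth, cfg, tg$genome),
      simulate_mnase_fragments(s, "t0", tg$genes, truth, cfg, tg$genome),
      tg$genes, tg$genome)
  })
  dep <- truth$gene_id[truth$class == "hog1_dependent"]
  res <- compare_eviction(occ$wt, occ$hog1, genes = dep)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_diff, 30)
})
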