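test_that("dedup caps identical (chrom,start,strand) keys and is idempotent", {
  ten <- make_reads("chrI", rep(100, 10), rep(136, 10), "+")
  expect_equal(nrow(dedup_reads(ten, 3)), 3)

  uniq <- make_reads("chrI", 1:20 * 10, 1:20 * 10 + 36, "+")
  expect_identical(dedup_reads(uniq, 1), uniq)

  set.seed(42)
  mixed <- make_reads("chrI", sample(1:50, 400, TRUE), 500,
                      sample(c("+", "-"), 400, TRUE))
  capped <- dedup_reads(mixed, 1)
  keys <- unique(paste(mixed$chrom, mixed$start, mixed$strand))
  expect_equal(nrow(capped), length(keys))          # key-counting oracle
  expect_identical(dedup_reads(capped, 1), capped)  # idempotent
  # first occurrences retained, order preserved
  expect_identical(capped, mixed[!duplicated(paste(mixed$start, mixed$strand)), ])
})

test_that("reads extend 3'-ward from their 5' end and clip at edges", {
  genome <- genome_build(c(chrI = 10000))
  plus <- make_reads("chrI", 100, 136, "+")
  expect_equal(extend_reads(plus, 250, genome)[, c("start", "end")],
               data.frame(start = 100, end = 350))
  minus <- make_reads("chrI", 100, 136, "-")
  expect_equal(extend_reads(minus, 250, genome)[, c("start", "end")],
               data.frame(start = 0, end = 136))
  expect_identical(extend_reads(plus, 36, genome), plus)
  near_end <- make_reads("chrI", 9900, 9936, "+")
  expect_equal(extend_reads(near_end, 250, genome)$end, 10000)
  expect_error(extend_reads(plus, 10), "shorter")
})

test_that("pileup counts covering intervals and conserves total mass", {
  genome <- genome_build(c(chrT = 50))
  one <- make_reads("chrT", 5, 8, "+")
  tr <- pileup(one, genome)
  expect_equal(tr$tracks$chrT[6:8], c(1, 1, 1))  # 0-based 5,6,7
  expect_equal(sum(tr$tracks$chrT), 3)

  two <- make_reads("chrT", c(5, 6), c(8, 10), "+")
  expect_equal(max(pileup(two, genome)$tracks$chrT), 2)

  genome2 <- genome_build(c(chrT = 20000))
  set.seed(7)
  ivs <- random_intervals(1000, 20000)
  tr2 <- pileup(ivs, genome2)
  expect_equal(sum(tr2$tracks$chrT), sum(ivs$end - ivs$start))
})

test_that("rpm conversion scales by depth and is depth-invariant", {
  genome <- genome_build(c(chrT = 100))
  ivs <- make_reads("chrT", c(10, 10, 50), c(20, 20, 60), "+")
  rpm <- to_rpm(pileup(ivs, genome))
  expect_equal(rpm$tracks$chrT[11], 2 * 1e6 / 3)  # hand computation
  doubled <- to_rpm(pileup(rbind(ivs, ivs), genome))
  expect_equal(doubled$tracks$chrT, rpm$tracks$chrT)
})

test_that("bedGraph export collapses runs and omits zero coverage", {
  genome <- genome_build(c(chrT = 30))
  ivs <- make_reads("chrT", c(5, 5, 10), c(10, 12, 20), "+")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(pileup(ivs, genome), f)
  # [5,10)+[5,12) give 2 up to 10; [10,20) starts as [5,10) ends, so the
  # value stays 2 through 12 and the runs collapse to [5,12)=2, [12,20)=1
  expect_identical(readLines(f), c("chrT\t5\t12\t2", "chrT\t12\t20\t1"))
})

test_that("region counting matches the brute-force midpoint/overlap oracles", {
  regions <- data.frame(region_id = c("a", "b"), chrom = "chrT",
                        start = c(0, 5000), end = c(2000, 5400))
  ten <- make_reads("chrT", seq(100, 1000, 100), seq(100, 1000, 100) + 50, "+")
  ct <- count_regions(ten, regions)
  expect_equal(ct$count, c(10, 0))
  expect_equal(ct$rpk, c(5, 0))

  expect_equal(count_regions(empty_reads <- make_reads("chrT", numeric(0),
                                                       numeric(0), character(0)),
                             regions)$count, c(0, 0))

  set.seed(11)
  ivs <- random_intervals(500, 20000)
  reg <- data.frame(region_id = paste0("r", 1:30), chrom = "chrT",
                    start = seq(0, 14500, 500), end = seq(0, 14500, 500) + 400)
  expect_equal(count_regions(ivs, reg)$count, oracle_count_midpoint(ivs, reg))
  expect_equal(count_regions(ivs, reg, method = "overlap")$count,
               oracle_count_overlap(ivs, reg))
  expect_error(count_regions(ivs, data.frame(region_id = "z", chrom = "chrT",
                                             start = 10, end = 10)), "length")
})

test_that("TMM factor is exact on identity and pure scale, robust to outliers", {
  set.seed(5)
  r <- rgamma(200, 5, 0.1)
  expect_equal(tmm_factor(r, r), 1.0)
  expect_equal(tmm_factor(2 * r, r), 2.0)

  s <- 3 * r
  s[1:10] <- s[1:10] * 50                      # 5% outlier regions
  expect_lt(abs(tmm_factor(s, r) / 3 - 1), 0.01)
  expect_gt(abs(2^mean(log2(s / r)) / 3 - 1), 0.05)  # untrimmed mean is off
  expect_equal(tmm_factor(s, r), oracle_tmm(s, r))

  set.seed(6)
  s2 <- r * 2^rnorm(200, 1, 0.3)
  expect_equal(tmm_factor(s2, r), oracle_tmm(s2, r))
  expect_error(tmm_factor(c(1, 2, 3), c(1, 2, 3)), "fewer than 10")
})

test_that("TMM is scale-equivariant so TRPK is depth-invariant", {
  set.seed(9)
  r <- rgamma(300, 4, 0.05)
  s <- r * 2^rnorm(300, 0.5, 0.4)
  f <- tmm_factor(s, r)
  expect_equal(tmm_factor(s * 7.3, r), f * 7.3, tolerance = 1e-6)
  tab <- data.frame(region_id = seq_along(s), length = 1000, count = s, rpk = s)
  t1 <- trpk(tab, f)
  tab2 <- tab; tab2$rpk <- tab2$rpk * 7.3
  t2 <- trpk(tab2, tmm_factor(tab2$rpk, r))
  expect_equal(t2$trpk, t1$trpk, tolerance = 1e-6)
})

test_that("trpk divides rpk by the factor exactly", {
  tab <- data.frame(region_id = 1:3, length = c(500, 1000, 2000),
                    count = c(5, 10, 40), rpk = c(10, 10, 20))
  expect_equal(trpk(tab, 1)$trpk, tab$rpk)
  expect_equal(trpk(tab, 2)$trpk, tab$rpk / 2)
  expect_equal(trpk(tab, 2)$trpk[3], 10)  # spot check by hand
  expect_error(trpk(tab, 0), "positive")
})
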