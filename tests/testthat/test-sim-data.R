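test_that("toy genome construction is deterministic and honours the GC profile", {
  g1 <- flat_genome(seed = 3)
  g2 <- flat_genome(seed = 3)
  expect_identical(g1, g2)
  expect_true(all(g1$gc$gc == 0.40))

  # empirical per-bin GC spread matches the generating distribution
  big <- build_toy_genome(c(chrZ = 30e6), gc_sd = 0.05,
                          gc_range = c(0.05, 0.95), seed = 11)
  expect_gte(nrow(big$gc), 1000)
  expect_lt(abs(sd(big$gc$gc) - 0.05), 0.01)

  expect_error(build_toy_genome(c(chrA = 5e4)), "at least 10 bins")
  expect_error(build_toy_genome(c(2e6)), "named")
})

test_that("genome annotations are internally consistent", {
  g <- prenatal_genome()
  for (ch in g$chroms$chrom) {
    L <- g$chroms$length[g$chroms$chrom == ch]
    cb <- g$cytobands[g$cytobands$chrom == ch, ]
    cb <- cb[order(cb$start), ]
    # cytobands tile the chromosome without overlap
    expect_equal(cb$start[1], 0)
    expect_equal(cb$end[nrow(cb)], L)
    expect_true(all(cb$start[-1] == cb$end[-nrow(cb)]))
    ex <- g$excluded[g$excluded$chrom == ch, ]
    expect_gte(nrow(ex), 2)  # an excluded region and a centromere
    expect_true(all(ex$start >= 0 & ex$end <= L))
  }
  expect_true(all(g$gc$gc >= 0 & g$gc$gc <= 1))
})

test_that("count-tier simulation has the Poisson mean structure", {
  # disomic sample, bias off: mean count ~ depth_per_bin
  g <- build_toy_genome(c(chrA = 1e8, chrB = 1e8), gc_sd = 0, seed = 1)
  s <- simulate_bin_counts(g, "46,XX", depth_per_bin = 100, seed = 2)
  expect_gte(nrow(s$counts), 1e4)
  expect_lt(abs(mean(s$counts$count) - 100), 1)

  # trisomic chromosome: mean ~ 1.5x depth over >= 1e4 bins
  s3 <- simulate_bin_counts(g, "47,XX,+A", depth_per_bin = 100, seed = 3)
  on_a <- s3$counts$chrom == "chrA"
  expect_equal(sum(on_a), 5000)
  expect_lt(abs(mean(s3$counts$count[on_a]) - 150), 1.5)
  expect_lt(abs(mean(s3$counts$count[!on_a]) - 100), 1.5)
})

test_that("mosaic CNVs carry the closed-form expected CN", {
  g <- flat_genome()
  cnv <- cnv_spec("chrA", 400001, 1200000, "dup", copies = 3, mosaic = 0.4)
  s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 50, seed = 1)
  ec <- s$truth$expected_cn
  inside <- ec$chrom == "chrA" & ec$start >= 400000 & ec$end <= 1200000
  # 2(1 - f) + c f = 2.4 at f = 0.4, c = 3
  expect_equal(ec$expected_cn[inside], rep(2.4, sum(inside)))
  outside <- ec$chrom == "chrB"
  expect_true(all(ec$expected_cn[outside] == 2))
  expect_equal(s$truth$cnvs$expected_cn, 2.4)
  expect_equal(s$truth$cnvs$state, "mosaic trisomy")
})

test_that("count-tier simulation is bit-reproducible and rejects bad input", {
  g <- flat_genome()
  a <- simulate_bin_counts(g, "46,XY", depth_per_bin = 30, seed = 99)
  b <- simulate_bin_counts(g, "46,XY", depth_per_bin = 30, seed = 99)
  expect_identical(a$counts$count, b$counts$count)

  overlapping <- dplyr::bind_rows(
    cnv_spec("chrA", 100001, 500000, "del"),
    cnv_spec("chrA", 400001, 900000, "dup")
  )
  expect_error(simulate_bin_counts(g, "46,XX", overlapping, 30),
               "overlapping")
  expect_error(simulate_bin_counts(g, "46,XX", NULL, depth_per_bin = 0),
               "depth_per_bin")
})

test_that("genome-wide expected totals are conserved under mosaic mixtures", {
  g <- flat_genome()
  cnv <- cnv_spec("chrA", 200001, 1000000, "del", mosaic = 0.6)
  s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 80, seed = 5)
  lambda_total <- 80 * sum(s$truth$expected_cn$expected_cn) / 2
  # Poisson total: sd = sqrt(lambda_total)
  expect_lt(abs(sum(s$counts$count) - lambda_total),
            4 * sqrt(lambda_total))
})

test_that("read-tier simulation matches its configuration", {
  g <- flat_genome()
  cfg <- sim_config(n_reads = 2000, p_unique = 1, p_dup = 0, seed = 4)
  sim <- simulate_reads(g, "46,XX", config = cfg)
  expect_true(all(nchar(sim$reads$sequence) == 45))
  expect_true(all(nchar(sim$reads$quality) == 45))
  expect_true(all(sim$alignments$status == "unique"))
  expect_false(any(sim$alignments$duplicate))
  expect_true(all(!is.na(sim$alignments$pos)))

  expect_error(sim_config(adapter = "ACGT"), "adapter length")
})

test_that("observed duplicate fraction tracks the configured probability", {
  g <- flat_genome()
  cfg <- sim_config(n_reads = 1e5, p_unique = 0.62, p_dup = 0.05, seed = 8)
  sim <- simulate_reads(g, "46,XX", config = cfg)
  uniq <- sim$alignments[sim$alignments$status == "unique", ]
  expect_lt(abs(mean(uniq$duplicate) - 0.05), 0.005)
  # duplicates re-emit an existing mapped position
  keys <- paste(uniq$chrom, uniq$pos, uniq$strand)
  expect_true(all(keys[uniq$duplicate] %in% keys[!uniq$duplicate]))
})

test_that("maternal cell contamination mixes counts in expectation", {
  g <- flat_genome(lens = c(chr1 = 4e6, chr2 = 4e6, chr3 = 4e6, chrX = 4e6))
  fetal <- simulate_bin_counts(g, "45,X", depth_per_bin = 200, seed = 1)
  maternal <- simulate_bin_counts(g, "46,XX", depth_per_bin = 200, seed = 2)

  expect_identical(spike_mcc(fetal, maternal, 0, seed = 3)$counts$count,
                   fetal$counts$count)
  expect_identical(spike_mcc(fetal, maternal, 1, seed = 3)$counts$count,
                   maternal$counts$count)

  half <- spike_mcc(fetal, maternal, 0.5, seed = 3)
  ec <- half$truth$expected_cn
  expect_true(all(ec$expected_cn[ec$chrom == "chrX"] == 1.5))
  x_counts <- half$counts$count[half$counts$chrom == "chrX"]
  expect_lt(abs(mean(x_counts) - 200 * 1.5 / 2), 5)
  expect_equal(half$truth$mcc, 0.5)

  other <- simulate_bin_counts(flat_genome(), "46,XX", depth_per_bin = 200)
  expect_error(spike_mcc(fetal, other, 0.1), "different bin grids")
})

test_that("FASTQ and truth tables round-trip through their writers", {
  g <- flat_genome()
  sim <- simulate_reads(g, "46,XX", config = sim_config(n_reads = 200, seed = 2))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, sim$reads)

  al <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(sim$alignments, al)
  expect_equal(read_alignments(al), sim$alignments)

  cnv <- cnv_spec("chrA", 113576, 31928290 %% 2e6, "del")
  s <- simulate_bin_counts(g, "46,XX", cnv, 30, seed = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_truth_cnvs(s$truth$cnvs, tf)
  expect_match(readLines(tf, n = 1), "1-based inclusive")
  back_cnv <- read_truth_cnvs(tf)
  expect_equal(back_cnv$start, s$truth$cnvs$start)
  expect_equal(back_cnv$end, s$truth$cnvs$end)
})
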