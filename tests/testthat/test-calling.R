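test_that("CN classification reproduces the clinical threshold table", {
  expect_equal(as.character(classify_cn(3.0)), "duplication")
  expect_equal(as.character(classify_cn(2.0)), "disomy")
  expect_equal(as.character(classify_cn(2.5)), "mosaic trisomy")
  expect_equal(as.character(classify_cn(1.5)), "mosaic monosomy")
  expect_equal(as.character(classify_cn(0.9)), "deletion")
  expect_equal(as.character(classify_cn(0)), "deletion")

  # total and piecewise constant with exactly these breakpoints:
  # probes straddling each threshold (thresholds themselves go to the
  # adjacent mosaic band)
  probes <- c(1.1999, 1.2, 1.2001, 1.7999, 1.8, 1.8001,
              2.1999, 2.2, 2.2001, 2.7999, 2.8, 2.8001)
  expect_equal(as.character(classify_cn(probes)),
               c("deletion", "mosaic monosomy", "mosaic monosomy",
                 "mosaic monosomy", "mosaic monosomy", "disomy",
                 "disomy", "mosaic trisomy", "mosaic trisomy",
                 "mosaic trisomy", "mosaic trisomy", "duplication"))
  expect_false(any(is.na(classify_cn(seq(0, 5, by = 0.01)))))

  expect_error(classify_cn(-0.1), "non-negative")
})

test_that("exact-threshold values fall in the adjacent mosaic band, flagged", {
  b <- classify_cn(c(1.2, 1.8, 2.2, 2.8))
  expect_equal(as.character(b),
               c("mosaic monosomy", "mosaic monosomy",
                 "mosaic trisomy", "mosaic trisomy"))
  expect_true(all(attr(b, "boundary")))
  expect_false(any(attr(classify_cn(c(1.19, 2.5)), "boundary")))
})

test_that("mosaic fraction inverts the mixture expectation", {
  expect_equal(estimate_mosaic_fraction(2.4, "mosaic trisomy"), 0.4)
  expect_equal(estimate_mosaic_fraction(1.5, "mosaic monosomy"), 0.5)
  expect_true(is.na(estimate_mosaic_fraction(2.0, "disomy")))
  expect_equal(estimate_mosaic_fraction(3.5, "mosaic trisomy"), 1)
})

test_that("segmentation of noise-free profiles is exact", {
  flat <- smooth_profile(manual_profile(rep(2, 400)), 5)
  expect_equal(nrow(segment_profile(flat)), 0)

  cn <- rep(2, 600); cn[101:340] <- 1    # 240-bin deletion
  prof <- smooth_profile(manual_profile(cn), 5)
  segs <- segment_profile(prof)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "deletion")
  # boundaries within one bin of truth
  expect_lte(abs(segs$start - (100 * 20000 + 1)), 20000)
  expect_lte(abs(segs$end - 340 * 20000), 20000)
  expect_equal(segs$cn, 1)

  cn3 <- rep(2, 100); cn3[50:52] <- 1    # 3-bin excursion, below min_bins
  expect_equal(nrow(segment_profile(smooth_profile(manual_profile(cn3), 5),
                                    min_bins = 5)), 0)
})

test_that("segments never overlap and never span only masked bins", {
  g <- prenatal_genome()
  for (seed in 1:5) {
    cnv <- cnv_spec("chr2", 500001, 1500000, "del")
    s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 30, seed = seed)
    prof <- smooth_profile(normalize_to_cn(gc_correct(s$counts)), 5)
    segs <- segment_profile(prof)
    expect_true(all(segs$n_bins >= 5))
    by_chrom <- split(segs, segs$chrom)
    for (sc in by_chrom) {
      sc <- sc[order(sc$start), ]
      if (nrow(sc) > 1) expect_true(all(sc$start[-1] > sc$end[-nrow(sc)]))
    }
    for (i in seq_len(nrow(segs))) {
      sel <- prof$chrom == segs$chrom[i] & prof$start >= segs$start[i] - 1 &
        prof$end <= segs$end[i]
      expect_gt(sum(!prof$masked[sel]), 0)
    }
  }
})

test_that("simulated CNVs are recovered with their state and boundaries", {
  g <- flat_genome(lens = c(chrA = 10e6, chrB = 10e6, chrC = 10e6))
  cnv <- cnv_spec("chrA", 2000001, 4500000, "dup")  # 2.5 Mb, bin-aligned
  n_rep <- 25
  ok <- vapply(seq_len(n_rep), function(seed) {
    s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 30, seed = seed)
    res <- call_sample(s$counts)
    calls <- res$calls[res$calls$chrom == "chrA", ]
    # exactly one call, right state, both boundaries within 3 bins
    nrow(calls) == 1 && calls$state[1] == "duplication" &&
      max(abs(calls$start[1] - cnv$start),
          abs(calls$end[1] - cnv$end)) <= 3 * 20000
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # the event itself is detected in every replicate
  detected <- vapply(seq_len(n_rep), function(seed) {
    s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 30, seed = seed)
    calls <- call_sample(s$counts)$calls
    any(calls$chrom == "chrA" & calls$state == "duplication")
  }, logical(1))
  expect_true(all(detected))
})

test_that("mosaic CNVs classify into the mosaic bands with the right fraction", {
  g <- flat_genome(lens = c(chrA = 10e6, chrB = 10e6, chrC = 10e6))
  cnvm <- cnv_spec("chrA", 2000001, 6000000, "dup", mosaic = 0.4)
  s <- simulate_bin_counts(g, "46,XX", cnvm, depth_per_bin = 60, seed = 11)
  res <- call_sample(s$counts)
  calls <- res$calls[res$calls$chrom == "chrA", ]
  # mosaic events may fragment; every piece sits in the mosaic band and
  # together they cover most of the truth interval
  expect_gte(nrow(calls), 1)
  expect_true(all(calls$state == "mosaic trisomy"))
  tr <- tibble::tibble(chrom = "chrA", start = cnvm$start, end = cnvm$end,
                       state = "mosaic trisomy")
  expect_gte(interval_concordance(calls, tr)$concordance, 85)
  main <- calls[which.max(calls$n_bins), ]
  expect_lt(abs(main$mosaic_fraction - 0.4), 0.12)
})

test_that("whole-chromosome calls assemble the clinical karyotype strings", {
  g <- prenatal_genome()
  run <- function(kary, seed = 7) {
    call_sample(simulate_bin_counts(g, kary, depth_per_bin = 30,
                                    seed = seed)$counts)
  }
  t21 <- run("47,XX,+21")
  expect_equal(t21$karyotype, "47XN,+21")
  expect_equal(t21$whole_chromosome$chrom, "chr21")
  expect_equal(t21$whole_chromosome$state, "duplication")

  xo <- run("45,X")
  expect_equal(xo$karyotype, "45,XO")
  expect_equal(xo$sex$composition, "XO")
  expect_equal(nrow(xo$whole_chromosome), 0)

  eu <- run("46,XX")
  expect_equal(eu$karyotype, "46,XN")
  expect_equal(nrow(eu$whole_chromosome), 0)
  expect_equal(nrow(eu$calls), 0)

  expect_equal(run("47,XXY")$karyotype, "47,XXY")
  expect_equal(run("47,XXX")$karyotype, "47,XXX")
  expect_equal(run("47,XYY")$karyotype, "47,XYY")
  expect_equal(run("46,XY")$karyotype, "46,XN")

  # sex reporting enabled spells the composition out
  cfg <- pipeline_config(report_sex = TRUE)
  s <- simulate_bin_counts(g, "46,XY", depth_per_bin = 30, seed = 7)
  expect_equal(call_sample(s$counts, cfg)$karyotype, "46,XY")
})

test_that("ISCN-style names follow the published result format", {
  cytobands <- tibble::tibble(
    chrom = "chr5",
    start = c(0, 10e6, 33e6),
    end = c(10e6, 33e6, 46e6),
    band = c("p15.33", "p13.3", "p12")
  )
  seg <- tibble::tibble(chrom = "chr5", start = 113576, end = 32013575,
                        n_bins = 1595L, cn = 1.02, state = "deletion",
                        boundary = FALSE, mosaic_fraction = NA_real_,
                        size_mb = 31.90)
  named <- name_cnv(seg, cytobands)
  expect_equal(named$name, "5p15.33-p13.3(del, 31.90 Mb)")

  one_band <- tibble::tibble(chrom = "chr5", start = 33000001, end = 33730000,
                             n_bins = 36L, cn = 2.95, state = "duplication",
                             boundary = FALSE, mosaic_fraction = NA_real_,
                             size_mb = 0.73)
  expect_equal(name_cnv(one_band, cytobands)$name, "5p12(dup, 0.73 Mb)")

  # coordinate fallback without cytoband coverage
  expect_equal(name_cnv(one_band, NULL)$name,
               "chr5:33000001-33730000(dup, 0.73 Mb)")
  mono <- one_band; mono$state <- "mosaic monosomy"
  expect_match(name_cnv(mono, cytobands)$name, "del")
})

test_that("sex-chromosome dosage is judged against the inferred ploidy", {
  g <- prenatal_genome()
  # male X at CN 1 and absent Y produce no segmental deletion calls
  s <- simulate_bin_counts(g, "46,XY", depth_per_bin = 30, seed = 13)
  res <- call_sample(s$counts)
  expect_equal(nrow(res$calls), 0)
  # a real deletion on the single male X is still called
  cnv <- cnv_spec("chrX", 1500001, 2900000, "del", copies = 0)
  s2 <- simulate_bin_counts(g, "46,XY", cnv, depth_per_bin = 30, seed = 13)
  res2 <- call_sample(s2$counts)
  xcalls <- res2$calls[res2$calls$chrom == "chrX", ]
  expect_equal(nrow(xcalls), 1)
  expect_equal(xcalls$state, "deletion")
})

test_that("sample results expose tidy and glance summaries", {
  g <- prenatal_genome()
  cnv <- cnv_spec("chr4", 200001, 1400000, "del")
  res <- call_sample(simulate_bin_counts(g, "46,XX", cnv, 30,
                                         seed = 21)$counts)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("name", "state", "cn", "whole_chromosome") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$karyotype, "46,XN")
  expect_gte(gl$n_calls, 1)
  expect_equal(gl$status, "PASS")
})
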