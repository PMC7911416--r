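truth_row <- function(chrom = "chr1", start, end, state = "deletion",
                      copies = 1, label = "t") {
  tibble::tibble(chrom = chrom, start = start, end = end, state = state,
                 copies = copies, label = label)
}

call_row <- function(chrom = "chr1", start, end, state = "deletion",
                     cn = 1.0) {
  tibble::tibble(chrom = chrom, start = start, end = end, state = state,
                 cn = cn)
}

test_that("interval concordance handles the canonical geometries", {
  tr <- truth_row(start = 1001, end = 2000)
  expect_equal(interval_concordance(call_row(start = 1001, end = 2000),
                                    tr)$concordance, 100)
  expect_equal(interval_concordance(call_row(start = 5001, end = 6000),
                                    tr)$concordance, 0)
  # call covering exactly half the truth
  half <- interval_concordance(call_row(start = 1001, end = 1500), tr)
  expect_equal(half$concordance, 50)
  # reciprocal overlap of identical intervals is 100
  expect_equal(interval_concordance(call_row(start = 1001, end = 2000),
                                    tr)$reciprocal_overlap, 100)
  # no same-side call: a duplication does not credit a deletion truth
  expect_equal(interval_concordance(
    call_row(start = 1001, end = 2000, state = "duplication"),
    tr)$concordance, 0)
  # mosaic monosomy is loss-side and credits a deletion truth
  m <- interval_concordance(
    call_row(start = 1001, end = 2000, state = "mosaic monosomy", cn = 1.5),
    tr)
  expect_equal(m$concordance, 100)
  expect_false(m$state_agreement)
})

test_that("concordance equals a brute-force per-base membership count", {
  set.seed(19)
  for (rep in 1:20) {
    t_start <- sample.int(5e4, 1)
    t_end <- t_start + sample.int(5e4, 1)
    n_calls <- sample.int(4, 1)
    calls <- purrr::map_dfr(seq_len(n_calls), function(i) {
      s <- sample.int(9e4, 1)
      call_row(start = s, end = s + sample.int(3e4, 1))
    })
    got <- interval_concordance(calls, truth_row(start = t_start,
                                                 end = t_end))$concordance
    bases <- rep(FALSE, t_end)
    for (i in seq_len(nrow(calls))) {
      lo <- max(t_start, calls$start[i]); hi <- min(t_end, calls$end[i])
      if (lo <= hi) bases[lo:hi] <- TRUE
    }
    brute <- 100 * sum(bases[t_start:t_end]) / (t_end - t_start + 1)
    expect_equal(got, brute)
  }
})

test_that("concordance is invariant to translation and call fragmentation", {
  tr <- truth_row(start = 10001, end = 50000)
  whole <- call_row(start = 12001, end = 46000)
  pieces <- dplyr::bind_rows(call_row(start = 12001, end = 30000),
                             call_row(start = 30001, end = 46000))
  c_whole <- interval_concordance(whole, tr)$concordance
  c_pieces <- interval_concordance(pieces, tr)$concordance
  expect_equal(c_whole, c_pieces)

  shift <- 7e6
  tr_s <- truth_row(start = 10001 + shift, end = 50000 + shift)
  whole_s <- call_row(start = 12001 + shift, end = 46000 + shift)
  expect_equal(interval_concordance(whole_s, tr_s)$concordance, c_whole)
})

test_that("truth on an unknown chromosome scores zero with a warning", {
  tr <- truth_row(chrom = "chrZZ", start = 1, end = 1000)
  expect_warning(
    rec <- interval_concordance(call_row(start = 1, end = 1000), tr,
                                chroms = c("chr1", "chr2")),
    "unknown chromosome")
  expect_equal(rec$concordance, 0)
})

test_that("CN agreement compares the rounded call CN to expected copies", {
  tr <- truth_row(start = 1001, end = 2000, copies = 1)
  rec <- interval_concordance(call_row(start = 1001, end = 2000, cn = 1.1), tr)
  expect_true(rec$cn_agreement)
  rec2 <- interval_concordance(call_row(start = 1001, end = 2000, cn = 1.6), tr)
  expect_false(rec2$cn_agreement)
})

test_that("the MCC gate is strict at the 5% threshold", {
  expect_true(mcc_gate(0))
  expect_true(mcc_gate(4.9))
  expect_false(mcc_gate(5.0))
  expect_false(mcc_gate(50))
})

test_that("STR-based MCC estimation inverts the dosage model", {
  fetal <- tibble::tibble(locus = rep(c("L1", "L2", "L3"), each = 2),
                          allele = c("a", "b", "c", "d", "e", "f"))
  maternal <- tibble::tibble(locus = rep(c("L1", "L2", "L3"), each = 2),
                             allele = c("b", "m1", "d", "m2", "f", "m3"))

  # exact closed form: a single informative locus with h_spec / total = 0.05
  peaks1 <- tibble::tibble(locus = "L1", allele = c("a", "b", "m1"),
                           height = c(475, 475, 50))
  r1 <- estimate_mcc(peaks1, maternal[maternal$locus == "L1", ],
                     fetal[fetal$locus == "L1", ])
  expect_equal(r1$percent, 10)

  # synthetic mixture at 10% maternal fraction
  peaks <- simulate_str_peaks(fetal, maternal, fraction = 0.10)
  r <- estimate_mcc(peaks, maternal, fetal)
  expect_lt(abs(r$percent - 10), 1)
  expect_false(r$pass)  # 10% exceeds the 5% clinical gate
  expect_equal(r$n_informative, 3L)

  # zero maternal-specific height everywhere: 0%
  clean <- simulate_str_peaks(fetal, maternal, fraction = 0)
  r0 <- estimate_mcc(clean, maternal, fetal)
  expect_equal(r0$percent, 0)
  expect_true(r0$pass)

  # heavy contamination fails the gate
  dirty <- simulate_str_peaks(fetal, maternal, fraction = 0.5)
  expect_false(estimate_mcc(dirty, maternal, fetal)$pass)

  # no informative locus: uninformative, default pass with warning
  same <- tibble::tibble(locus = c("L1", "L1"), allele = c("a", "b"))
  pk <- simulate_str_peaks(same, same, 0.2)
  expect_warning(ru <- estimate_mcc(pk, same, same), "uninformative")
  expect_true(ru$pass)
  expect_equal(ru$n_informative, 0L)
  expect_true(is.na(ru$percent))

  expect_s3_class(generics::tidy(r), "tbl_df")
})

test_that("called intervals cover simulated truth at the expected level", {
  g <- flat_genome(lens = c(chrA = 10e6, chrB = 10e6, chrC = 10e6))
  cnv <- cnv_spec("chrA", 1500001, 2600000, "del")  # 1.1 Mb
  truth <- tibble::tibble(chrom = cnv$chrom, start = cnv$start,
                          end = cnv$end, state = "deletion", copies = 1)
  conc <- vapply(1:10, function(seed) {
    s <- simulate_bin_counts(g, "46,XX", cnv, depth_per_bin = 30, seed = seed)
    res <- call_sample(s$counts)
    interval_concordance(generics::tidy(res), truth)$concordance
  }, numeric(1))
  expect_true(all(conc >= 93))
})
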