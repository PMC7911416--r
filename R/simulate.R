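#' GC bias multiplier
#'
#' Quadratic multiplier `1 + a1*(gc - 0.4) + a2*(gc - 0.4)^2`, normalised
#' to 1 at GC 0.40 and clamped at 0. With coefficients `c(0, 0)` bias is
#' off.
#' @param gc GC fractions.
#' @param coef Length-2 numeric `c(a1, a2)`.
#' @return Multipliers, same length as `gc`.
#' @export
gc_bias_multiplier <- function(gc, coef = c(0, 0)) {
  d <- gc - 0.4
  pmax(0, 1 + coef[1] * d + coef[2] * d^2)
}

check_cnv_overlap <- function(cnvs) {
  if (is.null(cnvs) || nrow(cnvs) < 2) return(invisible(cnvs))
  for (ch in unique(cnvs$chrom)) {
    cc <- cnvs[cnvs$chrom == ch, ]
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1 && any(cc$start[-1] <= cc$end[-nrow(cc)])) {
      abort(sprintf("overlapping CNV specs on %s", ch))
    }
  }
  invisible(cnvs)
}

# Expected copy number per grid bin under a karyotype + CNV set.
# CNV coordinates are 1-based inclusive; bins partially overlapped by a
# CNV get a length-weighted expectation.
expected_cn_bins <- function(grid, copies, cnvs = NULL) {
  base <- copies$copies[match(grid$chrom, copies$chrom)]
  expected <- as.numeric(base)
  if (!is.null(cnvs) && nrow(cnvs)) {
    for (i in seq_len(nrow(cnvs))) {
      cv <- cnvs[i, ]
      sel <- grid$chrom == cv$chrom
      if (!any(sel)) abort(sprintf("CNV on unknown chromosome %s", cv$chrom))
      frac <- overlap_width0(grid$start[sel], grid$end[sel],
                             cv$start - 1, cv$end) /
        (grid$end[sel] - grid$start[sel])
      carrier <- base[sel] * (1 - cv$mosaic) + cv$copies * cv$mosaic
      expected[sel] <- expected[sel] + frac * (carrier - base[sel])
    }
  }
  expected
}

#' Simulate a sample at the count tier
#'
#' Draws per-bin unique-read counts directly:
#' `count_i ~ Poisson(depth_per_bin * local_cn_i / 2 * bias(gc_i))`, where
#' `local_cn_i` is the expected copy number of bin `i` under the karyotype
#' and CNV set (a mosaic CNV with carrier fraction `f` contributes
#' `2(1 - f) + copies * f`). Masked bins still receive counts — excluding
#' them is the pipeline's job, not the sample's. The truth record carries
#' the exact CNV coordinates, the expected CN of every bin, and the seed.
#'
#' @param genome A `genome_model`.
#' @param karyotype Karyotype string or `karyotype_spec` (default
#'   `"46,XX"`).
#' @param cnvs Tibble of [cnv_spec()] rows (1-based inclusive), or `NULL`.
#' @param depth_per_bin Expected unique reads per disomic bin (> 0).
#' @param config A [sim_config()]; supplies GC-bias coefficients and the
#'   default seed.
#' @param seed Integer seed; identical seeds give bit-identical counts.
#' @return A `sim_sample`: list with `counts` (a `bin_counts`) and `truth`
#'   (karyotype, per-chromosome copies, CNV table with expected state,
#'   per-bin expected CN, depth, MCC fraction, seed).
#' @export
simulate_bin_counts <- function(genome, karyotype = "46,XX", cnvs = NULL,
                                depth_per_bin = 30,
                                config = sim_config(),
                                seed = config$seed) {
  if (depth_per_bin <= 0) abort("depth_per_bin must be > 0")
  check_cnv_overlap(cnvs)
  if (is.character(karyotype)) karyotype <- parse_karyotype(karyotype)
  copies <- karyotype_copies(genome, karyotype)
  grid <- build_bin_grid(genome)
  expected <- expected_cn_bins(grid, copies, cnvs)
  lambda <- depth_per_bin * expected / 2 *
    gc_bias_multiplier(grid$gc, config$gc_bias)

  counts <- with_local_seed(seed, {
    k <- grid
    k$count <- rpois(nrow(grid), lambda)
    k
  })
  counts <- structure(counts,
                      n_assigned = sum(counts$count),
                      tallies = list(n_input = sum(counts$count),
                                     filtered = 0L, off_grid = 0L,
                                     partial_bin = 0L),
                      class = unique(c("bin_counts", class(counts))))

  truth_cnvs <- if (!is.null(cnvs) && nrow(cnvs)) {
    dplyr::mutate(
      cnvs,
      expected_cn = 2 * (1 - .data$mosaic) + .data$copies * .data$mosaic,
      state = dplyr::case_when(
        .data$type == "deletion" & .data$mosaic == 1 ~ "deletion",
        .data$type == "duplication" & .data$mosaic == 1 ~ "duplication",
        .data$type == "deletion" ~ "mosaic monosomy",
        TRUE ~ "mosaic trisomy"
      ),
      label = sprintf("%s:%d-%d:%s", .data$chrom, .data$start, .data$end,
                      substr(.data$type, 1, 3))
    )
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           type = character(), copies = integer(), mosaic = numeric(),
           expected_cn = numeric(), state = character(), label = character())
  }

  structure(
    list(counts = counts,
         truth = list(karyotype = karyotype$string, copies = copies,
                      cnvs = truth_cnvs,
                      expected_cn = tibble(chrom = grid$chrom,
                                           start = grid$start, end = grid$end,
                                           expected_cn = expected),
                      depth_per_bin = depth_per_bin,
                      mcc = config$mcc, seed = seed)),
    class = "sim_sample"
  )
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("<sim_sample> %s, %d bins, %d CNV(s), depth %.1f, seed %s\n",
              x$truth$karyotype, nrow(x$counts), nrow(x$truth$cnvs),
              x$truth$depth_per_bin, format(x$truth$seed)))
  invisible(x)
}

#' Simulate a sample at the read tier
#'
#' Generates raw reads of `config$read_length` bp: a genomic insert of
#' `config$insert_length` bases (drawn base-by-base with the source bin's
#' GC fraction) followed by the adapter, with per-base qualities from a
#' two-state high/low model. Mapping positions are sampled proportionally
#' to local copy number and GC bias; each read is uniquely mapped with
#' probability `p_unique` (the remainder split between multi-mapped and
#' unmapped, which carry no position); uniquely mapped reads are
#' duplicates with probability `p_dup`, re-emitting an earlier unique
#' read's position and strand.
#'
#' @inheritParams simulate_bin_counts
#' @param config A [sim_config()] (read counts, lengths, adapter,
#'   probabilities, seed).
#' @return A `sim_reads`: list with `reads` (read_id, sequence, quality),
#'   `alignments` (read_id, chrom, pos 1-based, strand, status,
#'   duplicate), `truth`, and the `config` used.
#' @export
simulate_reads <- function(genome, karyotype = "46,XX", cnvs = NULL,
                           config = sim_config(), seed = config$seed) {
  check_cnv_overlap(cnvs)
  if (is.character(karyotype)) karyotype <- parse_karyotype(karyotype)
  copies <- karyotype_copies(genome, karyotype)
  grid <- build_bin_grid(genome)
  expected <- expected_cn_bins(grid, copies, cnvs)
  weight <- expected / 2 * gc_bias_multiplier(grid$gc, config$gc_bias)
  if (all(weight == 0)) abort("no sequenceable genome under this karyotype")
  n <- config$n_reads

  with_local_seed(seed, {
    src_bin <- sample.int(nrow(grid), n, replace = TRUE, prob = weight)
    offset <- floor(runif(n) * (attr(grid, "bin_size") - config$insert_length))
    pos <- grid$start[src_bin] + offset + 1  # 1-based 5' coordinate
    chrom <- grid$chrom[src_bin]
    strand <- sample(c("+", "-"), n, replace = TRUE)

    status <- sample(c("unique", "multi", "unmapped"), n, replace = TRUE,
                     prob = c(config$p_unique,
                              (1 - config$p_unique) * config$p_multi_given_nonunique,
                              (1 - config$p_unique) *
                                (1 - config$p_multi_given_nonunique)))
    chrom[status != "unique"] <- NA_character_
    pos[status != "unique"] <- NA_real_
    strand[status != "unique"] <- NA_character_

    # duplicates re-emit an earlier unique read's mapping
    duplicate <- rep(FALSE, n)
    uniq_idx <- which(status == "unique")
    if (length(uniq_idx) > 1) {
      is_dup <- runif(length(uniq_idx)) < config$p_dup
      is_dup[1] <- FALSE
      for (j in which(is_dup)) {
        donor <- uniq_idx[sample.int(j - 1L, 1L)]
        i <- uniq_idx[j]
        chrom[i] <- chrom[donor]; pos[i] <- pos[donor]
        strand[i] <- strand[donor]; src_bin[i] <- src_bin[donor]
        duplicate[i] <- TRUE
      }
    }

    gc <- grid$gc[src_bin]
    gc[is.na(gc)] <- 0.4
    L <- config$insert_length
    base_mat <- matrix("A", nrow = n, ncol = L)
    for (k in seq_len(L)) {
      u <- runif(n)
      base_mat[, k] <- ifelse(u < gc / 2, "G",
                        ifelse(u < gc, "C",
                          ifelse(u < gc + (1 - gc) / 2, "A", "T")))
    }
    inserts <- do.call(paste0, as.data.frame(base_mat,
                                             stringsAsFactors = FALSE))
    sequences <- paste0(inserts, config$adapter)

    qmat <- matrix(
      ifelse(runif(n * config$read_length) < config$p_high_quality,
             config$q_high, config$q_low),
      nrow = n
    )
    qual_chars <- matrix(intToUtf8(as.vector(qmat) + 33L, multiple = TRUE),
                         nrow = n)
    qualities <- do.call(paste0, as.data.frame(qual_chars,
                                               stringsAsFactors = FALSE))

    read_id <- sprintf("read%07d", seq_len(n))
    structure(
      list(
        reads = tibble(read_id = read_id, sequence = sequences,
                       quality = qualities),
        alignments = tibble(read_id = read_id, chrom = chrom, pos = pos,
                            strand = strand, status = status,
                            duplicate = duplicate),
        truth = list(karyotype = karyotype$string, copies = copies,
                     cnvs = cnvs %||% tibble(), seed = seed),
        config = config
      ),
      class = "sim_reads"
    )
  })
}

#' Mix a maternal sample into a fetal one
#'
#' Emulates maternal cell contamination (MCC): at the count tier, each
#' bin's mixed count is `Binomial(fetal_i, 1 - f) + Binomial(maternal_i,
#' f)`, so the expectation is the `(1 - f)`-fetal/`f`-maternal mixture
#' while counts stay integers. Both samples must be simulated on the same
#' grid.
#'
#' @param fetal,maternal `sim_sample` objects sharing one grid.
#' @param fraction Maternal fraction in \[0, 1\].
#' @param seed Integer seed for the thinning draws.
#' @return A `sim_sample` whose truth records `mcc = fraction` and the
#'   mixture expected CN.
#' @export
spike_mcc <- function(fetal, maternal, fraction, seed = 1) {
  assert_fraction(fraction, "fraction")
  fg <- fetal$counts; mg <- maternal$counts
  if (nrow(fg) != nrow(mg) ||
      !all(fg$chrom == mg$chrom) || !all(fg$start == mg$start)) {
    abort("fetal and maternal samples are on different bin grids")
  }
  mixed <- fetal
  mixed$counts$count <- with_local_seed(seed, {
    rbinom(nrow(fg), fg$count, 1 - fraction) +
      rbinom(nrow(mg), mg$count, fraction)
  })
  attr(mixed$counts, "n_assigned") <- sum(mixed$counts$count)
  mixed$truth$mcc <- fraction
  mixed$truth$expected_cn$expected_cn <-
    (1 - fraction) * fetal$truth$expected_cn$expected_cn +
    fraction * maternal$truth$expected_cn$expected_cn
  mixed
}

#' Simulate STR peak heights for an MCC mixture
#'
#' Builds semi-quantitative STR peak heights from the allele-dosage model:
#' the height of allele `a` at a locus is proportional to
#' `(1 - f) * dose_fetal(a) / 2 + f * dose_maternal(a) / 2`, scaled to
#' `total_height` per locus. This is the analytic model the MCC estimator
#' inverts.
#'
#' @param fetal_gt,maternal_gt Long genotype tibbles (`locus`, `allele`;
#'   two rows per locus, homozygotes repeat the allele).
#' @param fraction Maternal fraction in \[0, 1\].
#' @param total_height Total peak height per locus.
#' @param cv_noise Multiplicative noise CV on each peak (0 = exact).
#' @param seed Seed used when `cv_noise > 0`.
#' @return Tibble (locus, allele, height).
#' @export
simulate_str_peaks <- function(fetal_gt, maternal_gt, fraction,
                               total_height = 2000, cv_noise = 0, seed = 1) {
  assert_fraction(fraction, "fraction")
  dose <- function(gt) dplyr::count(gt, .data$locus, .data$allele,
                                    name = "dose")
  fd <- dose(fetal_gt); md <- dose(maternal_gt)
  all_alleles <- dplyr::full_join(fd, md, by = c("locus", "allele"),
                                  suffix = c("_f", "_m"))
  all_alleles$dose_f[is.na(all_alleles$dose_f)] <- 0
  all_alleles$dose_m[is.na(all_alleles$dose_m)] <- 0
  peaks <- dplyr::mutate(
    all_alleles,
    height = total_height * ((1 - fraction) * .data$dose_f / 2 +
                               fraction * .data$dose_m / 2)
  )
  if (cv_noise > 0) {
    peaks$height <- with_local_seed(seed, {
      pmax(0, peaks$height * rnorm(nrow(peaks), 1, cv_noise))
    })
  }
  peaks[c("locus", "allele", "height")]
}

#' Write reads as FASTQ
#'
#' Standard 4-line records with Phred+33 qualities.
#' @param reads Tibble (read_id, sequence, quality) — e.g.
#'   `simulate_reads()$reads`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path FASTQ path (uncompressed, Phred+33).
#' @return Tibble (read_id, sequence, quality).
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) abort("truncated FASTQ (not 4-line records)")
  i <- seq(1, length(lines), by = 4)
  tibble(read_id = sub("^@", "", sub("\\s.*", "", lines[i])),
         sequence = lines[i + 1],
         quality = lines[i + 3])
}

#' Write / read the simulator's alignment-truth table
#'
#' TSV dialect: read_id, chrom, pos (1-based 5' coordinate), strand,
#' status (`unique`/`multi`/`unmapped`), duplicate (0/1). Multi-mapped and
#' unmapped reads carry no position.
#' @param alignments Alignment tibble.
#' @param path TSV path.
#' @export
write_alignments <- function(alignments, path) {
  out <- alignments
  out$duplicate <- as.integer(out$duplicate)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccdcci", comment = "#")
  x$duplicate <- as.logical(x$duplicate)
  x$pos <- as.numeric(x$pos)
  x
}

#' Write truth CNV intervals
#'
#' BED-like TSV with 1-based inclusive coordinates; a header line states
#' the convention explicitly.
#' @param cnvs Truth CNV tibble (as in `sim_sample$truth$cnvs`).
#' @param path Output path.
#' @export
write_truth_cnvs <- function(cnvs, path) {
  writeLines(c("# rcnvseq truth CNVs; coordinates 1-based inclusive"), path)
  readr::write_tsv(cnvs, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_truth_cnvs
#' @export
read_truth_cnvs <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols())
}
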