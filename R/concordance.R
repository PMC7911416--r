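#' Score called CNVs against truth intervals
#'
#' For every truth (e.g. microarray-defined) interval, computes the
#' percentage of its bases covered by same-side calls — loss-side states
#' (deletion, mosaic monosomy) only credit loss truths and gain-side
#' states gain truths — as
#' `100 * |union of overlapping same-side calls ∩ truth| / |truth|`.
#' The best single overlapping call is also reported with its reciprocal
#' overlap (`100 * |intersection| / |union|`), an exact state-agreement
#' flag and, when expected copies and call CN are available, an
#' integer-CN agreement flag. A truth interval with no overlapping call
#' scores 0.
#'
#' Both tables use 1-based inclusive coordinates on the same assembly.
#'
#' @param calls Tibble of calls (chrom, start, end, state, optionally cn,
#'   name), e.g. `tidy()` of a `sample_result`.
#' @param truth Tibble of truth intervals (chrom, start, end, state;
#'   optionally copies, label).
#' @param chroms Optional character vector of known chromosome names;
#'   truth intervals on other chromosomes trigger a warning (and score 0).
#' @return Tibble, one row per truth interval: label, chrom, start, end,
#'   state, concordance, reciprocal_overlap, matched, state_agreement,
#'   cn_agreement.
#' @export
interval_concordance <- function(calls, truth, chroms = NULL) {
  side_of <- function(state) {
    dplyr::case_when(
      state %in% c("deletion", "mosaic monosomy", "del") ~ "loss",
      state %in% c("duplication", "mosaic trisomy", "dup") ~ "gain",
      TRUE ~ NA_character_
    )
  }
  truth <- as_tibble(truth)
  if (!"label" %in% names(truth)) {
    truth$label <- sprintf("%s:%d-%d", truth$chrom, as.integer(truth$start),
                           as.integer(truth$end))
  }
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    if (!is.null(chroms) && !tr$chrom %in% chroms) {
      warn(sprintf("truth interval %s on unknown chromosome", tr$label))
    }
    cand <- calls[calls$chrom == tr$chrom &
                    side_of(calls$state) == side_of(tr$state), ]
    cand <- cand[!is.na(cand$state), ]
    tr_ir <- IRanges::IRanges(start = tr$start, end = tr$end)
    base <- tibble(label = tr$label, chrom = tr$chrom,
                   start = tr$start, end = tr$end, state = tr$state)
    if (nrow(cand) == 0) {
      return(mutate(base, concordance = 0, reciprocal_overlap = 0,
                    matched = NA_character_, state_agreement = FALSE,
                    cn_agreement = NA))
    }
    call_ir <- IRanges::reduce(IRanges::IRanges(start = cand$start,
                                                end = cand$end))
    covered <- sum(IRanges::width(IRanges::intersect(call_ir, tr_ir)))
    concordance <- 100 * covered / IRanges::width(tr_ir)

    ov <- purrr::map2_dbl(cand$start, cand$end, function(s, e) {
      max(0, min(e, tr$end) - max(s, tr$start) + 1)
    })
    best <- which.max(ov)
    if (ov[best] == 0) {
      return(mutate(base, concordance = 0, reciprocal_overlap = 0,
                    matched = NA_character_, state_agreement = FALSE,
                    cn_agreement = NA))
    }
    union_w <- (cand$end[best] - cand$start[best] + 1) +
      (tr$end - tr$start + 1) - ov[best]
    matched <- if ("name" %in% names(cand)) cand$name[best] else
      sprintf("%s:%d-%d", cand$chrom[best], as.integer(cand$start[best]),
              as.integer(cand$end[best]))
    cn_agreement <- if ("copies" %in% names(tr) && "cn" %in% names(cand) &&
                        !is.na(tr$copies)) {
      as.integer(round(cand$cn[best])) == as.integer(tr$copies)
    } else NA
    mutate(base,
           concordance = concordance,
           reciprocal_overlap = 100 * ov[best] / union_w,
           matched = matched,
           state_agreement = identical(cand$state[best], tr$state),
           cn_agreement = cn_agreement)
  })
}

#' Maternal cell contamination gate
#'
#' An amniocyte sample passes when its estimated maternal cell
#' contamination is strictly below the threshold (default 5%): MCC levels
#' under 5% are considered acceptable for clinical testing, and exactly
#' 5% fails.
#'
#' @param percent Estimated MCC percentage.
#' @param threshold Gate threshold in percent.
#' @return Logical: `TRUE` (pass) iff `percent < threshold`.
#' @export
mcc_gate <- function(percent, threshold = 5) {
  percent < threshold
}

new_mcc_result <- function(percent, pass, loci, n_informative) {
  structure(list(percent = percent, pass = pass, loci = loci,
                 n_informative = n_informative),
            class = "mcc_result")
}

#' @export
print.mcc_result <- function(x, ...) {
  cat(sprintf("<mcc_result> %.2f%% (%s), %s informative locus/loci\n",
              x$percent, if (isTRUE(x$pass)) "pass" else "fail",
              format(x$n_informative)))
  invisible(x)
}

#' Estimate maternal cell contamination from STR peak heights
#'
#' Semi-quantitative STR assay readout: at each informative locus — one
#' where the mother carries an allele absent from the fetal genotype —
#' the maternal-specific peak carries half the maternal contribution's
#' dosage (the specific allele is heterozygous in the mother, since the
#' fetus inherits her other allele), so the contamination fraction is
#' `2 * h_specific / sum(heights)` and the reported MCC percentage is 100
#' times the median over informative loci. With no informative locus the
#' estimate is undefined; by default the gate then passes with a warning
#' (configurable).
#'
#' @param peaks Sample peak tibble (locus, allele, height).
#' @param maternal_gt Maternal genotypes, long form (locus, allele).
#' @param fetal_gt Fetal genotypes, long form; when `NULL`, the two
#'   tallest sample peaks per locus are taken as the fetal alleles.
#' @param threshold Gate threshold in percent (default 5).
#' @param uninformative_pass Verdict when no locus is informative.
#' @return An `mcc_result`: percent, pass, per-locus tibble, number of
#'   informative loci.
#' @export
estimate_mcc <- function(peaks, maternal_gt, fetal_gt = NULL,
                         threshold = 5, uninformative_pass = TRUE) {
  peaks <- as_tibble(peaks)
  if (is.null(fetal_gt)) {
    fetal_gt <- peaks |>
      group_by(.data$locus) |>
      dplyr::slice_max(.data$height, n = 2, with_ties = FALSE) |>
      ungroup() |>
      select("locus", "allele")
  }
  loci <- purrr::map_dfr(unique(maternal_gt$locus), function(lc) {
    m_alleles <- unique(maternal_gt$allele[maternal_gt$locus == lc])
    f_alleles <- unique(fetal_gt$allele[fetal_gt$locus == lc])
    specific <- setdiff(m_alleles, f_alleles)
    pk <- peaks[peaks$locus == lc, ]
    total <- sum(pk$height)
    h_spec <- sum(pk$height[pk$allele %in% specific])
    tibble(locus = lc,
           informative = length(specific) > 0 && total > 0,
           fraction = if (length(specific) > 0 && total > 0)
             min(1, 2 * h_spec / total) else NA_real_)
  })
  inf <- loci[loci$informative, ]
  if (nrow(inf) == 0) {
    warn("no informative STR locus; MCC uninformative")
    return(new_mcc_result(percent = NA_real_, pass = uninformative_pass,
                          loci = loci, n_informative = 0L))
  }
  pct <- 100 * median(inf$fraction)
  new_mcc_result(percent = pct, pass = mcc_gate(pct, threshold),
                 loci = loci, n_informative = nrow(inf))
}

#' Tidy an MCC result
#' @param x An `mcc_result`.
#' @param ... Unused.
#' @return Per-locus tibble (locus, informative, fraction).
#' @method tidy mcc_result
#' @export
tidy.mcc_result <- function(x, ...) {
  as_tibble(x$loci)
}

#' Write a concordance report
#' @param records Tibble from [interval_concordance()].
#' @param path TSV path.
#' @export
write_concordance <- function(records, path) {
  writeLines(sprintf(
    "# rcnvseq %s concordance; percent of truth interval covered by same-side calls",
    pkg_version()), path)
  readr::write_tsv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
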