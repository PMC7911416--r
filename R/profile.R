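#' GC-stratified count correction
#'
#' Library preparation and mapping make bin counts depend mildly on local
#' GC content. Bins are grouped into GC strata of width `stratum_width`
#' (default 0.01); each bin's count is divided by its stratum factor,
#' `median(counts in stratum) / median(all counts)`, estimated from
#' unmasked bins. Strata holding fewer than `min_stratum_bins` bins borrow
#' the factor of the nearest populated stratum. With a single populated
#' stratum (or `enabled = FALSE`) the correction is the identity.
#'
#' @param counts A `bin_counts`.
#' @param enabled Set `FALSE` to skip (factors all 1).
#' @param stratum_width GC stratum width.
#' @param min_stratum_bins Minimum unmasked bins for a stratum to estimate
#'   its own factor.
#' @return The input with a `corrected` column added and attribute
#'   `gc_factors` (tibble stratum, gc_mid, n, factor).
#' @export
gc_correct <- function(counts, enabled = TRUE, stratum_width = 0.01,
                       min_stratum_bins = 10) {
  out <- counts
  if (!enabled || all(is.na(counts$gc))) {
    out$corrected <- as.numeric(counts$count)
    attr(out, "gc_factors") <- tibble(stratum = integer(), gc_mid = numeric(),
                                      n = integer(), factor = numeric())
    return(out)
  }
  unm <- !counts$masked & !is.na(counts$gc)
  if (sum(unm) < 50) {
    warn("fewer than 50 unmasked bins; GC correction skipped")
    out$corrected <- as.numeric(counts$count)
    attr(out, "gc_factors") <- tibble(stratum = integer(), gc_mid = numeric(),
                                      n = integer(), factor = numeric())
    return(out)
  }
  global_med <- median(counts$count[unm])
  stratum <- as.integer(floor(counts$gc / stratum_width))
  tab <- tibble(stratum = stratum[unm], count = counts$count[unm]) |>
    group_by(.data$stratum) |>
    summarise(n = dplyr::n(), med = median(.data$count), .groups = "drop") |>
    mutate(factor = .data$med / global_med)

  populated <- tab[tab$n >= min_stratum_bins & tab$factor > 0, ]
  if (nrow(populated) == 0) {
    tab$factor <- 1
  } else {
    borrow <- function(s) {
      populated$factor[which.min(abs(populated$stratum - s))]
    }
    small <- tab$n < min_stratum_bins | tab$factor <= 0
    tab$factor[small] <- vapply(tab$stratum[small], borrow, numeric(1))
  }
  fac <- tab$factor[match(stratum, tab$stratum)]
  fac[is.na(fac)] <- 1
  out$corrected <- counts$count / fac
  attr(out, "gc_factors") <- tibble(
    stratum = tab$stratum,
    gc_mid = (tab$stratum + 0.5) * stratum_width,
    n = tab$n, factor = tab$factor
  )
  out
}

#' Normalise bin counts to copy number
#'
#' Scales (GC-corrected) counts to copy number against a within-sample
#' baseline: `CN_i = 2 * c_i / m`, where `m` is the median corrected count
#' over unmasked autosomal bins, so that the autosomal disomic state sits
#' at CN 2. With `reestimate = TRUE` (default) the baseline is re-computed
#' once from bins whose provisional CN falls inside the disomy band
#' (1.8, 2.2), which protects `m` against large aberrations. Sex
#' chromosomes never enter the baseline: an XX sample has expected X CN 2,
#' an XY sample X CN 1 and Y CN 1 (Y CN below 0.2 is read as absence of
#' Y). Masked bins carry no CN.
#'
#' @param counts A `bin_counts`, ideally from [gc_correct()] (plain counts
#'   are used when no `corrected` column is present).
#' @param reestimate One-pass baseline re-estimation from disomic bins.
#' @param disomy_band Provisional disomy interval for re-estimation.
#' @return A `cn_profile`: grid tibble plus `cn` (NA where masked), with
#'   attributes `baseline`, `gc_factors`, `window`, and the grid's
#'   annotation attributes.
#' @export
normalize_to_cn <- function(counts, reestimate = TRUE,
                            disomy_band = c(1.8, 2.2)) {
  c_i <- if ("corrected" %in% names(counts)) counts$corrected else
    as.numeric(counts$count)
  autosomal <- !is_sex_chrom(counts$chrom) & !counts$masked
  if (sum(autosomal) < 100) {
    abort("need at least 100 unmasked autosomal bins to set the baseline")
  }
  m <- median(c_i[autosomal])
  if (m == 0) abort("insufficient coverage: autosomal median count is zero")
  cn <- 2 * c_i / m
  if (reestimate) {
    # the integer-count median can be off by a whole count (~3% at 30
    # reads/bin); refine with an iterated trimmed mean over bins within
    # 2.5 robust SDs of the baseline — wide enough that trimming bias
    # is negligible, narrow enough to exclude single-copy changes. The
    # SD comes from successive differences, so the trimmed set (and the
    # resulting CN) is exactly invariant to count rescaling
    d <- diff(c_i[autosomal])
    sigma_c <- median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
    if (sigma_c == 0) sigma_c <- sqrt(max(m, 1))
    for (it in 1:10) {
      keep <- autosomal & abs(c_i - m) < 2.5 * sigma_c
      if (sum(keep) < 50) break
      m_new <- mean(c_i[keep])
      conv <- abs(m_new - m) / m < 1e-4
      m <- m_new
      if (conv) break
    }
    cn <- 2 * c_i / m
  }
  out <- counts
  out$cn <- ifelse(out$masked, NA_real_, cn)
  structure(out,
            baseline = m,
            gc_factors = attr(counts, "gc_factors"),
            window = 1L,
            class = unique(c("cn_profile", class(out))))
}

#' Smooth a copy-number profile
#'
#' Adds a `cn_smooth` column: a running median over `window` consecutive
#' unmasked bins within each chromosome (masked bins are skipped, not
#' zero-filled). Smoothing stabilises segmentation; segment quantification
#' downstream always uses the raw CN. `window = 1` is the identity.
#'
#' @param profile A `cn_profile`.
#' @param window Odd window size in bins (default 5).
#' @return The profile with `cn_smooth` added and attribute `window` set.
#' @export
smooth_profile <- function(profile, window = 5) {
  if (window %% 2 == 0) abort("smoothing window must be odd")
  out <- profile
  out$cn_smooth <- out$cn
  if (window > 1) {
    for (ch in unique(out$chrom)) {
      sel <- which(out$chrom == ch & !out$masked & !is.na(out$cn))
      if (length(sel) >= window) {
        out$cn_smooth[sel] <- as.numeric(
          runmed(out$cn[sel], k = window, endrule = "median")
        )
      }
    }
  }
  attr(out, "window") <- as.integer(window)
  out
}

#' Chromosome- or arm-level copy number
#'
#' Mean CN over the unmasked bins of each chromosome; with
#' `by_arm = TRUE`, separately for the p arm (bins ending at or before the
#' centromere start) and q arm (bins starting at or after the centromere
#' end), using the centromere intervals attached to the grid.
#'
#' @param profile A `cn_profile`.
#' @param chroms Optional subset of chromosome names.
#' @param by_arm Split at the centromere (requires grid centromere
#'   annotation).
#' @return Tibble (chrom, \[arm,\] n_bins, cn).
#' @export
chromosome_cn <- function(profile, chroms = NULL, by_arm = FALSE) {
  chroms <- chroms %||% unique(profile$chrom)
  if (!by_arm) {
    return(purrr::map_dfr(chroms, function(ch) {
      x <- profile$cn[profile$chrom == ch & !profile$masked]
      x <- x[!is.na(x)]
      tibble(chrom = ch, n_bins = length(x),
             cn = if (length(x)) mean(x) else NA_real_)
    }))
  }
  cen <- attr(profile, "centromeres")
  if (is.null(cen)) abort("profile grid carries no centromere annotation")
  purrr::map_dfr(chroms, function(ch) {
    ci <- cen[cen$chrom == ch, ]
    if (nrow(ci) == 0) abort(sprintf("no centromere for %s", ch))
    sel <- profile$chrom == ch & !profile$masked & !is.na(profile$cn)
    p <- profile$cn[sel & profile$end <= ci$cen_start]
    q <- profile$cn[sel & profile$start >= ci$cen_end]
    tibble(chrom = ch, arm = c("p", "q"),
           n_bins = c(length(p), length(q)),
           cn = c(if (length(p)) mean(p) else NA_real_,
                  if (length(q)) mean(q) else NA_real_))
  })
}

#' Serialise a copy-number profile
#'
#' TSV (chrom, start, end, cn, masked; 1-based inclusive) plus a JSON
#' sidecar (`<path>.json`) recording the normalization constants: the
#' autosomal baseline, the GC stratum factors and the smoothing window.
#'
#' @param profile A `cn_profile`.
#' @param path Output TSV path.
#' @export
write_profile <- function(profile, path) {
  out <- tibble(chrom = profile$chrom, start = profile$start + 1,
                end = profile$end, cn = profile$cn, masked = profile$masked)
  writeLines(sprintf("# rcnvseq %s CN profile; coordinates 1-based inclusive",
                     pkg_version()), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  gf <- attr(profile, "gc_factors")
  jsonlite::write_json(
    list(baseline = attr(profile, "baseline"),
         smoothing_window = attr(profile, "window"),
         gc_factors = if (!is.null(gf)) gf else list()),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
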