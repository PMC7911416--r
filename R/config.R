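#' Pipeline configuration
#'
#' Every tunable the pipeline exposes, with the defaults the package is
#' validated at. The configuration round-trips losslessly through its
#' flat `key: value` text representation ([write_config()] /
#' [read_config()]) and its hash is embedded in every output header so a
#' result can always be traced to the settings that produced it.
#'
#' @param bin_size Bin width in bp (default 20,000).
#' @param del_max,disomy_low,disomy_high,dup_min Classification
#'   thresholds, see [cn_thresholds()].
#' @param smooth_window Running-median window in bins (odd, default 5).
#' @param min_seg_bins Minimum bins per called segment (default 5 = 0.1 Mb
#'   at 20-kb bins).
#' @param min_seg_z Minimum segment-mean deviation from disomy in
#'   standard errors (see [segment_profile()]).
#' @param gap_bins Maximum in-run gap during segmentation.
#' @param merge_gap Maximum fully-masked gap bridged by the segment
#'   merge pass (see [segment_profile()]).
#' @param gc_correct Apply GC-stratum correction.
#' @param gc_mask_low,gc_mask_high GC bounds outside which bins are
#'   masked.
#' @param whole_chrom_frac Out-of-band bin fraction for a
#'   whole-chromosome call.
#' @param mcc_threshold MCC gate threshold in percent (strict `<`).
#' @param min_median_depth QC floor on median reads/bin.
#' @param report_sex Report actual sex composition instead of `XN`
#'   masking.
#' @param seed Seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bin_size = 20000,
                            del_max = 1.2, disomy_low = 1.8,
                            disomy_high = 2.2, dup_min = 2.8,
                            smooth_window = 5, min_seg_bins = 5,
                            gap_bins = 2, merge_gap = 10, min_seg_z = 5,
                            gc_correct = TRUE,
                            gc_mask_low = 0.28, gc_mask_high = 0.60,
                            whole_chrom_frac = 0.9,
                            mcc_threshold = 5,
                            min_median_depth = 10,
                            report_sex = FALSE,
                            seed = 1) {
  cn_thresholds(del_max, disomy_low, disomy_high, dup_min)  # validates
  structure(
    list(bin_size = bin_size, del_max = del_max, disomy_low = disomy_low,
         disomy_high = disomy_high, dup_min = dup_min,
         smooth_window = smooth_window, min_seg_bins = min_seg_bins,
         gap_bins = gap_bins, merge_gap = merge_gap,
         min_seg_z = min_seg_z,
         gc_correct = gc_correct,
         gc_mask_low = gc_mask_low, gc_mask_high = gc_mask_high,
         whole_chrom_frac = whole_chrom_frac,
         mcc_threshold = mcc_threshold,
         min_median_depth = min_median_depth,
         report_sex = report_sex, seed = seed),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path Text file path.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.logical(v)) as.character(v) else format(v, digits = 17)
  }, character(1))
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- stringr::str_split_fixed(lines, ":\\s*", 2)
  vals <- purrr::map(kv[, 2], function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  do.call(pipeline_config, setNames(vals, kv[, 1]))
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  fnv1a(paste0(names(config), "=",
               vapply(config, function(v) format(v, digits = 17),
                      character(1)),
               collapse = ";"))
}
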