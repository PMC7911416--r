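#' Adapter trimming specification
#'
#' Raw reads consist of a genomic insert followed by an artificial adapter;
#' trimming recovers the insert. Defaults match the targeted design: 45-bp
#' raw reads carrying a 36-bp genomic sequence and a 9-bp adapter.
#'
#' @param read_length Raw read length (bp).
#' @param insert_length Genomic bases per read.
#' @param adapter Adapter sequence; `nchar(adapter)` must equal
#'   `read_length - insert_length`.
#' @param seed_length Number of leading adapter bases used for the exact
#'   match (default 7). Error-tolerant trimming is unnecessary at this
#'   depth regime.
#' @return A `trim_spec` list.
#' @export
trim_spec <- function(read_length = 45, insert_length = 36,
                      adapter = "AGATCGGAA", seed_length = 7) {
  if (insert_length + nchar(adapter) != read_length) {
    abort("insert_length + nchar(adapter) must equal read_length")
  }
  if (seed_length > nchar(adapter)) abort("seed_length exceeds adapter length")
  structure(list(read_length = read_length, insert_length = insert_length,
                 adapter = adapter, seed_length = seed_length),
            class = "trim_spec")
}

#' Trim adapter sequence from reads
#'
#' Returns, per read, the prefix before the first exact occurrence of the
#' adapter seed (the first `seed_length` adapter bases). Reads without an
#' adapter match are returned unchanged and flagged; a read that begins
#' with the adapter trims to the empty string. Trimming is idempotent.
#'
#' @param sequences Character vector of read sequences.
#' @param spec A [trim_spec()].
#' @return Tibble (sequence, trimmed, adapter_found).
#' @export
trim_adapter <- function(sequences, spec = trim_spec()) {
  if (length(sequences) == 0 || any(!nzchar(sequences))) {
    abort("reads must be non-empty sequences")
  }
  seed <- substr(spec$adapter, 1, spec$seed_length)
  pos <- regexpr(seed, sequences, fixed = TRUE)
  found <- pos > 0
  trimmed <- ifelse(found, substr(sequences, 1, pos - 1), sequences)
  tibble(sequence = sequences, trimmed = trimmed, adapter_found = found)
}

#' Fraction of bases at or above Q30
#'
#' Decodes Phred+33 quality strings and reports the fraction of all bases
#' with Phred quality >= 30 (base-call error probability <= 1/1000).
#' Records containing characters outside the legal Phred+33 range are
#' rejected, counted, and reported via a warning; remaining records are
#' still scored.
#'
#' @param qualities Character vector of Phred+33 quality strings.
#' @return Q30 fraction in \[0, 1\] (attribute `n_rejected` carries the
#'   number of malformed records).
#' @export
q30_fraction <- function(qualities) {
  if (length(qualities) == 0) abort("no bases: empty quality input")
  scores <- lapply(qualities, function(q) utf8ToInt(q) - 33L)
  ok <- vapply(scores, function(s) length(s) > 0 && all(s >= 0 & s <= 93),
               logical(1))
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("%d quality record(s) malformed and skipped", n_rejected))
  }
  base_q <- unlist(scores[ok], use.names = FALSE)
  if (!length(base_q)) abort("no bases: all quality records malformed")
  structure(mean(base_q >= 30), n_rejected = n_rejected)
}

#' Unique-mapping and redundancy ratios
#'
#' `unique_mapping_ratio` is uniquely mapped reads over all raw reads.
#' `redundancy_ratio` is the fraction of uniquely mapped reads that are
#' duplicates — occurrences beyond the first at an identical (chrom, 5'
#' position, strand); when the table carries a `duplicate` flag column
#' (e.g. from a duplicate-marking aligner or the simulator) that flag is
#' used directly. The denominator choice (unique, not all mapped, reads)
#' is a documented convention of this package.
#'
#' @param alignments Alignment tibble with `status` and optionally
#'   `duplicate`, `chrom`, `pos`, `strand` columns.
#' @return One-row tibble (unique_mapping_ratio, redundancy_ratio,
#'   n_raw_reads, n_unique_reads).
#' @export
mapping_stats <- function(alignments) {
  n_raw <- nrow(alignments)
  if (n_raw == 0) abort("empty alignment table")
  uniq <- alignments[alignments$status == "unique", ]
  n_unique <- nrow(uniq)
  redundancy <- if (n_unique == 0) {
    0
  } else if ("duplicate" %in% names(alignments)) {
    mean(as.logical(uniq$duplicate))
  } else {
    key <- paste(uniq$chrom, uniq$pos, uniq$strand)
    sum(duplicated(key)) / n_unique
  }
  tibble(unique_mapping_ratio = n_unique / n_raw,
         redundancy_ratio = redundancy,
         n_raw_reads = n_raw, n_unique_reads = n_unique)
}

#' Coefficient of variation of bin coverage
#'
#' Population standard deviation over mean of the unmasked bin counts, for
#' the whole genome or a single chromosome. The population (not sample)
#' SD is used; with thousands of bins the difference is negligible but the
#' convention is fixed so results are exactly reproducible.
#'
#' @param counts A `bin_counts`.
#' @param scope `"genome"` or a chromosome name.
#' @return CV (dimensionless, >= 0).
#' @export
coverage_cv <- function(counts, scope = "genome") {
  x <- counts[!counts$masked, ]
  if (!identical(scope, "genome")) {
    if (!scope %in% x$chrom) abort(sprintf("unknown scope %s", dQuote(scope)))
    x <- x[x$chrom == scope, ]
  }
  if (nrow(x) < 2) abort("need at least 2 unmasked bins in scope")
  m <- mean(x$count)
  if (m == 0) abort("no coverage: mean bin count is zero")
  pop_sd(x$count) / m
}

#' Per-chromosome CV table
#' @param counts A `bin_counts`.
#' @return Tibble (chrom, cv).
#' @export
cv_per_chrom <- function(counts) {
  chroms <- unique(counts$chrom)
  tibble(chrom = chroms,
         cv = purrr::map_dbl(chroms, function(ch) {
           tryCatch(coverage_cv(counts, ch), error = function(e) NA_real_)
         }))
}

#' GC ratio of sequencing reads
#'
#' `(G + C) / (A + C + G + T)` over the supplied (uniquely mapped,
#' trimmed) read sequences; ambiguous bases are excluded from both
#' numerator and denominator.
#'
#' @param sequences Character vector of read sequences.
#' @return GC fraction in \[0, 1\].
#' @export
gc_ratio <- function(sequences) {
  gc <- sum(stringr::str_count(sequences, "[GCgc]"))
  acgt <- sum(stringr::str_count(sequences, "[ACGTacgt]"))
  if (acgt == 0) abort("no unambiguous bases")
  gc / acgt
}

#' Median read depth per bin
#' @param counts A `bin_counts`.
#' @return Median count over unmasked bins (reads/bin).
#' @export
median_depth <- function(counts) {
  x <- counts$count[!counts$masked]
  if (!length(x)) abort("no unmasked bins")
  median(x)
}

#' Assemble the sequencing QC report
#'
#' The seven library-quality indicators used to judge a low-pass CNV
#' sequencing run: unique mapping ratio, read redundancy, genome-wide CV
#' of bin coverage (plus per-chromosome CVs), median read depth, GC ratio
#' of the unique reads, and Q30. Indicators whose inputs are not supplied
#' (e.g. read-level metrics for a count-tier sample) are reported as `NA`.
#'
#' @param counts Optional `bin_counts` (CV, median depth).
#' @param alignments Optional alignment tibble (mapping ratios).
#' @param sequences Optional trimmed unique-read sequences (GC ratio).
#' @param qualities Optional Phred+33 quality strings (Q30).
#' @return A one-row `qc_report` tibble with attribute `cv_per_chrom`.
#' @export
qc_report <- function(counts = NULL, alignments = NULL,
                      sequences = NULL, qualities = NULL) {
  ms <- if (!is.null(alignments)) mapping_stats(alignments) else
    tibble(unique_mapping_ratio = NA_real_, redundancy_ratio = NA_real_,
           n_raw_reads = NA_integer_, n_unique_reads = NA_integer_)
  rep <- tibble(
    unique_mapping_ratio = ms$unique_mapping_ratio,
    redundancy_ratio = ms$redundancy_ratio,
    cv_genome = if (!is.null(counts)) coverage_cv(counts) else NA_real_,
    median_read_depth = if (!is.null(counts)) median_depth(counts) else NA_real_,
    gc_ratio = if (!is.null(sequences)) gc_ratio(sequences) else NA_real_,
    q30 = if (!is.null(qualities)) as.numeric(q30_fraction(qualities)) else NA_real_,
    n_raw_reads = ms$n_raw_reads,
    n_unique_reads = ms$n_unique_reads
  )
  structure(rep,
            cv_per_chrom = if (!is.null(counts)) cv_per_chrom(counts) else NULL,
            redundancy_denominator = "uniquely mapped reads",
            class = unique(c("qc_report", class(rep))))
}
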