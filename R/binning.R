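#' Build the fixed bin grid
#'
#' Tiles each chromosome with fixed-width bins (default 20 kb) into which
#' uniquely mapped reads are later counted. Per chromosome, `floor(L /
#' bin_size)` full bins are kept and the trailing partial bin is dropped:
#' variable-width bins would bias both the coefficient of variation and the
#' copy-number estimate. Bins overlapping any excluded interval (by even a
#' single base) are masked with reason `"excluded-region"`.
#'
#' Bin coordinates are 0-based half-open internally; serialised output is
#' 1-based inclusive.
#'
#' @param x A `genome_model`, a tibble with columns `chrom` and `length`,
#'   or the path to a two-column `chrom.sizes` file.
#' @param bin_size Bin width in bp (minimum 1000). When `x` is a
#'   `genome_model` this must equal its GC-landscape bin size.
#' @param exclude Optional tibble of intervals to mask (`chrom`, `start`,
#'   `end`, 0-based half-open), e.g. read with [read_bed()]. For a
#'   `genome_model` its own exclusion set is used in addition.
#' @param gc Optional tibble (`chrom`, `start`, `end`, `gc`) assigning a GC
#'   fraction per bin (matched by bin start).
#' @return A `bin_grid`: tibble (chrom, start, end, gc, masked,
#'   mask_reason) with attributes `bin_size` and, when built from a
#'   `genome_model`, `centromeres` and `cytobands`.
#' @export
build_bin_grid <- function(x, bin_size = 20000, exclude = NULL, gc = NULL) {
  if (bin_size < 1000) abort("bin_size must be >= 1000 bp")
  centromeres <- NULL
  cytobands <- NULL
  if (inherits(x, "genome_model")) {
    if (bin_size != x$bin_size && !missing(bin_size)) {
      abort("bin_size must match the genome model's GC-landscape bin size")
    }
    bin_size <- x$bin_size
    gc <- gc %||% x$gc
    exclude <- bind_rows(exclude, x$excluded[c("chrom", "start", "end")])
    centromeres <- x$chroms[c("chrom", "cen_start", "cen_end")]
    cytobands <- x$cytobands
    sizes <- x$chroms[c("chrom", "length")]
  } else if (is.character(x)) {
    sizes <- read_chrom_sizes(x)
  } else {
    sizes <- as_tibble(x)
    stopifnot(all(c("chrom", "length") %in% names(sizes)))
  }

  short <- sizes$length < bin_size
  if (any(short)) {
    warn(sprintf("chromosome(s) shorter than one bin, zero bins: %s",
                 paste(sizes$chrom[short], collapse = ", ")))
  }

  grid <- purrr::map2_dfr(sizes$chrom, sizes$length, function(nm, L) {
    n <- floor(L / bin_size)
    if (n == 0) return(tibble())
    tibble(chrom = nm,
           start = (seq_len(n) - 1) * bin_size,
           end = seq_len(n) * bin_size)
  })
  grid$gc <- NA_real_
  if (!is.null(gc)) {
    key <- paste(gc$chrom, gc$start)
    idx <- match(paste(grid$chrom, grid$start), key)
    grid$gc <- gc$gc[idx]
  }
  grid$masked <- FALSE
  grid$mask_reason <- NA_character_

  if (!is.null(exclude) && nrow(exclude)) {
    for (ch in unique(exclude$chrom)) {
      ex <- exclude[exclude$chrom == ch, ]
      sel <- grid$chrom == ch
      if (!any(sel)) next
      hit <- purrr::map2_lgl(grid$start[sel], grid$end[sel], function(s, e) {
        any(overlap_width0(s, e, ex$start, ex$end) > 0)
      })
      grid$masked[sel][hit] <- TRUE
      grid$mask_reason[sel][hit] <- "excluded-region"
    }
  }

  structure(grid,
            bin_size = bin_size,
            centromeres = centromeres,
            cytobands = cytobands,
            class = c("bin_grid", class(grid)))
}

#' Mask bins with extreme GC content
#'
#' Bins whose GC fraction falls outside `[low, high]` are masked with
#' reason `"gc-extreme"` (already-masked bins keep their original reason).
#' Extreme-GC bins behave unreliably under library preparation and mapping
#' and correspond to the repetitive/low-confidence regions flagged in
#' chromosome plots.
#'
#' @param grid A `bin_grid` or bin-counts tibble carrying `gc`/`masked`.
#' @param low,high GC bounds (defaults 0.28 and 0.60).
#' @return The grid with updated `masked`/`mask_reason`.
#' @export
mask_gc_extremes <- function(grid, low = 0.28, high = 0.60) {
  hit <- !is.na(grid$gc) & (grid$gc < low | grid$gc > high) & !grid$masked
  grid$masked[hit] <- TRUE
  grid$mask_reason[hit] <- "gc-extreme"
  grid
}

#' Count uniquely mapped reads per bin
#'
#' Only reads with `status == "unique"` and no duplicate flag are counted.
#' A read is assigned to the bin containing its 5'-most mapped coordinate
#' (1-based input positions, so position 1 falls in the first bin and
#' position `bin_size` still in the first, `bin_size + 1` in the second).
#' Reads on unknown chromosomes are tallied as off-grid with a warning;
#' reads landing in a dropped trailing partial bin are tallied separately.
#' The tallies satisfy
#' `n_assigned + off_grid + partial_bin + filtered == nrow(alignments)`.
#'
#' @param alignments Tibble with columns `chrom`, `pos` (1-based), `status`
#'   (`unique`/`multi`/`unmapped`) and optional `duplicate` (0/1 or
#'   logical).
#' @param grid A [build_bin_grid()] grid.
#' @return A `bin_counts`: the grid plus a `count` column, with attributes
#'   `n_assigned` and `tallies`.
#' @export
count_reads <- function(alignments, grid) {
  bin_size <- attr(grid, "bin_size")
  n_input <- nrow(alignments)
  dup <- if ("duplicate" %in% names(alignments)) {
    as.logical(alignments$duplicate)
  } else rep(FALSE, n_input)
  usable <- alignments$status == "unique" & !dup
  usable[is.na(usable)] <- FALSE
  n_filtered <- sum(!usable)
  al <- alignments[usable, ]

  n_bins_per_chrom <- table(grid$chrom)
  chrom_known <- al$chrom %in% names(n_bins_per_chrom)
  n_off_grid <- sum(!chrom_known)
  if (n_off_grid > 0) {
    warn(sprintf("%d unique reads on chromosomes absent from the grid",
                 n_off_grid))
  }
  al <- al[chrom_known, ]

  bin_idx0 <- (al$pos - 1) %/% bin_size
  in_grid <- bin_idx0 < as.vector(n_bins_per_chrom[al$chrom]) & al$pos >= 1
  n_partial <- sum(!in_grid)
  al <- al[in_grid, ]
  bin_idx0 <- bin_idx0[in_grid]

  counts <- grid
  counts$count <- 0L
  if (nrow(al)) {
    key <- paste(al$chrom, bin_idx0 * bin_size)
    tab <- table(key)
    idx <- match(names(tab), paste(grid$chrom, grid$start))
    counts$count[idx] <- as.integer(tab)
  }

  structure(counts,
            n_assigned = sum(counts$count),
            tallies = list(n_input = n_input, filtered = n_filtered,
                           off_grid = n_off_grid, partial_bin = n_partial),
            class = unique(c("bin_counts", class(counts))))
}

#' Read a chrom.sizes file
#' @param path Two-column whitespace-separated text (chrom, length).
#' @return Tibble with `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "cd", comment = "#")
}

#' Read a BED file of intervals
#'
#' Standard BED semantics: 0-based half-open, first three columns chrom,
#' start, end. Extra columns are kept.
#' @param path BED path.
#' @return Tibble with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols())
  names(x)[1:3] <- c("chrom", "start", "end")
  x
}

#' Serialise bin counts
#'
#' Writes a TSV with 1-based inclusive coordinates (chrom, start, end, gc,
#' masked, count) preceded by header comment lines recording the tool
#' version and the coordinate convention.
#' @param counts A `bin_counts`.
#' @param path Output path.
#' @param header Extra header lines (each will be prefixed with `# `).
#' @export
write_bin_counts <- function(counts, path, header = character()) {
  out <- tibble(chrom = counts$chrom,
                start = counts$start + 1, end = counts$end,
                gc = counts$gc, masked = counts$masked,
                count = counts$count)
  lines <- c(sprintf("# rcnvseq %s bin counts; coordinates 1-based inclusive",
                     pkg_version()),
             if (length(header)) paste("#", header))
  writeLines(lines, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read bin counts written by [write_bin_counts()]
#' @param path TSV path.
#' @param centromeres,cytobands Optional annotation tibbles to attach
#'   (0-based half-open), e.g. from [read_cytobands()].
#' @return A `bin_counts` tibble (0-based half-open internally).
#' @export
read_bin_counts <- function(path, centromeres = NULL, cytobands = NULL) {
  x <- readr::read_tsv(path, comment = "#", col_types = "cddnli")
  out <- tibble(chrom = x$chrom, start = x$start - 1, end = x$end,
                gc = x$gc, masked = x$masked,
                mask_reason = ifelse(x$masked, "excluded-region", NA_character_),
                count = as.integer(x$count))
  structure(out,
            bin_size = as.integer(stats::median(out$end - out$start)),
            n_assigned = sum(out$count),
            centromeres = centromeres, cytobands = cytobands,
            tallies = list(n_input = sum(out$count), filtered = 0L,
                           off_grid = 0L, partial_bin = 0L),
            class = unique(c("bin_counts", "bin_grid", class(out))))
}

#' Read a UCSC-style cytoband table
#'
#' Columns: chrom, start (0-based), end, band name, stain (optional).
#' @param path Path to a cytoBand.txt-layout file.
#' @return Tibble (chrom, start, end, band).
#' @export
read_cytobands <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols())
  names(x)[1:4] <- c("chrom", "start", "end", "band")
  x[c("chrom", "start", "end", "band")]
}

#' Write cytobands in UCSC column layout
#' @param cytobands Tibble (chrom, start, end, band), 0-based half-open.
#' @param path Output path.
#' @export
write_cytobands <- function(cytobands, path) {
  out <- cytobands[c("chrom", "start", "end", "band")]
  out$stain <- "gneg"
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
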