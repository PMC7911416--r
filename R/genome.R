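#' Build a toy genome model for simulation
#'
#' Constructs a small genome (a handful of chromosomes, tens of megabases)
#' with the annotations the pipeline needs: a per-bin GC landscape, an
#' exclusion set (including the centromere of every chromosome, which in
#' real genomes is repetitive and unmappable), and a simple cytoband table
#' so calls can be named in ISCN style. The model stands in, at desk scale,
#' for the reference genome that real low-pass sequencing reads are mapped
#' against.
#'
#' Intervals are stored 0-based half-open internally; conversion to the
#' 1-based inclusive convention used in reports happens at I/O boundaries.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, e.g. `c(chr1 = 4e6, chrX = 3e6)`). Every
#'   chromosome must hold at least 10 bins.
#' @param bin_size Bin width in bp used for the GC landscape (default
#'   20,000, matching the analysis grid).
#' @param gc_mean,gc_sd Mean and standard deviation of the per-bin GC
#'   fraction. `gc_sd = 0` gives a flat profile.
#' @param gc_range Truncation bounds for the GC fraction.
#' @param n_bands_per_arm Number of cytogenetic bands per chromosome arm.
#'   Bands are named `p1..pN` and `q1..qN` counting outward from the
#'   centromere.
#' @param cen_position Centromere midpoint as a fraction of chromosome
#'   length (0.45 gives a near-metacentric chromosome; larger values a
#'   longer p arm).
#' @param cen_frac Centromere span as a fraction of chromosome length.
#' @param seed Integer seed; the same seed reproduces the model exactly.
#'
#' @return A `genome_model`: a list with tibbles `chroms` (chrom, length,
#'   cen_start, cen_end), `gc` (per-bin GC), `excluded` (masked intervals
#'   with a reason), `cytobands`, plus `bin_size` and `seed`.
#' @export
build_toy_genome <- function(chrom_lengths,
                             bin_size = 20000,
                             gc_mean = 0.40,
                             gc_sd = 0.05,
                             gc_range = c(0.25, 0.65),
                             n_bands_per_arm = 3,
                             cen_position = 0.45,
                             cen_frac = 0.05,
                             seed = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  chrom_lengths <- round(chrom_lengths)
  if (any(chrom_lengths < 10 * bin_size)) {
    abort(sprintf(
      "every chromosome must hold at least 10 bins of %d bp; too short: %s",
      bin_size, paste(names(chrom_lengths)[chrom_lengths < 10 * bin_size],
                      collapse = ", ")
    ))
  }
  assert_fraction(gc_mean, "gc_mean")
  if (cen_position <= 0 || cen_position + cen_frac >= 1) {
    abort("centromere must lie strictly inside the chromosome")
  }

  with_local_seed(seed, {
    chroms <- purrr::map2(names(chrom_lengths), chrom_lengths, function(nm, L) {
      n_bins <- floor(L / bin_size)
      # centromere at cen_position of the chromosome, snapped to bin
      # boundaries, spanning cen_frac of the length (at least one bin)
      cen_start_bin <- floor(cen_position * n_bins)
      cen_n_bins <- max(1L, round(cen_frac * n_bins))
      cen_start <- cen_start_bin * bin_size
      cen_end <- (cen_start_bin + cen_n_bins) * bin_size

      gc <- if (gc_sd > 0) {
        pmin(gc_range[2], pmax(gc_range[1], rnorm(n_bins, gc_mean, gc_sd)))
      } else {
        rep(gc_mean, n_bins)
      }

      # one extra 2-bin excluded region per chromosome, placed on the p arm
      # clear of the centromere (emulates a repetitive/blacklisted region)
      excl_bin <- sample.int(max(1L, cen_start_bin - 3L), 1L)
      excl <- tibble(
        chrom = nm,
        start = (excl_bin - 1L) * bin_size,
        end = min((excl_bin + 1L) * bin_size, L),
        reason = "excluded-region"
      )
      cen <- tibble(chrom = nm, start = cen_start, end = cen_end,
                    reason = "excluded-region")

      bands_arm <- function(a_start, a_end, arm) {
        if (a_end <= a_start) return(tibble())
        cuts <- round(seq(a_start, a_end, length.out = n_bands_per_arm + 1))
        # p bands run distal -> centromere, so numbering counts outward
        idx <- if (arm == "p") rev(seq_len(n_bands_per_arm)) else
          seq_len(n_bands_per_arm)
        tibble(chrom = nm, start = cuts[-length(cuts)], end = cuts[-1],
               band = paste0(arm, idx))
      }
      bands <- bind_rows(
        bands_arm(0, cen_start, "p"),
        tibble(chrom = nm, start = cen_start, end = cen_end, band = "cen"),
        bands_arm(cen_end, L, "q")
      )

      list(
        chrom = tibble(chrom = nm, length = L,
                       cen_start = cen_start, cen_end = cen_end),
        gc = tibble(chrom = nm,
                    start = (seq_len(n_bins) - 1L) * bin_size,
                    end = seq_len(n_bins) * bin_size,
                    gc = gc),
        excluded = bind_rows(excl, cen),
        cytobands = bands
      )
    })

    structure(
      list(
        chroms = purrr::map_dfr(chroms, "chrom"),
        gc = purrr::map_dfr(chroms, "gc"),
        excluded = purrr::map_dfr(chroms, "excluded"),
        cytobands = purrr::map_dfr(chroms, "cytobands"),
        bin_size = bin_size,
        seed = seed
      ),
      class = "genome_model"
    )
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosomes, %.1f Mb total, %d-bp GC bins\n",
    nrow(x$chroms), sum(x$chroms$length) / 1e6, x$bin_size
  ))
  print(x$chroms, ...)
  invisible(x)
}

#' Toy genome emulating a prenatal analysis reference
#'
#' 21 autosome analogues (`chr1`..`chr21`) of 3 Mb each plus a 3-Mb `chrX`
#' and a 1-Mb `chrY`, every chromosome with a centromere and an excluded
#' region. Small enough that a full simulated sample runs in well under a
#' second, while keeping enough autosomes for a robust within-sample
#' normalization baseline and a `chr21` analogue with defined p/q arms.
#'
#' @param seed Integer seed for the GC landscape and excluded regions.
#' @param autosome_length,x_length,y_length Chromosome lengths in bp.
#' @return A [build_toy_genome()] `genome_model`.
#' @export
toy_genome_prenatal <- function(seed = 1,
                                autosome_length = 3e6,
                                x_length = 3e6,
                                y_length = 1e6) {
  lens <- c(setNames(rep(autosome_length, 21), paste0("chr", 1:21)),
            chrX = x_length, chrY = y_length)
  build_toy_genome(lens, seed = seed)
}

#' Parse a karyotype string
#'
#' Accepts the dialect used in clinical result tables: `"46,XX"`, `"46,XY"`,
#' `"45,X"` (or `"45,XO"`), `"47,XXY"`, `"47,XXX"`, `"47,XYY"`, and
#' whole-chromosome gains/losses as trailing `",+21"` / `",-13"` tokens
#' (e.g. `"47,XX,+21"`). `"XN"` (fetal sex masked) is treated as `XX` for
#' simulation purposes.
#'
#' @param x Karyotype string.
#' @return A `karyotype_spec`: list with `sex` (e.g. `"XX"`), integer counts
#'   `n_x`, `n_y`, and named integer vectors `gains`/`losses` of autosome
#'   names (without the `chr` prefix).
#' @export
parse_karyotype <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tokens <- strsplit(gsub(" ", "", x), ",", fixed = TRUE)[[1]]
  if (length(tokens) < 2) abort(sprintf("cannot parse karyotype %s", dQuote(x)))
  sex <- toupper(tokens[2])
  if (!grepl("^[XYON]+$", sex)) {
    abort(sprintf("unrecognised sex-chromosome token %s", dQuote(sex)))
  }
  sex_clean <- gsub("O", "", gsub("N", "X", sex))  # XO -> X, XN -> XX
  if (sex == "XN") sex_clean <- "XX"
  n_x <- stringr::str_count(sex_clean, "X")
  n_y <- stringr::str_count(sex_clean, "Y")
  rest <- tokens[-(1:2)]
  gains <- sub("^\\+", "", rest[grepl("^\\+", rest)])
  losses <- sub("^-", "", rest[grepl("^-", rest)])
  bad <- rest[!grepl("^[+-]", rest)]
  if (length(bad)) abort(sprintf("unrecognised karyotype token %s", dQuote(bad[1])))
  structure(list(sex = sex, n_x = n_x, n_y = n_y,
                 gains = gains, losses = losses, string = x),
            class = "karyotype_spec")
}

# Integer copy number of each chromosome of `genome` under a karyotype.
karyotype_copies <- function(genome, karyotype) {
  if (is.character(karyotype)) karyotype <- parse_karyotype(karyotype)
  chroms <- genome$chroms$chrom
  copies <- setNames(rep(2L, length(chroms)), chroms)
  copies[grepl("^(chr)?X$", chroms)] <- karyotype$n_x
  copies[grepl("^(chr)?Y$", chroms)] <- karyotype$n_y
  match_chrom <- function(token) {
    hit <- which(chroms == token | chroms == paste0("chr", token))
    if (!length(hit)) abort(sprintf("karyotype names unknown chromosome %s",
                                    dQuote(token)))
    hit
  }
  for (g in karyotype$gains) copies[match_chrom(g)] <- copies[match_chrom(g)] + 1L
  for (l in karyotype$losses) copies[match_chrom(l)] <- copies[match_chrom(l)] - 1L
  if (any(copies < 0)) abort("karyotype implies negative copy number")
  tibble(chrom = chroms, copies = as.integer(copies))
}

#' Specify a segmental CNV for simulation
#'
#' Coordinates are 1-based inclusive, matching the convention of clinical
#' microarray result tables. A mosaic fraction `f` means a fraction `f` of
#' cells carry the variant, giving an expected copy number
#' `2(1 - f) + copies * f` inside the interval.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds in bp.
#' @param type `"del"`/`"deletion"` or `"dup"`/`"duplication"`.
#' @param copies Integer copy number in carrier cells; defaults to 1 for
#'   deletions and 3 for duplications.
#' @param mosaic Mosaic cell fraction in \[0, 1\] (1 = constitutional).
#' @return One-row tibble with class `cnv_spec` semantics (chrom, start,
#'   end, type, copies, mosaic).
#' @export
cnv_spec <- function(chrom, start, end, type, copies = NULL, mosaic = 1) {
  type <- switch(tolower(type),
                 del = , deletion = "deletion",
                 dup = , duplication = "duplication",
                 abort(sprintf("unknown CNV type %s", dQuote(type))))
  if (start > end) abort("CNV start must be <= end")
  copies <- copies %||% if (type == "deletion") 1L else 3L
  if (type == "deletion" && copies >= 2) abort("deletion copies must be < 2")
  if (type == "duplication" && copies <= 2) abort("duplication copies must be > 2")
  assert_fraction(mosaic, "mosaic")
  tibble(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         type = type, copies = as.integer(copies), mosaic = mosaic)
}

#' Parse a CNV specification string
#'
#' Format: `chrom:start-end:del|dup[:mosaicFraction]`, e.g.
#' `"chr5:113576-31928290:del"` or `"chr21:1-2000000:dup:0.4"`.
#'
#' @param x Character vector of CNV strings.
#' @return Tibble of CNV specs (one row per string), as [cnv_spec()].
#' @export
parse_cnv_string <- function(x) {
  purrr::map_dfr(x, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3 || length(parts) > 4 ||
        !grepl("^[0-9]+-[0-9]+$", parts[2])) {
      abort(sprintf("malformed CNV spec %s (want chrom:start-end:del|dup[:f])",
                    dQuote(s)))
    }
    se <- as.numeric(strsplit(parts[2], "-", fixed = TRUE)[[1]])
    mosaic <- if (length(parts) == 4) as.numeric(parts[4]) else 1
    cnv_spec(parts[1], se[1], se[2], parts[3], mosaic = mosaic)
  })
}

#' Simulation configuration
#'
#' Defaults reflect the sequencing design the pipeline targets: about 5
#' million single-end 45-bp raw reads per sample, each carrying a 36-bp
#' genomic insert followed by a 9-bp sequencing adapter; a unique-mapping
#' probability around 0.62 (unique mapping ratios are stable at 60--65% in
#' this library type); a low duplicate rate; and a two-state base-quality
#' model whose default mix puts ~94% of bases at or above Q30.
#'
#' @param n_reads Total raw reads per sample.
#' @param read_length Raw read length in bp.
#' @param insert_length Genomic bases per read after adapter removal.
#' @param adapter Adapter sequence; its length must equal
#'   `read_length - insert_length`.
#' @param p_unique Probability a read maps uniquely.
#' @param p_multi_given_nonunique Of the non-unique reads, the fraction that
#'   are multi-mapped (the rest are unmapped).
#' @param p_dup Probability a uniquely mapped read is a duplicate
#'   (re-emission of an earlier read's mapped position).
#' @param gc_bias Length-2 numeric `c(a1, a2)`: per-bin count multiplier
#'   `1 + a1*(gc - 0.4) + a2*(gc - 0.4)^2`, normalised to 1 at GC 0.40.
#'   `c(0, 0)` (default) turns bias off.
#' @param q_high,q_low Phred scores of the two base-quality states.
#' @param p_high_quality Per-base probability of the high-quality state.
#' @param mcc Maternal cell contamination fraction in \[0, 1\].
#' @param seed Integer seed; count-level output is bit-reproducible for a
#'   fixed seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 5e6,
                       read_length = 45,
                       insert_length = 36,
                       adapter = "AGATCGGAA",
                       p_unique = 0.62,
                       p_multi_given_nonunique = 0.5,
                       p_dup = 0.02,
                       gc_bias = c(0, 0),
                       q_high = 37, q_low = 12,
                       p_high_quality = 0.94,
                       mcc = 0,
                       seed = 1) {
  if (read_length < insert_length) abort("read_length must be >= insert_length")
  if (nchar(adapter) != read_length - insert_length) {
    abort(sprintf(
      "adapter length (%d) must equal read_length - insert_length (%d)",
      nchar(adapter), read_length - insert_length
    ))
  }
  assert_fraction(p_unique, "p_unique")
  assert_fraction(p_dup, "p_dup")
  assert_fraction(p_multi_given_nonunique, "p_multi_given_nonunique")
  assert_fraction(p_high_quality, "p_high_quality")
  assert_fraction(mcc, "mcc")
  stopifnot(length(gc_bias) == 2, is.numeric(gc_bias))
  structure(
    list(n_reads = n_reads, read_length = as.integer(read_length),
         insert_length = as.integer(insert_length), adapter = adapter,
         p_unique = p_unique,
         p_multi_given_nonunique = p_multi_given_nonunique,
         p_dup = p_dup, gc_bias = gc_bias,
         q_high = as.integer(q_high), q_low = as.integer(q_low),
         p_high_quality = p_high_quality, mcc = mcc, seed = seed),
    class = "sim_config"
  )
}

#' Reproducibility-panel study design
#'
#' The fixed simulation design used to benchmark interval recovery: a
#' toy genome whose `chr5` analogue (44 Mb, submetacentric with a long p
#' arm) hosts one CNV per sample, plus ten 4-Mb support autosomes that
#' anchor the normalization baseline, with a flat GC landscape (the
#' panel is run with GC bias off). The panel spans deletions and a
#' duplication from 0.7 to 31.8 Mb, echoing the size range over which
#' reproducible detection is expected from ~30 reads per 20-kb bin;
#' coordinates start at an intentionally bin-unaligned offset and small
#' CNVs are placed clear of the host's masked regions (truth regions in
#' a validation study are chosen on assayable sequence).
#'
#' @param seed Integer seed for the genome build.
#' @return List with `genome` (a `genome_model`) and `cnvs` (tibble of
#'   [cnv_spec()] rows with a `size_mb` column).
#' @export
validation_panel <- function(seed = 1) {
  lens <- c(chr5 = 44e6,
            setNames(rep(4e6, 10), paste0("chr", c(1:4, 6:11))))
  genome <- build_toy_genome(lens, gc_sd = 0, cen_position = 0.75,
                             cen_frac = 0.02, seed = seed)
  avoid <- genome$excluded[genome$excluded$chrom == "chr5", ]
  cen <- genome$chroms[genome$chroms$chrom == "chr5", ]
  sizes_mb <- c(0.7, 1.4, 2.6, 4.8, 17.3, 31.8)
  types <- c("dup", "del", "del", "del", "del", "del")
  cnvs <- purrr::map2_dfr(sizes_mb, types, function(mb, ty) {
    size <- mb * 1e6
    start <- 113576
    repeat {
      end <- start + size - 1
      # 1-based inclusive vs 0-based half-open annotation intervals
      clash <- any(overlap_width0(start - 1, end, avoid$start, avoid$end) > 0) ||
        overlap_width0(start - 1, end, cen$cen_start, cen$cen_end) > 0
      if (!clash || mb > 5) break
      start <- start + 1e6
    }
    mutate(cnv_spec("chr5", start, end, ty), size_mb = mb)
  })
  list(genome = genome, cnvs = cnvs)
}
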