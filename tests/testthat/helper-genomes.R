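`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures, built in code.

# Two small flat-GC autosomes: fully deterministic, no GC masking, used
# wherever exact values matter.
flat_genome <- function(seed = 1, lens = c(chrA = 2e6, chrB = 2e6)) {
  build_toy_genome(lens, gc_sd = 0, seed = seed)
}

# Prenatal-style reference shared across calling tests.
prenatal_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- toy_genome_prenatal(seed = 1)
    g
  }
})

# Construct a bin_counts tibble directly (bypassing simulation) for
# exact-arithmetic tests.
manual_counts <- function(counts, chrom = "chrA", bin_size = 20000,
                          gc = 0.40, masked = FALSE) {
  n <- length(counts)
  x <- tibble::tibble(
    chrom = rep_len(chrom, n),
    start = (seq_len(n) - 1) * bin_size,
    end = seq_len(n) * bin_size,
    gc = rep_len(gc, n),
    masked = rep_len(masked, n),
    mask_reason = ifelse(rep_len(masked, n), "excluded-region", NA_character_),
    count = as.integer(counts)
  )
  structure(x, bin_size = bin_size, n_assigned = sum(counts),
            tallies = list(n_input = sum(counts), filtered = 0L,
                           off_grid = 0L, partial_bin = 0L),
            class = unique(c("bin_counts", "bin_grid", class(x))))
}

# Noise-free CN profile over one or more chromosomes from a vector (or
# named list of vectors) of per-bin CN values.
manual_profile <- function(cn, bin_size = 20000, masked = NULL) {
  if (!is.list(cn)) cn <- list(chrA = cn)
  df <- purrr::imap_dfr(cn, function(v, nm) {
    n <- length(v)
    tibble::tibble(chrom = nm, start = (seq_len(n) - 1) * bin_size,
                   end = seq_len(n) * bin_size, gc = 0.4,
                   masked = FALSE, mask_reason = NA_character_,
                   count = NA_integer_, cn = v)
  })
  if (!is.null(masked)) {
    df$masked[masked] <- TRUE
    df$cn[masked] <- NA_real_
  }
  structure(df, bin_size = bin_size, baseline = 1, window = 1L,
            class = unique(c("cn_profile", "bin_counts", class(df))))
}
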