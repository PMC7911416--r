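#' @importFrom rlang %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n row_number across all_of first last pull distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median rpois rbinom rnorm runif runmed setNames
NULL

# Sex-chromosome test tolerant of "chrX"/"X" naming.
is_sex_chrom <- function(chrom) {
  grepl("^(chr)?[XY]$", chrom)
}

# Strip a leading "chr" for report strings ("chr5" -> "5", Table-style).
chrom_label <- function(chrom) sub("^chr", "", chrom)

# Overlap width of 0-based half-open intervals (vectorised).
overlap_width0 <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# 32-bit FNV-1a over a character scalar; used for config hashes in
# report headers (stable, dependency-free).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h may exceed R's 32-bit integer range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619
    h <- (h * 16777619) %% 4294967296
  }
  # format in two 16-bit halves: h may exceed the integer range
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Run code with a locally-seeded RNG, restoring global RNG state after.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Population standard deviation (denominator n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", what))
  }
  invisible(x)
}

pkg_version <- function() {
  as.character(utils::packageVersion("rcnvseq"))
}
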