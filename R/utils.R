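# Internal helpers shared across modules: chromosome-name normalization,
# position ordering, and the numeric position keys used for fast matching.

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` / `"Chr"` / `"CHR"` prefix so that `"Chr1"` and
#' `"1"` refer to the same chromosome. Mismatched chromosome naming between a
#' query and the database is the most common cause of "no shared positions"
#' failures, so both the database builder and the sample readers apply this
#' rule by default.
#'
#' @param x character vector of chromosome names.
#' @param strip_prefix logical; if `FALSE` names are returned unchanged.
#' @return character vector of normalized names.
#' @examples
#' norm_chrom(c("Chr1", "chr2", "3"))
#' @export
norm_chrom <- function(x, strip_prefix = TRUE) {
  x <- as.character(x)
  if (strip_prefix) x <- sub("^[Cc][Hh][Rr]", "", x)
  x
}

# Order chromosome names naturally: numeric names ("1","2",...,"10") sort
# numerically, everything else lexicographically after the numeric ones.
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(u))
  ord <- order(is.na(num), num, u)  # numeric names first by value, then lexical
  match(chrom, u[ord])
}

# Strict (chromosome, position) ordering used everywhere positions are stored.
order_positions <- function(chrom, pos) {
  order(chrom_rank(chrom), pos)
}

# Encode (chromosome, position) as one double for O(1) matching. Chromosome
# index occupies the high digits; positions < 1e10 are exact in a double.
pos_key <- function(chrom, pos, levels) {
  idx <- match(chrom, levels)
  idx * 1e10 + as.numeric(pos)
}

# Internal logging: messages go to stderr via message(), keeping stdout
# pipeline-safe for the CLI.
sm_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[strainmatch] ", ...)
  invisible(NULL)
}
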