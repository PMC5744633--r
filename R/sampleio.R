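# Query-sample input: single-sample VCF (GT, optional PL) or a positional
# genotype table; per-call confidences from Phred-scaled genotype likelihoods.

new_sample_calls <- function(chrom, pos, codes, conf, source = NA_character_) {
  stopifnot(length(chrom) == length(pos),
            length(codes) == length(pos),
            length(conf) == length(pos))
  ord <- order_positions(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  codes <- as.integer(codes)[ord]; conf <- as.numeric(conf)[ord]
  stopifnot(all(codes %in% 0:2), all(conf > 0 & conf <= 1))
  structure(list(
    positions = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                           stringsAsFactors = FALSE),
    genotype_codes = codes,
    call_confidence = conf,
    n_total = length(codes),
    source = source
  ), class = "sample_calls")
}

#' @export
print.sample_calls <- function(x, ...) {
  cat("Sample SNP calls: ", x$n_total, " biallelic call(s) on ",
      length(unique(x$positions$chrom)), " chromosome(s)\n", sep = "")
  cat("  heterozygous fraction: ",
      if (x$n_total > 0) round(mean(x$genotype_codes == 2L), 4) else NA, "\n", sep = "")
  invisible(x)
}

#' Convert Phred-scaled genotype likelihoods to a call confidence
#'
#' PL values are Phred-scaled, `PL = -10 log10(likelihood)`, normalized so the
#' most likely genotype has PL 0. The confidence of the called genotype is its
#' normalized likelihood `10^(-PL[called]/10) / sum_i 10^(-PL[i]/10)`, a
#' probability in (0, 1].
#'
#' @param pl numeric vector of three non-negative PL values, ordered
#'   (hom-ref, het, hom-alt) as in the VCF specification.
#' @param called_index index of the called genotype in `pl` (1, 2 or 3).
#' @return probability that the called genotype is correct.
#' @examples
#' pl_to_confidence(c(0, 30, 200), 1)
#' pl_to_confidence(c(0, 0, 0), 2)  # uniform: 1/3
#' @export
pl_to_confidence <- function(pl, called_index) {
  if (length(pl) != 3 || anyNA(pl)) stop("PL must be three non-missing values")
  if (any(pl < 0)) stop("negative PL value")
  stopifnot(called_index %in% 1:3)
  lik <- 10^(-pl / 10)
  lik[called_index] / sum(lik)
}

# Genotype code -> index into the (hom-ref, het, hom-alt) PL triple.
code_to_pl_index <- function(code) c(`0` = 1L, `2` = 2L, `1` = 3L)[as.character(code)]

#' Read a query sample's SNP calls from a single-sample VCF
#'
#' Parses GT (mandatory) and PL (optional) of the single sample. Biallelic SNP
#' records only; records with missing GT are dropped; duplicate positions keep
#' the first occurrence. Per-call confidence is derived from PL via
#' [pl_to_confidence()] when PL is present, and 1.0 otherwise.
#'
#' @param path path to a single-sample VCF.
#' @param strip_chr_prefix normalize chromosome names with [norm_chrom()].
#' @param verbose emit progress messages.
#' @return a `sample_calls` object.
#' @export
read_sample_vcf <- function(path, strip_chr_prefix = TRUE, verbose = TRUE) {
  if (!file.exists(path)) stop("sample VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) > 2)
    stop("query VCF has ", ncol(v@gt) - 1,
         " samples; run one sample per query (split the VCF first)")
  if (ncol(v@gt) < 2) stop("query VCF has no sample column")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  codes <- gt_to_code(gt_raw)
  keep <- keep & codes >= 0L
  if (!any(keep)) stop("no usable biallelic SNP calls in ", path)

  pl_raw <- tryCatch(vcfR::extract.gt(v, element = "PL")[, 1],
                     error = function(e) rep(NA_character_, length(codes)))
  if (is.null(pl_raw)) pl_raw <- rep(NA_character_, length(codes))

  chrom <- norm_chrom(fix[keep, "CHROM"], strip_chr_prefix)
  pos <- as.integer(fix[keep, "POS"])
  codes <- codes[keep]; pl_raw <- pl_raw[keep]

  conf <- rep(1.0, length(codes))
  has_pl <- !is.na(pl_raw) & pl_raw != "."
  if (any(has_pl)) {
    pls <- strsplit(pl_raw[has_pl], ",", fixed = TRUE)
    idx <- code_to_pl_index(codes[has_pl])
    conf[has_pl] <- vapply(seq_along(pls), function(i) {
      pl <- suppressWarnings(as.numeric(pls[[i]]))
      if (length(pl) != 3 || anyNA(pl)) return(1.0)
      pl_to_confidence(pl, idx[i])
    }, numeric(1))
  }

  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    sm_log(sum(dup), " duplicate position(s) dropped (first kept)", verbose = verbose)
    chrom <- chrom[!dup]; pos <- pos[!dup]; codes <- codes[!dup]; conf <- conf[!dup]
  }
  new_sample_calls(chrom, pos, codes, conf, source = path)
}

#' Read a query sample from a positional genotype table
#'
#' The table dialect is three whitespace- or tab-separated columns:
#' chromosome, 1-based position, genotype string (`0/0`, `0/1`, `1/0`, `1/1`,
#' `/` and `|` interchangeable). Lines starting with `#` are ignored. Note the
#' position is 1-based (the VCF convention), not 0-based half-open as in
#' standard BED. All call confidences are 1.0.
#'
#' @param path path to the table.
#' @param strip_chr_prefix normalize chromosome names with [norm_chrom()].
#' @param verbose emit progress messages (skipped-row line numbers).
#' @return a `sample_calls` object.
#' @export
read_sample_table <- function(path, strip_chr_prefix = TRUE, verbose = TRUE) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  lines <- readLines(path)
  keep_line <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep_line)
  fields <- strsplit(trimws(lines[keep_line]), "\\s+")

  parsed <- lapply(fields, function(f) {
    if (length(f) < 3) return(NULL)
    p <- suppressWarnings(as.integer(f[2]))
    code <- gt_to_code(f[3])
    if (is.na(p) || p < 1 || code < 0L) return(NULL)
    list(chrom = f[1], pos = p, code = code)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    sm_log(sum(!ok), " malformed row(s) skipped (line ",
           paste(utils::head(lineno[!ok], 10), collapse = ", "), ")",
           verbose = verbose)
  if (!any(ok)) stop("no valid genotype rows in ", path)

  parsed <- parsed[ok]
  chrom <- norm_chrom(vapply(parsed, `[[`, character(1), "chrom"), strip_chr_prefix)
  pos <- vapply(parsed, `[[`, integer(1), "pos")
  codes <- vapply(parsed, `[[`, integer(1), "code")

  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    sm_log(sum(dup), " duplicate position(s) dropped (first kept)", verbose = verbose)
    chrom <- chrom[!dup]; pos <- pos[!dup]; codes <- codes[!dup]
  }
  new_sample_calls(chrom, pos, codes, rep(1.0, length(codes)), source = path)
}

#' Write sample calls in the positional-table dialect
#'
#' Serializes a `sample_calls` object to the three-column table accepted by
#' [read_sample_table()] (confidences are not representable in this dialect).
#'
#' @param sample a `sample_calls` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_table <- function(sample, path) {
  stopifnot(inherits(sample, "sample_calls"))
  gt <- c(`0` = "0/0", `1` = "1/1", `2` = "0/1")[as.character(sample$genotype_codes)]
  writeLines(c("# chrom\tpos\tgenotype",
               paste(sample$positions$chrom, sample$positions$pos, gt, sep = "\t")),
             path)
  invisible(path)
}

#' Heterozygosity fraction of a sample
#'
#' Fraction of calls that are heterozygous (code 2). Near zero for inbred
#' individuals; around 0.5 at segregating sites for F2 hybrids, so a high
#' value flags likely hybrid ancestry.
#'
#' @param sample a `sample_calls` object.
#' @return fraction in \[0, 1\].
#' @export
heterozygosity_fraction <- function(sample) {
  stopifnot(inherits(sample, "sample_calls"))
  if (sample$n_total == 0) stop("empty sample: no calls")
  mean(sample$genotype_codes == 2L)
}
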