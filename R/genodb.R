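# Strain-genotype database: construction from a multi-sample VCF, dual-layout
# persistence, pairwise strain distances and closeness groups.

GT_CODES <- c("0/0" = 0L, "0|0" = 0L,
              "1/1" = 1L, "1|1" = 1L,
              "0/1" = 2L, "1/0" = 2L, "0|1" = 2L, "1|0" = 2L)

# Map VCF GT strings to genotype codes {0 hom-ref, 1 hom-alt, 2 het, -1 missing}.
gt_to_code <- function(gt) {
  gt <- sub(":.*$", "", as.character(gt))
  code <- unname(GT_CODES[gt])
  code[is.na(code)] <- -1L
  code
}

new_genodb <- function(strain_ids, chrom, pos, genotype_matrix, provenance = list()) {
  stopifnot(length(chrom) == length(pos),
            nrow(genotype_matrix) == length(strain_ids),
            ncol(genotype_matrix) == length(chrom))
  storage.mode(genotype_matrix) <- "integer"
  rownames(genotype_matrix) <- strain_ids
  structure(list(
    strain_ids = as.character(strain_ids),
    positions = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                           stringsAsFactors = FALSE),
    genotype_matrix = genotype_matrix,
    chrom_levels = unique(as.character(chrom)),
    provenance = provenance
  ), class = "genodb")
}

#' @export
print.genodb <- function(x, ...) {
  cat("Strain genotype database\n")
  cat("  strains:  ", length(x$strain_ids), "\n")
  cat("  positions:", nrow(x$positions), " on ",
      length(unique(x$positions$chrom)), " chromosome(s)\n", sep = "")
  if (!is.null(x$provenance$source))
    cat("  source:   ", x$provenance$source, "\n")
  invisible(x)
}

#' Build a strain-genotype database from a multi-sample VCF
#'
#' Parses the `GT` field of every sample in a panel VCF into a strain-by-
#' position genotype matrix with codes 0 (homozygous reference), 1 (homozygous
#' alternate), 2 (heterozygous) and -1 (missing). Allele separators `/` and
#' `|` are treated identically. Only biallelic SNP records are used;
#' multi-allelic or non-SNP records are skipped and counted. Positions are
#' sorted by (chromosome, position) and de-duplicated (first record wins).
#'
#' @param panel_vcf path to a multi-sample VCF (v4.x) with a GT field.
#' @param out_prefix optional path stem; when given, the database is persisted
#'   as two stores via [write_genodb()].
#' @param strip_chr_prefix normalize chromosome names with [norm_chrom()].
#' @param verbose emit progress messages.
#' @return a `genodb` object.
#' @seealso [write_genodb()], [read_genodb()], [pairwise_differences()]
#' @export
build_database <- function(panel_vcf, out_prefix = NULL, strip_chr_prefix = TRUE,
                           verbose = TRUE) {
  if (!file.exists(panel_vcf)) stop("panel VCF not found: ", panel_vcf)
  v <- vcfR::read.vcfR(panel_vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (ncol(v@gt) < 2) stop("VCF has no sample genotype columns: ", panel_vcf)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("record ", which(!grepl("(^|:)GT(:|$)", fmt))[1],
         " has no GT field; a GT field is mandatory for database samples")

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    sm_log(n_skip, " non-biallelic/non-SNP record(s) skipped", verbose = verbose)
  if (!any(biallelic)) stop("no biallelic SNP records in ", panel_vcf)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  gt <- gt[biallelic, , drop = FALSE]
  chrom <- norm_chrom(fix[biallelic, "CHROM"], strip_chr_prefix)
  pos <- as.integer(fix[biallelic, "POS"])

  ord <- order_positions(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; gt <- gt[ord, , drop = FALSE]
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    sm_log(sum(dup), " duplicate position(s) dropped (first kept)", verbose = verbose)
    chrom <- chrom[!dup]; pos <- pos[!dup]; gt <- gt[!dup, , drop = FALSE]
  }

  codes <- matrix(gt_to_code(gt), nrow = nrow(gt))
  db <- new_genodb(colnames(gt), chrom, pos, t(codes),
                   provenance = list(source = normalizePath(panel_vcf),
                                     n_records_skipped = n_skip,
                                     strip_chr_prefix = strip_chr_prefix))
  sm_log("database: ", length(db$strain_ids), " strains x ",
         nrow(db$positions), " positions", verbose = verbose)
  if (!is.null(out_prefix)) write_genodb(db, out_prefix)
  db
}

#' Persist a genotype database as two ordered stores
#'
#' Writes the database twice: a position-major store (`<prefix>.snpdb.rds`,
#' positions-by-strains) optimized for positional scans, and a strain-major
#' store (`<prefix>.acc.snpdb.rds`, strains-by-positions) optimized for
#' per-strain access. Either store alone reconstructs the database; the
#' matcher CLI accepts both paths, mirroring the two-file convention of
#' genotype-database tools in this field.
#'
#' @param db a `genodb` object.
#' @param out_prefix path stem for the two stores.
#' @return invisibly, the two file paths (position-major first).
#' @export
write_genodb <- function(db, out_prefix) {
  stopifnot(inherits(db, "genodb"))
  paths <- genodb_paths(out_prefix)
  base <- db[c("strain_ids", "positions", "chrom_levels", "provenance")]
  pm <- c(base, list(layout = "position_major",
                     genotype_matrix = t(db$genotype_matrix)))
  am <- c(base, list(layout = "strain_major",
                     genotype_matrix = db$genotype_matrix))
  saveRDS(pm, paths[["db"]], compress = "gzip")
  saveRDS(am, paths[["acc"]], compress = "gzip")
  invisible(paths)
}

genodb_paths <- function(out_prefix) {
  c(db = paste0(out_prefix, ".snpdb.rds"),
    acc = paste0(out_prefix, ".acc.snpdb.rds"))
}

#' Load a genotype database from a persisted store
#'
#' Accepts either the position-major or the strain-major store written by
#' [write_genodb()]; the in-memory representation is identical regardless of
#' which file is read.
#'
#' @param path path to one of the two stores, or the common prefix.
#' @return a `genodb` object.
#' @export
read_genodb <- function(path) {
  if (!file.exists(path)) {
    pref <- genodb_paths(path)
    if (file.exists(pref[["db"]])) path <- pref[["db"]]
    else stop("database store not found: ", path)
  }
  x <- readRDS(path)
  m <- if (identical(x$layout, "position_major")) t(x$genotype_matrix) else x$genotype_matrix
  new_genodb(x$strain_ids, x$positions$chrom, x$positions$pos, m, x$provenance)
}

check_strain <- function(db, id) {
  if (!id %in% db$strain_ids)
    stop("unknown strain id '", id, "'; valid ids: ",
         paste(utils::head(db$strain_ids, 20), collapse = ", "),
         if (length(db$strain_ids) > 20) ", ..." else "")
  invisible(id)
}

#' Pairwise genotype differences between two strains
#'
#' Counts positions where both strains have non-missing genotype codes and the
#' codes differ. Missing (-1) sites are excluded, so the count is an
#' identity-by-state distance over jointly called sites. Symmetric in its
#' arguments.
#'
#' @param db a `genodb` object.
#' @param a,b strain ids present in `db`.
#' @return integer count of differing jointly-called positions.
#' @export
pairwise_differences <- function(db, a, b) {
  check_strain(db, a); check_strain(db, b)
  ga <- db$genotype_matrix[a, ]; gb <- db$genotype_matrix[b, ]
  ok <- ga >= 0L & gb >= 0L
  sum(ga[ok] != gb[ok])
}

# Full pairwise-difference matrix, vectorized through indicator cross-products:
# matches = sum over codes c of A_c A_c', valid = V V', distance = valid - matches.
pairwise_difference_matrix <- function(db) {
  m <- db$genotype_matrix
  V <- (m >= 0L) * 1
  valid <- tcrossprod(V)
  matches <- matrix(0, nrow(m), nrow(m))
  for (code in 0:2) {
    A <- (m == code) * 1
    matches <- matches + tcrossprod(A)
  }
  d <- valid - matches
  dimnames(d) <- list(db$strain_ids, db$strain_ids)
  d
}

#' Closeness groups of mutually confusable strains
#'
#' Partitions the panel into connected components of the graph that links two
#' strains when their pairwise difference count falls below `threshold`.
#' Strains in one group are expected to be mutually confusable by the matcher;
#' the default cutoff of 6,000 sites is appropriate for a ~10-million-marker
#' panel and should be scaled with marker count for smaller databases.
#'
#' @param db a `genodb` object.
#' @param threshold integer cutoff; strains with fewer than `threshold`
#'   pairwise differences are linked.
#' @return an object of class `closeness_groups`: list with `threshold`,
#'   `groups` (list of character vectors partitioning the strain ids) and
#'   `membership` (named integer vector, group index per strain).
#' @export
closeness_groups <- function(db, threshold = 6000) {
  stopifnot(threshold >= 0)
  d <- pairwise_difference_matrix(db)
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- db$strain_ids
  groups <- split(db$strain_ids, membership)
  names(groups) <- NULL
  structure(list(threshold = threshold, groups = groups, membership = membership),
            class = "closeness_groups")
}

#' @export
print.closeness_groups <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("Closeness groups (pairwise differences < ", x$threshold, ")\n", sep = "")
  cat("  strains:", sum(sizes), " groups:", length(sizes),
      " non-singleton:", sum(sizes > 1), "\n")
  invisible(x)
}

# Group index of one strain (NA when absent).
group_of <- function(groups, id) {
  unname(groups$membership[id])
}
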