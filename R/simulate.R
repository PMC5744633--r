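# Synthetic-data generator: inbred panels with controlled divergence, sparse
# error-prone query samples, and F2 recombinants.

#' Specification for a simulated inbred panel
#'
#' @param n_strains number of inbred strains.
#' @param n_snps number of biallelic SNP positions, placed uniformly along the
#'   chromosomes.
#' @param chrlen named vector of chromosome lengths in bp.
#' @param af_beta shape parameters of the Beta allele-frequency sampler; the
#'   default Beta(0.5, 0.5) yields both common and rare variants.
#' @param near_duplicate_pairs list of `list(pair = c(id_a, id_b), distance = d)`
#'   entries: strain `id_b` is rebuilt as a copy of `id_a` mutated at exactly
#'   `d` sites, emulating very closely related strains.
#' @param seed integer seed fixing all randomness of the panel.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_strains = 50, n_snps = 10000,
                       chrlen = tair10_chrlen(),
                       af_beta = c(0.5, 0.5),
                       near_duplicate_pairs = list(),
                       seed = 1L) {
  stopifnot(n_strains >= 1, n_snps >= 1, all(chrlen > 0))
  for (nd in near_duplicate_pairs)
    stopifnot(length(nd$pair) == 2, nd$distance >= 0, nd$distance < n_snps)
  structure(list(n_strains = n_strains, n_snps = n_snps, chrlen = chrlen,
                 af_beta = af_beta, near_duplicate_pairs = near_duplicate_pairs,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Specification for a simulated query sample
#'
#' @param n_query_snps number of panel positions subsampled into the query.
#' @param error_rate per-call probability of flipping the genotype to a
#'   uniformly chosen other code, in \[0, 0.5).
#' @param pl_alt Phred-scaled likelihood assigned to the two non-called
#'   genotypes when emitting PL triples (the called genotype gets PL 0).
#' @param variant_only subsample only sites where the individual carries an
#'   alternate allele (codes 1 or 2), emulating a single-sample variant
#'   caller's output, which reports no homozygous-reference positions. The
#'   default `FALSE` subsamples all panel positions uniformly.
#' @param seed integer seed for subsampling and errors.
#' @return a `query_spec` list.
#' @export
query_spec <- function(n_query_snps = 2000, error_rate = 0.001,
                       pl_alt = 40, variant_only = FALSE, seed = 1L) {
  stopifnot(n_query_snps >= 1, error_rate >= 0, error_rate < 0.5, pl_alt >= 20)
  structure(list(n_query_snps = n_query_snps, error_rate = error_rate,
                 pl_alt = pl_alt, variant_only = isTRUE(variant_only),
                 seed = as.integer(seed)),
            class = "query_spec")
}

# Candidate site indices honouring spec$variant_only (codes are the
# individual's true genotypes over all db positions).
candidate_sites <- function(codes, spec) {
  if (spec$variant_only) which(codes %in% c(1L, 2L)) else seq_along(codes)
}

# Uniform unique positions along the chromosomes, sorted; duplicates resampled.
sample_positions <- function(n_snps, chrlen) {
  chrom <- sample(names(chrlen), n_snps, replace = TRUE,
                  prob = chrlen / sum(chrlen))
  pos <- vapply(chrlen[chrom], function(L) sample.int(L, 1L), integer(1))
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    chrom[dup] <- sample(names(chrlen), sum(dup), replace = TRUE,
                         prob = chrlen / sum(chrlen))
    pos[dup] <- vapply(chrlen[chrom[dup]], function(L) sample.int(L, 1L), integer(1))
    key <- paste(chrom, pos)
  }
  ord <- order_positions(chrom, pos)
  list(chrom = chrom[ord], pos = as.integer(pos[ord]))
}

#' Simulate an inbred strain panel
#'
#' Positions are placed uniformly along the chromosomes; per-site alternate
#' allele frequencies are drawn from the Beta sampler and each inbred strain
#' carries the homozygous alternate code with that probability, independently
#' across strains and sites (codes 0/1 only; the inbred panel has no
#' heterozygous or missing entries). Near-duplicate pairs are then engineered
#' by copying the first strain of the pair and mutating exactly the target
#' number of uniformly chosen sites. All randomness derives from `spec$seed`.
#'
#' @param spec a `panel_spec`.
#' @return list with `db` (a `genodb`), and `truth`: the allele frequencies,
#'   the engineered pairs, and the full pairwise-difference matrix.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  loc <- sample_positions(spec$n_snps, spec$chrlen)
  af <- stats::rbeta(spec$n_snps, spec$af_beta[1], spec$af_beta[2])
  strain_ids <- sprintf("S%03d", seq_len(spec$n_strains))
  m <- matrix(stats::rbinom(spec$n_strains * spec$n_snps, 1L,
                            rep(af, each = spec$n_strains)),
              nrow = spec$n_strains, dimnames = list(strain_ids, NULL))

  for (nd in spec$near_duplicate_pairs) {
    a <- nd$pair[1]; b <- nd$pair[2]
    stopifnot(a %in% strain_ids, b %in% strain_ids)
    m[b, ] <- m[a, ]
    if (nd$distance > 0) {
      sites <- sample.int(spec$n_snps, nd$distance)
      m[b, sites] <- 1L - m[b, sites]
    }
  }

  db <- new_genodb(strain_ids, loc$chrom, loc$pos, m,
                   provenance = list(source = "simulate_panel",
                                     seed = spec$seed,
                                     n_strains = spec$n_strains,
                                     n_snps = spec$n_snps))
  list(db = db,
       truth = list(allele_freq = af,
                    near_duplicate_pairs = spec$near_duplicate_pairs,
                    pairwise = pairwise_difference_matrix(db)))
}

# Flip each call to one of the two other codes with probability error_rate.
apply_genotyping_errors <- function(codes, error_rate) {
  flip <- stats::runif(length(codes)) < error_rate
  if (any(flip)) {
    others <- vapply(codes[flip], function(g) sample(setdiff(0:2, g), 1L), integer(1))
    codes[flip] <- others
  }
  list(codes = codes, flipped = flip)
}

# Emit the PL-derived confidences used for the returned SampleCalls and VCF.
query_confidences <- function(codes, pl_alt) {
  conf <- pl_to_confidence(c(0, pl_alt, pl_alt), 1)
  rep(conf, length(codes))
}

#' Simulate a sparse query from one inbred strain
#'
#' Subsamples `spec$n_query_snps` panel positions uniformly without
#' replacement, takes the source strain's genotypes there, flips each call to
#' a random other code with probability `spec$error_rate`, and attaches
#' PL-derived confidences (called genotype PL 0, the others `spec$pl_alt`).
#' Optionally writes the query in both input dialects: a single-sample VCF
#' with GT:PL and a positional genotype table.
#'
#' @param db a `genodb` from [simulate_panel()].
#' @param source_strain strain id in `db`.
#' @param spec a `query_spec`.
#' @param out_prefix optional path stem; writes `<prefix>.vcf` and
#'   `<prefix>.txt` when given.
#' @return list with `sample` (a `sample_calls`), `truth` (site indices into
#'   the db, error flags), and the written paths if any.
#' @export
simulate_inbred_query <- function(db, source_strain, spec = query_spec(),
                                  out_prefix = NULL) {
  stopifnot(inherits(db, "genodb"), inherits(spec, "query_spec"))
  check_strain(db, source_strain)
  n_sites <- nrow(db$positions)
  if (spec$n_query_snps > n_sites)
    stop("n_query_snps (", spec$n_query_snps, ") exceeds available sites (",
         n_sites, ")")
  set.seed(spec$seed)
  cand <- candidate_sites(db$genotype_matrix[source_strain, ], spec)
  if (spec$n_query_snps > length(cand))
    stop("n_query_snps (", spec$n_query_snps, ") exceeds candidate sites (",
         length(cand), ")")
  sites <- sort(cand[sample.int(length(cand), spec$n_query_snps)])
  codes <- db$genotype_matrix[source_strain, sites]
  stopifnot(all(codes >= 0L))
  err <- apply_genotyping_errors(codes, spec$error_rate)
  conf <- query_confidences(err$codes, spec$pl_alt)
  sample_obj <- new_sample_calls(db$positions$chrom[sites], db$positions$pos[sites],
                                 err$codes, conf, source = "simulate_inbred_query")
  paths <- NULL
  if (!is.null(out_prefix)) {
    paths <- c(vcf = paste0(out_prefix, ".vcf"), table = paste0(out_prefix, ".txt"))
    write_sample_vcf(sample_obj, paths[["vcf"]], pl_alt = spec$pl_alt,
                     sample_name = source_strain)
    write_sample_table(sample_obj, paths[["table"]])
  }
  list(sample = sample_obj,
       truth = list(source_strain = source_strain, sites = sites,
                    flipped = err$flipped),
       paths = paths)
}

#' Simulate an F2 individual from two panel strains
#'
#' For each chromosome, two recombinant gametes are built independently: each
#' has Poisson(`crossovers_per_chromosome`)-many crossover points placed
#' uniformly, and alternates parental origin (random start parent) across the
#' resulting segments. The diplotype state at a site is the number of gametes
#' carrying parent A (2 = homozygous A, 1 = heterozygous, 0 = homozygous B);
#' the genotype is parent A's code, the het code 2 (when the parents differ;
#' sites where they agree are non-segregating and keep the shared code), or
#' parent B's code. Subsampling, genotyping errors and PL confidences are
#' applied as in [simulate_inbred_query()].
#'
#' @param db a `genodb` from [simulate_panel()].
#' @param parent_a,parent_b distinct strain ids.
#' @param spec a `query_spec`.
#' @param crossovers_per_chromosome mean crossovers per gamete per chromosome.
#' @param out_prefix optional path stem, as in [simulate_inbred_query()].
#' @return list with `sample` (a `sample_calls`), `truth` (per-site diplotype
#'   states, segregating flags, segment table chrom/start/end/state, error
#'   flags), and the written paths if any.
#' @export
simulate_f2 <- function(db, parent_a, parent_b, spec = query_spec(),
                        crossovers_per_chromosome = 1.5, out_prefix = NULL) {
  stopifnot(inherits(db, "genodb"), inherits(spec, "query_spec"))
  check_strain(db, parent_a); check_strain(db, parent_b)
  if (identical(parent_a, parent_b)) stop("parents must be distinct strains")
  n_sites <- nrow(db$positions)
  if (spec$n_query_snps > n_sites)
    stop("n_query_snps (", spec$n_query_snps, ") exceeds available sites (",
         n_sites, ")")
  set.seed(spec$seed)

  chroms <- unique(db$positions$chrom)
  chrlen <- vapply(chroms, function(cn)
    max(db$positions$pos[db$positions$chrom == cn]), integer(1))

  # one gamete = breakpoints + origin per segment (TRUE = parent A)
  gamete <- function(L) {
    k <- stats::rpois(1, crossovers_per_chromosome)
    bp <- sort(stats::runif(k, 1, L))
    start_a <- stats::runif(1) < 0.5
    list(breaks = c(0, bp, L + 1),
         from_a = rep(c(start_a, !start_a), length.out = k + 1))
  }
  carries_a <- function(g, pos) g$from_a[findInterval(pos, g$breaks)]

  state <- integer(n_sites)  # copies of parent A at each site: 0, 1, 2
  seg_list <- list()
  for (cn in chroms) {
    sel <- db$positions$chrom == cn
    pos <- db$positions$pos[sel]
    g1 <- gamete(chrlen[[cn]]); g2 <- gamete(chrlen[[cn]])
    state[sel] <- carries_a(g1, pos) + carries_a(g2, pos)
    cuts <- sort(unique(c(g1$breaks, g2$breaks)))
    mids <- utils::head(cuts, -1) + diff(cuts) / 2
    seg_state <- vapply(mids, function(x)
      sum(carries_a(g1, x), carries_a(g2, x)), numeric(1))
    seg_list[[cn]] <- data.frame(chrom = cn,
                                 start = utils::head(cuts, -1) + c(1, rep(0, length(cuts) - 2)),
                                 end = cuts[-1],
                                 state = as.integer(seg_state),
                                 stringsAsFactors = FALSE)
  }

  ga <- db$genotype_matrix[parent_a, ]; gb <- db$genotype_matrix[parent_b, ]
  segregating <- ga != gb
  codes <- ifelse(state == 2L, ga, ifelse(state == 0L, gb,
                  ifelse(segregating, 2L, ga)))

  cand <- candidate_sites(codes, spec)
  if (spec$n_query_snps > length(cand))
    stop("n_query_snps (", spec$n_query_snps, ") exceeds candidate sites (",
         length(cand), ")")
  sites <- sort(cand[sample.int(length(cand), spec$n_query_snps)])
  err <- apply_genotyping_errors(codes[sites], spec$error_rate)
  conf <- query_confidences(err$codes, spec$pl_alt)
  sample_obj <- new_sample_calls(db$positions$chrom[sites], db$positions$pos[sites],
                                 err$codes, conf, source = "simulate_f2")
  paths <- NULL
  if (!is.null(out_prefix)) {
    paths <- c(vcf = paste0(out_prefix, ".vcf"), table = paste0(out_prefix, ".txt"))
    write_sample_vcf(sample_obj, paths[["vcf"]], pl_alt = spec$pl_alt,
                     sample_name = paste0(parent_a, "x", parent_b))
    write_sample_table(sample_obj, paths[["table"]])
  }
  list(sample = sample_obj,
       truth = list(parents = c(parent_a, parent_b),
                    state = state, segregating = segregating, sites = sites,
                    segments = do.call(rbind, c(seg_list, list(make.row.names = FALSE))),
                    flipped = err$flipped),
       paths = paths)
}

#' Write sample calls as a minimal single-sample VCF
#'
#' Emits a VCFv4.2 file with GT:PL per record: the called genotype gets PL 0
#' and the two others `pl_alt`. REF/ALT are placeholder alleles (`A`/`T`);
#' the matcher uses only positions and genotype codes.
#'
#' @param sample a `sample_calls` object.
#' @param path output path.
#' @param pl_alt PL assigned to non-called genotypes.
#' @param sample_name sample column name.
#' @return invisibly, `path`.
#' @export
write_sample_vcf <- function(sample, path, pl_alt = 40, sample_name = "sample") {
  stopifnot(inherits(sample, "sample_calls"))
  gt <- c(`0` = "0/0", `1` = "1/1", `2` = "0/1")[as.character(sample$genotype_codes)]
  pl_idx <- code_to_pl_index(sample$genotype_codes)
  pl <- vapply(pl_idx, function(i) {
    v <- c(pl_alt, pl_alt, pl_alt); v[i] <- 0
    paste(v, collapse = ",")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=strainmatch-simulator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     sample_name))
  body <- paste(sample$positions$chrom, sample$positions$pos, ".", "A", "T",
                ".", "PASS", ".", "GT:PL", paste0(gt, ":", pl), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype database as a multi-sample panel VCF
#'
#' Inverse of [build_database()] for simulated panels: codes 0/1/2 become GT
#' `0/0`, `1/1`, `0/1`; missing becomes `./.`. Useful for round-trip tests and
#' for exercising the database builder on generated data.
#'
#' @param db a `genodb` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_panel_vcf <- function(db, path) {
  stopifnot(inherits(db, "genodb"))
  gt_map <- c(`-1` = "./.", `0` = "0/0", `1` = "1/1", `2` = "0/1")
  m <- db$genotype_matrix  # strains x positions
  gt <- matrix(gt_map[as.character(m)], nrow = nrow(m))
  recs <- apply(gt, 2, paste, collapse = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=strainmatch-simulator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(db$strain_ids, collapse = "\t")))
  body <- paste(db$positions$chrom, db$positions$pos, ".", "A", "T",
                ".", "PASS", ".", "GT", recs, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
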