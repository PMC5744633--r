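# Fixture builders and independent oracles used across the test files.
# Everything is generated in code at test time; no binary fixtures.

# Minimal multi-sample VCF writer, independent of the package's own writer.
write_test_panel_vcf <- function(path, chrom, pos, gt, strains,
                                 ref = NULL, alt = NULL, format = "GT") {
  stopifnot(nrow(gt) == length(chrom), ncol(gt) == length(strains))
  if (is.null(ref)) ref <- rep("A", length(chrom))
  if (is.null(alt)) alt <- rep("T", length(chrom))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="PL">',
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(strains, collapse = "\t")))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", format,
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# Independent Bernoulli log-likelihood-difference oracle for the binomial
# likelihood statistic (binomial coefficients cancel in the ratio).
oracle_L <- function(p_hat, n, p = 0.001) {
  xlg <- function(x) if (x == 0) 0 else x * log(x)
  n * (xlg(p_hat) + xlg(1 - p_hat)) -
    n * (p_hat * log(1 - p) + (1 - p_hat) * log(p))
}

# Brute-force pairwise distance: explicit loop over positions.
oracle_distance <- function(db, a, b) {
  ga <- db$genotype_matrix[a, ]; gb <- db$genotype_matrix[b, ]
  d <- 0L
  for (j in seq_along(ga)) {
    if (ga[j] >= 0L && gb[j] >= 0L && ga[j] != gb[j]) d <- d + 1L
  }
  d
}

# Transitive closure over the sub-threshold adjacency matrix by boolean
# matrix powers; returns a canonical membership labelling.
oracle_components <- function(adj) {
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  match(labels, unique(labels))
}

# Canonical form of a partition for comparison (order-independent).
canonical_partition <- function(groups) {
  sorted <- lapply(groups, sort)
  paste(sort(vapply(sorted, paste, character(1), collapse = ",")), collapse = ";")
}

# Small simulated panel shared by several scoring/crosswin tests. Short
# chromosomes keep 300 kb windows densely covered at modest SNP counts.
test_chrlen <- function() c(`1` = 3e6L, `2` = 2.4e6L, `3` = 1.8e6L)

make_test_panel <- function(n_strains = 12, n_snps = 6000, seed = 101, ...) {
  simulate_panel(panel_spec(n_strains = n_strains, n_snps = n_snps,
                            chrlen = test_chrlen(), seed = seed, ...))
}
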