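# The matching core: match probabilities, likelihood statistic, ambiguity
# sets, verdict interpretation.

mk_calls <- strainmatch:::new_sample_calls

# match_scores object with prescribed statistics, for threshold-logic tests
mk_scores <- function(L, n = 500, p = 0.9, error_rate = 0.001) {
  ids <- sprintf("T%02d", seq_along(L))
  structure(list(strain_ids = ids,
                 n_a = stats::setNames(rep(n, length(L)), ids),
                 score_a = stats::setNames(rep(p * n, length(L)), ids),
                 p_a = stats::setNames(rep(p, length(L)), ids),
                 L_a = stats::setNames(L, ids),
                 unscorable = stats::setNames(rep(FALSE, length(L)), ids),
                 error_rate = error_rate, n_total = n),
            class = "match_scores")
}

test_that("likelihood statistic agrees with the Bernoulli log-likelihood oracle", {
  for (p_hat in seq(0.05, 0.95, by = 0.1)) {
    for (n in c(1, 10, 500, 2000)) {
      expect_equal(likelihood_statistic(p_hat, n), oracle_L(p_hat, n),
                   tolerance = 1e-12)
    }
  }
  # boundary conventions: 0*ln0 = 0 keeps p_a in {0, 1} finite
  expect_equal(likelihood_statistic(1, 100), 100 * log(1 / 0.999))
  expect_equal(likelihood_statistic(0, 100), 100 * log(1 / 0.001))
  expect_identical(likelihood_statistic(1 - 0.001, 12345), 0)  # exact null
  expect_identical(likelihood_statistic(0.5, 0), 0)
  expect_error(likelihood_statistic(0.5, 10, error_rate = 1.5), "error_rate")
})

test_that("L equals n times the KL divergence and is V-shaped around 1 - p", {
  kl <- function(a, b) {
    xlg <- function(x, y) if (x == 0) 0 else x * log(x / y)
    xlg(a, b) + xlg(1 - a, 1 - b)
  }
  grid <- expand.grid(p_hat = seq(0.01, 0.99, length.out = 25),
                      n = c(3, 50, 1000))
  L <- likelihood_statistic(grid$p_hat, grid$n)
  L_kl <- mapply(function(a, n) n * kl(a, 1 - 0.001), grid$p_hat, grid$n)
  expect_equal(L, L_kl, tolerance = 1e-12)
  expect_true(all(L >= 0))

  # strictly decreasing below the null, strictly increasing above it
  lo <- likelihood_statistic(seq(0.01, 0.99, by = 0.01), 100)
  expect_true(all(diff(lo) < 0))
  hi <- likelihood_statistic(seq(0.9991, 0.9999, by = 1e-4), 1e5)
  expect_true(all(diff(hi) > 0))
})

test_that("score_sample reproduces the brute-force per-position loop", {
  panel <- make_test_panel(n_strains = 5, n_snps = 200, seed = 13)
  db <- panel$db
  set.seed(14)
  db$genotype_matrix[sample(length(db$genotype_matrix), 80)] <- -1L
  idx <- sort(sample(200, 120))
  codes <- sample(0:2, 120, replace = TRUE)
  conf <- runif(120, 0.9, 1)
  s <- mk_calls(db$positions$chrom[idx], db$positions$pos[idx], codes, conf)

  sc <- score_sample(s, db)
  for (a in db$strain_ids) {
    n_ref <- 0L; score_ref <- 0
    for (j in seq_along(idx)) {
      g <- db$genotype_matrix[a, idx[j]]
      if (g >= 0L) {
        n_ref <- n_ref + 1L
        if (g == codes[j]) score_ref <- score_ref + conf[j]
      }
    }
    expect_identical(sc$n_a[[a]], n_ref)
    expect_equal(sc$score_a[[a]], score_ref)
    expect_equal(sc$p_a[[a]], if (n_ref > 0) score_ref / n_ref else 0)
  }
  expect_true(all(sc$n_a <= s$n_total))
})

test_that("self-match and single-mismatch probabilities are exact", {
  panel <- make_test_panel(n_strains = 4, n_snps = 100, seed = 17)
  db <- panel$db
  s <- mk_calls(db$positions$chrom, db$positions$pos,
                db$genotype_matrix["S003", ], rep(1, 100))
  sc <- score_sample(s, db)
  expect_identical(sc$p_a[["S003"]], 1)
  expect_identical(sc$n_a[["S003"]], s$n_total)

  codes10 <- db$genotype_matrix["S003", 1:10]
  codes10[4] <- if (codes10[4] == 0L) 1L else 0L
  s10 <- mk_calls(db$positions$chrom[1:10], db$positions$pos[1:10],
                  codes10, rep(1, 10))
  expect_equal(score_sample(s10, db)$p_a[["S003"]], 0.9)
})

test_that("disjoint coordinates raise the chromosome-naming hint", {
  panel <- make_test_panel(n_strains = 3, n_snps = 50, seed = 29)
  s <- mk_calls(rep("molecule_9", 5), 1:5, rep(0L, 5), rep(1, 5))
  expect_error(score_sample(s, panel$db), "chromosome naming")
})

test_that("ambiguity set keeps strains within the chi-squared cutoff of the top hit", {
  # L = {10, 12, 100}: ratios 1, 1.2, 10 -> first two kept under 3.841
  amb <- ambiguity_set(mk_scores(c(10, 12, 100)))
  expect_identical(amb$strain, c("T01", "T02"))
  expect_equal(amb$LR, c(1, 1.2))

  # single-strain database: that strain with LR 1
  amb1 <- ambiguity_set(mk_scores(5))
  expect_identical(amb1$strain, "T01")
  expect_identical(amb1$LR, 1)

  # invariant under a positive rescaling when the floor is not active
  amb2x <- ambiguity_set(mk_scores(2 * c(10, 12, 100)))
  expect_identical(amb2x$strain, amb$strain)
  expect_equal(amb2x$LR, amb$LR)
})

test_that("the LR denominator is floored at one mismatch's worth of evidence", {
  # best L below the single-mismatch floor: ratios use the floor instead
  n <- 2000
  floor_L <- likelihood_statistic((n - 1) / n, n)
  sc <- mk_scores(c(floor_L / 8, floor_L * 2), n = n)
  amb <- ambiguity_set(sc)
  expect_identical(amb$strain, c("T01", "T02"))   # both within 2x of the floor
  expect_equal(amb$LR[1], 1)
  expect_equal(amb$LR[2], 2)

  # a perfect match (L = 0) no longer divides by zero
  sc0 <- mk_scores(c(0, floor_L * 3), n = n)
  expect_identical(ambiguity_set(sc0)$strain, c("T01", "T02"))
})

test_that("near-duplicate strains are co-reported when the query misses their differences", {
  panel <- make_test_panel(n_strains = 8, n_snps = 5000, seed = 37,
                           near_duplicate_pairs = list(
                             list(pair = c("S001", "S002"), distance = 30)))
  db <- panel$db
  same <- which(db$genotype_matrix["S001", ] == db$genotype_matrix["S002", ])
  idx <- sort(sample(same, 1000))
  s <- mk_calls(db$positions$chrom[idx], db$positions$pos[idx],
                db$genotype_matrix["S001", idx], rep(1, 1000))
  amb <- ambiguity_set(score_sample(s, db))
  expect_true(all(c("S001", "S002") %in% amb$strain))
  # direct L computation for both strains on this constructed query
  sc <- score_sample(s, db)
  expect_identical(sc$p_a[["S001"]], 1)
  expect_identical(sc$p_a[["S002"]], 1)
  expect_identical(sc$L_a[["S001"]], sc$L_a[["S002"]])
})

test_that("adding a site that matches only the true strain never worsens its rank", {
  withr::local_seed(43)
  for (rep in 1:20) {
    panel <- make_test_panel(n_strains = 6, n_snps = 300, seed = 500 + rep)
    db <- panel$db
    truth <- "S004"
    idx <- sort(sample(300, 80))
    codes <- db$genotype_matrix[truth, idx]
    flip <- sample(80, 3)
    codes[flip] <- 1L - codes[flip]
    s <- mk_calls(db$positions$chrom[idx], db$positions$pos[idx], codes, rep(1, 80))
    rank_of <- function(sc) rank(sc$L_a, ties.method = "min")[[truth]]
    r0 <- rank_of(score_sample(s, db))

    # extend with a site where the true strain differs from every other strain
    uniq <- setdiff(which(colSums(db$genotype_matrix !=
                      matrix(db$genotype_matrix[truth, ], nrow(db$genotype_matrix),
                             300, byrow = TRUE)) == nrow(db$genotype_matrix) - 1),
                    idx)
    if (!length(uniq)) next
    j <- uniq[1]
    s2 <- mk_calls(c(s$positions$chrom, db$positions$chrom[j]),
                   c(s$positions$pos, db$positions$pos[j]),
                   c(s$genotype_codes, db$genotype_matrix[truth, j]),
                   rep(1, 81))
    r1 <- rank_of(score_sample(s2, db))
    expect_lte(r1, r0)
  }
})

test_that("interpret_match applies the verdict rules in order", {
  panel <- make_test_panel(n_strains = 10, n_snps = 6000, seed = 53)
  db <- panel$db
  groups <- closeness_groups(db, threshold = 100)

  # error-free self-match against mutually distant strains: unique match
  q <- simulate_inbred_query(db, "S005",
                             query_spec(n_query_snps = 2500, error_rate = 0, seed = 2))
  v <- interpret_match(score_sample(q$sample, db), q$sample, groups)
  expect_identical(v$category, "unique_match")
  expect_identical(v$ambiguity_set, "S005")

  # below the SNP-count rule: insufficient regardless of fit
  q2 <- simulate_inbred_query(db, "S005",
                              query_spec(n_query_snps = 1500, seed = 3))
  v2 <- interpret_match(score_sample(q2$sample, db), q2$sample, groups)
  expect_identical(v2$category, "insufficient_snps")

  # an F2 shows enough heterozygous calls to trip the hybrid screen
  # (variant-only subsampling emulates a caller's het-enriched output)
  f2 <- simulate_f2(db, "S001", "S002",
                    query_spec(n_query_snps = 2500, variant_only = TRUE, seed = 4))
  expect_gte(heterozygosity_fraction(f2$sample), 0.10)
  v3 <- interpret_match(score_sample(f2$sample, db), f2$sample, groups)
  expect_identical(v3$category, "likely_hybrid")

  # a sample unrelated to every database strain matches nothing
  set.seed(56)
  rnd <- mk_calls(db$positions$chrom[1:2500], db$positions$pos[1:2500],
                  sample(0:1, 2500, replace = TRUE), rep(1, 2500))
  v4 <- interpret_match(score_sample(rnd, db), rnd, groups)
  expect_identical(v4$category, "no_match")

  # near-duplicate pair: ambiguous group contained in one closeness group
  panel2 <- make_test_panel(n_strains = 10, n_snps = 6000, seed = 55,
                            near_duplicate_pairs = list(
                              list(pair = c("S003", "S007"), distance = 2)))
  groups2 <- closeness_groups(panel2$db, threshold = 100)
  q5 <- simulate_inbred_query(panel2$db, "S003",
                              query_spec(n_query_snps = 2500, error_rate = 0, seed = 6))
  v5 <- interpret_match(score_sample(q5$sample, panel2$db), q5$sample, groups2)
  expect_identical(v5$category, "ambiguous_group")
  expect_true(setequal(v5$ambiguity_set, c("S003", "S007")))
  expect_true(v5$in_one_closeness_group)
})
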