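# Matching core: per-strain match probability, binomial likelihood statistic,
# chi-squared likelihood-ratio ambiguity set, and verdict interpretation.

#' Default likelihood-ratio cutoff
#'
#' The ambiguity set keeps every strain whose likelihood-ratio statistic
#' relative to the top hit does not exceed the 95th percentile of a
#' chi-squared distribution with one degree of freedom (3.841): those strains
#' are not significantly different from the best match at the 95% confidence
#' level.
#'
#' @return `qchisq(0.95, df = 1)`.
#' @export
default_lr_threshold <- function() stats::qchisq(0.95, df = 1)

#' Binomial likelihood statistic for a match probability
#'
#' For a strain with match probability `p_a` over `n_a` informative sites and
#' genotyping error rate `p`, the statistic is
#' \deqn{L_a = n_a [ p_a \ln(p_a / (1-p)) + (1-p_a) \ln((1-p_a) / p) ],}
#' the log-likelihood-ratio of the observed mismatch rate against the
#' null that the sample is the strain (mismatches arise only from genotyping
#' error at rate `p`). Equivalently `n_a` times the Kullback-Leibler
#' divergence of Bernoulli(`p_a`) from Bernoulli(`1-p`): non-negative, and
#' zero exactly at `p_a = 1-p`. Boundary values `p_a` of 0 or 1 use the
#' `0 * log(0) = 0` convention.
#'
#' @param p_a match probability in \[0, 1\] (vectorized).
#' @param n_a number of informative sites (vectorized).
#' @param error_rate genotyping error rate `p`, in (0, 1).
#' @return the statistic, same length as `p_a`.
#' @export
likelihood_statistic <- function(p_a, n_a, error_rate = 0.001) {
  if (error_rate <= 0 || error_rate >= 1) stop("error_rate must be in (0, 1)")
  stopifnot(all(p_a >= 0 & p_a <= 1), all(n_a >= 0))
  xlog <- function(x, y) ifelse(x == 0, 0, x * log(x / y))  # 0*ln0 := 0
  out <- xlog(p_a, 1 - error_rate) * n_a + xlog(1 - p_a, error_rate) * n_a
  # exactly zero at the null p_a = 1 - p (1 - p_a re-rounds away from p otherwise)
  out[p_a == 1 - error_rate] <- 0
  out
}

# One-pass position matching between a sample and the database. Returns the
# per-strain-by-shared-site informative and match indicators used by both the
# genome-wide and the windowed scorer.
match_sample_db <- function(sample, db) {
  stopifnot(inherits(sample, "sample_calls"), inherits(db, "genodb"))
  levels <- unique(c(db$chrom_levels, sample$positions$chrom))
  db_key <- pos_key(db$positions$chrom, db$positions$pos, levels)
  s_key <- pos_key(sample$positions$chrom, sample$positions$pos, levels)
  idx <- match(s_key, db_key)
  shared <- !is.na(idx)
  if (!any(shared))
    stop("no shared positions between sample and database; ",
         "check chromosome naming (e.g. 'Chr1' vs '1')")
  g <- db$genotype_matrix[, idx[shared], drop = FALSE]  # strains x shared sites
  codes <- sample$genotype_codes[shared]
  informative <- g >= 0L
  match_ind <- sweep(g, 2, codes, "==") & informative
  list(shared = shared,                      # which sample calls hit the db
       informative = informative,            # strains x shared
       match = match_ind,                    # strains x shared
       conf = sample$call_confidence[shared],
       chrom = sample$positions$chrom[shared],
       pos = sample$positions$pos[shared])
}

scores_from_indicators <- function(informative, match_ind, conf, strain_ids,
                                   n_total, error_rate) {
  n_a <- as.integer(rowSums(informative))
  score_a <- as.numeric(match_ind %*% conf)
  p_a <- ifelse(n_a > 0, score_a / n_a, 0)
  L_a <- likelihood_statistic(p_a, n_a, error_rate)
  L_a[n_a == 0] <- NA_real_
  structure(list(
    strain_ids = strain_ids,
    n_a = stats::setNames(n_a, strain_ids),
    score_a = stats::setNames(score_a, strain_ids),
    p_a = stats::setNames(p_a, strain_ids),
    L_a = stats::setNames(L_a, strain_ids),
    unscorable = stats::setNames(n_a == 0L, strain_ids),
    error_rate = error_rate,
    n_total = n_total
  ), class = "match_scores")
}

#' Score a query sample against every database strain
#'
#' For each strain, counts informative sites (positions where both the sample
#' and the strain have non-missing calls), sums the call confidences at sites
#' where the genotype codes agree, and forms the match probability
#' `p_a = score_a / n_a` and the binomial likelihood statistic `L_a`
#' ([likelihood_statistic()]). Heterozygous sample calls match only
#' heterozygous database codes (exact code equality). Strains with no
#' informative sites are flagged unscorable.
#'
#' @param sample a `sample_calls` object.
#' @param db a `genodb` object.
#' @param error_rate assumed genotyping error rate, in (0, 0.5).
#' @return a `match_scores` object with per-strain `n_a`, `score_a`, `p_a`,
#'   `L_a` and an `unscorable` flag.
#' @export
score_sample <- function(sample, db, error_rate = 0.001) {
  if (error_rate <= 0 || error_rate >= 0.5) stop("error_rate must be in (0, 0.5)")
  m <- match_sample_db(sample, db)
  scores_from_indicators(m$informative, m$match, m$conf, db$strain_ids,
                         sample$n_total, error_rate)
}

#' @export
print.match_scores <- function(x, ...) {
  amb <- ambiguity_set(x)
  cat("Match scores over", length(x$strain_ids), "strain(s);",
      "sample calls:", x$n_total, "\n")
  cat("Top hits (LR <= ", round(default_lr_threshold(), 3), "):\n", sep = "")
  print(utils::head(amb, 10), row.names = FALSE)
  invisible(x)
}

# Likelihood-ratio values with the degenerate-best guard. The statistic
# vanishes continuously as the best hit's mismatch rate approaches the model
# error rate, so a raw ratio against it is unstable at resolution finer than
# one mismatched site. Both numerator and denominator are therefore floored at
# the statistic of a single mismatch out of the best hit's n_a sites — the
# smallest imperfection the data can distinguish. The best hit keeps LR = 1,
# and whenever L_best is at or above the floor the ratios are the plain L/L_best.
lr_values <- function(L, n_a, error_rate) {
  i <- which.min(L)
  n <- max(n_a[i], 3L)
  floor_L <- likelihood_statistic((n - 1) / n, n, error_rate)
  if (floor_L <= 0)  # n == 1/error_rate: one mismatch IS the null expectation
    floor_L <- likelihood_statistic((n - 2) / n, n, error_rate)
  pmax(L, floor_L) / max(L[i], floor_L)
}

#' Likelihood-ratio ambiguity set
#'
#' Ratios every strain's likelihood statistic against the best (minimal) one,
#' so the top hit has LR 1, and returns all strains with LR at or below the
#' chi-squared cutoff — the set of strains not significantly different from
#' the top hit. The best statistic approaches 0 as the top hit's mismatch
#' rate approaches the assumed error rate, which would let the ratio blow up
#' on differences finer than a single genotype call; both sides of the ratio
#' are therefore floored at the statistic of one mismatch out of the top
#' hit's `n_a` sites — the smallest imperfection the data can distinguish.
#' The top hit always has LR 1, and the floor is inactive whenever the best
#' statistic is at least one mismatch's worth.
#'
#' @param scores a `match_scores` object.
#' @param lr_threshold likelihood-ratio cutoff; default
#'   [default_lr_threshold()], the 95% chi-squared(1) quantile 3.841.
#' @return a data.frame (strain, n, p, L, LR), sorted by L ascending, of the
#'   strains inside the cutoff.
#' @export
ambiguity_set <- function(scores, lr_threshold = default_lr_threshold()) {
  stopifnot(inherits(scores, "match_scores"))
  ok <- !scores$unscorable
  if (!any(ok)) stop("all strains unscorable: no informative sites")
  L <- scores$L_a[ok]
  LR <- lr_values(L, scores$n_a[ok], scores$error_rate)
  keep <- LR <= lr_threshold
  out <- data.frame(strain = scores$strain_ids[ok][keep],
                    n = scores$n_a[ok][keep],
                    p = scores$p_a[ok][keep],
                    L = L[keep],
                    LR = LR[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$L), , drop = FALSE]
}

#' Interpret match scores into a verdict
#'
#' Applies, in order: an insufficient-data rule (fewer than `min_snps` calls),
#' a hybrid screen (heterozygosity at or above `het_threshold` flags a likely
#' F1/F2 — follow up with the windowed cross analysis), a no-match rule (best
#' match probability below `match_prob_floor`), then unique match versus
#' ambiguous group according to the size of the likelihood-ratio ambiguity
#' set. For ambiguous groups the verdict notes whether the set lies within a
#' single closeness group of the database.
#'
#' @param scores a `match_scores` object from [score_sample()].
#' @param sample the scored `sample_calls` object.
#' @param db_groups optional `closeness_groups` for the database.
#' @param min_snps minimum number of sample calls for analysis.
#' @param match_prob_floor best-hit match probability below which the sample
#'   matches no database strain.
#' @param het_threshold heterozygosity fraction that triggers the hybrid flag.
#' @param lr_threshold cutoff passed to [ambiguity_set()].
#' @return a `match_verdict` object: `category` is one of `unique_match`,
#'   `ambiguous_group`, `no_match`, `likely_hybrid`, `insufficient_snps`.
#' @export
interpret_match <- function(scores, sample, db_groups = NULL,
                            min_snps = 2000, match_prob_floor = 0.90,
                            het_threshold = 0.10,
                            lr_threshold = default_lr_threshold()) {
  stopifnot(inherits(scores, "match_scores"), inherits(sample, "sample_calls"))
  het <- heterozygosity_fraction(sample)
  verdict <- function(category, amb = character(0), in_one_group = NA) {
    structure(list(
      category = category,
      ambiguity_set = amb,
      in_one_closeness_group = in_one_group,
      heterozygosity = het,
      diagnostics = list(n_total = sample$n_total,
                         best_strain = if (any(!scores$unscorable))
                           names(which.min(scores$L_a)) else NA_character_,
                         best_p = if (any(!scores$unscorable))
                           max(scores$p_a[!scores$unscorable]) else NA_real_,
                         best_n = if (any(!scores$unscorable))
                           scores$n_a[[names(which.min(scores$L_a))]] else NA_integer_),
      parameters = list(min_snps = min_snps, match_prob_floor = match_prob_floor,
                        het_threshold = het_threshold, lr_threshold = lr_threshold,
                        error_rate = scores$error_rate)
    ), class = "match_verdict")
  }

  if (sample$n_total < min_snps) return(verdict("insufficient_snps"))
  amb <- ambiguity_set(scores, lr_threshold)
  if (het >= het_threshold) return(verdict("likely_hybrid", amb$strain))
  best_p <- max(scores$p_a[!scores$unscorable])
  if (best_p < match_prob_floor) return(verdict("no_match", amb$strain))
  if (nrow(amb) == 1) return(verdict("unique_match", amb$strain))
  in_one <- if (!is.null(db_groups)) {
    g <- unique(group_of(db_groups, amb$strain))
    length(g) == 1 && !anyNA(g)
  } else NA
  verdict("ambiguous_group", amb$strain, in_one)
}

#' @export
print.match_verdict <- function(x, ...) {
  cat("Verdict:", x$category, "\n")
  cat("  calls:", x$diagnostics$n_total,
      " best p:", signif(x$diagnostics$best_p, 4),
      " het:", signif(x$heterozygosity, 4), "\n")
  if (length(x$ambiguity_set))
    cat("  ambiguity set (", length(x$ambiguity_set), "): ",
        paste(utils::head(x$ambiguity_set, 8), collapse = ", "),
        if (length(x$ambiguity_set) > 8) ", ..." else "", "\n", sep = "")
  if (identical(x$category, "likely_hybrid"))
    cat("  hint: run the windowed cross analysis to identify the parents\n")
  invisible(x)
}
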