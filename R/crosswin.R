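# Windowed matching: genome tiling, per-window ambiguity sets, and parent-pair
# inference for F1/F2 hybrids.

#' Chromosome lengths of the A. thaliana TAIR10 assembly
#'
#' The default chromosome-length table for window tiling. For other species,
#' supply your own named vector or edit a copy of the shipped config file
#' (`system.file("extdata", "tair10_chrlen.tsv", package = "strainmatch")`).
#'
#' @return named integer vector of chromosome lengths in bp.
#' @export
tair10_chrlen <- function() {
  c(`1` = 30427671L, `2` = 19698289L, `3` = 23459830L,
    `4` = 18585056L, `5` = 26975502L)
}

#' Read a chromosome-length table
#'
#' Two whitespace-separated columns: chromosome name, length in bp. Lines
#' starting with `#` are ignored. Chromosome names are normalized with
#' [norm_chrom()].
#'
#' @param path path to the table.
#' @param strip_chr_prefix normalize chromosome names.
#' @return named integer vector of lengths.
#' @export
read_chrlen <- function(path, strip_chr_prefix = TRUE) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (any(tab$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(tab$length, norm_chrom(tab$chrom, strip_chr_prefix))
}

#' Tile a genome into non-overlapping windows
#'
#' Each chromosome is tiled with contiguous windows of `window_size` bp;
#' windows are half-open 1-based intervals `[start, end)` covering
#' `[1, length]`, the last window possibly shorter. A window size exceeding a
#' chromosome's length yields a single window for that chromosome.
#'
#' @param chrlen named vector of chromosome lengths in bp.
#' @param window_size window width in bp (default 300 kb).
#' @return a `genome_windows` object: data.frame (chrom, start, end, window_id)
#'   with attributes `chrlen` and `window_size`.
#' @export
make_windows <- function(chrlen = tair10_chrlen(), window_size = 300000) {
  stopifnot(window_size > 0, all(chrlen > 0), !is.null(names(chrlen)))
  per_chrom <- lapply(names(chrlen), function(cn) {
    L <- chrlen[[cn]]
    starts <- seq.int(1L, L, by = window_size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + window_size, L + 1),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, per_chrom)
  w$window_id <- paste0(w$chrom, ":", w$start, "-", w$end - 1)
  structure(w, class = c("genome_windows", "data.frame"),
            chrlen = chrlen, window_size = window_size)
}

# Window index (row of `windows`) for each (chrom, pos); NA when the position
# falls on a chromosome absent from the tiling or beyond its length.
assign_windows <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(chrom))
  for (cn in unique(chrom)) {
    rows <- which(windows$chrom == cn)
    if (!length(rows)) next
    sel <- chrom == cn
    j <- findInterval(pos[sel], windows$start[rows])
    j[j < 1 | pos[sel] >= max(windows$end[rows])] <- NA_integer_
    idx[sel] <- rows[j]
  }
  idx
}

#' Score a sample in genomic windows
#'
#' Runs the matcher independently on the sample calls falling in each genome
#' window: per window it computes informative-site counts, likelihood
#' statistics and the likelihood-ratio ambiguity set, exactly as
#' [score_sample()] + [ambiguity_set()] restricted to the window's sites.
#' Windows with fewer than `min_window_snps` informative sites (for the
#' best-covered strain) are labelled uninformative. For an inbred sample
#' every informative window's set contains the true strain; for an F2 hybrid
#' the sets alternate between the two parents along the genome.
#'
#' @param sample a `sample_calls` object.
#' @param db a `genodb` object.
#' @param windows a `genome_windows` object from [make_windows()].
#' @param error_rate genotyping error rate for the likelihood statistic.
#' @param lr_threshold likelihood-ratio cutoff for the per-window sets.
#' @param min_window_snps minimum informative sites for a window to be scored.
#' @return a `window_results` object: list with `table` (data.frame: chrom,
#'   start, end, n_informative, status, set members collapsed by comma),
#'   `sets` (list of per-window ambiguity-set data.frames), `genome_scores`
#'   (the genome-wide `match_scores`), plus the parameters.
#' @export
window_scores <- function(sample, db, windows = make_windows(),
                          error_rate = 0.001,
                          lr_threshold = default_lr_threshold(),
                          min_window_snps = 10) {
  m <- match_sample_db(sample, db)
  genome_scores <- scores_from_indicators(m$informative, m$match, m$conf,
                                          db$strain_ids, sample$n_total,
                                          error_rate)
  widx <- assign_windows(m$chrom, m$pos, windows)

  n_win <- nrow(windows)
  sets <- vector("list", n_win)
  n_informative <- integer(n_win)
  status <- rep("uninformative", n_win)
  for (w in seq_len(n_win)) {
    cols <- which(widx == w)
    if (!length(cols)) next
    sc <- scores_from_indicators(m$informative[, cols, drop = FALSE],
                                 m$match[, cols, drop = FALSE],
                                 m$conf[cols], db$strain_ids,
                                 length(cols), error_rate)
    n_informative[w] <- max(sc$n_a)
    if (n_informative[w] < min_window_snps) next
    sets[[w]] <- ambiguity_set(sc, lr_threshold)
    status[w] <- "informative"
  }

  tab <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_informative = n_informative,
                    status = status,
                    set = vapply(sets, function(s)
                      if (is.null(s)) "" else paste(s$strain, collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, sets = sets, windows = windows,
                 genome_scores = genome_scores,
                 parameters = list(error_rate = error_rate,
                                   lr_threshold = lr_threshold,
                                   min_window_snps = min_window_snps)),
            class = "window_results")
}

#' @export
print.window_results <- function(x, ...) {
  n_inf <- sum(x$table$status == "informative")
  cat("Windowed match results: ", nrow(x$table), " window(s), ",
      n_inf, " informative\n", sep = "")
  invisible(x)
}

#' Infer the two parents of a hybrid from windowed match results
#'
#' Candidate parents are the strains appearing in window-level ambiguity sets
#' together with the genome-wide top `top_k` hits. The reported pair (A, B)
#' maximizes the number of informative windows whose ambiguity set intersects
#' `{A, B}` in exactly one strain (a window explained by one parent); ties
#' break towards the pair with the more balanced per-parent support. Windows
#' whose set contains both parents — the heterozygous blocks of an F2 — count
#' as ambiguous, not as evidence against the pair, so for a typical F2 about
#' half the windows are "explained" and the rest ambiguous. If the weaker
#' parent explains less than `min_parent_fraction` of informative windows the
#' sample is flagged as not a cross (an inbred degenerate case). A note is
#' attached when the best pair explains fewer than 80% of informative
#' windows, which is expected for F2s.
#'
#' @param wres a `window_results` object from [window_scores()].
#' @param top_k genome-wide top hits added to the candidate set.
#' @param min_parent_fraction minimal fraction of informative windows the
#'   weaker parent must explain for the sample to be called a cross.
#' @param db_groups optional `closeness_groups` of the database; other members
#'   of an inferred parent's group are reported as `alternatives` — windowed
#'   matching cannot tell a parent from its near-duplicate.
#' @return a `parent_call` object: list with `parents` (character 2 or 1),
#'   `is_cross`, per-parent window counts, fraction of windows explained,
#'   per-window labels (`parent_A`, `parent_B`, `ambiguous`, `uninformative`)
#'   aligned with the window table, alternatives from the pair's closeness
#'   neighbourhood if supplied, and a `note`.
#' @export
infer_parents <- function(wres, top_k = 10, min_parent_fraction = 0.05,
                          db_groups = NULL) {
  stopifnot(inherits(wres, "window_results"))
  inf_idx <- which(wres$table$status == "informative")
  if (length(inf_idx) < 2) stop("insufficient windows: need >= 2 informative windows")
  sets <- lapply(wres$sets[inf_idx], `[[`, "strain")

  gs <- wres$genome_scores
  ok <- !gs$unscorable
  top <- names(sort(gs$L_a[ok]))[seq_len(min(top_k, sum(ok)))]
  candidates <- union(unlist(sets), top)

  # windows x candidates membership matrix
  memb <- vapply(candidates, function(s)
    vapply(sets, function(set) s %in% set, logical(1)),
    logical(length(sets)))
  memb <- matrix(memb, nrow = length(sets),
                 dimnames = list(NULL, candidates))

  best <- list(score = -1, balance = -1, pair = NULL, nA = 0, nB = 0)
  nc <- length(candidates)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (j <= i) next
    inA <- memb[, i]; inB <- memb[, j]
    nA <- sum(inA & !inB); nB <- sum(inB & !inA)
    expl <- nA + nB
    bal <- min(nA, nB)
    if (expl > best$score || (expl == best$score && bal > best$balance)) {
      best <- list(score = expl, balance = bal,
                   pair = candidates[c(i, j)], nA = nA, nB = nB)
    }
  }

  n_inf <- length(sets)
  frac_explained <- best$score / n_inf
  # order pair by support, strongest first
  if (best$nB > best$nA) {
    best$pair <- rev(best$pair); tmp <- best$nA; best$nA <- best$nB; best$nB <- tmp
  }
  weaker_frac <- best$nB / n_inf
  is_cross <- weaker_frac >= min_parent_fraction

  labels <- rep("uninformative", nrow(wres$table))
  if (is_cross) {
    inA <- memb[, best$pair[1]]; inB <- memb[, best$pair[2]]
    lab <- ifelse(inA & !inB, "parent_A", ifelse(inB & !inA, "parent_B", "ambiguous"))
    labels[inf_idx] <- lab
  } else {
    labels[inf_idx] <- ifelse(memb[, best$pair[1]], "parent_A", "ambiguous")
  }

  note <- character(0)
  if (!is_cross)
    note <- c(note, paste0("not a cross: best strain '", best$pair[1],
                           "' explains the genome alone"))
  if (frac_explained < 0.80)
    note <- c(note, sprintf(paste0("best pair explains %.0f%% of informative ",
                                   "windows (heterozygous F2 blocks are ambiguous ",
                                   "by design)"), 100 * frac_explained))

  parents <- if (is_cross) best$pair else best$pair[1]
  alternatives <- if (!is.null(db_groups)) {
    grp <- unlist(db_groups$groups[unique(group_of(db_groups, parents))])
    setdiff(grp, parents)
  } else character(0)

  structure(list(
    parents = parents,
    alternatives = alternatives,
    is_cross = is_cross,
    windows_parent_A = best$nA,
    windows_parent_B = if (is_cross) best$nB else 0L,
    n_informative_windows = n_inf,
    fraction_explained = frac_explained,
    labels = labels,
    note = note
  ), class = "parent_call")
}

#' @export
print.parent_call <- function(x, ...) {
  if (x$is_cross) {
    cat("Inferred cross: ", x$parents[1], " x ", x$parents[2], "\n", sep = "")
    cat("  windows: ", x$windows_parent_A, " parent A, ", x$windows_parent_B,
        " parent B, of ", x$n_informative_windows, " informative\n", sep = "")
  } else {
    cat("Not a cross; best match: ", x$parents[1], "\n", sep = "")
  }
  if (length(x$alternatives))
    cat("  near-duplicate alternatives: ",
        paste(x$alternatives, collapse = ", "), "\n", sep = "")
  for (n in x$note) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Write per-window results as a tab-separated table
#'
#' Columns: chrom, start, end, n_informative, label (when a `parent_call` is
#' supplied) or status, and the comma-separated ambiguity-set members —
#' suitable for plotting parental-block tracks along the genome.
#'
#' @param wres a `window_results` object.
#' @param path output path.
#' @param parents optional `parent_call` whose labels replace the status column.
#' @return invisibly, `path`.
#' @export
write_window_table <- function(wres, path, parents = NULL) {
  tab <- wres$table
  if (!is.null(parents)) tab$status <- parents$labels
  names(tab)[names(tab) == "status"] <- "label"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
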