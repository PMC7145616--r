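# Cross-study comparison: duplicate detection by gene-score correlation,
# tissue-centric trait overlap statistics, and multi-study result alignment.

#' Pairwise study similarity and duplicate detection
#'
#' Pearson correlation of gene-based P-values over each pair's common
#' successfully scored genes. Pairs with correlation above the duplicate
#' threshold are flagged; within a duplicate group the first study by ID is
#' retained (deterministic), or a seeded random member with
#' \code{random_keep}.
#'
#' @param tables list of \code{gene_score_table} objects (>= 2).
#' @param threshold duplicate threshold on the correlation (default 0.99,
#'   strict: a pair at exactly 0.99 is retained as distinct).
#' @param min_common minimum number of common genes to compare a pair
#'   (default 100); pairs below it are skipped with a warning.
#' @param use_log10 correlate -log10 P instead of raw P (default FALSE).
#' @param random_keep,seed choose the retained study of each duplicate group
#'   at random (seeded) instead of first-by-ID.
#' @return object of class \code{study_similarity}: list with \code{pairs}
#'   (data.frame: study_a, study_b, pcc, n_common_genes, duplicate) and
#'   \code{retained} (character vector of study IDs kept after dedup).
#' @export
pairwise_pcc <- function(tables, threshold = 0.99, min_common = 100L,
                         use_log10 = FALSE, random_keep = FALSE, seed = 1L) {
  if (length(tables) < 2) stop("need at least two gene-score tables")
  ids <- vapply(tables, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop("duplicate study IDs")
  vecs <- lapply(tables, function(gs) {
    ok <- gs$table[gs$table$status == "ok", ]
    v <- stats::setNames(ok$pvalue, ok$gene_id)
    if (use_log10) -log10(v) else v
  })
  names(vecs) <- ids
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    common <- intersect(names(vecs[[pr[1]]]), names(vecs[[pr[2]]]))
    if (length(common) < min_common) {
      warning("pair ", pr[1], " / ", pr[2], ": only ", length(common),
              " common genes; skipped")
      return(NULL)
    }
    pcc <- stats::cor(vecs[[pr[1]]][common], vecs[[pr[2]]][common])
    data.frame(study_a = pr[1], study_b = pr[2], pcc = pcc,
               n_common_genes = length(common), duplicate = pcc > threshold,
               stringsAsFactors = FALSE)
  })
  pairs_df <- do.call(rbind, rows)
  # connected components over duplicate edges; keep one study per group
  retained <- ids
  if (!is.null(pairs_df) && any(pairs_df$duplicate)) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in which(pairs_df$duplicate)) {
      ra <- find(pairs_df$study_a[i]); rb <- find(pairs_df$study_b[i])
      if (ra != rb) parent[[rb]] <- ra
    }
    roots <- vapply(ids, find, "")
    if (random_keep) set.seed(seed)
    keep <- vapply(split(ids, roots), function(grp) {
      grp <- sort(grp)
      if (random_keep) sample(grp, 1) else grp[1]
    }, "")
    retained <- sort(unname(keep))
  }
  structure(list(pairs = pairs_df, retained = retained),
            class = "study_similarity")
}

#' Overlap of trait sets associated with two tissues
#'
#' Given the studies associated with tissue A (e.g. in one expression panel)
#' and tissue B (e.g. its counterpart in another panel) out of a universe of
#' studies, reports the overlap count, the overlap as a percentage of each
#' set (one decimal), and a one-sided Fisher exact P-value for
#' over-overlap.
#'
#' @param assoc_a,assoc_b character vectors of study IDs.
#' @param universe_n total number of studies the sets are drawn from.
#' @return object of class \code{overlap_stat}: list with \code{n_a},
#'   \code{n_b}, \code{n_overlap}, \code{n_universe}, \code{pct_of_a},
#'   \code{pct_of_b}, \code{fisher_p}.
#' @export
tissue_trait_overlap <- function(assoc_a, assoc_b, universe_n) {
  assoc_a <- unique(assoc_a); assoc_b <- unique(assoc_b)
  n_union <- length(union(assoc_a, assoc_b))
  if (universe_n < n_union)
    stop("universe_n (", universe_n, ") smaller than the union of the sets (",
         n_union, ")")
  n_a <- length(assoc_a); n_b <- length(assoc_b)
  ov <- length(intersect(assoc_a, assoc_b))
  tab <- matrix(c(ov, n_a - ov, n_b - ov, universe_n - n_a - n_b + ov), 2)
  fp <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(n_a = n_a, n_b = n_b, n_overlap = ov,
                 n_universe = universe_n,
                 pct_of_a = format_pct(ov, n_a),
                 pct_of_b = format_pct(ov, n_b),
                 fisher_p = fp),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("Overlap: %d studies (%.1f%% of A [n=%d], %.1f%% of B [n=%d]); Fisher one-sided P = %.3g\n",
              x$n_overlap, x$pct_of_a, x$n_a, x$pct_of_b, x$n_b, x$fisher_p))
  invisible(x)
}

#' Align multiple studies' enrichment results into one long table
#'
#' @param results list of \code{tsea_result} objects from the same panel
#'   (at most \code{max_studies}).
#' @param max_studies cap on the number of studies compared at once
#'   (default 10).
#' @return data.frame: study, tissue, threshold, pvalue, neg_log10_p.
#'   Cells absent because a TAG set was unqualified are missing (NA),
#'   never imputed.
#' @export
comparison_matrix <- function(results, max_studies = 10L) {
  if (length(results) > max_studies)
    stop("at most ", max_studies, " studies can be compared at once (got ",
         length(results), ")")
  panels <- unique(vapply(results, `[[`, "", "panel_id"))
  if (length(panels) > 1)
    stop("results come from different panels: ", paste(panels, collapse = ", "))
  long <- do.call(rbind, lapply(results, function(r) {
    df <- expand.grid(tissue = rownames(r$pvalues),
                      threshold = colnames(r$pvalues),
                      stringsAsFactors = FALSE)
    df$study <- r$study_id
    df$pvalue <- r$pvalues[cbind(df$tissue, df$threshold)]
    df
  }))
  long$neg_log10_p <- -log10(long$pvalue)
  long[, c("study", "tissue", "threshold", "pvalue", "neg_log10_p")]
}
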