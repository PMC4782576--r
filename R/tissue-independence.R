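# Differential methylation by t-test with rank-based DM labelling,
# phenotype-mean profiles, cross-cancer R^2 matrices and the
# own-normal vs other-normal comparison.

#' Per-region two-sample t-tests (cancer vs normal)
#'
#' Welch t-tests by default (`pooled = TRUE` for the classical pooled
#' variance test), oriented so positive t means higher methylation in
#' cancer.  Regions with zero variance in both groups are excluded (ids
#' returned in the `excluded` attribute).
#'
#' @param region_betas Region x sample matrix.
#' @param normal_ids,cancer_ids Column ids of the two groups (>= 2 each).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return `data.frame(region_id, t, p)` with attribute `excluded`.
#' @export
dm_t_test <- function(region_betas, normal_ids, cancer_ids, pooled = FALSE) {
  if (length(normal_ids) < 2 || length(cancer_ids) < 2) {
    stopf("need >= 2 samples per group")
  }
  xn <- region_betas[, normal_ids, drop = FALSE]
  xc <- region_betas[, cancer_ids, drop = FALSE]
  vn <- apply(xn, 1, stats::var)
  vc <- apply(xc, 1, stats::var)
  keep <- !(vn == 0 & vc == 0)
  res <- t(vapply(which(keep), function(i) {
    tt <- stats::t.test(xc[i, ], xn[i, ], var.equal = pooled)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2)))
  out <- data.frame(region_id = rownames(region_betas)[keep],
                    t = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- rownames(region_betas)[!keep]
  out
}

#' Rank regions by t statistic and label top/bottom N
#'
#' Hypermethylation direction sorts by t descending; hypomethylation by
#' t ascending (equivalently by negative t descending, as used for gene
#' bodies).  The top N become `DM`, the bottom N `nonDM`; ties are
#' broken by region id.  Default N = 300.
#'
#' @param tstats `data.frame(region_id, t)` (e.g. from [dm_t_test()]).
#' @param N Number of regions per label.
#' @param direction `"hyper"` or `"hypo"`.
#' @return `data.frame(region_id, t, rank, label)` sorted by rank;
#'   label in `{DM, nonDM, unlabeled}`.
#' @export
rank_and_label <- function(tstats, N = 300, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  n <- nrow(tstats)
  if (2 * N > n) stopf("2N = %d exceeds number of regions (%d)", 2 * N, n)
  key <- if (direction == "hyper") -tstats$t else tstats$t
  ord <- order(key, tstats$region_id)
  out <- tstats[ord, c("region_id", "t")]
  out$rank <- seq_len(n)
  out$label <- "unlabeled"
  out$label[seq_len(N)] <- "DM"
  out$label[seq(n - N + 1, n)] <- "nonDM"
  rownames(out) <- NULL
  out
}

#' Per-region mean beta over a sample group
#'
#' @param region_betas Region x sample matrix.
#' @param sample_ids Columns to average (>= 1).
#' @return Named vector of mean beta per region.
#' @export
phenotype_mean_profile <- function(region_betas, sample_ids) {
  if (!length(sample_ids)) stopf("empty sample group")
  rowMeans(region_betas[, sample_ids, drop = FALSE], na.rm = TRUE)
}

#' Pairwise R^2 matrix between phenotype profiles
#'
#' Pearson correlations of mean-methylation profiles over a shared
#' region subset, squared.  The matrix is symmetric with unit diagonal;
#' zero-variance profiles give `NA` entries (flagged by a warning).
#'
#' @param profiles Named list of per-region mean vectors (shared names),
#'   or a region x phenotype matrix.
#' @param region_subset Region ids to use (default: all shared).
#' @return List: `r2` (matrix), `r` (signed correlations),
#'   `mean_offdiag` (mean off-diagonal R^2), `n_regions`.
#' @export
pairwise_r2 <- function(profiles, region_subset = NULL) {
  if (is.list(profiles)) {
    ids <- Reduce(intersect, lapply(profiles, names))
    profiles <- vapply(profiles, function(p) p[ids], numeric(length(ids)))
    rownames(profiles) <- ids
  }
  if (!is.null(region_subset)) {
    profiles <- profiles[intersect(region_subset, rownames(profiles)), ,
                         drop = FALSE]
  }
  if (nrow(profiles) < 3) stopf("need >= 3 regions")
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) warnf("zero-variance profile(s): %s",
                           paste(colnames(profiles)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(profiles))
  r[!is.finite(r)] <- NA
  diag(r) <- 1
  r2 <- r^2
  off <- r2[upper.tri(r2)]
  list(r2 = r2, r = r, mean_offdiag = mean(off, na.rm = TRUE),
       n_regions = nrow(profiles))
}

#' Are cancers more similar to their own normal tissue?
#'
#' Two-sample t-test comparing the diagonal of a cancer x normal R^2
#' matrix (each cancer vs its own normal) against the off-diagonal
#' entries (cancer vs other tissues' normals).  Positive t means own
#' normals correlate more strongly.
#'
#' @param r2_matrix Square matrix, rows = cancers, cols = normals of the
#'   same tissue ordering (>= 3 tissues).
#' @param per_cancer Average off-diagonal entries within each cancer
#'   first instead of pooling all entries.
#' @return `htest`-like list: `t`, `p`, `mean_own`, `mean_other`.
#' @export
own_vs_other_normal_test <- function(r2_matrix, per_cancer = FALSE) {
  if (nrow(r2_matrix) != ncol(r2_matrix) || nrow(r2_matrix) < 3) {
    stopf("need a square R^2 matrix with >= 3 tissues")
  }
  own <- diag(r2_matrix)
  offm <- r2_matrix; diag(offm) <- NA
  other <- if (per_cancer) rowMeans(offm, na.rm = TRUE)
           else offm[!is.na(offm)]
  tt <- stats::t.test(own, other)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_own = mean(own), mean_other = mean(other))
}

#' Regions ranked by methylation in a reference cancer, plot-ready
#'
#' Sorts regions by the reference phenotype's mean beta (descending,
#' ties by region id), truncates to the top `n` (default 1500, the
#' heatmap size used for the tissue-independence figure) and carries all
#' phenotype columns along.
#'
#' @param profiles Region x phenotype matrix (or named list of vectors).
#' @param reference Column name of the reference cancer phenotype.
#' @param n Number of top regions.
#' @return Data frame: `region_id` then one column per phenotype.
#' @export
top_ranked_matrix <- function(profiles, reference, n = 1500) {
  if (is.list(profiles)) {
    ids <- Reduce(intersect, lapply(profiles, names))
    profiles <- vapply(profiles, function(p) p[ids], numeric(length(ids)))
    rownames(profiles) <- ids
  }
  if (!reference %in% colnames(profiles)) {
    stopf("unknown reference phenotype '%s'", reference)
  }
  if (n > nrow(profiles)) stopf("n exceeds number of regions")
  ord <- order(-profiles[, reference], rownames(profiles))
  out <- data.frame(region_id = rownames(profiles)[ord][seq_len(n)],
                    profiles[ord[seq_len(n)], , drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
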