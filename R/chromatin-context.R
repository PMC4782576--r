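# Promoter stratification by DNase hypersensitivity and bivalency in
# normal tissue, with per-stratum normal-vs-cancer t statistics.

#' Stratify promoters by DHS membership
#'
#' A promoter is `in` when its window overlaps any DHS interval of the
#' tissue's set (half-open semantics at the BED boundary).
#'
#' @param promoter_windows GRanges of promoter windows, named by gene.
#' @param dhs_set GRanges of DHS intervals.
#' @return Named character vector in `{"in","out"}`.
#' @export
dhs_stratify <- function(promoter_windows, dhs_set) {
  hit <- overlaps_any(promoter_windows, dhs_set)
  stats::setNames(ifelse(hit, "in", "out"), names(promoter_windows))
}

#' Call bivalent promoters from H3K4me3 and H3K27me3 signals
#'
#' Quantile rule: a gene is bivalent when both promoter signals exceed
#' their mark-specific `q`-quantile cutoff (default upper quartile).
#' Genes missing either signal are excluded.
#'
#' @param k4,k27 Named per-gene promoter signal vectors.
#' @param q Quantile cutoff in (0,1).
#' @return Character vector of bivalent gene ids, with attribute
#'   `excluded` (genes missing a signal).
#' @export
call_bivalent <- function(k4, k27, q = 0.75) {
  stopifnot(q > 0, q < 1)
  ids <- intersect(names(k4), names(k27))
  k4 <- k4[ids]; k27 <- k27[ids]
  ok <- !is.na(k4) & !is.na(k27)
  excluded <- ids[!ok]
  k4 <- k4[ok]; k27 <- k27[ok]
  cut4 <- stats::quantile(k4, q, names = FALSE)
  cut27 <- stats::quantile(k27, q, names = FALSE)
  out <- names(k4)[k4 > cut4 & k27 > cut27]
  attr(out, "excluded") <- excluded
  out
}

#' Normal-vs-cancer t statistics within promoter strata
#'
#' Within each stratum, per-gene phenotype means are pooled across
#' genes and compared with a two-sample Welch t-test (cancer minus
#' normal; positive t = hypermethylation).  `unit = "genes"` (default)
#' compares per-gene phenotype-mean beta across genes; `unit =
#' "samples"` compares per-sample stratum means across samples.
#'
#' @param region_betas Region x sample matrix (promoter level).
#' @param normal_ids,cancer_ids Sample columns per phenotype (>= 2).
#' @param strata Named character vector (gene -> stratum).
#' @param unit Unit of analysis (see above).
#' @return `data.frame(stratum, n_genes, mean_normal, mean_cancer, t, p)`.
#' @export
stratified_normal_cancer_t <- function(region_betas, normal_ids, cancer_ids,
                                       strata, unit = c("genes", "samples")) {
  unit <- match.arg(unit)
  if (length(normal_ids) < 2 || length(cancer_ids) < 2) {
    stopf("need >= 2 samples per phenotype")
  }
  ids <- intersect(rownames(region_betas), names(strata))
  out <- NULL
  for (st in sort(unique(strata[ids]))) {
    genes <- ids[strata[ids] == st]
    if (length(genes) < 3) {
      warnf("stratum '%s' has < 3 genes; skipped", st)
      next
    }
    mn <- phenotype_mean_profile(region_betas[genes, , drop = FALSE],
                                 normal_ids)
    mc <- phenotype_mean_profile(region_betas[genes, , drop = FALSE],
                                 cancer_ids)
    if (unit == "genes") {
      tt <- stats::t.test(mc, mn)
    } else {
      sn <- colMeans(region_betas[genes, normal_ids, drop = FALSE],
                     na.rm = TRUE)
      sc <- colMeans(region_betas[genes, cancer_ids, drop = FALSE],
                     na.rm = TRUE)
      tt <- stats::t.test(sc, sn)
    }
    out <- rbind(out, data.frame(
      stratum = st, n_genes = length(genes),
      mean_normal = mean(mn), mean_cancer = mean(mc),
      t = unname(tt$statistic), p = tt$p.value,
      stringsAsFactors = FALSE))
  }
  out
}
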