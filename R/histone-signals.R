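# ChIP-seq signal aggregation: bedGraph tracks carrying S = -log10 P,
# per-gene promoter/body mean signals, promoter window tuning against
# expression, hESC reference-line selection, and expression flooring.

#' Read a bedGraph signal track
#'
#' 4-column bedGraph (0-based half-open, numeric value = S = -log10 P).
#' The returned track is sorted; overlapping intervals or negative S
#' values are errors.
#'
#' @param path Path to a bedGraph file.
#' @return GRanges with a `score` metadata column.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(GenomicRanges::GRanges(score = numeric(0)))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) stopf("bedGraph line %d: fewer than 4 columns",
                         idx[which(nf < 4)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- is.na(start0) | is.na(end0) | is.na(score)
  if (any(bad)) stopf("bedGraph line %d: non-numeric field", idx[which(bad)[1]])
  bad <- end0 <= start0
  if (any(bad)) stopf("bedGraph line %d: end <= start", idx[which(bad)[1]])
  if (any(score < 0)) {
    stopf("bedGraph line %d: negative S value (%g); S = -log10 P must be >= 0",
          idx[which(score < 0)[1]], score[which(score < 0)[1]])
  }
  gr <- granges_from_bed0(chrom, start0, end0, score = score)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  validate_track(gr)
}

#' Validate a signal track (sorted, non-overlapping, S >= 0)
#' @param track GRanges with `score`.
#' @return `track`, sorted, invisibly on success.
#' @export
validate_track <- function(track) {
  if (any(S4Vectors::mcols(track)$score < 0)) stopf("negative S values in track")
  track <- GenomicRanges::sort(track, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(track, track, ignore.strand = TRUE)
  dup <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
  if (any(dup)) {
    off <- unique(S4Vectors::queryHits(hits)[dup])
    stopf("track has overlapping intervals (e.g. records %s)",
          paste(utils::head(off, 3), collapse = ", "))
  }
  invisible(track)
}

#' Write a signal track as bedGraph
#' @param track GRanges with `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- granges_to_bed0(track)
  utils::write.table(df[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean signal of tags overlapping intervals
#'
#' A tag "matches" an interval if it overlaps it at all; the unweighted
#' mean of matching S values is returned (`weighted = TRUE` weights by
#' overlap width instead).  Intervals with no matching tag get `NA`.
#'
#' @param track GRanges with `score`.
#' @param intervals GRanges of query intervals (names preserved).
#' @param weighted Weight tag values by overlap width instead of the
#'   per-tag mean.
#' @return Named numeric vector of mean S per interval.
#' @export
mean_signal_over_intervals <- function(track, intervals, weighted = FALSE) {
  out <- rep(NA_real_, length(intervals))
  names(out) <- names(intervals)
  if (!length(track) || !length(intervals)) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals, track, ignore.strand = TRUE))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  sc <- S4Vectors::mcols(track)$score[s]
  if (weighted) {
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(intervals)[q], GenomicRanges::ranges(track)[s]))
    num <- tapply(sc * w, q, sum)
    den <- tapply(w, q, sum)
    out[as.integer(names(num))] <- num / den
  } else {
    m <- tapply(sc, q, mean)
    out[as.integer(names(m))] <- m
  }
  out
}

#' Per-gene promoter signal matrix
#'
#' Mean S over the symmetric +/- `w` window at each TSS (the tuned
#' default is +/-300 bp).
#'
#' @param track GRanges signal track.
#' @param ann Gene annotation data frame.
#' @param w Window half-width in bp.
#' @param weighted Base-pair-weighted mean instead of per-tag mean.
#' @return Named vector of mean S per gene (`NA` where no tag overlaps).
#' @export
promoter_signal_matrix <- function(track, ann, w = 300, weighted = FALSE) {
  win <- promoter_window(ann, w, mode = "symmetric")
  sig <- mean_signal_over_intervals(track, win, weighted = weighted)
  n_missing <- sum(is.na(sig))
  if (n_missing > 0) {
    message(sprintf("promoter_signal_matrix: %d gene(s) with no overlapping tags",
                    n_missing))
  }
  sig
}

#' Per-gene gene-body signal
#'
#' Mean S over the gene body; `mode = "span"` (first to last exon,
#' introns included) is the ChIP mapping definition, and
#' `"exons_after_first"` the exon-only definition used for hESC line
#' similarity.  H3K36me3 is evaluated here.
#'
#' @param track GRanges signal track.
#' @param ann Gene annotation data frame.
#' @param mode Body definition (see [gene_body_intervals()]).
#' @param weighted Base-pair-weighted mean instead of per-tag mean.
#' @return Named vector of mean S per gene (`NA` for empty bodies, e.g.
#'   single-exon genes in exon mode).
#' @export
gene_body_signal <- function(track, ann, mode = c("span", "exons_after_first"),
                             weighted = FALSE) {
  mode <- match.arg(mode)
  iv <- gene_body_intervals(ann, mode)
  per_iv <- mean_signal_over_intervals(track, iv, weighted = weighted)
  if (mode == "span") return(per_iv)
  # several exon intervals per gene: tag-count-weighted combination via
  # pooled per-gene mean over all matching tags
  out <- rep(NA_real_, nrow(ann))
  names(out) <- ann$gene_id
  if (length(iv)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(iv, track, ignore.strand = TRUE))
    if (length(hits)) {
      gid <- names(iv)[S4Vectors::queryHits(hits)]
      sc <- S4Vectors::mcols(track)$score[S4Vectors::subjectHits(hits)]
      # a tag overlapping two exons of the same gene counts once
      key <- paste(gid, S4Vectors::subjectHits(hits))
      first <- !duplicated(key)
      m <- tapply(sc[first], gid[first], mean)
      out[names(m)] <- m
    }
  }
  out
}

#' Floor and log-transform an RPKM expression vector
#'
#' Zeros are substituted with the smallest positive observed RPKM; the
#' vector is log2-transformed and floored at
#' `round(log2(read_threshold / (total_reads_millions * mean_gene_kb)))`
#' — with the defaults (10 reads, 39 million reads, 1 kb genes) the
#' floor is `round(log2(10/39)) = -2`, i.e. genes with fewer than 10
#' matched reads are assigned log2 RPKM = -2.
#'
#' @param rpkm Raw RPKM vector (>= 0, not all zero).
#' @param total_reads_millions Library size in millions of reads.
#' @param read_threshold Read count calling a gene expressed.
#' @param mean_gene_kb Mean gene length in kb.
#' @return Named vector of floored log2 RPKM values, with the floor in
#'   attribute `floor`.
#' @export
floor_expression <- function(rpkm, total_reads_millions = 39,
                             read_threshold = 10, mean_gene_kb = 1) {
  if (any(rpkm < 0)) stopf("RPKM values must be >= 0")
  if (all(rpkm == 0)) stopf("all-zero expression vector")
  floor_exact <- log2(read_threshold / (total_reads_millions * mean_gene_kb))
  floor_val <- round(floor_exact)
  smallest <- min(rpkm[rpkm > 0])
  rpkm[rpkm == 0] <- smallest
  lg <- log2(rpkm)
  lg[lg < floor_val] <- floor_val
  attr(lg, "floor") <- floor_val
  attr(lg, "floor_exact") <- floor_exact
  lg
}

#' Tune the promoter window size against expression
#'
#' For each candidate half-width `w`, computes Pearson correlations of
#' the promoter H3K4me3 and H3K27me3 mean signals with log2 expression;
#' the objective is the mean of the two absolute correlations
#' (H3K27me3's association is expected negative, so absolute values put
#' the marks on one scale).  Ties go to the smallest window.  The
#' candidate list defaults to 200-1500 bp.
#'
#' @param track_k4,track_k27 GRanges signal tracks.
#' @param expression Named log2-expression vector (e.g. from
#'   [floor_expression()]).
#' @param ann Gene annotation data frame.
#' @param candidates Candidate window half-widths in bp.
#' @return List: `w` (chosen), `profile` (data.frame of per-window
#'   correlations and objective).
#' @export
tune_window <- function(track_k4, track_k27, expression, ann,
                        candidates = c(200, 300, 500, 700, 900, 1100,
                                       1300, 1500)) {
  if (length(candidates) < 2) stopf("need >= 2 candidate windows")
  profile <- data.frame(w = candidates, r_k4 = NA_real_, r_k27 = NA_real_)
  for (i in seq_along(candidates)) {
    s4 <- promoter_signal_matrix(track_k4, ann, candidates[i])
    s27 <- promoter_signal_matrix(track_k27, ann, candidates[i])
    common <- intersect(names(expression),
                        names(s4)[!is.na(s4) & !is.na(s27)])
    if (length(common) < 50) stopf("fewer than 50 genes shared between signals and expression")
    profile$r_k4[i] <- stats::cor(s4[common], expression[common])
    profile$r_k27[i] <- stats::cor(s27[common], expression[common])
  }
  profile$objective <- (abs(profile$r_k4) + abs(profile$r_k27)) / 2
  if (all(is.na(profile$objective))) {
    stopf("window tuning failed: constant signals or expression")
  }
  best <- which(profile$objective >= max(profile$objective, na.rm = TRUE) - 1e-12)
  w <- min(candidates[best])
  list(w = w, profile = profile)
}

#' Select the reference hESC line by histone-pattern similarity
#'
#' Each line's similarity is the mean of its pairwise Pearson
#' correlations with every other line, averaged over the three
#' mark/region combinations (promoter H3K4me3 and H3K27me3, exon-only
#' body H3K36me3).  Returns the most similar line; ties resolve
#' lexicographically.
#'
#' @param line_signals Named list (per line) of lists of named per-gene
#'   signal vectors (one per mark/region combination, same structure in
#'   every line).
#' @return List: `line` (chosen id), `similarity` (named vector).
#' @export
select_reference_line <- function(line_signals) {
  lines <- names(line_signals)
  if (length(lines) < 3) stopf("need >= 3 hESC lines")
  combos <- names(line_signals[[1]])
  sim <- matrix(NA_real_, length(lines), length(lines),
                dimnames = list(lines, lines))
  for (i in seq_along(lines)) {
    for (j in seq_along(lines)) {
      if (i == j) next
      rs <- vapply(combos, function(cb) {
        a <- line_signals[[i]][[cb]]
        b <- line_signals[[j]][[cb]]
        ids <- intersect(names(a), names(b))
        stats::cor(a[ids], b[ids])
      }, 0)
      sim[i, j] <- mean(rs)
    }
  }
  similarity <- rowMeans(sim, na.rm = TRUE)
  ord <- order(-similarity, lines)
  list(line = lines[ord[1]], similarity = similarity)
}
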