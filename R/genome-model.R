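# Genomic interval model: GRanges-backed intervals, gene annotation tables,
# probe manifests, and readers/writers for the plain-text formats the
# pipeline touches (BED, bedGraph, TSV annotation/manifest tables).
#
# External files use BED conventions (0-based, half-open).  Internally all
# intervals are GRanges (1-based, closed); the two helpers below are the
# single conversion boundary.

#' Convert 0-based half-open coordinates to a GRanges
#'
#' @param chrom Character vector of chromosome names.
#' @param start0,end0 Integer vectors, 0-based half-open (`end0 > start0`).
#' @param strand Strand vector (`"+"`, `"-"` or `"."`/`"*"`).
#' @param ... Further vectors stored as metadata columns.
#' @return A [GenomicRanges::GRanges] object.
#' @export
granges_from_bed0 <- function(chrom, start0, end0, strand = "*", ...) {
  if (any(end0 <= start0)) stopf("interval with end <= start")
  if (any(start0 < 0)) stopf("interval with negative start")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = strand
  )
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

#' View a GRanges as a 0-based half-open BED data frame
#'
#' @param gr A GRanges.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (BED coordinates) plus any metadata columns.
#' @export
granges_to_bed0 <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
}

#' Read a BED file (3+ columns) into a GRanges interval set
#'
#' `track`/`browser`/`#` lines are skipped.  Records with `end <= start`
#' raise an error naming the offending line.
#'
#' @param path Path to a BED file (0-based half-open).
#' @return GRanges, sorted within chromosomes.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(GenomicRanges::GRanges())
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("BED line %d: fewer than 3 columns", idx[which(nf < 3)[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) stopf("BED line %d: non-numeric coordinates", idx[which(bad)[1]])
  bad <- end0 <= start0
  if (any(bad)) {
    stopf("BED line %d: end (%g) <= start (%g)",
          idx[which(bad)[1]], end0[which(bad)[1]], start0[which(bad)[1]])
  }
  name <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  str <- if (all(nf >= 6)) vapply(fields, `[[`, "", 6L) else "*"
  gr <- granges_from_bed0(chrom, start0, end0, strand = str)
  if (!is.null(name)) names(gr) <- name
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges to a BED file (0-based half-open)
#'
#' @param gr GRanges to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- granges_to_bed0(gr)
  nm <- names(gr) %||% rep(".", length(gr))
  out <- data.frame(df$chrom, df$start, df$end, nm, 0L, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tss`
#' (0-based position of the TSS base), `exon_starts`, `exon_ends`
#' (comma-separated 0-based half-open, genomic order).
#'
#' @param path Path to the annotation TSV.
#' @return A validated annotation `data.frame` (see [validate_annotation()]).
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Write a gene annotation table
#' @param ann Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene annotation data frame
#'
#' Checks exon lists are sorted, non-overlapping and that the TSS
#' coincides with the 5' end of the first exon on the annotated strand.
#'
#' @param ann Annotation data frame (see [read_annotation()] for columns).
#' @return `ann`, invisibly classed as `"gene_annotation"`.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  if (!all(need %in% names(ann))) {
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  }
  starts <- exon_list(ann$exon_starts)
  ends <- exon_list(ann$exon_ends)
  for (i in seq_len(nrow(ann))) {
    s <- starts[[i]]; e <- ends[[i]]
    if (length(s) != length(e) || length(s) < 1L) {
      stopf("gene %s: malformed exon lists", ann$gene_id[i])
    }
    if (any(e <= s)) stopf("gene %s: exon end <= start", ann$gene_id[i])
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      stopf("gene %s: exons unsorted or overlapping", ann$gene_id[i])
    }
    tss5 <- if (ann$strand[i] == "+") s[1] else e[length(e)] - 1L
    if (ann$tss[i] != tss5) {
      stopf("gene %s: TSS (%d) does not match 5' end of first exon (%d)",
            ann$gene_id[i], ann$tss[i], tss5)
    }
  }
  class(ann) <- c("gene_annotation", "data.frame")
  invisible(ann)
}

exon_list <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), as.integer)
}

#' Promoter window around a TSS
#'
#' Symmetric windows span `[tss - w, tss + w)` in 0-based half-open
#' coordinates and ignore strand.  Upstream-only windows span the `w`
#' bases 5' of the TSS following transcription direction: `[tss - w, tss)`
#' on the plus strand, reflected to `[tss, tss + w)` on the minus strand.
#' Windows are clipped at position 0.
#'
#' @param ann Gene annotation data frame.
#' @param w Window half-width (symmetric) or width (upstream), in bp.
#' @param mode `"symmetric"` or `"upstream"`.
#' @return GRanges named by `gene_id`.
#' @export
promoter_window <- function(ann, w, mode = c("symmetric", "upstream")) {
  mode <- match.arg(mode)
  stopifnot(w > 0)
  tss <- ann$tss
  if (mode == "symmetric") {
    s0 <- tss - w
    e0 <- tss + w
  } else {
    minus <- ann$strand == "-"
    s0 <- ifelse(minus, tss, tss - w)
    e0 <- ifelse(minus, tss + w, tss)
  }
  s0 <- pmax(s0, 0)
  gr <- granges_from_bed0(ann$chrom, s0, e0, strand = ann$strand)
  names(gr) <- ann$gene_id
  gr
}

#' Gene-body intervals under the three body definitions
#'
#' * `"span"`: single interval from the first exon to the last, introns
#'   included (used for mapping ChIP-seq tags to gene bodies).
#' * `"exons_after_first"`: exon intervals from the end of the first exon
#'   (in transcription order) onward, introns excluded (used for the hESC
#'   line similarity signal).  Single-exon genes yield no interval and are
#'   flagged in the `single_exon` attribute.
#'
#' @param ann Gene annotation data frame.
#' @param mode `"span"` or `"exons_after_first"`.
#' @return GRanges named by `gene_id` (possibly several intervals per
#'   gene in exon mode), with attribute `single_exon` listing flagged
#'   genes in exon mode.
#' @export
gene_body_intervals <- function(ann, mode = c("span", "exons_after_first")) {
  mode <- match.arg(mode)
  starts <- exon_list(ann$exon_starts)
  ends <- exon_list(ann$exon_ends)
  if (mode == "span") {
    s0 <- vapply(starts, min, 0L)
    e0 <- vapply(ends, max, 0L)
    gr <- granges_from_bed0(ann$chrom, s0, e0, strand = ann$strand)
    names(gr) <- ann$gene_id
    return(gr)
  }
  chroms <- character(0); s0 <- integer(0); e0 <- integer(0)
  str <- character(0); ids <- character(0)
  single <- character(0)
  for (i in seq_len(nrow(ann))) {
    n <- length(starts[[i]])
    if (n < 2L) {
      single <- c(single, ann$gene_id[i])
      next
    }
    # transcription-order first exon is the rightmost genomic exon on "-"
    keep <- if (ann$strand[i] == "+") 2:n else 1:(n - 1L)
    chroms <- c(chroms, rep(ann$chrom[i], length(keep)))
    s0 <- c(s0, starts[[i]][keep])
    e0 <- c(e0, ends[[i]][keep])
    str <- c(str, rep(ann$strand[i], length(keep)))
    ids <- c(ids, rep(ann$gene_id[i], length(keep)))
  }
  gr <- if (length(s0)) granges_from_bed0(chroms, s0, e0, strand = str)
        else GenomicRanges::GRanges()
  names(gr) <- ids
  attr(gr, "single_exon") <- single
  gr
}

#' Does each query interval overlap an interval set?
#'
#' Half-open abutting intervals (BED `[100,200)` vs `[200,300)`) do not
#' overlap.
#'
#' @param query GRanges of query intervals.
#' @param subject GRanges interval set.
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  # absent chromosomes simply mean "no overlap"; silence the seqlevel note
  suppressWarnings(IRanges::overlapsAny(query, subject, ignore.strand = TRUE))
}

#' Read a probe manifest table
#'
#' Tab-separated with header: `probe_id`, `chrom`, `pos` (0-based),
#' `gene_id` (or NA), `region_class` (`TSS200`, `Body`, or NA), `cgi_id`
#' (or NA).  A probe may appear on several rows (multi-region mapping).
#'
#' @param path Path to the manifest TSV.
#' @return Manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = c(probe_id = "character",
                                          chrom = "character",
                                          pos = "integer",
                                          gene_id = "character",
                                          region_class = "character",
                                          cgi_id = "character"))
  validate_manifest(man)
}

#' Write a probe manifest table
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a probe manifest data frame
#' @param manifest Manifest data frame.
#' @return `manifest`, invisibly.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "gene_id", "region_class", "cgi_id")
  if (!all(need %in% names(manifest))) {
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  ok_class <- is.na(manifest$region_class) |
    manifest$region_class %in% c("TSS200", "Body")
  if (!all(ok_class)) stopf("region_class must be TSS200, Body or NA")
  invisible(manifest)
}
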