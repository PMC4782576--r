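# Probe-level preprocessing: coverage filter, kNN imputation, region
# aggregation, SVD phenotype sanity check and probe-density statistics.

#' Remove probes with low sample coverage
#'
#' A probe is kept when the fraction of non-missing sample values is at
#' least `min_frac` (strict `< min_frac` removal: 70% coverage is kept
#' at the default 0.7).  Probe order is preserved.
#'
#' @param m Beta matrix (probes x samples), possibly with `NA`s.
#' @param min_frac Minimum coverage fraction, in (0, 1].
#' @return Filtered matrix.
#' @export
filter_probes_by_coverage <- function(m, min_frac = 0.7) {
  stopifnot(min_frac > 0, min_frac <= 1)
  cov <- rowMeans(!is.na(m))
  keep <- cov >= min_frac
  if (!any(keep)) stopf("all probes removed by coverage filter")
  m[keep, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the mean, over that sample, of the
#' `k` nearest probes (Euclidean distance over jointly observed samples,
#' normalised by the number of such samples).  Neighbours must be
#' observed in the target sample; ties are broken by probe row order.
#' When fewer than `k` eligible neighbours exist, all available are used
#' with a warning.  Observed values are never altered.
#'
#' @param m Beta matrix (probes x samples).
#' @param k Number of neighbours (default 5).
#' @return Matrix with no missing entries.
#' @export
impute_knn <- function(m, k = 5) {
  stopifnot(k >= 1)
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0)) {
    stopf("probe with no observed values; filter before imputing")
  }
  obs <- !is.na(m)
  x0 <- m; x0[!obs] <- 0
  M <- obs * 1
  A <- x0^2 * M
  miss_rows <- which(!matrixStats_rowAlls(obs))
  short <- FALSE
  # squared distances in blocks: (a-b)^2 summed over joint observations
  blk_size <- max(1L, floor(2e7 / max(1L, nrow(m))))
  for (blk in split(miss_rows, ceiling(seq_along(miss_rows) / blk_size))) {
    D2 <- A[blk, , drop = FALSE] %*% t(M) +
      M[blk, , drop = FALSE] %*% t(A) -
      2 * x0[blk, , drop = FALSE] %*% t(x0)
    Np <- M[blk, , drop = FALSE] %*% t(M)
    D <- sqrt(pmax(D2, 0) / ifelse(Np > 0, Np, NA))
    for (bi in seq_along(blk)) {
      i <- blk[bi]
      d <- D[bi, ]
      d[i] <- NA            # not its own neighbour
      # cheap candidate preselection before the full tie-stable ordering
      d[is.na(d)] <- Inf
      kk <- min(sum(is.finite(d)), k + 50L)
      if (kk == 0) stopf("probe %s has no comparable neighbour", rownames(m)[i])
      thr <- sort.int(d, partial = kk)[kk]
      cand <- which(d <= thr)
      ord <- cand[order(d[cand], cand)]
      full <- FALSE
      for (s in which(!obs[i, ])) {
        elig <- ord[obs[ord, s]]
        if (length(elig) < k && !full) {
          # fall back to the full ordering when the preselection is thin
          ord <- order(d, seq_along(d))
          ord <- ord[is.finite(d[ord])]
          full <- TRUE
          elig <- ord[obs[ord, s]]
        }
        if (length(elig) < k) short <- TRUE
        use <- utils::head(elig, k)
        m[i, s] <- mean(x0[use, s])
      }
    }
  }
  if (short) warnf("fewer than k=%d eligible neighbours for some entries; used all available", k)
  m
}

# rowAlls without a matrixStats dependency
matrixStats_rowAlls <- function(x) rowSums(x) == ncol(x)

#' Average probe beta values into region-level values
#'
#' Region values are the arithmetic mean of member-probe beta values per
#' sample (`NA`s ignored).  Regions with no member probe present in the
#' matrix are dropped (a message reports how many).
#'
#' @param m Beta matrix (probes x samples), rownames = probe ids.
#' @param manifest Probe manifest (see [read_manifest()]).
#' @param region_class `"promoter"` (TSS200 probes, one region per
#'   gene), `"gene_body"` (Body probes per gene) or `"cgi"`.
#' @return Region x sample matrix, rownames = gene or CGI ids.
#' @export
aggregate_region_beta <- function(m, manifest,
                                  region_class = c("promoter", "gene_body",
                                                   "cgi")) {
  region_class <- match.arg(region_class)
  rows <- switch(region_class,
    promoter = which(!is.na(manifest$region_class) &
                       manifest$region_class == "TSS200"),
    gene_body = which(!is.na(manifest$region_class) &
                        manifest$region_class == "Body"),
    cgi = which(!is.na(manifest$cgi_id))
  )
  ids <- if (region_class == "cgi") manifest$cgi_id[rows]
         else manifest$gene_id[rows]
  probe <- manifest$probe_id[rows]
  present <- probe %in% rownames(m)
  n_regions <- length(unique(ids))
  ids <- ids[present]; probe <- probe[present]
  if (!length(probe)) stopf("no %s probes present in matrix", region_class)
  sub <- m[probe, , drop = FALSE]
  obs <- !is.na(sub)
  sub[!obs] <- 0
  sums <- rowsum(sub, ids)
  counts <- rowsum(obs * 1, ids)
  out <- sums / ifelse(counts > 0, counts, NA)
  dropped <- n_regions - nrow(out)
  if (dropped > 0) {
    message(sprintf("aggregate_region_beta: dropped %d %s region(s) with no probes",
                    dropped, region_class))
  }
  out
}

#' SVD check that the top variation axis tracks phenotype
#'
#' Probes are centred across samples; the top right-singular vector
#' (per-sample loadings) is correlated with the binary label.
#'
#' @param m Beta matrix (probes x samples), complete.
#' @param labels Vector with two levels (e.g. normal/cancer), one per
#'   sample.
#' @param threshold Absolute correlation needed for `pass`.
#' @return List: `r`, `t`, `p`, `singular_values` (top 5), `pass`.
#' @export
svd_phenotype_check <- function(m, labels, threshold = 0.5) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("labels must have at least two levels")
  if (any(table(labels) < 2)) stopf("need >= 2 samples per label")
  xc <- m - rowMeans(m)
  cp <- crossprod(xc)                     # samples x samples
  ei <- eigen(cp, symmetric = TRUE)
  v1 <- ei$vectors[, 1]
  y <- as.numeric(labels == levels(labels)[2])
  r <- stats::cor(v1, y)
  n <- length(y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, t = tstat, p = p,
       singular_values = sqrt(pmax(ei$values[seq_len(min(5, n))], 0)),
       pass = abs(r) > threshold)
}

#' Probe density per genomic region, with pairwise class comparisons
#'
#' Gene-anchored densities divide the probe count by the distance
#' between the two farthest probes of that gene/class (regions with < 2
#' probes are skipped); CGI densities divide by the CGI length
#' (end - start).
#'
#' @param manifest Probe manifest.
#' @param cgis GRanges of CGIs (named), or `NULL` to skip the CGI class.
#' @return List: `densities` (region_id, region_class, n_probes, span,
#'   density), `tests` (pairwise Welch t statistics between classes),
#'   `skipped` (region ids with < 2 probes under the gene-span rule).
#' @export
probe_density <- function(manifest, cgis = NULL) {
  gene_density <- function(class_name, out_class) {
    rows <- !is.na(manifest$region_class) &
      manifest$region_class == class_name
    if (!any(rows)) return(NULL)
    pos <- split(manifest$pos[rows], manifest$gene_id[rows])
    n <- lengths(pos)
    span <- vapply(pos, function(p) diff(range(p)), 0)
    ok <- n >= 2 & span > 0
    list(df = data.frame(region_id = names(pos)[ok],
                         region_class = out_class,
                         n_probes = n[ok], span = span[ok],
                         density = n[ok] / span[ok],
                         stringsAsFactors = FALSE),
         skipped = names(pos)[!ok])
  }
  prom <- gene_density("TSS200", "promoter")
  body <- gene_density("Body", "gene_body")
  dens <- rbind(prom$df, body$df)
  skipped <- c(prom$skipped, body$skipped)
  if (!is.null(cgis)) {
    rows <- !is.na(manifest$cgi_id)
    cnt <- table(manifest$cgi_id[rows])
    len <- GenomicRanges::width(cgis)[match(names(cnt), names(cgis))]
    dens <- rbind(dens, data.frame(region_id = names(cnt),
                                   region_class = "cgi",
                                   n_probes = as.integer(cnt), span = len,
                                   density = as.integer(cnt) / len,
                                   stringsAsFactors = FALSE))
  }
  cls <- unique(dens$region_class)
  tests <- NULL
  if (length(cls) > 1) {
    pairs <- utils::combn(cls, 2)
    tests <- data.frame(
      class_a = pairs[1, ], class_b = pairs[2, ],
      t = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
    for (i in seq_len(ncol(pairs))) {
      da <- dens$density[dens$region_class == pairs[1, i]]
      db <- dens$density[dens$region_class == pairs[2, i]]
      if (length(da) < 2 || length(db) < 2) next   # NA when under-sampled
      tt <- stats::t.test(da, db)
      tests$t[i] <- unname(tt$statistic)
      tests$p[i] <- tt$p.value
    }
  }
  list(densities = dens, tests = tests, skipped = skipped)
}
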