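# Shared fixtures: tiny configs and hand-built annotations used across
# test files.  Everything is generated in code; no stored data.

tiny_cfg <- function(...) {
  synth_config(n_genes = 60, n_cgis = 40, n_tissues = 3,
               samples_per_phenotype = 4, seed = 42, ...)
}

# two-gene annotation with known coordinates (one gene per strand)
toy_annotation <- function() {
  validate_annotation(data.frame(
    gene_id = c("gPlus", "gMinus"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "-"),
    tss = c(10000L, 20999L),
    exon_starts = c("10000,10600", "20000,20700"),
    exon_ends = c("10400,10900", "20300,21000"),
    stringsAsFactors = FALSE
  ))
}

# deterministic beta matrix with labelled groups
toy_beta <- function(n_probes = 20, n_per_group = 5, shift = 0.3,
                     seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rbeta(n_probes * 2 * n_per_group, 5, 15),
                n_probes, 2 * n_per_group)
    m[, (n_per_group + 1):(2 * n_per_group)] <-
      pmin(m[, (n_per_group + 1):(2 * n_per_group)] + shift, 1)
    dimnames(m) <- list(sprintf("p%02d", seq_len(n_probes)),
                        c(sprintf("n%d", seq_len(n_per_group)),
                          sprintf("c%d", seq_len(n_per_group))))
    m
  })
}

# brute-force mean-signal oracle: scan every tag for overlap
oracle_mean_signal <- function(track, iv) {
  tdf <- granges_to_bed0(track)
  qdf <- granges_to_bed0(iv)
  vapply(seq_len(nrow(qdf)), function(i) {
    hit <- tdf$chrom == qdf$chrom[i] &
      tdf$start < qdf$end[i] & tdf$end > qdf$start[i]
    if (!any(hit)) NA_real_ else mean(tdf$score[hit])
  }, 0)
}

# brute-force pairwise AUC oracle
oracle_auc <- function(signal, labels) {
  pos <- signal[labels == "DM"]
  neg <- signal[labels == "nonDM"]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}
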