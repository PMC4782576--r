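# End-to-end orchestration: simulate -> preprocess -> constitutive ->
# differential methylation / correlation -> histone signals ->
# prediction -> chromatin context, from a single config.

#' Pipeline configuration
#'
#' Bundles the generator config with the analysis parameters, all at
#' their study defaults: N = 300 DM genes per tail, 1000+1000 for the
#' multivariate model, 50/20/30 split, +/-300 bp promoter window,
#' coverage >= 70%, kNN k = 5.
#'
#' @param simulate A [synth_config()] describing the synthetic inputs.
#' @param N Top/bottom rank size for DM labelling.
#' @param model_N Per-class size of the multivariate DM gene set.
#' @param split_fractions Train/validation/test fractions.
#' @param window Promoter window half-width (bp) for histone signals.
#' @param coverage_min_frac Probe coverage filter threshold.
#' @param knn_k Imputation neighbours.
#' @param bivalent_q Bivalency quantile cutoff.
#' @param drop_inputs Character vector of inputs to withhold (e.g.
#'   `"histone"` skips the prediction stages with a logged reason).
#' @param seed Analysis seed (splits); generator seed lives in
#'   `simulate$seed`.
#' @return Classed list of settings.
#' @export
pipeline_config <- function(simulate = synth_config(),
                            N = 300,
                            model_N = 1000,
                            split_fractions = c(0.5, 0.2, 0.3),
                            window = 300,
                            coverage_min_frac = 0.7,
                            knn_k = 5,
                            bivalent_q = 0.75,
                            drop_inputs = character(),
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "ticmeth_pipeline_config"
  cfg
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Stages: simulate; per-cohort coverage filter and kNN imputation
#' (fetal pooled, then normal+cancer per tissue); region aggregation;
#' per-fetal-sample mixture thresholds; constitutive sets (cu-GP,
#' cu-CGI, cm-GB); per-tissue differential methylation and cross-cancer
#' R^2; histone signal aggregation; normal-vs-hESC AUC comparison and
#' multivariate model selection; DHS / bivalency stratification.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for tab-separated stage exports
#'   and a small JSON manifest.
#' @return List of stage results (see individual stage functions).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ticmeth_pipeline_config"))
  log <- function(fmt, ...) message(sprintf(paste0("[ticmeth] ", fmt), ...))
  scfg <- config$simulate

  log("simulate: %d genes, %d tissues, %d samples/phenotype",
      scfg$n_genes, scfg$n_tissues, scfg$samples_per_phenotype)
  sim <- simulate_dataset(scfg, tracks = FALSE)
  for (inp in config$drop_inputs) sim[[inp]] <- NULL
  sheet <- sim$samples
  tissues <- unique(sheet$tissue)

  # --- preprocess per cohort ----------------------------------------
  log("preprocess: coverage filter (>= %.0f%%) + kNN imputation (k = %d)",
      100 * config$coverage_min_frac, config$knn_k)
  cohorts <- c(list(fetal = sheet$sample_id[sheet$phenotype == "fetal"]),
               stats::setNames(lapply(tissues, function(t) {
                 sheet$sample_id[sheet$tissue == t &
                                   sheet$phenotype != "fetal"]
               }), tissues))
  imputed <- lapply(cohorts, function(ids) {
    m <- filter_probes_by_coverage(sim$beta[, ids, drop = FALSE],
                                   config$coverage_min_frac)
    impute_knn(m, k = config$knn_k)
  })
  # common probe set after per-cohort filtering
  probes <- Reduce(intersect, lapply(imputed, rownames))
  beta <- do.call(cbind, lapply(imputed, function(m) m[probes, ]))
  beta <- beta[, sheet$sample_id]
  log("preprocess: %d/%d probes retained across cohorts",
      length(probes), nrow(sim$beta))

  region <- list(
    promoter = aggregate_region_beta(beta, sim$manifest, "promoter"),
    gene_body = aggregate_region_beta(beta, sim$manifest, "gene_body"),
    cgi = aggregate_region_beta(beta, sim$manifest, "cgi")
  )

  # --- constitutive sets --------------------------------------------
  fetal_ids <- cohorts$fetal
  log("constitutive: fitting beta mixtures for %d fetal samples",
      length(fetal_ids))
  th <- sample_thresholds(beta, fetal_ids, seed = config$seed)
  consets <- list(
    cu_gp = constitutive_set(region$promoter[, fetal_ids], th, "cu_gp"),
    cu_cgi = constitutive_set(region$cgi[, fetal_ids], th, "cu_cgi"),
    cm_gb = constitutive_set(region$gene_body[, fetal_ids], th, "cm_gb")
  )
  log("constitutive: %d cu-GPs, %d cu-CGIs, %d cm-GBs",
      length(consets$cu_gp$members), length(consets$cu_cgi$members),
      length(consets$cm_gb$members))

  # --- differential methylation + correlation ----------------------
  ids_of <- function(t, ph) sheet$sample_id[sheet$tissue == t &
                                              sheet$phenotype == ph]
  dm <- list(); profiles_cancer <- list(); profiles_normal <- list()
  for (t in tissues) {
    tt <- dm_t_test(region$promoter[consets$cu_gp$members, , drop = FALSE],
                    ids_of(t, "normal"), ids_of(t, "cancer"))
    Nt <- min(config$N, floor(nrow(tt) / 2))
    dm[[t]] <- rank_and_label(tt, N = Nt, direction = "hyper")
    profiles_cancer[[t]] <- phenotype_mean_profile(
      region$promoter[consets$cu_gp$members, , drop = FALSE],
      ids_of(t, "cancer"))
    profiles_normal[[t]] <- phenotype_mean_profile(
      region$promoter[consets$cu_gp$members, , drop = FALSE],
      ids_of(t, "normal"))
  }
  corr <- pairwise_r2(profiles_cancer)
  # cancer (rows) vs normal (cols) R^2 for the own-vs-other test
  cn <- outer(seq_along(tissues), seq_along(tissues),
              Vectorize(function(i, j) {
                stats::cor(profiles_cancer[[i]], profiles_normal[[j]])^2
              }))
  dimnames(cn) <- list(tissues, tissues)
  own <- if (length(tissues) >= 3) own_vs_other_normal_test(cn) else NULL
  log("correlate: mean cross-cancer R^2 = %.3f over %d cu-GPs",
      corr$mean_offdiag, corr$n_regions)

  # --- histone signals + prediction ---------------------------------
  pred <- NULL
  if (!is.null(sim$histone)) {
    gs <- sim$histone$gene_signals
    auc_tab <- NULL
    for (t in tissues) {
      tab <- predict_dm_auc(
        list(normal = gs$normal[[t]], hesc = gs$hesc),
        dm[[t]], orientation = "association")
      tab$tissue <- t
      auc_tab <- rbind(auc_tab, tab)
    }
    wide <- function(mark) {
      n <- auc_tab$auc[auc_tab$mark == mark & auc_tab$source == "normal"]
      h <- auc_tab$auc[auc_tab$mark == mark & auc_tab$source == "hesc"]
      list(normal = n, hesc = h)
    }
    k4 <- wide("H3K4me3"); k27 <- wide("H3K27me3")
    wilcox_pooled <- paired_wilcoxon_auc(c(k4$normal, k27$normal),
                                         c(k4$hesc, k27$hesc))
    t1 <- tissues[1]
    tt_all <- dm_t_test(region$promoter[consets$cu_gp$members, ,
                                        drop = FALSE],
                        ids_of(t1, "normal"), ids_of(t1, "cancer"))
    Nm <- min(config$model_N, floor(nrow(tt_all) / 2))
    labeled <- build_dm_gene_set(tt_all, N = Nm)
    split <- stratified_split(labeled, config$split_fractions,
                              seed = config$seed)
    sigmat <- cbind(H3K4me3 = gs$normal[[t1]]$H3K4me3,
                    H3K27me3 = gs$normal[[t1]]$H3K27me3,
                    H3K36me3 = gs$normal[[t1]]$H3K36me3)
    msel <- model_selection(sigmat, labeled, split)
    log("predict: best model %s (test AUC %.3f); pooled Wilcoxon p = %.3g",
        msel$best, msel$test_auc, wilcox_pooled$p)
    pred <- list(auc = auc_tab, wilcoxon_pooled = wilcox_pooled,
                 model_selection = msel)
  } else {
    log("predict: histone inputs unavailable; stage skipped")
  }

  # --- chromatin context --------------------------------------------
  chrom <- NULL
  if (!is.null(sim$dhs) && !is.null(sim$histone)) {
    t1 <- tissues[1]
    win <- promoter_window(sim$annotation, config$window, "symmetric")
    strata <- dhs_stratify(win, sim$dhs[[t1]])
    biv <- call_bivalent(sim$histone$gene_signals$normal[[t1]]$H3K4me3,
                         sim$histone$gene_signals$normal[[t1]]$H3K27me3,
                         q = config$bivalent_q)
    strat_t <- stratified_normal_cancer_t(
      region$promoter, ids_of(t1, "normal"), ids_of(t1, "cancer"), strata)
    chrom <- list(tissue = t1, strata = strata, bivalent = biv,
                  stratified_t = strat_t)
    log("chromatin: t(in-DHS) = %.2f, t(out-DHS) = %.2f",
        strat_t$t[strat_t$stratum == "in"],
        strat_t$t[strat_t$stratum == "out"])
  }

  res <- list(config = config, samples = sheet, region = region,
              thresholds = th, constitutive = consets, dm = dm,
              correlation = corr, cancer_vs_normal_r2 = cn,
              own_vs_other = own, prediction = pred, chromatin = chrom)
  if (!is.null(out_dir)) export_pipeline(res, out_dir)
  invisible(res)
}

# Tab-separated stage exports plus a small JSON manifest.
export_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (k in names(res$constitutive)) {
    writeLines(c(sprintf("# set_kind: %s", k),
                 sprintf("# n_samples: %d", res$constitutive[[k]]$n_samples),
                 res$constitutive[[k]]$members),
               file.path(out_dir, paste0(k, "_members.txt")))
  }
  for (t in names(res$dm)) wt(res$dm[[t]], sprintf("dm_%s.tsv", t))
  wt(data.frame(tissue = rownames(res$correlation$r2),
                res$correlation$r2), "cross_cancer_r2.tsv")
  if (!is.null(res$prediction)) {
    wt(res$prediction$auc, "auc_normal_vs_hesc.tsv")
    wt(res$prediction$model_selection$report, "model_selection.tsv")
  }
  if (!is.null(res$chromatin)) wt(res$chromatin$stratified_t,
                                  "dhs_stratified_t.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      package = "ticmeth",
      version = as.character(utils::packageVersion("ticmeth")),
      generator_seed = res$config$simulate$seed,
      analysis_seed = res$config$seed,
      n_genes = res$config$simulate$n_genes,
      n_tissues = res$config$simulate$n_tissues,
      n_cu_gp = length(res$constitutive$cu_gp$members),
      n_cu_cgi = length(res$constitutive$cu_cgi$members),
      n_cm_gb = length(res$constitutive$cm_gb$members),
      mean_cross_cancer_r2 = res$correlation$mean_offdiag
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Read/write beta matrices and sample sheets
#'
#' Beta matrices are tab-separated with the probe/region id in the
#' first column and sample ids as header; sample sheets are two-or-more
#' column TSVs (`sample_id`, `tissue`, `phenotype`).
#'
#' @param m Matrix to write.
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_beta_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_beta_matrix
#' @export
read_sample_sheet <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname write_beta_matrix
#' @param sheet Sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
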