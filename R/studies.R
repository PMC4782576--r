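# Reproducibility studies: seeded multi-run experiments that quantify the
# pipeline's headline behaviours on synthetic data (oracle equivalence,
# mixture recovery, shared-fraction recovery, predictor sign structure,
# normal-vs-hESC benchmark, DHS stratification, constitutive-set
# soundness).  These back both the test suite and scripts/acceptance.R;
# problem sizes are the package's study conditions (see the vignette).

#' Equivalence of the ROC sweep and the Mann-Whitney AUC
#'
#' Runs random prediction instances (with ties) and returns the largest
#' absolute difference between the trapezoid AUC of [roc_curve()] and
#' the pairwise-concordance AUC of [auc_from_labels()].
#'
#' @param n_instances Number of random instances.
#' @param seed Seed.
#' @return List: `max_abs_diff`, `n_instances`.
#' @export
study_auc_equivalence <- function(n_instances = 500, seed = 1) {
  with_seed(seed, {
    worst <- 0
    for (i in seq_len(n_instances)) {
      n <- sample(20:200, 1)
      sig <- stats::setNames(round(stats::runif(n), 2), paste0("g", seq_len(n)))
      lab <- stats::setNames(
        sample(c("DM", "nonDM"), n, TRUE), names(sig))
      if (length(unique(lab)) < 2) next
      worst <- max(worst,
                   abs(roc_curve(sig, lab)$auc - auc_from_labels(sig, lab)))
    }
    list(max_abs_diff = worst, n_instances = n_instances)
  })
}

#' Three-state beta-mixture recovery across seeds
#'
#' Draws `n` values from the equal-weight mixture
#' Beta(2,18) / Beta(10,10) / Beta(18,2) (component means 0.1, 0.5,
#' 0.9), fits the EM and scores a run as recovered when all three
#' component means are within `tol` of the truth.
#'
#' @param n_seeds Number of independent runs.
#' @param n Draws per run.
#' @param tol Mean recovery tolerance.
#' @param seed Base seed.
#' @return List: `rate` (fraction recovered), `max_err` per run, `n`.
#' @export
study_mixture_recovery <- function(n_seeds = 20, n = 5000, tol = 0.05,
                                   seed = 1) {
  errs <- vapply(seq_len(n_seeds), function(i) {
    with_seed(seed + i, {
      k <- stats::rmultinom(1, n, rep(1 / 3, 3))
      x <- c(stats::rbeta(k[1], 2, 18), stats::rbeta(k[2], 10, 10),
             stats::rbeta(k[3], 18, 2))
      fit <- fit_beta_mixture(x, seed = seed + i)
      max(abs(fit$means - c(0.1, 0.5, 0.9)))
    })
  }, 0)
  list(rate = mean(errs <= tol), max_err = errs, n = n)
}

# shared internals: generate a cohort, call thresholds on fetal samples,
# and return promoter-level matrices plus the cu-GP set
cohort_pipeline <- function(cfg, n_max = 3000) {
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  sheet <- meth$samples
  beta <- filter_probes_by_coverage(meth$beta)
  if (anyNA(beta)) {
    fet <- sheet$sample_id[sheet$phenotype == "fetal"]
    beta_f <- impute_knn(beta[, fet, drop = FALSE])
  } else {
    beta_f <- beta[, sheet$sample_id[sheet$phenotype == "fetal"]]
  }
  th <- sample_thresholds(beta_f, seed = cfg$seed, n_max = n_max)
  prom_f <- aggregate_region_beta(beta_f, ann$manifest, "promoter")
  cu <- constitutive_set(prom_f, th, "cu_gp")
  prom <- aggregate_region_beta(beta, ann$manifest, "promoter")
  list(ann = ann, meth = meth, sheet = sheet, beta = beta,
       thresholds = th, cu = cu, prom = prom)
}

#' Recovery of the tissue-independent shared fraction
#'
#' For each seed, simulates the default cohort (complete matrices) at
#' the given shared fraction, recovers cu-GPs from per-fetal-sample
#' mixture thresholds, and computes the mean off-diagonal cross-cancer
#' R^2 of the cancer mean-methylation profiles over the cu-GPs.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param shared_fraction Generator shared fraction (expected R^2).
#' @param n_genes,n_tissues,samples_per_phenotype Cohort size.
#' @param seed Base seed.
#' @return List: `mean_r2` (over seeds), `per_seed`, `n_genes`.
#' @export
study_shared_fraction <- function(n_seeds = 20, shared_fraction = 0.6,
                                  n_genes = 2000, n_tissues = 10,
                                  samples_per_phenotype = 20, seed = 1) {
  per_seed <- vapply(seq_len(n_seeds), function(i) {
    cfg <- synth_config(n_genes = n_genes, n_tissues = n_tissues,
                        samples_per_phenotype = samples_per_phenotype,
                        shared_fraction = shared_fraction,
                        missing_frac = 0, low_cov_frac = 0,
                        seed = seed + 100 + i)
    cp <- cohort_pipeline(cfg)
    tiss <- unique(cp$sheet$tissue)
    profs <- lapply(tiss, function(t) {
      phenotype_mean_profile(
        cp$prom[cp$cu$members, , drop = FALSE],
        cp$sheet$sample_id[cp$sheet$tissue == t &
                             cp$sheet$phenotype == "cancer"])
    })
    names(profs) <- tiss
    pairwise_r2(profs)$mean_offdiag
  }, 0)
  list(mean_r2 = mean(per_seed), per_seed = per_seed, n_genes = n_genes)
}

#' Sign recovery of the three-predictor logistic model
#'
#' For each seed, simulates a cohort, recovers cu-GPs, builds the
#' top/bottom-1000 DM gene set from cancer-vs-normal t statistics in
#' one tissue, and fits the three-mark logistic model on that tissue's
#' normal histone signals.  A run succeeds when the Wald z signs are
#' (+, -, -) for (H3K27me3, H3K4me3, H3K36me3).
#'
#' @param n_seeds Number of simulated cohorts.
#' @param n_genes Genes per cohort (4000 so the 2000-gene DM set fits
#'   inside the recovered cu-GP set).
#' @param seed Base seed.
#' @return List: `rate`, `z` (n_seeds x 3 matrix), `n_genes`.
#' @export
study_sign_recovery <- function(n_seeds = 20, n_genes = 4000, seed = 1) {
  zs <- t(vapply(seq_len(n_seeds), function(i) {
    cfg <- synth_config(n_genes = n_genes, n_tissues = 2,
                        samples_per_phenotype = 20,
                        missing_frac = 0, low_cov_frac = 0,
                        seed = seed + 200 + i)
    cp <- cohort_pipeline(cfg)
    hist <- generate_histone_tracks(cfg, cp$meth$truth, cp$ann,
                                    tracks = FALSE)
    t1 <- unique(cp$sheet$tissue)[1]
    nid <- cp$sheet$sample_id[cp$sheet$tissue == t1 &
                                cp$sheet$phenotype == "normal"]
    cid <- cp$sheet$sample_id[cp$sheet$tissue == t1 &
                                cp$sheet$phenotype == "cancer"]
    tt <- dm_t_test(cp$prom[cp$cu$members, , drop = FALSE], nid, cid)
    lab <- build_dm_gene_set(tt, N = min(1000, floor(nrow(tt) / 2)))
    gs <- hist$gene_signals$normal[[t1]]
    design <- cbind(H3K4me3 = gs$H3K4me3, H3K27me3 = gs$H3K27me3,
                    H3K36me3 = gs$H3K36me3)[lab$region_id, ]
    fit <- fit_logistic(design, lab$label)
    fit$z[c("H3K27me3", "H3K4me3", "H3K36me3")]
  }, numeric(3)))
  colnames(zs) <- c("H3K27me3", "H3K4me3", "H3K36me3")
  rate <- mean(zs[, 1] > 0 & zs[, 2] < 0 & zs[, 3] < 0)
  list(rate = rate, z = zs, n_genes = n_genes)
}

#' Normal-tissue vs hESC histone signals as DM predictors
#'
#' For each seed, simulates a six-tissue cohort with hESC tracks
#' degraded to `rho_hesc`, labels N = 300 hyper-DM cu-GPs per tissue,
#' and compares association-oriented AUCs of the H3K4me3 and H3K27me3
#' promoter signals between the matched normal tissue and hESC.  The
#' paired one-tailed Wilcoxon over the six tissues is computed per mark.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param n_tissues Tissues per cohort.
#' @param rho_hesc hESC latent degradation.
#' @param seed Base seed.
#' @return List: `win_rate` (fraction of seeds where every tissue's
#'   normal AUC beats hESC for both marks), `wilcoxon_p` (median across
#'   seeds, per mark), `per_seed` data frame, `n_tissues`.
#' @export
study_source_comparison <- function(n_seeds = 20, n_tissues = 6,
                                    rho_hesc = 0.5, seed = 1) {
  res <- lapply(seq_len(n_seeds), function(i) {
    cfg <- synth_config(n_genes = 2000, n_tissues = n_tissues,
                        samples_per_phenotype = 20, rho_hesc = rho_hesc,
                        missing_frac = 0, low_cov_frac = 0,
                        seed = seed + 300 + i)
    cp <- cohort_pipeline(cfg)
    hist <- generate_histone_tracks(cfg, cp$meth$truth, cp$ann,
                                    tracks = FALSE)
    tiss <- unique(cp$sheet$tissue)
    aucs <- lapply(tiss, function(t) {
      nid <- cp$sheet$sample_id[cp$sheet$tissue == t &
                                  cp$sheet$phenotype == "normal"]
      cid <- cp$sheet$sample_id[cp$sheet$tissue == t &
                                  cp$sheet$phenotype == "cancer"]
      tt <- dm_t_test(cp$prom[cp$cu$members, , drop = FALSE], nid, cid)
      dm <- rank_and_label(tt, N = min(300, floor(nrow(tt) / 2)))
      predict_dm_auc(list(normal = hist$gene_signals$normal[[t]],
                          hesc = hist$gene_signals$hesc),
                     dm, orientation = "association")
    })
    tab <- do.call(rbind, aucs)
    get <- function(src, mark) tab$auc[tab$source == src & tab$mark == mark]
    list(
      all_win = all(get("normal", "H3K4me3") > get("hesc", "H3K4me3")) &&
        all(get("normal", "H3K27me3") > get("hesc", "H3K27me3")),
      p_k4 = paired_wilcoxon_auc(get("normal", "H3K4me3"),
                                 get("hesc", "H3K4me3"))$p,
      p_k27 = paired_wilcoxon_auc(get("normal", "H3K27me3"),
                                  get("hesc", "H3K27me3"))$p
    )
  })
  per_seed <- data.frame(
    all_win = vapply(res, `[[`, TRUE, "all_win"),
    p_k4 = vapply(res, `[[`, 0, "p_k4"),
    p_k27 = vapply(res, `[[`, 0, "p_k27"))
  list(win_rate = mean(per_seed$all_win),
       wilcoxon_p = c(H3K4me3 = stats::median(per_seed$p_k4),
                      H3K27me3 = stats::median(per_seed$p_k27)),
       per_seed = per_seed, n_tissues = n_tissues)
}

#' DHS stratification of cancer differential methylation
#'
#' Simulates a three-tissue cohort (default missingness, exercising the
#' full preprocessing path), stratifies promoters by DHS membership in
#' the first tissue and contrasts (i) normal methylation inside vs
#' outside DHSs and (ii) the cancer-vs-normal t statistic per stratum.
#'
#' @param n_genes Genes in the cohort.
#' @param seed Seed.
#' @return List: `p_normal_beta` (Welch p, normal beta in vs out),
#'   `mean_in`, `mean_out`, `t_in`, `t_out`, `n_genes`.
#' @export
study_dhs_context <- function(n_genes = 2000, seed = 1) {
  cfg <- synth_config(n_genes = n_genes, n_tissues = 3,
                      samples_per_phenotype = 20, seed = seed + 400)
  sim <- simulate_dataset(cfg, tracks = FALSE)
  sheet <- sim$samples
  t1 <- unique(sheet$tissue)[1]
  ids <- sheet$sample_id[sheet$tissue == t1 & sheet$phenotype != "fetal"]
  beta <- impute_knn(filter_probes_by_coverage(sim$beta[, ids]))
  prom <- aggregate_region_beta(beta, sim$manifest, "promoter")
  nid <- intersect(colnames(prom),
                   sheet$sample_id[sheet$tissue == t1 &
                                     sheet$phenotype == "normal"])
  cid <- intersect(colnames(prom),
                   sheet$sample_id[sheet$tissue == t1 &
                                     sheet$phenotype == "cancer"])
  win <- promoter_window(sim$annotation, 300, "symmetric")
  strata <- dhs_stratify(win, sim$dhs[[t1]])

  npro <- phenotype_mean_profile(prom, nid)
  genes <- intersect(names(npro), names(strata))
  tt <- stats::t.test(npro[genes][strata[genes] == "in"],
                      npro[genes][strata[genes] == "out"])
  st <- stratified_normal_cancer_t(prom, nid, cid, strata)
  list(p_normal_beta = tt$p.value,
       mean_in = mean(npro[genes][strata[genes] == "in"]),
       mean_out = mean(npro[genes][strata[genes] == "out"]),
       t_in = st$t[st$stratum == "in"],
       t_out = st$t[st$stratum == "out"],
       n_genes = n_genes)
}

#' Soundness of the recovered constitutive cu-GP set
#'
#' Simulates the default cohort (default noise and missingness), runs
#' coverage filtering, imputation, per-fetal-sample mixture thresholds
#' and cu-GP calling, and scores the recovered set against the
#' generator's ground states.
#'
#' @param seed Seed.
#' @return List: `recall` (fraction of unmethylated-ground-state
#'   promoters recovered), `contamination` (count of
#'   methylated-ground-state promoters in the set), `n_cu`, `n_genes`.
#' @export
study_constitutive_recovery <- function(seed = 1) {
  cfg <- synth_config(seed = seed + 500)
  cp <- cohort_pipeline(cfg)
  st <- cp$meth$truth$states$promoter
  unmeth <- names(st)[st == 1]
  meth <- names(st)[st == 3]
  list(recall = mean(unmeth %in% cp$cu$members),
       contamination = sum(meth %in% cp$cu$members),
       n_cu = length(cp$cu$members),
       n_genes = cfg$n_genes)
}
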