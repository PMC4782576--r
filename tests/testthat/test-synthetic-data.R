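test_that("generator is deterministic and annotation obeys its contracts", {
  cfg <- tiny_cfg()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  m1 <- generate_methylation(cfg, a1)
  m2 <- generate_methylation(cfg, a1)
  expect_identical(m1, m2)

  # every TSS200 probe lies inside the strand-aware upstream window
  man <- a1$manifest
  prom <- man[!is.na(man$region_class) & man$region_class == "TSS200", ]
  win <- granges_to_bed0(promoter_window(a1$annotation, 200, "upstream"))
  rownames(win) <- a1$annotation$gene_id
  expect_true(all(prom$pos >= win[prom$gene_id, "start"] &
                    prom$pos < win[prom$gene_id, "end"]))

  # probe counts per region match the config
  expect_true(all(table(prom$gene_id) == cfg$probes_per_promoter))
  body <- man[!is.na(man$region_class) & man$region_class == "Body", ]
  expect_true(all(table(body$gene_id) == cfg$probes_per_body))
  cgi <- man[!is.na(man$cgi_id) & is.na(man$region_class), ]
  expect_true(all(table(cgi$cgi_id) == cfg$probes_per_cgi))
  expect_length(a1$cgis, cfg$n_cgis)

  # body probes always fall in exons after the first (never exon 1)
  exb <- gene_body_intervals(a1$annotation, "exons_after_first")
  bdf <- granges_to_bed0(exb)
  bdf$gene <- names(exb)
  ok <- vapply(seq_len(nrow(body)), function(i) {
    rows <- bdf[bdf$gene == body$gene_id[i], , drop = FALSE]
    any(rows$start <= body$pos[i] & body$pos[i] < rows$end)
  }, TRUE)
  expect_true(all(ok))
})

test_that("beta values respect [0,1], missingness and low-coverage injection", {
  cfg <- tiny_cfg()
  sim <- simulate_dataset(cfg, tracks = FALSE)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1, na.rm = TRUE))
  expect_gt(mean(is.na(sim$beta)), 0)
  # injected low-coverage probes actually fall below the 70% filter in
  # expectation: their observed coverage is centred at 50%
  lowcov <- rowMeans(!is.na(sim$beta[sim$truth$low_coverage_probes, ]))
  expect_lt(mean(lowcov), 0.6)
})

test_that("shared fraction controls the cross-tissue structure of shifts", {
  # variance decomposition: the shared component carries sqrt(f) of the
  # shift variance, so that the cross-tissue R^2 of the shift equals f
  cfg <- synth_config(n_genes = 5000, n_tissues = 6,
                      samples_per_phenotype = 2, n_cgis = 10,
                      probes_per_promoter = 1, probes_per_body = 1,
                      probes_per_cgi = 1, shared_fraction = 0.6, seed = 5)
  lat <- ticmeth:::simulate_latents(cfg)
  d <- lat$delta_promoter
  a <- sqrt(sqrt(0.6)) * cfg$delta_sd
  shared_var <- stats::var(a * lat$u)
  expect_lt(abs(shared_var / mean(apply(d, 2, var)) - sqrt(0.6)), 0.03)

  r2 <- cor(d)^2
  expect_lt(abs(mean(r2[upper.tri(r2)]) - 0.6), 0.05)

  # limiting cases
  cfg1 <- synth_config(n_genes = 2000, n_tissues = 4,
                       samples_per_phenotype = 2, n_cgis = 10,
                       shared_fraction = 1, seed = 6)
  d1 <- ticmeth:::simulate_latents(cfg1)$delta_promoter
  expect_gt(min(cor(d1)^2), 0.999)
  cfg0 <- synth_config(n_genes = 2000, n_tissues = 4,
                       samples_per_phenotype = 2, n_cgis = 10,
                       shared_fraction = 0, seed = 6)
  d0 <- ticmeth:::simulate_latents(cfg0)$delta_promoter
  r20 <- cor(d0)^2
  expect_lt(mean(r20[upper.tri(r20)]), 0.01)
})

test_that("histone tracks encode the coupling signs and recover targets", {
  cfg <- tiny_cfg(bin_noise_sd = 0)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  hist <- generate_histone_tracks(cfg, meth$truth, ann, tracks = TRUE)

  # aggregating the emitted track over the +/-300 promoter window
  # recovers the per-gene target exactly when bin noise is off
  t1 <- names(hist$tracks$normal)[1]
  got <- promoter_signal_matrix(hist$tracks$normal[[t1]]$H3K27me3,
                                ann$annotation, 300)
  want <- hist$gene_signals$normal[[t1]]$H3K27me3
  expect_equal(got, want, tolerance = 1e-8)

  # K36 body track recovers its target
  got36 <- gene_body_signal(hist$tracks$normal[[t1]]$H3K36me3,
                            ann$annotation, "span")
  expect_equal(got36, hist$gene_signals$normal[[t1]]$H3K36me3,
               tolerance = 1e-8)

  # sign structure vs the promoter shift
  d <- meth$truth$delta_promoter[, t1]
  expect_gt(cor(hist$gene_signals$normal[[t1]]$H3K27me3, d), 0)
  expect_lt(cor(hist$gene_signals$normal[[t1]]$H3K4me3, d), 0)
  expect_lt(cor(hist$gene_signals$normal[[t1]]$H3K36me3, d), 0)

  # all signals are non-negative and tracks are valid (sorted,
  # non-overlapping)
  expect_true(all(S4Vectors::mcols(hist$tracks$normal[[t1]]$H3K4me3)$score >= 0))
  expect_silent(validate_track(hist$tracks$normal[[t1]]$H3K4me3))
})

test_that("expression couples to marks and zeroes match the configured rate", {
  cfg <- synth_config(n_genes = 3000, n_tissues = 2,
                      samples_per_phenotype = 2, n_cgis = 10, seed = 8)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  hist <- generate_histone_tracks(cfg, meth$truth, ann, tracks = FALSE)
  ref <- hist$gene_signals$hesc_lines$H1
  rpkm <- generate_expression(cfg, ref$H3K4me3, ref$H3K27me3)
  rpkm2 <- generate_expression(cfg, ref$H3K4me3, ref$H3K27me3)
  expect_identical(rpkm, rpkm2)
  expect_true(all(rpkm >= 0))

  nz <- rpkm > 0
  expect_gt(cor(log2(rpkm[nz]), ref$H3K4me3[nz]), 0)
  expect_lt(cor(log2(rpkm[nz]), ref$H3K27me3[nz]), 0)

  # zero fraction within binomial error of the configured rate
  phat <- mean(rpkm == 0)
  ci <- cfg$zero_rpkm_frac +
    c(-4, 4) * sqrt(cfg$zero_rpkm_frac * (1 - cfg$zero_rpkm_frac) / 3000)
  expect_gt(phat, ci[1]); expect_lt(phat, ci[2])
})

test_that("DHS coverage tracks normal methylation through the logistic link", {
  cfg <- synth_config(n_genes = 2000, n_tissues = 2,
                      samples_per_phenotype = 2, n_cgis = 10, seed = 9)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  mu0 <- cfg$state_means[meth$truth$states$promoter]
  npb <- matrix(mu0, nrow = length(mu0), ncol = 2,
                dimnames = list(ann$annotation$gene_id, c("t01", "t02")))

  dhs <- generate_dhs(cfg, npb, ann)
  win <- promoter_window(ann$annotation, 300, "symmetric")
  inside <- overlaps_any(win, dhs$t01)
  tt <- t.test(mu0[inside], mu0[!inside])
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(mu0[inside]), mean(mu0[!inside]))

  # zero slope -> coverage independent of methylation
  cfg0 <- synth_config(n_genes = 2000, n_tissues = 2,
                       samples_per_phenotype = 2, n_cgis = 10,
                       dhs_slope = 0, seed = 9)
  dhs0 <- generate_dhs(cfg0, npb, ann)
  in0 <- overlaps_any(win, dhs0$t01)
  expect_lt(abs(mean(mu0[in0]) - mean(mu0[!in0])), 0.05)

  # DHS intervals survive a BED round trip
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(dhs$t01, tf)
  expect_equal(granges_to_bed0(read_bed(tf))[, 1:3],
               granges_to_bed0(dhs$t01)[, 1:3])
})

test_that("true top-shift labels agree with recovered DM labels", {
  # cohort sized like a TCGA series: t-statistic ranking carries
  # variance-estimate noise, so truth agreement needs large cohorts
  # (it degrades to ~80% at 20 samples/phenotype)
  cfg <- synth_config(n_tissues = 2, samples_per_phenotype = 100,
                      missing_frac = 0, low_cov_frac = 0, seed = 13)
  sim <- simulate_dataset(cfg, tracks = FALSE)
  sheet <- sim$samples
  prom <- aggregate_region_beta(sim$beta, sim$manifest, "promoter")
  nid <- sheet$sample_id[sheet$tissue == "t01" & sheet$phenotype == "normal"]
  cid <- sheet$sample_id[sheet$tissue == "t01" & sheet$phenotype == "cancer"]
  # restrict to true unmethylated ground-state promoters (the cu analog)
  cu <- names(sim$truth$states$promoter)[sim$truth$states$promoter == 1]
  tt <- dm_t_test(prom[cu, ], nid, cid)
  lab <- rank_and_label(tt, N = 200)
  top_true <- cu[order(-sim$truth$delta_promoter[cu, "t01"])][1:200]
  overlap <- mean(lab$region_id[lab$label == "DM"] %in% top_true)
  expect_gte(overlap, 0.85)
})
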