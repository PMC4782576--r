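test_that("ROC sweep handles separation, ties and label flips", {
  sig <- c(g1 = 0.9, g2 = 0.8, g3 = 0.2, g4 = 0.1)
  lab <- c(g1 = "DM", g2 = "DM", g3 = "nonDM", g4 = "nonDM")
  r <- roc_curve(sig, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  # interleaved signals: 2 concordant of 4 pairs
  sig2 <- c(g1 = 0.1, g2 = 0.9, g3 = 0.2, g4 = 0.8)
  expect_equal(roc_curve(sig2, lab)$auc, 0.5)

  # flipping labels reflects the AUC
  flip <- ifelse(lab == "DM", "nonDM", "DM")
  names(flip) <- names(lab)
  expect_equal(roc_curve(sig, flip)$auc, 1 - roc_curve(sig, lab)$auc)

  # all-tied signal gives 0.5
  expect_equal(auc_from_labels(setNames(rep(1, 4), names(lab)), lab), 0.5)

  expect_error(roc_curve(sig, setNames(rep("DM", 4), names(lab))),
               "both DM and nonDM")
})

test_that("trapezoid AUC equals the Mann-Whitney oracle and pROC", {
  skip_if_not_installed("pROC")
  set.seed(161)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    sig <- setNames(round(runif(n), 2), paste0("g", 1:n))  # forces ties
    lab <- setNames(sample(c("DM", "nonDM"), n, TRUE, prob = c(0.4, 0.6)),
                    names(sig))
    if (length(unique(lab)) < 2) next
    a_sweep <- roc_curve(sig, lab)$auc
    a_rank <- auc_from_labels(sig, lab)
    a_pair <- oracle_auc(sig, lab)
    expect_equal(a_sweep, a_rank, tolerance = 1e-12)
    expect_equal(a_sweep, a_pair, tolerance = 1e-12)
  }
  # independent library cross-check on a handful of cases
  for (i in 1:5) {
    sig <- setNames(runif(60), paste0("g", 1:60))
    lab <- setNames(rep(c("DM", "nonDM"), 30), names(sig))
    a_ref <- as.numeric(suppressMessages(pROC::auc(
      response = factor(lab, c("nonDM", "DM")), predictor = sig,
      direction = "<")))
    expect_equal(roc_curve(sig, lab)$auc, a_ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and near 0.5 under permutation", {
  set.seed(171)
  sig <- setNames(rexp(600), paste0("g", 1:600))
  lab <- setNames(ifelse(sig + rnorm(600) > 1, "DM", "nonDM"), names(sig))
  a0 <- auc_from_labels(sig, lab)
  expect_equal(auc_from_labels(log(sig + 1), lab), a0, tolerance = 1e-12)
  expect_equal(auc_from_labels(sig + 100, lab), a0, tolerance = 1e-12)
  expect_equal(auc_from_labels(sig^3, lab), a0, tolerance = 1e-12)

  perm_auc <- vapply(1:100, function(i) {
    auc_from_labels(sig, setNames(sample(lab), names(lab)))
  }, 0)
  expect_gt(mean(perm_auc), 0.47)
  expect_lt(mean(perm_auc), 0.53)
})

test_that("orientation maps protective marks onto the accuracy scale", {
  set.seed(181)
  u <- rnorm(500); names(u) <- paste0("g", 1:500)
  lab <- ifelse(rank(-u) <= 150, "DM",
                ifelse(rank(-u) > 350, "nonDM", "unlabeled"))
  names(lab) <- names(u)
  dm <- data.frame(region_id = names(u), t = u, label = lab)
  sets <- list(normal = list(
    H3K27me3 = u + rnorm(500, sd = 0.5),
    H3K4me3 = -u + rnorm(500, sd = 0.5),
    H3K36me3 = -u + rnorm(500, sd = 0.5)))
  for (m in names(sets$normal)) names(sets$normal[[m]]) <- names(u)

  raw <- predict_dm_auc(sets, dm, orientation = "occupancy")
  expect_gt(raw$auc[raw$mark == "H3K27me3"], 0.5)
  expect_lt(raw$auc[raw$mark == "H3K4me3"], 0.5)

  assoc <- predict_dm_auc(sets, dm, orientation = "association")
  expect_gt(min(assoc$auc), 0.5)
  expect_equal(assoc$auc[assoc$mark == "H3K4me3"],
               1 - raw$auc[raw$mark == "H3K4me3"])
})

test_that("paired Wilcoxon on AUC pairs is exact where the paper's design is", {
  # 6 tissues, uniformly positive distinct differences -> p = 1/64
  normal <- c(0.91, 0.83, 0.85, 0.74, 0.95, 0.88)
  hesc <- normal - c(0.11, 0.12, 0.05, 0.14, 0.06, 0.07)
  res <- paired_wilcoxon_auc(normal, hesc)
  expect_equal(res$p, 1 / 2^6)
  expect_equal(res$n_used, 6L)

  # swapping the pair order tests the complementary tail
  res_sw <- paired_wilcoxon_auc(hesc, normal, alternative = "less")
  expect_equal(res_sw$p, 1 / 2^6)

  # zero differences are dropped before the exact test
  res_z <- paired_wilcoxon_auc(c(normal, 0.5), c(hesc, 0.5))
  expect_equal(res_z$n_used, 6L)
  expect_equal(res_z$p, 1 / 2^6)

  expect_warning(res0 <- paired_wilcoxon_auc(normal, normal), "zero")
  expect_equal(res0$p, 1)

  # symmetric null differences give a large p
  set.seed(191)
  d <- rnorm(20, 0, 0.05)
  resn <- paired_wilcoxon_auc(0.7 + d, 0.7 - d / 2 * 0 + 0)
  expect_gt(resn$p, 0.05)
})

test_that("the 2000-gene DM set and stratified split match the study design", {
  set.seed(201)
  tstats <- data.frame(region_id = sprintf("g%04d", 1:2500),
                       t = rnorm(2500))
  lab <- build_dm_gene_set(tstats)
  expect_equal(sum(lab$label == "DM"), 1000)
  expect_equal(sum(lab$label == "nonDM"), 1000)
  expect_length(intersect(lab$region_id[lab$label == "DM"],
                          lab$region_id[lab$label == "nonDM"]), 0)
  expect_error(build_dm_gene_set(tstats[1:1500, ]), "need >= 2000")

  sp <- stratified_split(lab, seed = 3)
  tab <- table(sp$part, sp$label)
  expect_equal(unname(tab["train", ]), c(500, 500))
  expect_equal(unname(tab["validation", ]), c(200, 200))
  expect_equal(unname(tab["test", ]), c(300, 300))
  expect_setequal(sp$region_id, lab$region_id)
  expect_identical(stratified_split(lab, seed = 3), sp)
  assign_of <- function(s) {
    x <- stats::setNames(s$part, s$region_id)
    x[lab$region_id]
  }
  expect_false(identical(assign_of(stratified_split(lab, seed = 4)),
                         assign_of(sp)))
})

test_that("logistic fits agree with closed forms and a generic optimiser", {
  set.seed(211)
  # null model: balanced labels, pure-noise predictor
  n <- 400
  X <- matrix(rnorm(n), n, 1, dimnames = list(paste0("g", 1:n), "H3K27me3"))
  y <- rep(c("DM", "nonDM"), n / 2)
  f0 <- fit_logistic(X, y)
  expect_lt(abs(f0$coefficients[["(Intercept)"]]), 0.25)
  # intercept-only likelihood bound: lnL = n*ln(1/2) up to the small
  # improvement a noise predictor can buy
  expect_lt(abs(f0$loglik - n * log(0.5)), 4)
  expect_gte(f0$loglik, n * log(0.5))
  expect_equal(f0$aic, 2 * 2 - 2 * f0$loglik)

  # ML solution matches optim on the same standardized design
  X3 <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(paste0("g", 1:n),
                               c("H3K4me3", "H3K27me3", "H3K36me3")))
  eta <- X3[, 2] - X3[, 1]
  y3 <- ifelse(runif(n) < plogis(eta), "DM", "nonDM")
  f3 <- fit_logistic(X3, y3)
  Z <- scale(X3)
  nll <- function(b) {
    -sum(ifelse(y3 == "DM", 1, 0) * (b[1] + Z %*% b[-1]) -
           log1p(exp(b[1] + Z %*% b[-1])))
  }
  o <- optim(rep(0, 4), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(f3$coefficients - o$par)), 1e-5)

  # perfect separation is flagged, not silently accepted
  Xs <- matrix(c(seq(-2, -0.1, length.out = 20),
                 seq(0.1, 2, length.out = 20)), 40, 1,
               dimnames = list(paste0("g", 1:40), "H3K27me3"))
  ys <- rep(c("nonDM", "DM"), each = 20)
  w <- capture_warnings(fs <- fit_logistic(Xs, ys))
  expect_true(any(grepl("separation", w)))
  expect_true(fs$separation)
})

test_that("three-mark models recover the coupling sign pattern", {
  set.seed(221)
  n <- 2000
  u <- rnorm(n); names(u) <- sprintf("g%04d", 1:n)
  S <- cbind(H3K4me3 = ticmeth:::softplus(-u + 2 + rnorm(n, sd = 0.5)),
             H3K27me3 = ticmeth:::softplus(u + 1 + rnorm(n, sd = 0.5)),
             H3K36me3 = ticmeth:::softplus(-u + 2 + rnorm(n, sd = 0.5)))
  rownames(S) <- names(u)
  tt <- data.frame(region_id = names(u), t = u + rnorm(n, sd = 0.3))
  lab <- build_dm_gene_set(tt)
  fit <- fit_logistic(S[lab$region_id, ], lab$label)
  expect_gt(fit$z[["H3K27me3"]], 0)
  expect_lt(fit$z[["H3K4me3"]], 0)
  expect_lt(fit$z[["H3K36me3"]], 0)
})

test_that("model selection prefers the data-generating predictor set", {
  set.seed(231)
  all3_wins <- 0; small_wins <- 0
  for (i in 1:10) {
    n <- 2000
    u <- rnorm(n); names(u) <- sprintf("g%04d", 1:n)
    tt <- data.frame(region_id = names(u), t = u + rnorm(n, sd = 0.3))
    lab <- build_dm_gene_set(tt)
    sp <- stratified_split(lab, seed = i)

    # all three marks informative
    S <- cbind(H3K4me3 = -u + rnorm(n, sd = 0.8),
               H3K27me3 = u + rnorm(n, sd = 0.8),
               H3K36me3 = -u + rnorm(n, sd = 0.8))
    rownames(S) <- names(u)
    ms <- model_selection(S, lab, sp)
    if (ms$best == "H3K4me3+H3K27me3+H3K36me3") all3_wins <- all3_wins + 1
    # generalisation: test AUC close to validation AUC
    val <- ms$report$validation_auc[ms$report$model == ms$best]
    expect_lt(abs(ms$test_auc - val), 0.1)

    # K27-only informative: AIC should prefer smaller models
    S1 <- cbind(H3K4me3 = rnorm(n), H3K27me3 = u + rnorm(n, sd = 0.8),
                H3K36me3 = rnorm(n))
    rownames(S1) <- names(u)
    ms1 <- model_selection(S1, lab, sp)
    # AIC prefers the true single-predictor model over the full model
    aic1 <- ms1$report$aic[ms1$report$model == "H3K27me3"]
    aic3 <- ms1$report$aic[ms1$report$model == "H3K4me3+H3K27me3+H3K36me3"]
    if (aic1 < aic3) small_wins <- small_wins + 1
  }
  expect_gte(all3_wins, 8)
  expect_gte(small_wins, 8)

  # report covers all seven predictor subsets
  expect_equal(nrow(ms$report), 7)
  expect_setequal(ms$report$k, c(1, 1, 1, 2, 2, 2, 3))
})
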