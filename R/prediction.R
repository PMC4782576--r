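# Prediction of cancer differential methylation from histone signals:
# threshold-sweep ROC/AUC, Mann-Whitney AUC oracle, normal-vs-hESC
# paired Wilcoxon comparison, and multivariate logistic model selection.

#' ROC curve of a signal against DM labels (threshold sweep)
#'
#' Occupancy at a threshold is `signal >= threshold`; sweeping the
#' threshold over all unique signal values yields a 2x2 contingency
#' table per threshold, from which sensitivity (DM positive) and
#' one-minus-specificity are computed.  `(0,0)` and `(1,1)` are
#' appended and the AUC is the trapezoid area.  Raw AUCs are reported
#' as-is: marks negatively associated with the outcome give AUC < 0.5.
#'
#' @param signal Named per-gene signal vector (genes with `NA` excluded).
#' @param labels Vector in `{"DM","nonDM"}` aligned with `signal` (or
#'   named; `"unlabeled"` entries are ignored).
#' @return Object of class `roc_result`: `points` (fpr, tpr), `auc`,
#'   `n_dm`, `n_nondm`.
#' @export
roc_curve <- function(signal, labels) {
  z <- align_signal_labels(signal, labels)
  pos <- z$labels == "DM"
  ord <- order(-z$signal)
  s <- z$signal[ord]; pos <- pos[ord]
  # cumulative counts at each distinct threshold (descending)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last_of_tie]
  fp <- cumsum(!pos)[last_of_tie]
  tpr <- c(0, tp / sum(z$labels == "DM"), 1)
  fpr <- c(0, fp / sum(z$labels == "nonDM"), 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  out <- list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
              n_dm = sum(pos), n_nondm = sum(!pos))
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d DM vs %d nonDM)\n",
              x$auc, x$n_dm, x$n_nondm))
  invisible(x)
}

#' Mann-Whitney AUC (pairwise concordance oracle)
#'
#' AUC = (concordant pairs + half the tied pairs) / (n_DM * n_nonDM)
#' over all DM x nonDM pairs; equals the trapezoid area of
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0,1]`.
#' @export
auc_from_labels <- function(signal, labels) {
  z <- align_signal_labels(signal, labels)
  pos <- z$labels == "DM"
  r <- rank(z$signal)                    # midranks handle ties
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

align_signal_labels <- function(signal, labels) {
  if (!is.null(names(signal)) && !is.null(names(labels))) {
    ids <- intersect(names(signal), names(labels))
    signal <- signal[ids]; labels <- labels[ids]
  }
  keep <- !is.na(signal) & labels %in% c("DM", "nonDM")
  signal <- signal[keep]; labels <- labels[keep]
  if (!any(labels == "DM") || !any(labels == "nonDM")) {
    stopf("need both DM and nonDM labels with non-missing signal")
  }
  list(signal = signal, labels = labels)
}

labels_vector <- function(dm) stats::setNames(dm$label, dm$region_id)

#' AUC table for predicting DM status from histone signals
#'
#' Computes one AUC per (mark, source) combination.  With
#' `orientation = "occupancy"` (the raw sweep) AUCs of negatively
#' associated marks fall below 0.5 and are reported as-is.  With
#' `orientation = "association"` the occupancy direction follows the
#' a-priori expected association of each mark with the outcome (e.g.
#' for promoter hypermethylation: H3K27me3 positive, H3K4me3 and
#' H3K36me3 protective), reporting prediction accuracy on the
#' conventional >= 0.5 scale.
#'
#' @param signal_sets Named list (per source, e.g. `normal`, `hesc`) of
#'   named lists (per mark) of per-gene signal vectors.
#' @param dm_labels [rank_and_label()] result (N = 300 default labels).
#' @param orientation `"occupancy"` or `"association"`.
#' @param expected_sign Named numeric (+1/-1) per mark, the a-priori
#'   association direction used by `"association"` orientation.
#' @return `data.frame(source, mark, auc, n_dm, n_nondm)`.
#' @export
predict_dm_auc <- function(signal_sets, dm_labels,
                           orientation = c("occupancy", "association"),
                           expected_sign = c(H3K4me3 = -1, H3K27me3 = 1,
                                             H3K36me3 = -1)) {
  orientation <- match.arg(orientation)
  lab <- labels_vector(dm_labels)
  out <- NULL
  for (src in names(signal_sets)) {
    for (mark in names(signal_sets[[src]])) {
      sig <- signal_sets[[src]][[mark]]
      if (is.null(sig)) next
      auc <- auc_from_labels(sig, lab)
      if (orientation == "association" &&
          !is.na(expected_sign[mark]) && expected_sign[mark] < 0) {
        auc <- 1 - auc
      }
      z <- align_signal_labels(sig, lab)
      out <- rbind(out, data.frame(source = src, mark = mark, auc = auc,
                                   n_dm = sum(z$labels == "DM"),
                                   n_nondm = sum(z$labels == "nonDM"),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Paired Wilcoxon test of normal-tissue vs hESC AUCs
#'
#' One-tailed exact signed-rank test of the alternative
#' "normal > hESC" across tissues.  Zero differences are dropped (all
#' zero returns p = 1 with a warning); the exact distribution is used
#' for up to 25 pairs without ties, otherwise the normal approximation
#' with continuity correction.
#'
#' @param auc_normal,auc_hesc Paired AUC vectors (one entry per tissue).
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   `"greater"`).
#' @return List: `p`, `statistic` (V), `n_used`.
#' @export
paired_wilcoxon_auc <- function(auc_normal, auc_hesc,
                                alternative = "greater") {
  stopifnot(length(auc_normal) == length(auc_hesc))
  d <- auc_normal - auc_hesc
  d <- d[d != 0]
  if (!length(d)) {
    warnf("all AUC differences are zero")
    return(list(p = 1, statistic = NA_real_, n_used = 0L))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(d))
}

#' Build the 2000-gene DM set for multivariate modelling
#'
#' Top 1000 and bottom 1000 genes by t statistic (hypermethylation
#' direction by default), labelled DM / nonDM.
#'
#' @param tstats `data.frame(region_id, t)` over >= 2000 genes.
#' @param N Genes per label (default 1000).
#' @param direction Ranking direction (see [rank_and_label()]).
#' @return Labelled data frame (DM and nonDM rows only).
#' @export
build_dm_gene_set <- function(tstats, N = 1000, direction = "hyper") {
  if (nrow(tstats) < 2 * N) {
    stopf("need >= %d genes, got %d", 2 * N, nrow(tstats))
  }
  lab <- rank_and_label(tstats, N = N, direction = direction)
  lab[lab$label != "unlabeled", ]
}

#' Stratified train/validation/test split
#'
#' Within each label class, genes are shuffled (seeded) and allocated to
#' the parts by largest-remainder rounding, so class balance is
#' preserved in every part.  Default fractions 50/20/30.
#'
#' @param labeled `data.frame(region_id, label)` with labels DM/nonDM.
#' @param fractions Numeric of length 3 summing to 1
#'   (train, validation, test).
#' @param seed Shuffle seed.
#' @return `data.frame(region_id, label, part)`.
#' @export
stratified_split <- function(labeled, fractions = c(0.5, 0.2, 0.3),
                             seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  parts <- c("train", "validation", "test")
  out <- NULL
  with_seed(seed, {
    for (cl in unique(labeled$label)) {
      ids <- sample(labeled$region_id[labeled$label == cl])
      n <- length(ids)
      base <- floor(fractions * n)
      rem <- fractions * n - base
      extra <- order(-rem, seq_along(rem))[seq_len(n - sum(base))]
      cnt <- base; cnt[extra] <- cnt[extra] + 1L
      out <- rbind(out, data.frame(
        region_id = ids, label = cl,
        part = rep(parts, cnt), stringsAsFactors = FALSE))
    }
  })
  bad <- table(factor(out$part, parts), out$label) == 0
  if (any(bad)) stopf("a split part received zero genes of one class")
  out
}

#' Logistic regression of DM status on histone signals
#'
#' Maximum-likelihood logit fit (IRLS via [stats::glm()]); predictors
#' are standardised to mean 0, SD 1 (scaling stored for prediction on
#' held-out genes).  Reports coefficients, Wald z, log-likelihood and
#' AIC = 2k - 2 lnL.  Perfect separation is flagged.
#'
#' @param design Gene x predictor matrix (no missing values; genes with
#'   `NA` are dropped with a message).
#' @param labels Vector in `{"DM","nonDM"}` along rows of `design`.
#' @param standardize Standardise predictors before fitting.
#' @return Object of class `dm_logit`: `coefficients`, `z`, `loglik`,
#'   `aic`, `predictors`, `center`, `scale`, `separation`.
#' @export
fit_logistic <- function(design, labels, standardize = TRUE) {
  design <- as.matrix(design)
  keep <- stats::complete.cases(design)
  if (!all(keep)) {
    message(sprintf("fit_logistic: dropped %d gene(s) with missing predictors",
                    sum(!keep)))
    design <- design[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  y <- as.integer(labels == "DM")
  ctr <- rep(0, ncol(design)); scl <- rep(1, ncol(design))
  if (standardize) {
    ctr <- colMeans(design)
    scl <- apply(design, 2, stats::sd)
    scl[scl == 0] <- 1
    design <- sweep(sweep(design, 2, ctr), 2, scl, "/")
  }
  df <- data.frame(y = y, design)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  out <- list(
    coefficients = stats::coef(fit),
    z = sm[, "z value"],
    loglik = as.numeric(stats::logLik(fit)),
    aic = fit$aic,
    predictors = colnames(design),
    center = ctr, scale = scl,
    separation = sep,
    glm = fit
  )
  if (sep) warnf("possible perfect separation in logistic fit")
  class(out) <- "dm_logit"
  out
}

#' Predicted DM probabilities from a logistic fit
#' @param object A `dm_logit` fit.
#' @param newdata Gene x predictor matrix on the original signal scale.
#' @param ... Unused.
#' @return Numeric vector of fitted probabilities.
#' @export
predict.dm_logit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  eta <- object$coefficients[1] +
    drop(z %*% object$coefficients[-1])
  stats::plogis(eta)
}

#' Fit and select among the seven histone predictor subsets
#'
#' All seven non-empty subsets of `{H3K4me3, H3K27me3, H3K36me3}` (3
#' single, 3 double, 1 triple) are fitted on the training part; models
#' are ranked by validation AUC (ties: fewer predictors, then lower
#' AIC) and the winner's blind test AUC is reported.
#'
#' @param signals Gene x mark signal matrix (all three marks).
#' @param labeled `data.frame(region_id, label)` (from
#'   [build_dm_gene_set()]).
#' @param split [stratified_split()] assignment.
#' @return List: `best` (model name), `best_fit` (`dm_logit`),
#'   `test_auc`, `report` (per-model train/validation AUC and AIC).
#' @export
model_selection <- function(signals, labeled, split) {
  marks <- colnames(signals)
  subsets <- unlist(lapply(seq_along(marks), function(k) {
    asplit(utils::combn(marks, k), 2)
  }), recursive = FALSE)
  part <- stats::setNames(split$part, split$region_id)
  lab <- stats::setNames(labeled$label, labeled$region_id)
  ids <- intersect(rownames(signals), names(lab))
  ids <- ids[stats::complete.cases(signals[ids, , drop = FALSE])]
  tr <- ids[part[ids] == "train"]
  va <- ids[part[ids] == "validation"]
  te <- ids[part[ids] == "test"]

  report <- NULL
  fits <- list()
  for (ss in subsets) {
    nm <- paste(ss, collapse = "+")
    fit <- tryCatch(
      fit_logistic(signals[tr, ss, drop = FALSE], lab[tr]),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      report <- rbind(report, data.frame(
        model = nm, k = length(ss), train_auc = NA, validation_auc = NA,
        aic = NA, note = conditionMessage(fit), stringsAsFactors = FALSE))
      next
    }
    fits[[nm]] <- fit
    p_tr <- predict(fit, signals[tr, , drop = FALSE])
    p_va <- predict(fit, signals[va, , drop = FALSE])
    report <- rbind(report, data.frame(
      model = nm, k = length(ss),
      train_auc = auc_from_labels(stats::setNames(p_tr, tr), lab),
      validation_auc = auc_from_labels(stats::setNames(p_va, va), lab),
      aic = fit$aic, note = "", stringsAsFactors = FALSE))
  }
  ok <- !is.na(report$validation_auc)
  ord <- order(-report$validation_auc[ok], report$k[ok], report$aic[ok])
  best <- report$model[ok][ord[1]]
  best_fit <- fits[[best]]
  p_te <- predict(best_fit, signals[te, , drop = FALSE])
  list(best = best, best_fit = best_fit,
       test_auc = auc_from_labels(stats::setNames(p_te, te), lab),
       report = report)
}
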