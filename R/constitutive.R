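# Constitutive region sets: regions unmethylated (or methylated) in
# every fetal ground-state sample, under per-sample mixture thresholds.

#' Call the methylation state of region values against thresholds
#'
#' Strict inequalities on both sides: `beta < L` is unmethylated,
#' `beta > U` is methylated, anything else (including `beta == L` or
#' `== U`) is intermediate.
#'
#' @param beta Numeric vector/matrix of beta values in `[0,1]`.
#' @param L,U Lower and upper thresholds, `0 < L < U < 1`.
#' @return Character vector/matrix of states in
#'   `{"unmethylated", "intermediate", "methylated"}`.
#' @export
call_region_state <- function(beta, L, U) {
  if (L >= U) stopf("lower threshold L (%g) must be < upper threshold U (%g)", L, U)
  stopifnot(L > 0, U < 1)
  out <- ifelse(beta < L, "unmethylated",
                ifelse(beta > U, "methylated", "intermediate"))
  out
}

#' Constitutive region sets across all fetal samples
#'
#' `cu_gp` / `cu_cgi`: regions called unmethylated in every fetal
#' sample; `cm_gb`: gene bodies called methylated in every fetal sample.
#' Thresholds are per sample, from each sample's three-state beta
#' mixture fit.
#'
#' @param region_betas Region x sample matrix over fetal samples.
#' @param thresholds Named list (one entry per sample, by sample id) of
#'   `c(L=, U=)` threshold vectors, e.g. from [state_thresholds()].
#' @param set_kind `"cu_gp"`, `"cu_cgi"` or `"cm_gb"`.
#' @return Object of class `constitutive_set`: `set_kind`, `members`
#'   (region ids), `n_samples`, `thresholds`.
#' @export
constitutive_set <- function(region_betas, thresholds,
                             set_kind = c("cu_gp", "cu_cgi", "cm_gb")) {
  set_kind <- match.arg(set_kind)
  samples <- colnames(region_betas)
  missing_fit <- setdiff(samples, names(thresholds))
  if (length(missing_fit)) {
    stopf("no mixture fit/thresholds for sample(s): %s",
          paste(missing_fit, collapse = ", "))
  }
  want <- if (set_kind == "cm_gb") "methylated" else "unmethylated"
  ok <- matrix(FALSE, nrow(region_betas), length(samples),
               dimnames = dimnames(region_betas))
  for (s in samples) {
    th <- thresholds[[s]]
    st <- call_region_state(region_betas[, s], th[["L"]], th[["U"]])
    ok[, s] <- !is.na(st) & st == want
  }
  members <- rownames(region_betas)[rowSums(ok) == length(samples)]
  out <- list(set_kind = set_kind, members = members,
              n_samples = length(samples),
              thresholds = thresholds[samples])
  class(out) <- "constitutive_set"
  out
}

#' @export
print.constitutive_set <- function(x, ...) {
  cat(sprintf("%s: %d member regions (constitutive across %d fetal samples)\n",
              x$set_kind, length(x$members), x$n_samples))
  invisible(x)
}

#' Fit per-sample mixtures and derive thresholds for a set of samples
#'
#' Convenience wrapper: fits [fit_beta_mixture()] on each sample's
#' probe-level values and returns [state_thresholds()] per sample.
#'
#' @param probe_betas Probe x sample matrix (probe-level values).
#' @param samples Sample ids (default: all columns).
#' @param ... Passed to [fit_beta_mixture()].
#' @return Named list of `c(L=, U=)` per sample.
#' @export
sample_thresholds <- function(probe_betas, samples = colnames(probe_betas),
                              ...) {
  out <- lapply(samples, function(s) {
    state_thresholds(fit_beta_mixture(probe_betas[, s], ...))
  })
  names(out) <- samples
  out
}
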