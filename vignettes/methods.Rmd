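---
title: "Dissecting tissue-independent cancer DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting tissue-independent cancer DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticmeth)
```

# The scientific question

Cancer genomes show two canonical DNA-methylation aberrations: gain of
methylation at gene promoters that are unmethylated in normal tissue,
and loss of methylation over gene bodies that are normally methylated.
`ticmeth` implements a pipeline that asks three questions about these
alterations, using Illumina 450k-style beta values (methylation
fractions in $[0,1]$):

1. **How tissue-independent are they?**  Starting from a fetal
   ground state, we call *constitutively unmethylated gene promoters*
   (cu-GPs), *constitutively unmethylated CpG islands* (cu-CGIs) and
   *constitutively methylated gene bodies* (cm-GBs) — regions in the
   ground state in *every* fetal sample of every tissue — and then
   correlate the cancer methylation profiles of these regions between
   tumour types.  The squared Pearson correlation ($R^2$) between two
   cancer types over cu-GPs measures how much of one cancer's
   methylation landscape is explained by another's.

2. **Can chromatin in the normal cell of origin predict them?**  We
   aggregate histone ChIP-seq significance tracks ($S = -\log_{10} P$
   per interval) over promoter windows (H3K4me3, H3K27me3) and gene
   bodies (H3K36me3), and ask how well each mark — measured in the
   matched normal tissue versus in embryonic stem cells — predicts
   which promoters hypermethylate (ROC/AUC on top-$N$ vs bottom-$N$
   genes ranked by a cancer-vs-normal $t$ statistic), and how the three
   marks combine in a logistic model selected by validation AUC and
   AIC.

3. **What does chromatin accessibility add?**  Promoters are
   stratified by DNase-hypersensitive-site (DHS) membership and by
   bivalency (H3K4me3 + H3K27me3) in normal tissue, and the
   cancer-vs-normal contrast is compared across strata.

Because the consortium data sets behind these questions (fetal 450k
compendia, TCGA level-3 arrays, Roadmap/IHEC ChIP-seq) cannot ship with
a package, `ticmeth` pairs every analysis stage with a seeded
synthetic-data generator whose structure encodes the biology the
pipeline is supposed to detect.  All tests and the acceptance script
run end-to-end on generated data.

# The methylation state model

## Three-state beta mixture

Per sample, probe-level beta values are modelled as a three-component
beta mixture (unmethylated / half-methylated / fully methylated):

$$p(\beta) = \sum_{k=1}^{3} \pi_k \,
  \mathrm{Beta}(\beta;\, a_k, b_k), \qquad \sum_k \pi_k = 1 .$$

`fit_beta_mixture()` fits this by EM.  The E-step uses the beta
log-densities through their sufficient statistics ($\log\beta$,
$\log(1-\beta)$); the M-step maximises each component's weighted beta
log-likelihood exactly by damped Newton steps on $(a_k, b_k)$ — the
objective reduces to
$(a-1)S_1 + (b-1)S_2 - W\log B(a,b)$ with scalar statistics, so the
inner optimisation is $O(1)$ per step.  Only likelihood-improving
steps are accepted, so the EM log-likelihood is non-decreasing (this
is asserted by a property test on arbitrary inputs).

Numerical choices:

* **Initialisation** is deterministic given the data: component means
  seeded at the 10th/50th/90th percentiles with concentration 10.
  This avoids label switching on the trimodal distributions typical of
  450k samples.
* Values at exactly 0 or 1 are nudged by $\varepsilon = 10^{-6}$
  (the beta density is unbounded there).
* **Convergence** is declared at a relative log-likelihood change below
  `tol` (default $10^{-6}$); non-convergence at `max_iter` returns the
  best fit with a flag and warning.  A component collapsing below
  weight $10^{-4}$ triggers one jittered re-initialisation, then a
  flag.
* **Subsampling**: fits use at most `n_max = 5000` values (seeded
  subsample).  Threshold estimates are stable well below this size;
  the multi-sample pipeline uses `n_max = 3000`.
* On *unimodal* data the three-component likelihood is not
  identifiable: many weight configurations achieve the same maximum,
  and the EM endpoint depends on the path.  The tests therefore assert
  that the *fitted density* matches unimodal truth, not any particular
  weight split.

## State thresholds

The thresholds that turn region-level beta values into states are the
posterior crossing points of the fitted mixture: $L$ is the smallest
$\beta$ between the first two component means where the
half-methylated posterior reaches the unmethylated one, and $U$ the
analogue between half- and fully methylated.  They are located by grid
search at resolution $10^{-4}$ (`state_thresholds()`).  State calls
are strict: $\beta < L$ is unmethylated, $\beta > U$ methylated,
boundary values intermediate (`call_region_state()`).

Constitutive sets then require the state in **every** fetal sample
individually (`constitutive_set()`), the strictest reading of
"constitutive across all tissues"; a per-tissue-mean mode can be
emulated by passing tissue-mean matrices.

## Preprocessing

Probes with coverage below 70% are removed (strictly `< 0.7`; 70%
exactly is kept).  Remaining missing entries are imputed by $k$-nearest
probes ($k = 5$): Euclidean distance over jointly observed samples,
normalised by their number; neighbours must be observed in the target
sample; ties break by probe row order; fewer than $k$ candidates falls
back to all available, with a warning.  Region-level beta values are
plain arithmetic means of member probes (TSS200 probes per promoter,
Body probes outside exon 1 per gene body, probes per CGI).  An SVD
check (`svd_phenotype_check()`) verifies that the top principal axis of
the probe-centred matrix tracks the normal/cancer label before any
differential analysis is trusted.

# Differential methylation and tissue independence

Per region, a two-tailed Welch $t$-test contrasts cancer vs normal
samples (positive $t$ = higher in cancer).  Welch is the default
because cohort sizes and variances differ between phenotypes; the
pooled-variance test is available via `pooled = TRUE`.  Genes are
ranked by $t$ (descending for promoter hypermethylation, ascending for
gene-body hypomethylation) and the top/bottom $N$ labelled DM/nonDM
with $N = 300$ by default; no multiple-testing correction enters the
ranking (p values are reported for reference only).

Cross-cancer similarity is computed on phenotype **mean profiles**
(per-region mean beta over a phenotype's samples), as a symmetric
matrix of squared Pearson correlations over a shared region subset
(`pairwise_r2()`), with the mean off-diagonal $R^2$ as the headline
summary.  `own_vs_other_normal_test()` contrasts the diagonal of a
cancer-by-normal $R^2$ matrix against its off-diagonal entries with a
two-sample $t$-test (pooled entries by default; a per-cancer averaging
mode exists because the figure underlying this comparison does not
state the pooling).

# Histone signals and prediction

bedGraph tracks carry $S = -\log_{10}P$ per interval; a tag "matches" a
region if it overlaps it at all, and the per-gene signal
$\langle S\rangle$ is the unweighted mean over matching tags
(base-pair-weighted averaging is available but not default, since tag
matching is defined by overlap, not coverage).  Promoter signals use
symmetric $\pm w$ windows; `tune_window()` scans
$w \in \{200, 300, 500, 700, 900, 1100, 1300, 1500\}$ and picks the $w$
maximising the mean absolute correlation of the H3K4me3 and H3K27me3
signals with log2 expression (H3K27me3's association is negative, so
absolute values put both marks on one scale; per-mark curves are always
returned).  Ties go to the smallest window.  The package default is
$w = 300$, the tuned optimum.  Gene bodies for H3K36me3 use the
first-to-last-exon span including introns; the exon-only definition
(used for the hESC line similarity) is `mode = "exons_after_first"`.

Expression is floored before use: zeros are replaced by the smallest
positive RPKM, and log2 values below
$\mathrm{round}(\log_2(10/(39 \times 1))) = -2$ — fewer than 10 reads
at a 39-million-read library and 1 kb mean gene length — are set to
$-2$.

## ROC/AUC

`roc_curve()` sweeps occupancy thresholds over the observed signal
values (occupancy = signal $\ge$ threshold, DM positive) and
integrates by trapezoid; ties receive half credit automatically.
`auc_from_labels()` is the independent Mann–Whitney oracle
(concordant pairs + half ties over all DM × nonDM pairs); the two are
asserted equal to $10^{-12}$ on random instances, and cross-checked
against `pROC` in the tests.  Raw AUCs are reported as-is, so a
protective mark can legitimately score below 0.5.  For benchmarking
normal-tissue signals against hESC signals, `predict_dm_auc()` also
offers `orientation = "association"`, which fixes the occupancy
direction a priori per mark (H3K27me3 positive; H3K4me3 and H3K36me3
protective for promoter hypermethylation) so that *prediction
accuracy* is compared on the conventional $\ge 0.5$ scale.  This is a
deliberate design choice: comparing raw AUCs across sources is
meaningless for a negatively associated mark, where a better predictor
has a *smaller* raw AUC.

Normal-vs-hESC comparisons across tissues use a one-tailed paired
Wilcoxon signed-rank test; zero differences are dropped, and the exact
distribution is used up to 25 tie-free pairs (six tissues with
uniformly positive differences give $p = 2^{-6} = 0.015625$ exactly).

## Multivariate models

The DM gene set for modelling is the top 1000 + bottom 1000 genes by
$t$ statistic.  Genes are split 50/20/30 into train / validation /
blind-test sets, stratified by label with largest-remainder rounding
(`stratified_split()`).  All seven non-empty subsets of
{H3K4me3, H3K27me3, H3K36me3} are fitted as logistic regressions on
the training set (`fit_logistic()`, maximum likelihood via IRLS;
predictors standardised on the training data — Wald $z$ statistics are
scale-invariant, so conclusions are unaffected; the raw-scale option is
simply not standardising upstream).  Models are ranked by validation
AUC, ties broken toward fewer predictors and then lower AIC
($\mathrm{AIC} = 2k - 2\ln L$, $k$ including the intercept), and the
winner is evaluated once on the blind test set.  With three predictors
the exhaustive seven-model search covers everything a forward selection
could visit, so the two strategies coincide in coverage.

# Chromatin context

Promoter windows ($\pm 300$ bp) are stratified by DHS overlap in the
matched normal tissue (`dhs_stratify()`).  Bivalency has no canonical
threshold definition from signal tracks, so `call_bivalent()` uses a
quantile rule — both promoter marks above their 0.75 quantile — with
the quantile exposed (`q`), and the standard report varies
$q \in \{0.5, 0.75, 0.9\}$.  Within each stratum,
`stratified_normal_cancer_t()` compares per-gene phenotype means
between cancer and normal with a Welch $t$ across genes; because the
unit of analysis behind the published stratified boxplots is not
stated, a per-sample mode (`unit = "samples"`) is also provided, and
neither is claimed to be "the" published convention.

# The synthetic-data generator

`synth_config()` / `simulate_dataset()` emulate the full input stack.
The structural choices:

* **Ground states.**  Every promoter, gene body and CGI draws a ground
  state with class-specific priors (promoters 60/20/20% for
  unmethylated/half/methylated, bodies 15/25/60%, CGIs 70/15/15%),
  with state means (0.1, 0.5, 0.9).  Fetal and normal region means
  equal the ground state; probe values add Beta-distributed noise with
  concentration $\kappa = 50$ (450k-like dispersion), plus
  missingness completely at random (0.2% of entries) and a 1% block of
  low-coverage probes that the coverage filter must remove.
* **The shared propensity.**  Each gene carries a latent
  $u_g \sim N(0,1)$; each tissue adds $v_{g,t} \sim N(0,1)$.  The
  promoter cancer shift is
  $\delta_{g,t} = 0.25 + a\,u_g + b\,v_{g,t}$ with
  $a^2/(a^2+b^2) = \sqrt{f}$ and total SD 0.12, so that the
  cross-tissue correlation of shifts is $\sqrt{f}$ and the expected
  cross-cancer $R^2$ equals the config's `shared_fraction` $f$.  This
  is the package's definition of the tissue-independent fraction: $f$
  parameterises the *explained variance between cancers*, the quantity
  the correlation stage measures.  Shifts are applied to all promoters
  and clipped to $[0.01, 0.99]$, so ground-methylated promoters
  saturate — which is exactly what makes their cancer contrast weak in
  the DHS analysis.
* **Gene bodies** hypomethylate with propensity $-u_g$ (shift
  $-(0.25 + a(-u_g) + b\,w_{g,t})$): active, H3K36me3-rich, low-$u$
  genes lose body methylation, while Polycomb-prone high-$u$ genes
  gain promoter methylation.  This single-axis coupling is the sign
  structure the prediction stage is supposed to recover — H3K27me3
  positive, H3K4me3 and H3K36me3 protective for promoter
  hypermethylation, and H3K36me3 positively predictive for body
  hypomethylation.
* **Histone signals** are
  $s_m = \mathrm{softplus}(c_m u_g + \mathrm{base}_m + \varepsilon)$
  with $c_{27} = +1$, $c_4 = c_{36} = -1$ and per-tissue noise
  SD 0.5.  Tracks tile $\pm1500$ bp around each TSS in 100 bp bins,
  carrying the per-gene target in the central $\pm300$ bp and
  uninformative background outside — so window tuning has a true
  optimum at 300 bp — and tile gene-body spans in 200 bp bins for
  H3K36me3.  hESC signals use a degraded latent
  $u^{hESC} = \rho u + \sqrt{1-\rho^2} z$ ($\rho = 0.5$ by default),
  which is what makes normal-tissue marks better predictors by
  construction.  The hESC panel contains eight lines as noisy views of
  $u^{hESC}$, with H1 least noisy, so the consensus-line selection has
  a designed answer.
* **Expression** follows
  $\log_2 \mathrm{RPKM} = 3 + s_4 - s_{27} + \varepsilon$, with 5% of
  genes zeroed; **DHS** coverage follows
  $\mathrm{logit}^{-1}(-6(\beta^{normal}-0.5))$, so open chromatin
  tracks low normal methylation.

What the generator does **not** emulate: type-II probe chemistry bias
(hence no BMIQ quantile normalisation — only the state model is in
scope), batch effects, tumour purity, copy-number artefacts, real CpG
spatial correlation, and tissue-specific *normal* methylation (normal
means equal the fetal ground state, so analyses contrasting a cancer
with *other tissues'* normals have no designed signal).  Passing tests
therefore demonstrate that the machinery recovers planted structure at
realistic noise, not that real data are this clean.

# Study conditions and reproducibility

The `study_*()` functions rerun the headline analyses on freshly
simulated cohorts; `scripts/acceptance.R` executes all of them and
writes their numbers as JSON.  The problem sizes are the package's
chosen desk-scale study conditions:

* default cohorts of 2000 genes × 10 tissues × 20 samples per
  phenotype per tissue, $\kappa = 50$, 3/4/5 probes per
  promoter/body/CGI;
* the shared-fraction study runs 20 cohorts at $f = 0.6$ with complete
  matrices (missingness is exercised by the constitutive-recovery and
  DHS studies, which run the full filter/impute path);
* the sign-recovery study uses 4000 genes so that the 1000+1000 DM set
  fits inside the recovered cu-GP set (~60% of promoters are
  ground-unmethylated);
* the source-comparison study uses six tissues (matching the six
  ChIP-profiled tissue types) and the DHS study three (matching the
  three DHS-profiled ones).

Two behaviours worth knowing when interpreting results at other sizes:
the $t$-statistic ranking carries variance-estimate noise, so
agreement between recovered DM labels and the generator's true
top-shift genes reaches ~90% only at consortium-scale cohorts
(~100 samples per phenotype) and drops to ~80% at 20; and the
cross-cancer $R^2$ is attenuated by a percent or two relative to $f$
by profile estimation noise and clipping, which is well inside the
acceptance tolerance at the default sizes.

# Known limitations

* The coverage filter and imputation operate per cohort (fetal pooled,
  then normal+cancer per tissue); whether the original analyses pooled
  cohorts differently is not recoverable from the text.
* The bivalency quantile rule is a stand-in for an unstated published
  definition; conclusions that depend on the exact bivalent set should
  be checked across `q`.
* `read_bed()`/`read_bedgraph()` deliberately support only the plain
  3+/4-column dialects the pipeline touches; bigWig conversion is
  upstream.
* The generator's per-gene latent is one-dimensional; real epigenomes
  have multiple coupled axes, so multivariate model comparisons on
  synthetic data are easier than on real data.
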