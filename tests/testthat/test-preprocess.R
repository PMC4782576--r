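test_that("coverage filter is strict below the threshold and keeps order", {
  m <- matrix(runif(100), 10, 10,
              dimnames = list(sprintf("p%02d", 1:10), paste0("s", 1:10)))
  m[1, 1:4] <- NA     # 6/10 present -> removed at 0.7
  m[2, 1:3] <- NA     # 7/10 present -> kept (strict "< 70%" removal)
  out <- filter_probes_by_coverage(m, 0.7)
  expect_false("p01" %in% rownames(out))
  expect_true("p02" %in% rownames(out))
  expect_equal(rownames(out), setdiff(rownames(m), "p01"))

  # fully observed matrix passes through unchanged
  m2 <- matrix(runif(20), 4, 5)
  expect_identical(filter_probes_by_coverage(m2), m2)

  # removing everything is an explicit error
  m3 <- matrix(NA_real_, 2, 4)
  m3[, 1] <- 0.5
  expect_error(filter_probes_by_coverage(m3, 0.7), "all probes removed")
})

test_that("kNN imputation matches an exhaustive-search oracle", {
  set.seed(21)
  n <- 30; p <- 8
  m <- matrix(rbeta(n * p, 2, 2), n, p,
              dimnames = list(sprintf("p%02d", 1:n), sprintf("s%d", 1:p)))
  holes <- cbind(sample(n, 12, TRUE), sample(p, 12, TRUE))
  m[unique(holes)] <- NA

  got <- impute_knn(m, k = 5)
  expect_false(anyNA(got))
  # observed entries never altered
  expect_identical(got[!is.na(m)], m[!is.na(m)])

  # exhaustive oracle: per entry, rank all probes by pairwise-complete
  # normalised Euclidean distance, average the 5 nearest observed there
  for (idx in which(is.na(m))) {
    i <- (idx - 1) %% n + 1; s <- (idx - 1) %/% n + 1
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      joint <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(joint)) return(Inf)
      sqrt(mean((m[i, joint] - m[j, joint])^2))
    }, 0)
    ord <- order(d, seq_len(n))
    ord <- ord[is.finite(d[ord])]
    elig <- ord[!is.na(m[ord, s])]
    expect_equal(got[i, s], mean(m[head(elig, 5), s]), tolerance = 1e-12)
  }

  # imputed values stay within the donor range
  expect_true(all(got[is.na(m)] >= min(m, na.rm = TRUE) &
                    got[is.na(m)] <= max(m, na.rm = TRUE)))

  # no-missing input is the identity; filter -> impute is idempotent
  expect_identical(impute_knn(got, 5), got)

  # fewer than k candidates -> use all available, with a warning
  sm <- matrix(c(0.1, 0.2, NA, 0.1, 0.2, 0.3, 0.15, 0.25, 0.35), 3, 3,
               dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  expect_warning(impute_knn(sm, k = 5), "fewer than k")
})

test_that("beta-mixture EM recovers well-separated components", {
  set.seed(31)
  x <- c(rbeta(1700, 2, 18), rbeta(1700, 10, 10), rbeta(1600, 18, 2))
  fit <- fit_beta_mixture(x)
  expect_s3_class(fit, "beta_mixture_fit")
  expect_lt(max(abs(fit$means - c(0.1, 0.5, 0.9))), 0.05)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-8)
  expect_true(all(diff(fit$means) > 0))
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[-1])))
})

test_that("EM log-likelihood is monotone on arbitrary inputs", {
  set.seed(32)
  inputs <- list(
    runif(500),
    c(rbeta(300, 1, 5), rbeta(200, 8, 2)),
    rbeta(400, 3, 3),
    c(rep(0, 10), rep(1, 10), runif(400))   # boundary values get nudged
  )
  for (x in inputs) {
    fit <- suppressWarnings(fit_beta_mixture(x, max_iter = 60))
    expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[-1])))
  }
})

test_that("single-component data yields an equivalent single-density fit", {
  set.seed(33)
  z <- rbeta(3000, 5, 5)
  fit <- suppressWarnings(fit_beta_mixture(z))
  # mixture mean/variance match the single-beta truth; no spurious
  # extreme-state component carries weight
  mix_mean <- sum(fit$pi * fit$means)
  mix_var <- sum(fit$pi * (fit$means * (1 - fit$means) /
                             (fit$shape1 + fit$shape2 + 1) +
                             fit$means^2)) - mix_mean^2
  expect_lt(abs(mix_mean - 0.5), 0.02)
  expect_lt(abs(mix_var - 0.5 * 0.5 / 11), 0.01)
  expect_true(all(fit$means > 0.2 & fit$means < 0.8))
})

test_that("state thresholds are posterior crossings with the right geometry", {
  set.seed(34)
  x <- c(rbeta(1700, 2, 18), rbeta(1700, 10, 10), rbeta(1600, 18, 2))
  fit <- fit_beta_mixture(x)
  th <- state_thresholds(fit)
  expect_gt(th[["L"]], 0.1); expect_lt(th[["L"]], 0.5)
  expect_gt(th[["U"]], 0.5); expect_lt(th[["U"]], 0.9)

  # grid-posterior oracle: at L the half-state posterior first wins
  grid <- seq(fit$means[1], fit$means[2], by = 1e-4)
  post <- vapply(1:2, function(k) {
    fit$pi[k] * dbeta(grid, fit$shape1[k], fit$shape2[k])
  }, numeric(length(grid)))
  expect_equal(th[["L"]], grid[which(post[, 2] >= post[, 1])[1]])

  # symmetric mixture -> L + U = 1
  sym <- fit
  sym$pi <- c(0.3, 0.4, 0.3)
  sym$shape1 <- c(2, 10, 18); sym$shape2 <- c(18, 10, 2)
  sym$means <- c(0.1, 0.5, 0.9)
  ths <- state_thresholds(sym)
  expect_equal(ths[["L"]] + ths[["U"]], 1, tolerance = 1e-3)

  # raising the unmethylated prior moves L rightward
  up <- fit
  up$pi <- c(0.8, 0.1, 0.1)
  expect_gt(state_thresholds(up)[["L"]], th[["L"]])
})

test_that("region aggregation is a per-region mean and commutes with subsetting", {
  m <- rbind(p1 = c(0.2, 0.6), p2 = c(0.4, 0.8), p3 = c(0.5, 0.5))
  colnames(m) <- c("s1", "s2")
  man <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                    pos = 1:3, gene_id = c("gA", "gA", "gB"),
                    region_class = "TSS200", cgi_id = NA,
                    stringsAsFactors = FALSE)
  ag <- aggregate_region_beta(m, man, "promoter")
  expect_equal(ag["gA", "s1"], 0.3)
  expect_equal(ag["gA", "s2"], 0.7)
  expect_equal(unname(ag["gB", ]), c(0.5, 0.5))

  # constant probes give the constant back
  mc <- matrix(0.42, 3, 2, dimnames = dimnames(m))
  expect_true(all(aggregate_region_beta(mc, man, "promoter") == 0.42))

  # 50-region random fixture vs a direct per-region mean oracle
  set.seed(41)
  big <- matrix(rbeta(500 * 6, 2, 2), 500, 6,
                dimnames = list(sprintf("q%03d", 1:500), paste0("s", 1:6)))
  bman <- data.frame(probe_id = rownames(big), chrom = "chr1", pos = 1:500,
                     gene_id = rep(sprintf("G%02d", 1:50), each = 10),
                     region_class = "Body", cgi_id = NA,
                     stringsAsFactors = FALSE)
  got <- aggregate_region_beta(big, bman, "gene_body")
  for (g in c("G01", "G17", "G50")) {
    expect_equal(got[g, ],
                 colMeans(big[bman$probe_id[bman$gene_id == g], ]),
                 tolerance = 1e-12)
  }

  # aggregation commutes with sample subsetting
  sub <- c("s2", "s5")
  expect_equal(aggregate_region_beta(big[, sub], bman, "gene_body"),
               got[, sub])

  expect_error(aggregate_region_beta(m, man, "nonsense"))
})

test_that("SVD phenotype check flags group structure and ignores labels otherwise", {
  set.seed(51)
  m <- matrix(rbeta(300 * 20, 2, 2), 300, 20)
  m[, 11:20] <- pmin(m[, 11:20] + 0.3, 1)
  lab <- rep(c("normal", "cancer"), each = 10)
  res <- svd_phenotype_check(m, lab)
  expect_gt(abs(res$r), 0.9)
  expect_true(res$pass)

  # label permutation leaves singular values unchanged
  res_perm <- svd_phenotype_check(m, sample(lab))
  expect_equal(res$singular_values, res_perm$singular_values)

  # pure noise rarely passes
  fails <- vapply(1:20, function(i) {
    set.seed(100 + i)
    noise <- matrix(rbeta(300 * 20, 2, 2), 300, 20)
    !svd_phenotype_check(noise, lab)$pass
  }, TRUE)
  expect_gte(mean(fails), 0.9)

  expect_error(svd_phenotype_check(m, rep("x", 20)), "two levels")
})

test_that("probe density follows the span and length definitions", {
  man <- data.frame(
    probe_id = paste0("p", 1:7), chrom = "chr1",
    pos = c(0, 300, 1000, 100, 200, 300, 400),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB", "gB"),
    region_class = c(rep("TSS200", 3), rep("Body", 4)),
    cgi_id = NA, stringsAsFactors = FALSE)
  pd <- probe_density(man)
  dd <- pd$densities
  expect_equal(dd$density[dd$region_id == "gA"], 3 / 1000)  # farthest pair
  expect_equal(dd$density[dd$region_id == "gB"], 4 / 300)

  # CGI density uses end - start
  cgis <- granges_from_bed0("chr1", 0, 500)
  names(cgis) <- "cgi1"
  man2 <- rbind(man, data.frame(
    probe_id = paste0("c", 1:10), chrom = "chr1", pos = seq(0, 450, 50),
    gene_id = NA, region_class = NA, cgi_id = "cgi1",
    stringsAsFactors = FALSE))
  pd2 <- probe_density(man2, cgis)
  expect_equal(pd2$densities$density[pd2$densities$region_class == "cgi"],
               10 / 500)
  expect_equal(nrow(pd2$tests), 3)   # all pairwise class comparisons

  # classes built with equal density produce mostly non-significant tests
  ps <- vapply(1:20, function(i) {
    set.seed(200 + i)
    n <- 40
    spans <- sample(500:1500, 2 * n, TRUE)
    manr <- data.frame(
      probe_id = sprintf("r%04d", 1:(6 * 2 * n)), chrom = "chr1",
      pos = unlist(lapply(spans, function(s) round(seq(0, s, length.out = 6)))),
      gene_id = rep(sprintf("g%03d", 1:(2 * n)), each = 6),
      region_class = rep(c("TSS200", "Body"), each = 6 * n),
      cgi_id = NA, stringsAsFactors = FALSE)
    probe_density(manr)$tests$p[1]
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})
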