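# Synthetic-data generator: 450k-style beta matrices for fetal / normal /
# cancer phenotypes across tissues, histone bedGraph-style tracks,
# expression and DHS interval sets, with full ground truth.
#
# Model sketch (see the methods vignette for the full account):
#   * every gene promoter, gene body and CGI has a ground methylation
#     state in {unmethylated ~0.1, half ~0.5, methylated ~0.9};
#   * each gene carries a latent shared hypermethylation propensity
#     u_g ~ N(0,1); each tissue adds a specific component v_{g,t};
#     the promoter cancer shift is
#       delta_{g,t} = d0 + a*u_g + b*v_{g,t},
#     with a^2/(a^2+b^2) = sqrt(shared_fraction), so that the expected
#     cross-cancer R^2 of the shift equals shared_fraction;
#   * the gene-body hypomethylation propensity is -u_g (active, low-u
#     genes lose body methylation), giving body shifts
#       deltaB_{g,t} = -(d0B + a*(-u_g) + b*w_{g,t});
#   * histone signals: s_m = softplus(c_m * u_g + base_m + eps), with
#     c27 > 0, c4 < 0, c36 < 0; hESC signals use a degraded copy
#     u_hESC = rho*u + sqrt(1-rho^2)*z;
#   * expression couples positively to promoter H3K4me3 and negatively
#     to H3K27me3; DHS coverage probability decreases with normal
#     promoter methylation.
# Probe-level beta values are Beta(mu*kappa, (1-mu)*kappa) around region
# means; identical config + seed gives bit-identical output.

#' Synthetic-data configuration
#'
#' Defaults encode the study conditions emulated throughout the package:
#' ten tissues (as in the fetal/TCGA panels), beta-mixture states centred
#' at 0.1/0.5/0.9, probe dispersion kappa = 50, a shared (tissue
#' independent) fraction of 0.6 of the cross-cancer shift variance, and
#' hESC histone tracks degraded to rho = 0.5 of the normal-tissue latent.
#'
#' @param n_genes Number of genes.
#' @param n_cgis Number of promoter CGIs (at most `n_genes`; each CGI is
#'   anchored at a host gene promoter).
#' @param n_tissues Number of tissues.
#' @param samples_per_phenotype Samples per tissue per phenotype
#'   (fetal / normal / cancer).
#' @param probes_per_promoter,probes_per_body,probes_per_cgi Probes per
#'   region.
#' @param shared_fraction Expected cross-cancer R^2 of the cancer shift
#'   (the tissue-independent fraction), in `[0,1]`.
#' @param delta_mean,delta_sd Mean and SD of the promoter hypermethylation
#'   shift (the body hypomethylation shift uses the same magnitudes with
#'   opposite sign).
#' @param state_means Means of the three methylation states.
#' @param state_probs_promoter,state_probs_body,state_probs_cgi Ground
#'   state priors per region class (unmeth, half, meth).
#' @param kappa Beta concentration of probe-level noise around region
#'   means.
#' @param missing_frac Fraction of matrix entries set missing completely
#'   at random.
#' @param low_cov_frac Fraction of probes injected with ~50% sample
#'   coverage (to exercise the coverage filter).
#' @param coupling Named numeric: histone couplings to `u_g`
#'   (`H3K4me3` < 0, `H3K27me3` > 0, `H3K36me3` < 0).
#' @param mark_baseline Named numeric baseline occupancy per mark (on the
#'   softplus input scale).
#' @param mark_noise_sd SD of the per-gene histone signal noise.
#' @param bin_noise_sd SD of per-bin track noise around the per-gene
#'   target signal.
#' @param rho_hesc Correlation of the hESC latent with `u_g`.
#' @param n_hesc_lines Number of simulated hESC lines (>= 3).
#' @param expr_alpha,expr_b4,expr_b27,expr_noise_sd,zero_rpkm_frac
#'   Expression model: `log2 RPKM = alpha + b4*s4 - b27*s27 + eps`, with
#'   a fraction of genes zeroed.
#' @param dhs_intercept,dhs_slope Logistic link from normal promoter beta
#'   (centred at 0.5) to DHS coverage probability; negative slope means
#'   methylated promoters sit in closed chromatin.
#' @param dhs_halfwidth Half-width (bp) of gene-anchored DHS intervals.
#' @param seed Master seed; each generator stage derives its own stream.
#' @return A classed list of settings.
#' @export
synth_config <- function(n_genes = 2000,
                         n_cgis = round(0.7 * n_genes),
                         n_tissues = 10,
                         samples_per_phenotype = 20,
                         probes_per_promoter = 3,
                         probes_per_body = 4,
                         probes_per_cgi = 5,
                         shared_fraction = 0.6,
                         delta_mean = 0.25,
                         delta_sd = 0.12,
                         state_means = c(0.1, 0.5, 0.9),
                         state_probs_promoter = c(0.60, 0.20, 0.20),
                         state_probs_body = c(0.15, 0.25, 0.60),
                         state_probs_cgi = c(0.70, 0.15, 0.15),
                         kappa = 50,
                         missing_frac = 0.002,
                         low_cov_frac = 0.01,
                         coupling = c(H3K4me3 = -1, H3K27me3 = 1,
                                      H3K36me3 = -1),
                         mark_baseline = c(H3K4me3 = 2, H3K27me3 = 1,
                                           H3K36me3 = 2),
                         mark_noise_sd = 0.5,
                         bin_noise_sd = 0.5,
                         rho_hesc = 0.5,
                         n_hesc_lines = 8,
                         expr_alpha = 3,
                         expr_b4 = 1,
                         expr_b27 = 1,
                         expr_noise_sd = 1,
                         zero_rpkm_frac = 0.05,
                         dhs_intercept = 0,
                         dhs_slope = -6,
                         dhs_halfwidth = 300,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
    cfg$kappa > 0,
    cfg$n_genes >= 1, cfg$n_tissues >= 1,
    cfg$samples_per_phenotype >= 1,
    cfg$probes_per_promoter >= 1, cfg$probes_per_body >= 1,
    cfg$probes_per_cgi >= 1,
    cfg$coupling[["H3K27me3"]] > 0, cfg$coupling[["H3K4me3"]] < 0,
    cfg$coupling[["H3K36me3"]] < 0
  )
  cfg$n_cgis <- min(cfg$n_cgis, cfg$n_genes)
  class(cfg) <- "synth_config"
  cfg
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

tissue_names <- function(cfg) sprintf("t%02d", seq_len(cfg$n_tissues))

#' Generate a synthetic gene annotation, probe manifest and CGI set
#'
#' Genes are placed on chr1..chr10 with >= 20 kb spacing, on both strands,
#' with 2-6 exons.  Every promoter carries `probes_per_promoter` TSS200
#' probes inside the 200 bp upstream window; Body probes lie in exons
#' after the first (so never in exon 1); CGIs are centred on a subset of
#' promoters and carry their own probes.
#'
#' @param cfg A [synth_config()].
#' @return List with `annotation` (gene table), `manifest` (probe table),
#'   `cgis` (GRanges named by CGI id, with `host_gene` metadata).
#' @export
generate_annotation <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %% 10L) + 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_ex <- sample(2:6, n, replace = TRUE)

    exon_starts <- vector("list", n)
    exon_ends <- vector("list", n)
    tss <- integer(n)
    offset <- integer(10L); names(offset) <- sprintf("chr%d", 1:10)
    offset[] <- 10000L
    for (i in seq_len(n)) {
      widths <- sample(150:400, n_ex[i], replace = TRUE)
      introns <- sample(300:1500, n_ex[i] - 1L, replace = TRUE)
      s <- offset[chrom[i]] + cumsum(c(0L, widths[-n_ex[i]] + introns))
      e <- s + widths
      exon_starts[[i]] <- s
      exon_ends[[i]] <- e
      tss[i] <- if (strand[i] == "+") s[1] else e[n_ex[i]] - 1L
      offset[chrom[i]] <- e[n_ex[i]] + 20000L + sample(0:5000, 1L)
    }
    ann <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
      exon_starts = vapply(exon_starts, paste, "", collapse = ","),
      exon_ends = vapply(exon_ends, paste, "", collapse = ","),
      stringsAsFactors = FALSE
    )
    ann <- validate_annotation(ann)

    # TSS200 probes: inside the strand-aware upstream window
    pp <- cfg$probes_per_promoter
    up_off <- replicate(n, sort(sample(0:199, pp)), simplify = FALSE)
    prom_pos <- unlist(lapply(seq_len(n), function(i) {
      if (strand[i] == "+") tss[i] - 200L + up_off[[i]]
      else tss[i] + up_off[[i]]          # reflected upstream window
    }))
    prom <- data.frame(
      probe_id = sprintf("cgP%05d_%d", rep(seq_len(n), each = pp),
                         rep(seq_len(pp), n)),
      chrom = rep(chrom, each = pp), pos = prom_pos,
      gene_id = rep(gene_id, each = pp),
      region_class = "TSS200", cgi_id = NA_character_,
      stringsAsFactors = FALSE
    )

    # Body probes: uniform over exons 2..n in transcription order
    pb <- cfg$probes_per_body
    body_pos <- unlist(lapply(seq_len(n), function(i) {
      s <- exon_starts[[i]]; e <- exon_ends[[i]]
      keep <- if (strand[i] == "+") -1L else -length(s)
      s <- s[keep]; e <- e[keep]
      pool <- unlist(mapply(function(a, b) a:(b - 1L), s, e,
                            SIMPLIFY = FALSE))
      sort(sample(pool, pb, replace = length(pool) < pb))
    }))
    body <- data.frame(
      probe_id = sprintf("cgB%05d_%d", rep(seq_len(n), each = pb),
                         rep(seq_len(pb), n)),
      chrom = rep(chrom, each = pb), pos = body_pos,
      gene_id = rep(gene_id, each = pb),
      region_class = "Body", cgi_id = NA_character_,
      stringsAsFactors = FALSE
    )

    # CGIs anchored at a random subset of promoters
    host_idx <- sort(sample.int(n, cfg$n_cgis))
    cgi_id <- sprintf("cgi%05d", seq_len(cfg$n_cgis))
    half <- sample(300:600, cfg$n_cgis, replace = TRUE)
    cgis <- granges_from_bed0(
      chrom[host_idx],
      pmax(tss[host_idx] - half, 0),
      tss[host_idx] + half,
      host_gene = gene_id[host_idx]
    )
    names(cgis) <- cgi_id
    pc <- cfg$probes_per_cgi
    cgi_pos <- unlist(lapply(seq_len(cfg$n_cgis), function(j) {
      s0 <- GenomicRanges::start(cgis)[j] - 1L
      e0 <- GenomicRanges::end(cgis)[j]
      sort(sample(s0:(e0 - 1L), pc))
    }))
    cgi_probes <- data.frame(
      probe_id = sprintf("cgC%05d_%d", rep(seq_len(cfg$n_cgis), each = pc),
                         rep(seq_len(pc), cfg$n_cgis)),
      chrom = rep(chrom[host_idx], each = pc), pos = cgi_pos,
      gene_id = NA_character_, region_class = NA_character_,
      cgi_id = rep(cgi_id, each = pc),
      stringsAsFactors = FALSE
    )

    manifest <- validate_manifest(rbind(prom, body, cgi_probes))
    list(annotation = ann, manifest = manifest, cgis = cgis)
  })
}

# Latent propensities and per-(gene, tissue) shifts.  Variance share of
# the shared component is sqrt(shared_fraction) so that the cross-tissue
# R^2 of the shift equals shared_fraction.
simulate_latents <- function(cfg) {
  n <- cfg$n_genes; Tn <- cfg$n_tissues
  s <- sqrt(cfg$shared_fraction)
  a <- sqrt(s) * cfg$delta_sd
  b <- sqrt(1 - s) * cfg$delta_sd
  u <- stats::rnorm(n)
  v <- matrix(stats::rnorm(n * Tn), n, Tn)
  w <- matrix(stats::rnorm(n * Tn), n, Tn)
  delta_promoter <- cfg$delta_mean + a * u + b * v
  delta_body <- -(cfg$delta_mean + a * (-u) + b * w)
  dimnames(delta_promoter) <- list(NULL, tissue_names(cfg))
  dimnames(delta_body) <- list(NULL, tissue_names(cfg))
  list(u = u, v = v, w = w,
       delta_promoter = delta_promoter, delta_body = delta_body)
}

#' Generate synthetic fetal/normal/cancer beta matrices with ground truth
#'
#' @param cfg A [synth_config()].
#' @param ann Output of [generate_annotation()].
#' @return List with `beta` (probes x samples matrix, with missing
#'   entries), `samples` (sample sheet: `sample_id`, `tissue`,
#'   `phenotype`), and `truth` (latents, per-tissue shifts, ground
#'   states, low-coverage probe ids).
#' @export
generate_methylation <- function(cfg, ann) {
  with_seed(cfg$seed + 1L, {
    man <- ann$manifest
    genes <- ann$annotation$gene_id
    n <- cfg$n_genes
    lat <- simulate_latents(cfg)

    st_prom <- sample.int(3L, n, replace = TRUE,
                          prob = cfg$state_probs_promoter)
    st_body <- sample.int(3L, n, replace = TRUE,
                          prob = cfg$state_probs_body)
    host <- match(S4Vectors::mcols(ann$cgis)$host_gene, genes)
    st_cgi <- st_prom[host]
    names(st_prom) <- genes; names(st_body) <- genes
    names(st_cgi) <- names(ann$cgis)

    mu0 <- cfg$state_means
    # per-probe ground mean and per-probe (gene x tissue) cancer shift
    is_prom <- !is.na(man$region_class) & man$region_class == "TSS200"
    is_body <- !is.na(man$region_class) & man$region_class == "Body"
    is_cgi <- !is.na(man$cgi_id) & is.na(man$region_class)
    gidx <- match(man$gene_id, genes)
    cidx <- match(man$cgi_id, names(ann$cgis))

    base <- numeric(nrow(man))
    base[is_prom] <- mu0[st_prom[gidx[is_prom]]]
    base[is_body] <- mu0[st_body[gidx[is_body]]]
    base[is_cgi] <- mu0[st_cgi[cidx[is_cgi]]]

    # shift per probe per tissue (cancer only)
    shift <- matrix(0, nrow(man), cfg$n_tissues)
    shift[is_prom, ] <- lat$delta_promoter[gidx[is_prom], , drop = FALSE]
    shift[is_body, ] <- lat$delta_body[gidx[is_body], , drop = FALSE]
    shift[is_cgi, ] <- lat$delta_promoter[host[cidx[is_cgi]], , drop = FALSE]

    tn <- tissue_names(cfg)
    spp <- cfg$samples_per_phenotype
    phen <- c("fetal", "normal", "cancer")
    samples <- expand.grid(rep = seq_len(spp), phenotype = phen,
                           tissue = tn, stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = sprintf("%s_%s_%02d", samples$tissue, samples$phenotype,
                          samples$rep),
      tissue = samples$tissue, phenotype = samples$phenotype,
      stringsAsFactors = FALSE
    )

    mu_col <- function(tissue, phenotype) {
      if (phenotype == "cancer") {
        pmin(pmax(base + shift[, match(tissue, tn)], 0.01), 0.99)
      } else {
        pmin(pmax(base, 0.01), 0.99)
      }
    }
    npr <- nrow(man)
    beta <- matrix(NA_real_, npr, nrow(samples),
                   dimnames = list(man$probe_id, samples$sample_id))
    grp <- paste(samples$tissue, samples$phenotype)
    for (g in unique(grp)) {
      cols <- which(grp == g)
      mu <- mu_col(samples$tissue[cols[1]], samples$phenotype[cols[1]])
      m <- length(cols)
      beta[, cols] <- stats::rbeta(npr * m, rep(mu * cfg$kappa, m),
                                   rep((1 - mu) * cfg$kappa, m))
    }

    # missingness: MCAR entries plus a block of low-coverage probes
    n_na <- round(cfg$missing_frac * length(beta))
    if (n_na > 0) beta[sample.int(length(beta), n_na)] <- NA_real_
    low <- sample(man$probe_id, round(cfg$low_cov_frac * npr))
    if (length(low)) {
      drop <- matrix(stats::runif(length(low) * ncol(beta)) < 0.5,
                     length(low), ncol(beta))
      blk <- beta[low, , drop = FALSE]
      blk[drop] <- NA_real_
      beta[low, ] <- blk
    }

    truth <- list(
      u = stats::setNames(lat$u, genes),
      v = lat$v, w = lat$w,
      delta_promoter = `rownames<-`(lat$delta_promoter, genes),
      delta_body = `rownames<-`(lat$delta_body, genes),
      states = list(promoter = st_prom, body = st_body, cgi = st_cgi),
      low_coverage_probes = low
    )
    list(beta = beta, samples = samples, truth = truth)
  })
}

# per-gene target signal for one mark given a latent vector
mark_target <- function(cfg, mark, latent, noise_sd = cfg$mark_noise_sd) {
  softplus(cfg$coupling[[mark]] * latent + cfg$mark_baseline[[mark]] +
             stats::rnorm(length(latent), sd = noise_sd))
}

# Tile one value vector over per-gene windows as bedGraph-like bins.
tile_track <- function(cfg, ann_df, targets, region = c("promoter", "body")) {
  region <- match.arg(region)
  n <- nrow(ann_df)
  if (region == "promoter") {
    width <- 100L
    offs <- seq(-1500L, 1500L - width, by = width)
    k <- length(offs)
    starts <- rep(ann_df$tss, each = k) + rep(offs, n)
    informative <- abs(rep(offs, n) + width / 2) < 300
    vals <- ifelse(informative, rep(targets, each = k), NA_real_)
    bg <- softplus(stats::rnorm(sum(!informative), sd = 1))
    vals[!informative] <- bg
    vals[informative] <- pmax(vals[informative] +
                                stats::rnorm(sum(informative),
                                             sd = cfg$bin_noise_sd), 0)
    gr <- granges_from_bed0(rep(ann_df$chrom, each = k),
                            pmax(starts, 0), pmax(starts, 0) + width,
                            score = vals)
  } else {
    width <- 200L
    starts_l <- exon_list(ann_df$exon_starts)
    ends_l <- exon_list(ann_df$exon_ends)
    s0 <- vapply(starts_l, min, 0L)
    e0 <- vapply(ends_l, max, 0L)
    nb <- pmax((e0 - s0) %/% width, 1L)
    starts <- unlist(lapply(seq_len(n), function(i) {
      s0[i] + (seq_len(nb[i]) - 1L) * width
    }))
    vals <- pmax(rep(targets, nb) +
                   stats::rnorm(length(starts), sd = cfg$bin_noise_sd), 0)
    gr <- granges_from_bed0(rep(ann_df$chrom, nb),
                            starts, starts + width, score = vals)
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Generate histone signal tracks and per-gene target signals
#'
#' Normal-tissue signals couple to the shared latent `u_g` (H3K27me3
#' positively, H3K4me3 and H3K36me3 negatively); hESC signals couple to a
#' degraded copy of `u_g` (correlation `rho_hesc`), so normal-tissue
#' tracks out-predict hESC tracks by construction.  Promoter tracks tile
#' +/-1500 bp around each TSS in 100 bp bins, with the per-gene target
#' emitted in the central +/-300 bp and uninformative background outside;
#' H3K36me3 tracks tile the gene-body span in 200 bp bins.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth component of [generate_methylation()] output.
#' @param ann Output of [generate_annotation()].
#' @param tracks Emit bedGraph-style GRanges tracks (set `FALSE` to keep
#'   only per-gene signals, which is much lighter).
#' @return List with `gene_signals` (`normal[[tissue]][[mark]]`,
#'   `hesc[[mark]]`, `hesc_lines[[line]][[mark]]`, each a named vector
#'   over genes), `tracks` (same nesting, GRanges with `score`), and
#'   `u_hesc`.
#' @export
generate_histone_tracks <- function(cfg, truth, ann, tracks = TRUE) {
  with_seed(cfg$seed + 2L, {
    genes <- ann$annotation$gene_id
    u <- as.numeric(truth$u)
    marks <- c("H3K4me3", "H3K27me3", "H3K36me3")
    tn <- tissue_names(cfg)

    normal <- lapply(tn, function(t) {
      sig <- lapply(marks, function(m) {
        stats::setNames(mark_target(cfg, m, u), genes)
      })
      names(sig) <- marks
      sig
    })
    names(normal) <- tn

    u_h <- cfg$rho_hesc * u +
      sqrt(1 - cfg$rho_hesc^2) * stats::rnorm(length(u))
    hesc <- lapply(marks, function(m) {
      stats::setNames(mark_target(cfg, m, u_h), genes)
    })
    names(hesc) <- marks

    # hESC panel: per-line noisy views of the hESC latent; H1 is the
    # least noisy line and so the natural consensus.
    line_names <- c("H1", "H9", "HUES48", "HUES6", "HUES64", "I3",
                    "UCSF4", "WA7")[seq_len(cfg$n_hesc_lines)]
    line_sd <- c(0.15, seq(0.35, 0.65,
                           length.out = cfg$n_hesc_lines - 1L))
    hesc_lines <- lapply(seq_along(line_names), function(i) {
      sig <- lapply(marks, function(m) {
        stats::setNames(mark_target(cfg, m, u_h, noise_sd = line_sd[i]),
                        genes)
      })
      names(sig) <- marks
      sig
    })
    names(hesc_lines) <- line_names

    out <- list(gene_signals = list(normal = normal, hesc = hesc,
                                    hesc_lines = hesc_lines),
                u_hesc = stats::setNames(u_h, genes))
    if (tracks) {
      ann_df <- ann$annotation
      out$tracks <- list(
        normal = lapply(normal, function(sig) {
          list(H3K4me3 = tile_track(cfg, ann_df, sig$H3K4me3, "promoter"),
               H3K27me3 = tile_track(cfg, ann_df, sig$H3K27me3, "promoter"),
               H3K36me3 = tile_track(cfg, ann_df, sig$H3K36me3, "body"))
        }),
        hesc = list(
          H3K4me3 = tile_track(cfg, ann_df, hesc$H3K4me3, "promoter"),
          H3K27me3 = tile_track(cfg, ann_df, hesc$H3K27me3, "promoter"),
          H3K36me3 = tile_track(cfg, ann_df, hesc$H3K36me3, "body"))
      )
    }
    out
  })
}

#' Generate an RPKM expression vector coupled to promoter marks
#'
#' `log2 RPKM = alpha + b4*s4 - b27*s27 + eps`, then a configurable
#' fraction of genes is zeroed (non-expressed).
#'
#' @param cfg A [synth_config()].
#' @param s4,s27 Named per-gene promoter H3K4me3 / H3K27me3 signals of
#'   the reference cell type.
#' @return Named vector of raw RPKM values (>= 0).
#' @export
generate_expression <- function(cfg, s4, s27) {
  with_seed(cfg$seed + 3L, {
    lg <- cfg$expr_alpha + cfg$expr_b4 * s4 - cfg$expr_b27 * s27 +
      stats::rnorm(length(s4), sd = cfg$expr_noise_sd)
    rpkm <- 2^lg
    nz <- round(cfg$zero_rpkm_frac * length(rpkm))
    if (nz > 0) rpkm[sample.int(length(rpkm), nz)] <- 0
    rpkm
  })
}

#' Generate per-tissue DHS interval sets
#'
#' A promoter is covered by a DHS with probability
#' `plogis(dhs_intercept + dhs_slope * (beta_normal - 0.5))`; with the
#' default negative slope, unmethylated promoters sit in open chromatin.
#'
#' @param cfg A [synth_config()].
#' @param normal_promoter_beta Matrix (genes x tissues) of normal-tissue
#'   mean promoter beta values, or a named vector for a single tissue.
#' @param ann Output of [generate_annotation()].
#' @return Named list (per tissue) of GRanges DHS sets.
#' @export
generate_dhs <- function(cfg, normal_promoter_beta, ann) {
  if (is.null(dim(normal_promoter_beta))) {
    normal_promoter_beta <- matrix(normal_promoter_beta,
                                   ncol = 1,
                                   dimnames = list(names(normal_promoter_beta),
                                                   tissue_names(cfg)[1]))
  }
  with_seed(cfg$seed + 4L, {
    ann_df <- ann$annotation
    idx <- match(rownames(normal_promoter_beta), ann_df$gene_id)
    out <- lapply(colnames(normal_promoter_beta), function(t) {
      p <- stats::plogis(cfg$dhs_intercept +
                           cfg$dhs_slope * (normal_promoter_beta[, t] - 0.5))
      hit <- stats::runif(length(p)) < p
      if (!any(hit)) return(GenomicRanges::GRanges())
      tss <- ann_df$tss[idx[hit]]
      jit <- sample(0:100, sum(hit), replace = TRUE)
      gr <- granges_from_bed0(ann_df$chrom[idx[hit]],
                              pmax(tss - cfg$dhs_halfwidth - jit, 0),
                              tss + cfg$dhs_halfwidth + jit)
      names(gr) <- ann_df$gene_id[idx[hit]]
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    })
    names(out) <- colnames(normal_promoter_beta)
    out
  })
}

#' Simulate a complete synthetic data set
#'
#' Runs all generator stages in order and returns their outputs in one
#' list.  DHS sets are generated from the *true* normal promoter means
#' (ground-state means), which the preprocessing stage re-estimates.
#'
#' @param cfg A [synth_config()].
#' @param tracks Emit full histone GRanges tracks (see
#'   [generate_histone_tracks()]).
#' @return List: `cfg`, `annotation`, `manifest`, `cgis`, `beta`,
#'   `samples`, `truth`, `histone`, `rpkm`, `dhs`.
#' @export
simulate_dataset <- function(cfg = synth_config(), tracks = TRUE) {
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann)
  hist <- generate_histone_tracks(cfg, meth$truth, ann, tracks = tracks)
  ref <- hist$gene_signals$hesc_lines[[1]]
  rpkm <- generate_expression(cfg, ref$H3K4me3, ref$H3K27me3)
  # true normal promoter region means per tissue (identical across
  # tissues by construction; kept per-tissue for interface generality)
  mu0 <- cfg$state_means[meth$truth$states$promoter]
  npb <- matrix(mu0, nrow = cfg$n_genes, ncol = cfg$n_tissues,
                dimnames = list(ann$annotation$gene_id, tissue_names(cfg)))
  dhs <- generate_dhs(cfg, npb, ann)
  c(list(cfg = cfg), ann,
    meth[c("beta", "samples", "truth")],
    list(histone = hist, rpkm = rpkm, dhs = dhs))
}
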