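# Synthetic ddPCR panels with ground truth.
#
# The generator emulates the statistical structure of a two-subclone PDX
# ecosystem measured by ddPCR: per-sample mixing fractions drawn per
# treatment cohort, AF values from the exact mixture ratio, CN values
# from the affine mixture, independent Gaussian measurement noise
# (sigma_AF = 0.011, sigma_CN = 0.10), occasional bottleneck outliers
# displacing a single AF dimension, CRPC clone samples with quantized
# (pure-genotype) values, and a cohort-specific linear volume response.
# It emulates the measured data's statistical structure, not the
# underlying cell kinetics.

#' Default two-subclone genotypes
#'
#' The reconstruction the generator emulates: subclone 1 carries the
#' LRP1B (1 of 4) and ERBB4 (1 of 3) mutations and the
#' EPHA3/EPHA5/PTPRD amplifications; subclone 2 lacks them, carries the
#' MET mutation on 2 of 3 copies and an AR amplification. BRCA2
#' (2 of 4), PTCH1 (2 of 3) and TP53 (3 of 3) are truncal; EXOC4 and
#' AKR1B1 are diploid controls. ERBB4 mean copy numbers 2.8 and 1.3
#' encode residual within-subclone heterogeneity at the CN locus.
#'
#' @return A list with \code{\link{subclone_genotype}} elements
#'   \code{subclone1} and \code{subclone2}.
#' @export
default_genotypes <- function() {
  loci <- c("LRP1B", "ERBB4", "MET", "PTCH1", "TP53", "BRCA2", "SAAL1",
            "EPHA3", "EPHA5", "PTPRD", "AR", "EXOC4", "AKR1B1")
  g1 <- subclone_genotype(
    loci,
    m = c(1, 1, 1, 2, 3, 2, 2, 0, 0, 0, 0, 0, 0),
    t = c(4, 3, 2, 3, 3, 4, 5, 4, 4, 4, 2, 2, 2),
    mean_cn = c(NA, 2.8, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA))
  g2 <- subclone_genotype(
    loci,
    m = c(0, 0, 2, 2, 3, 2, 1, 0, 0, 0, 0, 0, 0),
    t = c(2, 1, 3, 3, 3, 4, 4, 2, 2, 2, 4, 2, 2),
    mean_cn = c(NA, 1.3, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA))
  list(subclone1 = g1, subclone2 = g2)
}

#' Simulation configuration
#'
#' Collects every knob of \code{\link{simulate_two_subclone_panel}} with
#' the defaults the package's validation studies use: 47 xenograft
#' samples split over the treatment arms of a PDX study, mixing
#' fractions Normal(0.70, 0.10) in non-cisplatin cohorts and
#' Normal(0.43, 0.15) in cisplatin cohorts (clipped to \[0, 1\]),
#' measurement noise sigma_af = 0.011 and sigma_cn = 0.10, no injected
#' outliers, and a positive volume/anchor-CN coupling only under
#' cisplatin.
#'
#' @param n_samples number of samples (default 47).
#' @param genotypes list with \code{subclone1}/\code{subclone2}
#'   (default \code{\link{default_genotypes}()}).
#' @param panel \code{\link{marker_panel}} (default
#'   \code{\link{default_panel}()}); every marker's gene must be in the
#'   genotypes.
#' @param cohort_template named integer vector allocating samples to
#'   treatments; recycled/truncated to \code{n_samples}.
#' @param fraction_distribution list with numeric \code{mean}/\code{sd}
#'   pairs \code{non_cisplatin} and \code{cisplatin}, or the string
#'   \code{"uniform"} for p ~ Uniform(0, 1) in every cohort (the design
#'   used for identifiability studies, which need samples spanning the
#'   whole mixing axis; see the vignette).
#' @param sigma_af,sigma_cn Gaussian measurement noise SDs.
#' @param outlier_rate probability a sample gets one displaced AF
#'   dimension.
#' @param outlier_displacement magnitude of the AF displacement.
#' @param crpc_fraction fraction of samples emitted as CRPC clone
#'   cultures (pure single-subclone, quantized AF) instead of
#'   xenografts.
#' @param volume_model list of \code{c(intercept, slope, sd)} vectors
#'   (\code{cisplatin}, \code{non_cisplatin}): percent volume change as
#'   a linear function of the true anchor (LRP1B) CN.
#' @param anchor_gene gene anchoring the volume model (default LRP1B).
#' @param seed integer RNG seed.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_samples = 47,
                              genotypes = default_genotypes(),
                              panel = default_panel(),
                              cohort_template = c(vehicle = 8, none = 8,
                                                  cisplatin = 9,
                                                  cisplatin_retreat = 6,
                                                  docetaxel = 8,
                                                  doxorubicin = 4,
                                                  cyclophosphamide = 4),
                              fraction_distribution = list(
                                non_cisplatin = c(mean = 0.70, sd = 0.10),
                                cisplatin = c(mean = 0.43, sd = 0.15)),
                              sigma_af = 0.011, sigma_cn = 0.10,
                              outlier_rate = 0, outlier_displacement = 0.15,
                              crpc_fraction = 0,
                              volume_model = list(
                                cisplatin = c(intercept = -360, slope = 120,
                                              sd = 30),
                                non_cisplatin = c(intercept = 50, slope = 0,
                                                  sd = 40)),
                              anchor_gene = "LRP1B",
                              seed = 1L) {
  stopifnot(n_samples >= 1, sigma_af >= 0, sigma_cn >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            crpc_fraction >= 0, crpc_fraction <= 1)
  missing_genes <- setdiff(panel$gene, genotypes$subclone1$locus)
  if (length(missing_genes)) {
    stop("panel genes without genotypes: ",
         paste(missing_genes, collapse = ", "))
  }
  structure(list(n_samples = n_samples, genotypes = genotypes, panel = panel,
                 cohort_template = cohort_template,
                 fraction_distribution = fraction_distribution,
                 sigma_af = sigma_af, sigma_cn = sigma_cn,
                 outlier_rate = outlier_rate,
                 outlier_displacement = outlier_displacement,
                 crpc_fraction = crpc_fraction, volume_model = volume_model,
                 anchor_gene = anchor_gene, seed = as.integer(seed)),
            class = "simulation_config")
}

.rnorm_clip <- function(n, mean, sd, lo = 0, hi = 1) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a two-subclone ddPCR measurement panel
#'
#' Draws a mixing fraction p per sample from its cohort's distribution,
#' emits each AF assay from the exact mixture ratio and each CN assay
#' from the affine mixture of the two genotypes, adds independent
#' Gaussian noise (AF truncated to \[0, 1\], CN to >= 0), optionally
#' injects bottleneck outliers by displacing one randomly chosen AF
#' dimension by \code{outlier_displacement} with random sign, and draws
#' percent volume change from the cohort's linear model on the true
#' anchor CN. CRPC clone samples are drawn as a pure single subclone:
#' their AF values are quantized at m/T (and CN at the integer T)
#' before noise. The same config and seed reproduce the output
#' bit-exactly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list with \code{table} (a \code{\link{measurement_table}}
#'   with metadata attached), \code{metadata} (the sample
#'   \code{data.frame}) and \code{truth} (per-sample true p, cohort,
#'   source and injected-outlier record; genotypes and volume model in
#'   attributes).
#' @export
simulate_two_subclone_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  g1 <- config$genotypes$subclone1; g2 <- config$genotypes$subclone2
  panel <- config$panel

  treatment <- rep(rep(names(config$cohort_template),
                       times = config$cohort_template),
                   length.out = n)
  source <- rep("xenograft", n)
  n_crpc <- round(config$crpc_fraction * n)
  if (n_crpc > 0) {
    idx <- sample.int(n, n_crpc)
    source[idx] <- "crpc_clone"
    treatment[idx] <- "none"
  }
  is_cis <- treatment %in% c("cisplatin", "cisplatin_retreat")
  fd <- config$fraction_distribution
  p <- numeric(n)
  if (identical(fd, "uniform")) {
    p <- stats::runif(n)
  } else {
    p[!is_cis] <- .rnorm_clip(sum(!is_cis), fd$non_cisplatin["mean"],
                              fd$non_cisplatin["sd"])
    p[is_cis] <- .rnorm_clip(sum(is_cis), fd$cisplatin["mean"],
                             fd$cisplatin["sd"])
  }
  clone <- source == "crpc_clone"
  p[clone] <- as.numeric(stats::runif(sum(clone)) < 0.5)  # pure subclone

  sample_id <- sprintf("S%03d", seq_len(n))
  vals <- matrix(NA_real_, n, nrow(panel),
                 dimnames = list(sample_id, panel$marker_id))
  for (j in seq_len(nrow(panel))) {
    gene <- panel$gene[j]
    if (panel$assay_kind[j] == "AF") {
      mu <- expected_allele_frequency(p, g1, g2, gene)
      vals[, j] <- pmin(pmax(mu + stats::rnorm(n, 0, config$sigma_af), 0), 1)
    } else {
      mu <- expected_copy_number(p, g1, g2, gene)
      # single-cell-derived clones are homogeneous: integer copy number
      if (any(clone)) {
        t1 <- .locus_row(g1, gene)$t; t2 <- .locus_row(g2, gene)$t
        mu[clone] <- ifelse(p[clone] == 1, t1, t2)
      }
      vals[, j] <- pmax(mu + stats::rnorm(n, 0, config$sigma_cn), 0)
    }
  }

  # bottleneck outliers: displace one AF dimension of selected samples
  out_dims <- intersect(c("BRCA2_AF", "PTCH1_AF", "TP53_AF",
                          "ERBB4_AF", "MET_AF", "SAAL1_AF"),
                        panel$marker_id)
  outlier_dim <- rep(NA_character_, n)
  outlier_sign <- rep(NA_integer_, n)
  if (config$outlier_rate > 0 && length(out_dims)) {
    hit <- stats::runif(n) < config$outlier_rate
    for (i in which(hit)) {
      d <- sample(out_dims, 1L)
      s <- sample(c(-1L, 1L), 1L)
      # AF is bounded: flip the sign when the displacement would leave
      # [0, 1], so the recorded injection is actually present in the data
      if (vals[i, d] + s * config$outlier_displacement > 1) s <- -1L
      if (vals[i, d] + s * config$outlier_displacement < 0) s <- 1L
      outlier_dim[i] <- d; outlier_sign[i] <- s
      vals[i, d] <- min(max(vals[i, d] + s * config$outlier_displacement, 0), 1)
    }
  }

  # volume response: linear in the true anchor CN under cisplatin
  true_anchor_cn <- expected_copy_number(p, g1, g2, config$anchor_gene)
  vm <- config$volume_model
  volume <- numeric(n)
  volume[is_cis] <- vm$cisplatin["intercept"] +
    vm$cisplatin["slope"] * true_anchor_cn[is_cis] +
    stats::rnorm(sum(is_cis), 0, vm$cisplatin["sd"])
  volume[!is_cis] <- vm$non_cisplatin["intercept"] +
    vm$non_cisplatin["slope"] * true_anchor_cn[!is_cis] +
    stats::rnorm(sum(!is_cis), 0, vm$non_cisplatin["sd"])
  volume <- pmax(volume, -100)
  days <- ifelse(treatment == "cisplatin_retreat",
                 round(stats::runif(n, 40, 70)),
                 round(stats::runif(n, 21, 60)))

  metadata <- data.frame(
    sample_id = sample_id, model_id = "SIM099", source = source,
    treatment = treatment, volume_change_pct = round(volume, 2),
    days = days, spatial_label = NA_character_, stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = sample_id, p_true = p, source = source,
    treatment = treatment, outlier_dim = outlier_dim,
    outlier_sign = outlier_sign,
    outlier_displacement = ifelse(is.na(outlier_dim), NA_real_,
                                  config$outlier_displacement),
    true_anchor_cn = true_anchor_cn, stringsAsFactors = FALSE)
  attr(truth, "genotypes") <- config$genotypes
  attr(truth, "volume_model") <- config$volume_model
  list(table = measurement_table(vals, panel, samples = metadata),
       metadata = metadata, truth = truth)
}

#' Simulate a spatial-drift AF panel
#'
#' Emulates untreated spatiotemporally dissected tumor sections: samples
#' sit on a grid, each marker's latent cellularity follows a spatially
#' autocorrelated Gaussian field (covariance
#' \code{spatial_correlation^distance}), independent across markers, and
#' is scaled to the marker's AF range. Occasional bottleneck jumps boost
#' one sample-marker to high cellularity (a 30--40% takeover).
#' Measurement noise as in the main simulator. With
#' \code{spatial_correlation = 0} markers are mutually and spatially
#' independent.
#'
#' @param n_samples number of grid samples (default 8).
#' @param marker_ranges named numeric vector of per-marker maximum AF
#'   (defaults: TTN 0.164, ERBB4 0.194, DNMT3B 0.023).
#' @param spatial_correlation field correlation at unit grid distance,
#'   in \[0, 1).
#' @param sigma_af measurement noise SD (default 0.011).
#' @param bottleneck_rate per-sample-per-marker jump probability
#'   (default 0.05).
#' @param seed integer RNG seed.
#' @return A list with \code{table}, \code{metadata}, \code{truth}
#'   (latent AF field, grid coordinates, bottleneck flags).
#' @export
simulate_spatial_drift_panel <- function(n_samples = 8,
                                         marker_ranges = c(TTN = 0.164,
                                                           ERBB4 = 0.194,
                                                           DNMT3B = 0.023),
                                         spatial_correlation = 0.8,
                                         sigma_af = 0.011,
                                         bottleneck_rate = 0.05,
                                         seed = 1L) {
  stopifnot(n_samples >= 1, all(marker_ranges >= 0 & marker_ranges <= 1),
            spatial_correlation >= 0, spatial_correlation < 1)
  set.seed(as.integer(seed))
  ncol_grid <- ceiling(sqrt(n_samples))
  row_i <- (seq_len(n_samples) - 1L) %/% ncol_grid + 1L
  col_i <- (seq_len(n_samples) - 1L) %% ncol_grid + 1L
  label <- paste0(LETTERS[row_i], col_i)
  dist_mat <- as.matrix(stats::dist(cbind(row_i, col_i)))
  cov_mat <- spatial_correlation^dist_mat
  diag(cov_mat) <- 1
  ch <- chol(cov_mat + diag(1e-8, n_samples))

  markers <- names(marker_ranges)
  sample_id <- sprintf("G%03d", seq_len(n_samples))
  latent <- matrix(NA_real_, n_samples, length(markers),
                   dimnames = list(sample_id, markers))
  bottleneck <- matrix(FALSE, n_samples, length(markers),
                       dimnames = list(sample_id, markers))
  vals <- latent
  for (k in seq_along(markers)) {
    z <- drop(crossprod(ch, stats::rnorm(n_samples)))
    af <- stats::pnorm(z) * marker_ranges[k]     # latent AF in [0, range]
    jump <- stats::runif(n_samples) < bottleneck_rate
    # takeover of ~30-40% of cells: heterozygous cellularity/2 -> AF
    af[jump] <- stats::runif(sum(jump), 0.30, 0.40) / 2
    bottleneck[, k] <- jump
    latent[, k] <- af
    vals[, k] <- pmin(pmax(af + stats::rnorm(n_samples, 0, sigma_af), 0), 1)
  }
  colnames(vals) <- paste0(markers, "_AF")
  panel <- marker_panel(colnames(vals), markers, "AF")
  metadata <- data.frame(
    sample_id = sample_id, model_id = "SIM096", source = "xenograft",
    treatment = "none", volume_change_pct = NA_real_, days = NA_real_,
    spatial_label = label, stringsAsFactors = FALSE)
  truth <- list(latent_af = latent, bottleneck = bottleneck,
                grid = data.frame(sample_id = sample_id, row = row_i,
                                  col = col_i, stringsAsFactors = FALSE))
  list(table = measurement_table(vals, panel, samples = metadata),
       metadata = metadata, truth = truth)
}
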