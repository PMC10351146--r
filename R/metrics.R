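#' Drift and homozygosity inbreeding coefficients
#'
#' With generation-five allele frequencies `p_ref` as base:
#' * `f_drift` = mean over loci of (p_t - p_ref)^2 / (p_ref (1 - p_ref)),
#'   the squared frequency deviation scaled by its value under complete
#'   random inbreeding;
#' * `f_hom` = 1 - mean over loci of 2 p_t (1 - p_t) / (2 p_ref (1 - p_ref)),
#'   the relative loss of expected heterozygosity (0 at the reference
#'   generation, 1 when every locus is fixed).
#'
#' Loci with reference MAF at or below the threshold are excluded by the
#' caller-supplied mask to avoid the large influence of rare alleles.
#'
#' @param p_t current allele frequencies.
#' @param p_ref reference (generation-five) allele frequencies.
#' @param mask logical or index vector of loci to include; masked loci must
#'   have 0 < p_ref < 1.
#' @return a single coefficient.
#' @export
f_drift <- function(p_t, p_ref, mask) {
  p_t <- p_t[mask]; p_ref <- p_ref[mask]
  if (length(p_t) == 0) stop("empty locus mask")
  mean((p_t - p_ref)^2 / (p_ref * (1 - p_ref)))
}

#' @rdname f_drift
#' @export
f_hom <- function(p_t, p_ref, mask) {
  p_t <- p_t[mask]; p_ref <- p_ref[mask]
  if (length(p_t) == 0) stop("empty locus mask")
  1 - mean((p_t * (1 - p_t)) / (p_ref * (1 - p_ref)))
}

#' Additive genic variance
#'
#' sigma2_G = sum over QTL of p (1 - p) alpha^2: the additive variance under
#' linkage equilibrium and Hardy-Weinberg proportions, insensitive to the
#' Bulmer effect.  The default follows the sum as stated (without the
#' conventional factor 2); `factor2 = TRUE` gives 2 sum p(1-p) alpha^2.
#' Reported trajectories are expressed relative to generation five, so the
#' factor cancels there.
#'
#' @param p QTL allele frequencies.
#' @param alpha QTL allele-substitution effects.
#' @param factor2 use the conventional factor-2 form.
#' @return the genic variance.
#' @export
genic_variance <- function(p, alpha, factor2 = FALSE) {
  v <- sum(p * (1 - p) * alpha^2)
  if (factor2) 2 * v else v
}

#' Expected heterozygosity deficit from finite parent numbers
#'
#' Heterozygosity falls short of its Hardy-Weinberg expectation by
#' 1/(8M) + 1/(8F) when M sires and F dams are used.
#'
#' @param n_males,n_females numbers of male and female parents (> 0).
#' @return the deficit.
#' @examples
#' expected_het_deficit(40, 6000)  # 0.0031
#' @export
expected_het_deficit <- function(n_males, n_females) {
  stopifnot(n_males > 0, n_females > 0)
  1 / (8 * n_males) + 1 / (8 * n_females)
}

#' Per-generation metrics panel of a scenario run
#'
#' Assembles, per generation: mean TBV in generation-zero additive genetic
#' standard deviations, mean empirical IBD kinship, F_drift and F_hom per
#' locus class (markers, QTL, neutral; relative to the generation-five
#' frequencies, loci with reference MAF <= the threshold excluded), the
#' additive genetic variance (variance of TBV), the genic variance, the mean
#' MAF at QTL and neutral loci and the segregating fraction per class.
#'
#' @param log a `scenario_log` from [run_scenario()].
#' @param cfg the [program_config()] used for the run.
#' @return data.frame with one row per generation.
#' @export
metrics_panel <- function(log, cfg) {
  map <- log$map
  ref_gen <- cfg$metrics$reference_generation
  thr <- cfg$metrics$maf_threshold
  p_ref <- log$freq[, ref_gen + 1]
  classes <- c(marker = "MARKER", qtl = "QTL", neutral = "NEUTRAL")
  masks <- lapply(classes, function(cl) {
    which(map$class == cl & pmin(p_ref, 1 - p_ref) > thr)
  })
  qtl_idx <- which(map$class == "QTL")
  neu_idx <- which(map$class == "NEUTRAL")
  alpha <- log$alpha
  sd0 <- sqrt(log$sigma2_a0)
  n_gen <- ncol(log$freq)
  rows <- lapply(seq_len(n_gen), function(g) {
    p <- log$freq[, g]
    fs <- lapply(names(classes), function(cl) {
      if (g - 1 < ref_gen) c(NA_real_, NA_real_) else
        c(f_drift(p, p_ref, masks[[cl]]), f_hom(p, p_ref, masks[[cl]]))
    })
    names(fs) <- names(classes)
    data.frame(
      generation = g - 1L,
      mean_tbv_sd0 = log$mean_tbv[g] / sd0,
      mean_kinship = log$mean_f[g],
      f_drift_marker = fs$marker[1], f_hom_marker = fs$marker[2],
      f_drift_qtl = fs$qtl[1], f_hom_qtl = fs$qtl[2],
      f_drift_neutral = fs$neutral[1], f_hom_neutral = fs$neutral[2],
      var_a = log$var_tbv[g],
      var_g = genic_variance(p[qtl_idx], alpha, cfg$metrics$genic_factor2),
      maf_qtl = mean(pmin(p[qtl_idx], 1 - p[qtl_idx])),
      maf_neutral = mean(pmin(p[neu_idx], 1 - p[neu_idx])),
      seg_marker = {
        pm <- p[map$class == "MARKER"]; mean(pm > 0 & pm < 1)
      },
      seg_qtl = mean(p[qtl_idx] > 0 & p[qtl_idx] < 1),
      seg_neutral = mean(p[neu_idx] > 0 & p[neu_idx] < 1)
    )
  })
  out <- do.call(rbind, rows)
  out$scenario <- log$scenario
  out$replicate <- log$replicate
  out
}
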