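#' True breeding value from phased haplotypes
#'
#' TBV is the sum over QTL of the allele count times the allele-substitution
#' effect.
#'
#' @param hap phased haplotype matrix (loci x 2n, alleles 0/1).
#' @param qtl_idx row indices of the QTL.
#' @param alpha QTL effects, one per entry of `qtl_idx`.
#' @return numeric vector of n true breeding values.
#' @export
tbv_from_hap <- function(hap, qtl_idx, alpha) {
  n <- ncol(hap) / 2
  g <- hap[qtl_idx, 2 * seq_len(n) - 1, drop = FALSE] +
    hap[qtl_idx, 2 * seq_len(n), drop = FALSE]
  drop(crossprod(g, alpha))
}

#' Genotype dosage matrix of a set of individuals
#'
#' @param hap phased haplotype matrix (loci x 2n).
#' @param loci row indices to extract (e.g. the marker loci).
#' @param ind individual indices (default all).
#' @return animals x loci matrix of allele counts in 0, 1, 2.
#' @export
dosage_matrix <- function(hap, loci, ind = seq_len(ncol(hap) / 2)) {
  t(hap[loci, 2 * ind - 1, drop = FALSE] + hap[loci, 2 * ind, drop = FALSE])
}

founder_segments <- function(n, glen) {
  lapply(seq_len(2 * n), function(h) matrix(c(glen, h), 1, 2))
}

#' Generation-zero cohort from a founder population
#'
#' @param founders a [make_founders()] object.
#' @return a `cohort` list: ids, pedigree links (0 for founders), sex,
#'   haplotypes, founder-segment lists, TBV, phenotype and GEBV slots.
#' @export
founder_cohort <- function(founders) {
  n <- length(founders$sex)
  glen <- attr(founders$map, "glen")
  structure(list(
    gen = 0L, id = seq_len(n), sire = rep(0L, n), dam = rep(0L, n),
    sex = founders$sex, hap = founders$hap,
    segs = founder_segments(n, glen),
    tbv = tbv_from_hap(founders$hap, founders$arch$qtl_idx, founders$arch$alpha),
    phen = rep(NA_real_, n), gebv = rep(NA_real_, n),
    genotyped = rep(FALSE, n)
  ), class = "cohort")
}

#' Single meiosis with founder-segment provenance
#'
#' Per chromosome the crossover count is Poisson(length in Morgan), crossover
#' positions are uniform, and the starting parental haplotype is chosen with
#' probability 1/2.  There is no mutation in the breeding phase, so an allele
#' absent from the parent cannot appear in the gamete.
#'
#' @param hap parent's two haplotypes as a loci x 2 matrix.
#' @param segs list of the parent's two segment matrices (columns: global end
#'   position, founder label).
#' @param map a [genome_map()] data.frame.
#' @return list with `alleles` (length-loci vector) and `seg` (segment matrix
#'   of the gamete).
#' @export
meiose <- function(hap, segs, map) {
  geo <- map_geometry(map)
  cpp_meiose(hap, segs, geo$pos, geo$chr_first, geo$chr_lo, geo$chr_hi)
}

#' Assign phenotypes to the females of a cohort
#'
#' The trait is recorded on females only: y = mu + TBV + e with e drawn from
#' Normal(0, sigma2_e), sigma2_e fixed at its generation-zero value (so
#' realized heritability drifts with the additive variance).  Phenotypes
#' become usable for evaluation one generation after birth, when the female
#' enters the dam pool; the birth cohort stores the value, the caller is
#' responsible for the availability rule.
#'
#' @param cohort a cohort.
#' @param arch trait architecture from [assign_qtl_effects()].
#' @param mu trait mean (default 0).
#' @return the cohort with female phenotypes filled in.
#' @export
assign_phenotypes <- function(cohort, arch, mu = 0) {
  f <- which(cohort$sex == 2L)
  cohort$phen[f] <- mu + cohort$tbv[f] + rnorm(length(f), 0, sqrt(arch$sigma2_e))
  cohort
}

#' Mate selected sires to all cohort females
#'
#' Each dam produces exactly two calves by two distinct sires; each sire is
#' used equally, receiving 2 * n_dams / n_sires offspring (rebalanced by at
#' most 1 when not divisible).  Offspring sexes are assigned by random
#' permutation so the cohort is exactly half male, half female.
#'
#' @param cohort parent cohort (provides dams = all its females and the
#'   sires' haplotypes).
#' @param sire_ids ids (within `cohort$id`) of the selected sires.
#' @param founders the founder population (map and trait architecture).
#' @param gen generation index of the offspring.
#' @param id_start first id to assign to offspring.
#' @return the offspring cohort.
#' @export
mate_cohort <- function(cohort, sire_ids, founders, gen, id_start) {
  dams <- which(cohort$sex == 2L)
  sires <- match(sire_ids, cohort$id)
  if (anyNA(sires)) stop("sire ids not in cohort")
  ns <- length(sires); nd <- length(dams)
  if (ns < 2) stop("need at least two sires: each dam requires two distinct sires")
  n_off <- 2L * nd
  q <- n_off %/% ns; r <- n_off %% ns
  slots <- rep(sires, times = q + (seq_len(ns) <= r))
  slots <- sample(slots)
  sire_of <- matrix(slots, nrow = 2)      # columns = dams
  # repair dams assigned the same sire twice
  for (j in which(sire_of[1, ] == sire_of[2, ])) {
    if (sire_of[1, j] != sire_of[2, j]) next  # fixed by an earlier swap
    k <- which(sire_of[1, ] != sire_of[2, j] & sire_of[2, ] != sire_of[2, j])
    if (length(k) == 0) stop("cannot satisfy the distinct-sire rule")
    k <- k[[1]]
    tmp <- sire_of[2, j]; sire_of[2, j] <- sire_of[1, k]; sire_of[1, k] <- tmp
  }
  sire_vec <- as.integer(sire_of)
  dam_vec <- rep(dams, each = 2)
  geo <- map_geometry(founders$map)
  res <- cpp_mate(cohort$hap, cohort$segs, sire_vec, dam_vec,
                  geo$pos, geo$chr_first, geo$chr_lo, geo$chr_hi)
  sex <- sample(rep(1:2, each = n_off / 2))
  structure(list(
    gen = as.integer(gen), id = id_start + seq_len(n_off) - 1L,
    sire = cohort$id[sire_vec], dam = cohort$id[dam_vec],
    sex = sex, hap = res$hap, segs = res$segs,
    tbv = tbv_from_hap(res$hap, founders$arch$qtl_idx, founders$arch$alpha),
    phen = rep(NA_real_, n_off), gebv = rep(NA_real_, n_off),
    genotyped = rep(FALSE, n_off)
  ), class = "cohort")
}

#' Mean empirical IBD kinship of a cohort
#'
#' The pairwise kinship of two individuals is the probability that a haplotype
#' drawn at random from each is identical by descent, computed exactly from
#' the founder-segment bookkeeping as the mean over the four haplotype
#' pairings of the shared-founder-segment genome fraction.  The cohort mean is
#' estimated from `n_pairs` distinct pairs sampled without replacement.
#'
#' @param cohort a cohort.
#' @param n_pairs number of pairs to sample.
#' @param seed integer seed for the pair sample.
#' @return list with `mean` and the sampled per-pair kinships `f`.
#' @export
empirical_ibd_kinship <- function(cohort, n_pairs, seed) {
  n <- length(cohort$id)
  npair_all <- n * (n - 1) / 2
  if (n_pairs > npair_all) stop("n_pairs exceeds the number of distinct pairs")
  set.seed(seed)
  ks <- sort(sample.int(npair_all, n_pairs))
  # unrank pair index k -> (i < j), pairs ordered by i then j;
  # pairs before row i: (i-1) n - (i-1) i / 2
  pbase <- function(i) (i - 1) * n - (i - 1) * i / 2
  i <- pmax(1, pmin(n - 1, ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * ks))))
  bad <- ks - pbase(i) < 1 | ks - pbase(i) > n - i
  while (any(bad)) {  # correct sqrt round-off at bin edges
    i[bad] <- i[bad] + ifelse(ks[bad] - pbase(i[bad]) < 1, -1, 1)
    bad <- ks - pbase(i) < 1 | ks - pbase(i) > n - i
  }
  j <- i + (ks - pbase(i))
  f <- cpp_ibd_pairs(cohort$segs, cbind(as.integer(i), as.integer(j)),
                     attr_glen(cohort))
  list(mean = mean(f), f = f)
}

attr_glen <- function(cohort) {
  # genome length recovered from any segment list (last end)
  s <- cohort$segs[[1]]
  s[nrow(s), 1]
}

#' Exact pairwise empirical IBD kinship
#'
#' @param cohort a cohort.
#' @param i,j individual positions within the cohort; `i == j` gives the
#'   self-kinship (1 + F)/2.
#' @return kinship on the kinship scale (founder self-kinship 1/2).
#' @export
kinship_pair <- function(cohort, i, j) {
  as.numeric(cpp_ibd_pairs(cohort$segs, cbind(as.integer(i), as.integer(j)),
                           attr_glen(cohort)))
}
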