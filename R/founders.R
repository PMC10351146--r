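#' Build the locus map for a configured genome
#'
#' Loci are evenly spaced: locus i of a chromosome sits at genetic position
#' (i - 1/2) / n_loci Morgan, so no locus lies exactly on a chromosome end.
#' Global positions (`gpos`) lay chromosomes end to end, which is the
#' coordinate system used by meiosis and segment bookkeeping.
#'
#' @param cfg a [program_config()] object.
#' @return data.frame with columns `chrom`, `id`, `pos` (Morgan within
#'   chromosome), `gpos` (global Morgan) and `class` (initially all
#'   `"MARKER"`), plus attributes `chr_first`, `chr_lo`, `chr_hi`, `glen`.
#' @export
genome_map <- function(cfg) {
  g <- cfg$genome
  nc <- g$n_chromosomes; nl <- g$loci_per_chromosome; len <- g$chromosome_length
  chrom <- rep(seq_len(nc), each = nl)
  pos <- rep((seq_len(nl) - 0.5) / nl * len, nc)
  offset <- (chrom - 1) * len
  map <- data.frame(
    chrom = chrom,
    id = sprintf("c%d_l%d", chrom, rep(seq_len(nl), nc)),
    pos = pos,
    gpos = pos + offset,
    class = factor(rep("MARKER", nc * nl),
                   levels = c("MARKER", "QTL", "NEUTRAL", "DISCARDED")),
    stringsAsFactors = FALSE
  )
  attr(map, "chr_first") <- as.integer(seq(0L, nc * nl, by = nl))
  attr(map, "chr_lo") <- (seq_len(nc) - 1) * len
  attr(map, "chr_hi") <- seq_len(nc) * len
  attr(map, "glen") <- nc * len
  map
}

map_geometry <- function(map) {
  list(pos = map$gpos, chr_first = attr(map, "chr_first"),
       chr_lo = attr(map, "chr_lo"), chr_hi = attr(map, "chr_hi"),
       glen = attr(map, "glen"))
}

#' Simulate the historical population
#'
#' Runs a dioecious Wright-Fisher population through the configured size
#' trajectory with random mating, discrete generations, Poisson(1 per Morgan)
#' recombination and recurrent symmetric mutation (allele state flipped with
#' the configured probability per transmitted allele; historical phase only).
#' Every locus starts at allele frequency 0.5 in expectation (haplotype
#' alleles drawn Bernoulli(0.5)).  The last trajectory generation is expanded
#' into the base cohort of `base_males + base_females` individuals.
#'
#' @param cfg a [program_config()] object.
#' @param seed integer seed.
#' @param map optional precomputed [genome_map()].
#' @return list with `hap` (loci x 2n phased 0/1 matrix of the base cohort),
#'   `p0` (realized initial allele frequencies), `freq` (base-cohort allele
#'   frequencies) and `map`.
#' @export
simulate_historical <- function(cfg, seed, map = genome_map(cfg)) {
  g <- cfg$genome
  n_base <- g$base_males + g$base_females
  geo <- map_geometry(map)
  set.seed(seed)
  res <- cpp_wright_fisher(geo$pos, geo$chr_first, geo$chr_lo, geo$chr_hi,
                           g$historical_sizes, g$mutation_rate, n_base)
  res$freq <- rowMeans(res$hap)
  res$map <- map
  res
}

#' Classify loci into markers, QTL, neutral loci and discards
#'
#' QTL and neutral loci are sampled uniformly from the segregating loci (no
#' MAF criterion), in that order.  The remaining segregating loci pass the
#' SNP-chip ascertainment filter: MAF < 0.01 is discarded with probability
#' 0.5, MAF in [0.01, 0.02) with probability 0.2; survivors are markers.
#' Non-segregating loci are discarded.  "Segregating" means 0 < freq < 1 in
#' the base cohort.
#'
#' @param freq per-locus base-cohort allele frequency.
#' @param map a [genome_map()] data.frame.
#' @param cfg a [program_config()] object (for the QTL/neutral counts).
#' @param seed integer seed.
#' @return `map` with its `class` column filled in.
#' @export
partition_loci <- function(freq, map, cfg, seed) {
  stopifnot(length(freq) == nrow(map))
  n_qtl <- cfg$genome$n_qtl; n_neu <- cfg$genome$n_neutral
  seg <- which(freq > 0 & freq < 1)
  if (length(seg) < n_qtl + n_neu)
    stop("fewer segregating loci than QTL + neutral loci required")
  set.seed(seed)
  cls <- rep("DISCARDED", nrow(map))
  pick <- sample(seg, n_qtl + n_neu)
  cls[pick[seq_len(n_qtl)]] <- "QTL"
  cls[pick[n_qtl + seq_len(n_neu)]] <- "NEUTRAL"
  rest <- setdiff(seg, pick)
  maf <- pmin(freq[rest], 1 - freq[rest])
  u <- runif(length(rest))
  drop <- (maf < 0.01 & u < 0.5) | (maf >= 0.01 & maf < 0.02 & u < 0.2)
  cls[rest[!drop]] <- "MARKER"
  map$class <- factor(cls, levels = levels(map$class))
  map
}

#' Assign QTL effects and derive the trait architecture
#'
#' Allele-substitution effects have magnitude gamma(shape 0.4, scale 1.66)
#' with sign randomized to +1 or -1 with probability 1/2 each.  The base
#' additive variance is the variance of base-cohort true breeding values and
#' the residual variance is fixed from it via the base heritability
#' (`sigma2_e = sigma2_a0 (1 - h2) / h2`), so heritability drifts in later
#' generations as the additive variance changes.
#'
#' @param map locus map with classes assigned ([partition_loci()]).
#' @param hap base-cohort phased haplotype matrix (loci x 2n).
#' @param cfg a [program_config()] object.
#' @param seed integer seed.
#' @return list with `qtl_idx`, `alpha`, `sigma2_a0`, `sigma2_e`, `h2`.
#' @export
assign_qtl_effects <- function(map, hap, cfg, seed) {
  qtl_idx <- which(map$class == "QTL")
  if (length(qtl_idx) == 0) stop("no QTL designated")
  set.seed(seed)
  mag <- rgamma(length(qtl_idx), shape = cfg$trait$gamma_shape,
                scale = cfg$trait$gamma_scale)
  sign <- ifelse(runif(length(qtl_idx)) < 0.5, -1, 1)
  alpha <- mag * sign
  tbv <- tbv_from_hap(hap, qtl_idx, alpha)
  h2 <- cfg$trait$heritability
  s2a <- var(tbv)
  list(qtl_idx = qtl_idx, alpha = alpha, sigma2_a0 = s2a,
       sigma2_e = s2a * (1 - h2) / h2, h2 = h2)
}

#' Generate the base population
#'
#' Composes [simulate_historical()], [partition_loci()] and
#' [assign_qtl_effects()] into the generation-zero founder population.  The
#' first `base_males` individuals are male.  Founder haplotype h of
#' individual i carries the founder-segment label 2(i-1)+h used by the
#' empirical IBD kinship estimator.
#'
#' @param cfg a [program_config()] object.
#' @param seed integer seed (sub-seeds are derived per concern).
#' @return an object of class `founder_pop`: list with `map`, `hap`, `arch`,
#'   `sex` (1 = male, 2 = female), `freq` and `cfg`.
#' @export
make_founders <- function(cfg, seed) {
  hist <- simulate_historical(cfg, seed_stream(seed, "historical"))
  map <- partition_loci(hist$freq, hist$map, cfg, seed_stream(seed, "loci"))
  arch <- assign_qtl_effects(map, hist$hap, cfg, seed_stream(seed, "qtl"))
  n <- cfg$genome$base_males + cfg$genome$base_females
  structure(list(map = map, hap = hist$hap, arch = arch,
                 sex = rep(1:2, c(cfg$genome$base_males, cfg$genome$base_females)),
                 freq = hist$freq, cfg = cfg),
            class = "founder_pop")
}

#' @exportS3Method base::print
print.founder_pop <- function(x, ...) {
  cat("Founder population:", length(x$sex), "individuals,",
      nrow(x$map), "loci (", sum(x$map$class == "MARKER"), "markers,",
      sum(x$map$class == "QTL"), "QTL,",
      sum(x$map$class == "NEUTRAL"), "neutral )\n")
  cat(sprintf("sigma2_A0 = %.3f, sigma2_e = %.3f (h2 = %.2f)\n",
              x$arch$sigma2_a0, x$arch$sigma2_e, x$arch$h2))
  invisible(x)
}
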