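#' Breeding program configuration
#'
#' Returns the full parameterization of the simulated breeding program.  The
#' defaults at `scale = 1` are the study conditions: 29 chromosomes of 1 Morgan
#' with 1800 evenly spaced biallelic loci each, a historical population of
#' 2000 individuals for 2000 generations bottlenecked to 200 and re-expanded
#' to 1000 (100 generations each), recurrent mutation 2e-5, a base cohort of
#' 6000 males and 6000 females, 3000 QTL with gamma(0.4, 1.66) effects, 3000
#' neutral loci, heritability 0.4, 120 PBLUP sires, 40 OCS sires, 2000
#' genotyped males per generation, 1000 selection candidates, a kinship-rate
#' target of 0.005 (effective population size 100), an 8-generation data
#' window and 360,000 sampled pairs for the mean empirical kinship.
#'
#' `scale` multiplies every count (cohort sizes, loci, QTL, sires, candidates,
#' sampled pairs, target effective population size, and both the sizes and the
#' durations of the historical phases, which preserves drift per phase in
#' diffusion time t/2N).  Rates and structural constants (mutation rate,
#' heritability, the 21-generation program, the 8-generation window) are not
#' scaled.  The kinship-rate bound is derived from the scaled target Ne as
#' `delta_f = 1/(2 Ne)`, so the constraint pressure on OCS is comparable
#' across scales; at `scale = 1` this is exactly 0.005.
#'
#' @param scale global size multiplier in (0, 1].
#' @param n_chromosomes number of chromosomes; default 29 at full scale and
#'   `max(5, round(29 * scale))` below it (total locus count is preserved by
#'   adjusting loci per chromosome).
#' @param n_generations number of cohorts simulated (generations 0 to
#'   `n_generations - 1`).
#' @param always_gblup if `TRUE`, use GBLUP instead of ssGBLUP from the second
#'   OCS round on (the first round always uses ssGBLUP because generation-5
#'   females have no phenotypes yet, so a genomic-records-only model is empty).
#'   Defaults to `TRUE` below full scale.
#' @param heritability base-population heritability of the female-recorded
#'   trait.
#' @return a validated nested list of class `kinocs_config` with sections
#'   `genome`, `trait`, `program`, `evaluation`, `ocs` and `metrics`.
#' @examples
#' cfg <- program_config(scale = 0.02)
#' cfg$program$ocs_sires
#' @export
program_config <- function(scale = 1, n_chromosomes = NULL,
                           n_generations = 21,
                           always_gblup = scale < 1,
                           heritability = 0.4) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0, scale <= 1)
  sc <- function(x) max(1L, as.integer(round(x * scale)))
  even <- function(x) max(2L, 2L * as.integer(round(x / 2)))

  total_loci <- sc(29 * 1800)
  if (is.null(n_chromosomes)) {
    n_chromosomes <- if (scale == 1) 29L else min(29L, max(5L, sc(29)))
  }
  loci_per_chromosome <- max(10L, as.integer(round(total_loci / n_chromosomes)))

  # historical trajectory: constant 2000 (2000 gen), linear 2000 -> 200
  # (100 gen), linear 200 -> 1000 (100 gen); sizes and durations both scaled
  ph1 <- rep(sc(2000), sc(2000))
  ph2 <- round(seq(sc(2000), sc(200), length.out = sc(100) + 1))[-1]
  ph3 <- round(seq(sc(200), sc(1000), length.out = sc(100) + 1))[-1]
  hist_sizes <- vapply(c(ph1, ph2, ph3), even, integer(1))

  target_ne <- sc(100)
  cfg <- list(
    scale = scale,
    genome = list(
      n_chromosomes = as.integer(n_chromosomes),
      loci_per_chromosome = loci_per_chromosome,
      chromosome_length = 1.0,          # Morgan
      mutation_rate = 2e-5,
      historical_sizes = as.integer(hist_sizes),
      base_males = even(6000 * scale),
      base_females = even(6000 * scale),
      n_qtl = sc(3000),
      n_neutral = sc(3000)
    ),
    trait = list(
      heritability = heritability,
      gamma_shape = 0.4,
      gamma_scale = 1.66
    ),
    program = list(
      n_generations = as.integer(n_generations),
      pblup_sires = max(2L, sc(120)),
      ocs_sires = max(2L, sc(40)),
      genotyped_males = sc(2000),
      candidate_males = sc(1000),
      genomic_start = 5L                # first OCS round selects generation-5 males
    ),
    evaluation = list(
      window_generations = 8L,
      ssgblup_rounds = 3L,
      always_gblup = isTRUE(always_gblup),
      blend = 0.95
    ),
    ocs = list(
      target_ne = target_ne,
      delta_f = 1 / (2 * target_ne)
    ),
    metrics = list(
      n_pairs = sc(360000),
      maf_threshold = 0.001,
      reference_generation = 5L,
      genic_factor2 = FALSE
    )
  )
  class(cfg) <- "kinocs_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  g <- cfg$genome; p <- cfg$program
  if (g$mutation_rate < 0) stop("genome.mutation_rate must be >= 0")
  if (length(g$historical_sizes) < 1) stop("historical trajectory is empty")
  if (any(g$historical_sizes <= 0)) stop("historical sizes must be positive")
  if (g$n_chromosomes < 1 || g$loci_per_chromosome < 1)
    stop("genome dimensions must be positive")
  if (g$n_qtl + g$n_neutral >= g$n_chromosomes * g$loci_per_chromosome)
    stop("QTL + neutral loci exceed the genome")
  if (p$ocs_sires < 2 || p$pblup_sires < 2) stop("need at least 2 sires")
  if (p$candidate_males > p$genotyped_males)
    stop("candidate_males cannot exceed genotyped_males")
  if (cfg$ocs$delta_f <= 0 || cfg$ocs$delta_f >= 1) stop("delta_f out of range")
  invisible(cfg)
}

#' Deterministic child seeds from a master seed and labels
#'
#' Derives reproducible, collision-resistant child seeds so that each concern
#' (founders, pedigree phase, each scenario's OCS phase, pair sampling) has
#' its own stream: identical labels give identical seeds, and the founder seed
#' of a replicate does not depend on the scenario.  Seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return a single integer seed.
#' @examples
#' seed_stream(1, "founders", 2)
#' @export
seed_stream <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(labels)) h <- (h * 69069 + ch * 2654435761) %% 2147483647
  as.integer((h %% 2147483646) + 1)
}
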