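test_that("heterozygosity decays at rate 1/(2N) under neutral drift", {
  # Monte-Carlo against the closed-form geometric decay of expected
  # heterozygosity; mutation off, constant N
  cfg <- program_config(scale = 0.02, n_chromosomes = 2)
  cfg$genome$mutation_rate <- 0
  N <- 20; t_gen <- 10
  cfg$genome$historical_sizes <- rep(N, t_gen)
  cfg$genome$base_males <- cfg$genome$base_females <- N / 2
  map <- genome_map(cfg)
  reps <- 60
  ratio <- vapply(seq_len(reps), function(r) {
    h <- simulate_historical(cfg, seed = 1000 + r, map = map)
    h0 <- 2 * h$p0 * (1 - h$p0)
    ht <- 2 * h$freq * (1 - h$freq)
    mean(ht) / mean(h0)
  }, 0)
  expected <- (1 - 1 / (2 * N))^t_gen
  se <- sd(ratio) / sqrt(reps)
  expect_lt(abs(mean(ratio) - expected), 3 * se + 0.01)
})

test_that("final allele-frequency spectrum is symmetric about 0.5", {
  cfg <- tiny_config()
  h <- simulate_historical(cfg, seed = 7)
  expect_equal(mean(h$freq), 0.5, tolerance = 0.02)
  expect_equal(nrow(h$hap),
               cfg$genome$n_chromosomes * cfg$genome$loci_per_chromosome)
  expect_equal(ncol(h$hap),
               2 * (cfg$genome$base_males + cfg$genome$base_females))
})

test_that("full-scale configuration simulates 29 x 1800 = 52,200 loci", {
  cfg <- program_config(scale = 1)
  expect_equal(cfg$genome$n_chromosomes * cfg$genome$loci_per_chromosome,
               52200)
  expect_equal(cfg$genome$base_males, 6000)
  expect_equal(cfg$genome$base_females, 6000)
  expect_equal(cfg$ocs$delta_f, 0.005)
})

test_that("locus partition respects counts, disjointness and the MAF filter", {
  cfg <- tiny_config()
  map <- genome_map(cfg)
  L <- nrow(map)
  set.seed(2)
  freq <- runif(L)
  freq[1:10] <- 0          # non-segregating
  freq[11] <- 0.30         # safely above both thresholds
  out <- partition_loci(freq, map, cfg, seed = 3)
  expect_equal(sum(out$class == "QTL"), cfg$genome$n_qtl)
  expect_equal(sum(out$class == "NEUTRAL"), cfg$genome$n_neutral)
  expect_true(all(out$class[1:10] == "DISCARDED"))
  expect_true(out$class[11] %in% c("MARKER", "QTL", "NEUTRAL"))
  # classes exhaustive and disjoint by construction of a single factor
  expect_false(anyNA(out$class))
  # a common locus is never dropped by the ascertainment filter
  freq2 <- rep(0.3, L)
  out2 <- partition_loci(freq2, map, cfg, seed = 4)
  expect_equal(sum(out2$class == "DISCARDED"), 0)
  # rare loci are retained with probability ~ 0.5
  freq3 <- rep(0.005, L)
  out3 <- partition_loci(freq3, map, cfg, seed = 5)
  n_rest <- L - cfg$genome$n_qtl - cfg$genome$n_neutral
  kept <- sum(out3$class == "MARKER")
  expect_lt(abs(kept - 0.5 * n_rest), 3 * sqrt(n_rest * 0.25) + 1)
  # error when there are too few segregating loci
  expect_error(partition_loci(rep(0, L), map, cfg, seed = 1), "segregating")
})

test_that("ascertained markers have a flatter MAF spectrum than the raw pool", {
  f <- tiny_founders(seed = 5)
  maf <- pmin(f$freq, 1 - f$freq)
  seg <- f$freq > 0 & f$freq < 1
  pool <- maf[seg & f$map$class %in% c("MARKER", "DISCARDED")]
  kept <- maf[f$map$class == "MARKER"]
  expect_gt(mean(kept), mean(pool) - 1e-12)
})

test_that("QTL effect magnitudes follow gamma(0.4, 1.66) with random signs", {
  cfg <- tiny_config()
  f <- tiny_founders(seed = 9)
  expect_length(f$arch$alpha, cfg$genome$n_qtl)
  set.seed(11)
  draws <- abs(rgamma(2e5, shape = 0.4, scale = 1.66))
  # large-sample law: mean = shape*scale, var = shape*scale^2
  expect_equal(mean(draws), 0.4 * 1.66, tolerance = 0.02)
  expect_equal(var(draws), 0.4 * 1.66^2, tolerance = 0.05)
  # package draws come from the same law
  big_cfg <- tiny_config()
  big_cfg$genome$n_qtl <- 500L
  map <- genome_map(big_cfg)
  set.seed(3)
  freq <- runif(nrow(map), 0.05, 0.95)
  map2 <- partition_loci(freq, map, big_cfg, seed = 8)
  hap <- matrix(rbinom(nrow(map) * 20, 1, 0.5), nrow(map))
  arch <- assign_qtl_effects(map2, hap, big_cfg, seed = 10)
  expect_equal(mean(abs(arch$alpha)), 0.664, tolerance = 0.25)
  expect_lt(abs(mean(sign(arch$alpha))), 0.1)
  # residual variance follows the base heritability of 0.4
  expect_equal(arch$sigma2_e / arch$sigma2_a0, 1.5, tolerance = 1e-12)
})

test_that("PLINK ped/map round-trip preserves the unphased genotypes", {
  f <- tiny_founders(seed = 6)
  keep <- 1:20
  hap <- f$hap[, 1:(2 * length(keep))]
  path <- file.path(tempdir(), "kinocs_plink_test")
  write_plink(hap, f$map, path, sex = f$sex[keep])
  back <- read_plink(path)
  want <- hap[, seq(1, ncol(hap), 2)] + hap[, seq(2, ncol(hap), 2)]
  expect_equal(unname(back$geno), unname(want))
  expect_equal(ncol(back$geno), length(keep))
  expect_equal(nrow(back$map), nrow(f$map))
  expect_equal(back$sex, f$sex[keep])
  # a heterozygote is written as two different allele codes
  line1 <- strsplit(readLines(paste0(path, ".ped"), n = 1), " ")[[1]][-(1:6)]
  het <- which(want[, 1] == 1)[1]
  expect_setequal(line1[c(2 * het - 1, 2 * het)], c("1", "2"))
  unlink(paste0(path, c(".ped", ".map")))
})
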