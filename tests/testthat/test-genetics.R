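test_that("meiosis copies a parental haplotype verbatim when no crossover occurs", {
  f <- tiny_founders(seed = 3, n_chromosomes = 1)
  coh <- founder_cohort(f)
  # shrink the genome so Poisson(length) is essentially always zero
  tiny_map <- f$map
  attr(tiny_map, "chr_lo") <- attr(f$map, "chr_lo") * 1e-6
  attr(tiny_map, "chr_hi") <- attr(f$map, "chr_hi") * 1e-6
  tiny_map$gpos <- f$map$gpos * 1e-6
  set.seed(1)
  g <- meiose(coh$hap[, 1:2], coh$segs[1:2], tiny_map)
  expect_true(identical(g$alleles, coh$hap[, 1]) ||
                identical(g$alleles, coh$hap[, 2]))
  expect_equal(nrow(g$seg), 1)
})

test_that("a fully homozygous parent transmits its alleles regardless of crossovers", {
  f <- tiny_founders(seed = 3)
  hap <- cbind(f$hap[, 1], f$hap[, 1])
  segs <- list(matrix(c(attr(f$map, "glen"), 1), 1, 2),
               matrix(c(attr(f$map, "glen"), 2), 1, 2))
  set.seed(2)
  for (i in 1:5) {
    g <- meiose(hap, segs, f$map)
    expect_equal(g$alleles, f$hap[, 1])
  }
})

test_that("crossover count per Morgan is Poisson with mean 1", {
  f <- tiny_founders(seed = 3, n_chromosomes = 2)
  coh <- founder_cohort(f)
  set.seed(4)
  n_m <- 4000
  chr_hi <- attr(f$map, "chr_hi")
  # founder labels alternate at every crossover, so every interior segment
  # boundary is a crossover (chromosome-end boundaries are not)
  ncx <- vapply(seq_len(n_m), function(i) {
    g <- meiose(coh$hap[, 1:2], coh$segs[1:2], f$map)
    ends <- g$seg[, 1]
    sum(vapply(ends, function(e) all(abs(e - chr_hi) > 1e-12), TRUE))
  }, 0)
  n_chr <- f$cfg$genome$n_chromosomes
  # total expectation: 1 crossover per Morgan per chromosome
  se <- sd(ncx) / sqrt(n_m)
  expect_lt(abs(mean(ncx) - n_chr * 1.0), 3 * se)
})

test_that("true breeding value is the QTL dosage-effect dot product", {
  f <- tiny_founders(seed = 8)
  L <- nrow(f$map)
  hap0 <- matrix(0L, L, 2)
  expect_equal(tbv_from_hap(hap0, f$arch$qtl_idx, f$arch$alpha), 0)
  hap1 <- hap0
  hap1[f$arch$qtl_idx[3], 1] <- 1L   # heterozygous at one QTL
  expect_equal(tbv_from_hap(hap1, f$arch$qtl_idx, f$arch$alpha),
               f$arch$alpha[3])
  # brute-force dot product on a random individual
  i <- 5
  dos <- f$hap[f$arch$qtl_idx, 2 * i - 1] + f$hap[f$arch$qtl_idx, 2 * i]
  expect_equal(tbv_from_hap(f$hap, f$arch$qtl_idx, f$arch$alpha)[i],
               sum(dos * f$arch$alpha))
})

test_that("phenotypes follow y = mu + TBV + e on females only", {
  f <- tiny_founders(seed = 10)
  coh <- founder_cohort(f)
  arch0 <- f$arch
  arch0$sigma2_e <- 0
  set.seed(1)
  c0 <- assign_phenotypes(coh, arch0)
  fem <- c0$sex == 2
  expect_equal(c0$phen[fem], c0$tbv[fem])
  expect_true(all(is.na(c0$phen[!fem])))
  # with the base residual variance, var(y) ~ 2.5 sigma2_A0 (h2 = 0.4)
  set.seed(2)
  c1 <- assign_phenotypes(coh, f$arch)
  ratio <- var(c1$phen[fem]) / f$arch$sigma2_a0
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 3.6)
})

test_that("the mating design gives exact offspring counts and balanced sexes", {
  f <- tiny_founders(seed = 12)
  coh <- founder_cohort(f)
  sires <- coh$id[which(coh$sex == 1)[1:6]]
  n_d <- sum(coh$sex == 2)
  set.seed(3)
  off <- mate_cohort(coh, sires, f, 1L, id_start = 1000L)
  expect_equal(length(off$id), 2 * n_d)
  expect_true(all(table(off$sire) == 2 * n_d / 6))
  expect_true(all(table(off$dam) == 2))
  expect_true(all(tapply(off$sire, off$dam,
                         function(x) length(unique(x))) == 2))
  expect_equal(sum(off$sex == 1), sum(off$sex == 2))
  expect_error(mate_cohort(coh, sires[1], f, 1L, 1L), "two sires")
})

test_that("no breeding-phase mutation: offspring alleles exist in a parent", {
  f <- tiny_founders(seed = 13)
  coh <- founder_cohort(f)
  # make locus 1 monomorphic 0 in two chosen parents
  s <- which(coh$sex == 1)[1]; d <- which(coh$sex == 2)[1]
  coh$hap[1, c(2 * s - 1, 2 * s, 2 * d - 1, 2 * d)] <- 0L
  geo_off <- mate_cohort(coh, coh$id[which(coh$sex == 1)[1:2]], f, 1L, 500L)
  kids <- which(geo_off$sire == coh$id[s] & geo_off$dam == coh$id[d])
  if (length(kids)) {
    expect_true(all(geo_off$hap[1, c(2 * kids - 1, 2 * kids)] == 0L))
  }
  # generic conservation: every offspring allele at every locus is carried
  # by the matching parent haplotype pool
  set.seed(9)
  off <- mate_cohort(coh, coh$id[which(coh$sex == 1)[1:3]], f, 1L, 700L)
  i <- 1
  sp <- match(off$sire[i], coh$id); dp <- match(off$dam[i], coh$id)
  par_has <- (coh$hap[, 2 * sp - 1] | coh$hap[, 2 * sp] |
                coh$hap[, 2 * dp - 1] | coh$hap[, 2 * dp])
  kid_has <- off$hap[, 2 * i - 1] | off$hap[, 2 * i]
  expect_true(all(!kid_has | par_has))
})

test_that("segment lists reconstruct offspring allele arrays exactly", {
  f <- tiny_founders(seed = 14)
  coh <- founder_cohort(f)
  set.seed(5)
  off <- mate_cohort(coh, coh$id[which(coh$sex == 1)[1:4]], f, 1L, 900L)
  pos <- f$map$gpos
  for (h in c(1, 7, 20)) {
    seg <- off$segs[[h]]
    rec <- integer(length(pos)); prev <- 0
    for (s in seq_len(nrow(seg))) {
      sel <- pos > prev & pos <= seg[s, 1]
      rec[sel] <- f$hap[sel, seg[s, 2]]
      prev <- seg[s, 1]
    }
    expect_identical(rec, off$hap[, h])
  }
})

test_that("full sibs from unrelated parents average kinship 1/4", {
  f <- tiny_founders(seed = 15)
  coh <- founder_cohort(f)
  set.seed(6)
  # build sib pairs directly from repeated meioses of unrelated parent pairs
  n_fam <- 120
  segs <- vector("list", 4 * n_fam)
  for (fam in seq_len(n_fam)) {
    s <- 2 * fam - 1; d <- 2 * fam   # founder s x founder d
    for (kid in 1:2) {
      g1 <- meiose(coh$hap[, (2 * s - 1):(2 * s)],
                   coh$segs[(2 * s - 1):(2 * s)], f$map)
      g2 <- meiose(coh$hap[, (2 * d - 1):(2 * d)],
                   coh$segs[(2 * d - 1):(2 * d)], f$map)
      segs[[4 * (fam - 1) + 2 * kid - 1]] <- g1$seg
      segs[[4 * (fam - 1) + 2 * kid]] <- g2$seg
    }
  }
  sibs <- list(segs = segs)
  k <- vapply(seq_len(n_fam), function(fam) {
    kinship_pair(sibs, 2 * fam - 1, 2 * fam)
  }, 0)
  se <- sd(k) / sqrt(n_fam)
  expect_lt(abs(mean(k) - 0.25), 3 * se + 0.005)
  # self-kinship of a non-inbred individual is exactly 1/2
  expect_equal(kinship_pair(sibs, 1, 1), 0.5)
  # kinship between two distinct founders is exactly 0
  expect_equal(kinship_pair(coh, 1, 2), 0)
})
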