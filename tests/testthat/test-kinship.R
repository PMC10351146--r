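test_that("reference allele frequencies are pooled dosage counts", {
  M <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(compute_raf(M), 0.5)
  expect_equal(compute_raf(fixed_half = TRUE, m = 4), rep(0.5, 4))
  # pooled over a history equals a per-animal tally
  set.seed(1)
  h1 <- matrix(rbinom(20, 2, 0.3), 5)
  h2 <- matrix(rbinom(12, 2, 0.7), 3)
  expect_equal(compute_raf(list(h1, h2)),
               colSums(rbind(h1, h2)) / (2 * 8))
  expect_error(compute_raf(h1[0, , drop = FALSE]), "empty")
})

test_that("VR1 matches its printed formula and the brute-force sums", {
  # single locus, p = 0.5, genotypes (0,1,2): Z = (-1,0,1), denominator 0.5
  G <- build_vr1(matrix(c(0, 1, 2), 3, 1), 0.5)
  expect_equal(bare(G),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3))
  # centring identity: p computed from the same animals => sum(G) = 0
  set.seed(2)
  M <- matrix(rbinom(10 * 20, 2, runif(20, 0.2, 0.8)), 10, byrow = TRUE)
  p <- compute_raf(M)
  expect_equal(sum(build_vr1(M, p)), 0, tolerance = 1e-10)
  # element-wise brute force
  p2 <- runif(20, 0.1, 0.9)
  G2 <- build_vr1(M, p2)
  den <- 2 * sum(p2 * (1 - p2))
  for (idx in list(c(1, 1), c(3, 7), c(10, 2))) {
    zi <- M[idx[1], ] - 2 * p2; zk <- M[idx[2], ] - 2 * p2
    expect_equal(G2[idx[1], idx[2]], sum(zi * zk) / den, tolerance = 1e-12)
  }
  expect_error(build_vr1(matrix(2, 3, 2), c(1, 1)), "monomorphic")
})

test_that("VR2 weights loci by reciprocal heterozygosity", {
  M1 <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(bare(build_vr2(M1, 0.5)),
               bare(build_vr1(M1, 0.5)))   # m = 1 equivalence
  set.seed(3)
  M <- matrix(rbinom(8 * 12, 2, 0.5), 8, byrow = TRUE)
  # uniform frequencies 0.5: VR2 = VR1 for any M
  p05 <- rep(0.5, 12)
  expect_equal(bare(build_vr2(M, p05)),
               bare(build_vr1(M, p05)), tolerance = 1e-12)
  # weight ratio between a MAF-0.1 and a MAF-0.5 locus is (0.5/0.09)
  M2 <- cbind(rbinom(10, 2, 0.2), rbinom(10, 2, 0.5))
  p <- c(0.1, 0.5)
  Zc <- sweep(M2, 2, 2 * p)
  d <- 1 / (2 * (2 * p * (1 - p)))
  expect_equal(d[1] / d[2], (2 * 0.5 * 0.5) / (2 * 0.1 * 0.9))
  expect_equal(bare(build_vr2(M2, p)),
               Zc %*% diag(d) %*% t(Zc), tolerance = 1e-12)
  # brute-force on a random 10 x 20 matrix
  M3 <- matrix(rbinom(10 * 20, 2, runif(20, 0.2, 0.8)), 10, byrow = TRUE)
  p3 <- runif(20, 0.1, 0.9)
  d3 <- 1 / (20 * 2 * p3 * (1 - p3))
  Z3 <- sweep(M3, 2, 2 * p3)
  expect_equal(bare(build_vr2(M3, p3)),
               Z3 %*% diag(d3) %*% t(Z3), tolerance = 1e-12)
})

test_that("NRM tabular method matches textbook values and path counting", {
  # unrelated founders
  expect_equal(bare(build_nrm(c(0, 0, 0), c(0, 0, 0))), diag(3))
  # parent-offspring and full sibs 0.5; full-sib mating diagonal 1.25
  s <- c(0, 0, 1, 1, 3); d <- c(0, 0, 2, 2, 4)
  A <- build_nrm(s, d)
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[3, 4], 0.5)
  expect_equal(A[5, 5], 1.25)
  for (ped in textbook_pedigrees()) {
    expect_equal(bare(build_nrm(ped$sire, ped$dam)),
                 path_kinship(ped$sire, ped$dam), tolerance = 1e-12)
  }
  expect_error(build_nrm(c(2, 0), c(0, 0)), "sorted")
})

test_that("A-inverse, pedigree F/D and Colleau blocks agree with dense algebra", {
  for (ped in textbook_pedigrees()) {
    A <- build_nrm(ped$sire, ped$dam)
    n <- length(ped$sire)
    Ainv <- build_ainverse(ped$sire, ped$dam)
    expect_equal(max(abs(as.matrix(Ainv %*% A) - diag(n))), 0,
                 tolerance = 1e-10)
    fd <- pedigree_fd(ped$sire, ped$dam)
    expect_equal(fd$F, diag(A) - 1, tolerance = 1e-12)
    idx <- c(2, n - 1, n)
    expect_equal(nrm_block(ped$sire, ped$dam, idx),
                 unname(A[idx, idx]), tolerance = 1e-12)
  }
})

test_that("H-inverse reduces to A-inverse in the degenerate cases", {
  ped <- list(sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
  A <- build_nrm(ped$sire, ped$dam)
  expect_equal(build_h_inverse(A, NULL, integer(0)), solve(A))
  # all animals genotyped with G = A22 = A: blending leaves A, so H = A
  expect_equal(build_h_inverse(A, A, 1:5), solve(A), tolerance = 1e-10)
  # toy: 3 of 5 genotyped, compare against the direct block formula
  set.seed(4)
  gidx <- c(2, 4, 5)
  G <- A[gidx, gidx] + tcrossprod(matrix(rnorm(9), 3)) / 10
  G <- (G + t(G)) / 2
  H <- build_h_inverse(A, G, gidx, blend = 0.9)
  A22 <- A[gidx, gidx]
  Gw <- 0.9 * G + 0.1 * A22
  want <- solve(A)
  want[gidx, gidx] <- want[gidx, gidx] + solve(Gw) - solve(A22)
  expect_equal(H, want, tolerance = 1e-10)
})

test_that("builders return symmetric matrices and NRM is PSD", {
  set.seed(5)
  M <- matrix(rbinom(12 * 30, 2, 0.4), 12, byrow = TRUE)
  p <- runif(30, 0.1, 0.9)
  for (G in list(build_vr1(M, p), build_vr2(M, p))) {
    expect_lt(max(abs(G - t(G))), 1e-12 * max(abs(G)))
  }
  for (ped in textbook_pedigrees()) {
    A <- build_nrm(ped$sire, ped$dam)
    expect_lt(max(abs(A - t(A))), 1e-14)
    expect_gt(min(eigen(A, symmetric = TRUE)$values), -1e-10)
  }
  # VR1 with fixed 0.5 frequencies equals ZZ' / (m/2)
  phalf <- rep(0.5, 30)
  Z <- M - 1
  expect_equal(bare(build_vr1(M, phalf)),
               tcrossprod(Z) / (30 / 2), tolerance = 1e-12)
  # kinship scale is relationship / 2 at the single conversion point
  expect_equal(as.matrix(to_kinship(build_vr1(M, p))),
               as.matrix(build_vr1(M, p)) / 2, ignore_attr = TRUE)
})
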