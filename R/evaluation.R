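#' Solve the animal-model mixed-model equations
#'
#' Fits y = 1 mu + Z a + e with a ~ N(0, K sigma2_A) and
#' e ~ N(0, I sigma2_e), where K is a relationship-scale matrix (numerator,
#' genomic or combined).  Solves
#' \[1'1 1'Z; Z'1 Z'Z + K^-1 lambda\] (mu; a) = (1'y; Z'y) with
#' lambda = sigma2_e / sigma2_A.  Animals without records obtain predictions
#' through K.  Supply either a dense `K` or a (possibly sparse) precomputed
#' `Kinv`.
#'
#' @param y phenotype vector (one record per recorded animal).
#' @param record_animal animal position (1..n) of each record.
#' @param lambda variance ratio sigma2_e / sigma2_A (> 0).
#' @param K dense relationship matrix over all evaluated animals.
#' @param Kinv inverse relationship matrix (dense or `Matrix` sparse).
#' @return list with `mu` and `a` (predicted breeding values, length n).
#' @export
solve_blup <- function(y, record_animal, lambda, K = NULL, Kinv = NULL) {
  if (length(y) == 0) stop("no records")
  stopifnot(lambda > 0, length(y) == length(record_animal))
  if (is.null(Kinv)) {
    if (is.null(K)) stop("supply K or Kinv")
    Kinv <- solve(K)
  }
  n <- nrow(Kinv)
  sparse <- inherits(Kinv, "Matrix")
  zt1 <- tabulate(record_animal, n)            # Z'1 and diag(Z'Z)
  zty <- numeric(n)
  tmp <- rowsum(y, record_animal)
  zty[as.integer(rownames(tmp))] <- tmp[, 1]
  if (sparse) {
    C <- Kinv * lambda + Matrix::Diagonal(n, x = zt1)
    C <- rbind(cbind(length(y), Matrix::Matrix(zt1, 1, n)),
               cbind(Matrix::Matrix(zt1, n, 1), C))
    sol <- as.numeric(Matrix::solve(C, c(sum(y), zty)))
  } else {
    C <- Kinv * lambda
    diag(C) <- diag(C) + zt1
    C <- rbind(c(length(y), zt1), cbind(zt1, C))
    sol <- solve(C, c(sum(y), zty))
  }
  sol <- unname(as.numeric(sol))
  list(mu = sol[1], a = sol[-1])
}

#' Ridge-regression (SNP-BLUP) solve of the marker-effect model
#'
#' Fits y = 1 mu + W u + e with u ~ N(0, I sigma2_u).  With
#' sigma2_u = sigma2_A / (2 sum_j p_j (1 - p_j)) and W the centered dosages,
#' predictions (M - 2p) u-hat are identical to GBLUP with the VanRaden-1 GRM,
#' but the system is m x m and remains well posed when there are more
#' genotyped animals than markers (where the unblended GRM is singular).
#'
#' @param W records x markers (centered) dosage matrix.
#' @param y phenotype vector.
#' @param lambda_u sigma2_e / sigma2_u.
#' @return list with `mu` and marker effects `u`.
#' @export
snp_blup <- function(W, y, lambda_u) {
  stopifnot(nrow(W) == length(y), lambda_u > 0)
  snp_blup_solve(crossprod(W), colSums(W), crossprod(W, y), length(y), sum(y),
                 lambda_u)
}

# core solver on precomputed cross-products (the pipeline maintains these
# incrementally over the sliding data window)
snp_blup_solve <- function(WtW, Wt1, Wty, n, sumy, lambda_u) {
  m <- ncol(WtW)
  C <- matrix(0, m + 1, m + 1)
  C[1, 1] <- n
  C[1, -1] <- Wt1
  C[-1, 1] <- Wt1
  C[-1, -1] <- WtW
  idx <- cbind(2:(m + 1), 2:(m + 1))
  C[idx] <- C[idx] + lambda_u
  ch <- chol(C)
  sol <- backsolve(ch, forwardsolve(t(ch), c(sumy, Wty)))
  list(mu = sol[1], u = sol[-1])
}

#' Parent average and top-n pre-selection
#'
#' PA = (GEBV_sire + GEBV_dam) / 2.  `select_top` returns the positions of
#' the `n_top` largest values with ties broken by a seeded random order, as
#' used to pick the males that are genotyped.
#'
#' @param gebv_sire,gebv_dam parental (G)EBVs, aligned with the individuals.
#' @return `parent_average`: the PA vector.
#' @export
parent_average <- function(gebv_sire, gebv_dam) {
  if (anyNA(gebv_sire) || anyNA(gebv_dam)) stop("missing parental (G)EBV")
  (gebv_sire + gebv_dam) / 2
}

#' @rdname parent_average
#' @param x values to rank.
#' @param n_top how many to keep.
#' @param seed seed for the random tie-break.
#' @return `select_top`: positions of the selected entries.
#' @export
select_top <- function(x, n_top, seed) {
  set.seed(seed)
  ord <- order(-x, sample.int(length(x)))
  ord[seq_len(min(n_top, length(x)))]
}
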