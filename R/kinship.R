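#' Reference allele frequencies from genotype dosages
#'
#' Computes the allele frequency of the counted allele per marker,
#' `p_j = (dosage sum) / (2 n)`, over one or several genotype matrices (the
#' resolver for a RAF policy supplies the right animals: the generation-one
#' cohort for Base, the selected genotyped bulls of generations 0-3 for Old,
#' all genotyped animals to date for All, the current generation's genotyped
#' animals for Current).  `fixed_half = TRUE` ignores the genotypes and
#' returns 0.5 everywhere.
#'
#' @param geno animals x markers dosage matrix, or a list of such matrices
#'   pooled together.
#' @param fixed_half return the constant-0.5 policy.
#' @param m number of markers (only needed with `fixed_half` and no `geno`).
#' @return per-marker frequency vector.
#' @export
compute_raf <- function(geno = NULL, fixed_half = FALSE, m = NULL) {
  if (fixed_half) {
    if (is.null(m)) m <- ncol(if (is.list(geno)) geno[[1]] else geno)
    return(rep(0.5, m))
  }
  if (is.list(geno)) {
    n <- sum(vapply(geno, nrow, 0L))
    if (n == 0) stop("empty reference cohort")
    cs <- Reduce(`+`, lapply(geno, colSums))
    return(cs / (2 * n))
  }
  if (is.null(geno) || nrow(geno) == 0) stop("empty reference cohort")
  colSums(geno) / (2 * nrow(geno))
}

#' VanRaden genomic relationship matrices
#'
#' `build_vr1` scales the cross-product of centered dosages by the sum of
#' locus heterozygosities: G = Z Z' / (2 sum_j p_j (1 - p_j)) with
#' Z = M - 2p.  `build_vr2` instead weights each locus by the reciprocal of
#' its expected heterozygosity: G = Z D Z' with
#' d_jj = 1 / (m 2 p_j (1 - p_j)), giving low-MAF loci greater weight.  No
#' MAF filtering is applied.  For VR2, frequencies are clamped to
#' [1/(2n+1), 1 - 1/(2n+1)] inside the weights only, so monomorphic reference
#' loci (whose centered column is constant) cannot produce infinite weights;
#' VR1 includes them unclamped (they contribute zero to Z and to the
#' denominator).
#'
#' @param M animals x markers dosage matrix (0/1/2).
#' @param p reference allele frequencies (length = markers).
#' @return relationship-scale matrix (diagonal around 1) with attributes
#'   `method` and `scale = "relationship"`.
#' @export
build_vr1 <- function(M, p) {
  stopifnot(ncol(M) == length(p))
  den <- 2 * sum(p * (1 - p))
  if (den <= 0) stop("all loci monomorphic under this RAF: zero denominator")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / den
  structure(G, method = "VR1", scale = "relationship")
}

#' @rdname build_vr1
#' @export
build_vr2 <- function(M, p) {
  stopifnot(ncol(M) == length(p))
  m <- ncol(M); n <- nrow(M)
  eps <- 1 / (2 * n + 1)
  pc <- pmin(pmax(p, eps), 1 - eps)
  d <- 1 / (m * 2 * pc * (1 - pc))
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z %*% diag(sqrt(d), m))
  structure(G, method = "VR2", scale = "relationship")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' A_ii = 1 + A_sd / 2 and A_ij = (A_js + A_jd) / 2, with unknown parents
#' contributing zero.  The pedigree must be sorted so parents precede
#' offspring; parent codes are positions in the pedigree (0 = unknown).
#'
#' @param sire,dam integer vectors of parent positions (0 = unknown).
#' @return relationship-scale matrix with attribute `method = "NRM"`.
#' @export
build_nrm <- function(sire, dam) {
  structure(cpp_nrm(as.integer(sire), as.integer(dam)),
            method = "NRM", scale = "relationship")
}

#' Inbreeding coefficients and Mendelian-sampling variances of a pedigree
#'
#' @param sire,dam parent position vectors (0 = unknown, parents precede
#'   offspring).
#' @param F_init optional previously computed inbreeding coefficients for a
#'   pedigree prefix (incremental extension).
#' @return list with `F` and `D` (d_i = 0.5 - 0.25 (F_s + F_d), with -1 for
#'   an unknown parent's F).
#' @export
pedigree_fd <- function(sire, dam, F_init = numeric(0)) {
  cpp_ped_fd(as.integer(sire), as.integer(dam), as.numeric(F_init))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted through the
#' Mendelian-sampling variances from [pedigree_fd()].
#'
#' @inheritParams pedigree_fd
#' @return a `Matrix::sparseMatrix` A-inverse.
#' @export
build_ainverse <- function(sire, dam) {
  fd <- pedigree_fd(sire, dam)
  tr <- cpp_ainv_triplets(as.integer(sire), as.integer(dam), fd$D)
  n <- length(sire)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
}

#' Relationship block of selected animals via Colleau's indirect method
#'
#' Computes A restricted to `idx` without forming the full matrix,
#' in O(pedigree size) per selected animal.
#'
#' @inheritParams pedigree_fd
#' @param idx animal positions whose relationship block is wanted.
#' @param fd optional precomputed [pedigree_fd()] result.
#' @return the |idx| x |idx| relationship block.
#' @export
nrm_block <- function(sire, dam, idx, fd = pedigree_fd(sire, dam)) {
  cpp_a_block(as.integer(sire), as.integer(dam), fd$D, as.integer(idx))
}

#' Inverse of the combined pedigree-genomic relationship matrix (ssGBLUP)
#'
#' H-inverse = A-inverse + [0 0; 0 Gw^-1 - A22^-1] on the genotyped block,
#' where Gw = blend * G + (1 - blend) * A22 is the blended, invertible GRM.
#' Dense reference implementation for moderate problem sizes; the pipeline
#' assembles the same quantity sparsely.
#'
#' @param A full numerator relationship matrix.
#' @param G genomic relationship matrix over the genotyped subset.
#' @param geno_idx positions of the genotyped animals within `A`.
#' @param blend weight on G in the blended matrix (default 0.95).
#' @return dense H-inverse.
#' @export
build_h_inverse <- function(A, G, geno_idx, blend = 0.95) {
  Hinv <- solve(A)
  if (length(geno_idx) == 0) return(Hinv)
  A22 <- A[geno_idx, geno_idx, drop = FALSE]
  Gw <- blend * G + (1 - blend) * A22
  Hinv[geno_idx, geno_idx] <- Hinv[geno_idx, geno_idx] + solve(Gw) - solve(A22)
  Hinv
}

#' Convert a relationship-scale matrix to the kinship scale
#'
#' The single conversion point: kinship = relationship / 2, so founder
#' self-kinship is 1/2 and the OCS kinship bound lives on the same scale as
#' the empirical IBD kinship.
#'
#' @param R relationship-scale matrix.
#' @return kinship-scale matrix.
#' @export
to_kinship <- function(R) {
  out <- R / 2
  attr(out, "scale") <- "kinship"
  attr(out, "method") <- attr(R, "method")
  out
}
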