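#' Aggregate all females into a pseudofemale kinship entry
#'
#' Because there is no selection on the female side, the female half of the
#' contribution vector can be collapsed into a single pseudofemale: its
#' self-kinship is the mean over all female-by-female entries including
#' self-kinships, and its kinship with each bull is the mean kinship of that
#' bull to all females.
#'
#' @param R kinship-scale matrix over bulls and females.
#' @param female_idx positions of the females within `R`.
#' @return kinship matrix over the bulls plus the pseudofemale (last
#'   row/column).
#' @export
build_pseudofemale <- function(R, female_idx) {
  if (length(female_idx) == 0) stop("no females")
  males <- setdiff(seq_len(nrow(R)), female_idx)
  nb <- length(males)
  out <- matrix(0, nb + 1, nb + 1)
  out[seq_len(nb), seq_len(nb)] <- R[males, males]
  bf <- rowMeans(R[males, female_idx, drop = FALSE])
  out[nb + 1, seq_len(nb)] <- bf
  out[seq_len(nb), nb + 1] <- bf
  out[nb + 1, nb + 1] <- mean(R[female_idx, female_idx])
  out
}

#' Per-generation kinship bound for OCS
#'
#' C = f_t + delta_f (1 - f_t): the mean kinship the next generation may
#' reach when kinship increases at rate `delta_f` from the current population
#' mean `f_t` (computed over the whole cohort - genotyped or not - under the
#' scenario's matrix).
#'
#' @param fbar current population mean kinship, in `[0, 1)`.
#' @param delta_f target rate of kinship increase (default 0.005, i.e. an
#'   effective population size of 100).
#' @return the bound C.
#' @export
kinship_target <- function(fbar, delta_f = 0.005) {
  if (any(fbar >= 1)) stop("mean kinship must be < 1")
  fbar + delta_f * (1 - fbar)
}

#' Define a cardinality-fixed OCS problem
#'
#' Contributions are structural: each selected bull contributes 1/(2k) and
#' the pseudofemale 1/2, so male and female contributions each sum to 1/2 and
#' the optimized parameter is only which k bulls are selected.  The objective
#' is the contribution-weighted GEBV c'a of the candidates, the constraint is
#' the group kinship c'Rc <= C.
#'
#' @param a candidate GEBV vector (length n).
#' @param R (n+1) x (n+1) kinship-scale matrix over the candidates plus the
#'   pseudofemale (last).
#' @param k number of sires to select.
#' @param C kinship bound from [kinship_target()].
#' @return an `ocs_problem` list.
#' @export
ocs_problem <- function(a, R, k, C) {
  n <- length(a)
  stopifnot(nrow(R) == n + 1, ncol(R) == n + 1, k >= 1)
  if (k > n) stop("k exceeds the number of candidates")
  structure(list(a = as.numeric(a), R = unname(as.matrix(R)),
                 k = as.integer(k), C = as.numeric(C)),
            class = "ocs_problem")
}

ocs_quad <- function(prob, S) {
  k <- prob$k; n <- length(prob$a); R <- prob$R
  cb <- 1 / (2 * k)
  sum(R[S, S]) * cb^2 + sum(R[S, n + 1]) * cb + 0.25 * R[n + 1, n + 1]
}

ocs_obj <- function(prob, S) sum(prob$a[S]) / (2 * prob$k)

#' Exhaustive-enumeration OCS (testing oracle)
#'
#' Enumerates every k-subset (pure R, independent of the optimizer) and
#' returns the exact optimum; guarded against combinatorial blow-up.
#'
#' @param prob an [ocs_problem()].
#' @param max_subsets enumeration guard.
#' @return list with `selected` (candidate positions), `objective`,
#'   `quad` (achieved c'Rc) and `feasible`.
#' @export
brute_force_ocs <- function(prob, max_subsets = 1e6) {
  n <- length(prob$a)
  if (choose(n, prob$k) > max_subsets) stop("too many subsets to enumerate")
  subsets <- utils::combn(n, prob$k)
  objs <- apply(subsets, 2, function(S) ocs_obj(prob, S))
  quads <- apply(subsets, 2, function(S) ocs_quad(prob, S))
  feas <- quads <= prob$C
  if (any(feas)) {
    best <- which(feas)[which.max(objs[feas])]
    list(selected = subsets[, best], objective = objs[best],
         quad = quads[best], feasible = TRUE)
  } else {
    best <- which.min(quads)
    list(selected = subsets[, best], objective = objs[best],
         quad = quads[best], feasible = FALSE)
  }
}

#' Optimize genetic contributions with a fixed number of sires
#'
#' Maximizes c'a subject to c'Rc <= C over k-subsets with equal bull
#' contributions 1/(2k) and pseudofemale contribution 1/2.  Uses exact
#' enumeration (compiled) when `choose(n, k) <= enum_limit`, otherwise a
#' seeded multi-start local search with simulated-annealing restarts.  If no
#' subset satisfies the bound, the minimum-c'Rc subset is returned with
#' `feasible = FALSE` so a simulation never halts.
#'
#' @param prob an [ocs_problem()].
#' @param method `"auto"`, `"exact"` or `"anneal"`.
#' @param seed seed for the stochastic search (and deterministic output).
#' @param restarts number of local-search starts for the heuristic.
#' @param enum_limit subset-count threshold for the exact path.
#' @return list with `selected`, `objective`, `quad`, `feasible`.
#' @export
optimize_contributions <- function(prob, method = c("auto", "exact", "anneal"),
                                   seed = 1, restarts = 8, enum_limit = 1e6) {
  method <- match.arg(method)
  n <- length(prob$a); k <- prob$k
  if (method == "exact" ||
      (method == "auto" && choose(n, k) <= enum_limit)) {
    res <- cpp_enum_ocs(prob$a, prob$R, k, prob$C)
    if (res$feasible) {
      return(list(selected = sort(res$selected), objective = res$objective,
                  quad = res$quad, feasible = TRUE))
    }
    return(list(selected = sort(res$minq_selected), objective = res$minq_objective,
                quad = res$minq, feasible = FALSE))
  }
  ocs_anneal(prob, seed = seed, restarts = restarts)
}

# multi-start best-improvement swaps + annealing pass; all moves are single
# in/out swaps with incrementally maintained row sums
ocs_anneal <- function(prob, seed, restarts) {
  set.seed(seed)
  n <- length(prob$a); k <- prob$k; R <- prob$R; a <- prob$a; C <- prob$C
  cb <- 1 / (2 * k)
  pf <- R[seq_len(n), n + 1]
  base <- 0.25 * R[n + 1, n + 1]
  dR <- diag(R)[seq_len(n)]
  quad_of <- function(S, rs) base + cb * sum(pf[S]) + cb^2 * sum(rs[S])
  rowsums <- function(S) rowSums(R[seq_len(n), S, drop = FALSE])

  eval_swap <- function(S, rs, quad, i, j) {
    # remove i in S, add j not in S
    quad + cb * (pf[j] - pf[i]) +
      cb^2 * (dR[j] + 2 * (rs[j] - R[j, i]) - (2 * rs[i] - dR[i]))
  }
  apply_swap <- function(S, rs, i, j) {
    S <- c(setdiff(S, i), j)
    rs <- rs + R[seq_len(n), j] - R[seq_len(n), i]
    list(S = S, rs = rs)
  }
  local_min_quad <- function(S) {
    rs <- rowsums(S); quad <- quad_of(S, rs)
    repeat {
      out <- S; ins <- setdiff(seq_len(n), S)
      bq <- quad; bi <- bj <- NA
      for (i in out) for (j in ins) {
        q2 <- eval_swap(S, rs, quad, i, j)
        if (q2 < bq - 1e-12) { bq <- q2; bi <- i; bj <- j }
      }
      if (is.na(bi)) break
      sw <- apply_swap(S, rs, bi, bj); S <- sw$S; rs <- sw$rs; quad <- bq
    }
    list(S = S, quad = quad)
  }
  improve_obj <- function(S) {
    rs <- rowsums(S); quad <- quad_of(S, rs); obj <- sum(a[S])
    repeat {
      out <- S; ins <- setdiff(seq_len(n), S)
      bo <- obj; bi <- bj <- NA; bq <- quad
      for (i in out) for (j in ins) {
        if (a[j] <= a[i]) next
        q2 <- eval_swap(S, rs, quad, i, j)
        if (q2 <= C && obj + a[j] - a[i] > bo + 1e-12) {
          bo <- obj + a[j] - a[i]; bi <- i; bj <- j; bq <- q2
        }
      }
      if (is.na(bi)) break
      sw <- apply_swap(S, rs, bi, bj); S <- sw$S; rs <- sw$rs
      obj <- bo; quad <- bq
    }
    list(S = S, obj = obj, quad = quad)
  }
  repair <- function(S) {  # steepest descent on c'Rc until feasible
    rs <- rowsums(S); quad <- quad_of(S, rs)
    while (quad > C) {
      out <- S; ins <- setdiff(seq_len(n), S)
      bq <- quad; bi <- bj <- NA
      for (i in out) for (j in ins) {
        q2 <- eval_swap(S, rs, quad, i, j)
        if (q2 < bq - 1e-12) { bq <- q2; bi <- i; bj <- j }
      }
      if (is.na(bi)) break
      sw <- apply_swap(S, rs, bi, bj); S <- sw$S; rs <- sw$rs; quad <- bq
    }
    list(S = S, quad = quad)
  }

  mq <- local_min_quad(sort(order(-a)[seq_len(k)]))
  mq2 <- local_min_quad(sample.int(n, k))
  if (mq2$quad < mq$quad) mq <- mq2
  if (mq$quad > C) {   # infeasible: best effort minimum-kinship subset
    return(list(selected = sort(mq$S), objective = ocs_obj(prob, mq$S),
                quad = ocs_quad(prob, mq$S), feasible = FALSE))
  }
  starts <- c(list(order(-a)[seq_len(k)], mq$S),
              replicate(max(0, restarts - 2),
                        unique(c(sample(order(-a)[seq_len(min(n, 3 * k))], k))),
                        simplify = FALSE))
  best <- NULL
  for (S0 in starts) {
    S0 <- sort(S0)
    rp <- repair(S0)
    if (rp$quad > C) next
    res <- improve_obj(rp$S)
    if (is.null(best) || res$obj > best$obj + 1e-12) best <- res
  }
  if (is.null(best)) {
    res <- improve_obj(mq$S)
    best <- res
  }
  list(selected = sort(best$S), objective = best$obj / (2 * k),
       quad = best$quad, feasible = TRUE)
}
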