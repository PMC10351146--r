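#' The nine kinship-matrix scenarios
#'
#' VR1/VR2 genomic matrices under the Base (generation-one animals), Old
#' (selected genotyped bulls of generations 0-3), All (all genotyped animals
#' to date), Current (current generation's genotyped animals) and fixed-0.5
#' RAF policies, plus the pedigree numerator relationship matrix.
#'
#' @return data.frame with columns `name`, `method`, `raf`.
#' @export
scenario_specs <- function() {
  data.frame(
    name = c("VR1 Base", "VR1 Old", "VR2 Base", "VR1 All", "VR2 All",
             "VR1 0.5", "VR1 Current", "VR2 Current", "Pedigree"),
    method = c("VR1", "VR1", "VR2", "VR1", "VR2", "VR1", "VR1", "VR2", "PED"),
    raf = c("base", "old", "base", "all", "all", "half", "current",
            "current", NA),
    stringsAsFactors = FALSE
  )
}

snapshot_cohort <- function(st, coh, cfg, seed) {
  g <- coh$gen + 1L
  st$freq[, g] <- rowMeans(coh$hap)
  st$mean_tbv[g] <- mean(coh$tbv)
  st$var_tbv[g] <- var(coh$tbv)
  np <- min(cfg$metrics$n_pairs, length(coh$id) * (length(coh$id) - 1) / 2)
  st$mean_f[g] <- empirical_ibd_kinship(coh, np, seed)$mean
  st
}

append_pedigree <- function(st, coh) {
  st$sire <- c(st$sire, coh$sire)
  st$dam <- c(st$dam, coh$dam)
  st$sex <- c(st$sex, coh$sex)
  st$gen <- c(st$gen, rep(coh$gen, length(coh$id)))
  st$phen <- c(st$phen, coh$phen)
  st$ebv <- c(st$ebv, rep(NA_real_, length(coh$id)))
  st
}

pblup_records <- function(st, round, window) {
  # females whose phenotype is available at this round (born before it),
  # within the data window
  which(st$sex == 2L & st$gen <= round - 1L & st$gen >= round - window &
          !is.na(st$phen))
}

run_pblup <- function(st, round, lambda, window) {
  rec <- pblup_records(st, round, window)
  if (length(rec) == 0) stop("no phenotype records for PBLUP")
  Ainv <- build_ainverse(st$sire, st$dam)
  sol <- solve_blup(st$phen[rec], rec, lambda, Kinv = Ainv)
  sol$a
}

#' Run the shared pedigree-selection phase of a replicate
#'
#' Generation 0 is mated with randomly chosen sires; generations 1-4 select
#' sires by PBLUP truncation.  Selected sires are genotyped.  Because the
#' scenario matrices only act from the first OCS round, this phase is common
#' to all scenarios of a replicate and is computed once.
#'
#' @param founders a [make_founders()] object.
#' @param cfg the [program_config()].
#' @param seed replicate-level phase seed.
#' @return a `pedigree_phase` list consumed by [run_scenario()].
#' @export
run_pedigree_phase <- function(founders, cfg, seed) {
  map <- founders$map
  mk <- which(map$class == "MARKER")
  lambda <- (1 - founders$arch$h2) / founders$arch$h2
  n_gen <- cfg$program$n_generations
  L <- nrow(map)
  st <- list(sire = integer(0), dam = integer(0), sex = integer(0),
             gen = integer(0), phen = numeric(0), ebv = numeric(0),
             freq = matrix(NA_real_, L, n_gen),
             mean_tbv = rep(NA_real_, n_gen), var_tbv = rep(NA_real_, n_gen),
             mean_f = rep(NA_real_, n_gen))
  coh <- founder_cohort(founders)
  set.seed(seed_stream(seed, "phen", 0))
  coh <- assign_phenotypes(coh, founders$arch)
  st <- append_pedigree(st, coh)
  st <- snapshot_cohort(st, coh, cfg, seed_stream(seed, "pairs", 0))

  sel_log <- list()
  geno_batches <- list()   # genotyped animals: ids + marker dosages
  p_base <- NULL
  for (t in 0:(cfg$program$genomic_start - 1L)) {
    males <- which(coh$sex == 1L)
    if (t == 0) {
      set.seed(seed_stream(seed, "select", t))
      sel <- sample(males, cfg$program$pblup_sires)
    } else {
      st$ebv <- run_pblup(st, t, lambda, cfg$evaluation$window_generations)
      sel <- males[select_top(st$ebv[coh$id][males], cfg$program$pblup_sires,
                              seed_stream(seed, "select", t))]
    }
    sire_ids <- coh$id[sel]
    geno_batches[[length(geno_batches) + 1]] <-
      list(ids = sire_ids, M = dosage_matrix(coh$hap, mk, sel), gen = t)
    sel_log[[length(sel_log) + 1]] <-
      data.frame(round = t, model = if (t == 0) "random" else "pblup",
                 n_sires = length(sel))
    set.seed(seed_stream(seed, "mate", t))
    nxt <- mate_cohort(coh, sire_ids, founders, t + 1L,
                       id_start = length(st$gen) + 1L)
    set.seed(seed_stream(seed, "phen", t + 1))
    nxt <- assign_phenotypes(nxt, founders$arch)
    st <- append_pedigree(st, nxt)
    st <- snapshot_cohort(st, nxt, cfg, seed_stream(seed, "pairs", t + 1))
    if (t == 0) p_base <- colMeans(dosage_matrix(nxt$hap, mk)) / 2
    coh <- nxt
  }
  # refresh PBLUP with the newest records for the first parent-average step
  st$ebv <- run_pblup(st, cfg$program$genomic_start, lambda,
                      cfg$evaluation$window_generations)
  old_idx <- which(vapply(geno_batches, function(b) b$gen <= 3, TRUE))
  p_old <- compute_raf(lapply(geno_batches[old_idx], `[[`, "M"))
  list(st = st, cohort = coh, geno_batches = geno_batches,
       p_base = p_base, p_old = p_old, marker_idx = mk,
       lambda = lambda, sel_log = do.call(rbind, sel_log))
}

scenario_R <- function(spec, coh, st2, mk, cfg) {
  # kinship-scale matrix over the whole current cohort under this scenario
  if (spec$method == "PED") {
    n_ped <- length(st2$sire)
    if (length(st2$fd_F) < n_ped) {
      fd <- pedigree_fd(st2$sire, st2$dam, st2$fd_F)
      st2$fd_F <- fd$F; st2$fd_D <- fd$D
    }
    idx <- match(coh$id, seq_len(n_ped))
    A <- cpp_a_block(st2$sire, st2$dam, st2$fd_D, idx)
    R <- A / 2
  } else {
    M <- dosage_matrix(coh$hap, mk)
    p <- switch(spec$raf,
      base = st2$p_base,
      old = st2$p_old,
      all = st2$all_sum / (2 * st2$all_n),
      current = st2$p_current,
      half = rep(0.5, length(mk)))
    G <- if (spec$method == "VR1") build_vr1(M, p) else build_vr2(M, p)
    R <- to_kinship(G)
  }
  list(R = R, st2 = st2)
}

#' Run one scenario's genomic-selection phase
#'
#' From the first OCS round on: males are pre-selected for genotyping on
#' parent average, all females are genotyped, breeding values come from
#' ssGBLUP (first round, and the first three rounds unless `always_gblup`)
#' or GBLUP in marker-effect form on the sliding data window, candidates are
#' the genotyped males with GEBV above the median, and the scenario's kinship
#' matrix with a pseudofemale drives the contribution optimization with bound
#' C = f + delta_f (1 - f).
#'
#' @param spec one row of [scenario_specs()] (as a list or one-row
#'   data.frame).
#' @param founders the replicate's [make_founders()] object.
#' @param cfg the [program_config()].
#' @param phase1 result of [run_pedigree_phase()] for this replicate.
#' @param seed scenario-level operational seed.
#' @param replicate replicate label carried into the log.
#' @return a `scenario_log` list (frequencies, TBV statistics, mean kinship,
#'   OCS log) consumed by [metrics_panel()].
#' @export
run_scenario <- function(spec, founders, cfg, phase1, seed, replicate = 1L) {
  spec <- as.list(spec)
  map <- founders$map
  mk <- phase1$marker_idx
  lambda <- phase1$lambda
  window <- cfg$evaluation$window_generations
  n_gen <- cfg$program$n_generations
  k <- cfg$program$ocs_sires
  st <- phase1$st
  coh <- phase1$cohort
  # accumulators for the All policy: every genotyped animal so far
  all_sum <- Reduce(`+`, lapply(phase1$geno_batches, function(b) colSums(b$M)))
  all_n <- sum(vapply(phase1$geno_batches, function(b) nrow(b$M), 0L))
  st2 <- list(sire = st$sire, dam = st$dam,
              p_base = phase1$p_base, p_old = phase1$p_old,
              all_sum = all_sum, all_n = all_n, p_current = NULL,
              fd_F = numeric(0), fd_D = numeric(0))
  win <- list()    # per-generation genotyped-female records: W, y
  WtW <- NULL; win_gens <- integer(0)
  geno_hist <- phase1$geno_batches   # grows only while ssGBLUP rounds remain
  sigma2_u_lambda <- lambda * 2 * sum(phase1$p_base * (1 - phase1$p_base))
  ocs_log <- list()

  for (t in cfg$program$genomic_start:(n_gen - 2L)) {
    males <- which(coh$sex == 1L)
    females <- which(coh$sex == 2L)
    # 1. parent-average pre-selection of males for genotyping
    pa <- parent_average(st$ebv[coh$sire[males]], st$ebv[coh$dam[males]])
    topm <- males[select_top(pa, cfg$program$genotyped_males,
                             seed_stream(seed, "pa", t))]
    M_males <- dosage_matrix(coh$hap, mk, topm)
    M_fem <- dosage_matrix(coh$hap, mk, females)
    st2$all_sum <- st2$all_sum + colSums(M_males) + colSums(M_fem)
    st2$all_n <- st2$all_n + length(topm) + length(females)
    st2$p_current <- (colSums(M_males) + colSums(M_fem)) /
      (2 * (length(topm) + length(females)))
    coh$genotyped[c(topm, females)] <- TRUE

    use_ssgblup <- t == cfg$program$genomic_start ||
      (!cfg$evaluation$always_gblup &&
         t < cfg$program$genomic_start + cfg$evaluation$ssgblup_rounds)
    if (use_ssgblup) {
      geno_ids <- c(unlist(lapply(geno_hist, `[[`, "ids")),
                    coh$id[topm], coh$id[females])
      M_geno <- rbind(do.call(rbind, lapply(geno_hist, `[[`, "M")),
                      M_males, M_fem)
      G <- build_vr1(M_geno, st2$p_base)
      fd <- pedigree_fd(st$sire, st$dam)
      A22 <- cpp_a_block(st$sire, st$dam, fd$D, geno_ids)
      Gw <- cfg$evaluation$blend * G + (1 - cfg$evaluation$blend) * A22
      corr <- solve(Gw) - solve(A22)
      tr <- cpp_ainv_triplets(st$sire, st$dam, fd$D)
      n_ped <- length(st$sire)
      ng <- length(geno_ids)
      Hinv <- Matrix::sparseMatrix(
        i = c(tr$i, rep(geno_ids, ng)),
        j = c(tr$j, rep(geno_ids, each = ng)),
        x = c(tr$x, as.vector(corr)),
        dims = c(n_ped, n_ped))
      rec <- pblup_records(st, t, window)
      sol <- solve_blup(st$phen[rec], rec, lambda, Kinv = Hinv)
      st$ebv <- sol$a
      if (!cfg$evaluation$always_gblup &&
          t + 1L < cfg$program$genomic_start + cfg$evaluation$ssgblup_rounds) {
        geno_hist <- c(geno_hist,
                       list(list(ids = coh$id[topm], M = M_males, gen = t),
                            list(ids = coh$id[females], M = M_fem, gen = t)))
      }
    } else {
      # marker-effect GBLUP on the sliding window of genotyped-female records
      target <- seq(max(cfg$program$genomic_start, t - window), t - 1L)
      target <- intersect(target, as.integer(names(win)))
      for (g in setdiff(target, win_gens)) {
        blk <- win[[as.character(g)]]
        WtW <- if (is.null(WtW)) crossprod(blk$W) else WtW + crossprod(blk$W)
      }
      for (g in setdiff(win_gens, target)) {
        WtW <- WtW - crossprod(win[[as.character(g)]]$W)
        win[[as.character(g)]] <- NULL
      }
      win_gens <- target
      Wall <- do.call(rbind, lapply(as.character(target),
                                    function(g) win[[g]]$W))
      yall <- unlist(lapply(as.character(target), function(g) win[[g]]$y))
      sol <- snp_blup_solve(WtW, colSums(Wall), crossprod(Wall, yall),
                            length(yall), sum(yall), sigma2_u_lambda)
      W_cur <- sweep(rbind(M_males, M_fem), 2, 2 * st2$p_base)
      gv <- drop(W_cur %*% sol$u)
      ids_cur <- c(coh$id[topm], coh$id[females])
      st$ebv[ids_cur] <- gv
      gebv_geno <- setNames(gv, ids_cur)
    }
    coh$gebv[c(topm, females)] <- st$ebv[coh$id[c(topm, females)]]

    # 2. candidates: genotyped males with GEBV above the median (top half)
    cand_local <- topm[select_top(st$ebv[coh$id[topm]],
                                  cfg$program$candidate_males,
                                  seed_stream(seed, "cand", t))]
    # 3. scenario kinship matrix over the whole cohort, bound, pseudofemale
    sr <- scenario_R(spec, coh, st2, mk, cfg)
    st2 <- sr$st2
    R <- sr$R
    fbar <- mean(R)
    C <- kinship_target(fbar, cfg$ocs$delta_f)
    pf_row <- rowMeans(R[cand_local, females, drop = FALSE])
    Rp <- rbind(cbind(R[cand_local, cand_local, drop = FALSE], pf_row),
                c(pf_row, mean(R[females, females])))
    prob <- ocs_problem(st$ebv[coh$id[cand_local]], Rp, k, C)
    dec <- optimize_contributions(prob, seed = seed_stream(seed, "ocs", t))
    sel <- cand_local[dec$selected]
    ocs_log[[length(ocs_log) + 1]] <- data.frame(
      round = t, scenario = spec$name, fbar = fbar, C = C,
      achieved = dec$quad, objective = dec$objective,
      feasible = dec$feasible, n_candidates = length(cand_local))

    # 4. record the window block for the females genotyped this round
    W_f <- sweep(M_fem, 2, 2 * st2$p_base)
    win[[as.character(t)]] <- list(W = W_f, y = coh$phen[females], gen = t)

    # 5. mate and advance
    set.seed(seed_stream(seed, "mate", t))
    nxt <- mate_cohort(coh, coh$id[sel], founders, t + 1L,
                       id_start = length(st$gen) + 1L)
    set.seed(seed_stream(seed, "phen", t + 1))
    nxt <- assign_phenotypes(nxt, founders$arch)
    st <- append_pedigree(st, nxt)
    st2$sire <- st$sire; st2$dam <- st$dam
    st <- snapshot_cohort(st, nxt, cfg, seed_stream(seed, "pairs", t + 1))
    coh <- nxt
  }
  structure(list(map = map, freq = st$freq, mean_tbv = st$mean_tbv,
                 var_tbv = st$var_tbv, mean_f = st$mean_f,
                 alpha = founders$arch$alpha,
                 sigma2_a0 = founders$arch$sigma2_a0,
                 scenario = spec$name, replicate = replicate,
                 ocs_log = do.call(rbind, ocs_log),
                 sel_log = phase1$sel_log),
            class = "scenario_log")
}

#' Run the full experiment: replicates by scenarios
#'
#' Each replicate draws one founder population and one shared
#' pedigree-selection phase; every scenario then runs its genomic phase from
#' that common state, so scenarios within a replicate share the base
#' population and generations 0-5 exactly.  Seeds are derived
#' hierarchically: founders and the pedigree phase from (master, replicate),
#' the genomic phase from (master, replicate, scenario).
#'
#' @param cfg the [program_config()].
#' @param replicates number of replicates.
#' @param scenarios data.frame as [scenario_specs()] (possibly a subset).
#' @param master_seed master seed.
#' @param out_dir optional directory: per-replicate metrics are streamed to
#'   CSV as they complete.
#' @return list with `metrics` (long data.frame over replicates, scenarios,
#'   generations) and `ocs_logs`.
#' @export
run_experiment <- function(cfg, replicates = 1, scenarios = scenario_specs(),
                           master_seed = 1, out_dir = NULL) {
  metrics <- list(); logs <- list()
  for (r in seq_len(replicates)) {
    founders <- make_founders(cfg, seed_stream(master_seed, "founders", r))
    phase1 <- run_pedigree_phase(founders, cfg,
                                 seed_stream(master_seed, "pedigree", r))
    for (s in seq_len(nrow(scenarios))) {
      spec <- scenarios[s, ]
      log <- run_scenario(spec, founders, cfg, phase1,
                          seed = seed_stream(master_seed, "scenario", r,
                                             spec$name),
                          replicate = r)
      metrics[[length(metrics) + 1]] <- metrics_panel(log, cfg)
      logs[[length(logs) + 1]] <- log$ocs_log
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(do.call(rbind, metrics),
                  file.path(out_dir, "metrics.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  list(metrics = do.call(rbind, metrics), ocs_logs = do.call(rbind, logs))
}
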