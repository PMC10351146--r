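#' Trend regression comparing scenarios
#'
#' Fits, by ordinary least squares, y = beta_k + beta_l X + e over
#' generations 5 to 20, where beta_k are replicate fixed intercepts and
#' beta_l is a scenario-specific regression on generation number X.  The
#' dependent variable is one of: mean TBV in sigma_A0 units (`"G"`),
#' additive genetic or genic variance as a percentage of its generation-five
#' value (`"var_a"`, `"var_g"`), or -log(1 - x) for the mean kinship
#' (`"f"`) and the drift/homozygosity coefficients (`"f_drift"`, `"f_hom"`;
#' natural log).  The fitted slope per scenario is the reported rate of
#' change per generation (Delta).
#'
#' A single pooled model with a scenario-by-generation interaction is used so
#' that slope-difference standard errors are well defined.
#'
#' @param metrics long metrics table ([metrics_panel()] rows over scenarios
#'   and replicates).
#' @param response one of `"G"`, `"var_a"`, `"var_g"`, `"f"`, `"f_drift"`,
#'   `"f_hom"`.
#' @param locus_class locus class for the inbreeding responses
#'   (`"neutral"`, `"qtl"` or `"marker"`).
#' @param generations generations to include (default 5:20).
#' @return object of class `trend_model` with `slopes`, their covariance
#'   `vcov`, residual `df`, the underlying `lm` fit, and the response label.
#' @export
fit_trend <- function(metrics, response = c("G", "var_a", "var_g", "f",
                                            "f_drift", "f_hom"),
                      locus_class = "neutral", generations = 5:20) {
  response <- match.arg(response)
  d <- metrics[metrics$generation %in% generations, , drop = FALSE]
  ref <- metrics[metrics$generation == min(generations), , drop = FALSE]
  key <- paste(d$scenario, d$replicate)
  refkey <- paste(ref$scenario, ref$replicate)
  y <- suppressWarnings(switch(response,
    G = d$mean_tbv_sd0,
    var_a = 100 * d$var_a / ref$var_a[match(key, refkey)],
    var_g = 100 * d$var_g / ref$var_g[match(key, refkey)],
    f = -log(1 - d$mean_kinship),
    f_drift = -log(1 - d[[paste0("f_drift_", locus_class)]]),
    f_hom = -log(1 - d[[paste0("f_hom_", locus_class)]])
  ))
  # the -log(1 - x) transform is undefined once x >= 1 (F_drift is unbounded
  # above 1 under selection); such generation points are excluded from the fit
  keep <- is.finite(y)
  y <- y[keep]; d <- d[keep, , drop = FALSE]
  rep_f <- factor(d$replicate)
  sc_f <- factor(d$scenario)
  # explicit design: one intercept per replicate, one slope per scenario
  Xr <- sapply(levels(rep_f), function(l) as.numeric(rep_f == l))
  Xs <- sapply(levels(sc_f), function(l) (sc_f == l) * d$generation)
  X <- cbind(Xr, Xs)
  if (nrow(X) <= ncol(X)) stop("not enough observations for the trend model")
  fit <- lm.fit(X, y)
  if (anyNA(fit$coefficients)) stop("rank-deficient trend model")
  df <- nrow(X) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(chol(crossprod(X)))
  slope_idx <- nlevels(rep_f) + seq_len(nlevels(sc_f))
  slopes <- fit$coefficients[slope_idx]
  names(slopes) <- levels(sc_f)
  V <- s2 * XtXi[slope_idx, slope_idx, drop = FALSE]
  dimnames(V) <- list(names(slopes), names(slopes))
  structure(list(slopes = slopes, vcov = V, df = df,
                 fit = fit, response = response, locus_class = locus_class),
            class = "trend_model")
}

#' Pairwise t-tests on scenario slopes with Bonferroni correction
#'
#' Tests every pair of scenario slopes with a t statistic based on the pooled
#' model's residual variance, rejecting at alpha divided by the number of
#' pairwise comparisons (36 for nine scenarios).  Scenarios that are not
#' significantly different share a letter; letters are a deterministic greedy
#' clique cover of the non-significance graph, ordered by slope.
#'
#' @param model a [fit_trend()] object.
#' @param alpha familywise significance level before correction.
#' @return list with `t`, `p` (uncorrected), `significant` (logical matrix
#'   after Bonferroni), `n_comparisons`, and `letters` per scenario.
#' @export
pairwise_slope_tests <- function(model, alpha = 0.05) {
  if (model$df <= 0) stop("non-positive residual degrees of freedom")
  b <- model$slopes; V <- model$vcov
  s <- length(b)
  n_comp <- s * (s - 1) / 2
  tmat <- pmat <- matrix(NA_real_, s, s, dimnames = list(names(b), names(b)))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (i == j) next
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    tmat[i, j] <- (b[i] - b[j]) / se
    pmat[i, j] <- 2 * pt(-abs(tmat[i, j]), model$df)
  }
  sig <- pmat < alpha / n_comp
  diag(sig) <- FALSE
  list(t = tmat, p = pmat, significant = sig, n_comparisons = n_comp,
       letters = letter_groups(b, sig))
}

# greedy clique cover of the non-significance graph: walk scenarios in slope
# order, extend each group while mutually non-significant
letter_groups <- function(slopes, sig) {
  ord <- order(slopes)
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(!sig[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  lab <- vapply(seq_along(slopes), function(i) {
    paste(letters[which(vapply(groups, function(g) i %in% g, TRUE))],
          collapse = "")
  }, "")
  names(lab) <- names(slopes)
  lab
}

#' Scenario comparison tables and plot data
#'
#' Fits the six trend responses and assembles (i) the rates table: Delta f
#' (percent), Delta G (sigma_A0 units), Delta sigma2_A and Delta sigma2_G
#' (percent per generation), each with significance letters and expressed
#' relative to the Pedigree scenario, plus mean MAF at QTL and neutral loci
#' in the last generation; (ii) the inbreeding table: Delta F_drift and
#' Delta F_hom (percent) per locus class and the last-generation
#' F_hom - F_drift gap; and (iii) the genetic-gain-versus-inbreeding plot
#' data.
#'
#' @param metrics long metrics table.
#' @param generations generations used in the trend fits.
#' @return list with `rates`, `inbreeding`, `plot_data` and the fitted
#'   `models`.
#' @export
make_tables <- function(metrics, generations = 5:20) {
  last_gen <- max(metrics$generation)
  mods <- list(
    f = fit_trend(metrics, "f", generations = generations),
    G = fit_trend(metrics, "G", generations = generations),
    var_a = fit_trend(metrics, "var_a", generations = generations),
    var_g = fit_trend(metrics, "var_g", generations = generations)
  )
  tests <- lapply(mods, pairwise_slope_tests)
  scen <- names(mods$f$slopes)
  ped <- grep("Pedigree", scen, value = TRUE)[1]
  rel <- function(x) if (is.na(ped)) rep(NA_real_, length(x)) else x / x[[ped]]
  lastg <- metrics[metrics$generation == last_gen, , drop = FALSE]
  maf <- do.call(rbind, lapply(split(lastg, lastg$scenario),
                               function(d) data.frame(maf_qtl = mean(d$maf_qtl),
                                                      maf_neutral = mean(d$maf_neutral))))
  rates <- data.frame(
    scenario = scen,
    delta_f_pct = 100 * mods$f$slopes,
    delta_g = mods$G$slopes,
    delta_var_a_pct = mods$var_a$slopes,
    delta_var_g_pct = mods$var_g$slopes,
    rel_delta_f = rel(mods$f$slopes),
    rel_delta_g = rel(mods$G$slopes),
    rel_delta_var_a = rel(mods$var_a$slopes),
    rel_delta_var_g = rel(mods$var_g$slopes),
    letters_f = tests$f$letters[scen],
    letters_g = tests$G$letters[scen],
    maf_qtl = maf[scen, "maf_qtl"],
    maf_neutral = maf[scen, "maf_neutral"],
    row.names = NULL
  )
  inb_mods <- list()
  inb <- data.frame(scenario = scen)
  for (cl in c("neutral", "qtl", "marker")) {
    md <- fit_trend(metrics, "f_drift", locus_class = cl,
                    generations = generations)
    mh <- fit_trend(metrics, "f_hom", locus_class = cl,
                    generations = generations)
    inb[[paste0("delta_f_drift_", cl, "_pct")]] <- 100 * md$slopes[scen]
    inb[[paste0("delta_f_hom_", cl, "_pct")]] <- 100 * mh$slopes[scen]
    gap <- vapply(scen, function(s) {
      d <- lastg[lastg$scenario == s, ]
      100 * mean(d[[paste0("f_hom_", cl)]] - d[[paste0("f_drift_", cl)]])
    }, 0)
    inb[[paste0("fhom_minus_fdrift_", cl, "_pct")]] <- gap
    inb_mods[[paste0("f_drift_", cl)]] <- md
    inb_mods[[paste0("f_hom_", cl)]] <- mh
  }
  plot_data <- metrics[metrics$generation >= min(generations),
                       c("scenario", "replicate", "generation",
                         "mean_tbv_sd0", "mean_kinship",
                         "f_drift_neutral", "f_hom_neutral")]
  list(rates = rates, inbreeding = inb, plot_data = plot_data,
       models = c(mods, inb_mods), tests = tests)
}
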