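# synthetic long metrics table with known intercepts and slopes
synth_metrics <- function(slopes, reps = 3, gens = 5:20, noise = 0,
                          intercepts = seq_along(1:reps) * 0.1) {
  grid <- expand.grid(scenario = names(slopes), replicate = seq_len(reps),
                      generation = gens, stringsAsFactors = FALSE)
  grid$mean_tbv_sd0 <- intercepts[grid$replicate] +
    slopes[grid$scenario] * grid$generation +
    rnorm(nrow(grid), 0, noise)
  # fill remaining responses with simple transforms so fit_trend runs
  grid$mean_kinship <- 1 - exp(-(0.002 * grid$generation))
  grid$var_a <- 100 - grid$generation
  grid$var_g <- 100 - 0.5 * grid$generation
  grid$f_drift_neutral <- grid$f_hom_neutral <- 1 - exp(-0.001 * grid$generation)
  grid$f_drift_qtl <- grid$f_hom_qtl <- grid$f_drift_neutral
  grid$f_drift_marker <- grid$f_hom_marker <- grid$f_drift_neutral
  grid$maf_qtl <- grid$maf_neutral <- 0.2
  grid
}

test_that("noiseless trends are recovered to machine precision", {
  set.seed(1)
  b <- c(A = 0.10, B = 0.25, C = -0.05)
  m <- synth_metrics(b, noise = 0)
  fit <- fit_trend(m, "G")
  expect_equal(fit$slopes[names(b)], b, tolerance = 1e-10)
  # intercept absorption: shifting one replicate's y changes no slope
  m2 <- m
  m2$mean_tbv_sd0[m2$replicate == 2] <- m2$mean_tbv_sd0[m2$replicate == 2] + 5
  fit2 <- fit_trend(m2, "G")
  expect_equal(fit2$slopes, fit$slopes, tolerance = 1e-10)
})

test_that("trend estimates equal an independent normal-equations solve", {
  set.seed(2)
  b <- c(S1 = 0.2, S2 = 0.3)
  m <- synth_metrics(b, reps = 2, noise = 0.3)
  fit <- fit_trend(m, "G")
  # independent OLS via explicit design matrix and normal equations
  X <- cbind(m$replicate == 1, m$replicate == 2,
             (m$scenario == "S1") * m$generation,
             (m$scenario == "S2") * m$generation)
  beta <- solve(crossprod(X), crossprod(X, m$mean_tbv_sd0))
  expect_equal(unname(fit$slopes[c("S1", "S2")]), beta[3:4, 1],
               tolerance = 1e-10)
})

test_that("pairwise slope tests count comparisons and group letters", {
  set.seed(3)
  # nine scenarios: 36 comparisons
  b9 <- setNames(seq(0.1, 0.9, length.out = 9), paste0("S", 1:9))
  m9 <- synth_metrics(b9, noise = 0.001)
  fit9 <- fit_trend(m9, "G")
  tst9 <- pairwise_slope_tests(fit9)
  expect_equal(tst9$n_comparisons, 36)
  # huge separation, tiny noise: all pairs significant, 9 distinct letters
  expect_true(all(tst9$significant[upper.tri(tst9$significant)]))
  expect_length(unique(tst9$letters), 9)
  # two identical scenarios share data: t = 0 and a shared letter
  m2 <- synth_metrics(c(X = 0.2, Y = 0.2), noise = 0.001)
  m2$mean_tbv_sd0 <- ave(m2$mean_tbv_sd0,
                         paste(m2$replicate, m2$generation))
  fitb <- fit_trend(m2, "G")
  tstb <- pairwise_slope_tests(fitb)
  expect_equal(tstb$t["X", "Y"], 0, tolerance = 1e-8)
  expect_equal(tstb$letters[["X"]], tstb$letters[["Y"]])
})

test_that("letter groups are a deterministic function of the tests", {
  b <- setNames(c(0.1, 0.102, 0.3), c("a1", "a2", "b1"))
  set.seed(4)
  m <- synth_metrics(b, noise = 0.3)
  fit <- fit_trend(m, "G")
  l1 <- pairwise_slope_tests(fit)$letters
  l2 <- pairwise_slope_tests(fit)$letters
  expect_identical(l1, l2)
  # close slopes share a letter, the distant one does not
  expect_equal(l1[["a1"]], l1[["a2"]])
  expect_false(l1[["b1"]] == l1[["a1"]])
})

test_that("comparison tables report slopes and Pedigree-relative ratios", {
  set.seed(5)
  run <- cached_tiny_run()
  tab <- make_tables(run$res$metrics, generations = 5:8)
  expect_setequal(tab$rates$scenario, c("VR1 Base", "Pedigree"))
  ped <- tab$rates[tab$rates$scenario == "Pedigree", ]
  # self-ratios are exactly 1
  expect_equal(ped$rel_delta_f, 1)
  expect_equal(ped$rel_delta_g, 1)
  # table columns are the fitted slopes, not a recomputation
  fit_f <- fit_trend(run$res$metrics, "f", generations = 5:8)
  expect_equal(tab$rates$delta_f_pct,
               unname(100 * fit_f$slopes[tab$rates$scenario]),
               tolerance = 1e-12)
  # ratios are invariant to a linear rescaling of the response
  m_scaled <- run$res$metrics
  m_scaled$mean_tbv_sd0 <- 3 * m_scaled$mean_tbv_sd0
  t2 <- make_tables(m_scaled, generations = 5:8)
  expect_equal(t2$rates$rel_delta_g, tab$rates$rel_delta_g, tolerance = 1e-10)
})

test_that("the -log(1 - f) slope recovers a constant kinship rate", {
  # geometric kinship growth at rate dF: f_t = 1 - (1 - dF)^(t - 5)
  dF <- 0.0125
  gens <- 5:20
  b <- c(Z = NA)
  m <- synth_metrics(c(Z = 0), gens = gens, reps = 2, noise = 0)
  m$mean_kinship <- 1 - (1 - dF)^(m$generation - 5)
  fit <- fit_trend(m, "f", generations = gens)
  expect_equal(unname(fit$slopes), -log(1 - dF), tolerance = 1e-10)
})
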