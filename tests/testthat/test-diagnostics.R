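test_that("CWRES are calibrated under the true model", {
  m <- scr_model_th_final()
  coh <- generate_cohort(400, seed = 90)
  dat <- generate_observations(coh, m,
    config = utils::modifyList(idms_only,
                               list(n_obs_min = 5, n_obs_max = 5,
                                    n_obs_mean = 5)), seed = 91)
  cw <- cwres(m, dat)
  expect_equal(length(cw), nrow(dat))
  expect_true(all(is.finite(cw)))
  # the first-order conditional linearisation carries a small positive
  # mean offset on this strongly curved maturation model (~0.05-0.12
  # across simulation seeds); dispersion is the calibrated quantity
  expect_lt(abs(mean(cw)), 0.15)
  expect_gt(sd(cw), 0.85)
  expect_lt(sd(cw), 1.15)
})

test_that("CWRES vanish for noise-free data and flag inflated
           observations", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 1e-8)
  cov3 <- data.frame(ga = c(39, 38, 40), aki = 0, death = 0)
  exact <- tiny_dataset(m, cov3, list(c(1, 3, 6), c(2, 5), c(1, 4, 8)),
                        list(1, 1, 1))
  expect_lt(max(abs(cwres(m, exact))), 1e-3)
  m2 <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227)
  high <- tiny_dataset(m2, cov3, list(c(1, 3, 6), c(2, 5), c(1, 4, 8)),
                       list(1.5, 1.5, 1.5))
  expect_true(all(cwres(m2, high) > 0))
})

test_that("CIWRES standardise the individual residual exactly", {
  m <- flat_model(sigma2 = 0.0227)   # no random effects
  cov1 <- data.frame(ga = 39, aki = 0, death = 0)
  at_pred <- tiny_dataset(m, cov1, list(c(1, 4)), list(1))
  expect_equal(ciwres(m, at_pred), c(0, 0))
  one_sd <- tiny_dataset(m, cov1, list(c(1, 4)),
                         list(exp(c(1, -1) * sqrt(0.0227))))
  expect_equal(ciwres(m, one_sd), c(1, -1))
})

test_that("CIWRES dispersion grows under a misspecified maturation
           slope", {
  truth <- scr_model_th_final()
  coh <- generate_cohort(150, seed = 92)
  dat <- generate_observations(coh, truth, config = idms_only, seed = 93)
  wrong <- truth
  wrong$theta["gamma"] <- truth$theta[["gamma"]] / 2
  wrong$effects <- Filter(function(e) !(e$kind == "split" &&
                                          e$target == "gamma"),
                          wrong$effects)
  sd_true <- sd(ciwres(truth, dat))
  sd_wrong <- sd(ciwres(wrong, dat))
  expect_lt(sd_true, sd_wrong)
})

test_that("residuals are invariant to subject ordering", {
  m <- scr_model_th_final()
  coh <- generate_cohort(25, seed = 94)
  dat <- generate_observations(coh, m, config = idms_only, seed = 95)
  df <- as.data.frame(dat)
  ids <- unique(df$ID)
  df2 <- do.call(rbind, lapply(rev(ids), function(id) df[df$ID == id, ]))
  dat2 <- scr_dataset(df2)
  cw1 <- cwres(m, dat)
  cw2 <- cwres(m, dat2)
  key1 <- paste(df$ID, df$TIME)
  key2 <- paste(df2$ID, df2$TIME)
  expect_equal(cw2[match(key1, key2)], cw1, tolerance = 1e-8)
})

test_that("the VPC covers self-simulated data and is seed-reproducible", {
  m <- scr_model_th_final()
  coh <- generate_cohort(150, seed = 96)
  dat <- generate_observations(coh, m, config = idms_only, seed = 97)
  v <- vpc(m, dat, n_reps = 400, seed = 98)
  med <- v$table[v$table$statistic == "p50", ]
  inside <- med$observed >= med$sim_lo & med$observed <= med$sim_hi
  expect_gte(sum(inside), ceiling(0.8 * nrow(med)))
  v2 <- vpc(m, dat, n_reps = 400, seed = 98)
  expect_identical(v$table, v2$table)
})

test_that("VPC degenerates with one replicate and flags misfit by
           direction", {
  m <- scr_model_th_final()
  coh <- generate_cohort(60, seed = 99)
  dat <- generate_observations(coh, m, config = idms_only, seed = 100)
  v1 <- vpc(m, dat, n_reps = 1, seed = 101)
  expect_equal(v1$table$sim_lo, v1$table$sim_hi)
  # a model that doubles creatinine synthesis simulates too high:
  # observed percentiles fall below the envelopes
  double <- m
  double$theta["ksyn_gfr0"] <- m$theta[["ksyn_gfr0"]] * 2
  for (j in seq_along(double$effects)) {
    ef <- double$effects[[j]]
    if (ef$kind == "split" && ef$target == "ksyn_gfr0")
      double$effects[[j]]$levels <- ef$levels * 2
  }
  vd <- vpc(double, dat, n_reps = 200, seed = 102)
  med <- vd$table[vd$table$statistic == "p50", ]
  expect_true(all(med$observed < med$sim_lo))
})

test_that("thin bins merge into their neighbours", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227)
  cov <- data.frame(ga = rep(39, 8), aki = 0, death = 0)
  # all observations in days 1-3 except a single one at day 9
  set.seed(103)
  times <- c(replicate(7, sort(runif(4, 1, 3)), simplify = FALSE),
             list(c(2, 9.5)))
  devs <- replicate(8, exp(rnorm(4, 0, 0.15)), simplify = FALSE)
  devs[[8]] <- devs[[8]][1:2]
  dat <- tiny_dataset(m, cov, times, devs)
  v <- vpc(m, dat, n_reps = 50, bins = 0:10, seed = 104)
  expect_true(length(v$merged) > 0)
  expect_true(all(v$table$n_obs >= 5 | length(v$bins) == 2))
})
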