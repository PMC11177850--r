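test_that("joint -2LL has its closed form at a perfect observation", {
  p <- th_typ()
  dv <- scr_value(2, p)
  w2 <- c(ksyn_gfr0 = 0.0180, pna50 = 0.220)
  val <- joint_neg2ll(dv, 2, p, eta = c(ksyn_gfr0 = 0, pna50 = 0),
                      omega2 = w2, sigma2 = 0.0227)
  expect_equal(val, log(2 * pi * 0.0227) + sum(log(2 * pi * w2)))
  # doubling sigma2 with zero residual raises the data term by log 2 per
  # observation
  val2 <- joint_neg2ll(rep(dv, 3), rep(2, 3), p,
                       eta = c(ksyn_gfr0 = 0), omega2 = w2,
                       sigma2 = 2 * 0.0227)
  val1 <- joint_neg2ll(rep(dv, 3), rep(2, 3), p,
                       eta = c(ksyn_gfr0 = 0), omega2 = w2,
                       sigma2 = 0.0227)
  expect_equal(val2 - val1, 3 * log(2))
  # prior term is symmetric in the sign of eta (zero-residual comparison)
  at_eta <- function(e) {
    pe <- p
    pe[["ksyn_gfr0"]] <- pe[["ksyn_gfr0"]] * exp(e)
    joint_neg2ll(scr_value(2, pe), 2, p, eta = c(ksyn_gfr0 = e),
                 omega2 = w2, sigma2 = 0.0227)
  }
  expect_equal(at_eta(0.3), at_eta(-0.3))
  expect_error(joint_neg2ll(dv, 2, p, eta = c(gamma = 0.1),
                            omega2 = c(gamma = 0), sigma2 = 0.0227),
               "omega2 > 0")
})

test_that("Laplace equals the closed-form marginal on the log-linear
           submodel", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0233), sigma2 = 0.0218)
  coh <- generate_cohort(20, seed = 60)
  dat <- generate_observations(coh, m, config = idms_only, seed = 61)
  oracle <- closedform_loglin_ofv(m, dat)
  # generic Laplace path (fast path off), both curvature options
  lap_fd <- marginal_neg2ll(m, dat,
                            settings = scr_settings(linear_fast_path =
                                                      FALSE))
  lap_gn <- marginal_neg2ll(m, dat,
                            settings = scr_settings(hessian =
                                                      "gauss_newton",
                                                    linear_fast_path =
                                                      FALSE))
  expect_equal(as.numeric(lap_fd), oracle, tolerance = 1e-6)
  expect_equal(as.numeric(lap_gn), oracle, tolerance = 1e-6)
  # and the dedicated closed-form fast path agrees too
  expect_equal(as.numeric(marginal_neg2ll(m, dat)), oracle,
               tolerance = 1e-8)
})

test_that("the marginal likelihood degenerates correctly as omega2 -> 0", {
  m <- flat_model(omega2 = c(pna50 = 1e-9), sigma2 = 0.0227)
  coh <- generate_cohort(10, seed = 62)
  dat <- generate_observations(coh, m, config = idms_only, seed = 63)
  st <- scr_settings(omega2_bounds = c(1e-12, 4))
  ofv <- marginal_neg2ll(m, dat, settings = st)
  m0 <- flat_model(sigma2 = 0.0227)
  ofv0 <- marginal_neg2ll(m0, dat, settings = st)
  # joint at eta = 0 plus the vanishing prior-vs-correction constant
  expect_equal(as.numeric(ofv), as.numeric(ofv0), tolerance = 1e-6)
})

test_that("importance sampling agrees with Laplace on a mildly nonlinear
           model", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180, gfrss_gfr0 = 0.0955),
                  sigma2 = 0.0227)
  coh <- generate_cohort(20, seed = 64)
  dat <- generate_observations(coh, m, config = idms_only, seed = 65)
  lap <- marginal_neg2ll(m, dat)
  set.seed(66)
  is1 <- marginal_neg2ll(m, dat, method = "importance",
                         settings = scr_settings(is_draws = 10000))
  expect_lt(abs(as.numeric(is1) - as.numeric(lap)), 0.5)
})

test_that("OFV is invariant to subject ordering", {
  m <- scr_model_th_final()
  coh <- generate_cohort(25, seed = 67)
  dat <- generate_observations(coh, m, config = idms_only, seed = 68)
  df <- as.data.frame(dat)
  ids <- unique(df$ID)
  perm <- rev(ids)
  df2 <- do.call(rbind, lapply(perm, function(id) df[df$ID == id, ]))
  dat2 <- scr_dataset(df2)
  expect_equal(as.numeric(marginal_neg2ll(m, dat)),
               as.numeric(marginal_neg2ll(m, dat2)), tolerance = 1e-9)
})

test_that("a residual-only model recovers sigma2 with the Fisher RSE", {
  m <- flat_model(sigma2 = 0.0227,
                  fixed = c("qmax_uf", "k", "pna_p", "ksyn_gfr0",
                            "gfrss_gfr0", "pna50", "gamma"))
  coh <- generate_cohort(120, seed = 70)
  dat <- generate_observations(coh, m, config = idms_only, seed = 71)
  start <- m
  start$sigma2 <- 0.05
  fit <- scr_fit(dat, start, compute_se = TRUE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["sigma2"]), 0.0227, tolerance = 0.1)
  n <- fit$n_obs
  expect_equal(unname(fit$rse_pct["sigma2"]), 100 * sqrt(2 / n),
               tolerance = 0.15)
  # refitting from the optimum does not increase the OFV
  refit <- scr_fit(dat, fit$model)
  expect_lte(refit$ofv, fit$ofv + 0.01)
})

test_that("a single-random-effect model recovers its parameters", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227,
                  fixed = c("qmax_uf", "k", "pna_p", "gfrss_gfr0",
                            "pna50", "gamma"))
  coh <- generate_cohort(150, seed = 72)
  dat <- generate_observations(coh, m, config = idms_only, seed = 73)
  start <- m
  start$theta["ksyn_gfr0"] <- 0.9
  start$omega2["ksyn_gfr0"] <- 0.05
  start$sigma2 <- 0.05
  fit <- scr_fit(dat, start,
                 settings = scr_settings(
                   theta_bounds = c(1e-4, 1e4)))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["ksyn_gfr0"]), 0.631,
               tolerance = 0.05)
  expect_equal(unname(fit$estimates["sigma2"]), 0.0227, tolerance = 0.15)
  # deterministic: same data, same start, same result
  fit2 <- scr_fit(dat, start,
                  settings = scr_settings(theta_bounds = c(1e-4, 1e4)))
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("empirical Bayes estimates shrink and track the simulated
           truth", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227)
  coh <- generate_cohort(120, seed = 74)
  dat <- generate_observations(coh, m,
    config = utils::modifyList(idms_only,
                               list(n_obs_min = 5, n_obs_max = 5,
                                    n_obs_mean = 5)), seed = 75)
  eb <- empirical_bayes(m, dat)
  eta_true <- attr(dat, "eta")[, "ksyn_gfr0"]
  expect_gt(cor(eta_true, eb[, "ksyn_gfr0"]), 0.7)
  # near-zero residual error pins the EBE at the simulated eta
  m0 <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 1e-8)
  dat0 <- generate_observations(coh, m0,
    config = utils::modifyList(idms_only,
                               list(n_obs_min = 3, n_obs_max = 3,
                                    n_obs_mean = 3)), seed = 76)
  eb0 <- empirical_bayes(m0, dat0)
  expect_equal(unname(eb0[, 1]), unname(attr(dat0, "eta")[, "ksyn_gfr0"]),
               tolerance = 1e-3)
  # an uninformative subject shrinks towards zero
  mbig <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 5)
  one <- tiny_dataset(mbig, data.frame(ga = 39, aki = 0, death = 0),
                      list(3), list(2))   # one obs, double the prediction
  ebo <- empirical_bayes(mbig, one)
  expect_lt(abs(ebo[1, 1]), 0.01)
})

test_that("shrinkage and lognormal CV follow their defining formulas", {
  ebes <- cbind(ksyn_gfr0 = c(0, 0, 0, 0))
  expect_equal(unname(eta_shrinkage(ebes, c(ksyn_gfr0 = 0.04))), 100)
  set.seed(1)
  x <- rnorm(2000)
  x <- (x - mean(x)) / sd(x) * 0.2
  expect_equal(unname(eta_shrinkage(cbind(ksyn_gfr0 = x),
                                    c(ksyn_gfr0 = 0.04))), 0,
               tolerance = 1e-9)
  expect_equal(unname(eta_shrinkage(cbind(ksyn_gfr0 = x / 2),
                                    c(ksyn_gfr0 = 0.04))), 50,
               tolerance = 1e-9)
  expect_true(is.na(eta_shrinkage(cbind(gamma = x), c(gamma = 0))))
  expect_equal(cv_percent(0.413), 71.5, tolerance = 0.01)
  expect_equal(cv_percent(0.168), 42.8, tolerance = 0.01)
  expect_equal(cv_percent(0), 0)
  expect_error(cv_percent(-0.1), ">= 0")
})

test_that("information adds up: duplicating the data shrinks SEs by
           sqrt(2)", {
  m <- flat_model(sigma2 = 0.0227,
                  fixed = c("qmax_uf", "k", "pna_p", "ksyn_gfr0",
                            "gfrss_gfr0", "pna50", "gamma"))
  coh <- generate_cohort(40, seed = 77)
  dat <- generate_observations(coh, m, config = idms_only, seed = 78)
  fit1 <- scr_fit(dat, m, compute_se = TRUE)
  df <- as.data.frame(dat)
  df2 <- df
  df2$ID <- df2$ID + max(df$ID)
  both <- scr_dataset(rbind(df, df2))
  fit2 <- scr_fit(both, m, compute_se = TRUE)
  expect_equal(unname(fit2$se["sigma2"] / fit1$se["sigma2"]),
               1 / sqrt(2), tolerance = 0.05)
  # fixed parameters carry no SE entries
  expect_false(any(grepl("pna50|gamma|gfrss", names(fit1$se))))
})
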