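test_that("EBE-covariate screening ranks by squared correlation", {
  covs <- data.frame(ga = c(38, 39, 40, 41, 39, 38),
                     aki = c(0, 1, 0, 1, 0, 0))
  # constant EBEs: nothing correlates
  none <- screen_covariates(cbind(pna50 = rep(0, 6)), covs)
  expect_true(all(!none$candidate))
  # EBE an exact linear function of gestational age
  lin <- screen_covariates(cbind(pna50 = (covs$ga - 39) / 2), covs)
  expect_equal(lin$r2[lin$covariate == "ga"], 1)
  expect_true(lin$candidate[lin$covariate == "ga"])
  # zero-variance covariates are excluded with a warning
  expect_warning(
    z <- screen_covariates(cbind(pna50 = rnorm(6)),
                           data.frame(death = rep(0, 6))),
    "zero variance")
  expect_true(all(!z$candidate))
})

test_that("a simulated AKI shift on ksyn survives the r2 > 0.1 screen", {
  truth <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227,
                      fixed = c("qmax_uf", "k", "pna_p", "gfrss_gfr0",
                                "pna50", "gamma"))
  truth$effects <- c(truth$effects,
                     list(effect_split("ksyn_gfr0", "aki",
                                       c("0" = 0.631, "1" = 0.785))))
  coh <- generate_cohort(300, config = list(aki_prev = 0.3), seed = 80)
  dat <- generate_observations(coh, truth, config = idms_only, seed = 81)
  # base model without the covariate: its EBEs absorb the AKI shift
  base <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227,
                     fixed = truth$fixed)
  fit <- scr_fit(dat, base)
  sc <- screen_covariates(fit$ebes,
                          as.data.frame(coh)[c("ga", "aki", "death")],
                          r2_threshold = 0.1)
  row <- sc[sc$parameter == "ksyn_gfr0" & sc$covariate == "aki", ]
  expect_gt(row$r2, 0.1)
  expect_true(row$candidate)
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  # 10.83 sits just above the df=1 critical value at alpha 0.001
  r <- lrt(110.83, 100, df = 1, alpha = 0.001)
  expect_true(r$significant)
  expect_equal(r$chi2, 10.83)
  expect_equal(r$p, pchisq(10.83, 1, lower.tail = FALSE))
  expect_lt(qchisq(0.999, 1), 10.83)
  # zero change is never significant
  r0 <- lrt(100, 100, df = 1)
  expect_equal(r0$p, 1)
  expect_false(r0$significant)
  # 15.14 on 2 df clears the 13.816 critical value
  r2 <- lrt(115.14, 100, df = 2, alpha = 0.001)
  expect_true(r2$significant)
  expect_lt(qchisq(0.999, 2), 15.14)
  expect_gt(qchisq(0.999, 2), 13.8)
  # a better-fitting reduced model violates nesting
  expect_error(lrt(100, 100.5, df = 1), "nested")
})

test_that("covariate terms add and drop with correct degrees of freedom", {
  m <- flat_model(omega2 = c(pna50 = 0.22), sigma2 = 0.0227)
  m1 <- add_covariate_term(m, "pna50", "aki")
  expect_equal(attr(m1, "df"), 1L)
  expect_error(add_covariate_term(m1, "pna50", "aki"), "already split")
  m2 <- add_covariate_term(m1, "pna50", "death")
  expect_equal(attr(m2, "df"), 2L)   # 2 levels -> 4 levels
  ef <- m2$effects[[length(m2$effects)]]
  expect_setequal(names(ef$levels), c("0:0", "1:0", "0:1", "1:1"))
  m3 <- drop_covariate_term(m2, "pna50", "death")
  expect_equal(attr(m3, "df"), -2L)
  m4 <- drop_covariate_term(m3, "pna50", "aki")
  expect_equal(attr(m4, "df"), -1L)
  expect_length(m4$effects, length(m$effects))
})

test_that("forward-backward selection finds a simulated PNA50 AKI effect
           and stays deterministic", {
  truth <- flat_model(omega2 = c(pna50 = 0.10), sigma2 = 0.0227,
                      fixed = c("qmax_uf", "k", "pna_p", "ksyn_gfr0",
                                "gfrss_gfr0", "gamma"))
  truth$effects <- c(truth$effects,
                     list(effect_split("pna50", "aki",
                                       c("0" = 1.94, "1" = 6.21))))
  coh <- generate_cohort(150, config = list(aki_prev = 0.3,
                                            death_prev = 0.3), seed = 82)
  dat <- generate_observations(coh, truth,
    config = utils::modifyList(idms_only,
                               list(n_obs_min = 4, n_obs_max = 8,
                                    n_obs_mean = 5)), seed = 83)
  base <- flat_model(omega2 = c(pna50 = 0.10), sigma2 = 0.0227,
                     fixed = truth$fixed)
  cands <- data.frame(parameter = c("pna50", "pna50"),
                      covariate = c("aki", "death"))
  sel <- forward_backward_select(base, cands, dat)
  expect_true("pna50~aki" %in% sel$included)
  expect_false("pna50~death" %in% sel$included)
  expect_lte(sel$final_fit$ofv, sel$base_ofv)
  # accepted additions were significant at alpha_in
  acc <- sel$steps[sel$steps$accepted & sel$steps$phase == "forward", ]
  expect_true(all(acc$p_value < 0.001))
  sel2 <- forward_backward_select(base, cands, dat)
  expect_identical(sel$steps, sel2$steps)
  expect_identical(sel$included, sel2$included)
})

test_that("selection degenerates correctly without candidates or with
           alpha_in = 0", {
  m <- flat_model(omega2 = c(ksyn_gfr0 = 0.0180), sigma2 = 0.0227,
                  fixed = c("qmax_uf", "k", "pna_p", "gfrss_gfr0",
                            "pna50", "gamma"))
  coh <- generate_cohort(40, seed = 84)
  dat <- generate_observations(coh, m, config = idms_only, seed = 85)
  none <- forward_backward_select(m, data.frame(parameter = character(0),
                                                covariate = character(0)),
                                  dat)
  expect_identical(nrow(none$steps), 0L)
  expect_length(none$included, 0)
  cands <- data.frame(parameter = "ksyn_gfr0", covariate = "aki")
  frozen <- forward_backward_select(m, cands, dat, alpha_in = 0)
  expect_length(frozen$included, 0)
})
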