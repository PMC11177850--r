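test_that("assay conversion is the published linear recalibration", {
  expect_equal(jaffe_to_idms(0), 0.057)
  expect_equal(jaffe_to_idms(1.0), 1.060)
  x <- seq(0, 3, by = 0.1)
  expect_true(all(diff(jaffe_to_idms(x)) > 0))
  expect_error(jaffe_to_idms(-0.1), ">= 0")
  # SI display conversion
  expect_equal(scr_to_umol(1), 88.4)
})

test_that("cohort margins match the configured prevalences", {
  coh <- generate_cohort(975, seed = 20)
  # +-3 SD binomial bracket around the study AKI count
  expect_gte(sum(coh$aki), 56)
  expect_lte(sum(coh$aki), 103)
  expect_true(all(coh$ga >= 34 & coh$ga <= 42))
  expect_equal(median(coh$ga), 39)
  expect_true(all(coh$bwt > 0))
  expect_identical(nrow(generate_cohort(0)), 0L)
  all_aki <- generate_cohort(50, config = list(aki_prev = 1), seed = 1)
  expect_true(all(all_aki$aki == 1))
  expect_error(generate_cohort(10, config = list(aki_prev = 1.5)),
               "prevalence")
})

test_that("observation generator reproduces the residual-error model", {
  m <- flat_model(sigma2 = 0)
  coh <- generate_cohort(40, seed = 21)
  dat <- generate_observations(coh, m, config = idms_only, seed = 22)
  # no residual error: observations sit exactly on the structural curve
  pred <- vapply(seq_len(nrow(dat)), function(r) {
    scr_value(dat$TIME[r], th_typ())
  }, numeric(1))
  expect_equal(dat$DV, pred, tolerance = 1e-12)
  # moment recovery of the residual variance
  m2 <- flat_model(sigma2 = 0.0227)
  big <- generate_cohort(21000, seed = 23)
  datb <- generate_observations(big, m2, config = idms_only, seed = 24)
  predb <- scr_value(datb$TIME, th_typ())
  expect_equal(var(log(datb$DV / predb)), 0.0227, tolerance = 0.03)
  # log residuals pass a normality sanity check
  lr <- log(datb$DV / predb)
  skew <- mean((lr - mean(lr))^3) / sd(lr)^3
  expect_lt(abs(skew), 0.1)
})

test_that("generation is reproducible under a fixed seed", {
  m <- scr_model_th_final()
  coh <- generate_cohort(30, seed = 30)
  d1 <- generate_observations(coh, m, seed = 31)
  d2 <- generate_observations(coh, m, seed = 31)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("inclusion filters implement the published data-preparation rules",
{
  mk <- function(id, dv, ga, assay = "idms")
    data.frame(ID = id, TIME = seq_along(dv), DV = dv, MDV = 0L,
               ASSAY = assay, GA = ga, BWT = 3300, AKI = 0, DEATH = 0)
  ds <- scr_dataset(rbind(
    mk(1, c(0.9, 0.7), 39),
    mk(2, c(0.8, 2.5), 39),          # one value above 2 mg/dL
    mk(3, c(0.9, 0.8), 43),          # GA above 42 weeks
    mk(4, c(0.9, 0.8), 38, "unknown"),
    mk(5, c(0.843, 0.743), 40, "jaffe")))
  out <- apply_inclusion_filters(ds)
  expect_setequal(unique(out$ID), c(1, 5))
  # jaffe values converted before thresholding
  expect_equal(out$DV[out$ID == 5], jaffe_to_idms(c(0.843, 0.743)))
  expect_true(all(out$ASSAY == "idms"))
  prov <- attr(out, "provenance")
  expect_true(all(diff(prov$n_subjects) <= 0))
  expect_true(all(diff(prov$n_obs) <= 0))
  # observation-level alternative keeps subject 2 minus the bad row
  out2 <- apply_inclusion_filters(ds, scr_filter = "observation")
  expect_setequal(unique(out2$ID), c(1, 2, 5))
  expect_equal(sum(out2$ID == 2), 1L)
  # a compliant dataset passes unchanged, and filtering is idempotent
  clean <- scr_dataset(mk(1, c(0.9, 0.7), 39))
  once <- apply_inclusion_filters(clean)
  expect_equal(as.data.frame(once), as.data.frame(clean))
  twice <- apply_inclusion_filters(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("jaffe-assay conversion round-trips through the generator", {
  m <- flat_model(sigma2 = 0)
  coh <- generate_cohort(60, seed = 40)
  dat <- generate_observations(coh, m,
    config = list(assay_probs = c(jaffe = 1, idms = 0, unknown = 0)),
    seed = 41)
  out <- apply_inclusion_filters(dat)
  pred <- scr_value(out$TIME, th_typ())
  expect_equal(out$DV, pred, tolerance = 1e-6)
})
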