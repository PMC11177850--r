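test_that("back-flow profile peaks at pna_p with height qmax_uf", {
  expect_equal(backflow_q(2.42, 0.575, 0.709, 2.42), 0.575)
  # one Gaussian standard deviation (1/k) from the peak
  expect_equal(backflow_q(2.42 + 1 / 0.709, 0.575, 0.709, 2.42),
               0.575 * exp(-1 / 2))
  expect_equal(backflow_q(1, 0.575, 0.709, 2.42), 0.3464, tolerance = 1e-4)
  # maximum over a dense grid is attained at the peak
  grid <- seq(0, 10, by = 0.001)
  expect_equal(max(backflow_q(grid, 0.575, 0.709, 2.42)), 0.575,
               tolerance = 1e-6)
  expect_error(backflow_q(-0.1, 0.575, 0.709, 2.42), "pna")
})

test_that("back-flow is symmetric about its peak", {
  d <- seq(0, 2, by = 0.25)
  expect_equal(backflow_q(2.42 + d, 0.575, 0.709, 2.42),
               backflow_q(2.42 - d, 0.575, 0.709, 2.42))
})

test_that("GFR maturation is 1 at birth, half-maximal at pna50, monotone", {
  expect_identical(gfr_ratio(0, 1.74, 1.94, 4.46), 1)
  expect_equal(gfr_ratio(1.94, 1.74, 1.94, 4.46), (1 + 1.74) / 2)
  expect_equal(gfr_ratio(6, 1.74, 1.94, 4.46), 1.7352, tolerance = 1e-4)
  g <- gfr_ratio(seq(0, 20, by = 0.01), 1.74, 1.94, 4.46)
  expect_true(all(diff(g) >= 0))
  # steep Hill coefficients must not overflow
  expect_equal(gfr_ratio(10, 1.74, 6.21, 80), 1.74, tolerance = 1e-6)
  expect_error(gfr_ratio(-1, 1.74, 1.94, 4.46), "pna")
})

test_that("sCr composes back-flow, synthesis and filtration", {
  p39 <- scr_params(qmax_uf = 0.62413, k = 0.709, pna_p = 1.5523,
                    ksyn_gfr0 = 0.631, gfrss_gfr0 = 1.74, pna50 = 1.94,
                    gamma = 4.46)
  expect_equal(scr_value(1, p39), 0.9606, tolerance = 1e-4)
  # steady state: back-flow gone, GFR at plateau
  p <- th_typ()
  far <- p[["pna_p"]] + 20 / p[["k"]] + 20 * p[["pna50"]]
  expect_equal(scr_value(far, p), 0.631 / 1.74, tolerance = 1e-6)
  # no back-flow: pure synthesis over filtration
  p0 <- p
  p0[["qmax_uf"]] <- 1e-300   # numerically zero back-flow
  expect_equal(scr_value(3, p0),
               0.631 / gfr_ratio(3, 1.74, 1.94, 4.46), tolerance = 1e-10)
  expect_true(all(scr_value(seq(0, 10, 0.5), p) > 0))
})

test_that("continuous covariate adjustment matches both published forms", {
  expect_equal(apply_continuous_covariate(0.575, 0.0178, 34.2), 0.575)
  expect_equal(apply_continuous_covariate(0.575, 0.0178, 39), 0.62413,
               tolerance = 1e-4)
  expect_equal(apply_continuous_covariate(2.42, -0.0747, 39,
                                          form = "additive"), 2.0614,
               tolerance = 1e-4)
  # slope zero is the identity for any gestational age
  ga <- seq(24, 42, by = 0.5)
  expect_equal(apply_continuous_covariate(1.94, 0, ga), rep(1.94,
                                                            length(ga)))
  expect_error(apply_continuous_covariate(0.5, -1, 44), "non-positive")
})

test_that("dichotomous splits return level-specific typical values", {
  sp <- effect_split("pna50", "aki", c("0" = 1.94, "1" = 6.21))
  expect_equal(apply_categorical_covariate(sp, list(aki = 1)), 6.21)
  ks <- effect_split("ksyn_gfr0", c("aki", "death"),
                     c("0:0" = 0.631, "1:0" = 0.785, "0:1" = 0.750,
                       "1:1" = 0.834))
  expect_equal(apply_categorical_covariate(ks, list(aki = 0, death = 1)),
               0.750)
  same <- effect_split("gamma", "death", c("0" = 4.46, "1" = 4.46))
  expect_equal(apply_categorical_covariate(same, list(death = 0)),
               apply_categorical_covariate(same, list(death = 1)))
  expect_error(effect_split("pna50", "aki", c("0" = 1.94)), "combination")
})

test_that("typical-value resolution applies splits before linear effects", {
  m <- scr_model_th_final()
  cov <- data.frame(ga = c(39, 39, 34.2), aki = c(0, 1, 1),
                    death = c(0, 0, 1))
  typ <- resolve_typicals(m, cov)
  expect_equal(typ[, "qmax_uf"], rep(c(0.62413, 0.575), c(2, 1)),
               tolerance = 1e-4)
  expect_equal(unname(typ[1, "pna_p"]), 2.42 * (1 - 0.0747 * 4.8))
  expect_equal(typ[, "pna50"], c(1.94, 6.21, 6.21))
  expect_equal(typ[, "ksyn_gfr0"], c(0.631, 0.785, 0.834))
  # additive reading of the pna_p slope
  ma <- scr_model_th_final(covariate_form = "additive")
  expect_equal(unname(resolve_typicals(ma, cov)[1, "pna_p"]),
               2.42 - 0.0747 * 4.8)
})
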