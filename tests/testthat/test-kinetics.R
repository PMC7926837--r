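test_that("two-sample fit is exact: one halving over 20 h", {
  fit <- fit_monoexp(new_tac(c(4, 24), c(8, 4)))
  expect_equal(fit$half_life_h, 20)
  expect_equal(fit$lambda_per_h, log(2) / 20)
  expect_equal(fit$A0_Bq_per_ml, 8 * 2^(4 / 20))
  expect_equal(fit$r_squared, 1)
  expect_false(fit$degenerate)
  expect_equal(unname(coef(fit)["lambda_per_h"]), log(2) / 20)
  expect_equal(predict(fit, c(4, 24)), c(8, 4))
})

test_that("constant samples fit as degenerate with no clearance", {
  fit <- fit_monoexp(new_tac(c(4, 24, 48), c(7, 7, 7)))
  expect_equal(fit$lambda_per_h, 0)
  expect_true(fit$degenerate)
  expect_identical(fit$half_life_h, Inf)
})

test_that("three-sample fit matches an independent log-linear regression", {
  # clinical distant-node TAC: (4, 33.56), (24, 14.36), (48, 9.8)
  t <- c(4, 24, 48); y <- c(33.56, 14.36, 9.8)
  oracle <- stats::lm(log(y) ~ t)
  fit <- fit_monoexp(new_tac(t, y))
  expect_equal(fit$lambda_per_h, -unname(coef(oracle)[2]), tolerance = 1e-12)
  expect_equal(fit$A0_Bq_per_ml, exp(unname(coef(oracle)[1])),
               tolerance = 1e-12)
  # frozen value from the regression: lambda_eff = 0.0276 to 3 sig figs
  expect_equal(signif(fit$lambda_per_h, 3), 0.0276)
})

test_that("fit rejects unusable inputs", {
  expect_error(fit_monoexp(new_tac(4, 10)), ">= 2")
  expect_error(fit_monoexp(data.frame(time_h = c(4, 24),
                                      conc_Bq_per_ml = c(1, 0))),
               "positive")
  expect_error(new_tac(c(4, 4), c(1, 1)), "increasing")
  expect_error(new_tac(c(4, 24), c(-1, 1)), ">= 0")
})

test_that("extract_tac reduces maps by the requested statistic", {
  ph <- build_phantom(sphere_spec(A0 = 1000, lambda = log(2) / 24,
                                  fwhm = 0))
  tac_mean <- extract_tac(ph, ph$masks$s, "mean")
  tac_max <- extract_tac(ph, ph$masks$s, "max")
  # closed form: samples in ratio 2^(-4/24) : 2^(-1) : 2^(-2) of A0
  expect_equal(tac_mean$conc_Bq_per_ml, 1000 * 2^(-c(4, 24, 48) / 24))
  expect_equal(tac_max$conc_Bq_per_ml, tac_mean$conc_Bq_per_ml)

  # blurred small sphere: max exceeds mean
  phb <- build_phantom(sphere_spec(radius_mm = 5, fwhm = 10))
  tb_mean <- extract_tac(phb, phb$masks$s, "mean")
  tb_max <- extract_tac(phb, phb$masks$s, "max")
  expect_true(all(tb_max$conc_Bq_per_ml > tb_mean$conc_Bq_per_ml))

  empty <- region_mask(array(FALSE, dim(ph$maps[[1]]$values)), "e",
                       "lesion", 1.95)
  expect_error(extract_tac(ph, empty), "empty")
})

test_that("global mono-exponential TIA equals A0 / lambda on analytic TACs", {
  for (hl in c(12, 24, 60)) {
    lam <- log(2) / hl
    tac <- new_tac(c(4, 24, 48), 1000 * exp(-lam * c(4, 24, 48)))
    tia <- time_integrated_activity(tac, "monoexp_global")
    expect_lt(abs(tia - 1000 / lam) / (1000 / lam), 1e-9)
  }
})

test_that("single-time-point estimator is exact when sampled at the half-life", {
  lam <- log(2) / 24
  tia_1p <- time_integrated_activity(new_tac(24, 1000 * exp(-lam * 24)),
                                     "single_time_point")
  expect_equal(tia_1p, 1000 / lam, tolerance = 1e-12)
  expect_error(time_integrated_activity(new_tac(c(4, 24), c(2, 1)),
                                        "single_time_point"), "exactly one")
})

test_that("piecewise TIA matches a fine-step quadrature of its own model", {
  lam <- log(2) / 24
  t <- c(4, 24, 48); y <- 1000 * exp(-lam * t)
  tia <- time_integrated_activity(new_tac(t, y), "piecewise_exp")

  # independent oracle: trapezoid at 0.01 h over the defined interpolant
  # (linear rise, exponential segments, mono-exponential tail)
  interp <- function(x) {
    if (x <= t[1]) return(y[1] * x / t[1])
    for (i in 1:2) if (x <= t[i + 1]) {
      l <- log(y[i] / y[i + 1]) / (t[i + 1] - t[i])
      return(y[i] * exp(-l * (x - t[i])))
    }
    l_tail <- log(y[2] / y[3]) / (t[3] - t[2])
    y[3] * exp(-l_tail * (x - t[3]))
  }
  xs <- seq(0, 2000, by = 0.01)
  fx <- vapply(xs, interp, 0)
  oracle <- sum((fx[-1] + fx[-length(fx)]) / 2) * 0.01
  expect_lt(abs(tia - oracle) / oracle, 1e-3)

  # against the closed form the deficit is the linear 0->4 h rise: ~5.8%
  expect_equal(tia / (1000 / lam), 1 - 0.0576, tolerance = 0.002)
  # plateau uptake halves that deficit's source by doubling the rise area
  tia_plateau <- time_integrated_activity(new_tac(t, y), "piecewise_exp",
                                          uptake = "plateau")
  expect_gt(tia_plateau, tia)
})

test_that("piecewise scheme truncates at an exact-zero final sample", {
  tia <- time_integrated_activity(new_tac(c(4, 24), c(10, 0)),
                                  "piecewise_exp")
  # linear rise (20) + linear down-segment to zero (100), no tail
  expect_equal(tia, 0.5 * 4 * 10 + 0.5 * 20 * 10)
  expect_error(time_integrated_activity(new_tac(c(4, 24, 48), c(10, 0, 5)),
                                        "piecewise_exp"), "positive")
})

test_that("extrapolated decay constants are clamped at physical decay", {
  kc <- lu177_constants()
  # rising tail: apparent lambda < 0 must clamp to lambda_phys
  t <- c(4, 24, 48); y <- c(5, 6, 8)
  tia <- time_integrated_activity(new_tac(t, y), "piecewise_exp")
  rise <- 0.5 * 4 * 5
  seg <- function(i) (y[i] - y[i + 1]) /
    (log(y[i] / y[i + 1]) / (t[i + 1] - t[i]))
  expect_equal(tia, rise + seg(1) + seg(2) + 8 / kc$lambda_phys_per_h)
  expect_error(time_integrated_activity(new_tac(t, y), "piecewise_exp",
                                        clamp_to_physical = FALSE),
               "diverges")
  # flat TAC under the global scheme also clamps
  tia_g <- time_integrated_activity(new_tac(t, c(5, 5, 5)), "monoexp_global")
  expect_equal(tia_g, 5 / kc$lambda_phys_per_h)
})

test_that("TIA is linear under uniform scaling of the TAC", {
  t <- c(4, 24, 48); y <- c(30, 14, 9)
  for (scheme in c("piecewise_exp", "monoexp_global")) {
    tia1 <- time_integrated_activity(new_tac(t, y), scheme)
    tia3 <- time_integrated_activity(new_tac(t, 3 * y), scheme)
    expect_equal(tia3, 3 * tia1, tolerance = 1e-12)
  }
})

test_that("effective half-life inverts the decay constant", {
  kc <- lu177_constants()
  expect_equal(effective_half_life(kc$lambda_phys_per_h), 6.647 * 24)
  expect_equal(effective_half_life(log(2) / 24), 24)
  expect_equal(effective_half_life(2 * log(2) / 24), 12)
  expect_error(effective_half_life(0), "> 0")
  fit <- fit_monoexp(new_tac(c(4, 24), c(8, 4)))
  expect_equal(effective_half_life(fit), 20)
})

test_that("noiseless phantom TACs recover the generating parameters", {
  lam <- log(2) / 30
  ph <- build_phantom(sphere_spec(radius_mm = 8, A0 = 2000, lambda = lam,
                                  fwhm = 0))
  fit <- fit_monoexp(extract_tac(ph, ph$masks$s))
  expect_lt(abs(fit$lambda_per_h - lam) / lam, 1e-3)
  expect_lt(abs(fit$A0_Bq_per_ml - 2000) / 2000, 1e-3)
})
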