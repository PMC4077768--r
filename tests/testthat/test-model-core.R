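k <- model_constants()
pp <- promoter_presets()

test_that("default constants reproduce the published simulation values", {
  expect_equal(k$mu_max, 1.7)
  expect_equal(k$gamma, 0.041)
  expect_equal(k$K_s, 8)
  expect_equal(k$K_c, 0.06)
  expect_equal(k$hill_h, 2)
  expect_equal(k$K_p, 3)
  expect_equal(k$alpha_d, 3.5e-6)
  expect_equal(k$alpha_c, 0.75)
  expect_equal(k$beta, 1)
  expect_error(model_constants(mu_max = -1), "positive")
  expect_error(model_constants(hill_h = 0.5))
})

test_that("growth rate saturates at mu_max and halves at each half-point", {
  sat <- growth_rate(1e12, 0, 0, k)
  expect_equal(sat, k$mu_max, tolerance = 1e-9)
  expect_equal(growth_rate(k$K_s, 0, 0, k), sat / 2, tolerance = 1e-9)
  expect_equal(growth_rate(1e12, k$K_c, 0, k), sat / 2, tolerance = 1e-9)
  expect_equal(growth_rate(1e12, 0, k$K_p, k), sat / 2, tolerance = 1e-9)
  # all three factors at their half-points: 1.7 / 8
  expect_equal(growth_rate(8, 0.06, 3, k), 0.2125)
  expect_error(growth_rate(-1, 0, 0, k), "non-negative")
})

test_that("growth rate is monotone in each argument", {
  S <- seq(0.5, 30, length.out = 20)
  expect_true(all(diff(growth_rate(S, 0.02, 1, k)) > 0))
  ci <- seq(0, 0.5, length.out = 20)
  expect_true(all(diff(growth_rate(10, ci, 1, k)) < 0))
  p <- seq(0, 10, length.out = 20)
  expect_true(all(diff(growth_rate(10, 0.02, p, k)) < 0))
})

test_that("pump rate implements the three controller laws", {
  # basal expression only at p = 0
  expect_equal(pump_rate(pp$promoterless, 0.3, 0, k), 0.014)
  # constitutive: alpha_p0 + alpha_p regardless of IL
  expect_equal(pump_rate(pp$PlacUV5, 0, 0, k), 0.34)
  expect_equal(pump_rate(pp$PlacUV5, 0.5, 0, k), 0.34)
  # promoterless independent of c_i
  expect_equal(pump_rate(pp$promoterless, 0, 1, k),
               pump_rate(pp$promoterless, 0.4, 1, k))
  # dynamic: half-maximal induction at gamma_c
  ps <- pp$PydfO
  expect_equal(pump_rate(ps, ps$gamma_c, 0, k), ps$alpha_p0 + ps$alpha_p / 2)
  # decay gives a signed rate
  expect_lt(pump_rate(pp$promoterless, 0, 1, k), 0)
  expect_error(promoter_spec("dynamic", alpha_p0 = 0.1, alpha_p = 0.2),
               "gamma_c")
})

test_that("dynamic pump rate increases in c_i and is bounded by full induction", {
  ps <- pp$PmarR
  ci <- seq(0, 0.5, length.out = 30)
  r <- pump_rate(ps, ci, 0.2, k)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < ps$alpha_p0 + ps$alpha_p - k$beta * 0.2))
})

test_that("intracellular volume is linear in biomass", {
  expect_equal(intracellular_volume(0, k), 0)
  v1 <- intracellular_volume(0.2, k)
  expect_equal(intracellular_volume(0.4, k), 2 * v1)
  # hand arithmetic: 0.4 g/L * 1 L / 3e-13 g * 1e-15 L
  expect_equal(intracellular_volume(0.4, k), 0.4 / 3e-13 * 1e-15,
               tolerance = 1e-12)
})

test_that("extracellular IL derives from the mass balance", {
  expect_equal(extracellular_il(0.4, 0, 1e-3, k), 0.4 / (1 - 1e-3))
  expect_equal(extracellular_il(0, 0, 1e-3, k), 0)
  # hand arithmetic: (0.4 - 0.1 * 1e-3) / 0.999
  expect_equal(extracellular_il(0.4, 0.1, 1e-3, k), 0.3999 / 0.999,
               tolerance = 1e-12)
  expect_error(extracellular_il(0.4, 0, 2, k), "culture volume")
  expect_warning(extracellular_il(0.1, 0.5, 0.9, k), "clipped")
})

test_that("IL exchange rate has the diffusion and export terms", {
  expect_equal(il_rate(0.1, 0.1, 0, 1e-3, 0.999, k), 0)
  expect_gt(il_rate(0, 0.4, 0, 1e-3, 0.999, k), 0)
  # export term alone: alpha_c * p * c_i = 0.75 * 1 * 0.1
  no_grad <- il_rate(0.1, 0.1, 1, 1e-3, 0.999, k)
  expect_equal(no_grad, -0.075)
  expect_error(il_rate(0.1, 0.1, 0, 0, 0.999, k), "V_i")
})

test_that("the assembled rhs matches its independently summed terms", {
  ps <- pp$PmarR
  y <- c(N = 0.1, S = 4, p = 0.3, c_i = 0.05)
  total_il <- 0.2
  parms <- list(constants = k, promoter = ps, total_il = total_il)
  d <- model_rhs(0, y, parms)[[1L]]
  V_i <- intracellular_volume(y[["N"]], k)
  V_e <- k$culture_volume - V_i
  c_e <- extracellular_il(total_il, y[["c_i"]], V_i, k)
  mu <- growth_rate(y[["S"]], y[["c_i"]], y[["p"]], k)
  expect_equal(d[1L], mu * y[["N"]])
  expect_equal(d[2L], -mu * y[["N"]] / k$gamma)
  expect_equal(d[3L], pump_rate(ps, y[["c_i"]], y[["p"]], k))
  expect_equal(d[4L], il_rate(y[["c_i"]], c_e, y[["p"]], V_i, V_e, k))
  expect_true(all(is.finite(d)))
})

test_that("rhs handles exhausted substrate and fixed points", {
  parms <- list(constants = k, promoter = pp$PlacUV5, total_il = 0)
  d0 <- model_rhs(0, c(N = 0.4, S = 0, p = 0.34, c_i = 0), parms)[[1L]]
  expect_equal(d0[1L], 0)   # no substrate, no growth
  expect_equal(d0[2L], 0)
  # constitutive steady state p* = (alpha_p0 + alpha_p) / beta
  expect_equal(d0[3L], 0)
})

test_that("config round-trips constants and promoters through YAML and JSON", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("constants:", "  mu_max: 2.1", "  K_s: 5",
               "promoters:", "  test:", "    kind: dynamic",
               "    alpha_p0: 0.1", "    alpha_p: 0.5",
               "    gamma_c: 0.01"), tmp)
  cfg <- read_model_config(tmp)
  expect_equal(cfg$constants$mu_max, 2.1)
  expect_equal(cfg$constants$K_s, 5)
  expect_equal(cfg$constants$gamma, 0.041)  # default preserved
  expect_equal(cfg$promoters$test$gamma_c, 0.01)
  tmp2 <- tempfile(fileext = ".json")
  writeLines('{"constants": {"K_c": 0.1}}', tmp2)
  cfg2 <- read_model_config(tmp2)
  expect_equal(cfg2$constants$K_c, 0.1)
  expect_named(cfg2$promoters, names(promoter_presets()))
})
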