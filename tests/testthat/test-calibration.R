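k <- model_constants()
pp <- promoter_presets()
no_noise <- noise_model("multiplicative-lognormal", 0, 0)

test_that("growth kinetics are recovered from a noise-free curve", {
  gc <- gen_growth_curve(scenario(pp$promoterless, il_mM = 0, t_end = 16),
                         noise = no_noise, n_reps = 1)
  fit <- fit_growth_params(gc)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(k$mu_max, k$gamma, k$K_s), tolerance = 1e-8)
})

test_that("growth kinetics tolerate replicate measurement noise", {
  gc <- gen_growth_curve(scenario(pp$promoterless, il_mM = 0, t_end = 16,
                                  seed = 42L),
                         noise = noise_model("multiplicative-lognormal",
                                             0.05, 42L),
                         n_reps = 3)
  fit <- fit_growth_params(gc)
  expect_lt(abs(fit$estimates[["mu_max"]] - k$mu_max) / k$mu_max, 0.10)
})

test_that("degenerate growth curves are rejected", {
  flat <- growth_curve_data(seq(0, 5, by = 0.5), rep(0.01, 11))
  expect_error(fit_growth_params(flat), "flat|non-convergence")
  short <- growth_curve_data(c(0, 1, 2), c(0.01, 0.02, 0.04))
  expect_error(fit_growth_params(short), "insufficient")
  with_il <- growth_curve_data(seq(0, 5, by = 0.5), seq(0.01, 0.2,
                                                        length.out = 11),
                               il_mM = 100)
  expect_error(fit_growth_params(with_il), "zero-IL")
})

final_od_curve <- function(ils, constants = k, t_end = 20) {
  data.frame(il_mM = ils, final_od = vapply(ils, function(il) {
    tail(simulate_growth(scenario(pp$promoterless, il_mM = il, t_end = t_end,
                                  constants = constants),
                         times = c(0, t_end))$od, 1L)
  }, 0))
}

test_that("IL toxicity parameters are recovered from the dose response", {
  fb <- final_od_curve(seq(0, 400, by = 50))
  fit <- fit_il_toxicity(fb)
  expect_lt(abs(fit$estimates[["K_c"]] - k$K_c) / k$K_c, 0.10)
  expect_lt(abs(fit$estimates[["hill_h"]] - k$hill_h) / k$hill_h, 0.10)
})

test_that("fitted K_c scales with the IL axis", {
  ils <- seq(0, 400, by = 50)
  fit1 <- fit_il_toxicity(final_od_curve(ils))
  k2 <- model_constants(K_c = 2 * k$K_c)
  fb2 <- data.frame(il_mM = 2 * ils, final_od = vapply(2 * ils, function(il) {
    tail(simulate_growth(scenario(pp$promoterless, il_mM = il, t_end = 20,
                                  constants = k2), times = c(0, 20))$od, 1L)
  }, 0))
  fit2 <- fit_il_toxicity(fb2)
  expect_equal(fit2$estimates[["K_c"]] / fit1$estimates[["K_c"]], 2,
               tolerance = 1e-3)
})

test_that("toxicity fit flags uninformative or inverted dose responses", {
  flat <- data.frame(il_mM = c(0, 100, 200, 400), final_od = rep(1.03, 4))
  expect_error(fit_il_toxicity(flat), "unidentifiable")
  rising <- data.frame(il_mM = c(0, 100, 200, 400),
                       final_od = c(0.2, 0.4, 0.8, 1.0))
  expect_warning(try(fit_il_toxicity(rising), silent = TRUE),
                 "increases with IL")
  expect_error(fit_il_toxicity(flat[1:3, ]), "at least 4")
})

burden_sweep <- function(aps, constants = k) {
  lapply(aps, function(a) {
    ps <- promoter_spec("constitutive", alpha_p0 = 0.06, alpha_p = a)
    gen_growth_curve(scenario(ps, il_mM = 0, t_end = 16,
                              constants = constants),
                     noise = no_noise, n_reps = 1)
  })
}

test_that("pump burden K_p is recovered from the expression sweep", {
  aps <- c(0, 0.05, 0.1, 0.2, 0.3)
  fit <- fit_pump_burden(burden_sweep(aps), aps)
  expect_lt(abs(fit$estimates[["K_p"]] - k$K_p) / k$K_p, 0.15)
  # stronger expression lowers the early-time density for any finite K_p
  curves <- burden_sweep(c(0, 0.3))
  mid <- which.min(abs(curves[[1]]$times - 6))
  expect_gt(curves[[1]]$od600[mid, 1], curves[[2]]$od600[mid, 1])
})

test_that("burden-free sweeps are flagged at the K_p search bound", {
  aps <- c(0, 0.1, 0.3)
  ps0 <- promoter_spec("constitutive", alpha_p0 = 0, alpha_p = 0)
  base <- gen_growth_curve(scenario(ps0, il_mM = 0, t_end = 16),
                           noise = no_noise, n_reps = 1)
  same <- list(base, base, base)
  w <- capture_warnings(fit_pump_burden(same, aps, alpha_p0 = 0))
  expect_true(any(grepl("bound|burden", w)))
  expect_error(fit_pump_burden(same[1], aps[1]), "single")
})

test_that("promoter parameters round-trip through noiseless measurement grids", {
  for (nm in names(pp)) {
    truth <- pp[[nm]]
    got <- derive_promoter_params(gen_protein_measurement_grid(truth, k))
    expect_equal(got$kind, truth$kind)
    expect_equal(got$alpha_p0, truth$alpha_p0, tolerance = 1e-6)
    if (truth$alpha_p > 0) {
      expect_equal(got$alpha_p, truth$alpha_p, tolerance = 1e-6)
    } else {
      expect_equal(got$alpha_p, 0)
    }
    if (!is.null(truth$gamma_c)) {
      expect_equal(got$gamma_c, truth$gamma_c, tolerance = 1e-6)
    }
  }
})

test_that("basal rate equals beta times the zero-IL exponential level", {
  g <- gen_protein_measurement_grid(pp$PmarR, k)
  lev0 <- g$data$level[g$data$phase == "exponential" & g$data$il_mM == 0][1]
  d <- derive_promoter_params(g, beta = 1)
  expect_equal(d$alpha_p0, 1 * lev0)
  d2 <- derive_promoter_params(g, beta = 2)
  expect_equal(d2$alpha_p0, 2 * lev0)
})

test_that("flat induction responses and missing baselines raise errors", {
  g <- gen_protein_measurement_grid(pp$PmarR, k)
  g$data$level[g$data$phase == "exponential"] <-
    g$data$level[g$data$phase == "exponential" & g$data$il_mM == 0][1]
  expect_error(derive_promoter_params(g), "flat")
  g2 <- gen_protein_measurement_grid(pp$PmarR, k)
  g2$data <- g2$data[g2$data$il_mM != 0 | g2$data$phase != "exponential", ]
  expect_error(derive_promoter_params(g2), "zero-IL")
})

test_that("gamma_c estimation error shrinks with measurement noise", {
  errs <- vapply(1:20, function(s) {
    g <- gen_protein_measurement_grid(pp$PydfO, k, noise_sd = 0.01, seed = s)
    d <- derive_promoter_params(g)
    abs(d$gamma_c - 0.0075) / 0.0075
  }, 0)
  expect_lt(median(errs), 0.20)
  # interpolation fallback stays in the measured range
  g <- gen_protein_measurement_grid(pp$PydfA, k)
  gi <- derive_promoter_params(g, method = "interpolate")
  expect_gt(gi$gamma_c, 0)
  expect_lt(gi$gamma_c, 0.4)
})
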