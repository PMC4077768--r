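#' Growth-curve data container
#'
#' Replicated OD600 time series for one strain at one IL concentration,
#' as produced by a plate reader or by [gen_growth_curve()].
#'
#' @param times Time points (h), strictly increasing.
#' @param od600 Numeric vector (one replicate) or matrix with
#'   `length(times)` rows and one column per replicate.
#' @param il_mM IL concentration of the assay (mmol/L).
#' @param label Controller / strain label.
#' @return An object of class `il_growth_data`.
#' @export
growth_curve_data <- function(times, od600, il_mM = 0, label = "") {
  od600 <- as.matrix(od600)
  stopifnot(length(times) == nrow(od600), all(diff(times) > 0),
            all(od600 >= 0), il_mM >= 0)
  structure(list(times = as.numeric(times), od600 = od600,
                 il_mM = il_mM, label = label),
            class = "il_growth_data")
}

# Shared LM driver: residuals between observed replicate ODs and the
# model trajectory under a constants/promoter override.
.sim_od_at <- function(times, promoter, il_mM, constants, rtol, atol) {
  sc <- scenario(promoter, il_mM = il_mM, t_end = max(times),
                 constants = constants)
  simulate_growth(sc, times = times, rtol = rtol, atol = atol)$od
}

#' Fit growth kinetics (mu_max, gamma, K_s) to zero-IL growth curves
#'
#' Nonlinear least squares (Levenberg-Marquardt on log-parameters, so the
#' estimates stay positive) of the simulated OD600 trajectory against
#' replicated observations in the absence of IL. All remaining constants
#' are taken from `constants`; the strain's controller only contributes
#' its (small) basal pump burden.
#'
#' @param data An [growth_curve_data()] object with `il_mM = 0` and at
#'   least 5 time points.
#' @param constants An [model_constants()] object supplying everything not
#'   being fitted.
#' @param promoter Controller carried by the assayed strain (default: the
#'   promoterless preset).
#' @param start Optional named start values `c(mu_max=, gamma=, K_s=)`;
#'   defaults are data-driven (max log-slope, final-yield, `S0/2`).
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return A list of class `il_fit`: `estimates` (named vector),
#'   `residual_norm`, `converged`, `message`, `start`.
#' @export
fit_growth_params <- function(data, constants = model_constants(),
                              promoter = promoter_presets()$promoterless,
                              start = NULL, rtol = 1e-8, atol = 1e-10,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(inherits(data, "il_growth_data"))
  if (data$il_mM != 0) {
    stop("fit_growth_params expects zero-IL growth curves", call. = FALSE)
  }
  if (length(data$times) < 5L) {
    stop("insufficient data: need at least 5 time points", call. = FALSE)
  }
  odbar <- rowMeans(data$od600)
  if (max(odbar) - odbar[1L] < 0.05 * max(odbar[1L], .Machine$double.eps)) {
    stop("non-convergence: flat growth curve, kinetic parameters are not ",
         "identifiable", call. = FALSE)
  }
  if (is.null(start)) {
    lod <- log(pmax(odbar, 1e-12))
    slopes <- diff(lod) / diff(data$times)
    mu0 <- min(max(max(slopes), 0.1), 5)
    gamma0 <- min(max((max(odbar) - odbar[1L]) * constants$od_to_biomass /
                        constants$S0, 1e-3), 1)
    start <- c(mu_max = mu0, gamma = gamma0, K_s = constants$S0 / 2)
  }
  obs <- as.vector(data$od600)
  n_rep <- ncol(data$od600)
  resid_fn <- function(par) {
    kk <- constants
    kk$mu_max <- exp(par[1L]); kk$gamma <- exp(par[2L]); kk$K_s <- exp(par[3L])
    sim <- .sim_od_at(data$times, promoter, 0, kk, rtol, atol)
    obs - rep(sim, n_rep)
  }
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn, control = control)
  est <- exp(fit$par)
  names(est) <- c("mu_max", "gamma", "K_s")
  converged <- fit$info %in% 1:3
  if (!converged) {
    warning("growth fit did not converge (", fit$message,
            "); returning best iterate", call. = FALSE)
  }
  structure(list(estimates = est, residual_norm = sqrt(fit$deviance),
                 converged = converged, message = fit$message,
                 start = start),
            class = "il_fit")
}

#' Fit the IL toxicity parameters (K_c, hill_h) to final-biomass data
#'
#' Least-squares fit of simulated stationary-phase density against
#' observed final OD600 across IL concentrations. `K_c` is optimised on
#' the log scale; the Hill coefficient is box-constrained to [1, 6].
#'
#' In this model the substrate yield is IL-independent, so given unlimited
#' time every surviving culture reaches the same density; the dose response
#' of final biomass exists at the assay horizon, where inhibited cultures
#' have not yet caught up. The default horizon is the 20-h growth-assay
#' window.
#'
#' @param final_biomass Data frame with columns `il_mM` and `final_od`
#'   (>= 4 IL levels spanning the inhibition range).
#' @param constants,promoter,rtol,atol,control As in [fit_growth_params()].
#' @param t_end Horizon used to read off the end-of-assay density (h).
#' @param start Optional `c(K_c=, hill_h=)` start values; the default
#'   `K_c` start interpolates the IL level at half-maximal final OD, with
#'   `hill_h = 2`.
#' @return An `il_fit` list with `estimates = c(K_c, hill_h)`.
#' @export
fit_il_toxicity <- function(final_biomass, constants = model_constants(),
                            promoter = promoter_presets()$promoterless,
                            t_end = 20, start = NULL,
                            rtol = 1e-8, atol = 1e-10,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(is.data.frame(final_biomass),
            all(c("il_mM", "final_od") %in% names(final_biomass)))
  fb <- final_biomass[order(final_biomass$il_mM), ]
  if (nrow(fb) < 4L) {
    stop("need at least 4 IL levels to fit (K_c, hill_h)", call. = FALSE)
  }
  if (stats::sd(fb$final_od) < 1e-6 * max(abs(fb$final_od), 1e-12)) {
    stop("final biomass does not vary with IL: K_c is unidentifiable",
         call. = FALSE)
  }
  if (all(diff(fb$final_od) >= 0) && any(diff(fb$final_od) > 0)) {
    warning("final biomass increases with IL concentration: ",
            "inconsistent with an inhibition model", call. = FALSE)
  }
  resid_fn <- function(par) {
    kk <- constants
    kk$K_c <- exp(par[1L]); kk$hill_h <- par[2L]
    sim <- vapply(fb$il_mM, function(il) {
      tt <- c(0, t_end)
      utils::tail(.sim_od_at(tt, promoter, il, kk, rtol, atol), 1L)
    }, 0)
    fb$final_od - sim
  }
  if (is.null(start)) {
    half <- (max(fb$final_od) + min(fb$final_od)) / 2
    kc0_mM <- tryCatch(
      stats::approx(fb$final_od, fb$il_mM, xout = half, ties = "ordered")$y,
      error = function(e) NA_real_)
    if (!is.finite(kc0_mM) || kc0_mM <= 0) kc0_mM <- stats::median(fb$il_mM)
    # the end-of-assay dose response has flat plateaus, so seed the local
    # optimiser from a coarse global search
    grid <- expand.grid(K_c = kc0_mM / 1000 * c(0.2, 0.4, 0.7, 1, 1.5, 2.5),
                        hill_h = 1:6)
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum(resid_fn(c(log(grid$K_c[i]), grid$hill_h[i]))^2)
    }, 0)
    best <- which.min(sse)
    start <- c(K_c = grid$K_c[best], hill_h = grid$hill_h[best])
  }
  fit <- minpack.lm::nls.lm(par = c(log(start[["K_c"]]), start[["hill_h"]]),
                            fn = resid_fn,
                            lower = c(log(1e-6), 1), upper = c(log(100), 6),
                            control = control)
  est <- c(K_c = exp(fit$par[1L]), hill_h = fit$par[2L])
  converged <- fit$info %in% 1:3
  if (!converged) {
    warning("toxicity fit did not converge (", fit$message,
            "); returning best iterate", call. = FALSE)
  }
  structure(list(estimates = est, residual_norm = sqrt(fit$deviance),
                 converged = converged, message = fit$message,
                 start = start),
            class = "il_fit")
}

#' Fit the pump-burden half-saturation K_p from an expression-rate sweep
#'
#' Emulates the IPTG dose-response assay: growth curves recorded (without
#' IL) at several constitutive expression rates `alpha_p` are fitted
#' jointly by the single burden parameter `K_p`, minimising the squared
#' OD error across the whole sweep.
#'
#' @param curves List of [growth_curve_data()] objects, parallel to
#'   `alpha_p`.
#' @param alpha_p Non-basal expression rates of the sweep (pump units/h;
#'   at least 2 distinct levels, >= 3 recommended).
#' @param constants An [model_constants()] object.
#' @param alpha_p0 Basal rate of the construct used in the sweep.
#' @param upper Upper search bound for `K_p`; hitting it flags a
#'   burden-free dataset.
#' @param rtol,atol,control As in [fit_growth_params()].
#' @return An `il_fit` list with `estimates = c(K_p)`.
#' @export
fit_pump_burden <- function(curves, alpha_p, constants = model_constants(),
                            alpha_p0 = 0.06, upper = 1000,
                            rtol = 1e-8, atol = 1e-10,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(is.list(curves), length(curves) == length(alpha_p))
  if (length(unique(alpha_p)) < 2L) {
    stop("a single expression level cannot identify K_p", call. = FALSE)
  }
  if (length(unique(alpha_p)) < 3L) {
    warning("fewer than 3 expression levels: K_p estimate may be weak",
            call. = FALSE)
  }
  resid_fn <- function(par) {
    kk <- constants
    kk$K_p <- exp(par[1L])
    unlist(lapply(seq_along(curves), function(i) {
      ps <- promoter_spec("constitutive", alpha_p0 = alpha_p0,
                          alpha_p = alpha_p[i])
      sim <- .sim_od_at(curves[[i]]$times, ps, 0, kk, rtol, atol)
      as.vector(curves[[i]]$od600) - rep(sim, ncol(curves[[i]]$od600))
    }))
  }
  fit <- minpack.lm::nls.lm(par = log(constants$K_p), fn = resid_fn,
                            lower = log(1e-2), upper = log(upper),
                            control = control)
  est <- c(K_p = exp(fit$par[1L]))
  sse_upper <- sum(resid_fn(log(upper))^2)
  if (est >= 0.95 * upper || sse_upper <= fit$deviance * (1 + 1e-6)) {
    warning("K_p is unbounded above (burden-free data): the sweep shows no ",
            "measurable expression burden", call. = FALSE)
  }
  converged <- fit$info %in% 1:3
  if (!converged) {
    warning("pump-burden fit did not converge (", fit$message,
            "); returning best iterate", call. = FALSE)
  }
  structure(list(estimates = est, residual_norm = sqrt(fit$deviance),
                 converged = converged, message = fit$message,
                 start = c(K_p = constants$K_p)),
            class = "il_fit")
}

#' @export
print.il_fit <- function(x, ...) {
  cat("<il_fit>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$estimates, ...)
  cat("residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Protein measurement grid container
#'
#' Cat-normalised pump-protein levels measured at two growth phases over a
#' range of IL concentrations, the input of [derive_promoter_params()].
#'
#' @param df Data frame with columns `phase` (`"exponential"` /
#'   `"stationary"`), `il_mM`, `level` (relative units, >= 0) and
#'   optionally `replicate`.
#' @param kind Controller kind of the assayed construct (see
#'   [promoter_spec()]).
#' @param label Construct label.
#' @return An object of class `il_protein_grid`.
#' @export
protein_measurement_grid <- function(df, kind = c("promoterless",
                                                  "constitutive", "dynamic"),
                                     label = "") {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(df),
            all(c("phase", "il_mM", "level") %in% names(df)),
            all(df$phase %in% c("exponential", "stationary")),
            all(df$level >= 0))
  if (is.null(df$replicate)) df$replicate <- 1L
  structure(list(data = df, kind = kind, label = label),
            class = "il_protein_grid")
}

#' Derive promoter expression parameters from protein measurements
#'
#' Implements the measurement-based parameterisation of a controller:
#' \itemize{
#'   \item `alpha_p0` = `beta` times the exponential-phase level without
#'     IL (basal expression balances decay in steady state);
#'   \item `alpha_p` = `beta` times the average stationary-phase level,
#'     minus the basal rate (toggle `subtract_basal`);
#'   \item `gamma_c` (dynamic controllers) = the IL concentration at which
#'     the exponential-phase level reaches half of its maximum rise above
#'     basal.
#' }
#' Two estimators for `gamma_c` are available. `"invert"` (default)
#' inverts the saturating induction curve point-wise, using the
#' stationary-phase level as the saturating plateau; it is exact on
#' noise-free measurements and averages over the usable IL levels.
#' `"interpolate"` linearly interpolates the measured level-vs-IL curve at
#' the half-maximum level.
#'
#' @param grid An [protein_measurement_grid()] object. Must contain a
#'   zero-IL exponential-phase measurement; the dynamic derivation needs
#'   at least 3 exponential-phase IL levels.
#' @param beta Pump decay coefficient (1/h) used to convert steady-state
#'   levels back to expression rates.
#' @param subtract_basal Subtract `alpha_p0` from the stationary-derived
#'   total rate when setting `alpha_p` (default TRUE).
#' @param method `"invert"` or `"interpolate"` (for `gamma_c`).
#' @return An [promoter_spec()] object.
#' @examples
#' ps <- promoter_presets()$PydfO
#' g <- gen_protein_measurement_grid(ps, model_constants())
#' derive_promoter_params(g)$gamma_c   # recovers 0.0075 M
#' @export
derive_promoter_params <- function(grid, beta = 1, subtract_basal = TRUE,
                                   method = c("invert", "interpolate")) {
  stopifnot(inherits(grid, "il_protein_grid"), beta > 0)
  method <- match.arg(method)
  df <- grid$data
  agg <- stats::aggregate(level ~ phase + il_mM, data = df, FUN = mean)
  e <- agg[agg$phase == "exponential", ]
  s <- agg[agg$phase == "stationary", ]
  e <- e[order(e$il_mM), ]
  if (!any(e$il_mM == 0)) {
    stop("grid lacks the zero-IL exponential-phase measurement needed for ",
         "alpha_p0", call. = FALSE)
  }
  e0 <- e$level[e$il_mM == 0]
  alpha_p0 <- beta * e0
  if (nrow(s) == 0L) {
    stop("grid lacks stationary-phase measurements needed for alpha_p",
         call. = FALSE)
  }
  alpha_total <- beta * mean(s$level)
  alpha_p <- if (subtract_basal) alpha_total - alpha_p0 else alpha_total
  if (alpha_p < 0) {
    if (alpha_p < -1e-6 * max(alpha_total, 1e-12)) {
      warning("stationary-derived rate below basal; clamping alpha_p at 0",
              call. = FALSE)
    }
    alpha_p <- 0
  }
  kind <- grid$kind
  if (kind != "dynamic") {
    return(promoter_spec(kind, alpha_p0 = alpha_p0,
                         alpha_p = if (kind == "promoterless") 0 else alpha_p,
                         label = grid$label))
  }
  if (nrow(e) < 3L) {
    stop("dynamic derivation needs exponential-phase levels at >= 3 IL ",
         "concentrations", call. = FALSE)
  }
  full <- alpha_p / beta                 # saturating rise above basal
  inc <- e$level - e0
  if (max(inc) <= 1e-9 * max(e$level, 1e-12)) {
    stop("exponential-phase levels are flat in IL: gamma_c is undefined",
         call. = FALSE)
  }
  half_level <- e0 + full / 2
  if (max(e$level) < half_level) {
    stop("half-maximum level lies above the measured IL range: gamma_c ",
         "would require extrapolation", call. = FALSE)
  }
  c_M <- e$il_mM / 1000
  if (method == "invert") {
    usable <- c_M > 0 & inc > 0 & inc < full
    if (!any(usable)) {
      stop("no usable IL level to invert the induction curve", call. = FALSE)
    }
    gamma_c <- mean(c_M[usable] * (full / inc[usable] - 1))
    # refine by least squares on the induction curve: exact when the
    # point-wise estimates already agree, stabler under measurement noise
    sse <- function(lg) {
      g <- exp(lg)
      sum((inc[c_M > 0] - full * c_M[c_M > 0] / (g + c_M[c_M > 0]))^2)
    }
    opt <- stats::optimize(sse, interval = log(gamma_c) + c(-3, 3),
                           tol = 1e-12)
    gamma_c <- exp(opt$minimum)
  } else {
    gamma_c <- stats::approx(e$level, c_M, xout = half_level,
                             ties = "ordered")$y
  }
  promoter_spec("dynamic", alpha_p0 = alpha_p0, alpha_p = alpha_p,
                gamma_c = gamma_c, label = grid$label)
}
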