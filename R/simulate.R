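#' Define a simulation scenario
#'
#' A scenario fixes the promoter controller, the nominal (initial
#' extracellular) IL concentration, the horizon and the model constants.
#' The seed is carried along for stochastic downstream steps (e.g. noisy
#' synthetic growth curves); the ODE model itself is deterministic.
#'
#' @param promoter An [promoter_spec()] object.
#' @param il_mM Initial extracellular IL concentration (mmol/L, >= 0).
#' @param t_end Simulation horizon (h, > 0).
#' @param constants An [model_constants()] object.
#' @param seed Integer seed recorded in the scenario.
#' @return An object of class `il_scenario`.
#' @examples
#' sc <- scenario(promoter_presets()$PmarR, il_mM = 200)
#' @export
scenario <- function(promoter, il_mM = 0, t_end = 48,
                     constants = model_constants(), seed = 0L) {
  stopifnot(inherits(promoter, "il_promoter"),
            inherits(constants, "il_constants"),
            is.numeric(il_mM), length(il_mM) == 1L, il_mM >= 0,
            is.numeric(t_end), length(t_end) == 1L, t_end > 0)
  structure(list(promoter = promoter, il_mM = il_mM, t_end = t_end,
                 constants = constants, seed = as.integer(seed)),
            class = "il_scenario")
}

#' Simulate the growth / pump / IL model for one scenario
#'
#' Integrates [model_rhs()] with an adaptive Runge-Kutta solver
#' (Dormand-Prince 4(5), rel. tol. 1e-8, abs. tol. 1e-10 by default) from
#' the inoculation state: `N = N0`, `S = S0`, pump at the controller's
#' zero-IL steady state and no intracellular IL. The extracellular
#' concentration is recovered pointwise from the reactor mass balance, so
#' total IL is conserved by construction; the residual drift of the
#' balance is stored in the `conservation_drift` attribute.
#'
#' @param sc An [scenario()] object.
#' @param times Output time grid (h). Default: 20-min intervals from 0 to
#'   `sc$t_end`, mirroring a plate-reader protocol.
#' @param method Solver passed to [deSolve::ode()] (default `"ode45"`).
#' @param rtol,atol Relative / absolute integration tolerances.
#' @return A data frame of class `il_trajectory` with columns `time`, `N`,
#'   `S`, `p`, `c_i`, `c_e`, `od`, and attributes `scenario`, `total_il`,
#'   `conservation_drift`.
#' @examples
#' traj <- simulate_growth(scenario(promoter_presets()$promoterless))
#' tail(traj$od, 1)   # stationary density ~ (N0 + gamma * S0) / od_to_biomass
#' @export
simulate_growth <- function(sc, times = NULL, method = "ode45",
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sc, "il_scenario"))
  k <- sc$constants
  if (is.null(times)) times <- seq(0, sc$t_end, by = 1 / 3)
  if (times[1L] != 0) times <- c(0, times)
  V_i0 <- intracellular_volume(k$N0, k)
  total_il <- (sc$il_mM / 1000) * (k$culture_volume - V_i0)
  y0 <- c(N = k$N0, S = k$S0, p = initial_pump_state(sc$promoter, k), c_i = 0)
  parms <- list(constants = k, promoter = sc$promoter, total_il = total_il)

  out <- tryCatch(
    deSolve::ode(y = y0, times = times, func = model_rhs, parms = parms,
                 method = method, rtol = rtol, atol = atol),
    error = function(e) {
      stop("integration failed for scenario '", sc$promoter$label, "' at ",
           sc$il_mM, " mM IL: ", conditionMessage(e), call. = FALSE)
    })
  out <- as.data.frame(out)
  names(out) <- c("time", "N", "S", "p", "c_i")
  if (nrow(out) < length(times) || anyNA(out)) {
    last <- out[stats::complete.cases(out), , drop = FALSE]
    last <- last[nrow(last), ]
    stop(sprintf(paste0("integration stopped early for '%s' at %g mM IL ",
                        "(last valid state: t=%.3g h, N=%.3g, S=%.3g, ",
                        "p=%.3g, c_i=%.3g)"),
                 sc$promoter$label, sc$il_mM, last$time, last$N, last$S,
                 last$p, last$c_i), call. = FALSE)
  }
  # numerical overshoot only; the model never drives states negative
  out$N <- pmax(out$N, 0)
  out$S <- pmax(out$S, 0)
  out$p <- pmax(out$p, 0)
  out$c_i <- pmax(out$c_i, 0)
  V_i <- intracellular_volume(out$N, k)
  out$c_e <- extracellular_il(total_il, out$c_i, V_i, k)
  out$od <- od_from_biomass(out$N, k)
  drift <- if (total_il > 0) {
    max(abs(V_i * out$c_i + (k$culture_volume - V_i) * out$c_e - total_il)) /
      total_il
  } else 0
  structure(out, class = c("il_trajectory", "data.frame"),
            scenario = sc, total_il = total_il, conservation_drift = drift)
}

#' Convert biomass concentration to OD600
#'
#' @param N Biomass concentration (g/L).
#' @param k An [model_constants()] object (supplies the calibration
#'   `od_to_biomass`, g/L per OD600 unit).
#' @return OD600 values; the inverse map is `od * od_to_biomass`.
#' @export
od_from_biomass <- function(N, k) {
  if (any(N < 0)) stop("od_from_biomass: N must be >= 0", call. = FALSE)
  N / k$od_to_biomass
}

#' Normalise a growth curve to start 0 and maximum 0.5
#'
#' Affine rescaling used when comparing plate-reader growth curves across
#' days: the first value maps to 0 and the maximum to 0.5. A constant
#' series maps to all zeros.
#'
#' @param od Numeric OD series (non-empty).
#' @return Rescaled series of the same length.
#' @examples
#' normalize_curve(c(0.1, 0.3, 0.6))
#' @export
normalize_curve <- function(od) {
  if (length(od) == 0L) stop("normalize_curve: empty series", call. = FALSE)
  shifted <- od - od[1L]
  m <- max(shifted)
  if (m <= 0) return(rep(0, length(od)))
  0.5 * shifted / m
}

#' Lag time, doubling time and final density of a trajectory
#'
#' The doubling time is `ln(2)` over the maximum instantaneous specific
#' growth rate along the trajectory; the lag is where the tangent to the
#' log-OD curve at the point of maximum growth intersects the initial OD
#' level. For an `il_trajectory` the specific growth rate is evaluated
#' exactly from the model state; for a plain data frame with `time` and
#' `od` columns it is estimated by central differences of log OD.
#'
#' @param traj An `il_trajectory`, or any data frame with `time` and `od`
#'   columns and at least 3 rows.
#' Because intracellular IL starts at zero, a culture inoculated into IL
#' grows unhindered for the first instants; the tangent lag can therefore
#' be blind to slow-influx inhibition. The summary additionally reports
#' `t_half_h`, the time at which the curve completes half of its total
#' rise, which captures such delayed inhibition.
#'
#' @param mu_eps Below this maximum growth rate (1/h) the culture is
#'   treated as non-growing and infinite sentinels are returned.
#' @return A list with `lag_h`, `doubling_h`, `final_od`, `t_half_h`,
#'   `mu_max_obs` (1/h) and `t_mu_max` (h).
#' @examples
#' traj <- simulate_growth(scenario(promoter_presets()$PmarR, il_mM = 0))
#' growth_summary(traj)
#' @export
growth_summary <- function(traj, mu_eps = 1e-6) {
  if (nrow(traj) < 3L) {
    stop("growth_summary needs at least 3 trajectory points", call. = FALSE)
  }
  tt <- traj$time
  od <- traj$od
  if (inherits(traj, "il_trajectory")) {
    k <- attr(traj, "scenario")$constants
    mu <- growth_rate(traj$S, traj$c_i, traj$p, k)
  } else {
    lod <- log(pmax(od, .Machine$double.xmin))
    n <- length(tt)
    mu <- c((lod[2L] - lod[1L]) / (tt[2L] - tt[1L]),
            (lod[-(1:2)] - lod[1:(n - 2L)]) / (tt[-(1:2)] - tt[1:(n - 2L)]),
            (lod[n] - lod[n - 1L]) / (tt[n] - tt[n - 1L]))
  }
  i <- which.max(mu)
  mu_max <- mu[i]
  rise <- max(od) - od[1L]
  t_half <- if (rise > mu_eps * od[1L]) {
    tt[which(od >= od[1L] + rise / 2)[1L]]
  } else Inf
  if (!is.finite(mu_max) || mu_max < mu_eps) {
    return(list(lag_h = Inf, doubling_h = Inf, final_od = od[length(od)],
                t_half_h = t_half, mu_max_obs = mu_max, t_mu_max = tt[i]))
  }
  lag <- tt[i] - (log(od[i]) - log(od[1L])) / mu_max
  list(lag_h = lag, doubling_h = log(2) / mu_max,
       final_od = od[length(od)], t_half_h = t_half,
       mu_max_obs = mu_max, t_mu_max = tt[i])
}

#' Simulate every controller at every IL level
#'
#' Runs [simulate_growth()] over the full (controller x IL concentration)
#' grid and summarises each cell with [growth_summary()]. Cells whose
#' integration fails are reported as no-growth rows rather than aborting
#' the grid. The run is deterministic.
#'
#' @param controllers Named list of [promoter_spec()] objects.
#' @param il_levels IL concentrations (mmol/L).
#' @param constants An [model_constants()] object.
#' @param t_end Horizon per cell (h).
#' @param ... Passed on to [simulate_growth()].
#' @return A list of class `il_grid` with `summary` (one row per cell:
#'   `controller`, `kind`, `il_mM`, `final_od`, `max_od`, `lag_h`,
#'   `doubling_h`, `mu_max_obs`, `drift`, `status`) and `trajectories`
#'   (nested list, `[[controller]][[as.character(il_mM)]]`).
#' @examples
#' \donttest{
#' g <- run_controller_grid(promoter_presets(), c(0, 200, 400))
#' g$summary
#' }
#' @export
run_controller_grid <- function(controllers, il_levels,
                                constants = model_constants(), t_end = 48,
                                ...) {
  stopifnot(length(controllers) >= 1L, length(il_levels) >= 1L)
  if (is.null(names(controllers))) {
    names(controllers) <- vapply(controllers, `[[`, "", "label")
  }
  rows <- list()
  trajs <- list()
  for (nm in names(controllers)) {
    trajs[[nm]] <- list()
    for (il in il_levels) {
      res <- tryCatch({
        traj <- simulate_growth(scenario(controllers[[nm]], il_mM = il,
                                         t_end = t_end,
                                         constants = constants), ...)
        sm <- growth_summary(traj)
        list(traj = traj, sm = sm, status = "ok",
             drift = attr(traj, "conservation_drift"))
      }, error = function(e) {
        list(traj = NULL,
             sm = list(lag_h = Inf, doubling_h = Inf, final_od = NA_real_,
                       t_half_h = Inf, mu_max_obs = NA_real_),
             status = paste0("no-growth: ", conditionMessage(e)),
             drift = NA_real_)
      })
      trajs[[nm]][[as.character(il)]] <- res$traj
      rows[[length(rows) + 1L]] <- data.frame(
        controller = nm, kind = controllers[[nm]]$kind, il_mM = il,
        final_od = res$sm$final_od,
        max_od = if (is.null(res$traj)) NA_real_ else max(res$traj$od),
        lag_h = res$sm$lag_h, doubling_h = res$sm$doubling_h,
        t_half_h = res$sm$t_half_h,
        mu_max_obs = res$sm$mu_max_obs, drift = res$drift,
        status = res$status, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), trajectories = trajs),
            class = "il_grid")
}

#' @export
print.il_grid <- function(x, ...) {
  cat("Controller x IL simulation grid\n")
  print(x$summary, digits = 4, row.names = FALSE, ...)
  invisible(x)
}
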