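#' Specific growth rate under substrate limitation, IL toxicity and pump burden
#'
#' Monod kinetics modified by two inhibition factors: a Hill-type toxicity
#' term in the intracellular IL concentration (half-point `K_c`, steepness
#' `hill_h`) and a first-order burden term in the pump level (half-point
#' `K_p`):
#' \deqn{\mu(S, c_i, p) = \mu_{max} \frac{S}{K_s + S}
#'   \frac{1}{1 + (c_i/K_c)^h} \frac{1}{1 + p/K_p}}
#'
#' @param S Substrate concentration (g/L).
#' @param c_i Intracellular IL concentration (mol/L).
#' @param p Pump protein level (relative units).
#' @param k An [model_constants()] object.
#' @return Specific growth rate (1/h). Vectorised over `S`, `c_i`, `p`.
#' @examples
#' k <- model_constants()
#' growth_rate(1e9, 0, 0, k)       # saturating limit: mu_max
#' growth_rate(8, 0.06, 3, k)      # all three factors at half-effect
#' @export
growth_rate <- function(S, c_i, p, k) {
  if (any(S < 0) || any(c_i < 0) || any(p < 0)) {
    stop("growth_rate: S, c_i and p must be non-negative", call. = FALSE)
  }
  k$mu_max * S / (k$K_s + S) *
    1 / (1 + (c_i / k$K_c)^k$hill_h) *
    1 / (1 + p / k$K_p)
}

#' Net pump protein expression rate under a promoter controller
#'
#' The signed rate of change of pump protein for a given controller law.
#' All controllers share basal expression `alpha_p0` and first-order decay
#' `beta * p`. A constitutive controller adds the inducer-set constant rate
#' `alpha_p`; a dynamic (IL-responsive) controller adds a saturating
#' induction term `alpha_p * c_i / (gamma_c + c_i)`.
#'
#' @param ps An [promoter_spec()] object.
#' @param c_i Intracellular IL concentration (mol/L).
#' @param p Current pump level (relative units).
#' @param k An [model_constants()] object (supplies `beta`).
#' @return Net expression rate (pump units/h); may be negative.
#' @examples
#' k <- model_constants()
#' pump_rate(promoter_presets()$promoterless, 0, 0, k)   # basal rate
#' ps <- promoter_presets()$PydfO
#' pump_rate(ps, ps$gamma_c, 0, k)  # alpha_p0 + alpha_p/2 at half-maximum
#' @export
pump_rate <- function(ps, c_i, p, k) {
  if (any(c_i < 0) || any(p < 0)) {
    stop("pump_rate: c_i and p must be non-negative", call. = FALSE)
  }
  production <- switch(ps$kind,
    promoterless = ps$alpha_p0,
    constitutive = ps$alpha_p0 + ps$alpha_p,
    dynamic = {
      if (is.null(ps$gamma_c)) {
        stop("dynamic promoter specification lacks gamma_c", call. = FALSE)
      }
      ps$alpha_p0 + ps$alpha_p * c_i / (ps$gamma_c + c_i)
    })
  production - k$beta * p
}

#' Total intracellular volume of the culture
#'
#' Converts biomass concentration to a cell count (via the dry mass per
#' cell) and scales by the volume of a single cell:
#' `V_i = N * culture_volume / cell_mass * cell_volume`.
#'
#' @param N Biomass concentration (g/L).
#' @param k An [model_constants()] object.
#' @return Intracellular volume of the whole reactor (L). Linear in `N`.
#' @export
intracellular_volume <- function(N, k) {
  if (any(N < 0)) stop("intracellular_volume: N must be >= 0", call. = FALSE)
  N * k$culture_volume / k$cell_mass * k$cell_volume
}

#' Extracellular IL concentration from the reactor mass balance
#'
#' The total amount of IL in the reactor is constant and split between the
#' intracellular and extracellular pools, so the extracellular
#' concentration is derived, never integrated:
#' `c_e = (total_il - c_i * V_i) / (culture_volume - V_i)`.
#' Tiny negative values arising from numerical overshoot are clipped to
#' zero; a clip beyond rounding noise raises a warning.
#'
#' @param total_il Total IL amount in the reactor (mol).
#' @param c_i Intracellular IL concentration (mol/L).
#' @param V_i Intracellular volume (L); must be below `culture_volume`.
#' @param k An [model_constants()] object.
#' @return Extracellular IL concentration (mol/L).
#' @export
extracellular_il <- function(total_il, c_i, V_i, k) {
  if (any(V_i >= k$culture_volume)) {
    stop("intracellular volume exceeds the culture volume", call. = FALSE)
  }
  V_e <- k$culture_volume - V_i
  c_e <- (total_il - c_i * V_i) / V_e
  neg <- c_e < 0
  if (any(neg)) {
    if (any(c_e < -1e-9 * max(total_il, 1e-300))) {
      warning("extracellular IL clipped at 0 (mass-balance overshoot)",
              call. = FALSE)
    }
    c_e[neg] <- 0
  }
  c_e
}

#' Rate of change of the intracellular IL concentration
#'
#' Passive diffusion down the transmembrane gradient, scaled by the
#' extracellular-to-intracellular volume ratio, minus active export
#' proportional to pump level and intracellular concentration:
#' \deqn{dc_i/dt = \alpha_d \frac{V_e}{V_i} (c_e - c_i) - \alpha_c \, p \, c_i}
#' The exported mass reappears in the extracellular pool through the
#' reactor mass balance (see [extracellular_il()]).
#'
#' @param c_i,c_e Intracellular / extracellular IL concentrations (mol/L).
#' @param p Pump level (relative units).
#' @param V_i,V_e Intracellular / extracellular volumes (L); `V_i` must be
#'   positive (diffusion is undefined before inoculation).
#' @param k An [model_constants()] object.
#' @return d(c_i)/dt (mol/L/h).
#' @export
il_rate <- function(c_i, c_e, p, V_i, V_e, k) {
  if (any(c_i < 0) || any(c_e < 0) || any(p < 0) || any(V_e < 0)) {
    stop("il_rate: inputs must be non-negative", call. = FALSE)
  }
  if (any(V_i <= 0)) {
    stop("il_rate: V_i must be positive (no cells, no intracellular pool)",
         call. = FALSE)
  }
  k$alpha_d * (V_e / V_i) * (c_e - c_i) - k$alpha_c * p * c_i
}

#' Right-hand side of the coupled growth/pump/IL model
#'
#' Assembles the four state derivatives (biomass `N`, substrate `S`, pump
#' `p`, intracellular IL `c_i`) in the signature expected by
#' [deSolve::ode()]. Substrate and intracellular IL are clamped at zero
#' inside the evaluation, and growth stops when substrate is exhausted.
#'
#' @param t Time (h); unused (the system is autonomous) but required by the
#'   solver interface.
#' @param y Named state vector `c(N=, S=, p=, c_i=)`.
#' @param parms List with elements `constants` (an [model_constants()]
#'   object), `promoter` (an [promoter_spec()] object) and `total_il`
#'   (mol of IL in the reactor).
#' @return A list whose first element is the derivative vector
#'   `(dN, dS, dp, dc_i)`.
#' @export
model_rhs <- function(t, y, parms) {
  k <- parms$constants
  ps <- parms$promoter
  N <- max(y[[1L]], 0)
  S <- max(y[[2L]], 0)
  p <- max(y[[3L]], 0)
  c_i <- max(y[[4L]], 0)

  V_i <- N * k$culture_volume / k$cell_mass * k$cell_volume
  V_e <- k$culture_volume - V_i
  c_e <- (parms$total_il - c_i * V_i) / V_e
  if (c_e < 0) c_e <- 0

  mu <- if (S > 0) growth_rate(S, c_i, p, k) else 0
  dN <- mu * N
  dS <- if (S > 0) -mu * N / k$gamma else 0
  dp <- pump_rate(ps, c_i, p, k)
  dc_i <- if (V_i > 0) {
    k$alpha_d * (V_e / V_i) * (c_e - c_i) - k$alpha_c * p * c_i
  } else 0

  list(c(dN, dS, dp, dc_i))
}

#' Pump level at the zero-IL steady state of a controller
#'
#' The pre-culture (no IL) fixed point of the pump equation:
#' `alpha_p0 / beta` for promoterless and dynamic controllers,
#' `(alpha_p0 + alpha_p) / beta` for a constitutive controller (the
#' inducer is assumed present throughout).
#'
#' @param ps An [promoter_spec()] object.
#' @param k An [model_constants()] object.
#' @return Steady-state pump level (relative units).
#' @export
initial_pump_state <- function(ps, k) {
  if (ps$kind == "constitutive") (ps$alpha_p0 + ps$alpha_p) / k$beta
  else ps$alpha_p0 / k$beta
}
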