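#' Kinetic and physical constants of the IL-tolerance model
#'
#' Bundles every numerical constant of the coupled growth / substrate /
#' pump / intracellular-IL model. The defaults are the published simulation
#' constants for \emph{E. coli} expressing the EilA efflux pump, plus the
#' physical conversion constants (cell mass and volume, OD600 calibration,
#' reactor volume, inoculum and medium composition) needed to close the
#' reactor-level IL mass balance.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param gamma Growth yield (g cells per g substrate).
#' @param K_s Substrate half-saturation constant of the Monod term (g/L).
#' @param K_c IL toxicity half-saturation constant (mol/L); growth is halved
#'   when intracellular IL equals `K_c` (other factors fixed).
#' @param hill_h Hill coefficient of the IL toxicity term (dimensionless,
#'   must be >= 1).
#' @param K_p Pump-burden half-saturation constant (relative pump units);
#'   growth is halved when pump level equals `K_p`.
#' @param alpha_d Membrane permeability rate for passive IL diffusion (1/h).
#' @param alpha_c Active IL export rate per pump unit (1/h per pump unit).
#' @param beta First-order pump decay coefficient (1/h), covering both
#'   dilution by growth and degradation.
#' @param cell_mass Dry mass of one cell (g).
#' @param cell_volume Volume of one cell (L).
#' @param od_to_biomass Biomass concentration equivalent to one OD600 unit
#'   (g dry weight per L per OD600).
#' @param culture_volume Reactor (culture) volume (L).
#' @param S0 Initial substrate concentration (g/L).
#' @param N0 Initial biomass concentration (g/L).
#'
#' @return An object of class `il_constants` (a validated named list).
#' @examples
#' k <- model_constants()
#' k$mu_max
#' # growth is halved at S = K_s
#' growth_rate(k$K_s, 0, 0, k) / growth_rate(1e9, 0, 0, k)
#' @export
model_constants <- function(mu_max = 1.7,
                            gamma = 0.041,
                            K_s = 8,
                            K_c = 0.06,
                            hill_h = 2,
                            K_p = 3,
                            alpha_d = 3.5e-6,
                            alpha_c = 0.75,
                            beta = 1,
                            cell_mass = 3e-13,
                            cell_volume = 1e-15,
                            od_to_biomass = 0.4,
                            culture_volume = 1,
                            S0 = 10,
                            N0 = 0.004) {
  k <- list(mu_max = mu_max, gamma = gamma, K_s = K_s, K_c = K_c,
            hill_h = hill_h, K_p = K_p, alpha_d = alpha_d, alpha_c = alpha_c,
            beta = beta, cell_mass = cell_mass, cell_volume = cell_volume,
            od_to_biomass = od_to_biomass, culture_volume = culture_volume,
            S0 = S0, N0 = N0)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model constant '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (hill_h < 1) stop("hill_h must be >= 1", call. = FALSE)
  structure(k, class = "il_constants")
}

#' @export
print.il_constants <- function(x, ...) {
  cat("IL-tolerance model constants\n")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}

#' Promoter controller specification
#'
#' A controller law for pump expression. Three kinds are supported:
#' `promoterless` (basal expression only), `constitutive` (a constant,
#' inducer-set expression rate on top of basal, as for an IPTG-induced
#' promoter) and `dynamic` (IL-responsive expression following a
#' saturating Michaelis-type induction curve in the intracellular IL
#' concentration with half-maximum `gamma_c`).
#'
#' @param kind One of `"promoterless"`, `"constitutive"`, `"dynamic"`.
#' @param alpha_p0 Basal expression rate (pump units/h, >= 0).
#' @param alpha_p Maximum non-basal expression rate (pump units/h, >= 0;
#'   0 for promoterless).
#' @param gamma_c Induction half-maximum IL concentration (mol/L). Required
#'   (and only meaningful) for `kind = "dynamic"`.
#' @param label Free-text label, e.g. `"PmarR'-eilA"`.
#' @return An object of class `il_promoter`.
#' @seealso [promoter_presets()] for the five study constructs.
#' @examples
#' promoter_spec("dynamic", alpha_p0 = 0.22, alpha_p = 0.34, gamma_c = 0.02,
#'               label = "PmarR'-eilA")
#' @export
promoter_spec <- function(kind = c("promoterless", "constitutive", "dynamic"),
                          alpha_p0,
                          alpha_p = 0,
                          gamma_c = NULL,
                          label = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(alpha_p0), length(alpha_p0) == 1L, is.finite(alpha_p0),
            is.numeric(alpha_p), length(alpha_p) == 1L, is.finite(alpha_p))
  if (alpha_p0 < 0) stop("alpha_p0 must be >= 0", call. = FALSE)
  if (alpha_p < 0) stop("alpha_p must be >= 0", call. = FALSE)
  if (kind == "dynamic") {
    if (is.null(gamma_c) || !is.numeric(gamma_c) || length(gamma_c) != 1L ||
        !is.finite(gamma_c) || gamma_c <= 0) {
      stop("a dynamic controller requires gamma_c > 0 (mol/L)", call. = FALSE)
    }
  } else {
    gamma_c <- NULL
  }
  if (kind == "promoterless" && alpha_p != 0) {
    stop("a promoterless controller has alpha_p = 0", call. = FALSE)
  }
  if (is.null(label)) label <- kind
  structure(list(kind = kind, alpha_p0 = alpha_p0, alpha_p = alpha_p,
                 gamma_c = gamma_c, label = label),
            class = "il_promoter")
}

#' @export
print.il_promoter <- function(x, ...) {
  cat(sprintf("<il_promoter> %s (%s)\n", x$label, x$kind))
  cat(sprintf("  alpha_p0 = %g /h, alpha_p = %g /h", x$alpha_p0, x$alpha_p))
  if (!is.null(x$gamma_c)) cat(sprintf(", gamma_c = %g M", x$gamma_c))
  cat("\n")
  invisible(x)
}

#' The five pump-expression constructs of the study
#'
#' Named presets for the promoter controllers compared in the study:
#' the three IL-responsive native promoters (`PydfO`, `PydfA`, `PmarR`),
#' the IPTG-induced constitutive `PlacUV5`, and the `promoterless`
#' negative control. Expression parameters are the published simulation
#' constants (pump units/h; induction half-maxima in mol/L).
#'
#' @return A named list of [promoter_spec()] objects.
#' @examples
#' names(promoter_presets())
#' promoter_presets()$PmarR
#' @export
promoter_presets <- function() {
  list(
    PydfO = promoter_spec("dynamic", alpha_p0 = 0.015, alpha_p = 0.015,
                          gamma_c = 0.0075, label = "PydfO'-eilA"),
    PydfA = promoter_spec("dynamic", alpha_p0 = 0.22, alpha_p = 0.523,
                          gamma_c = 0.02, label = "PydfA'-eilA"),
    PmarR = promoter_spec("dynamic", alpha_p0 = 0.22, alpha_p = 0.34,
                          gamma_c = 0.02, label = "PmarR'-eilA"),
    PlacUV5 = promoter_spec("constitutive", alpha_p0 = 0.06, alpha_p = 0.28,
                            label = "PlacUV5-eilA"),
    promoterless = promoter_spec("promoterless", alpha_p0 = 0.014,
                                 label = "P-eilA")
  )
}

#' Read model constants and promoter specifications from a config file
#'
#' Loads a YAML or JSON configuration holding overrides for
#' [model_constants()] under a `constants` key and/or a named list of
#' promoter definitions under a `promoters` key (each with `kind`,
#' `alpha_p0`, `alpha_p`, `gamma_c`, `label`). Missing fields fall back to
#' the built-in defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `constants` (class `il_constants`) and
#'   `promoters` (named list of `il_promoter`; the presets if the file
#'   defines none).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  const_args <- cfg$constants
  constants <- if (is.null(const_args)) model_constants() else
    do.call(model_constants, as.list(const_args))
  promoters <- promoter_presets()
  if (!is.null(cfg$promoters)) {
    promoters <- lapply(cfg$promoters, function(p) do.call(promoter_spec, as.list(p)))
  }
  list(constants = constants, promoters = promoters)
}
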