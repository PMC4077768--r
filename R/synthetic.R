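# Run code under a local RNG stream without disturbing the caller's state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Noise model specification
#'
#' Describes the replicate noise applied by the synthetic-data
#' generators: multiplicative log-normal (mean-one factors, suited to OD
#' and peak-area measurements) or additive Gaussian (suited to Ct values
#' and log intensities).
#'
#' @param kind `"multiplicative-lognormal"` or `"additive-gaussian"`.
#' @param sd Noise scale (coefficient of variation for multiplicative
#'   noise, native units for additive noise; >= 0).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return An object of class `il_noise`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        sd = 0, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "il_noise")
}

# Draw an n-vector of noise factors/offsets for a noise model.
.noise_draw <- function(noise, n) {
  if (noise$sd == 0) {
    if (noise$kind == "multiplicative-lognormal") rep(1, n) else rep(0, n)
  } else if (noise$kind == "multiplicative-lognormal") {
    # sdlog chosen so the coefficient of variation equals sd, mean 1
    sdlog <- sqrt(log(1 + noise$sd^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  } else {
    stats::rnorm(n, 0, noise$sd)
  }
}

#' Generate replicated plate-reader growth curves from the model
#'
#' Simulates the scenario, samples the OD600 trajectory on a 20-min grid
#' and applies replicate measurement noise. With `sd = 0` the replicates
#' equal the deterministic trajectory exactly.
#'
#' @param sc An [scenario()] object.
#' @param noise An [noise_model()] (default: 5% multiplicative).
#' @param n_reps Number of replicates.
#' @param dt Sampling interval (h; default 20 min).
#' @return An [growth_curve_data()] object; the noise-free trajectory is
#'   attached as attribute `truth`.
#' @export
gen_growth_curve <- function(sc, noise = noise_model("multiplicative-lognormal",
                                                     0.05, sc$seed),
                             n_reps = 3, dt = 1 / 3) {
  stopifnot(inherits(sc, "il_scenario"), inherits(noise, "il_noise"),
            n_reps >= 1L)
  times <- seq(0, sc$t_end, by = dt)
  traj <- simulate_growth(sc, times = times)
  od <- with_local_seed(noise$seed, {
    vapply(seq_len(n_reps), function(r) {
      if (noise$kind == "multiplicative-lognormal") {
        traj$od * .noise_draw(noise, length(times))
      } else {
        pmax(traj$od + .noise_draw(noise, length(times)), 0)
      }
    }, numeric(length(times)))
  })
  out <- growth_curve_data(times, od, il_mM = sc$il_mM,
                           label = sc$promoter$label)
  attr(out, "truth") <- traj
  out
}

#' Generate a synthetic expression matrix with planted DE genes
#'
#' Null genes share their condition means; planted genes are shifted by
#' `log2(fold)` up or down in the treated condition. Additive Gaussian
#' noise on the log2 scale emulates array measurement error. Truth labels
#' are returned for sensitivity/false-discovery scoring.
#'
#' @param n_genes Total number of genes.
#' @param planted_up,planted_down Length-2 vectors `c(count, fold)`.
#' @param noise_sd Additive noise sd (log2 units).
#' @param n_reps Replicates per condition.
#' @param seed Integer seed.
#' @param base_range Range of baseline log2 intensities.
#' @return List with `table` (an [expression_table()]) and `truth` (data
#'   frame `gene`, `status` in up/down/null, `true_fold`).
#' @export
gen_expression_matrix <- function(n_genes = 1000, planted_up = c(10, 8),
                                  planted_down = c(5, 8), noise_sd = 0.2,
                                  n_reps = 3, seed = 0L,
                                  base_range = c(6, 12)) {
  nu <- as.integer(planted_up[1L]); fu <- planted_up[2L]
  nd <- as.integer(planted_down[1L]); fd <- planted_down[2L]
  stopifnot(nu + nd <= n_genes, fu > 0, fd > 0, noise_sd >= 0, n_reps >= 2L)
  genes <- sprintf("g%04d", seq_len(n_genes))
  with_local_seed(seed, {
    idx <- sample.int(n_genes, nu + nd)
    up_idx <- idx[seq_len(nu)]
    down_idx <- idx[nu + seq_len(nd)]
    base <- stats::runif(n_genes, base_range[1L], base_range[2L])
    shift <- numeric(n_genes)
    shift[up_idx] <- log2(fu)
    shift[down_idx] <- -log2(fd)
    ctrl <- matrix(base, n_genes, n_reps) +
      matrix(stats::rnorm(n_genes * n_reps, 0, noise_sd), n_genes)
    trt <- matrix(base + shift, n_genes, n_reps) +
      matrix(stats::rnorm(n_genes * n_reps, 0, noise_sd), n_genes)
    values <- cbind(ctrl, trt)
    rownames(values) <- genes
    colnames(values) <- c(paste0("control_", seq_len(n_reps)),
                          paste0("treated_", seq_len(n_reps)))
    status <- rep("null", n_genes)
    status[up_idx] <- "up"
    status[down_idx] <- "down"
    true_fold <- rep(1, n_genes)
    true_fold[up_idx] <- fu
    true_fold[down_idx] <- 1 / fd
    list(table = expression_table(values,
                                  rep(c("control", "treated"),
                                      each = n_reps)),
         truth = data.frame(gene = genes, status = status,
                            true_fold = true_fold, stringsAsFactors = FALSE))
  })
}

#' Generate a replicated qPCR Ct table with a known fold change
#'
#' Target Ct values in the treated condition sit `log2(true_fold)` cycles
#' below the control condition; the reference gene is constant up to the
#' stability noise. Additive Gaussian noise of sd `sd` is applied to every
#' Ct. With `sd = 0`, [ddct_fold_change()] returns `true_fold` exactly.
#'
#' @param true_fold True expression fold change (> 0).
#' @param sd Ct noise sd (cycles).
#' @param n_reps Replicates per condition.
#' @param seed Integer seed.
#' @param target_ct Baseline target Ct in the control condition (cycles).
#' @param reference_ct Reference-gene Ct (cycles).
#' @return A data frame in the layout expected by [ddct_fold_change()].
#' @export
gen_ct_table <- function(true_fold, sd = 0, n_reps = 3, seed = 0L,
                         target_ct = 25, reference_ct = 18) {
  stopifnot(true_fold > 0, sd >= 0, n_reps >= 1L)
  with_local_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_reps),
                        condition = c("control", "treated"),
                        gene = c("target", "reference"),
                        stringsAsFactors = FALSE)
    rows$sample <- paste(rows$condition, rows$replicate, sep = "_")
    base <- ifelse(rows$gene == "reference", reference_ct,
                   ifelse(rows$condition == "treated",
                          target_ct - log2(true_fold), target_ct))
    rows$ct <- base + .noise_draw(noise_model("additive-gaussian", sd), nrow(rows))
    rows[, c("sample", "condition", "gene", "ct", "replicate")]
  })
}

#' Generate an SRM peak-area table with a known target/Cat ratio
#'
#' Cat (control) peptide areas are drawn around a base level and target
#' peptide areas around `base * true_ratio`, with multiplicative
#' log-normal replicate noise of coefficient of variation `cv`. With
#' `cv = 0`, [srm_protein_ratio()] returns `true_ratio` exactly.
#'
#' @param true_ratio True target/Cat level (>= 0).
#' @param n_peptides Peptides per protein.
#' @param cv Coefficient of variation of the peptide areas.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param base_area Mean Cat peptide area (arbitrary units).
#' @return A data frame in the layout expected by [srm_protein_ratio()].
#' @export
gen_peak_area_table <- function(true_ratio, n_peptides = 2, cv = 0,
                                n_reps = 3, seed = 0L, base_area = 1e5) {
  stopifnot(true_ratio >= 0, n_peptides >= 1L, cv >= 0, n_reps >= 1L)
  with_local_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_reps),
                        peptide = seq_len(n_peptides),
                        protein = c("control", "target"),
                        stringsAsFactors = FALSE)
    rows$peptide <- paste(substr(rows$protein, 1, 3), rows$peptide, sep = "_pep")
    mean_area <- ifelse(rows$protein == "target", base_area * true_ratio,
                        base_area)
    noise <- .noise_draw(noise_model("multiplicative-lognormal", cv),
                         nrow(rows))
    rows$area <- mean_area * noise
    rows[, c("protein", "peptide", "area", "replicate")]
  })
}

#' Generate a protein measurement grid for promoter parameterisation
#'
#' Emulates the Cat-normalised pump-protein measurements used to derive
#' controller parameters. Exponential-phase levels are the controller's
#' steady-state pump level with the intracellular IL clamped at the
#' nominal medium concentration of each sample; for the constitutive
#' (IPTG-set) controller the zero-IL exponential sample is taken without
#' inducer, so it reports basal activity. Stationary-phase levels are the
#' fully induced steady state, reflecting the protein accumulated over
#' growth. Multiplicative noise is applied per replicate; noise-free
#' grids round-trip through [derive_promoter_params()] to the generating
#' parameters.
#'
#' @param ps An [promoter_spec()] object.
#' @param k An [model_constants()] object (supplies `beta`).
#' @param il_mM IL concentrations of the grid (mmol/L; must include 0).
#' @param noise_sd Coefficient of variation of the measurement noise.
#' @param n_reps Replicates per grid cell.
#' @param seed Integer seed.
#' @return An [protein_measurement_grid()] object.
#' @export
gen_protein_measurement_grid <- function(ps, k, il_mM = c(0, 50, 150, 400),
                                         noise_sd = 0, n_reps = 3,
                                         seed = 0L) {
  stopifnot(inherits(ps, "il_promoter"), inherits(k, "il_constants"),
            0 %in% il_mM, noise_sd >= 0, n_reps >= 1L)
  c_M <- il_mM / 1000
  exp_level <- vapply(c_M, function(ci) {
    prod <- switch(ps$kind,
      promoterless = ps$alpha_p0,
      constitutive = if (ci == 0) ps$alpha_p0 else ps$alpha_p0 + ps$alpha_p,
      dynamic = ps$alpha_p0 + ps$alpha_p * ci / (ps$gamma_c + ci))
    prod / k$beta
  }, 0)
  stat_level <- rep((ps$alpha_p0 + ps$alpha_p) / k$beta, length(c_M))
  df <- rbind(
    data.frame(phase = "exponential", il_mM = il_mM, level = exp_level),
    data.frame(phase = "stationary", il_mM = il_mM, level = stat_level))
  df <- df[rep(seq_len(nrow(df)), each = n_reps), ]
  df$replicate <- rep(seq_len(n_reps), length.out = nrow(df))
  df$level <- with_local_seed(seed, {
    df$level * .noise_draw(noise_model("multiplicative-lognormal", noise_sd),
                           nrow(df))
  })
  rownames(df) <- NULL
  protein_measurement_grid(df, kind = ps$kind, label = ps$label)
}
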