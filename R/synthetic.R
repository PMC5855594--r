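#' Noise specification for synthetic data
#'
#' Statistical structure added to noise-free model output: additive i.i.d.
#' Gaussian noise, an optional linear baseline drift, and an optional
#' square-pulse bulk refractive-index offset present only while analyte is
#' injected. A fixed seed makes every generated object byte-identical
#' across runs.
#'
#' @param sd Gaussian noise standard deviation (RU for sensorgrams,
#'   absorbance units for ELISA curves). Default 0.5 RU is typical
#'   short-term instrument noise.
#' @param drift linear baseline drift in RU/s (default 0).
#' @param bulk bulk offset in RU during the association phase (default 0).
#' @param seed integer RNG seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.5, drift = 0, bulk = 0, seed = 1L) {
  if (!is.finite(sd) || sd < 0) stop("'sd' must be >= 0")
  if (!is.finite(drift) || !is.finite(bulk)) stop("'drift' and 'bulk' must be finite")
  structure(list(sd = sd, drift = drift, bulk = bulk, seed = as.integer(seed)),
            class = "noise_spec")
}

# Evaluate an expression with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Serial dilution ladder
#'
#' Descending concentration series `top, top/factor, top/factor^2, ...` as
#' produced by serially diluting an analyte stock.
#'
#' @param top highest concentration in M (> 0).
#' @param factor dilution factor (> 1).
#' @param n number of concentrations (>= 1).
#' @return Numeric vector of length `n`, descending; the last element is
#'   exactly `top / factor^(n-1)`.
#' @examples
#' serial_dilution(250e-9, 2, 5) * 1e9  # 250 125 62.5 31.25 15.625 nM
#' @export
serial_dilution <- function(top, factor, n) {
  if (!is.finite(top) || top <= 0) stop("'top' must be > 0")
  if (!is.finite(factor) || factor <= 1) stop("'factor' must be > 1")
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  top / factor^(seq_len(n) - 1)
}

#' Generate a noisy sensorgram series with reference channels
#'
#' Emulates a parallel multi-concentration SPR experiment on one ligand
#' surface: for each analyte concentration the active channel is the
#' noise-free model trace plus drift, a square-pulse bulk offset during
#' injection, and Gaussian noise; the paired interspot channel (unmodified
#' surface seeing only analyte flow) carries the same drift and bulk terms
#' with independent noise; and the blank channel (zero-concentration
#' injection, already interspot-corrected) carries independent noise only.
#' Passing the three channels through [double_reference()] recovers the
#' model trace up to the combined noise.
#'
#' @param params a [kinetic_params()] of any supported kind.
#' @param concs analyte concentrations in M (>= 1 value, pairwise distinct).
#' @param sched a [phase_schedule()].
#' @param noise a [noise_spec()].
#' @param concs_b optional second-species concentrations (heterogeneous
#'   analyte kind only), same length as `concs`; default all zero.
#' @return A list of class `sensorgram_set` with elements `active`,
#'   `interspot`, `blank`, each a [sensorgram_series()] on one common grid,
#'   plus the `params`, `sched` and `noise` used.
#' @export
generate_sensorgram_series <- function(params, concs, sched = phase_schedule(),
                                       noise = noise_spec(),
                                       concs_b = NULL) {
  stopifnot(inherits(params, "kinetic_params"), inherits(sched, "phase_schedule"),
            inherits(noise, "noise_spec"))
  if (!length(concs)) stop("need at least one concentration")
  if (is.null(concs_b)) concs_b <- rep(0, length(concs))
  if (length(concs_b) != length(concs)) stop("'concs_b' must match 'concs' in length")
  sim <- switch(params$kind,
    langmuir_1to1 = function(C, Cb) simulate_langmuir(params, C, sched),
    heterogeneous_ligand = function(C, Cb) simulate_heterogeneous_ligand(params, C, sched),
    bivalent_analyte = function(C, Cb) simulate_bivalent_analyte(params, C, sched),
    heterogeneous_analyte = function(C, Cb) simulate_heterogeneous_analyte(params, C, Cb, sched),
    stop("invalid model kind"))
  with_seed(noise$seed, {
    t <- schedule_grid(sched)
    assoc <- as.numeric(t <= sched$t_assoc)
    n <- length(t)
    mk <- function(i, channel) {
      C <- concs[i]
      base <- switch(channel,
        active = sim(C, concs_b[i])$response + noise$drift * t + noise$bulk * assoc,
        interspot = noise$drift * t + noise$bulk * assoc,
        blank = rep(0, n))
      eps <- if (noise$sd > 0) stats::rnorm(n, 0, noise$sd) else rep(0, n)
      sensorgram(t, base + eps, C, sched,
                 label = sprintf("%s_%d", channel, i),
                 conc_b = concs_b[i])
    }
    active <- lapply(seq_along(concs), mk, channel = "active")
    interspot <- lapply(seq_along(concs), mk, channel = "interspot")
    blank <- lapply(seq_along(concs), mk, channel = "blank")
    # reference channels share the active curve's concentration label so the
    # set stays aligned curve-by-curve
    structure(list(active = sensorgram_series(active, "active"),
                   interspot = sensorgram_series(interspot, "interspot"),
                   blank = sensorgram_series(blank, "blank"),
                   params = params, sched = sched, noise = noise),
              class = "sensorgram_set")
  })
}

#' @export
print.sensorgram_set <- function(x, ...) {
  cat("Synthetic sensorgram set (", x$params$kind, "), ",
      length(x$active$curves), " concentrations + interspot/blank channels\n",
      sep = "")
  invisible(x)
}

#' Double-reference every curve of a generated set
#'
#' Applies [double_reference()] curve-by-curve to a `sensorgram_set`.
#'
#' @param set a `sensorgram_set` from [generate_sensorgram_series()].
#' @return A [sensorgram_series()] of corrected curves.
#' @export
reference_set <- function(set) {
  stopifnot(inherits(set, "sensorgram_set"))
  corrected <- Map(double_reference, set$active$curves, set$interspot$curves,
                   set$blank$curves)
  sensorgram_series(corrected, "corrected")
}

#' Generate a noisy ELISA saturation curve
#'
#' One-site specific-binding model S(c) = bg + Smax c / (Kd + c) plus
#' Gaussian noise, reproducible under the noise seed.
#'
#' @param Kd apparent dissociation constant (same unit as `concs`).
#' @param Smax saturating specific signal.
#' @param bg background signal.
#' @param concs concentrations (pairwise distinct).
#' @param noise a [noise_spec()]; only `sd` (absorbance units) and `seed`
#'   are used.
#' @return A [dose_response_curve()] with `mode = "saturation"`.
#' @export
generate_saturation_curve <- function(Kd, Smax, bg, concs,
                                      noise = noise_spec(sd = 0.02)) {
  stopifnot(inherits(noise, "noise_spec"), Kd > 0)
  with_seed(noise$seed, {
    s <- bg + Smax * concs / (Kd + concs)
    if (noise$sd > 0) s <- s + stats::rnorm(length(concs), 0, noise$sd)
    dose_response_curve(concs, s, "saturation")
  })
}

#' Generate a noisy ELISA inhibition curve
#'
#' Four-parameter logistic S(i) = bottom + (top - bottom)/(1 + (i/IC50)^hill)
#' plus Gaussian noise, reproducible under the noise seed.
#'
#' @param IC50 half-maximal inhibitory concentration (same unit as `concs`).
#' @param top,bottom upper and lower signal plateaus.
#' @param hill Hill coefficient (> 0).
#' @param concs inhibitor concentrations (pairwise distinct).
#' @param noise a [noise_spec()]; only `sd` and `seed` are used.
#' @return A [dose_response_curve()] with `mode = "inhibition"`.
#' @export
generate_inhibition_curve <- function(IC50, top, bottom, hill = 1, concs,
                                      noise = noise_spec(sd = 0.02)) {
  stopifnot(inherits(noise, "noise_spec"), IC50 > 0, hill > 0)
  with_seed(noise$seed, {
    s <- bottom + (top - bottom) / (1 + (concs / IC50)^hill)
    if (noise$sd > 0) s <- s + stats::rnorm(length(concs), 0, noise$sd)
    dose_response_curve(concs, s, "inhibition")
  })
}

#' Published binding parameters of the neo-glycoprotein series
#'
#' Central values printed for the galectin-3 / neo-glycoprotein series:
#' ELISA inhibition constants of the monovalent glycans (micromolar) and
#' multivalent neo-glycoproteins (nanomolar), glycan loading `m`, relative
#' potencies, apparent ELISA Kd values, and the SPR rate constants
#' (ka, kd) with derived KD for the setup with the immobilized lectin;
#' asialofetuin (ASF) is the positive-control analyte and lactose the
#' monovalent control inhibitor. Each column's origin is recorded in the
#' `"provenance"` attribute. These rate constants were fitted from
#' instrument sensorgrams that are not redistributable; in this package
#' they serve only as generator inputs and as the basis of derived-quantity
#' checks (KD = kd/ka, potency ratios, fold differences), never as outputs
#' the package could re-estimate without the raw data.
#'
#' @return A data frame of class `fixture_set`, one row per compound
#'   (`id` "9".."16", "ASF", "lactose"), with attribute `"provenance"`
#'   (named character vector describing the origin of every column).
#' @examples
#' fx <- table_fixtures()
#' fx[fx$id == "11", c("ka", "kd", "KD")]
#' @export
table_fixtures <- function() {
  df <- data.frame(
    id = c("9", "10", "11", "12", "13", "14", "15", "16", "ASF", "lactose"),
    glycan = c("LacdiNAc", "LacNAc", "LacdiNAc-LacNAc", "LacNAc-LacNAc",
               "LacdiNAc-LacNAc-LacNAc", "LacNAc-LacNAc-LacNAc",
               "LacNAc type 1-LacNAc-LacNAc", "Galili-LacNAc-LacNAc",
               "asialofetuin (positive control)", "lactose (control inhibitor)"),
    Mw_kDa = c(76.4, 78.2, 87.4, 84.7, 86.6, 86.6, 85.9, 89.6, NA, NA),
    m = c(17, 18, 21, 19, 16, 17, 17, 18, NA, NA),
    ic50_glycan_uM = c(42, 36, 7, 13, 6.20, 20.1, 12.5, 8.4, NA, 137),
    se_ic50_glycan_uM = c(2, 1, 1, 3, 0.02, 0.1, 0.1, 0.1, NA, 27),
    ic50_neo_nM = c(2026, 344, 11, 31, 37, 76, 212, 65, NA, NA),
    se_ic50_neo_nM = c(147, 38, 2, 1, 7, 8, 22, 4, NA, NA),
    rp = c(20.7, 104.7, 642.9, 419.4, 169.9, 263.4, 58.9, 128.2, NA, NA),
    rp_per_glycan = c(1.2, 5.8, 30.6, 22.1, 10.6, 15.5, 3.5, 7.1, NA, NA),
    kd_elisa_nM = c(6290, 4780, 30, 300, 76, 350, 700, 290, NA, NA),
    se_kd_elisa_nM = c(530, 1240, 4, 60, 19, 110, 100, 90, NA, NA),
    ka = c(NA, NA, 5.9e6, 6.2e6, 5.8e6, 7.8e6, 4.9e6, 9.3e6, 4.8e4, NA),
    se_ka = c(NA, NA, 1.3e6, 2.1e6, 2.2e6, 2.9e6, 1.8e6, 3.1e6, 1.9e4, NA),
    kd = c(NA, NA, 8.5e-5, 4.2e-4, 1.5e-4, 5.1e-4, 1.3e-3, 6.3e-4, 4.0e-4, NA),
    se_kd = c(NA, NA, 2.5e-5, 3.1e-4, 0.4e-4, 2.8e-4, 0.3e-3, 2.0e-4, 1.7e-4, NA),
    KD = c(NA, NA, 1.4e-11, 6.8e-11, 2.6e-11, 6.5e-11, 2.7e-10, 6.8e-11, 8.3e-9, NA),
    se_KD = c(NA, NA, 0.4e-11, 3.9e-11, 0.9e-11, 2.6e-11, 1.0e-10, 3.5e-11, 3.1e-9, NA),
    stringsAsFactors = FALSE)
  attr(df, "provenance") <- c(
    id = "published compound numbering of the neo-glycoprotein series",
    glycan = "published name of the glycan attached to the BSA carrier",
    Mw_kDa = "published molecular weight of the neo-glycoprotein (kDa)",
    m = "published average number of glycans per BSA molecule",
    ic50_glycan_uM = "published competitive-ELISA IC50 of the monovalent glycan (uM)",
    se_ic50_glycan_uM = "published +- spread of the glycan IC50 (uM)",
    ic50_neo_nM = "published competitive-ELISA IC50 of the neo-glycoprotein (nM)",
    se_ic50_neo_nM = "published +- spread of the neo-glycoprotein IC50 (nM)",
    rp = "published relative potency, IC50(glycan)/IC50(neo-glycoprotein)",
    rp_per_glycan = "published relative potency per conjugated glycan (rp/m)",
    kd_elisa_nM = "published apparent ELISA Kd of the lectin/neo-glycoprotein complex (nM)",
    se_kd_elisa_nM = "published +- spread of the apparent ELISA Kd (nM)",
    ka = "published association rate constant, instrument-fitted from SPR sensorgrams (M^-1 s^-1); generator input only",
    se_ka = "published +- of ka (M^-1 s^-1)",
    kd = "published dissociation rate constant, instrument-fitted from SPR sensorgrams (s^-1); generator input only",
    se_kd = "published +- of kd (s^-1)",
    KD = "published equilibrium dissociation constant kd/ka (M)",
    se_KD = "published +- of KD (M)")
  class(df) <- c("fixture_set", "data.frame")
  df
}
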