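#' Kinetic model parameters
#'
#' Container for the rate and capacity parameters of one of the four
#' supported biosensor binding models. Units are fixed package-wide:
#' association rate constants in M^-1 s^-1, dissociation rate constants in
#' s^-1, surface capacities in response units (RU), concentrations in M and
#' time in seconds.
#'
#' Model kinds:
#' \describe{
#'   \item{`langmuir_1to1`}{Single-step reversible binding A + L = AL with
#'     rate constants `ka1`, `kd1` and capacity `Rmax1`. Second-event fields
#'     are ignored.}
#'   \item{`heterogeneous_ligand`}{Two independent immobilized site classes;
#'     the response is the sum of two 1:1 terms (`ka1`,`kd1`,`Rmax1`) and
#'     (`ka2`,`kd2`,`Rmax2`).}
#'   \item{`bivalent_analyte`}{Analyte carrying two equivalent binding
#'     moieties; a second surface attachment (rate `ka2` in RU^-1 s^-1,
#'     `kd2` in s^-1) follows the first. Integrated numerically.}
#'   \item{`heterogeneous_analyte`}{Two analyte species competing for one
#'     shared capacity `Rmax1`; species A binds with (`ka1`,`kd1`), species
#'     B with (`ka2`,`kd2`).}
#' }
#'
#' @param kind one of `"langmuir_1to1"`, `"heterogeneous_ligand"`,
#'   `"bivalent_analyte"`, `"heterogeneous_analyte"`.
#' @param ka1,kd1 first-event association / dissociation rate constants
#'   (must be > 0).
#' @param Rmax1 first (or shared) surface capacity in RU (>= 0).
#' @param ka2,kd2,Rmax2 second-event parameters; required for every kind
#'   except `langmuir_1to1`, where they are ignored.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params("langmuir_1to1", ka1 = 5.9e6, kd1 = 8.5e-5, Rmax1 = 100)
#' @export
kinetic_params <- function(kind = c("langmuir_1to1", "heterogeneous_ligand",
                                    "bivalent_analyte", "heterogeneous_analyte"),
                           ka1, kd1, Rmax1,
                           ka2 = NA_real_, kd2 = NA_real_, Rmax2 = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(ka1), is.numeric(kd1), is.numeric(Rmax1))
  if (!is.finite(ka1) || ka1 <= 0) stop("'ka1' must be a positive finite number")
  if (!is.finite(kd1) || kd1 <= 0) stop("'kd1' must be a positive finite number")
  if (!is.finite(Rmax1) || Rmax1 < 0) stop("'Rmax1' must be a non-negative finite number")
  if (kind != "langmuir_1to1") {
    if (!is.finite(ka2) || ka2 < 0) stop("'ka2' must be a non-negative finite number for kind '", kind, "'")
    if (!is.finite(kd2) || kd2 <= 0) stop("'kd2' must be a positive finite number for kind '", kind, "'")
    if (kind == "heterogeneous_ligand") {
      if (!is.finite(Rmax2) || Rmax2 < 0) stop("'Rmax2' must be a non-negative finite number")
    } else {
      Rmax2 <- NA_real_
    }
  } else {
    ka2 <- kd2 <- Rmax2 <- NA_real_
  }
  structure(list(kind = kind, ka1 = ka1, kd1 = kd1, Rmax1 = Rmax1,
                 ka2 = ka2, kd2 = kd2, Rmax2 = Rmax2),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters [", x$kind, "]\n", sep = "")
  cat(sprintf("  ka1 = %.4g M^-1 s^-1, kd1 = %.4g s^-1, Rmax1 = %.4g RU\n",
              x$ka1, x$kd1, x$Rmax1))
  if (x$kind != "langmuir_1to1")
    cat(sprintf("  ka2 = %.4g, kd2 = %.4g s^-1, Rmax2 = %.4g RU\n",
                x$ka2, x$kd2, x$Rmax2))
  invisible(x)
}

#' Injection phase schedule
#'
#' Timing of one association/dissociation cycle: analyte is injected over
#' the surface for `t_assoc` seconds, then running buffer flows for
#' `t_dissoc` seconds while the complex dissociates. The defaults (120 s
#' association, 600 s dissociation, 0.5 s sampling) give a dissociation
#' window long enough to constrain dissociation rates around 1e-4 s^-1.
#'
#' @param t_assoc association (injection) duration in seconds (> 0).
#' @param t_dissoc dissociation duration in seconds (>= 0).
#' @param dt sampling interval in seconds (0 < dt < t_assoc).
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(t_assoc = 120, t_dissoc = 600, dt = 0.5) {
  if (!is.numeric(t_assoc) || !is.finite(t_assoc) || t_assoc <= 0)
    stop("'t_assoc' must be > 0")
  if (!is.numeric(t_dissoc) || !is.finite(t_dissoc) || t_dissoc < 0)
    stop("'t_dissoc' must be >= 0")
  if (!is.numeric(dt) || !is.finite(dt) || dt <= 0 || dt >= t_assoc)
    stop("'dt' must satisfy 0 < dt < t_assoc")
  structure(list(t_assoc = t_assoc, t_dissoc = t_dissoc, dt = dt),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("Phase schedule: %g s association, %g s dissociation, dt = %g s\n",
              x$t_assoc, x$t_dissoc, x$dt))
  invisible(x)
}

# Sample grid of a schedule; t = 0 is injection start and the grid always
# contains t_assoc so the phase boundary is sampled exactly.
schedule_grid <- function(sched) {
  t <- seq(0, sched$t_assoc + sched$t_dissoc, by = sched$dt)
  if (!any(abs(t - sched$t_assoc) < 1e-9)) t <- sort(c(t, sched$t_assoc))
  t
}

#' Sensorgram object
#'
#' One SPR trace: response (RU) on a time grid (seconds from injection
#' start; pre-injection baseline samples may carry negative times), together
#' with the analyte concentration and the phase schedule used.
#'
#' @param time numeric vector, strictly increasing, seconds.
#' @param response numeric vector of the same length, RU, all finite.
#' @param conc analyte concentration in M (>= 0).
#' @param schedule a [phase_schedule()] or NULL.
#' @param label free-text label.
#' @param conc_b optional second analyte-species concentration in M
#'   (heterogeneous-analyte experiments); default 0.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(time, response, conc, schedule = NULL, label = "",
                       conc_b = 0) {
  time <- as.numeric(time); response <- as.numeric(response)
  if (length(time) != length(response))
    stop("'time' and 'response' must have equal length")
  if (length(time) < 2L) stop("a sensorgram needs at least 2 samples")
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (!all(is.finite(response))) stop("'response' must be finite")
  if (!is.numeric(conc) || !is.finite(conc) || conc < 0)
    stop("'conc' must be a finite concentration >= 0")
  if (!is.finite(conc_b) || conc_b < 0) stop("'conc_b' must be >= 0")
  structure(list(time = time, response = response, conc = conc,
                 schedule = schedule, label = as.character(label)[1L],
                 conc_b = conc_b),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram '%s': %d samples, t in [%g, %g] s, conc = %.4g M, max R = %.3g RU\n",
              x$label, length(x$time), min(x$time), max(x$time), x$conc,
              max(x$response)))
  invisible(x)
}

#' @export
as.data.frame.sensorgram <- function(x, ...) {
  data.frame(time_s = x$time, response_RU = x$response,
             conc_M = x$conc, label = x$label)
}

#' Sensorgram series
#'
#' An ordered set of sensorgrams recorded on one ligand surface at distinct
#' analyte concentrations — the unit of global fitting. All curves must
#' share one time grid.
#'
#' @param curves list of [sensorgram()] objects.
#' @param surface_label free-text label for the shared surface.
#' @return An object of class `sensorgram_series`.
#' @export
sensorgram_series <- function(curves, surface_label = "") {
  if (!length(curves)) stop("'curves' must be a non-empty list of sensorgrams")
  if (!all(vapply(curves, inherits, logical(1), "sensorgram")))
    stop("all elements of 'curves' must be sensorgram objects")
  grid <- curves[[1L]]$time
  same <- vapply(curves, function(s)
    length(s$time) == length(grid) && all(s$time == grid), logical(1))
  if (!all(same)) stop("all curves in a series must share an identical time grid")
  concs <- vapply(curves, `[[`, numeric(1), "conc")
  if (anyDuplicated(concs)) stop("curve concentrations must be pairwise distinct")
  structure(list(curves = curves, surface_label = as.character(surface_label)[1L]),
            class = "sensorgram_series")
}

#' @export
print.sensorgram_series <- function(x, ...) {
  concs <- vapply(x$curves, `[[`, numeric(1), "conc")
  cat(sprintf("Sensorgram series '%s': %d curves, conc %s M\n",
              x$surface_label, length(x$curves),
              paste(signif(sort(concs, decreasing = TRUE), 4), collapse = ", ")))
  invisible(x)
}

#' @export
length.sensorgram_series <- function(x) length(x$curves)

#' @export
as.data.frame.sensorgram_series <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$curves), function(i) {
    d <- as.data.frame(x$curves[[i]])
    d$curve_id <- if (nzchar(x$curves[[i]]$label)) x$curves[[i]]$label else paste0("curve", i)
    d
  }))
}

# Closed-form 1:1 Langmuir trace on an arbitrary grid (t >= 0).
langmuir_response <- function(t, ka, kd, Rmax, conc, t_assoc) {
  kobs <- ka * conc + kd
  Req <- if (conc > 0) ka * conc * Rmax / kobs else 0
  R <- numeric(length(t))
  ia <- t <= t_assoc
  R[ia] <- Req * (1 - exp(-kobs * t[ia]))
  if (any(!ia)) {
    R_end <- Req * (1 - exp(-kobs * t_assoc))
    R[!ia] <- R_end * exp(-kd * (t[!ia] - t_assoc))
  }
  R
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Noise-free trace of the single-site model A + L = AL. During association
#' the closed form is R(t) = Req (1 - exp(-(ka C + kd) t)) with
#' Req = ka C Rmax / (ka C + kd); during dissociation the response decays
#' exponentially at rate kd from its value at the end of injection.
#'
#' @param params a [kinetic_params()] of kind `langmuir_1to1`.
#' @param conc analyte concentration in M (>= 0).
#' @param sched a [phase_schedule()].
#' @param label label attached to the returned trace.
#' @return A [sensorgram()] over `[0, t_assoc + t_dissoc]` with R(0) = 0.
#' @examples
#' p <- kinetic_params("langmuir_1to1", ka1 = 5.9e6, kd1 = 8.5e-5, Rmax1 = 100)
#' s <- simulate_langmuir(p, conc = 250e-12, phase_schedule())
#' @export
simulate_langmuir <- function(params, conc, sched = phase_schedule(), label = "") {
  stopifnot(inherits(params, "kinetic_params"), inherits(sched, "phase_schedule"))
  if (params$kind != "langmuir_1to1")
    stop("simulate_langmuir requires params of kind 'langmuir_1to1'")
  if (!is.numeric(conc) || !is.finite(conc) || conc < 0)
    stop("'conc' must be a finite concentration >= 0")
  t <- schedule_grid(sched)
  R <- langmuir_response(t, params$ka1, params$kd1, params$Rmax1, conc,
                         sched$t_assoc)
  sensorgram(t, R, conc, sched, label)
}

#' Simulate a heterogeneous-ligand sensorgram
#'
#' Two independent immobilized site classes, each following its own 1:1
#' kinetics against the same analyte; the observed response is the sum of
#' the two site contributions.
#'
#' @inheritParams simulate_langmuir
#' @param params a [kinetic_params()] of kind `heterogeneous_ligand`.
#' @return A [sensorgram()]; the per-site traces are attached as the
#'   `"components"` attribute (two-column matrix).
#' @export
simulate_heterogeneous_ligand <- function(params, conc, sched = phase_schedule(),
                                          label = "") {
  stopifnot(inherits(params, "kinetic_params"), inherits(sched, "phase_schedule"))
  if (params$kind != "heterogeneous_ligand")
    stop("simulate_heterogeneous_ligand requires params of kind 'heterogeneous_ligand'")
  if (!is.numeric(conc) || !is.finite(conc) || conc < 0)
    stop("'conc' must be a finite concentration >= 0")
  t <- schedule_grid(sched)
  R1 <- langmuir_response(t, params$ka1, params$kd1, params$Rmax1, conc, sched$t_assoc)
  R2 <- if (params$ka2 > 0)
    langmuir_response(t, params$ka2, params$kd2, params$Rmax2, conc, sched$t_assoc)
  else rep(0, length(t))
  out <- sensorgram(t, R1 + R2, conc, sched, label)
  attr(out, "components") <- cbind(site1 = R1, site2 = R2)
  out
}

# Integrate a two-state model over the association then dissociation phase,
# with the analyte switched off at t_assoc. `deriv(t, state, conc)` returns
# the state derivative. Returns the state matrix on the schedule grid.
integrate_phases <- function(deriv, state0, sched, conc_assoc,
                             rtol = 1e-8, atol = 1e-10) {
  t <- schedule_grid(sched)
  ta <- sched$t_assoc
  t1 <- t[t <= ta + 1e-12]
  if (abs(t1[length(t1)] - ta) > 1e-9) t1 <- c(t1, ta)
  f1 <- function(tt, y, parms) list(deriv(tt, y, conc_assoc))
  out1 <- deSolve::ode(y = state0, times = t1, func = f1, parms = NULL,
                       method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out1, "istate")[1L] < 0)
    stop("ODE integration failed during association (conc = ", conc_assoc, ")")
  t2 <- t[t > ta + 1e-12]
  if (length(t2)) {
    y_ta <- out1[nrow(out1), -1L]
    f2 <- function(tt, y, parms) list(deriv(tt, y, 0))
    out2 <- deSolve::ode(y = y_ta, times = c(ta, t2), func = f2, parms = NULL,
                         method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out2, "istate")[1L] < 0)
      stop("ODE integration failed during dissociation (conc = ", conc_assoc, ")")
  }
  # assemble states on the requested grid
  res <- matrix(NA_real_, length(t), length(state0))
  for (j in seq_along(state0)) {
    res[t <= ta + 1e-12, j] <- out1[match(round(t[t <= ta + 1e-12], 9),
                                          round(out1[, 1L], 9)), j + 1L]
    if (length(t2))
      res[t > ta + 1e-12, j] <- out2[match(round(t2, 9), round(out2[, 1L], 9)), j + 1L]
  }
  colnames(res) <- names(state0)
  list(time = t, state = res)
}

#' Simulate a bivalent-analyte sensorgram
#'
#' The analyte carries two equivalent binding moieties. A first surface
#' attachment (rate constants 2*ka1 / kd1, with the statistical factor 2 for
#' two free moieties) forms a singly-bound complex of response R1; a second
#' attachment of the remaining moiety to a free surface site
#' (ka2 in RU^-1 s^-1, detachment 2*kd2) converts it to a doubly-bound
#' complex R2. Free capacity is Rmax1 - R1 - R2 and the observed response is
#' R1 + R2. Integrated with an adaptive solver (rtol 1e-8, atol 1e-10).
#'
#' @inheritParams simulate_langmuir
#' @param params a [kinetic_params()] of kind `bivalent_analyte`.
#' @return A [sensorgram()] with the per-state traces in the `"components"`
#'   attribute.
#' @export
simulate_bivalent_analyte <- function(params, conc, sched = phase_schedule(),
                                      label = "") {
  stopifnot(inherits(params, "kinetic_params"), inherits(sched, "phase_schedule"))
  if (params$kind != "bivalent_analyte")
    stop("simulate_bivalent_analyte requires params of kind 'bivalent_analyte'")
  if (!is.numeric(conc) || !is.finite(conc) || conc < 0)
    stop("'conc' must be a finite concentration >= 0")
  ka1 <- params$ka1; kd1 <- params$kd1; Rmax <- params$Rmax1
  ka2 <- params$ka2; kd2 <- params$kd2
  deriv <- function(t, y, C) {
    free <- Rmax - y[1L] - y[2L]
    d1 <- 2 * ka1 * C * free - kd1 * y[1L] - ka2 * y[1L] * free + 2 * kd2 * y[2L]
    d2 <- ka2 * y[1L] * free - 2 * kd2 * y[2L]
    c(d1, d2)
  }
  sol <- integrate_phases(deriv, c(R1 = 0, R2 = 0), sched, conc)
  out <- sensorgram(sol$time, sol$state[, 1L] + sol$state[, 2L], conc, sched, label)
  attr(out, "components") <- sol$state
  out
}

#' Simulate a heterogeneous-analyte sensorgram
#'
#' Two analyte species A and B compete for one shared surface capacity:
#' dRi/dt = kai Ci (Rmax - R1 - R2) - kdi Ri. The observed response is
#' R1 + R2 and can never exceed Rmax1.
#'
#' @inheritParams simulate_langmuir
#' @param params a [kinetic_params()] of kind `heterogeneous_analyte`;
#'   (`ka1`,`kd1`) belong to species A, (`ka2`,`kd2`) to species B.
#' @param conc_a,conc_b concentrations of the two species in M (>= 0).
#' @return A [sensorgram()] with `conc = conc_a`, `conc_b = conc_b` and the
#'   per-species traces in the `"components"` attribute.
#' @export
simulate_heterogeneous_analyte <- function(params, conc_a, conc_b,
                                           sched = phase_schedule(), label = "") {
  stopifnot(inherits(params, "kinetic_params"), inherits(sched, "phase_schedule"))
  if (params$kind != "heterogeneous_analyte")
    stop("simulate_heterogeneous_analyte requires params of kind 'heterogeneous_analyte'")
  for (cc in c(conc_a, conc_b))
    if (!is.numeric(cc) || !is.finite(cc) || cc < 0)
      stop("concentrations must be finite and >= 0")
  ka1 <- params$ka1; kd1 <- params$kd1; Rmax <- params$Rmax1
  ka2 <- params$ka2; kd2 <- params$kd2
  deriv <- function(t, y, on) {
    free <- Rmax - y[1L] - y[2L]
    c(ka1 * (conc_a * on) * free - kd1 * y[1L],
      ka2 * (conc_b * on) * free - kd2 * y[2L])
  }
  # `on` switches both injections off together at t_assoc
  sol <- integrate_phases(deriv, c(RA = 0, RB = 0), sched, 1)
  out <- sensorgram(sol$time, sol$state[, 1L] + sol$state[, 2L], conc_a, sched,
                    label, conc_b = conc_b)
  attr(out, "components") <- sol$state
  out
}

#' Equilibrium (steady-state) response
#'
#' Closed-form t -> Inf limit of the association phase for the 1:1 and
#' heterogeneous-ligand models: sum over sites of Rmax_i C / (C + kd_i/ka_i).
#'
#' @param params a [kinetic_params()] of kind `langmuir_1to1` or
#'   `heterogeneous_ligand`.
#' @param conc analyte concentration in M (>= 0); may be vectorized.
#' @return Equilibrium response in RU.
#' @export
equilibrium_response <- function(params, conc) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!params$kind %in% c("langmuir_1to1", "heterogeneous_ligand"))
    stop("equilibrium_response supports only 'langmuir_1to1' and 'heterogeneous_ligand' models")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be finite and >= 0")
  KD1 <- params$kd1 / params$ka1
  R <- params$Rmax1 * conc / (conc + KD1)
  if (params$kind == "heterogeneous_ligand" && params$ka2 > 0) {
    KD2 <- params$kd2 / params$ka2
    R <- R + params$Rmax2 * conc / (conc + KD2)
  }
  R
}

#' Equilibrium dissociation constant from rate constants
#'
#' KD = kd / ka, with first-order (delta-method) error propagation when
#' standard errors of the rate constants are supplied:
#' se_KD = KD * sqrt((se_ka/ka)^2 + (se_kd/kd)^2).
#'
#' @param ka association rate constant, M^-1 s^-1 (> 0).
#' @param kd dissociation rate constant, s^-1 (> 0).
#' @param se_ka,se_kd optional standard errors (>= 0).
#' @return A list with elements `KD` (M) and `se_KD` (M or NA when no
#'   errors were supplied).
#' @examples
#' kd_from_rates(5.9e6, 8.5e-5, se_ka = 1.3e6, se_kd = 2.5e-5)
#' @export
kd_from_rates <- function(ka, kd, se_ka = NULL, se_kd = NULL) {
  if (!is.numeric(ka) || any(!is.finite(ka)) || any(ka <= 0))
    stop("'ka' must be positive and finite")
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be positive and finite")
  KD <- kd / ka
  se_KD <- NA_real_
  if (!is.null(se_ka) && !is.null(se_kd)) {
    if (any(is.finite(se_ka) & se_ka < 0) || any(is.finite(se_kd) & se_kd < 0))
      stop("standard errors must be >= 0")
    # undefined (NA) input errors propagate as NA rather than failing
    se_KD <- KD * sqrt((se_ka / ka)^2 + (se_kd / kd)^2)
  }
  list(KD = KD, se_KD = se_KD)
}
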