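#' ELISA dose-response curve
#'
#' Concentration-signal pairs from a plate assay: either a saturation
#' (direct binding) series, where signal rises with lectin concentration,
#' or a competitive inhibition series, where signal falls with inhibitor
#' concentration. Signals are absorbance readings (e.g. OD450); the
#' concentration unit is whatever the caller used, and fitted Kd/IC50 are
#' reported in that same unit.
#'
#' @param conc concentrations (>= 0, pairwise distinct, >= 5 values for
#'   fitting).
#' @param signal absorbance signals, same length, finite.
#' @param mode `"saturation"` or `"inhibition"`.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(conc, signal, mode = c("saturation", "inhibition")) {
  mode <- match.arg(mode)
  conc <- as.numeric(conc); signal <- as.numeric(signal)
  if (length(conc) != length(signal)) stop("'conc' and 'signal' lengths differ")
  if (any(!is.finite(conc)) || any(conc < 0)) stop("'conc' must be finite and >= 0")
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  if (anyDuplicated(conc)) stop("'conc' values must be pairwise distinct")
  structure(list(conc = conc, signal = signal, mode = mode),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve (%s): %d points, conc in [%.3g, %.3g]\n",
              x$mode, length(x$conc), min(x$conc), max(x$conc)))
  invisible(x)
}

#' @export
as.data.frame.dose_response_curve <- function(x, ...) {
  data.frame(conc = x$conc, signal = x$signal, mode = x$mode)
}

elisa_se <- function(resid_fn, theta, lower, upper, rss, dof) {
  p <- length(theta)
  se <- rep(NA_real_, p)
  J <- tryCatch({
    eps <- pmax(abs(theta) * 1e-6, 1e-8)
    do.call(cbind, lapply(seq_len(p), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- min(tp[j] + eps[j], upper[j])
      tm[j] <- max(tm[j] - eps[j], lower[j])
      (resid_fn(tp) - resid_fn(tm)) / (tp[j] - tm[j])
    }))
  }, error = function(e) NULL)
  if (!is.null(J) && dof > 0) {
    cv <- tryCatch(rss / dof * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  se
}

#' Fit a one-site saturation binding curve
#'
#' Nonlinear least-squares fit of the one-site specific-binding model
#' S(c) = background + Smax c / (Kd_app + c), the standard description of a
#' single carbohydrate-recognition domain titrated against an immobilized
#' (multivalent) ligand in excess. `Kd_app` is fitted on a log10 scale and
#' reported in the unit of the input concentrations.
#'
#' @param curve a [dose_response_curve()] with `mode = "saturation"` and at
#'   least 5 points.
#' @return A list of class `elisa_fit`: `Kd_app`, `Smax`, `background`,
#'   their standard errors, `rss`, `dof`, `fitted`, and possibly a
#'   `warnings` character vector (e.g. when the fitted Kd falls outside
#'   100x the sampled concentration range, indicating no usable curvature).
#' @export
fit_saturation <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (curve$mode != "saturation") stop("curve mode must be 'saturation'")
  if (length(curve$conc) < 5L) stop("need >= 5 points to fit")
  cc <- curve$conc; ss <- curve$signal
  pos <- cc[cc > 0]
  lKd_bounds <- c(log10(min(pos)) - 6, log10(max(pos)) + 6)
  smax0 <- max(ss) - min(ss)
  bg0 <- min(ss)
  half <- bg0 + smax0 / 2
  Kd0 <- if (smax0 > 0) cc[which.min(abs(ss - half))] else stats::median(pos)
  Kd0 <- min(max(Kd0, 10^lKd_bounds[1]), 10^lKd_bounds[2])
  theta0 <- c(log10(Kd0), smax0, bg0)
  lower <- c(lKd_bounds[1], 0, -Inf)
  upper <- c(lKd_bounds[2], Inf, Inf)
  model <- function(th) th[3] + th[2] * cc / (10^th[1] + cc)
  resid_fn <- function(th) ss - model(th)
  fit <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-12, ftol = 1e-12))
  th <- fit$par
  rss <- fit$deviance
  dof <- length(ss) - length(th)
  se <- elisa_se(resid_fn, th, lower, upper, rss, dof)
  Kd <- 10^th[1]
  se_Kd <- log(10) * Kd * se[1]
  warns <- character()
  if (Kd < min(pos) / 100 || Kd > max(pos) * 100)
    warns <- c(warns, sprintf(
      "ill-conditioned: fitted Kd_app (%.3g) lies outside 100x the sampled concentration range [%.3g, %.3g]",
      Kd, min(pos), max(pos)))
  structure(list(Kd_app = Kd, Smax = th[2], background = th[3],
                 se = c(Kd_app = se_Kd, Smax = se[2], background = se[3]),
                 rss = rss, dof = dof, fitted = model(th),
                 warnings = warns, mode = "saturation"),
            class = "elisa_fit")
}

#' Fit a sigmoidal (four-parameter logistic) inhibition curve
#'
#' Nonlinear least-squares fit of
#' S(i) = bottom + (top - bottom) / (1 + (i / IC50)^hill)
#' to a competitive-inhibition series. The Hill coefficient is free within
#' \[0.3, 5\] by default; IC50 is fitted on a log10 scale and reported in
#' the unit of the input concentrations. The fitted curve passes through
#' (top + bottom)/2 at i = IC50 by construction.
#'
#' @param curve a [dose_response_curve()] with `mode = "inhibition"` and at
#'   least 5 points.
#' @param hill_bounds allowed Hill-coefficient range.
#' @return A list of class `elisa_fit`: `IC50`, `top`, `bottom`, `hill`,
#'   standard errors, `rss`, `dof`, `fitted`, and a `warnings` vector (a
#'   poor-fit warning with RSS diagnostics is attached when the data rise
#'   with concentration beyond noise).
#' @export
fit_inhibition <- function(curve, hill_bounds = c(0.3, 5)) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (curve$mode != "inhibition") stop("curve mode must be 'inhibition'")
  if (length(curve$conc) < 5L) stop("need >= 5 points to fit")
  cc <- curve$conc; ss <- curve$signal
  pos <- cc[cc > 0]
  lIC_bounds <- c(log10(min(pos)) - 6, log10(max(pos)) + 6)
  top0 <- max(ss); bot0 <- min(ss)
  half <- (top0 + bot0) / 2
  IC0 <- cc[which.min(abs(ss - half))]
  IC0 <- min(max(IC0, 10^lIC_bounds[1]), 10^lIC_bounds[2])
  theta0 <- c(log10(IC0), top0, bot0, 1)
  lower <- c(lIC_bounds[1], -Inf, -Inf, hill_bounds[1])
  upper <- c(lIC_bounds[2], Inf, Inf, hill_bounds[2])
  model <- function(th) {
    ic <- 10^th[1]
    th[3] + (th[2] - th[3]) / (1 + (cc / ic)^th[4])
  }
  resid_fn <- function(th) ss - model(th)
  fit <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-12, ftol = 1e-12))
  th <- fit$par
  rss <- fit$deviance
  dof <- length(ss) - length(th)
  se <- elisa_se(resid_fn, th, lower, upper, rss, dof)
  IC50 <- 10^th[1]
  warns <- character()
  # monotonicity check: signal should fall with inhibitor concentration
  ord <- order(cc)
  rho <- suppressWarnings(stats::cor(cc[ord], ss[ord], method = "spearman"))
  if (is.finite(rho) && rho > 0.5)
    warns <- c(warns, sprintf(
      "poor fit: signal rises with inhibitor concentration (spearman rho = %.2f, RSS = %.4g)",
      rho, rss))
  structure(list(IC50 = IC50, top = th[2], bottom = th[3], hill = th[4],
                 se = c(IC50 = log(10) * IC50 * se[1], top = se[2],
                        bottom = se[3], hill = se[4]),
                 rss = rss, dof = dof, fitted = model(th),
                 warnings = warns, mode = "inhibition"),
            class = "elisa_fit")
}

#' @export
print.elisa_fit <- function(x, ...) {
  if (x$mode == "saturation") {
    cat(sprintf("Saturation fit: Kd_app = %.4g (se %.3g), Smax = %.4g, background = %.4g\n",
                x$Kd_app, x$se[["Kd_app"]], x$Smax, x$background))
  } else {
    cat(sprintf("Inhibition fit: IC50 = %.4g (se %.3g), top = %.4g, bottom = %.4g, hill = %.3g\n",
                x$IC50, x$se[["IC50"]], x$top, x$bottom, x$hill))
  }
  cat(sprintf("  RSS = %.4g on %d dof\n", x$rss, x$dof))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Relative potency of a multivalent neo-glycoprotein
#'
#' Quantifies the cluster glycoside effect: the relative potency is the
#' IC50 of the monovalent glycan divided by the IC50 of the multivalent
#' neo-glycoprotein carrying it (both converted to a common unit before the
#' ratio), and the relative potency per glycan divides that by the average
#' number `m` of glycans conjugated to the carrier protein. Values above 1
#' per glycan indicate a greater-than-additive gain from multivalent
#' presentation.
#'
#' @param ic50_glycan IC50 of the free monovalent glycan, in micromolar.
#' @param ic50_neo IC50 of the neo-glycoprotein, in nanomolar.
#' @param m average number of glycans per carrier molecule (> 0).
#' @return A list of class `potency_record`: `ic50_glycan_uM`,
#'   `ic50_neo_nM`, `m`, `rp` and `rp_per_glycan`.
#' @examples
#' relative_potency(42, 2026, 17)  # rp 20.7, rp/m 1.2
#' @export
relative_potency <- function(ic50_glycan, ic50_neo, m) {
  for (v in list(ic50_glycan, ic50_neo, m))
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("all inputs must be positive and finite")
  rp <- (ic50_glycan * 1000) / ic50_neo  # both in nM
  structure(list(ic50_glycan_uM = ic50_glycan, ic50_neo_nM = ic50_neo, m = m,
                 rp = rp, rp_per_glycan = rp / m),
            class = "potency_record")
}

#' @export
print.potency_record <- function(x, ...) {
  cat(sprintf("Relative potency: IC50(glycan) = %.4g uM, IC50(neo) = %.4g nM, m = %g\n",
              x$ic50_glycan_uM, x$ic50_neo_nM, x$m))
  cat(sprintf("  rp = %.4g, rp/m = %.4g\n", x$rp, x$rp_per_glycan))
  invisible(x)
}
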