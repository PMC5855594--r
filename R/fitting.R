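#' Options controlling a global kinetic fit
#'
#' The optimizer works in transformed parameter space: rate constants are
#' fitted as log10 values (they span decades, and log-space stabilizes the
#' Jacobian), capacities and per-curve offsets linearly. Starting points are
#' one data-driven heuristic start (dissociation rate from the tail slope of
#' the highest-concentration curve, association rate from end-of-injection
#' responses versus concentration) plus `starts - 1` Latin-hypercube draws
#' over the bounds, all run to convergence; the lowest residual sum of
#' squares wins.
#'
#' @param starts total number of optimizer starts (>= 1; the first is the
#'   heuristic start).
#' @param seed integer seed controlling the Latin-hypercube draws.
#' @param offsets logical; fit an additive per-curve baseline offset.
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @param ka_bounds,kd_bounds bounds on first-event (and heterogeneous
#'   second-site) rate constants, in M^-1 s^-1 and s^-1. Defaults cover the
#'   physically plausible biosensor range.
#' @param ka2_bounds bounds for second-step rate constants expressed per
#'   response unit (bivalent-analyte model only), RU^-1 s^-1.
#' @param rmax_factor upper bound on fitted capacity as a multiple of the
#'   largest observed response.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(starts = 8L, seed = 1L, offsets = FALSE, maxit = 200L,
                        ka_bounds = c(1e2, 1e9), kd_bounds = c(1e-6, 1),
                        ka2_bounds = c(1e-8, 1), rmax_factor = 10) {
  stopifnot(starts >= 1, maxit >= 1, ka_bounds[1] > 0, kd_bounds[1] > 0,
            ka2_bounds[1] > 0, rmax_factor > 0)
  structure(list(starts = as.integer(starts), seed = as.integer(seed),
                 offsets = isTRUE(offsets), maxit = as.integer(maxit),
                 ka_bounds = ka_bounds, kd_bounds = kd_bounds,
                 ka2_bounds = ka2_bounds, rmax_factor = rmax_factor),
            class = "fit_options")
}

# --- parameterization ------------------------------------------------------

# Describe the transformed parameter vector for a model kind.
# Each parameter: name in natural units, transform ("log10" or "identity"),
# lower/upper bounds in transformed space.
par_spec <- function(kind, options, max_obs) {
  lb <- function(x) log10(x)
  rmax_hi <- options$rmax_factor * max(max_obs, 1e-6)
  base <- switch(kind,
    langmuir_1to1 = data.frame(
      name = c("ka1", "kd1", "Rmax1"),
      transform = c("log10", "log10", "identity"),
      lower = c(lb(options$ka_bounds[1]), lb(options$kd_bounds[1]), 1e-6),
      upper = c(lb(options$ka_bounds[2]), lb(options$kd_bounds[2]), rmax_hi)),
    heterogeneous_ligand = data.frame(
      name = c("ka1", "kd1", "Rmax1", "ka2", "kd2", "Rmax2"),
      transform = c("log10", "log10", "identity", "log10", "log10", "identity"),
      lower = c(lb(options$ka_bounds[1]), lb(options$kd_bounds[1]), 1e-6,
                lb(options$ka_bounds[1]), lb(options$kd_bounds[1]), 1e-6),
      upper = c(lb(options$ka_bounds[2]), lb(options$kd_bounds[2]), rmax_hi,
                lb(options$ka_bounds[2]), lb(options$kd_bounds[2]), rmax_hi)),
    bivalent_analyte = data.frame(
      name = c("ka1", "kd1", "Rmax1", "ka2", "kd2"),
      transform = c("log10", "log10", "identity", "log10", "log10"),
      lower = c(lb(options$ka_bounds[1]), lb(options$kd_bounds[1]), 1e-6,
                lb(options$ka2_bounds[1]), lb(options$kd_bounds[1])),
      upper = c(lb(options$ka_bounds[2]), lb(options$kd_bounds[2]), rmax_hi,
                lb(options$ka2_bounds[2]), lb(options$kd_bounds[2]))),
    heterogeneous_analyte = data.frame(
      name = c("ka1", "kd1", "Rmax1", "ka2", "kd2"),
      transform = c("log10", "log10", "identity", "log10", "log10"),
      lower = c(lb(options$ka_bounds[1]), lb(options$kd_bounds[1]), 1e-6,
                lb(options$ka_bounds[1]), lb(options$kd_bounds[1])),
      upper = c(lb(options$ka_bounds[2]), lb(options$kd_bounds[2]), rmax_hi,
                lb(options$ka_bounds[2]), lb(options$kd_bounds[2]))),
    stop("unknown model kind '", kind, "'"))
  base
}

to_natural <- function(theta, spec) {
  x <- ifelse(spec$transform == "log10", 10^theta, theta)
  names(x) <- spec$name
  x
}

to_transformed <- function(natural, spec) {
  x <- ifelse(spec$transform == "log10", log10(natural), natural)
  pmin(pmax(x, spec$lower), spec$upper)
}

# Kinetic parameters object from a natural-parameter vector.
params_from_vector <- function(kind, p) {
  switch(kind,
    langmuir_1to1 = kinetic_params(kind, p[["ka1"]], p[["kd1"]], p[["Rmax1"]]),
    heterogeneous_ligand = kinetic_params(kind, p[["ka1"]], p[["kd1"]],
                                          p[["Rmax1"]], p[["ka2"]], p[["kd2"]],
                                          p[["Rmax2"]]),
    bivalent_analyte = kinetic_params(kind, p[["ka1"]], p[["kd1"]], p[["Rmax1"]],
                                      p[["ka2"]], p[["kd2"]]),
    heterogeneous_analyte = kinetic_params(kind, p[["ka1"]], p[["kd1"]],
                                           p[["Rmax1"]], p[["ka2"]], p[["kd2"]]))
}

# Predicted responses for every curve of a series under natural parameters.
predict_series <- function(kind, p, series) {
  params <- params_from_vector(kind, p)
  lapply(series$curves, function(cv) {
    t <- cv$time
    ta <- cv$schedule$t_assoc
    if (kind == "langmuir_1to1") {
      r <- langmuir_response(pmax(t, 0), p[["ka1"]], p[["kd1"]], p[["Rmax1"]],
                             cv$conc, ta)
    } else if (kind == "heterogeneous_ligand") {
      r <- langmuir_response(pmax(t, 0), p[["ka1"]], p[["kd1"]], p[["Rmax1"]],
                             cv$conc, ta) +
           langmuir_response(pmax(t, 0), p[["ka2"]], p[["kd2"]], p[["Rmax2"]],
                             cv$conc, ta)
    } else if (kind == "bivalent_analyte") {
      s <- simulate_bivalent_analyte(params, cv$conc, cv$schedule)
      r <- s$response
    } else {
      s <- simulate_heterogeneous_analyte(params, cv$conc, cv$conc_b, cv$schedule)
      r <- s$response
    }
    r[t < 0] <- 0
    r
  })
}

# Heuristic natural-parameter start from linearized 1:1 kinetics: during
# association dR/dt = ka C Rmax - (ka C + kd) R, so regressing dR/dt on R per
# curve gives the observed rate kobs_i and intercept ka C_i Rmax; regressing
# kobs on C gives ka (slope) and kd (intercept). The dissociation tail slope
# of the highest-concentration curve refines kd when usable.
heuristic_start <- function(series) {
  concs <- vapply(series$curves, `[[`, numeric(1), "conc")
  ta <- series$curves[[1L]]$schedule$t_assoc
  kobs <- icpt <- rep(NA_real_, length(series$curves))
  for (i in seq_along(series$curves)) {
    cv <- series$curves[[i]]
    ia <- which(cv$time >= 0 & cv$time <= ta)
    if (length(ia) < 5L) next
    R <- cv$response[ia]; tt <- cv$time[ia]
    dR <- diff(R) / diff(tt)
    Rm <- (R[-1L] + R[-length(R)]) / 2
    co <- tryCatch(stats::coef(stats::lm(dR ~ Rm)), error = function(e) c(NA, NA))
    if (all(is.finite(co)) && co[2L] < 0) {
      kobs[i] <- -co[2L]; icpt[i] <- co[1L]
    }
  }
  ok <- is.finite(kobs) & concs > 0
  ka0 <- 1e6; kd0 <- 1e-3; Rmax0 <- 1.5 * max(vapply(series$curves, function(cv)
    max(cv$response), numeric(1)))
  if (sum(ok) >= 2L) {
    co <- stats::coef(stats::lm(kobs[ok] ~ concs[ok]))
    if (is.finite(co[2L]) && co[2L] > 0) ka0 <- min(max(co[2L], 1e2), 1e9)
    if (is.finite(co[1L]) && co[1L] > 0) kd0 <- min(max(co[1L], 1e-6), 1)
    rm0 <- stats::median(icpt[ok] / (ka0 * concs[ok]), na.rm = TRUE)
    if (is.finite(rm0) && rm0 > 0) Rmax0 <- rm0
  }
  # refine kd from the dissociation tail of the highest-concentration curve
  hi <- series$curves[[which.max(concs)]]
  dis <- hi$time > ta & hi$response > 0
  if (sum(dis) >= 3L) {
    sl <- stats::coef(stats::lm(log(hi$response[dis]) ~ hi$time[dis]))[2L]
    if (is.finite(sl) && sl < 0) kd0 <- min(max(-sl, 1e-6), 1)
  }
  c(ka1 = ka0, kd1 = kd0, Rmax1 = Rmax0)
}

# Expand the 1:1 heuristic into a small family of plausible starts for the
# two-event models (second-event rates around the first-event estimates).
expand_start <- function(kind, h) {
  ka <- unname(h["ka1"]); kd <- unname(h["kd1"]); Rm <- unname(h["Rmax1"])
  cl <- function(x, lo, hi) min(max(x, lo), hi)
  switch(kind,
    langmuir_1to1 = list(h),
    heterogeneous_ligand = lapply(c(10, 100), function(f)
      c(ka1 = ka, kd1 = kd, Rmax1 = Rm / 2, ka2 = ka / f,
        kd2 = cl(kd * f, 1e-6, 1), Rmax2 = Rm / 2)),
    bivalent_analyte = {
      out <- list()
      for (ka2 in c(1e-5, 1e-3, 1e-1))
        for (f2 in c(1, 10))
          out[[length(out) + 1L]] <-
            c(ka1 = ka, kd1 = kd, Rmax1 = Rm, ka2 = ka2,
              kd2 = cl(kd * f2, 1e-6, 1))
      out
    },
    heterogeneous_analyte = {
      out <- list()
      for (f1 in c(1, 10))
        for (f2 in c(1, 10))
          out[[length(out) + 1L]] <-
            c(ka1 = ka, kd1 = kd, Rmax1 = Rm, ka2 = cl(ka * f1, 1e2, 1e9),
              kd2 = cl(kd * f2, 1e-6, 1))
      out
    })
}

#' Global fit of a sensorgram series to a kinetic model
#'
#' Fits one kinetic model to all curves of a series jointly: rate constants
#' and capacities are shared across curves (optionally with a per-curve
#' additive offset), and the summed squared residual over every sample of
#' every curve is minimized by bounded Levenberg-Marquardt from multiple
#' starting points (see [fit_options()]). Standard errors come from the
#' Jacobian-based covariance at the optimum (residual variance RSS/dof) and
#' equilibrium dissociation constants are derived per [kd_from_rates()]
#' with first-order error propagation.
#'
#' @param series a [sensorgram_series()] with at least two distinct
#'   concentrations and at least 10 samples per phase.
#' @param kind model kind (see [kinetic_params()]).
#' @param options a [fit_options()] list.
#' @return An object of class `spr_fit`: named `estimates` and `se` in
#'   natural units, derived `KD` (with `KD2` for two-site kinds) and
#'   propagated errors, `rss`, `dof`, per-curve `fitted` traces,
#'   `converged`, and the seed/starts used.
#' @export
global_fit <- function(series, kind, options = fit_options()) {
  stopifnot(inherits(series, "sensorgram_series"))
  kind <- match.arg(kind, c("langmuir_1to1", "heterogeneous_ligand",
                            "bivalent_analyte", "heterogeneous_analyte"))
  if (!inherits(options, "fit_options")) stop("'options' must be a fit_options() list")
  concs <- vapply(series$curves, `[[`, numeric(1), "conc")
  if (length(unique(concs)) < 2L)
    stop("global fitting needs >= 2 distinct analyte concentrations")
  cv1 <- series$curves[[1L]]
  if (is.null(cv1$schedule)) stop("curves must carry a phase schedule")
  ta <- cv1$schedule$t_assoc
  n_assoc <- sum(cv1$time >= 0 & cv1$time <= ta)
  n_dissoc <- sum(cv1$time > ta)
  if (n_assoc < 10L || (cv1$schedule$t_dissoc > 0 && n_dissoc < 10L))
    stop("each phase must contain >= 10 samples")

  obs <- lapply(series$curves, `[[`, "response")
  n_obs <- sum(lengths(obs))
  max_obs <- max(unlist(obs))
  spec <- par_spec(kind, options, max_obs)
  n_curve <- length(series$curves)
  n_off <- if (options$offsets) n_curve else 0L

  resid_fn <- function(theta) {
    p <- to_natural(theta[seq_len(nrow(spec))], spec)
    off <- if (n_off) theta[nrow(spec) + seq_len(n_off)] else rep(0, n_curve)
    pred <- tryCatch(predict_series(kind, p, series), error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, n_obs))
    unlist(Map(function(o, f, oo) o - (f + oo), obs, pred, off))
  }

  lower <- c(spec$lower, rep(-Inf, n_off))
  upper <- c(spec$upper, rep(Inf, n_off))

  # Starting points: data-driven heuristic family, plus Latin-hypercube
  # candidates screened by a single residual evaluation; only the
  # best-ranked candidates are polished by Levenberg-Marquardt.
  hs <- expand_start(kind, heuristic_start(series))
  starts <- lapply(hs, function(h)
    c(to_transformed(h[spec$name], spec), rep(0, n_off)))
  n_lhs <- max(0L, options$starts - length(starts))
  if (n_lhs > 0L) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(options$seed)
    u <- lhs::randomLHS(min(10L * n_lhs, 200L), nrow(spec))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    cand <- lapply(seq_len(nrow(u)), function(i)
      c(spec$lower + u[i, ] * (spec$upper - spec$lower), rep(0, n_off)))
    rss0 <- vapply(cand, function(th) sum(resid_fn(th)^2), numeric(1))
    starts <- c(starts, cand[order(rss0)[seq_len(n_lhs)]])
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxit, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("global fit failed from every starting point (kind = ", kind, ")")
  converged <- best$info %in% 1:4

  theta <- best$par
  p_hat <- to_natural(theta[seq_len(nrow(spec))], spec)
  offsets <- if (n_off) theta[nrow(spec) + seq_len(n_off)] else NULL
  rss <- best$deviance
  p_tot <- length(theta)
  dof <- n_obs - p_tot

  # covariance from a central-difference Jacobian at the optimum
  se_theta <- rep(NA_real_, p_tot)
  J <- tryCatch({
    eps <- pmax(abs(theta) * 1e-6, 1e-8)
    cols <- lapply(seq_len(p_tot), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- min(tp[j] + eps[j], upper[j])
      tm[j] <- max(tm[j] - eps[j], lower[j])
      (resid_fn(tp) - resid_fn(tm)) / (tp[j] - tm[j])
    })
    do.call(cbind, cols)
  }, error = function(e) NULL)
  if (!is.null(J) && dof > 0) {
    sigma2 <- rss / dof
    cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se_theta <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  # delta-method back-transform of log10 parameters
  se_nat <- se_theta[seq_len(nrow(spec))]
  is_log <- spec$transform == "log10"
  se_nat[is_log] <- log(10) * p_hat[is_log] * se_nat[is_log]
  names(se_nat) <- spec$name

  KD1 <- kd_from_rates(p_hat[["ka1"]], p_hat[["kd1"]],
                       se_ka = se_nat[["ka1"]], se_kd = se_nat[["kd1"]])
  KD2 <- if (kind != "langmuir_1to1" && p_hat[["ka2"]] > 0)
    kd_from_rates(p_hat[["ka2"]], p_hat[["kd2"]],
                  se_ka = se_nat[["ka2"]], se_kd = se_nat[["kd2"]])
  else NULL

  pred <- predict_series(kind, p_hat, series)
  if (n_off) pred <- Map(`+`, pred, as.list(offsets))

  out <- structure(list(
    kind = kind,
    estimates = p_hat,
    se = se_nat,
    offsets = offsets,
    KD = KD1$KD, se_KD = KD1$se_KD,
    KD2 = if (!is.null(KD2)) KD2$KD else NA_real_,
    se_KD2 = if (!is.null(KD2)) KD2$se_KD else NA_real_,
    rss = rss, dof = dof, n_obs = n_obs, n_par = p_tot,
    fitted = pred,
    converged = converged,
    seed = options$seed, starts = options$starts,
    concs = concs), class = "spr_fit")
  if (!converged) {
    cond <- structure(class = c("sprkin_convergence_error", "error", "condition"),
                      list(message = paste0("global fit did not converge (info = ",
                                            best$info, "); best candidate attached"),
                           call = sys.call(-1), fit = out))
    stop(cond)
  }
  out
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Global kinetic fit [", x$kind, "]\n", sep = "")
  est <- x$estimates
  for (nm in names(est))
    cat(sprintf("  %-6s = %.4g (se %.3g)\n", nm, est[[nm]], x$se[[nm]]))
  cat(sprintf("  KD  = %.4g M (se %.3g)\n", x$KD, x$se_KD))
  if (is.finite(x$KD2)) cat(sprintf("  KD2 = %.4g M (se %.3g)\n", x$KD2, x$se_KD2))
  cat(sprintf("  RSS = %.6g over %d observations (%d parameters)\n",
              x$rss, x$n_obs, x$n_par))
  invisible(x)
}

# Small-sample corrected Akaike information criterion on Gaussian residuals.
aicc_from_rss <- function(rss, n, p) {
  k <- p + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare candidate kinetic models on one series
#'
#' Fits every candidate model kind by [global_fit()] and ranks them by the
#' small-sample corrected Akaike information criterion (AICc) computed on
#' the pooled residuals. Candidates within 2 AICc units of the minimum are
#' treated as ties and resolved toward the model with fewer parameters.
#'
#' @param series a [sensorgram_series()].
#' @param kinds character vector of >= 1 candidate model kinds.
#' @param options a [fit_options()] list applied to every candidate.
#' @return An object of class `model_selection`: a `table` data frame
#'   (kind, parameters, RSS, AICc), the list of `fits`, the `selected` kind
#'   and a human-readable `rationale`.
#' @export
compare_models <- function(series, kinds, options = fit_options()) {
  if (length(kinds) < 1L) stop("need at least one candidate kind")
  fits <- list(); errs <- character()
  for (k in kinds) {
    f <- tryCatch(global_fit(series, k, options), error = function(e) {
      if (inherits(e, "sprkin_convergence_error")) e$fit else e
    })
    if (inherits(f, "spr_fit")) fits[[k]] <- f
    else errs <- c(errs, paste0(k, ": ", conditionMessage(f)))
  }
  if (!length(fits))
    stop("every candidate model failed to fit: ", paste(errs, collapse = "; "))
  tab <- data.frame(
    kind = names(fits),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    row.names = NULL)
  tab$aicc <- mapply(aicc_from_rss, tab$rss, vapply(fits, `[[`, numeric(1), "n_obs"),
                     tab$n_par)
  tied <- which(tab$aicc - min(tab$aicc) < 2)
  sel <- tied[order(tab$n_par[tied], tab$aicc[tied])][1L]
  rationale <- if (length(tied) > 1L)
    sprintf("models %s within 2 AICc units; selected '%s' (fewest parameters)",
            paste(tab$kind[tied], collapse = ", "), tab$kind[sel])
  else
    sprintf("'%s' has the minimal AICc (%.2f)", tab$kind[sel], tab$aicc[sel])
  structure(list(table = tab, fits = fits, selected = tab$kind[sel],
                 rationale = rationale, failed = errs),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Kinetic model comparison\n")
  print(x$table, row.names = FALSE)
  cat("Selected:", x$selected, "-", x$rationale, "\n")
  invisible(x)
}

#' Fold difference between two affinities
#'
#' Ratio of two equilibrium dissociation constants (or any two positive
#' affinity measures), `kd_a / kd_b`; a value above 1 means `a` binds more
#' weakly than `b`.
#'
#' @param kd_a,kd_b positive dissociation constants in a common unit.
#' @return The dimensionless ratio.
#' @export
fold_difference <- function(kd_a, kd_b) {
  if (any(!is.finite(kd_a)) || any(kd_a <= 0) ||
      any(!is.finite(kd_b)) || any(kd_b <= 0))
    stop("both affinities must be positive and finite")
  kd_a / kd_b
}
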