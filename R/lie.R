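#' Linear Interaction Energy binding free energy
#'
#' End-point free-energy estimate from mean ligand-environment interaction
#' energies in the protein-bound and free (solvated) states:
#' \deqn{\Delta G = \alpha (\langle V_{LJ} \rangle_{bound} -
#'   \langle V_{LJ} \rangle_{free}) + \beta (\langle V_{el} \rangle_{bound} -
#'   \langle V_{el} \rangle_{free})}
#' The default scaling factors are alpha = 0.181 for the Lennard-Jones term
#' and beta = 0.3 for the electrostatic term.
#'
#' @param vdw_bound,vdw_free mean Lennard-Jones ligand-environment
#'   interaction energies (kJ/mol) in the bound and free state.
#' @param elec_bound,elec_free mean electrostatic interaction energies
#'   (kJ/mol).
#' @param alpha,beta non-negative dimensionless scaling factors.
#' @return Binding free energy estimate in kJ/mol.
#' @examples
#' lie_free_energy(-100, 0, -50, 0)  # 0.181*(-100) + 0.3*(-50) = -33.1
#' @export
lie_free_energy <- function(vdw_bound, vdw_free, elec_bound, elec_free,
                            alpha = 0.181, beta = 0.3) {
  for (v in list(vdw_bound, vdw_free, elec_bound, elec_free))
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("all interaction energies must be finite numbers")
  if (!is.finite(alpha) || alpha < 0 || !is.finite(beta) || beta < 0)
    stop("'alpha' and 'beta' must be >= 0")
  alpha * (vdw_bound - vdw_free) + beta * (elec_bound - elec_free)
}

#' Read an interaction-energy time series
#'
#' Reads a two-column delimited text file with columns `time_ps` and
#' `energy_kJ_mol`, the usual export of per-frame ligand-environment
#' interaction energies from a molecular-dynamics trajectory.
#'
#' @param path file path (CSV).
#' @return A data frame with columns `time_ps` and `energy_kJ_mol`.
#' @export
read_energy_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ps", "energy_kJ_mol")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("energy series '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  for (nm in need) {
    if (!is.numeric(d[[nm]])) stop("column '", nm, "' must be numeric")
    if (any(!is.finite(d[[nm]]))) stop("column '", nm, "' contains non-finite values")
  }
  if (any(diff(d$time_ps) <= 0)) stop("'time_ps' must be strictly increasing")
  d[need]
}

#' Tail-window mean of an energy time series
#'
#' Average of the energy over the final window of the trajectory (default
#' 10 ns = 10000 ps), the equilibrated segment conventionally used for
#' end-point free-energy estimates.
#'
#' @param series data frame from [read_energy_series()] (or with the same
#'   columns).
#' @param window_ps window length in ps, measured back from the last frame.
#' @return Mean energy (kJ/mol) over frames with
#'   `time_ps >= max(time_ps) - window_ps`.
#' @export
tail_window_mean <- function(series, window_ps = 10000) {
  if (!all(c("time_ps", "energy_kJ_mol") %in% names(series)))
    stop("'series' needs columns time_ps and energy_kJ_mol")
  if (!is.finite(window_ps) || window_ps <= 0) stop("'window_ps' must be > 0")
  keep <- series$time_ps >= max(series$time_ps) - window_ps
  mean(series$energy_kJ_mol[keep])
}

#' LIE estimate from four energy time series
#'
#' Convenience wrapper: averages each supplied trajectory over its tail
#' window ([tail_window_mean()]) and evaluates [lie_free_energy()] on the
#' four means.
#'
#' @param vdw_bound,vdw_free,elec_bound,elec_free energy time series (data
#'   frames with `time_ps`, `energy_kJ_mol`).
#' @inheritParams lie_free_energy
#' @param window_ps averaging window in ps.
#' @return A list with the four window means (`vdw_bound`, `vdw_free`,
#'   `elec_bound`, `elec_free`) and `dG` in kJ/mol.
#' @export
lie_from_series <- function(vdw_bound, vdw_free, elec_bound, elec_free,
                            alpha = 0.181, beta = 0.3, window_ps = 10000) {
  means <- lapply(list(vdw_bound = vdw_bound, vdw_free = vdw_free,
                       elec_bound = elec_bound, elec_free = elec_free),
                  tail_window_mean, window_ps = window_ps)
  c(means, list(dG = lie_free_energy(means$vdw_bound, means$vdw_free,
                                     means$elec_bound, means$elec_free,
                                     alpha, beta)))
}
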