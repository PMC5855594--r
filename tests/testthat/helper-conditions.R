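# Canonical study conditions shared across tests.

# Strongest neo-glycoprotein ligand regime: slow dissociation, picomolar KD.
cmpd11_params <- function(Rmax = 100)
  kinetic_params("langmuir_1to1", ka1 = 5.9e6, kd1 = 8.5e-5, Rmax1 = Rmax)

# Positive-control glycoprotein regime: nanomolar KD, slower association.
asf_params <- function(Rmax = 100)
  kinetic_params("langmuir_1to1", ka1 = 4.8e4, kd1 = 4.0e-4, Rmax1 = Rmax)

# Analyte ladders: sub-nanomolar for the immobilized-lectin setup,
# 16-250 nM for the reversed setup.
ladder_pM <- function() serial_dilution(250e-12, 2, 5)
ladder_nM <- function() serial_dilution(250e-9, 2, 5)

# Independent ODE oracle for the 1:1 rate equation
# dR/dt = ka C (Rmax - R) - kd R, association then dissociation, on the
# schedule grid. Deliberately does not reuse the closed-form code path.
ode_oracle_1to1 <- function(ka, kd, Rmax, conc, sched) {
  grid <- seq(0, sched$t_assoc + sched$t_dissoc, by = sched$dt)
  if (!any(abs(grid - sched$t_assoc) < 1e-9)) grid <- sort(c(grid, sched$t_assoc))
  f <- function(t, y, p) list(p$ka * p$C * (p$Rmax - y) - p$kd * y)
  t1 <- grid[grid <= sched$t_assoc + 1e-12]
  o1 <- deSolve::ode(c(R = 0), t1, f, list(ka = ka, kd = kd, Rmax = Rmax, C = conc),
                     method = "lsoda", rtol = 1e-10, atol = 1e-12)
  t2 <- grid[grid > sched$t_assoc + 1e-12]
  R <- o1[, 2L]
  if (length(t2)) {
    o2 <- deSolve::ode(c(R = R[length(R)]), c(sched$t_assoc, t2), f,
                       list(ka = ka, kd = kd, Rmax = Rmax, C = 0),
                       method = "lsoda", rtol = 1e-10, atol = 1e-12)
    R <- c(R, o2[-1L, 2L])
  }
  list(time = grid, response = unname(R))
}
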