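# Light capture, linear/cyclic electron flow stoichiometry, and the
# electron-transport-limited assimilation rate.
#
# The light reactions are modelled as one pooled chain: whole-chain (linear)
# electron transport J is split between the C4 cycle (fraction x, regenerating
# PEP at 2 ATP per PEP) and the C3 cycle (fraction 1 - x). Protons come from
# linear flow (3 H+ per electron with a Q-cycle) and from cyclic flow around
# PSI (2 H+ per electron), so the ATP yield per linear electron is
# z = (3 - f_cyc) / (h * (1 - f_cyc)).

#' ATP produced per linear electron
#'
#' `z = (3 - f_cyc) / (h * (1 - f_cyc))`: linear flow contributes 3 protons
#' per electron, cyclic flow 2, and `h` protons make one ATP. The ATP
#' production rate is `z * J`.
#'
#' @param f_cyc Fraction of PSI electron flow that is cyclic, in `[0, 1)`.
#' @param h Protons per ATP (> 0).
#' @return z, ATP per electron.
#' @examples
#' atp_per_electron(0, 4)    # 0.75
#' atp_per_electron(0.5, 4)  # 1.25
#' @export
atp_per_electron <- function(f_cyc, h) {
  if (any(f_cyc < 0) || any(f_cyc >= 1)) {
    stop("f_cyc must lie in [0, 1)", call. = FALSE)
  }
  if (any(h <= 0)) stop("h must be > 0", call. = FALSE)
  (3 - f_cyc) / (h * (1 - f_cyc))
}

#' Fraction of absorbed light allocated to PSII
#'
#' `rho = (1 - f_cyc) / (2 - f_cyc)`. With no cyclic flow the two
#' photosystems share light equally (rho = 0.5); cyclic flow around PSI
#' shifts allocation towards PSI.
#'
#' @inheritParams atp_per_electron
#' @return rho, dimensionless.
#' @export
psii_light_fraction <- function(f_cyc) {
  if (any(f_cyc < 0) || any(f_cyc >= 1)) {
    stop("f_cyc must lie in [0, 1)", call. = FALSE)
  }
  (1 - f_cyc) / (2 - f_cyc)
}

#' Photosynthetically useful irradiance absorbed by PSII
#'
#' `I2 = I * absorptance * rho * (1 - f_spectral)`.
#'
#' @param I Incident irradiance, umol quanta m-2 s-1 (>= 0). Vectorized.
#' @param absorptance Leaf absorptance.
#' @param f_spectral Spectral quality correction.
#' @param rho PSII light fraction, see [psii_light_fraction()].
#' @return I2, umol quanta m-2 s-1.
#' @export
useful_irradiance <- function(I, absorptance, f_spectral, rho) {
  if (any(I < 0)) stop("irradiance must be >= 0", call. = FALSE)
  I * absorptance * rho * (1 - f_spectral)
}

#' Potential whole-chain electron transport rate
#'
#' Non-rectangular hyperbola in absorbed light:
#' `theta*J^2 - J*(I2 + Jmax) + I2*Jmax = 0`, taking the smaller root so that
#' J saturates at Jmax. At `theta = 0` the analytic rectangular-hyperbola
#' limit `I2*Jmax/(I2 + Jmax)` is used.
#'
#' @param I2 Useful absorbed irradiance, umol m-2 s-1 (>= 0). Vectorized.
#' @param Jmax Maximal electron transport, umol electrons m-2 s-1 (> 0).
#' @param theta Curvature factor in `[0, 1]`.
#' @return J, umol electrons m-2 s-1.
#' @export
electron_transport_rate <- function(I2, Jmax, theta) {
  if (any(I2 < 0)) stop("I2 must be >= 0", call. = FALSE)
  if (any(Jmax <= 0)) stop("Jmax must be > 0", call. = FALSE)
  if (any(theta < 0) || any(theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  s <- I2 + Jmax
  disc <- pmax(s^2 - 4 * theta * I2 * Jmax, 0)
  # smaller root written in the cancellation-free form 2c/(s + sqrt(disc)),
  # which degrades gracefully into the rectangular hyperbola at theta = 0
  2 * I2 * Jmax / (s + sqrt(disc))
}

#' Light-reaction state at a given irradiance
#'
#' Bundles the full electron-transport bookkeeping for one or more incident
#' irradiances: PSII-useful light, linear flow J, PSI flow `J1 = J/(1-f_cyc)`,
#' cyclic flow `Jcyc = J1 - J`, proton production
#' `JH = J*(3-f_cyc)/(1-f_cyc)`, ATP production `JATP = JH/h = z*J`, and the
#' mesophyll/bundle-sheath allocations `Jm = x*J`, `Js = (1-x)*J`.
#'
#' @param I Incident irradiance, umol quanta m-2 s-1. Vectorized.
#' @param adj A [adjust_to_temperature()] object (or a `c4_parameters` object,
#'   taken at 25 C).
#' @return A tibble with columns `I, I2, J, J1, Jcyc, JH, JATP, z, rho, Jm,
#'   Js`.
#' @export
light_reaction_state <- function(I, adj) {
  adj <- as_adjusted(adj, 25)
  I2 <- useful_irradiance(I, adj$absorptance, adj$f_spectral, adj$rho)
  J <- electron_transport_rate(I2, adj$Jmax, adj$theta)
  J1 <- J / (1 - adj$f_cyc)
  JH <- J * (3 - adj$f_cyc) / (1 - adj$f_cyc)
  tibble::tibble(
    I = I, I2 = I2, J = J, J1 = J1, Jcyc = J1 - J,
    JH = JH, JATP = JH / adj$h, z = adj$z, rho = adj$rho,
    Jm = adj$x * J, Js = (1 - adj$x) * J
  )
}

#' ATP and NADPH consumption of the carbon reactions
#'
#' ATP: `2*Vp + (3 + 7*gamma_star*Os/Cs) * Vc` (2 ATP per PEP regenerated,
#' 3 per RuBP, plus the photorespiratory surcharge). NADPH:
#' `(2 + 4*gamma_star*Os/Cs) * Vc` (the C4 cycle itself consumes no net
#' NADPH).
#'
#' @param Vc Rubisco carboxylation rate, umol m-2 s-1. Vectorized.
#' @param Vp PEP carboxylation rate, umol m-2 s-1.
#' @param Cs Bundle-sheath CO2, ubar (> 0).
#' @param Os Bundle-sheath O2, mbar.
#' @param gamma_star Half reciprocal Rubisco specificity.
#' @return A tibble with columns `atp_rate`, `nadph_rate` (umol m-2 s-1).
#' @export
energy_budget <- function(Vc, Vp, Cs, Os, gamma_star) {
  if (any(Cs <= 0)) stop("Cs must be > 0", call. = FALSE)
  g <- gamma_star * Os * MBAR_TO_UBAR / Cs
  tibble::tibble(
    atp_rate = 2 * Vp + (3 + 7 * g) * Vc,
    nadph_rate = (2 + 4 * g) * Vc
  )
}

# Quadratic coefficients for the electron-transport-limited net rate.
# Derived by eliminating Cs and Os from the two flux-balance forms of Aj
# (C4 side: Aj = z*x*J/2 - gbs*(Cs - Cm) - Rm; C3 side via the
# photorespiration-corrected RuBP-regeneration rate) and the O2 balance.
light_limited_coefficients <- function(Cm, Om, J, adj) {
  Om_u <- Om * MBAR_TO_UBAR
  Vp_j <- adj$z * adj$x * J / 2          # C4-cycle carboxylation supported by J
  Jsc <- adj$z * (1 - adj$x) * J / 3     # C3-cycle carboxylation capacity
  P <- Vp_j - adj$Rm + adj$gbs * Cm
  g_al <- adj$gamma_star * adj$alpha / adj$ao
  a <- 1 - (7 / 3) * g_al
  b <- -(P + (Jsc - adj$Rd) +
           (7 / 3) * adj$gbs * adj$gamma_star * Om_u +
           g_al * (Jsc + (7 / 3) * adj$Rd))
  cc <- P * (Jsc - adj$Rd) -
    adj$gbs * adj$gamma_star * Om_u * (Jsc + (7 / 3) * adj$Rd)
  list(a = a, b = b, c = cc, Vp = Vp_j, Jsc = Jsc)
}

# bare Aj root for the inner loops
light_aj_core <- function(Cm, Om, J, adj) {
  co <- light_limited_coefficients(Cm, Om, J, adj)
  solve_quadratic_lower(rep_len(co$a, length(co$b)), co$b, co$c,
                        "electron-transport-limited")
}

#' Electron-transport-limited net CO2 assimilation
#'
#' Given the linear electron transport rate `J`, co-solves the C4-cycle and
#' C3-cycle ATP-limited flux balances with the bundle-sheath CO2 and O2
#' diffusion balances. Under the default partitioning `x = 0.4` the two
#' cycles co-limit exactly when respiration, photorespiration and inward CO2
#' diffusion are negligible.
#'
#' @param Cm Mesophyll CO2, ubar. Vectorized (recycled with `Om`, `J`).
#' @param Om Mesophyll O2, mbar. Default 200.
#' @param J Whole-chain electron transport, umol electrons m-2 s-1 (>= 0).
#' @param adj A [adjust_to_temperature()] object.
#' @return A tibble with columns `Aj`, `Vp`, `Vc`, `Vo`, `Cs`, `Os`, `L`,
#'   `atp_rate`, `nadph_rate`.
#' @examples
#' adj <- adjust_to_temperature(c4_parameters(), 25)
#' J <- light_reaction_state(2000, adj)$J
#' light_limited_assimilation(200, 200, J, adj)
#' @export
light_limited_assimilation <- function(Cm, Om = 200, J, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(J < 0)) stop("J must be >= 0", call. = FALSE)
  if (any(Om <= 0)) stop("Om must be > 0", call. = FALSE)
  n <- max(length(Cm), length(Om), length(J))
  Cm <- rep_len(Cm, n)
  Om <- rep_len(Om, n)
  J <- rep_len(J, n)
  co <- light_limited_coefficients(Cm, Om, J, adj)
  Aj <- solve_quadratic_lower(rep_len(co$a, n), co$b, co$c,
                              "electron-transport-limited")
  Cs <- Cm + (co$Vp - Aj - adj$Rm) / adj$gbs
  Os <- bundle_sheath_o2(Aj, adj$alpha, adj$ao, adj$gbs, Om)
  Os_u <- Os * MBAR_TO_UBAR
  ratio <- ifelse(Cs > 0, adj$gamma_star * Os_u / Cs, NA_real_)
  Vc <- (Aj + adj$Rd) / (1 - ratio)
  Vo <- 2 * ratio * Vc
  budget <- energy_budget(Vc, co$Vp, pmax(Cs, .Machine$double.eps), Os,
                          adj$gamma_star)
  tibble::tibble(
    Aj = Aj, Vp = co$Vp, Vc = Vc, Vo = Vo, Cs = Cs, Os = Os,
    L = leak_rate(adj$gbs, Cs, Cm),
    atp_rate = budget$atp_rate, nadph_rate = budget$nadph_rate
  )
}

#' Min-rule approximation to the electron-transport-limited rate
#'
#' `Aj = min(z*x*J/2 - Rm + gbs*Cm, z*(1-x)*J/3 - Rd)`: the C4-cycle and
#' C3-cycle branches evaluated without the photorespiratory coupling.
#'
#' @inheritParams light_limited_assimilation
#' @return A tibble with columns `Aj` and `branch` (`"c4_cycle"` or
#'   `"c3_cycle"`).
#' @export
light_limited_approx <- function(Cm, J, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  b1 <- adj$z * adj$x * J / 2 - adj$Rm + adj$gbs * Cm
  b2 <- adj$z * (1 - adj$x) * J / 3 - adj$Rd
  tibble::tibble(
    Aj = pmin(b1, b2),
    branch = ifelse(b1 <= b2, "c4_cycle", "c3_cycle")
  )
}

#' Optimal partitioning of electron transport to the C4 cycle
#'
#' Finds the fraction `x` of whole-chain electron transport allocated to PEP
#' regeneration that maximizes the electron-transport-limited rate at fixed
#' `J` (i.e. at a given irradiance). In the idealized limit with no
#' respiration, no photorespiration and no inward diffusion, the optimum is
#' exactly 0.4 (two of the five ATP per net fixation are needed in the
#' mesophyll); bundle-sheath O2 evolution (`alpha > 0`) and photorespiration
#' shift it slightly.
#'
#' @param Cm Mesophyll CO2, ubar (single value).
#' @param Om Mesophyll O2, mbar.
#' @param I Incident irradiance, umol quanta m-2 s-1.
#' @param adj A [adjust_to_temperature()] object.
#' @param tol Search tolerance on x (default 1e-4).
#' @return A list with `x_opt` and the maximized `Aj`.
#' @export
optimal_partitioning <- function(Cm, Om = 200, I, adj, tol = 1e-4) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  J <- light_reaction_state(I, adj)$J
  f <- function(x) {
    a2 <- adj
    a2$x <- x
    light_limited_assimilation(Cm, Om, J, a2)$Aj
  }
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  list(x_opt = opt$maximum, Aj = opt$objective)
}
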