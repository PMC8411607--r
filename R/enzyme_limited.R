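# Enzyme-limited (high-irradiance) assimilation: PEPC supply into the bundle
# sheath, Rubisco demand inside it, and the CO2/O2 diffusion balances across
# the bundle-sheath wall, co-solved as one quadratic in the net rate.
#
# Pressure bookkeeping: CO2 in ubar, O2 in mbar at every interface; whenever
# an O2 pressure multiplies gamma_star or divides Kc-type terms it is first
# converted to ubar (x 1000) so compensation pressures emerge in ubar.

MBAR_TO_UBAR <- 1000

#' PEP carboxylation rate
#'
#' Michaelis-Menten PEPC kinetics in the mesophyll cytosol capped by the
#' PEP-regeneration ceiling: `Vp = min(Cm * Vpmax / (Cm + Kp), Vpr)`.
#' Ties are labelled `"regeneration"`.
#'
#' @param Cm Mesophyll CO2 partial pressure, ubar (>= 0). Vectorized.
#' @param Vpmax Maximum PEPC rate, umol m-2 s-1.
#' @param Kp PEPC Michaelis constant for CO2, ubar.
#' @param Vpr PEP-regeneration-limited rate, umol m-2 s-1.
#' @return A tibble with columns `Vp` (umol m-2 s-1) and `vp_limited_by`
#'   (`"carboxylation"` or `"regeneration"`).
#' @examples
#' pep_carboxylation_rate(82, 200, 82, 1000)
#' @export
pep_carboxylation_rate <- function(Cm, Vpmax, Kp, Vpr) {
  if (any(Cm < 0)) stop("Cm must be >= 0", call. = FALSE)
  if (any(Vpmax <= 0) || any(Kp <= 0) || any(Vpr <= 0)) {
    stop("Vpmax, Kp and Vpr must be > 0", call. = FALSE)
  }
  mm <- Cm * Vpmax / (Cm + Kp)
  tibble::tibble(
    Vp = pmin(mm, Vpr),
    vp_limited_by = ifelse(mm < Vpr, "carboxylation", "regeneration")
  )
}

#' Bundle-sheath O2 partial pressure
#'
#' O2 evolved by bundle-sheath PSII (a fraction `alpha` of net assimilation)
#' must leak out through the O2 conductance `go = ao * gbs`, raising the
#' steady-state bundle-sheath O2 above the mesophyll value:
#' `Os = alpha * A / (ao * gbs) + Om`.
#'
#' @param A Net CO2 assimilation, umol m-2 s-1. Vectorized.
#' @param alpha Fraction of PSII activity in the bundle sheath.
#' @param ao O2/CO2 solubility-diffusivity ratio.
#' @param gbs Bundle-sheath CO2 conductance, mol m-2 s-1 bar-1.
#' @param Om Mesophyll O2 partial pressure, mbar.
#' @return Os in mbar.
#' @export
bundle_sheath_o2 <- function(A, alpha, ao, gbs, Om) {
  if (any(ao <= 0) || any(gbs <= 0)) {
    stop("ao and gbs must be > 0", call. = FALSE)
  }
  # alpha * A / (ao * gbs) is in ubar; report mbar
  alpha * A / (ao * gbs) / MBAR_TO_UBAR + Om
}

#' CO2 leak rate out of the bundle sheath
#'
#' `L = gbs * (Cs - Cm)`; negative values mean inward diffusion of CO2 from
#' the mesophyll into the bundle sheath.
#'
#' @param gbs Bundle-sheath conductance to CO2, mol m-2 s-1 bar-1.
#' @param Cs Bundle-sheath CO2, ubar. Vectorized.
#' @param Cm Mesophyll CO2, ubar.
#' @return Leak rate, umol m-2 s-1.
#' @export
leak_rate <- function(gbs, Cs, Cm) {
  if (any(gbs <= 0)) stop("gbs must be > 0", call. = FALSE)
  gbs * (Cs - Cm)
}

#' Bundle-sheath CO2 implied by a Rubisco-limited assimilation rate
#'
#' Inverts the Rubisco-limited rate equation for the bundle-sheath CO2
#' pressure:
#' `Cs = (gamma_star*Os + Kc*(1 + Os/Ko) * r) / (1 - r)` with
#' `r = (A + Rd)/Vcmax`. Only feasible while the demanded carboxylation stays
#' below capacity (`r < 1`).
#'
#' @param A Net assimilation, umol m-2 s-1. Vectorized.
#' @param Os Bundle-sheath O2, mbar.
#' @param adj A [adjust_to_temperature()] object.
#' @return Cs in ubar.
#' @export
bundle_sheath_co2_from_rubisco <- function(A, Os, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  r <- (A + adj$Rd) / adj$Vcmax
  if (any(r >= 1)) {
    stop("infeasible: demanded carboxylation (A + Rd) reaches Vcmax",
         call. = FALSE)
  }
  Os_u <- Os * MBAR_TO_UBAR
  (adj$gamma_star * Os_u + adj$Kc * (1 + Os / adj$Ko) * r) / (1 - r)
}

# Quadratic coefficients for the enzyme-limited net rate, all CO2-equivalent
# pressures in ubar. Derived by eliminating Cs and Os from the Rubisco rate,
# the mass balance Cs = Cm + (Vp - A - Rm)/gbs, and the O2 balance.
enzyme_limited_coefficients <- function(Cm, Om, adj) {
  Om_u <- Om * MBAR_TO_UBAR
  Ko_u <- adj$Ko * MBAR_TO_UBAR
  Vp <- pmin(Cm * adj$Vpmax / (Cm + adj$Kp), adj$Vpr)
  Vp[Cm == 0] <- 0
  P <- Vp - adj$Rm + adj$gbs * Cm
  a <- 1 - (adj$alpha / adj$ao) * (adj$Kc / Ko_u)
  b <- -(P + (adj$Vcmax - adj$Rd) +
           adj$gbs * adj$Kc * (1 + Om_u / Ko_u) +
           (adj$alpha / adj$ao) *
             (adj$gamma_star * adj$Vcmax + adj$Rd * adj$Kc / Ko_u))
  cc <- (adj$Vcmax - adj$Rd) * P -
    (adj$Vcmax * adj$gbs * adj$gamma_star * Om_u +
       adj$Rd * adj$gbs * adj$Kc * (1 + Om_u / Ko_u))
  list(a = a, b = b, c = cc, Vp = Vp)
}

# Physical (smaller) root of a*x^2 + b*x + c = 0, vectorized, with a linear
# fallback when the leading coefficient vanishes.
solve_quadratic_lower <- function(a, b, cc, what = "assimilation") {
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0)) {
    stop("negative discriminant while solving the ", what,
         " quadratic; check parameter values", call. = FALSE)
  }
  root <- (-b - sqrt(disc)) / (2 * a)
  lin <- abs(a) < 1e-12
  if (any(lin)) root[lin] <- (-cc / b)[lin]
  root
}

# bare Ac root, no state assembly: the inner-loop workhorse
enzyme_ac_core <- function(Cm, Om, adj) {
  co <- enzyme_limited_coefficients(Cm, Om, adj)
  solve_quadratic_lower(rep_len(co$a, length(co$b)), co$b, co$c,
                        "enzyme-limited")
}

#' Enzyme-limited net CO2 assimilation
#'
#' Co-solves PEPC supply, Rubisco demand, and the bundle-sheath CO2 and O2
#' diffusion balances for the net enzyme-limited rate `Ac`, returning the full
#' internal state. The closed-form root reproduces the simultaneous solution
#' of the component equations (guarded by oracle tests); `Ac` may be negative
#' below the compensation point.
#'
#' @param Cm Mesophyll CO2, ubar (>= 0). Vectorized (recycled with `Om`).
#' @param Om Mesophyll O2, mbar (> 0). Default 200 mbar.
#' @param adj A [adjust_to_temperature()] object.
#' @return A tibble with columns `Ac`, `Vp`, `Vc`, `Vo`, `Cs` (ubar), `Os`
#'   (mbar), `L`, `vp_limited_by`.
#' @examples
#' adj <- adjust_to_temperature(c4_parameters(), 25)
#' enzyme_limited_assimilation(100, 200, adj)
#' @export
enzyme_limited_assimilation <- function(Cm, Om = 200, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(Cm < 0)) stop("Cm must be >= 0", call. = FALSE)
  if (any(Om <= 0)) stop("Om must be > 0", call. = FALSE)
  n <- max(length(Cm), length(Om))
  Cm <- rep_len(Cm, n)
  Om <- rep_len(Om, n)
  co <- enzyme_limited_coefficients(Cm, Om, adj)
  Ac <- solve_quadratic_lower(rep_len(co$a, n), co$b, co$c, "enzyme-limited")
  Cs <- Cm + (co$Vp - Ac - adj$Rm) / adj$gbs
  Os <- bundle_sheath_o2(Ac, adj$alpha, adj$ao, adj$gbs, Om)
  Os_u <- Os * MBAR_TO_UBAR
  # Vo/Vc = 2 gamma* Os / Cs and A = Vc - Vo/2 - Rd
  ratio <- ifelse(Cs > 0, adj$gamma_star * Os_u / Cs, NA_real_)
  Vc <- (Ac + adj$Rd) / (1 - ratio)
  Vo <- 2 * ratio * Vc
  flag <- pep_carboxylation_rate(Cm, adj$Vpmax, adj$Kp, adj$Vpr)$vp_limited_by
  tibble::tibble(
    Ac = Ac, Vp = co$Vp, Vc = Vc, Vo = Vo, Cs = Cs, Os = Os,
    L = leak_rate(adj$gbs, Cs, Cm), vp_limited_by = flag
  )
}

#' Low-CO2 approximation to the enzyme-limited rate
#'
#' On the initial slope of an A-Ci curve the enzyme-limited rate reduces to
#' the PEPC rate less mesophyll respiration plus the small inward diffusion
#' of CO2 into the bundle sheath:
#' `Ac = Cm*Vpmax/(Cm+Kp) - Rm + gbs*Cm`.
#'
#' @inheritParams enzyme_limited_assimilation
#' @return Approximate `Ac`, umol m-2 s-1.
#' @export
enzyme_limited_lowco2_approx <- function(Cm, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(Cm < 0)) stop("Cm must be >= 0", call. = FALSE)
  Cm * adj$Vpmax / (Cm + adj$Kp) - adj$Rm + adj$gbs * Cm
}
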