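#' Default photosynthetic parameter set for a C4 leaf
#'
#' Constructs the parameter collection describing a C4 leaf at the reference
#' temperature of 25 degrees C. Defaults are the *Setaria viridis*
#' parameterization (an NADP-ME C4 grass): Rubisco and PEP carboxylase (PEPC)
#' kinetics, bundle-sheath and mesophyll conductances, respiration, the
#' light-reaction stoichiometry constants, and per-parameter Arrhenius
#' activation energies.
#'
#' Unit conventions used throughout the package: CO2 partial pressures and
#' their Michaelis constants in ubar; O2 partial pressures and `Ko` in mbar;
#' fluxes in umol m-2 s-1; conductances in mol m-2 s-1 bar-1 (so that
#' conductance times a pressure difference in ubar is a flux in umol m-2 s-1).
#'
#' @param ... Named overrides for any field listed below. Unknown names are an
#'   error.
#'
#' @details Fields (defaults in parentheses):
#' \describe{
#'   \item{Vcmax25}{maximum Rubisco carboxylation rate, umol m-2 s-1 (40)}
#'   \item{Kc25}{Rubisco Michaelis constant for CO2, ubar (1210)}
#'   \item{Ko25}{Rubisco Michaelis constant for O2, mbar (292)}
#'   \item{gamma_star25}{half the reciprocal Rubisco CO2/O2 specificity,
#'     dimensionless (0.5/1310 = 0.0003817); the bundle-sheath photorespiratory
#'     compensation pressure is `gamma_star * Os`}
#'   \item{Vpmax25}{maximum PEPC carboxylation rate, umol m-2 s-1 (200)}
#'   \item{Vpr}{PEP-regeneration-limited carboxylation ceiling, umol m-2 s-1
#'     (80); temperature-invariant}
#'   \item{Kp25}{PEPC Michaelis constant for CO2, ubar (82)}
#'   \item{gbs}{bundle-sheath conductance to CO2, mol m-2 s-1 bar-1 (0.003);
#'     temperature-invariant}
#'   \item{ao25}{ratio of O2 to CO2 solubility-diffusivity, dimensionless
#'     (0.047); bundle-sheath O2 conductance is `go = ao * gbs`}
#'   \item{Rd25}{mitochondrial respiration, umol m-2 s-1 (0.01 * Vcmax25)}
#'   \item{Rm_fraction}{mesophyll share of Rd, dimensionless (0.5)}
#'   \item{alpha}{fraction of PSII activity in the bundle sheath, in `[0,1]`
#'     (0, the NADP-ME assumption)}
#'   \item{x}{fraction of electron transport allocated to the C4 cycle, in
#'     `[0,1]` (0.4)}
#'   \item{Jmax25}{maximal whole-chain electron transport at 25 C, umol
#'     electrons m-2 s-1 (248)}
#'   \item{Jmax_To}{maximal electron transport at the temperature optimum,
#'     umol electrons m-2 s-1 (400)}
#'   \item{To}{temperature optimum of Jmax, C (43)}
#'   \item{Omega}{Gaussian width of the Jmax temperature response, C (26);
#'     the offset from `To` at which Jmax falls to 1/e of its peak}
#'   \item{h}{protons required per ATP, dimensionless (4)}
#'   \item{f_cyc}{fraction of PSI electron flow that is cyclic, in `[0,1)`
#'     (0.3)}
#'   \item{theta}{empirical curvature of the light response, in `[0,1]` (0.7)}
#'   \item{absorptance}{leaf absorptance, in (0,1) (0.85)}
#'   \item{f_spectral}{spectral-quality correction, in (0,1) (0.15)}
#'   \item{gm25}{mesophyll conductance to CO2, mol m-2 s-1 bar-1 (1)}
#'   \item{activation_energies}{named numeric vector of Arrhenius activation
#'     energies in kJ mol-1 for Vcmax (78), Kc (64.2), Ko (10.5), gamma_star
#'     (31.1), Vpmax (50.1), Kp (38.3), Rd (66.4), ao (1.63) and gm (49.8)}
#' }
#'
#' `Rd25`, when not overridden, is derived from `Vcmax25` at construction time
#' and thereafter carries its own activation energy.
#'
#' @return An object of class `c4_parameters` (a named list).
#' @examples
#' p <- c4_parameters()
#' p$Kc25
#' c4_parameters(Vpmax25 = 120, f_cyc = 0)$Vpmax25
#' @export
c4_parameters <- function(...) {
  defaults <- list(
    Vcmax25 = 40,
    Kc25 = 1210,
    Ko25 = 292,
    gamma_star25 = 0.5 / 1310,
    Vpmax25 = 200,
    Vpr = 80,
    Kp25 = 82,
    gbs = 0.003,
    ao25 = 0.047,
    Rd25 = NULL, # filled from Vcmax25 below
    Rm_fraction = 0.5,
    alpha = 0,
    x = 0.4,
    Jmax25 = 248,
    Jmax_To = 400,
    To = 43,
    Omega = 26,
    h = 4,
    f_cyc = 0.3,
    theta = 0.7,
    absorptance = 0.85,
    f_spectral = 0.15,
    gm25 = 1,
    activation_energies = c(
      Vcmax = 78, Kc = 64.2, Ko = 10.5, gamma_star = 31.1,
      Vpmax = 50.1, Kp = 38.3, Rd = 66.4, ao = 1.63, gm = 49.8
    )
  )
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  if (is.null(params$Rd25)) params$Rd25 <- 0.01 * params$Vcmax25
  class(params) <- "c4_parameters"
  validate_c4_parameters(params)
  params
}

validate_c4_parameters <- function(p) {
  num_fields <- setdiff(names(p), "activation_energies")
  for (nm in num_fields) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  pos <- c("Vcmax25", "Kc25", "Ko25", "gamma_star25", "Vpmax25", "Vpr",
           "Kp25", "gbs", "ao25", "Jmax25", "Jmax_To", "To", "Omega", "h",
           "gm25")
  for (nm in pos) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0", call. = FALSE)
  }
  if (p$Rd25 < 0) stop("Rd25 must be >= 0", call. = FALSE)
  unit <- c(alpha = p$alpha, x = p$x, theta = p$theta,
            Rm_fraction = p$Rm_fraction)
  for (nm in names(unit)) {
    if (unit[[nm]] < 0 || unit[[nm]] > 1) {
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$f_cyc < 0 || p$f_cyc >= 1) {
    stop("f_cyc must lie in [0, 1)", call. = FALSE)
  }
  for (nm in c("absorptance", "f_spectral")) {
    if (p[[nm]] <= 0 || p[[nm]] >= 1) {
      stop("parameter '", nm, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  ae <- p$activation_energies
  needed <- c("Vcmax", "Kc", "Ko", "gamma_star", "Vpmax", "Kp", "Rd", "ao",
              "gm")
  if (!is.numeric(ae) || !all(needed %in% names(ae))) {
    stop("activation_energies must be a named numeric vector covering: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.c4_parameters <- function(x, ...) {
  cat("<c4_parameters> reference temperature 25 C\n")
  flat <- x[setdiff(names(x), "activation_energies")]
  df <- data.frame(parameter = names(flat),
                   value = vapply(flat, format, character(1)))
  print(df, row.names = FALSE)
  cat("activation energies (kJ mol-1):\n")
  print(x$activation_energies)
  invisible(x)
}

#' Arrhenius temperature scaling of a photosynthetic parameter
#'
#' Scales a quantity known at 25 C to another leaf temperature with the
#' simple Arrhenius form
#' `value25 * exp((T - 25) * E / (298 * R * (273 + T)))`,
#' where `R` = 8.314 J K-1 mol-1 and `E` is the activation energy.
#'
#' @param value25 Value of the quantity at 25 C (> 0).
#' @param E Activation energy, kJ mol-1 (converted to J mol-1 internally).
#' @param T Leaf temperature, degrees C (> -273).
#' @return The scaled value at `T`. Vectorized over `T`.
#' @examples
#' arrhenius_scale(1210, 64.2, 35)
#' @export
arrhenius_scale <- function(value25, E, T) {
  stopifnot(is.numeric(value25), is.numeric(E), is.numeric(T))
  if (any(!is.finite(value25)) || any(!is.finite(E)) || any(!is.finite(T))) {
    stop("non-finite input to arrhenius_scale", call. = FALSE)
  }
  if (any(value25 <= 0)) stop("value25 must be > 0", call. = FALSE)
  if (any(T <= -273)) stop("temperature must exceed -273 C", call. = FALSE)
  R <- 8.314
  value25 * exp((T - 25) * (E * 1000) / (298 * R * (273 + T)))
}

#' Gaussian temperature response of the maximal electron transport rate
#'
#' `Jmax(T) = Jmax(To) * exp(-((T - To) / Omega)^2)`: a peaked response with
#' optimum `To`; `Omega` is the temperature offset at which Jmax has fallen to
#' 1/e of its peak.
#'
#' @param Jmax_To Jmax at the optimum, umol electrons m-2 s-1 (> 0).
#' @param To Temperature optimum, C.
#' @param Omega Gaussian width, C (> 0).
#' @param T Leaf temperature, C. Vectorized.
#' @return Jmax at `T`.
#' @examples
#' jmax_at_temperature(400, 43, 26, 25)
#' @export
jmax_at_temperature <- function(Jmax_To, To, Omega, T) {
  if (any(Jmax_To <= 0)) stop("Jmax_To must be > 0", call. = FALSE)
  if (any(Omega <= 0)) stop("Omega must be > 0", call. = FALSE)
  Jmax_To * exp(-((T - To) / Omega)^2)
}

#' Rescale the PEPC Michaelis constant for a different cytosolic pH
#'
#' PEPC uses bicarbonate, so a Km measured for HCO3- is converted to a CO2
#' pressure constant through the Henderson-Hasselbalch equilibrium. Changing
#' the assumed cytosolic pH therefore rescales `Kp` by
#' `10^(pH_ref - pH_new)`. The packaged default `Kp25 = 82` ubar assumes
#' pH 7.2 (pKa 6.12).
#'
#' @param Kp_ref Reference Kp, ubar (> 0).
#' @param pH_ref pH at which `Kp_ref` applies.
#' @param pH_new New assumed cytosolic pH.
#' @return Rescaled Kp in ubar.
#' @examples
#' rescale_kp_for_ph(82, 7.2, 7.4)
#' @export
rescale_kp_for_ph <- function(Kp_ref, pH_ref, pH_new) {
  stopifnot(is.finite(Kp_ref), is.finite(pH_ref), is.finite(pH_new))
  if (Kp_ref <= 0) stop("Kp_ref must be > 0", call. = FALSE)
  Kp_ref * 10^(pH_ref - pH_new)
}

#' Temperature-adjust a C4 parameter set
#'
#' Applies the Arrhenius scaling to each parameter with a listed activation
#' energy (Vcmax, Kc, Ko, gamma_star, Vpmax, Kp, Rd, ao, gm), the Gaussian
#' response to Jmax, and leaves `gbs` and `Vpr` unchanged. Also derives the
#' quantities that depend only on the stoichiometry constants: the
#' bundle-sheath O2 conductance `go = ao * gbs`, the ATP yield per linear
#' electron `z`, the PSII light fraction `rho`, and the mesophyll/bundle-sheath
#' partition of respiration (`Rm = Rm_fraction * Rd`, `Rs = Rd - Rm`).
#'
#' @param params A [c4_parameters()] object.
#' @param T Leaf temperature, degrees C.
#' @return An object of class `c4_parameters_adj`: a named list with the
#'   temperature-adjusted values `Vcmax, Kc, Ko, gamma_star, Vpmax, Vpr, Kp,
#'   gbs, ao, go, Rd, Rm, Rs, Jmax, gm`, the unchanged stoichiometry fields,
#'   and `z`, `rho`, `T_leaf`.
#' @examples
#' adjust_to_temperature(c4_parameters(), 35)$Kc
#' @export
adjust_to_temperature <- function(params, T) {
  stopifnot(inherits(params, "c4_parameters"))
  validate_c4_parameters(params)
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T)) {
    stop("T must be a single finite temperature in C", call. = FALSE)
  }
  ae <- params$activation_energies
  Rd <- if (params$Rd25 > 0) {
    arrhenius_scale(params$Rd25, ae[["Rd"]], T)
  } else {
    0 # a respiration-free idealization stays respiration-free
  }
  adj <- list(
    Vcmax = arrhenius_scale(params$Vcmax25, ae[["Vcmax"]], T),
    Kc = arrhenius_scale(params$Kc25, ae[["Kc"]], T),
    Ko = arrhenius_scale(params$Ko25, ae[["Ko"]], T),
    gamma_star = arrhenius_scale(params$gamma_star25, ae[["gamma_star"]], T),
    Vpmax = arrhenius_scale(params$Vpmax25, ae[["Vpmax"]], T),
    Vpr = params$Vpr,
    Kp = arrhenius_scale(params$Kp25, ae[["Kp"]], T),
    gbs = params$gbs,
    ao = arrhenius_scale(params$ao25, ae[["ao"]], T),
    Rd = Rd,
    Rm = params$Rm_fraction * Rd,
    Rs = (1 - params$Rm_fraction) * Rd,
    gm = arrhenius_scale(params$gm25, ae[["gm"]], T),
    Jmax = jmax_at_temperature(params$Jmax_To, params$To, params$Omega, T),
    alpha = params$alpha,
    x = params$x,
    h = params$h,
    f_cyc = params$f_cyc,
    theta = params$theta,
    absorptance = params$absorptance,
    f_spectral = params$f_spectral,
    z = atp_per_electron(params$f_cyc, params$h),
    rho = psii_light_fraction(params$f_cyc),
    T_leaf = T
  )
  adj$go <- adj$ao * adj$gbs
  class(adj) <- "c4_parameters_adj"
  adj
}

#' @export
print.c4_parameters_adj <- function(x, ...) {
  cat(sprintf("<c4_parameters_adj> at %.1f C\n", x$T_leaf))
  flat <- x[setdiff(names(x), "T_leaf")]
  df <- data.frame(parameter = names(flat),
                   value = vapply(flat, function(v) format(v, digits = 6),
                                  character(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

as_adjusted <- function(params, T) {
  if (inherits(params, "c4_parameters_adj")) {
    return(params)
  }
  adjust_to_temperature(params, T)
}

#' Read a parameter configuration file
#'
#' Reads a flat `key = value` text file (one assignment per line, `#`
#' comments allowed) and builds a parameter set; omitted keys keep their
#' defaults, unknown keys are an error. Activation energies are addressed as
#' `E_<name>`, e.g. `E_Vcmax = 72`.
#'
#' @param path Path to the configuration file.
#' @return A [c4_parameters()] object.
#' @export
read_c4_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  energies <- c4_parameters()$activation_energies
  energies_touched <- FALSE
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed configuration line (expected key = value): '", ln, "'",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", ln))))
    if (is.na(val)) {
      stop("non-numeric value for key '", key, "'", call. = FALSE)
    }
    if (grepl("^E_", key)) {
      enm <- sub("^E_", "", key)
      if (!enm %in% names(energies)) {
        stop("unknown activation-energy key: ", key, call. = FALSE)
      }
      energies[[enm]] <- val
      energies_touched <- TRUE
    } else {
      overrides[[key]] <- val
    }
  }
  if (energies_touched) overrides$activation_energies <- energies
  do.call(c4_parameters, overrides)
}
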