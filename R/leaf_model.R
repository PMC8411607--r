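# The full leaf model: temperature scaling, mesophyll conductance coupling,
# the enzyme/electron-transport minimum rule, and the diagnostic quantities
# (leakiness, overcycling) for each simulated observation.

# Vectorized evaluation of Ac, Aj and the min rule at known mesophyll CO2.
assimilation_at_cm <- function(Cm, Om, J, adj, colimit_tol = 1e-3) {
  enz <- enzyme_limited_assimilation(Cm, Om, adj)
  lig <- light_limited_assimilation(Cm, Om, J, adj)
  enzyme_wins <- enz$Ac <= lig$Aj
  A <- pmin(enz$Ac, lig$Aj)
  limitation <- ifelse(abs(enz$Ac - lig$Aj) < colimit_tol, "co-limited",
                       ifelse(enzyme_wins, "enzyme", "electron_transport"))
  pick <- function(col) ifelse(enzyme_wins, enz[[col]], lig[[col]])
  Vp <- pick("Vp")
  L <- pick("L")
  phi <- ifelse(A > 0 & Vp > 0, L / Vp, NA_real_)
  over <- ifelse(A > 0, L / A, NA_real_)
  tibble::tibble(
    A = A, Ac = enz$Ac, Aj = lig$Aj, limitation = limitation,
    Cm = Cm, Cs = pick("Cs"), Os = pick("Os"),
    Vp = Vp, Vc = pick("Vc"), Vo = pick("Vo"), L = L,
    phi = phi, overcycling = over, J = J, z = adj$z, rho = adj$rho
  )
}

# Solve A(Cm) = gm * (Ci - Cm) for Cm by vectorized bisection. A(Cm) is
# non-decreasing and the supply line is decreasing, so the residual is
# monotone in Cm. Below the compensation point the root can sit above Ci,
# hence the widened upper bracket.
solve_cm <- function(Ci, Om, J, adj, tol = 1e-8, max_iter = 100) {
  n <- length(Ci)
  lo <- rep(0, n)
  hi <- Ci + (adj$Rd + adj$Rm) / adj$gm + 1
  resid <- function(Cm) {
    A <- pmin(enzyme_ac_core(Cm, Om, adj), light_aj_core(Cm, Om, J, adj))
    A - adj$gm * (Ci - Cm)
  }
  flo <- resid(lo)
  fhi <- resid(hi)
  bad <- flo > 0 | fhi < 0
  if (any(bad)) {
    stop("mesophyll CO2 bisection failed to bracket a root for ",
         sum(bad), " point(s); check parameter values", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    up <- fm < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Simulate steady-state C4 gas exchange
#'
#' The single entry point for forward simulation. Takes a table of
#' environments, temperature-adjusts the parameters per distinct leaf
#' temperature, computes the light-reaction state, couples intercellular to
#' mesophyll CO2 through the mesophyll conductance (or not, see `gm_mode`),
#' evaluates the enzyme-limited and electron-transport-limited rates and
#' applies the minimum rule, reporting the full internal state per row.
#'
#' @param env A data frame with columns `Ci` (intercellular CO2, ubar) or
#'   `Cm` (mesophyll CO2, ubar, bypassing the conductance), and optionally
#'   `Om` (O2, mbar; default 200), `I` (irradiance, umol quanta m-2 s-1;
#'   default 2000), `T` (leaf temperature, C; default 25).
#' @param params A [c4_parameters()] object.
#' @param gm_mode `"finite"` (solve `A = gm*(Ci - Cm)` numerically) or
#'   `"infinite"` (`Cm = Ci`). Ignored for rows supplying `Cm` directly.
#' @param colimit_tol Absolute tolerance (umol m-2 s-1) within which the two
#'   limitations are flagged `"co-limited"`.
#' @return A tibble: the input columns plus `A`, `Ac`, `Aj`, `limitation`,
#'   `Cm`, `Cs`, `Os`, `Vp`, `Vc`, `Vo`, `L`, `phi` (leakiness `L/Vp`; `NA`
#'   when `A <= 0` or `Vp = 0`), `overcycling` (`L/A`), `J`, `z`, `rho`.
#' @examples
#' env <- data.frame(Ci = c(50, 150, 400), I = 2000, T = 25)
#' simulate_gas_exchange(env, c4_parameters())
#' @export
simulate_gas_exchange <- function(env, params = c4_parameters(),
                                  gm_mode = c("finite", "infinite"),
                                  colimit_tol = 1e-3) {
  gm_mode <- match.arg(gm_mode)
  stopifnot(is.data.frame(env))
  env <- tibble::as_tibble(env)
  has_cm <- "Cm" %in% names(env)
  if (!has_cm && !"Ci" %in% names(env)) {
    stop("env must contain a 'Ci' or 'Cm' column", call. = FALSE)
  }
  if (!"Om" %in% names(env)) env$Om <- 200
  if (!"I" %in% names(env)) env$I <- 2000
  if (!"T" %in% names(env)) env$T <- 25
  if (any(env$Om <= 0) || any(env$I < 0)) {
    stop("Om must be > 0 and I >= 0", call. = FALSE)
  }
  if (!has_cm && any(env$Ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  if (has_cm && any(env$Cm < 0)) stop("Cm must be >= 0", call. = FALSE)

  env$.row <- seq_len(nrow(env))
  pieces <- lapply(split(env, env$T), function(chunk) {
    adj <- adjust_to_temperature(params, chunk$T[[1]])
    J <- light_reaction_state(chunk$I, adj)$J
    if (has_cm) {
      Cm <- chunk$Cm
    } else if (gm_mode == "infinite") {
      Cm <- chunk$Ci
    } else {
      Cm <- solve_cm(chunk$Ci, chunk$Om, J, adj)
    }
    state <- assimilation_at_cm(Cm, chunk$Om, J, adj, colimit_tol)
    dplyr::bind_cols(chunk[setdiff(names(chunk), names(state))], state)
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$.row)
  out$.row <- NULL
  out
}

#' Initial slope of the A-Ci curve
#'
#' The series combination of mesophyll diffusion and PEPC kinetics gives
#' `dA/dCi = gm * Vpmax / (gm * Kp + Vpmax)` at `Ci = 0`. Ignoring the
#' mesophyll resistance (infinite gm) and reading the same slope as
#' `Vpmax_apparent / Kp` understates PEPC capacity.
#'
#' @param gm Mesophyll conductance, mol m-2 s-1 bar-1.
#' @param Vpmax Maximum PEPC rate, umol m-2 s-1.
#' @param Kp PEPC Michaelis constant, ubar.
#' @return Slope in mol m-2 s-1 bar-1 (equivalently umol m-2 s-1 ubar-1).
#' @examples
#' sl <- initial_slope(1, 200, 82)
#' sl * 82  # apparent Vpmax under the infinite-gm reading
#' @export
initial_slope <- function(gm, Vpmax, Kp) {
  if (any(gm <= 0) || any(Vpmax <= 0) || any(Kp <= 0)) {
    stop("gm, Vpmax and Kp must be > 0", call. = FALSE)
  }
  gm * Vpmax / (gm * Kp + Vpmax)
}

#' Low-CO2 assimilation with mesophyll conductance (closed form)
#'
#' On the initial slope, combining the PEPC approximation (without the
#' `gbs*Cm` term) with the diffusion law `A = gm*(Ci - Cm)` yields
#' `A^2 - A*(gm*(Ci+Kp) + Vpmax - Rm) + gm*(Vpmax*Ci - Rm*(Ci+Kp)) = 0`,
#' of which the smaller root is the physical branch (the analogue of the
#' C3 initial-slope quadratic). Valid only at low Ci.
#'
#' @param Ci Intercellular CO2, ubar (>= 0). Vectorized.
#' @param adj A [adjust_to_temperature()] object.
#' @return A, umol m-2 s-1.
#' @export
lowco2_assimilation_with_gm <- function(Ci, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(Ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  b <- -(adj$gm * (Ci + adj$Kp) + adj$Vpmax - adj$Rm)
  cc <- adj$gm * (adj$Vpmax * Ci - adj$Rm * (Ci + adj$Kp))
  disc <- b^2 - 4 * cc
  if (any(disc < 0)) {
    stop("negative discriminant in the low-CO2 quadratic", call. = FALSE)
  }
  (-b - sqrt(disc)) / 2
}
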