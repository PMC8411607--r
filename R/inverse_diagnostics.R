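# Inverse use of the model: the electron transport rate actually needed to
# sustain a measured assimilation rate, and C4-cycle fluxes reconstructed
# from isotope-derived leakiness.

# Quadratic coefficients (in J) obtained by re-arranging the
# electron-transport-limited flux balances at a known net rate A.
ja_coefficients <- function(A, Cm, Om, adj) {
  Om_u <- Om * MBAR_TO_UBAR
  u <- adj$z * adj$x / 2
  v <- adj$z * (1 - adj$x) / 3
  g_al <- adj$gamma_star * adj$alpha / adj$ao
  a <- u * v
  b <- v * (adj$gbs * (Cm - adj$gamma_star * Om_u) - adj$Rm -
              A * (1 + g_al)) - u * (A + adj$Rd)
  cc <- (A + adj$Rd) *
    (adj$Rm - adj$gbs * (Cm + (7 / 3) * adj$gamma_star * Om_u) +
       A * (1 - (7 / 3) * g_al))
  list(a = a, b = b, c = cc)
}

#' Electron transport rate required to sustain a measured assimilation rate
#'
#' Inverts the electron-transport-limited model: given a measured net CO2
#' assimilation rate, returns the whole-chain electron transport rate `Ja`
#' whose forward prediction reproduces it. The binding (larger) root of the
#' resulting quadratic is taken; every returned value is verified by a
#' forward round trip, and if the companion root reproduces the input
#' instead, it is returned with a warning.
#'
#' @param A Measured net assimilation, umol m-2 s-1 (> -Rd). Vectorized
#'   (recycled with `Cm`, `Om`).
#' @param Cm Mesophyll CO2, ubar.
#' @param Om Mesophyll O2, mbar. Default 200.
#' @param adj A [adjust_to_temperature()] object.
#' @return Ja, umol electrons m-2 s-1.
#' @examples
#' adj <- adjust_to_temperature(c4_parameters(), 25)
#' A <- light_limited_assimilation(150, 200, 150, adj)$Aj
#' actual_electron_transport(A, 150, 200, adj)  # ~150
#' @export
actual_electron_transport <- function(A, Cm, Om = 200, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(A <= -adj$Rd)) {
    stop("A must exceed -Rd to be sustained by any electron transport",
         call. = FALSE)
  }
  n <- max(length(A), length(Cm), length(Om))
  A <- rep_len(A, n)
  Cm <- rep_len(Cm, n)
  Om <- rep_len(Om, n)
  co <- ja_coefficients(A, Cm, Om, adj)
  disc <- co$b^2 - 4 * co$a * co$c
  if (any(disc < 0)) {
    stop("no real electron transport rate can sustain the requested A",
         call. = FALSE)
  }
  Ja <- (-co$b + sqrt(disc)) / (2 * co$a)
  # round-trip validation; fall back to the companion root if needed
  ok <- is.finite(Ja) & Ja >= 0 &
    abs(light_limited_assimilation(Cm, Om, pmax(Ja, 0), adj)$Aj - A) < 1e-6
  if (!all(ok)) {
    alt <- (-co$b - sqrt(disc)) / (2 * co$a)
    alt_ok <- is.finite(alt) & alt >= 0 &
      abs(light_limited_assimilation(Cm, Om, pmax(alt, 0), adj)$Aj - A) < 1e-6
    swap <- !ok & alt_ok
    if (any(swap)) {
      warning("companion quadratic root used for ", sum(swap),
              " point(s) after round-trip validation", call. = FALSE)
      Ja[swap] <- alt[swap]
    }
    if (any(!ok & !alt_ok)) {
      stop("electron transport inversion failed round-trip validation",
           call. = FALSE)
    }
  }
  Ja
}

#' C4-cycle flux, leak rate and bundle-sheath CO2 from measured leakiness
#'
#' When net assimilation and leakiness `phi = L/Vp` are known (the latter
#' typically from carbon isotope discrimination), the C4-cycle flux follows
#' from the mesophyll mass balance: `Vp = (A + Rm)/(1 - phi)`, `L = phi*Vp`,
#' and, assuming a bundle-sheath conductance, `Cs = Cm + L/gbs`.
#'
#' @param A Net assimilation, umol m-2 s-1. Vectorized (recycled).
#' @param phi Leakiness, in `[0, 1)`.
#' @param Cm Mesophyll CO2, ubar.
#' @param adj A [adjust_to_temperature()] object.
#' @return A tibble with columns `Vp`, `L`, `Cs` plus the echoed inputs
#'   `A`, `phi`, `Cm`.
#' @examples
#' adj <- adjust_to_temperature(c4_parameters(), 25)
#' c4_cycle_from_leakiness(30, 0.2, 100, adj)
#' @export
c4_cycle_from_leakiness <- function(A, phi, Cm, adj) {
  stopifnot(inherits(adj, "c4_parameters_adj"))
  if (any(phi < 0) || any(phi >= 1)) {
    stop("phi must lie in [0, 1)", call. = FALSE)
  }
  Vp <- (A + adj$Rm) / (1 - phi)
  L <- phi * Vp
  tibble::tibble(A = A, phi = phi, Cm = Cm,
                 Vp = Vp, L = L, Cs = Cm + L / adj$gbs)
}

#' Overcycling: leak rate as a fraction of net assimilation
#'
#' `L/A`, the fraction by which the C4-cycle flux must exceed net CO2
#' assimilation; equivalently `(Vp - (A + Rm))/A` by the mesophyll mass
#' balance.
#'
#' @param L Leak rate, umol m-2 s-1. Vectorized.
#' @param A Net assimilation, umol m-2 s-1 (nonzero).
#' @return Dimensionless overcycling fraction.
#' @export
overcycling <- function(L, A) {
  if (any(A == 0)) stop("A must be nonzero", call. = FALSE)
  L / A
}

#' Augment a measured gas-exchange table with inverse diagnostics
#'
#' For each row computes the electron transport rate `Ja` sustaining the
#' measured `A` and, where a `phi` column is present, the leakiness-derived
#' `Vp`, `L` and `Cs`.
#'
#' @param data A data frame with columns `A`, `Ci` or `Cm`, and optionally
#'   `Om` (default 200), `T` (default 25), `phi`. When only `Ci` is given,
#'   `Cm` is inferred from the diffusion law `Cm = Ci - A/gm`.
#' @param params A [c4_parameters()] object.
#' @return The input tibble with `Cm`, `Ja` and (if `phi` present)
#'   `Vp`, `L`, `Cs` columns added.
#' @export
invert_gas_exchange <- function(data, params = c4_parameters()) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!"A" %in% names(data)) stop("data must contain 'A'", call. = FALSE)
  if (!"Om" %in% names(data)) data$Om <- 200
  if (!"T" %in% names(data)) data$T <- 25
  data$.row <- seq_len(nrow(data))
  pieces <- lapply(split(data, data$T), function(chunk) {
    adj <- adjust_to_temperature(params, chunk$T[[1]])
    if (!"Cm" %in% names(chunk)) {
      if (!"Ci" %in% names(chunk)) {
        stop("data must contain 'Ci' or 'Cm'", call. = FALSE)
      }
      chunk$Cm <- chunk$Ci - chunk$A / adj$gm
    }
    chunk$Ja <- actual_electron_transport(chunk$A, chunk$Cm, chunk$Om, adj)
    if ("phi" %in% names(chunk)) {
      lk <- c4_cycle_from_leakiness(chunk$A, chunk$phi, chunk$Cm, adj)
      chunk$Vp <- lk$Vp
      chunk$L <- lk$L
      chunk$Cs <- lk$Cs
    }
    chunk
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$.row)
  out$.row <- NULL
  out
}
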