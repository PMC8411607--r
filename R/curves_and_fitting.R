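# Response-curve generation (A-Ci, light, temperature), synthetic noisy
# gas-exchange data, and least-squares estimation of capacity parameters.

new_c4_curve <- function(df, swept, provenance, noise_sd = NA_real_,
                         seed = NA_integer_) {
  structure(df,
            class = c("c4_curve", class(tibble::as_tibble(df))),
            swept = swept, provenance = provenance,
            noise_sd = noise_sd, seed = seed)
}

#' @export
print.c4_curve <- function(x, ...) {
  cat(sprintf("<c4_curve> %s sweep (%s, %d points)\n",
              attr(x, "swept"), attr(x, "provenance"), nrow(x)))
  if (!is.na(attr(x, "noise_sd"))) {
    cat(sprintf("  noise sd %.3g, seed %s\n", attr(x, "noise_sd"),
                format(attr(x, "seed"))))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Sweep one environmental driver and model the response curve
#'
#' Evaluates the full leaf model along a grid of one driver, holding the
#' others at base values: `"Ci"` gives an A-Ci curve, `"I"` a light-response
#' curve, `"T"` a temperature-response curve.
#'
#' @param variable One of `"Ci"`, `"I"`, `"T"`. When `env_base` carries a
#'   `Cm` entry and `variable` is not `"Ci"`, the sweep runs at fixed
#'   mesophyll CO2 (no conductance coupling), as in light-response analyses.
#' @param grid Strictly increasing numeric grid for the swept driver.
#' @param env_base Named list of the held drivers (`Ci` or `Cm`, `Om`, `I`,
#'   `T`); defaults `Ci = 400`, `Om = 200`, `I = 2000`, `T = 25`.
#' @param params A [c4_parameters()] object.
#' @param gm_mode Passed to [simulate_gas_exchange()].
#' @return A `c4_curve` tibble (the [simulate_gas_exchange()] output).
#' @examples
#' sweep_curve("Ci", seq(20, 1000, by = 70))
#' @export
sweep_curve <- function(variable = c("Ci", "I", "T"), grid,
                        env_base = list(), params = c4_parameters(),
                        gm_mode = "finite") {
  variable <- match.arg(variable)
  if (length(grid) == 0 || any(!is.finite(grid))) {
    stop("grid must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  base <- utils::modifyList(list(Ci = 400, Om = 200, I = 2000, T = 25),
                            env_base)
  if (!is.null(base$Cm) && variable != "Ci") base$Ci <- NULL
  env <- tibble::as_tibble(base)
  env <- env[rep(1, length(grid)), , drop = FALSE]
  env[[variable]] <- grid
  out <- simulate_gas_exchange(env, params, gm_mode = gm_mode)
  new_c4_curve(out, swept = variable, provenance = "modelled")
}

#' Synthesize a noisy gas-exchange curve
#'
#' Runs [sweep_curve()] and adds independent additive Gaussian measurement
#' noise to the assimilation rate, reproducibly for a given seed. The noise
#' model is homoscedastic, the simplest defensible description of infrared
#' gas-analyser scatter.
#'
#' @inheritParams sweep_curve
#' @param noise_sd Noise standard deviation, umol m-2 s-1 (>= 0).
#' @param seed Integer seed; recorded in the curve's metadata.
#' @return A `c4_curve` tibble with provenance `"synthetic"`.
#' @export
synthesize_curve <- function(variable = c("Ci", "I", "T"), grid,
                             env_base = list(), params = c4_parameters(),
                             noise_sd = 0.5, seed = 1L,
                             gm_mode = "finite") {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  curve <- sweep_curve(variable, grid, env_base, params, gm_mode)
  noise <- withr::with_seed(seed, stats::rnorm(nrow(curve), 0, noise_sd))
  curve$A <- curve$A + noise
  new_c4_curve(curve, swept = attr(curve, "swept"),
               provenance = "synthetic", noise_sd = noise_sd,
               seed = as.integer(seed))
}

#' Default A-Ci measurement grid
#'
#' Fifteen intercellular CO2 set points from 20 to 1500 ubar with denser
#' low-CO2 coverage, where the initial slope carries the PEPC and mesophyll
#' conductance information.
#'
#' @return Numeric vector of Ci values, ubar.
#' @export
default_aci_grid <- function() {
  c(20, 30, 40, 52, 66, 82, 100, 130, 170, 250, 400, 600, 850, 1150, 1500)
}

fittable_parameters <- c("Vpmax25", "Vcmax25", "Vpr", "Jmax25", "gm25")

default_fit_bounds <- function(free) {
  lower <- c(Vpmax25 = 1, Vcmax25 = 1, Vpr = 1, Jmax25 = 1, gm25 = 0.01)
  upper <- c(Vpmax25 = 1000, Vcmax25 = 500, Vpr = 500, Jmax25 = 1500,
             gm25 = 20)
  list(lower = lower[free], upper = upper[free])
}

fit_predict <- function(theta, curve, params, gm_mode) {
  p <- params
  for (nm in names(theta)) p[[nm]] <- theta[[nm]]
  validate_c4_parameters(p)
  drivers <- intersect(c("Ci", "Cm", "Om", "I", "T"), names(curve))
  # a modelled curve carries its solved Cm alongside Ci; Ci is the driver
  if (all(c("Ci", "Cm") %in% drivers)) drivers <- setdiff(drivers, "Cm")
  env <- tibble::as_tibble(as.data.frame(curve)[drivers])
  simulate_gas_exchange(env, p, gm_mode = gm_mode)$A
}

#' Estimate capacity parameters from a gas-exchange curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the full leaf
#' model against measured or synthetic assimilation rates. Any subset of
#' `Vpmax25`, `Vcmax25`, `Vpr`, `Jmax25`, `gm25` may be freed; the remaining
#' parameters are held at their values in `params`.
#'
#' @param curve A data frame with an `A` column and the drivers `Ci` (or
#'   `Cm`) and optionally `Om`, `I`, `T`.
#' @param free Character vector of parameter names to estimate.
#' @param start Named numeric starting values; defaults to the values in
#'   `params`.
#' @param lower,upper Named bounds; sensible physiological defaults are used
#'   when omitted.
#' @param params Base [c4_parameters()] object supplying the fixed
#'   parameters.
#' @param gm_mode Passed to [simulate_gas_exchange()].
#' @return An object of class `c4_fit` with the estimates, approximate
#'   standard errors, residual sum of squares, convergence information, and
#'   a weak-identifiability flag based on the curvature-matrix condition
#'   number. Inspect with [tidy()][generics::tidy],
#'   [glance()][generics::glance] or `autoplot()`.
#' @examples
#' curve <- synthesize_curve("Ci", seq(20, 1500, length.out = 12),
#'                           noise_sd = 0.3, seed = 7)
#' fit <- fit_curve(curve, free = "Vpmax25", start = c(Vpmax25 = 120))
#' tidy(fit)
#' @export
fit_curve <- function(curve, free = c("Vpmax25", "Vcmax25"), start = NULL,
                      lower = NULL, upper = NULL,
                      params = c4_parameters(), gm_mode = "finite") {
  stopifnot(is.data.frame(curve), "A" %in% names(curve))
  bad <- setdiff(free, fittable_parameters)
  if (length(bad) > 0) {
    stop("cannot fit parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(curve) < 2 * length(free)) {
    stop("need at least ", 2 * length(free), " rows to fit ",
         length(free), " parameter(s)", call. = FALSE)
  }
  bounds <- default_fit_bounds(free)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  theta0 <- vapply(free, function(nm) {
    if (!is.null(start) && nm %in% names(start)) start[[nm]]
    else params[[nm]]
  }, numeric(1))
  names(theta0) <- free
  obs <- curve$A
  resid_fn <- function(theta) {
    names(theta) <- free
    obs - fit_predict(theta, curve = curve, params = params,
                      gm_mode = gm_mode)
  }
  fm <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    lower = bounds$lower, upper = bounds$upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- fm$info %in% 1:3
  if (!converged) {
    warning("least-squares fit did not converge: ", fm$message,
            call. = FALSE)
  }
  est <- stats::setNames(as.numeric(fm$par), free)
  n <- length(obs)
  p <- length(free)
  rss <- sum(fm$fvec^2)
  sigma2 <- rss / max(n - p, 1)
  # curvature matrix from a forward-difference jacobian at the optimum
  base_res <- resid_fn(est)
  Jm <- vapply(seq_along(est), function(k) {
    hstep <- max(1e-6 * abs(est[[k]]), 1e-8)
    th <- est
    th[[k]] <- th[[k]] + hstep
    (resid_fn(th) - base_res) / hstep
  }, numeric(n))
  JtJ <- crossprod(Jm)
  # collinearity index: condition number of the column-normalized curvature
  # matrix, so the flag is invariant to parameter scale
  norms <- sqrt(diag(JtJ))
  scaled <- JtJ / tcrossprod(pmax(norms, .Machine$double.eps))
  cond <- tryCatch(kappa(scaled, exact = TRUE), error = function(e) Inf)
  # kappa > 100 means >10x error inflation along the weakest direction
  weakly_identified <- !is.finite(cond) || cond > 100 || any(norms == 0)
  if (weakly_identified) {
    warning("near-singular curvature matrix: the freed parameters are ",
            "weakly identified by this curve design", call. = FALSE)
  }
  se <- tryCatch(sqrt(diag(solve(JtJ)) * sigma2),
                 error = function(e) rep(NA_real_, p))
  structure(
    list(estimate = est, std_error = stats::setNames(se, free),
         rss = rss, sigma = sqrt(sigma2), n = n, free = free,
         converged = converged, info = fm$info, message = fm$message,
         condition_number = cond, weakly_identified = weakly_identified,
         fitted = obs - base_res, residuals = base_res,
         curve = tibble::as_tibble(curve), params = params,
         gm_mode = gm_mode),
    class = "c4_fit"
  )
}

#' @export
print.c4_fit <- function(x, ...) {
  cat("<c4_fit> nonlinear least squares,", x$n, "observations\n")
  print(tidy(x))
  cat(sprintf("RSS %.4g, sigma %.4g, converged: %s\n",
              x$rss, x$sigma, x$converged))
  if (x$weakly_identified) cat("warning: weakly identified design\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted gas-exchange curve
#'
#' @param x A [fit_curve()] object.
#' @param ... Unused.
#' @return One row per freed parameter with `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.c4_fit <- function(x, ...) {
  tibble::tibble(term = x$free,
                 estimate = as.numeric(x$estimate),
                 std.error = as.numeric(x$std_error))
}

#' One-row summary of a fitted gas-exchange curve
#'
#' @inheritParams tidy.c4_fit
#' @return A tibble with `rss`, `sigma`, `nobs`, `nparam`, `converged`,
#'   `condition.number`, `weakly.identified`.
#' @export
glance.c4_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = x$sigma, nobs = x$n,
                 nparam = length(x$free), converged = x$converged,
                 condition.number = x$condition_number,
                 weakly.identified = x$weakly_identified)
}

#' Plot a modelled or synthetic response curve
#'
#' Assimilation against the swept driver, coloured by the limiting process.
#'
#' @param object A `c4_curve` from [sweep_curve()] or [synthesize_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.c4_curve <- function(object, ...) {
  swept <- attr(object, "swept")
  xlab <- switch(swept,
                 Ci = expression(C[i] ~ "(µbar)"),
                 I = expression(irradiance ~ "(µmol" ~ m^-2 ~ s^-1 * ")"),
                 T = "leaf temperature (°C)")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[swept]], y = .data$A)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$limitation)) +
    ggplot2::labs(x = xlab,
                  y = expression(A ~ "(µmol" ~ m^-2 ~ s^-1 * ")"),
                  colour = "limitation") +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted assimilation for a curve fit
#'
#' @param object A [fit_curve()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.c4_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$curve$A, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fitted A", y = "observed A") +
    ggplot2::theme_minimal()
}

# ---- CSV interchange ------------------------------------------------------

csv_name_map <- c(Ci = "Ci_ubar", Cm = "Cm_ubar", I = "I_umol_m2_s",
                  T = "T_C", Om = "Om_mbar", A = "A_umol_m2_s",
                  limitation = "limitation", phi = "phi")

#' Read a gas-exchange CSV
#'
#' Expects the unit-suffixed header convention `Ci_ubar`, `Cm_ubar`,
#' `I_umol_m2_s`, `T_C`, `Om_mbar`, `A_umol_m2_s`, `limitation`, `phi`;
#' missing optional columns are tolerated and unknown columns preserved.
#'
#' @param path CSV path (comma separator, dot decimal, header required).
#' @return A tibble with internal column names (`Ci`, `Cm`, `I`, `T`, `Om`,
#'   `A`, ...).
#' @export
read_gas_exchange <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty gas-exchange file: ", path, call. = FALSE)
  hit <- match(names(df), csv_name_map)
  names(df)[!is.na(hit)] <- names(csv_name_map)[hit[!is.na(hit)]]
  tibble::as_tibble(df)
}

#' Write a gas-exchange table as CSV
#'
#' Inverse of [read_gas_exchange()]: internal column names gain their unit
#' suffixes; other columns pass through unchanged.
#'
#' @param data A data frame (e.g. a `c4_curve` or [simulate_gas_exchange()]
#'   output).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(data, path) {
  df <- as.data.frame(data)
  hit <- match(names(df), names(csv_name_map))
  names(df)[!is.na(hit)] <- csv_name_map[hit[!is.na(hit)]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
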