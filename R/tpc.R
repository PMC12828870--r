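#' Parameters of an O'Neill thermal performance curve
#'
#' The asymmetric O'Neill form rises to `pmax` at `topt` and falls to
#' zero at `tmax_param`; a constant respiration `offset` is subtracted so
#' net rates can go negative. The shape exponent is
#' `x = (W^2 / 400) * (1 + sqrt(1 + 40 / W))^2` with
#' `W = (q10_shape - 1) * (tmax_param - topt)`.
#'
#' @param pmax Curve maximum height (> 0, rate units).
#' @param topt Temperature of the maximum (deg C).
#' @param tmax_param Temperature where the O'Neill term reaches zero
#'   (deg C, > `topt`).
#' @param q10_shape Dimensionless shape parameter (> 1).
#' @param offset Constant subtracted from the curve (>= 0, rate units).
#' @return An object of class `oneill_params`.
#' @export
oneill_params <- function(pmax, topt, tmax_param, q10_shape = 2, offset = 0) {
  if (!is_scalar_number(pmax) || pmax <= 0) stop("`pmax` must be > 0")
  if (!is_scalar_number(topt) || !is_scalar_number(tmax_param) ||
      topt >= tmax_param)
    stop("`topt` must be below `tmax_param`")
  if (!is_scalar_number(q10_shape) || q10_shape <= 1)
    stop("`q10_shape` must be > 1")
  if (!is_scalar_number(offset) || offset < 0) stop("`offset` must be >= 0")
  structure(list(pmax = pmax, topt = topt, tmax_param = tmax_param,
                 q10_shape = q10_shape, offset = offset),
            class = "oneill_params")
}

#' @noRd
oneill_shape_exponent <- function(q10_shape, topt, tmax_param) {
  w <- (q10_shape - 1) * (tmax_param - topt)
  (w^2 / 400) * (1 + sqrt(1 + 40 / w))^2
}

# Positive O'Neill term (no offset); 0 at and beyond tmax.
#' @noRd
oneill_term <- function(temp, pmax, topt, tmax_param, q10_shape) {
  x <- oneill_shape_exponent(q10_shape, topt, tmax_param)
  dt <- tmax_param - topt
  v <- numeric(length(temp))
  below <- temp < tmax_param
  v[below] <- pmax * ((tmax_param - temp[below]) / dt)^x *
    exp(x * (temp[below] - topt) / dt)
  v
}

#' Evaluate an O'Neill net-performance curve
#'
#' @param temp Temperatures (deg C), vectorised.
#' @param params An [oneill_params()] object.
#' @return Net rate at each temperature: the O'Neill term minus the
#'   offset (`-offset` at and beyond `tmax_param`).
#' @examples
#' p <- oneill_params(pmax = 10, topt = 20, tmax_param = 30, q10_shape = 2)
#' oneill_curve(c(20, 25, 30), p)
#' @export
oneill_curve <- function(temp, params) {
  stopifnot(inherits(params, "oneill_params"))
  oneill_term(temp, params$pmax, params$topt, params$tmax_param,
              params$q10_shape) - params$offset
}

#' Fit an O'Neill thermal performance curve
#'
#' Nonlinear least squares over (`pmax`, `topt`, `tmax_param`,
#' `q10_shape`, optionally `offset`), with `q10_shape` bounded in
#' (1, 5]. Fitting is multi-start: the optimum temperature is initialised
#' at the warmest-performing observation, the zero temperature at the
#' maximum observed temperature plus 3 deg C, and seeded jittered
#' restarts guard against local minima; the best residual sum of squares
#' wins. Levenberg–Marquardt (bounded) is the primary optimiser with a
#' Nelder–Mead fallback, and the `converged` flag is honest.
#'
#' @param observations Data frame with columns `temp_c` and `rate`;
#'   at least 5 observations spanning both sides of the apparent maximum.
#' @param fit_offset Fit the respiration offset (default FALSE: fixed 0).
#' @param n_starts Number of jittered restarts (default 10).
#' @param seed Integer seed for the restart jitter.
#' @return An object of class `kelp_tpc_fit`: list with `params`
#'   ([oneill_params()]), `topt_hat`, `ctmax_hat`, `rss`, `n_obs`,
#'   `converged`, `method`.
#' @export
fit_tpc <- function(observations, fit_offset = FALSE, n_starts = 10,
                    seed = 1L) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("temp_c", "rate") %in% names(obs)))
  obs <- obs[is.finite(obs$temp_c) & is.finite(obs$rate), , drop = FALSE]
  if (nrow(obs) < 5)
    stop("need at least 5 observations to fit a thermal performance curve")
  if (stats::sd(obs$rate) == 0)
    stop("degenerate data: all rates are equal")
  t_at_max <- obs$temp_c[which.max(obs$rate)]
  if (!any(obs$temp_c < t_at_max) || !any(obs$temp_c > t_at_max))
    stop("observations must span both sides of the apparent maximum")

  t_rng <- range(obs$temp_c)
  base_start <- c(pmax = max(obs$rate), topt = t_at_max,
                  dt = t_rng[2] + 3 - t_at_max, q10 = 2,
                  off = if (fit_offset) max(0.01, -min(obs$rate)) else 0)
  jit <- withr::with_seed(as.integer(seed), {
    cbind(stats::runif(n_starts, 0.7, 1.3),      # pmax factor
          stats::runif(n_starts, -2, 2),          # topt shift
          stats::runif(n_starts, 0.6, 1.6),       # dt factor
          stats::runif(n_starts, 1.3, 4.5),       # q10 value
          stats::runif(n_starts, 0.5, 2))         # offset factor
  })
  starts <- rbind(base_start,
                  t(apply(jit, 1, function(j)
                    c(base_start["pmax"] * j[1], base_start["topt"] + j[2],
                      base_start["dt"] * j[3], j[4], base_start["off"] * j[5]))))

  lower <- c(pmax = 1e-8, topt = t_rng[1] - 10, dt = 0.5, q10 = 1.0001,
             off = 0)
  upper <- c(pmax = Inf, topt = t_rng[2] + 10, dt = 100, q10 = 5, off = Inf)
  par_names <- if (fit_offset) c("pmax", "topt", "dt", "q10", "off") else
    c("pmax", "topt", "dt", "q10")

  predict_fun <- function(p) {
    oneill_term(obs$temp_c, p[["pmax"]], p[["topt"]], p[["topt"]] + p[["dt"]],
                p[["q10"]]) - if (fit_offset) p[["off"]] else 0
  }
  rss_fun <- function(par) {
    p <- stats::setNames(as.list(par), par_names)
    r <- obs$rate - predict_fun(p)
    sum(r^2)
  }

  fml <- if (fit_offset)
    rate ~ oneill_term(temp_c, pmax, topt, topt + dt, q10) - off
  else
    rate ~ oneill_term(temp_c, pmax, topt, topt + dt, q10)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, par_names])
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      fml, data = obs, start = st,
      lower = lower[par_names], upper = upper[par_names],
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss, converged = TRUE,
                   method = "nlsLM")
  }
  if (is.null(best)) {
    # all LM starts failed; direct RSS minimisation from the base start
    opt <- stats::optim(starts[1, par_names], function(par) {
      par <- pmin(pmax(par, lower[par_names]), upper[par_names])
      rss_fun(par)
    }, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14))
    best <- list(par = pmin(pmax(opt$par, lower[par_names]),
                            upper[par_names]),
                 rss = opt$value, converged = opt$convergence == 0,
                 method = "optim")
  }
  if (!best$converged || !is.finite(best$rss))
    stop("thermal performance curve fit did not converge (best rss = ",
         signif(best$rss, 4), ")")
  p <- best$par
  params <- oneill_params(pmax = unname(p["pmax"]), topt = unname(p["topt"]),
                          tmax_param = unname(p["topt"] + p["dt"]),
                          q10_shape = unname(p["q10"]),
                          offset = if (fit_offset) unname(p["off"]) else 0)
  limits <- derive_limits_params(params)
  structure(list(params = params, topt_hat = limits$topt_hat,
                 ctmax_hat = limits$ctmax_hat, rss = best$rss,
                 n_obs = nrow(obs), converged = best$converged,
                 method = best$method),
            class = "kelp_tpc_fit")
}

#' @export
print.kelp_tpc_fit <- function(x, ...) {
  cat(sprintf(
    "O'Neill TPC fit (%s): Topt %.2f degC, CTmax %.2f degC, rss %.4g (n = %d)\n",
    x$method, x$topt_hat, x$ctmax_hat, x$rss, x$n_obs))
  invisible(x)
}

#' @noRd
derive_limits_params <- function(params) {
  if (params$pmax - params$offset <= 0)
    stop("fitted net curve is entirely non-positive")
  if (params$offset == 0)
    return(list(topt_hat = params$topt, ctmax_hat = params$tmax_param))
  topt_hat <- stats::optimize(function(t) oneill_curve(t, params),
                              c(params$topt - 1, params$topt + 1),
                              maximum = TRUE, tol = 1e-6)$maximum
  # net curve is positive at topt and -offset just below tmax: bracketed root
  ctmax_hat <- stats::uniroot(function(t) oneill_curve(t, params),
                              c(topt_hat, params$tmax_param),
                              tol = 1e-4)$root
  list(topt_hat = topt_hat, ctmax_hat = ctmax_hat)
}

#' Derive thermal limits from a fitted curve
#'
#' `topt_hat` is the temperature of the fitted maximum (the `topt`
#' parameter when the offset is zero; located numerically otherwise) and
#' `ctmax_hat` is the smallest zero crossing of the fitted net curve
#' above `topt_hat`, found by bracketed root-finding to better than
#' 1e-3 deg C. With a zero offset the crossing is exactly `tmax_param`.
#'
#' @param fit A converged [fit_tpc()] result (or an [oneill_params()]
#'   object).
#' @return List with `topt_hat` and `ctmax_hat` (deg C).
#' @export
derive_limits <- function(fit) {
  if (inherits(fit, "oneill_params")) return(derive_limits_params(fit))
  stopifnot(inherits(fit, "kelp_tpc_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  derive_limits_params(fit$params)
}
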