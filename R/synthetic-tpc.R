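#' Configuration for synthetic thermal-performance observations
#'
#' Parameters of the O'Neill net-photosynthesis curve from which noisy
#' rate-vs-temperature observations are drawn; see [oneill_curve()] for
#' the functional form.
#'
#' @param pmax Height of the curve maximum (rate units).
#' @param topt Temperature of the maximum (deg C).
#' @param ctmax_param Temperature at which the O'Neill term reaches zero
#'   (deg C); must exceed `topt`. With `offset = 0` this is the curve's
#'   zero crossing (CTmax).
#' @param shape_q10 Dimensionless shape parameter (> 1) controlling
#'   steepness of the supra-optimal decline.
#' @param offset Constant respiration offset subtracted from the curve
#'   (rate units, >= 0), allowing negative net rates.
#' @param temps Test temperatures (deg C).
#' @param reps_per_temp Replicates per temperature (>= 1).
#' @param noise_sd SD of additive Gaussian observation noise (rate units).
#' @param seed Integer seed.
#' @return An object of class `tpc_gen_config`.
#' @export
tpc_gen_config <- function(pmax, topt, ctmax_param, shape_q10 = 2,
                           offset = 0, temps, reps_per_temp = 1,
                           noise_sd = 0, seed = 1L) {
  if (!is_scalar_number(reps_per_temp) || reps_per_temp < 1)
    stop("`reps_per_temp` must be >= 1")
  params <- oneill_params(pmax = pmax, topt = topt, tmax_param = ctmax_param,
                          q10_shape = shape_q10, offset = offset)
  structure(
    list(params = params, temps = as.numeric(temps),
         reps_per_temp = as.integer(reps_per_temp),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "tpc_gen_config")
}

#' Default thermal-performance configurations for the range edges
#'
#' The cool-edge configuration has its net-photosynthesis zero crossing at
#' 28.9 deg C; the warm-edge configuration crosses zero at 41 deg C,
#' above the 40 deg C mark that separates the two edges' laboratory-derived
#' thermal limits.
#'
#' @param seed Integer master seed.
#' @return Named list of [tpc_gen_config()] objects
#'   (`cool_edge`, `warm_edge`).
#' @export
default_tpc_configs <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    cool_edge = tpc_gen_config(pmax = 5, topt = 18, ctmax_param = 28.9,
                               shape_q10 = 2, offset = 0, temps = 5:30,
                               reps_per_temp = 1, noise_sd = 0,
                               seed = (seed * 131L + 21L) %% 2147483647L),
    warm_edge = tpc_gen_config(pmax = 7, topt = 25, ctmax_param = 41,
                               shape_q10 = 2, offset = 0, temps = 10:42,
                               reps_per_temp = 1, noise_sd = 0,
                               seed = (seed * 131L + 22L) %% 2147483647L))
}

#' Generate synthetic net-photosynthesis observations
#'
#' Draws `reps_per_temp` observations at each test temperature:
#' the O'Neill curve value plus seeded Gaussian noise.
#'
#' @param config A [tpc_gen_config()].
#' @return Data frame with columns `temp_c` and `rate`.
#' @export
generate_tpc_observations <- function(config) {
  stopifnot(inherits(config, "tpc_gen_config"))
  temps <- rep(config$temps, each = config$reps_per_temp)
  rate <- oneill_curve(temps, config$params)
  if (config$noise_sd > 0) {
    rate <- rate + withr::with_seed(
      config$seed, stats::rnorm(length(temps), 0, config$noise_sd))
  }
  data.frame(temp_c = temps, rate = rate)
}
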