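#' Differential-privacy configuration
#'
#' Settings of the gradient mechanism: L2 clipping of the per-batch
#' gradient followed by Gaussian noise injection. `noise_multiplier`
#' defaults to the calibration `mechanism_constant * sensitivity /
#' epsilon` (see [calibrate_sigma()]). Two noise conventions are
#' supported: `"multiplier"` adds noise with standard deviation
#' `sigma * clip_norm` (sigma read as a multiplier of the clipping norm,
#' standard DP-SGD usage), `"literal"` adds noise with standard deviation
#' `sigma` itself. `mechanism_constant` and `sensitivity` both default to
#' `clip_norm` (the L2 sensitivity of a clipped gradient).
#'
#' No formal (epsilon, delta) accountant is provided: epsilon enters only
#' through the calibration formula. This is a documented limitation.
#'
#' @param epsilon Privacy budget (> 0).
#' @param clip_norm L2 bound `C` imposed on gradients (> 0).
#' @param noise_multiplier Noise scale sigma; `NULL` calibrates from
#'   epsilon.
#' @param mechanism_constant Constant of the calibration formula.
#' @param sensitivity Maximal gradient change from one record.
#' @param schedule `"constant"` or `"linear_decay"` (sigma decays
#'   linearly to `floor_fraction` of its initial value over the rounds;
#'   the clipping norm is held fixed).
#' @param floor_fraction Final sigma as a fraction of the initial sigma
#'   under `linear_decay`.
#' @param noise_convention `"multiplier"` or `"literal"`.
#' @return A list of class `dp_config`.
#' @export
dp_config <- function(epsilon = 1, clip_norm = 1, noise_multiplier = NULL,
                      mechanism_constant = clip_norm, sensitivity = clip_norm,
                      schedule = c("constant", "linear_decay"),
                      floor_fraction = 0.5,
                      noise_convention = c("multiplier", "literal")) {
  if (epsilon <= 0) abort("epsilon must be positive")
  if (clip_norm <= 0) abort("clip_norm must be positive")
  sigma <- noise_multiplier %||%
    calibrate_sigma(mechanism_constant, sensitivity, epsilon)
  if (sigma < 0) abort("noise_multiplier must be nonnegative")
  structure(
    list(
      epsilon = epsilon, clip_norm = clip_norm, noise_multiplier = sigma,
      mechanism_constant = mechanism_constant, sensitivity = sensitivity,
      schedule = match.arg(schedule), floor_fraction = floor_fraction,
      noise_convention = match.arg(noise_convention)
    ),
    class = "dp_config"
  )
}

#' Clip a gradient to an L2 norm bound
#'
#' Returns `g * min(1, clip_norm / ||g||_2)`: the direction is preserved
#' and the output norm never exceeds `clip_norm`.
#'
#' @param g Numeric gradient vector.
#' @param clip_norm Positive L2 bound.
#' @return The clipped gradient.
#' @export
clip_gradient <- function(g, clip_norm) {
  if (!all(is.finite(g))) abort("gradient contains non-finite values")
  if (clip_norm <= 0) abort("clip_norm must be positive")
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) {
    return(g)
  }
  g * min(1, clip_norm / nrm)
}

#' Add independent Gaussian noise to a gradient
#'
#' @param g Numeric vector.
#' @param noise_std Per-coordinate standard deviation (>= 0). Uses the
#'   R RNG, so results are reproducible under `set.seed()`.
#' @return `g` plus N(0, noise_std^2) noise.
#' @export
add_gaussian_noise <- function(g, noise_std) {
  if (noise_std < 0) abort("noise_std must be nonnegative")
  if (noise_std == 0) {
    return(g)
  }
  g + rnorm(length(g), 0, noise_std)
}

#' Calibrate the noise scale from the privacy budget
#'
#' `sigma = mechanism_constant * sensitivity / epsilon`: noise shrinks as
#' the budget epsilon grows and scales linearly with the sensitivity.
#'
#' @param mechanism_constant Constant of the Gaussian mechanism.
#' @param sensitivity Maximal gradient change from one record.
#' @param epsilon Privacy budget (> 0).
#' @return The noise scale sigma.
#' @export
calibrate_sigma <- function(mechanism_constant, sensitivity, epsilon) {
  if (epsilon <= 0) abort("epsilon must be positive")
  mechanism_constant * sensitivity / epsilon
}

#' Per-round DP schedule
#'
#' Returns the noise scale and clipping norm for a given global round.
#' The constant schedule returns the configured values; `linear_decay`
#' interpolates sigma from its initial value down to `floor_fraction` of
#' it across the rounds (clipping norm held fixed), so sigma is
#' non-increasing in the round index.
#'
#' @param round_index Current round, 1-based.
#' @param total_rounds Total number of rounds.
#' @param dp A [dp_config()].
#' @return A list with `sigma` and `clip_norm`.
#' @export
dp_schedule_step <- function(round_index, total_rounds, dp) {
  stopifnot(inherits(dp, "dp_config"))
  if (round_index < 1 || round_index > total_rounds) {
    abort("round_index must be in [1, total_rounds]")
  }
  sigma0 <- dp$noise_multiplier
  sigma <- if (dp$schedule == "constant" || total_rounds == 1) {
    sigma0
  } else {
    frac <- (round_index - 1) / (total_rounds - 1)
    sigma0 * (1 - (1 - dp$floor_fraction) * frac)
  }
  list(sigma = sigma, clip_norm = dp$clip_norm)
}

# Apply the full mechanism to a flat gradient: clip then add noise with
# the convention-dependent standard deviation.
dp_transform_gradient <- function(g, sigma, clip_norm, convention = "multiplier") {
  g <- clip_gradient(g, clip_norm)
  std <- if (convention == "multiplier") {
    if (is.finite(clip_norm)) sigma * clip_norm else sigma
  } else {
    sigma
  }
  add_gaussian_noise(g, std)
}
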