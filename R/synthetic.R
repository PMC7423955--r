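#' Toy lambda-coupled potential specification
#'
#' Defines the one-particle model systems the built-in Metropolis Monte
#' Carlo simulator samples in place of molecular dynamics. Two kinds are
#' supported:
#'
#' * `"harmonic"`: a 1-D oscillator whose spring constant and center are
#'   interpolated linearly in lambda between initial and final values.
#'   Its free energy difference has the closed form implemented in
#'   [analytic_dg_harmonic()], making it the validation oracle.
#' * `"softcore_lj"`: a particle in a 1-D box of length `box_length`
#'   interacting with a fixed site through the lambda-scaled soft-core
#'   Lennard-Jones potential of [softcore_pair_energy()], exercising the
#'   finite-at-contact behaviour the soft core exists for.
#'
#' @param kind `"harmonic"` or `"softcore_lj"`
#' @param spring_constant_initial,spring_constant_final spring constants
#'   at lambda 0 and 1, kcal/mol/A^2 (> 0; harmonic kind)
#' @param center_initial,center_final oscillator centers at lambda 0 and
#'   1, Angstrom (harmonic kind)
#' @param epsilon well depth, kcal/mol (>= 0; softcore_lj kind)
#' @param sigma LJ zero crossing, Angstrom (> 0; softcore_lj kind)
#' @param softcore_alpha soft-core shift parameter (>= 0)
#' @param box_length box length, Angstrom (> 0; softcore_lj kind)
#' @param temperature temperature, Kelvin (> 0)
#' @return an object of class `toy_potential`
#' @examples
#' toy_potential("harmonic", spring_constant_initial = 1,
#'               spring_constant_final = 2)
#' @export
toy_potential <- function(kind = c("harmonic", "softcore_lj"),
                          spring_constant_initial = 1,
                          spring_constant_final = 1,
                          center_initial = 0, center_final = 0,
                          epsilon = 0.5, sigma = 3, softcore_alpha = 0.5,
                          box_length = 10, temperature = 300) {
  kind <- match.arg(kind)
  if (temperature <= 0) stop("temperature must be > 0")
  if (kind == "harmonic") {
    if (spring_constant_initial <= 0 || spring_constant_final <= 0) {
      stop("spring constants must be > 0")
    }
    spec <- list(kind = kind,
                 spring_constant_initial = spring_constant_initial,
                 spring_constant_final = spring_constant_final,
                 center_initial = center_initial,
                 center_final = center_final,
                 temperature = temperature)
  } else {
    if (epsilon < 0) stop("epsilon must be >= 0")
    if (sigma <= 0) stop("sigma must be > 0")
    if (softcore_alpha < 0) stop("softcore_alpha must be >= 0")
    if (box_length <= 0) stop("box_length must be > 0")
    spec <- list(kind = kind, epsilon = epsilon, sigma = sigma,
                 softcore_alpha = softcore_alpha, box_length = box_length,
                 temperature = temperature)
  }
  structure(spec, class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("toy potential [", x$kind, "] at ", x$temperature, " K\n", sep = "")
  invisible(x)
}

# numeric parameter vector handed to the compiled sampler
.toy_params <- function(spec) {
  if (spec$kind == "harmonic") {
    c(spec$spring_constant_initial, spec$spring_constant_final,
      spec$center_initial, spec$center_final)
  } else {
    c(spec$epsilon, spec$sigma, spec$softcore_alpha, spec$box_length)
  }
}

.toy_kind_code <- function(spec) if (spec$kind == "harmonic") 0L else 1L

# sensible chain start: the lambda-interpolated minimum (harmonic) or
# the LJ minimum distance (soft-core)
.toy_start <- function(spec, lambda) {
  if (spec$kind == "harmonic") {
    (1 - lambda) * spec$center_initial + lambda * spec$center_final
  } else {
    min(spec$sigma * 2^(1 / 6), spec$box_length / 2)
  }
}

#' Analytic free energy difference of the 1-D harmonic oscillator
#'
#' Closed-form oracle for the toy harmonic transformation: the
#' configurational partition function of a 1-D oscillator with spring
#' constant k is proportional to k^(-1/2), so
#' \deqn{\Delta G = \frac{k_B T}{2} \ln \frac{k_{final}}{k_{initial}}.}
#' The center of the oscillator does not affect the free energy.
#'
#' @param k_initial,k_final spring constants, kcal/mol/A^2 (> 0)
#' @param temperature temperature, Kelvin (> 0)
#' @return free energy difference in kcal/mol; antisymmetric under
#'   swapping `k_initial` and `k_final`
#' @examples
#' analytic_dg_harmonic(1, 4, 300) # ~0.41327
#' @export
analytic_dg_harmonic <- function(k_initial, k_final, temperature) {
  if (any(k_initial <= 0) || any(k_final <= 0)) {
    stop("spring constants must be > 0")
  }
  kBT(temperature) / 2 * log(k_final / k_initial)
}

#' Toy potential energy at a coordinate and coupling value
#'
#' @param spec a [toy_potential()]
#' @param coordinate position (harmonic) or pair distance (softcore_lj),
#'   Angstrom; vectorised
#' @param lambda coupling value in \[0, 1\]
#' @return energy in kcal/mol; finite for all coordinates, including
#'   r = 0 for the soft-core kind at lambda < 1
#' @export
potential_energy <- function(spec, coordinate, lambda) {
  stopifnot(inherits(spec, "toy_potential"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  if (spec$kind == "harmonic") {
    k <- (1 - lambda) * spec$spring_constant_initial +
      lambda * spec$spring_constant_final
    ctr <- (1 - lambda) * spec$center_initial + lambda * spec$center_final
    0.5 * k * (coordinate - ctr)^2
  } else {
    softcore_pair_energy(coordinate, lambda, spec$epsilon, spec$sigma,
                         spec$softcore_alpha)
  }
}

#' Per-window forward/reverse energy-difference samples
#'
#' Container for the work values of one lambda window: `forward_dU`
#' holds U(lambda_high) - U(lambda_low) sampled in the lambda_low
#' ensemble, `reverse_dU` holds U(lambda_low) - U(lambda_high) sampled
#' in the lambda_high ensemble.
#'
#' @param lambda_low,lambda_high window bounds, 0 <= low < high <= 1
#' @param forward_dU,reverse_dU finite energy differences, kcal/mol
#' @param temperature temperature, Kelvin
#' @return an object of class `window_samples`
#' @export
window_samples <- function(lambda_low, lambda_high, forward_dU, reverse_dU,
                           temperature) {
  if (!is.finite(lambda_low) || !is.finite(lambda_high) ||
      lambda_low < 0 || lambda_high > 1 || lambda_low >= lambda_high) {
    stop("require 0 <= lambda_low < lambda_high <= 1")
  }
  if (any(!is.finite(forward_dU)) || any(!is.finite(reverse_dU))) {
    stop(sprintf("non-finite energy difference in window [%g, %g]",
                 lambda_low, lambda_high))
  }
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(lambda_low = lambda_low, lambda_high = lambda_high,
                 forward_dU = as.numeric(forward_dU),
                 reverse_dU = as.numeric(reverse_dU),
                 temperature = temperature),
            class = "window_samples")
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf("window [%g, %g]: %d forward / %d reverse samples at %g K\n",
              x$lambda_low, x$lambda_high, length(x$forward_dU),
              length(x$reverse_dU), x$temperature))
  invisible(x)
}

# deterministic per-window, per-direction seed stream
.window_seed <- function(master_seed, window_index, direction_flag) {
  (as.integer(master_seed) + 2L * as.integer(window_index) +
     as.integer(direction_flag)) %% .Machine$integer.max
}

#' Sample one lambda window by Metropolis Monte Carlo
#'
#' Runs two independent Metropolis chains: one in the `lambda_low`
#' ensemble recording forward energy differences and one in the
#' `lambda_high` ensemble recording reverse differences. The first 20%
#' of each chain is discarded as burn-in (mirroring a 1 ns
#' equilibration / 4 ns production split). Acceptance uses
#' k_B = 0.0019872041 kcal/mol/K; runs are bit-reproducible for a fixed
#' seed.
#'
#' @param spec a [toy_potential()]
#' @param lambda_low,lambda_high window bounds
#' @param n_steps Monte Carlo steps per direction (> 0)
#' @param step_size maximum displacement of the symmetric uniform move,
#'   Angstrom; the default is tuned to roughly 40% acceptance on the
#'   default harmonic spec
#' @param seed integer seed; forward and reverse chains draw from
#'   independent streams derived from it
#' @param burn_in_fraction fraction of initial steps discarded
#' @return a [window_samples()] object
#' @export
sample_window <- function(spec, lambda_low, lambda_high, n_steps,
                          step_size = 3.0, seed, burn_in_fraction = 0.2) {
  stopifnot(inherits(spec, "toy_potential"))
  if (n_steps <= 0) stop("n_steps must be > 0")
  if (missing(seed)) stop("a seed must be supplied")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must be in [0, 1)")
  }
  keep_from <- floor(burn_in_fraction * n_steps) + 1L
  run <- function(lambda_sim, lambda_other, chain_seed) {
    set.seed(chain_seed)
    out <- .mc_chain_dU(.toy_kind_code(spec), .toy_params(spec),
                        lambda_sim, lambda_other,
                        .toy_start(spec, lambda_sim), as.integer(n_steps),
                        step_size, kBT(spec$temperature))
    out$dU[keep_from:length(out$dU)]
  }
  fwd <- run(lambda_low, lambda_high, .window_seed(seed, 0L, 0L))
  rev <- run(lambda_high, lambda_low, .window_seed(seed, 0L, 1L))
  window_samples(lambda_low, lambda_high, fwd, rev, spec$temperature)
}

#' Generate a full toy alchemical transformation
#'
#' Samples every window of an equally spaced lambda schedule with
#' [sample_window()], deriving per-window seeds deterministically from
#' the master seed and window index so windows are mutually independent
#' yet fully reproducible.
#'
#' @param spec a [toy_potential()]
#' @param n_windows number of equally spaced windows (>= 1)
#' @param n_steps_per_window Monte Carlo steps per direction per window
#' @param seed master integer seed
#' @param step_size Monte Carlo move size, Angstrom
#' @return list of [window_samples()] in lambda order
#' @examples
#' spec <- toy_potential("harmonic", spring_constant_initial = 1,
#'                       spring_constant_final = 2)
#' tw <- generate_transformation(spec, n_windows = 4,
#'                               n_steps_per_window = 2000, seed = 7)
#' @export
generate_transformation <- function(spec, n_windows, n_steps_per_window,
                                    seed, step_size = 3.0) {
  sched <- make_windows(n_windows)
  bounds <- window_bounds(sched)
  lapply(seq_len(n_windows), function(i) {
    sample_window(spec, bounds$lambda_low[i], bounds$lambda_high[i],
                  n_steps_per_window, step_size = step_size,
                  seed = .window_seed(seed, i, 0L))
  })
}
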