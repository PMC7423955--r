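#' Equally spaced lambda-window schedule
#'
#' Builds the grid of coupling-parameter windows used for an alchemical
#' transformation. The transformation from the initial state (lambda = 0)
#' to the final state (lambda = 1) is subdivided into `n_windows`
#' equally spaced windows, so with the conventional 40 windows the first
#' spans lambda 0 to 0.025 and the last 0.975 to 1.
#'
#' @param n_windows number of windows (>= 1)
#' @return an object of class `lambda_schedule`: a list with `n_windows`
#'   and `edges`, the `n_windows + 1` strictly increasing lambda values
#'   from 0 to 1
#' @examples
#' s <- make_windows(40)
#' s$edges[2] # 0.025
#' @export
make_windows <- function(n_windows) {
  if (!is.numeric(n_windows) || length(n_windows) != 1L ||
      !is.finite(n_windows) || n_windows < 1 || n_windows != round(n_windows)) {
    stop("n_windows must be a single integer >= 1")
  }
  n_windows <- as.integer(n_windows)
  edges <- seq(0, 1, length.out = n_windows + 1L)
  structure(list(n_windows = n_windows, edges = edges),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("lambda schedule:", x$n_windows, "equally spaced windows, width",
      format(1 / x$n_windows), "\n")
  invisible(x)
}

#' Window bounds of a lambda schedule
#'
#' @param schedule a `lambda_schedule` from [make_windows()]
#' @return data frame with columns `window`, `lambda_low`, `lambda_high`
#' @export
window_bounds <- function(schedule) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  n <- schedule$n_windows
  data.frame(window = seq_len(n),
             lambda_low = schedule$edges[seq_len(n)],
             lambda_high = schedule$edges[seq_len(n) + 1L])
}

#' Dual-topology coupling state at a given lambda
#'
#' In the dual-topology scheme both end-state atom sets are present but
#' mutually non-interacting; their nonbonded interactions with the
#' environment are scaled oppositely in lambda. Van der Waals
#' interactions are scaled linearly across the full range, while
#' electrostatics are split: the outgoing (annihilating) atoms are
#' linearly decoupled over the first half of the transformation and the
#' incoming atoms linearly coupled over the second half, so the two
#' charge sets are never simultaneously active.
#'
#' @param lambda coupling value(s) in \[0, 1\]
#' @return data frame with one row per lambda and columns
#'   `elec_outgoing`, `elec_incoming`, `vdw_outgoing`, `vdw_incoming`,
#'   all scale factors in \[0, 1\]
#' @examples
#' coupling_at(c(0, 0.5, 0.75, 1))
#' @export
coupling_at <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) ||
      any(lambda < 0 | lambda > 1)) {
    stop("lambda must lie in [0, 1]")
  }
  data.frame(
    lambda = lambda,
    elec_outgoing = pmax(0, 1 - 2 * lambda),
    elec_incoming = pmax(0, 2 * lambda - 1),
    vdw_outgoing = 1 - lambda,
    vdw_incoming = lambda
  )
}

#' Soft-core Lennard-Jones pair energy
#'
#' Beutler-style soft-core potential used to avoid end-point
#' singularities when partially coupled atoms approach other particles:
#'
#' \deqn{E(r) = 4 \epsilon \lambda \left[ s^2 - s \right], \quad
#'       s = \frac{\sigma^6}{\alpha (1 - \lambda) \sigma^6 + r^6}}
#'
#' The r^6 term alone is shifted, so at `lambda_vdw = 1` the expression
#' reduces exactly to the Lennard-Jones 12-6 potential, while for
#' `lambda_vdw < 1` the energy stays finite down to r = 0.
#'
#' @param r pair distance(s) in Angstrom (>= 0)
#' @param lambda_vdw van der Waals coupling scale in \[0, 1\]
#' @param epsilon well depth, kcal/mol (>= 0)
#' @param sigma zero-crossing distance, Angstrom (> 0)
#' @param alpha soft-core shift parameter (>= 0), default 0.5
#' @return energy in kcal/mol, vectorised over `r`
#' @examples
#' softcore_pair_energy(1, 1, epsilon = 1, sigma = 1) # LJ zero crossing
#' @export
softcore_pair_energy <- function(r, lambda_vdw, epsilon, sigma, alpha = 0.5) {
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  if (length(lambda_vdw) != 1L || !is.finite(lambda_vdw) ||
      lambda_vdw < 0 || lambda_vdw > 1) {
    stop("lambda_vdw must be a single value in [0, 1]")
  }
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (lambda_vdw == 0) return(rep(0, length(r)))
  s <- sigma^6 / (alpha * (1 - lambda_vdw) * sigma^6 + r^6)
  4 * epsilon * lambda_vdw * (s^2 - s)
}

#' Simulation time bookkeeping for a full FEP study
#'
#' Accounts for the total sampling a standard protocol implies: each leg
#' of the thermodynamic cycle runs every lambda window in both the
#' forward and reverse directions. With the default protocol (40
#' windows, 5 ns each, both directions) a single mutation in a single
#' system costs 400 ns, and a study of 7 mutations in 3 systems (apo
#' plus two ligand tautomers) totals 8.4 microseconds.
#'
#' @param n_windows lambda windows per direction
#' @param ns_per_window simulated time per window (equilibration +
#'   production), ns
#' @param n_directions sampling directions (2 = forward and reverse)
#' @param n_mutations number of alchemical mutations in the study
#' @param n_systems systems per mutation (e.g. apo, holo tautomer 1,
#'   holo tautomer 2)
#' @return list with `ns_per_leg` (per mutation per system), `total_ns`
#'   and `total_us`
#' @export
simulation_time_budget <- function(n_windows = 40, ns_per_window = 5,
                                   n_directions = 2, n_mutations = 7,
                                   n_systems = 3) {
  stopifnot(n_windows >= 1, ns_per_window > 0, n_directions >= 1,
            n_mutations >= 1, n_systems >= 1)
  ns_per_leg <- n_windows * ns_per_window * n_directions
  total_ns <- ns_per_leg * n_mutations * n_systems
  list(ns_per_leg = ns_per_leg, total_ns = total_ns,
       total_us = total_ns / 1000)
}
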