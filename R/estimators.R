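#' Free energy estimate container
#'
#' @param value free energy difference, kcal/mol
#' @param stderr standard error, kcal/mol (>= 0)
#' @param method one of `"zwanzig_forward"`, `"zwanzig_reverse"`, `"bar"`
#' @param n_effective_forward,n_effective_reverse effective (post
#'   subsampling) sample counts per direction; `NA` for a direction the
#'   method does not use
#' @return an object of class `fe_estimate`
#' @export
fe_estimate <- function(value, stderr, method,
                        n_effective_forward = NA_integer_,
                        n_effective_reverse = NA_integer_) {
  method <- match.arg(method, c("zwanzig_forward", "zwanzig_reverse", "bar"))
  if (!is.finite(value)) stop("estimate value must be finite")
  if (!is.finite(stderr) || stderr < 0) stop("stderr must be finite and >= 0")
  structure(list(value = value, stderr = stderr, method = method,
                 n_effective_forward = n_effective_forward,
                 n_effective_reverse = n_effective_reverse),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("dG = %s +- %s kcal/mol [%s]\n",
              format(x$value, digits = digits),
              format(x$stderr, digits = digits), x$method))
  invisible(x)
}

#' Zwanzig (exponential averaging) free energy estimator
#'
#' One-sided free energy perturbation:
#' \deqn{\Delta G = -k_B T \ln \langle e^{-\Delta U / k_B T} \rangle}
#' computed with a max-shift so the exponentials cannot overflow. The
#' standard error is propagated from the sample variance of the
#' exponential mean (delta method), which presumes effectively
#' independent samples — decorrelate first (see
#' [statistical_inefficiency()]).
#'
#' @param dU energy-difference samples, kcal/mol (non-empty, finite)
#' @param temperature temperature, Kelvin
#' @return an [fe_estimate()] with method `"zwanzig_forward"`
#' @examples
#' zwanzig(rep(1.5, 100), 300) # constant work: dG = 1.5 exactly
#' @export
zwanzig <- function(dU, temperature) {
  if (length(dU) == 0) stop("empty sample set")
  if (any(!is.finite(dU))) stop("non-finite energy differences")
  kT <- kBT(temperature)
  a <- -dU / kT
  m <- max(a)
  y <- exp(a - m)
  ybar <- mean(y)
  value <- -kT * (m + log(ybar))
  se <- if (length(y) > 1) kT * stats::sd(y) / (sqrt(length(y)) * ybar) else 0
  fe_estimate(value, se, "zwanzig_forward",
              n_effective_forward = length(dU))
}

# Fermi function, overflow-safe in both tails
.fermi <- function(x) 1 / (1 + exp(x))

#' Bennett acceptance ratio (BAR) free energy estimator
#'
#' Combines forward and reverse work samples into the minimum-variance
#' two-state estimate by solving Bennett's self-consistent equation. With
#' `forward_w` the energy differences sampled in the low-lambda state A
#' and `reverse_w` those sampled in the high-lambda state B, the shift C
#' solves
#' \deqn{\sum_F f(\beta(w_F - C)) = \sum_R f(\beta(w_R + C))}
#' with the Fermi function f(x) = 1/(1+e^x), and the A-to-B free energy
#' is \eqn{\Delta G = C - k_B T \ln(n_R / n_F)}. The left side is
#' increasing and the right side decreasing in C, so the root is unique;
#' it is bracketed from the two one-sided Zwanzig estimates +- 50 k_B T
#' and refined to `tolerance`. The standard error is Bennett's
#' asymptotic variance evaluated at the solution.
#'
#' Zero-variance inputs with consistent constants (all forward work c,
#' all reverse work -c) short-circuit to the exact answer c with zero
#' standard error.
#'
#' @param forward_w work samples from the A (low-lambda) ensemble,
#'   kcal/mol
#' @param reverse_w work samples from the B (high-lambda) ensemble,
#'   kcal/mol
#' @param temperature temperature, Kelvin
#' @param tolerance convergence tolerance on the free energy, kcal/mol
#' @param window optional label used in error messages
#' @return an [fe_estimate()] with method `"bar"`
#' @examples
#' bar(rep(2, 50), rep(-2, 50), 300) # dG = 2 exactly
#' @export
bar <- function(forward_w, reverse_w, temperature, tolerance = 1e-8,
                window = NULL) {
  if (length(forward_w) == 0 || length(reverse_w) == 0) {
    stop("empty sample set for BAR")
  }
  if (any(!is.finite(forward_w)) || any(!is.finite(reverse_w))) {
    stop("non-finite work values")
  }
  kT <- kBT(temperature)
  nF <- length(forward_w)
  nR <- length(reverse_w)

  # degenerate zero-variance case: exact constant-work answer
  if (stats::var(c(forward_w, -reverse_w)) == 0 ||
      (nF == 1 && nR == 1 && forward_w == -reverse_w)) {
    if (isTRUE(all.equal(forward_w[1], -reverse_w[1]))) {
      return(fe_estimate(forward_w[1], 0, "bar",
                         n_effective_forward = nF,
                         n_effective_reverse = nR))
    }
  }

  objective <- function(C) {
    sum(.fermi((forward_w - C) / kT)) - sum(.fermi((reverse_w + C) / kT))
  }
  zf <- zwanzig(forward_w, temperature)$value
  zr <- -zwanzig(reverse_w, temperature)$value
  lo <- min(zf, zr) - 50 * kT
  hi <- max(zf, zr) + 50 * kT
  root <- tryCatch(
    stats::uniroot(objective, lower = lo, upper = hi, extendInt = "upX",
                   tol = tolerance),
    error = function(e) {
      lab <- if (is.null(window)) "" else paste0(" in window ", window)
      stop(sprintf("BAR failed to bracket a root%s: %s", lab,
                   conditionMessage(e)))
    })
  C <- root$root
  dG <- C - kT * log(nR / nF)

  fF <- .fermi((forward_w - C) / kT)
  fR <- .fermi((reverse_w + C) / kT)
  vF <- (mean(fF^2) / mean(fF)^2 - 1) / nF
  vR <- (mean(fR^2) / mean(fR)^2 - 1) / nR
  se <- kT * sqrt(max(vF + vR, 0))
  fe_estimate(dG, se, "bar", n_effective_forward = nF,
              n_effective_reverse = nR)
}

#' Statistical inefficiency and decorrelation subsampling
#'
#' Estimates the statistical inefficiency
#' \eqn{g = 1 + 2 \sum_t \rho_t} of a scalar time series, truncating the
#' sum of normalized autocorrelations at the first non-positive value,
#' and proposes the retained indices for extracting effectively
#' independent samples: every `ceiling(g)`-th observation starting at
#' the first. g is clamped to \[1, length\]; a constant series carries
#' no information and returns g = length with a warning.
#'
#' @param series numeric time series, length >= 2
#' @return an object of class `decorrelation`: list with `g` and
#'   `retained_indices` (1-based, strictly increasing, spaced by
#'   `ceiling(g)`)
#' @examples
#' statistical_inefficiency(rnorm(1000))$g # ~1 for white noise
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 2) stop("series must have length >= 2")
  if (any(!is.finite(series))) stop("non-finite values in series")
  v <- stats::var(series)
  if (v == 0) {
    warning("constant series: statistical inefficiency set to its length")
    g <- n
  } else {
    x <- series - mean(series)
    g <- 1
    for (t in seq_len(n - 1L)) {
      rho <- sum(x[1:(n - t)] * x[(1 + t):n]) / ((n - t) * v)
      if (rho <= 0) break
      g <- g + 2 * rho
    }
    g <- min(max(g, 1), n)
  }
  structure(list(g = g,
                 retained_indices = seq.int(1L, n, by = as.integer(ceiling(g)))),
            class = "decorrelation")
}

#' @export
print.decorrelation <- function(x, ...) {
  cat(sprintf("statistical inefficiency g = %.3f, %d samples retained\n",
              x$g, length(x$retained_indices)))
  invisible(x)
}

#' Subsample a series to effectively independent observations
#'
#' @param series numeric time series
#' @return the retained observations per [statistical_inefficiency()]
#' @export
decorrelate <- function(series) {
  series[statistical_inefficiency(series)$retained_indices]
}

#' Estimate the free energy of one lambda window
#'
#' Optionally subsamples each direction independently to uncorrelated
#' samples, then applies the chosen estimator. `"zwanzig_reverse"`
#' reports the A-to-B free energy inferred from the reverse-direction
#' samples (the negated one-sided estimate from the high-lambda
#' ensemble), so all three methods share a sign convention.
#'
#' @param samples a [window_samples()] object
#' @param method `"bar"` (default), `"zwanzig_forward"` or
#'   `"zwanzig_reverse"`
#' @param decorrelate subsample each direction first? default TRUE
#' @param tolerance BAR convergence tolerance, kcal/mol
#' @return an [fe_estimate()] with effective sample counts recorded
#' @export
estimate_window <- function(samples,
                            method = c("bar", "zwanzig_forward",
                                       "zwanzig_reverse"),
                            decorrelate = TRUE, tolerance = 1e-8) {
  stopifnot(inherits(samples, "window_samples"))
  method <- match.arg(method)
  fw <- samples$forward_dU
  rv <- samples$reverse_dU
  if (length(fw) == 0 || length(rv) == 0) stop("empty window samples")
  if (decorrelate) {
    if (length(fw) > 1) fw <- suppressWarnings(decorrelate(fw))
    if (length(rv) > 1) rv <- suppressWarnings(decorrelate(rv))
  }
  Tk <- samples$temperature
  lab <- sprintf("[%g, %g]", samples$lambda_low, samples$lambda_high)
  if (method == "bar") {
    est <- bar(fw, rv, Tk, tolerance = tolerance, window = lab)
  } else if (method == "zwanzig_forward") {
    est <- zwanzig(fw, Tk)
    est$n_effective_reverse <- NA_integer_
  } else {
    z <- zwanzig(rv, Tk)
    est <- fe_estimate(-z$value, z$stderr, "zwanzig_reverse",
                       n_effective_reverse = length(rv))
  }
  est
}

#' Accumulate per-window estimates across a transformation
#'
#' Window estimates are treated as statistically independent (each
#' window is sampled by its own simulation), so values add and standard
#' errors combine as the root sum of squares.
#'
#' @param estimates list of [fe_estimate()] objects in window order
#' @return an [fe_estimate()] for the whole transformation; the method
#'   tag is carried over when all windows share one
#' @examples
#' accumulate(list(fe_estimate(1, 0.3, "bar"), fe_estimate(2, 0.4, "bar")))
#' @export
accumulate <- function(estimates) {
  if (length(estimates) == 0) stop("no estimates to accumulate")
  stopifnot(all(vapply(estimates, inherits, logical(1), "fe_estimate")))
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  ses <- vapply(estimates, `[[`, numeric(1), "stderr")
  methods <- unique(vapply(estimates, `[[`, character(1), "method"))
  nf <- vapply(estimates, `[[`, numeric(1), "n_effective_forward")
  nr <- vapply(estimates, `[[`, numeric(1), "n_effective_reverse")
  fe_estimate(sum(vals), sqrt(sum(ses^2)),
              if (length(methods) == 1) methods else "bar",
              n_effective_forward = if (all(is.na(nf))) NA else sum(nf, na.rm = TRUE),
              n_effective_reverse = if (all(is.na(nr))) NA else sum(nr, na.rm = TRUE))
}

#' Estimate and accumulate a whole transformation
#'
#' Convenience wrapper: [estimate_window()] on every window, then
#' [accumulate()].
#'
#' @inheritParams estimate_window
#' @param windows list of [window_samples()] in lambda order
#' @return list with `total` (an [fe_estimate()]) and `per_window`
#'   (data frame of per-window values)
#' @export
estimate_transformation <- function(windows,
                                    method = c("bar", "zwanzig_forward",
                                               "zwanzig_reverse"),
                                    decorrelate = TRUE, tolerance = 1e-8) {
  method <- match.arg(method)
  ests <- lapply(windows, estimate_window, method = method,
                 decorrelate = decorrelate, tolerance = tolerance)
  per_window <- data.frame(
    lambda_low = vapply(windows, `[[`, numeric(1), "lambda_low"),
    lambda_high = vapply(windows, `[[`, numeric(1), "lambda_high"),
    dG = vapply(ests, `[[`, numeric(1), "value"),
    stderr = vapply(ests, `[[`, numeric(1), "stderr"),
    n_eff_forward = vapply(ests, `[[`, numeric(1), "n_effective_forward"),
    n_eff_reverse = vapply(ests, `[[`, numeric(1), "n_effective_reverse")
  )
  list(total = accumulate(ests), per_window = per_window, estimates = ests)
}
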