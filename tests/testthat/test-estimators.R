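test_that("Zwanzig handles constant and Gaussian work distributions", {
  expect_equal(zwanzig(rep(1.5, 10), 300)$value, 1.5)
  expect_equal(zwanzig(rep(1.5, 10), 300)$stderr, 0)
  expect_equal(zwanzig(c(0, 0, 0), 300)$value, 0)
  # Gaussian work: dG = mu - sigma^2 / (2 kB T)
  set.seed(101)
  dU <- rnorm(1e5, mean = 2, sd = 1)
  z <- zwanzig(dU, 300)
  expect_lt(abs(z$value - (2 - 1 / (2 * kT300))), 3 * z$stderr)
  expect_equal(z$n_effective_forward, 1e5)
  # overflow safety: huge negative works must not blow up
  expect_true(is.finite(zwanzig(c(-5000, -5001), 300)$value))
  expect_error(zwanzig(numeric(0), 300), "empty")
})

test_that("BAR solves Bennett's equation and matches a brute-force root", {
  # symmetric constant works: dG = c exactly, by the equation's symmetry
  est <- bar(rep(2, 40), rep(-2, 40), 300)
  expect_equal(est$value, 2)
  expect_equal(est$stderr, 0)

  # direction antisymmetry
  set.seed(7)
  fw <- rnorm(400, 1.0, 0.8)
  rv <- rnorm(300, -0.6, 0.8)
  expect_equal(bar(fw, rv, 300)$value, -bar(rv, fw, 300)$value,
               tolerance = 1e-6)

  # independent grid-search oracle for the implicit equation,
  # including unequal sample counts
  expect_equal(bar(fw, rv, 300)$value, bar_grid_oracle(fw, rv, 300),
               tolerance = 1e-6)

  # shifting forward works by +c and reverse works by -c shifts the
  # estimate by exactly c
  b0 <- bar(fw, rv, 300)
  b1 <- bar(fw + 1.25, rv - 1.25, 300)
  expect_equal(b1$value - b0$value, 1.25, tolerance = 1e-6)
  expect_equal(b1$stderr, b0$stderr, tolerance = 1e-9)

  expect_error(bar(numeric(0), rv, 300), "empty")
})

test_that("BAR lies between the forward and negated-reverse Zwanzig", {
  spec <- harmonic_spec(1, 3)
  for (seed in c(3, 17)) {
    w <- sample_window(spec, 0, 1, 20000, seed = seed)
    zf <- estimate_window(w, method = "zwanzig_forward")$value
    zr <- estimate_window(w, method = "zwanzig_reverse")$value
    b <- estimate_window(w, method = "bar")$value
    expect_gte(b, min(zf, zr) - 1e-9)
    expect_lte(b, max(zf, zr) + 1e-9)
  }
})

test_that("statistical inefficiency matches iid and AR(1) limits", {
  set.seed(5)
  g_iid <- statistical_inefficiency(rnorm(1e4))$g
  expect_lt(abs(g_iid - 1), 0.2)

  set.seed(6)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  g_ar <- statistical_inefficiency(ar)$g
  expect_lt(abs(g_ar - 19) / 19, 0.2) # (1+rho)/(1-rho) = 19

  # retained indices spaced by ceiling(g), starting at the first sample
  d <- statistical_inefficiency(ar)
  expect_equal(d$retained_indices[1], 1L)
  expect_true(all(diff(d$retained_indices) == ceiling(d$g)))

  # constant series: g = length, with a warning, no division by zero
  expect_warning(gc_ <- statistical_inefficiency(rep(1, 50)), "constant")
  expect_equal(gc_$g, 50)

  # g = 1 makes subsampling the identity
  set.seed(8)
  x <- rnorm(500)
  d1 <- statistical_inefficiency(x)
  if (ceiling(d1$g) == 1) expect_equal(decorrelate(x), x)
  expect_error(statistical_inefficiency(1), "length")
})

test_that("estimate_window subsamples per direction and delegates", {
  spec <- harmonic_spec(1, 2)
  w <- sample_window(spec, 0, 0.5, 10000, seed = 31)
  direct <- bar(decorrelate(w$forward_dU), decorrelate(w$reverse_dU), 300)
  via <- estimate_window(w, method = "bar", decorrelate = TRUE)
  expect_equal(via$value, direct$value)
  expect_equal(via$n_effective_forward, direct$n_effective_forward)

  # on effectively independent data the subsampled estimate agrees
  # with the full-data one within statistical error (property over
  # seeds). The Gaussian work pair satisfies the fluctuation relation:
  # negated-reverse mean = forward mean - beta * sigma^2.
  sig <- 0.6
  muF <- 1
  muR <- muF - sig^2 / kT300
  ok <- logical(5)
  for (s in 1:5) {
    set.seed(s)
    iid <- window_samples(0, 1, rnorm(5000, muF, sig),
                          rnorm(5000, -muR, sig), 300)
    on <- estimate_window(iid, decorrelate = TRUE)
    off <- estimate_window(iid, decorrelate = FALSE)
    ok[s] <- abs(on$value - off$value) <
      3 * sqrt(on$stderr^2 + off$stderr^2)
  }
  expect_gte(mean(ok), 0.8)

  null_w <- window_samples(0, 1, rep(0, 100), rep(0, 100), 300)
  est0 <- suppressWarnings(estimate_window(null_w))
  expect_equal(est0$value, 0)
  expect_equal(est0$stderr, 0)
})

test_that("accumulation sums values and errors in quadrature", {
  e <- accumulate(list(fe_estimate(1, 0.3, "bar"),
                       fe_estimate(2, 0.4, "bar")))
  expect_equal(e$value, 3)
  expect_equal(e$stderr, 0.5)

  single <- fe_estimate(1.2, 0.1, "bar")
  acc1 <- accumulate(list(single))
  expect_equal(acc1$value, single$value)
  expect_equal(acc1$stderr, single$stderr)

  nulls <- replicate(40, fe_estimate(0, 0, "bar"), simplify = FALSE)
  expect_equal(accumulate(nulls)$value, 0)
  expect_equal(accumulate(nulls)$stderr, 0)

  # permutation invariance of the accumulated uncertainty
  set.seed(12)
  ests <- lapply(1:6, function(i) fe_estimate(rnorm(1), runif(1), "bar"))
  perm <- sample(ests)
  expect_equal(accumulate(ests)$stderr, accumulate(perm)$stderr)
  expect_equal(accumulate(ests)$value, accumulate(perm)$value)
  expect_error(accumulate(list()), "no estimates")
})
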