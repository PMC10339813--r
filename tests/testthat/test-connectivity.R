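test_that("analytic signal recovers the Hilbert pair of a cosine", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  f <- 16
  x <- cos(2 * pi * f * t)
  a <- analytic_signal(x)
  mid <- seq(round(0.1 * length(x)), round(0.9 * length(x)))
  expect_lt(max(abs(a$hilbert[mid] - sin(2 * pi * f * t[mid]))), 1e-3)
  expect_lt(max(abs(a$amplitude[mid] - 1)), 1e-3)
  # modulus identity A^2 = x^2 + H[x]^2
  expect_lt(max(abs(a$amplitude^2 - (a$x^2 + a$hilbert^2))), 1e-8)
  expect_true(all(a$phase > -pi & a$phase <= pi))
})

test_that("unwrapped phase slope matches the oscillation frequency", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  f <- 11
  ph <- analytic_signal(cos(2 * pi * f * t))$phase
  # unwrap and fit a line on the central 80%
  un <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi)) -
    2 * pi * cumsum(c(0, diff(ph) > pi))
  mid <- seq(round(0.1 * length(un)), round(0.9 * length(un)))
  slope <- coef(lm(un[mid] ~ mid))[2]
  expect_equal(unname(slope), 2 * pi * f / fs, tolerance = 1e-3)
})

test_that("constant input is the documented degenerate case", {
  a <- analytic_signal(rep(3.2, 64))
  expect_equal(a$amplitude, rep(0, 64))
  expect_equal(a$phase, rep(0, 64))
  expect_error(analytic_signal(1:4), "8 samples")
})

test_that("PSI is 1 for self and constant-offset pairs, symmetric, length-checked", {
  t <- seq(0, 2, by = 1 / 256)
  x <- cos(2 * pi * 10 * t)
  y <- cos(2 * pi * 10 * t - pi / 3)
  expect_equal(psi(x, x), 1, tolerance = 1e-12)
  expect_gte(psi(x, y), 0.999)
  set.seed(5)
  a <- rnorm(512); b <- rnorm(512)
  expect_equal(psi(a, b), psi(b, a), tolerance = 1e-12)
  expect_error(psi(a, b[-1]), "equal length")
})

test_that("PSI is invariant to positive amplitude scaling", {
  set.seed(6)
  x <- bandpass(rnorm(2048), 256, "alpha")$samples
  y <- bandpass(rnorm(2048), 256, "alpha")$samples
  expect_equal(psi(3.7 * x, y), psi(x, y), tolerance = 1e-10)
  expect_equal(psi(x, 0.01 * y), psi(x, y), tolerance = 1e-10)
})

test_that("independent alpha-band noise has low PSI (Rayleigh-scale baseline)", {
  # ~4 Hz bandwidth x 10 s gives ~40-50 independent phase patches, so the
  # no-coupling PSI baseline is ~0.12 in the mean with 95th percentile ~0.25
  # (verified against a closed-form Rayleigh oracle and an independent
  # scipy implementation); drifting-phase sinusoids sit strictly between
  # that baseline and perfect locking.
  fs <- 1024
  vals <- psinetfs:::with_seed(11, replicate(40, {
    x <- bandpass(rnorm(10240), fs, "alpha")$samples
    y <- bandpass(rnorm(10240), fs, "alpha")$samples
    psi(x, y)
  }))
  expect_lt(mean(vals), 0.2)
  expect_lt(quantile(vals, 0.95), 0.32)

  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  drift <- cos(2 * pi * 10 * t + 0.8 * sin(2 * pi * 0.05 * t))
  ref <- cos(2 * pi * 10 * t)
  p <- psi(ref, drift)
  expect_lt(p, 1 - 1e-4)
  expect_gt(p, quantile(vals, 0.95))
})

test_that("connectivity matrix is symmetric, zero-diagonal, and matches pairwise psi()", {
  set.seed(8)
  fs <- 256
  ep <- list(samples = matrix(rnorm(4 * fs * 4), 4), fs = fs)
  be <- bandpass(ep, band = "beta")
  cm <- connectivity_matrix(be)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(diag(cm), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(cm >= 0 & cm <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cm[i, j], psi(be$samples[i, ], be$samples[j, ]),
                 tolerance = 1e-10)
  }
  # identical channels are perfectly synchronous
  same <- connectivity_matrix(list(samples = be$samples[c(1, 1, 1), ]))
  expect_equal(unclass(same), matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PLI discards zero-lag coupling but sees lagged coupling", {
  t <- seq(0, 4 - 1 / 256, by = 1 / 256)
  x <- cos(2 * pi * 10 * t)
  expect_lt(pli(x, 2 * x), 0.1)          # zero-lag: signs average out
  expect_gt(pli(x, cos(2 * pi * 10 * t - pi / 4)), 0.9)
  set.seed(9)
  ep <- list(samples = matrix(rnorm(3 * 1024), 3), fs = 256)
  be <- bandpass(ep, band = "alpha")
  cmp <- connectivity_matrix(be, method = "pli")
  expect_equal(cmp[2, 3], pli(be$samples[2, ], be$samples[3, ]),
               tolerance = 1e-10)
})

test_that("binarization uses a strict threshold and validates tau", {
  cm <- matrix(c(0, 0.31, 0.30, 0.31, 0, 0.29, 0.30, 0.29, 0), 3)
  net <- binarize(cm, tau = 0.3)
  expect_equal(net$adjacency[1, 2], 1)
  expect_equal(net$adjacency[1, 3], 0)   # exactly tau -> no edge
  expect_equal(net$adjacency[2, 3], 0)
  all_pos <- matrix(0.2, 4, 4); diag(all_pos) <- 0
  expect_equal(sum(binarize(all_pos, 0)$adjacency), 12)  # complete graph
  expect_error(binarize(cm, tau = 1), "tau")
  expect_error(binarize(cm, tau = -0.1), "tau")
})

test_that("edge count is monotone non-increasing in tau", {
  set.seed(10)
  cm <- matrix(0, 6, 6)
  cm[upper.tri(cm)] <- runif(15)
  cm <- cm + t(cm)
  taus <- seq(0, 0.9, by = 0.1)
  counts <- vapply(taus, function(tt) sum(binarize(cm, tt)$adjacency),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("matrix CSV and edge-list writers round-trip", {
  set.seed(12)
  cm <- matrix(0, 3, 3)
  cm[upper.tri(cm)] <- round(runif(3), 6)
  cm <- cm + t(cm)
  dimnames(cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(cm, path)
  expect_equal(read_matrix_csv(path), cm, tolerance = 1e-9)
  net <- binarize(cm, tau = 0.4)
  el <- edge_list(net)
  expect_equal(nrow(el), sum(net$adjacency) / 2)
})
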