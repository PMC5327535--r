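test_that("gape size follows the length-mass allometry", {
  expect_equal(gape_size(0), 0)
  expect_equal(gape_size(260), 0.01 * 10^(-5.289) * 260^3.063)
  expect_equal(gape_size(260), 1.282, tolerance = 1e-3)
  expect_equal(gape_size(97), 0.0626, tolerance = 1e-2)
  expect_error(gape_size(-1), "nonnegative")
})

test_that("raker spacing responds to alleles and body mass and stays bounded", {
  tp <- tp_default()
  # all raker alleles -> minimum spacing at any mass
  for (w in c(tp$wMn, 1, 50, tp$wMx)) {
    expect_equal(raker_spacing(16, 8, w, tp), 0.001)
  }
  # no raker alleles at maximum mass -> maximum spacing (both modes)
  expect_equal(raker_spacing(0, 8, tp$wMx, tp), 0.02)
  tpr <- tp_default(eb_mode = "reciprocal")
  expect_equal(raker_spacing(0, 8, tpr$wMx, tpr), 0.02)
  # half the alleles at maximum mass: l = 0.001 + 0.019 * 0.5
  expect_equal(raker_spacing(8, 8, tp$wMx, tp), 0.0105)
  expect_error(raker_spacing(17, 8, 1, tp), "nml")
  expect_warning(raker_spacing(0, 8, 2 * tp$wMx, tp), "clamping")
  # monotonicity: nonincreasing in nml, nondecreasing in w, for both modes
  for (mode in c("direct", "reciprocal")) {
    tpm <- tp_default(eb_mode = mode, eb = 0.125)
    l_by_nml <- raker_spacing(0:16, 8, rep(10, 17), tpm)
    expect_true(all(diff(l_by_nml) <= 0))
    ws <- seq(tpm$wMn, tpm$wMx, length.out = 40)
    l_by_w <- raker_spacing(rep(2, 40), 8, ws, tpm)
    expect_true(all(diff(l_by_w) >= -1e-15))
    expect_true(all(l_by_w >= tpm$lMn - 1e-15 & l_by_w <= tpm$lMx + 1e-15))
  }
  # eb = 0 direct mode: point benefit exactly at minimum mass
  tp0 <- tp_default(eb = 0, eb_mode = "direct")
  expect_equal(raker_spacing(0, 8, tp0$wMn, tp0), tp0$lMn)
  expect_equal(raker_spacing(0, 8, tp0$wMn + 1e-6, tp0), tp0$lMx)
  # eb = 0 reciprocal mode: cliff at maximum mass instead
  tp0r <- tp_default(eb = 0, eb_mode = "reciprocal")
  expect_equal(raker_spacing(0, 8, tp0r$wMx, tp0r), tp0r$lMx)
  expect_equal(raker_spacing(0, 8, tp0r$wMx - 1e-6, tp0r), tp0r$lMn)
})

test_that("clog penalty matches its closed form and monotonicities", {
  expect_equal(clog_penalty(0.0005, 0.001, 0.5), 1) # k <= l
  expect_equal(clog_penalty(5, 0.001, 0), 1)        # lp = 0
  expect_equal(clog_penalty(0.01, 0.001, 0.5), sqrt(0.1))
  expect_equal(clog_penalty(0.01, 0.001, 0.5), 0.3162, tolerance = 1e-4)
  ks <- seq(0.002, 1, length.out = 50)
  expect_true(all(diff(clog_penalty(ks, 0.001, 0.5)) <= 0))
  lps <- seq(0, 2, length.out = 20)
  pen <- vapply(lps, function(lp) clog_penalty(0.01, 0.001, lp), numeric(1))
  expect_true(all(diff(pen) <= 0))
})

test_that("efficiency normalizer equals the printed quotient form", {
  # quotient form, written independently from the implementation
  quotient_cF <- function(u, l, fs) {
    tau <- (log10(u) + log10(l)) / 2
    (2 + exp(-fs * (tau - log10(l))) + exp(-fs * (tau - log10(u)))) /
      exp(-fs * (tau - log10(l)))
  }
  set.seed(3)
  for (i in 1:25) {
    l <- 10^runif(1, -3.5, -1.5)
    u <- l * 10^runif(1, 0.1, 2.5)
    fs <- sample(c(5, 10, 20), 1)
    expect_equal(efficiency_normalizer(u, l, fs), quotient_cF(u, l, fs),
                 tolerance = 1e-12)
  }
  expect_equal(efficiency_normalizer(0.1, 0.001, 10), (1 + exp(10))^2)
  expect_equal(efficiency_normalizer(0.1, 0.001, 10), 4.852e8,
               tolerance = 1e-3)
  # fs*d -> 0 limit gives 4
  expect_equal(efficiency_normalizer(1.0001e-3, 1e-3, 1e-4), 4,
               tolerance = 1e-4)
  expect_error(efficiency_normalizer(0.001, 0.001, 10), "u > l")
})

test_that("foraging efficiency has the documented shape", {
  # degenerate traits: zero everywhere
  expect_equal(foraging_efficiency(c(0.001, 0.01, 1), 0.001, 0.01, 10, 0),
               c(0, 0, 0))
  # with the clog penalty off, the maximum is 1 at the geometric mean
  u <- 0.1; l <- 0.001
  expect_equal(foraging_efficiency(sqrt(u * l), u, l, 10, 0), 1)
  # boundary value: fe(k = u) ~ 0.5
  expect_equal(foraging_efficiency(u, u, l, 10, 0), 0.5, tolerance = 1e-3)
  expect_equal(foraging_efficiency(l, u, l, 10, 0), 0.5, tolerance = 1e-3)
  # fe in [0, 1] on a dense grid across parameter sets; argmax at sqrt(u*l)
  ks <- 10^seq(-4, 1, length.out = 800)
  set.seed(17)
  for (i in 1:20) {
    l <- 10^runif(1, -3.2, -1.8)
    u <- l * 10^runif(1, 0.3, 2.8)
    fs <- sample(c(10, 20), 1)
    lp <- sample(c(0, 0.5, 1), 1)
    fe <- foraging_efficiency(ks, u, l, fs, lp)
    expect_true(all(fe >= 0 & fe <= 1 + 1e-9))
    if (lp == 0) {
      k_hat <- ks[which.max(fe)]
      step <- 5 / 799
      expect_lt(abs(log10(k_hat) - log10(sqrt(u * l))), 2 * step)
    }
  }
})

test_that("handling multiplier satisfies the 50-percent constraint", {
  h <- handling_params(cH = 0.1, bf = 1)
  ra <- 1.58e8
  expect_equal(handling_multiplier(0.1 * ra, ra, h), 0.5)
  expect_equal(handling_multiplier(ra, ra, h), 1 / 1.1)
  expect_equal(handling_multiplier(0, ra, h), 0)
  expect_equal(handling_multiplier(c(10, 1e6), ra, handling_params(cH = 0)),
               c(1, 1))
  expect_error(handling_multiplier(10, -1, h), "positive")
  Ns <- seq(1, 2 * ra, length.out = 50)
  expect_true(all(diff(handling_multiplier(Ns, ra, h)) >= 0))
  cHs <- c(0.01, 0.05, 0.1, 0.25, 1)
  m <- vapply(cHs, function(cH)
    handling_multiplier(0.3 * ra, ra, handling_params(cH = cH)), numeric(1))
  expect_true(all(diff(m) <= 0))
})

test_that("allocation weights are normalised time fractions", {
  # single class with a nonzero score takes all the time
  w <- allocation_weights(u = 0.1, l = 0.001, k = c(0.01, 0.5, 5),
                          N = c(1e6, 0, 0), M = c(1, 1, 1), fs = 10, lp = 0)
  expect_equal(w, c(1, 0, 0))
  # two identical classes split evenly
  w2 <- allocation_weights(0.1, 0.001, c(0.01, 0.01), c(1e6, 1e6), c(1, 1),
                           10, 0)
  expect_equal(w2, c(0.5, 0.5))
  # all-zero scores fall back to uniform
  w3 <- allocation_weights(0.1, 0.001, c(0.01, 0.02), c(0, 0), c(1, 1),
                           10, 0)
  expect_equal(w3, c(0.5, 0.5))
  # normalisation for arbitrary inputs
  set.seed(23)
  for (i in 1:20) {
    k <- 10^runif(6, -3, 0.5)
    N <- runif(6, 0, 1e7)
    w <- allocation_weights(0.3, 0.002, k, N, runif(6), 10, 0.5, q = 2)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("the vectorised allocation matrix agrees with the scalar route", {
  set.seed(29)
  k <- 10^seq(-2.3, 0.6, length.out = 12)
  N <- runif(12, 1e4, 1e7)
  M <- rep(runif(3), each = 4)
  us <- c(0.05, 0.3, 1.2, 0.0005) # last one degenerate (u <= l)
  ls <- c(0.001, 0.004, 0.018, 0.001)
  am <- alewifesim:::allocation_matrix(us, ls, k, N, M, fs = 10, lp = 0.5,
                                       q = 10)
  for (i in seq_along(us)) {
    fe_scalar <- foraging_efficiency(k, us[i], ls[i], 10, 0.5)
    expect_equal(am$fe[i, ], fe_scalar, tolerance = 1e-12)
    w_scalar <- allocation_weights(us[i], ls[i], k, N, M, 10, 0.5, q = 10)
    expect_equal(am$w[i, ], w_scalar, tolerance = 1e-10)
  }
})
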