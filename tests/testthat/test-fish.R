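test_that("length-mass conversion matches the printed allometry", {
  expect_equal(length_to_mass(0), 0)
  expect_equal(length_to_mass(260), 10^(-5.289) * 260^3.063)
  expect_equal(length_to_mass(260), 128.2, tolerance = 1e-3)
  expect_equal(length_to_mass(97), 6.26, tolerance = 1e-3)
  expect_error(length_to_mass(-5), "nonnegative")
})

test_that("asymptotic length maps the growth genotype linearly at default bA", {
  gp <- growth_params()
  expect_equal(asymptotic_length(1, gp), 273.684)
  expect_equal(asymptotic_length(0, gp), 134.3)
  expect_equal(asymptotic_length(0.5, gp), (134.3 + 273.684) / 2)
  expect_equal(asymptotic_length(0.5, gp), 203.99, tolerance = 1e-4)
  # larger bA weakens each allele: same p, smaller L-infinity
  gp2 <- growth_params(bA = 0.5)
  expect_lt(asymptotic_length(0.5, gp2), asymptotic_length(0.5, gp))
  expect_equal(asymptotic_length(0.5, gp2),
               134.3 + (273.684 - 134.3) * 0.25)
  # saturation at gamma = 1
  gp3 <- growth_params(bA = 0.125)
  expect_equal(asymptotic_length(0.6, gp3), 273.684)
})

test_that("deterministic growth reproduces the calibration anchors", {
  gp <- growth_params(bcv = 0)
  # largest genotype from bMn to age 5: ~260 mm (anadromous adult anchor)
  bO <- gp$bMn
  for (t in 1:5) bO <- annual_growth(bO, asymptotic_length(1, gp), gp)
  expect_equal(bO, 260, tolerance = 2 / 260) # +-2 mm
  # smallest genotype at age 2: ~95 mm, a little under the 97 mm landlocked
  bO <- gp$bMn
  for (t in 1:2) bO <- annual_growth(bO, asymptotic_length(0, gp), gp)
  expect_equal(bO, 95, tolerance = 5 / 95) # +-5 mm
  # no growth at the asymptote; never exceeds it
  expect_equal(annual_growth(200, 200, gp), 200)
  expect_lte(annual_growth(199.99, 200, gp), 200)
})

test_that("growth noise is lognormal with unit mean and the configured cv", {
  gp <- growth_params(bcv = 0.2)
  set.seed(19)
  n <- 2e4
  increments <- annual_growth(rep(100, n), rep(200, n), gp) - 100
  det <- (200 - 100) * (1 - exp(-gp$K))
  eps <- increments / det
  expect_lt(abs(mean(eps) - 1), 3 * 0.2 / sqrt(n))
  expect_lt(abs(stats::sd(eps) - 0.2), 0.01)
})

test_that("Beverton-Holt survival saturates in intake", {
  dp <- demography_params(sMx = 0.95, cm = 0.2)
  w <- 50
  demand <- 0.2 * w^0.75
  expect_equal(survival_probability(0, w, dp), 0)
  expect_equal(survival_probability(demand, w, dp), 0.95 / 2)
  expect_equal(survival_probability(3 * demand, w, dp), 0.75 * 0.95)
  expect_equal(survival_probability(1e9, w, dp), 0.95, tolerance = 1e-6)
  expect_error(survival_probability(-1, w, dp), "nonnegative")
  expect_error(survival_probability(1, 0, dp), "positive")
})

test_that("maturation age delays with growth alleles, round-half-up", {
  dp <- demography_params()
  expect_identical(maturation_age(0, dp), 2L)
  expect_identical(maturation_age(1, dp), 5L)
  expect_identical(maturation_age(0.5, dp), 4L) # 2 + round-half-up(1.5)
  expect_identical(maturation_age(1 / 3, dp), 3L)
})

test_that("fecundity scales linearly with body mass", {
  dp <- demography_params(fec_max = 10)
  wMx <- length_to_mass(273.684)
  expect_equal(fecundity_mean(wMx, wMx, dp), 10)
  expect_equal(fecundity_mean(wMx / 2, wMx, dp), 5)
  ws <- seq(1, wMx, length.out = 30)
  expect_true(all(diff(fecundity_mean(ws, wMx, dp)) > 0))
})

test_that("intake partition balances the mass ledger", {
  # no removal -> zero intake
  alloc <- matrix(c(0.5, 0.5, 0.25, 0.75), 2, byrow = TRUE)
  fe <- matrix(c(0.5, 0.1, 0.2, 0.9), 2, byrow = TRUE)
  expect_equal(partition_intake(alloc, fe, c(0, 0)), c(0, 0))
  # single fish receives everything
  expect_equal(partition_intake(alloc[1, , drop = FALSE],
                                fe[1, , drop = FALSE], c(3, 7)), 10)
  # identical fish split evenly
  two <- partition_intake(alloc[c(1, 1), ], fe[c(1, 1), ], c(3, 7))
  expect_equal(two[1], two[2], tolerance = 1e-12)
  # ledger: total intake equals total removed mass, arbitrary inputs
  set.seed(43)
  for (i in 1:10) {
    nf <- sample(2:30, 1); nc <- sample(2:40, 1)
    a <- matrix(runif(nf * nc), nf); a <- a / rowSums(a)
    f <- matrix(runif(nf * nc), nf)
    r <- runif(nc, 0, 100)
    A <- partition_intake(a, f, r)
    expect_equal(sum(A), sum(r), tolerance = 1e-9)
    expect_true(all(A >= 0))
  }
  # zero-efficiency column with removal falls back to allocation shares
  a0 <- matrix(c(1, 0.5, 0, 0.5), 2)
  f0 <- matrix(0, 2, 2)
  A0 <- partition_intake(a0, f0, c(4, 6))
  expect_equal(sum(A0), 10, tolerance = 1e-12)
})

test_that("survival, aging and the age cap behave", {
  dp <- demography_params(max_age = 10)
  pop <- make_test_population(rep(100, 20), age = rep(4L, 20))
  kept <- annual_survival_and_aging(pop, rep(1, 20), dp)
  expect_identical(fish_count(kept), 20L)
  expect_true(all(kept$age == 5L))
  gone <- annual_survival_and_aging(pop, rep(0, 20), dp)
  expect_identical(fish_count(gone), 0L)
  old <- make_test_population(rep(100, 5), age = rep(10L, 5))
  expect_identical(fish_count(annual_survival_and_aging(old, rep(1, 5), dp)),
                   0L)
  expect_error(annual_survival_and_aging(pop, rep(1.5, 20), dp), "\\[0, 1\\]")
  set.seed(47)
  n <- 1e4
  big <- make_test_population(rep(100, n), age = rep(1L, n))
  surv <- fish_count(annual_survival_and_aging(big, rep(0.5, n), dp))
  expect_lt(abs(surv - 5000), 3 * sqrt(n * 0.25))
})

test_that("reproduction: mating, inheritance, and sex ratio", {
  gp <- growth_params(); dp <- demography_params()
  wMx <- length_to_mass(gp$bMx)
  # no mature females -> empty
  males <- make_test_population(rep(200, 10), female = rep(FALSE, 10))
  out <- reproduce(males, gp, dp, 0, wMx)
  expect_identical(fish_count(out$offspring), 0L)
  # mature females but no males -> warning, empty
  females <- make_test_population(rep(200, 10), female = rep(TRUE, 10))
  expect_warning(out2 <- reproduce(females, gp, dp, 0, wMx), "no mature males")
  expect_identical(fish_count(out2$offspring), 0L)
  # monomorphic parents, mu = 0: offspring genotypes identical to parents
  set.seed(53)
  pop <- make_test_population(rep(250, 40))
  out3 <- reproduce(pop, gp, dp, 0, wMx)
  off <- out3$offspring
  expect_gt(fish_count(off), 0)
  expect_true(all(off$gA1 == 1L) && all(off$gA2 == 1L))
  expect_true(all(off$gB1 == 0L) && all(off$gB2 == 0L))
  expect_true(all(off$age == 0L))
  expect_true(all(off$bO == gp$bMn))
  # sex ratio and allele transmission at scale
  set.seed(59)
  n <- 600
  pop2 <- make_test_population(
    rep(250, n),
    gB = list(alewifesim:::sample_haplotype_matrix(n, 8, 0.3),
              alewifesim:::sample_haplotype_matrix(n, 8, 0.3)))
  p_parent <- population_allele_frequency(pop2, "raker")
  out4 <- reproduce(pop2, gp, dp, 0, wMx)
  noff <- fish_count(out4$offspring)
  expect_gt(noff, 2000)
  expect_lt(abs(mean(out4$offspring$female) - 0.5), 3 * sqrt(0.25 / noff))
  p_off <- population_allele_frequency(out4$offspring, "raker")
  se <- sqrt(p_parent * (1 - p_parent) / (16 * noff)) +
    sqrt(p_parent * (1 - p_parent) / (16 * n))
  expect_lt(abs(p_off - p_parent), 3 * se)
})

test_that("raker alleles strictly improve efficiency on the smallest prey", {
  # two fish identical except for the raker genotype, facing prey smaller
  # than both gapes: the high-raker fish is strictly better on the smallest
  # class (selection wiring of the spacing trade-off)
  tp <- tp_default()
  bO <- 150
  w <- length_to_mass(bO)
  u <- gape_size(bO)
  l_low <- raker_spacing(0, 8, w, tp)
  l_high <- raker_spacing(16, 8, w, tp)
  k_small <- 0.002
  expect_lt(k_small, u)
  fe_low <- foraging_efficiency(k_small, u, l_low, tp$fs, tp$lp)
  fe_high <- foraging_efficiency(k_small, u, l_high, tp$fs, tp$lp)
  expect_gt(fe_high, fe_low)
})
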