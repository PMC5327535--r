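# Individual fish demography: genotype-dependent von Bertalanffy growth,
# length-mass allometry, prey intake, Beverton-Holt survival, maturation and
# sexual reproduction.

#' Length-to-mass conversion for alewives
#'
#' `w = 10^-5.289 * bO^3.063` with `bO` in mm and `w` in g.
#'
#' @param bO Body length mm (vectorised).
#' @return Body mass g.
#' @export
length_to_mass <- function(bO) {
  if (any(bO < 0)) stop("body length must be nonnegative")
  10^(-5.289) * bO^3.063
}

#' Growth parameters
#'
#' @param bMx Asymptotic length of the all-growth-allele genotype (mm,
#'   default 273.684): calibrated so 5-year-old females of the largest
#'   genotype average about 260 mm, the mean adult length of anadromous
#'   populations.
#' @param bMn Length at age 0 (mm, default 5).
#' @param bLo Asymptotic length of the no-growth-allele genotype (mm,
#'   default 134.3): calibrated so the smallest genotype reaches about 95 mm
#'   at age 2, slightly under the 97 mm mean adult length of landlocked
#'   populations.
#' @param K von Bertalanffy rate (1/yr, default 0.5955), solved jointly with
#'   `bLo` from the two length anchors above.
#' @param bA Per-allele effect control (default 0.25): the genetic factor is
#'   `min(1, p / (4 * bA))`, so larger `bA` weakens each growth allele and at
#'   the default the factor is the allele fraction itself.
#' @param bcv Coefficient of variation of the annual growth increment
#'   (default 0.01; sensitivity grid 0.001, 0.01, 0.1, 0.2).
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(bMx = 273.684, bMn = 5, bLo = 134.3, K = 0.5955,
                          bA = 0.25, bcv = 0.01) {
  stopifnot(bMn < bLo, bLo < bMx, K > 0, bA > 0, bcv >= 0)
  structure(list(bMx = bMx, bMn = bMn, bLo = bLo, K = K, bA = bA, bcv = bcv),
            class = "growth_params")
}

#' Demography parameters
#'
#' @param sMx Maximum annual survival probability (default 0.95).
#' @param cm Metabolic scale, g prey per yr per g^em of fish (default 0.2,
#'   calibrated by [calibrate_demography()] so both default communities
#'   support a persistent fish population of order 1e3-1e4; see the methods
#'   vignette).
#' @param em Metabolic exponent (0.75, the Kleiber power law).
#' @param age_mat_min Maturation age of the smallest genotype (2 yr).
#' @param age_mat_span Additional years of delay for the largest genotype (3,
#'   so the all-growth-allele genotype matures at 5).
#' @param fec_max Mean offspring of a female at maximum body mass
#'   (default 10, calibrated).
#' @param max_age Maximum age in years (10); older fish are removed.
#' @param pop_cap Optional hard cap on population size (default `Inf`).
#' @return A list of class `demography_params`.
#' @export
demography_params <- function(sMx = 0.95, cm = 0.2, em = 0.75,
                              age_mat_min = 2L, age_mat_span = 3L,
                              fec_max = 10, max_age = 10L, pop_cap = Inf) {
  stopifnot(sMx > 0, sMx <= 1, cm > 0, em > 0, fec_max > 0,
            max_age >= age_mat_min)
  structure(list(sMx = sMx, cm = cm, em = em,
                 age_mat_min = as.integer(age_mat_min),
                 age_mat_span = as.integer(age_mat_span),
                 fec_max = fec_max, max_age = as.integer(max_age),
                 pop_cap = pop_cap),
            class = "demography_params")
}

#' Genotype-dependent asymptotic length
#'
#' `Linf = bLo + (bMx - bLo) * min(1, p / (4 * bA))` with `p` the fraction of
#' growth-facilitating alleles. At the default `bA = 0.25` the genetic factor
#' equals `p`; larger `bA` shrinks each allele's effect.
#'
#' @param p Growth allele fraction in \[0, 1\] (vectorised).
#' @param gp A [growth_params()].
#' @return Asymptotic length mm.
#' @export
asymptotic_length <- function(p, gp) {
  gamma <- pmin(1, p / (4 * gp$bA))
  gp$bLo + (gp$bMx - gp$bLo) * gamma
}

#' One year of stochastic von Bertalanffy growth
#'
#' The deterministic increment is `(Linf - bO) * (1 - exp(-K))`; the realised
#' increment multiplies it by a lognormal noise with mean 1 and coefficient of
#' variation `bcv`. Length never exceeds `Linf`.
#'
#' @param bO Current lengths mm (vectorised).
#' @param Linf Asymptotic lengths mm (recycled).
#' @param gp A [growth_params()].
#' @return New lengths mm.
#' @export
annual_growth <- function(bO, Linf, gp) {
  delta <- pmax(Linf - bO, 0) * (1 - exp(-gp$K))
  if (gp$bcv > 0) {
    sdlog <- sqrt(log(1 + gp$bcv^2))
    eps <- rlnorm(length(bO), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    delta <- delta * eps
  }
  pmin(bO + delta, Linf)
}

#' Beverton-Holt survival from prey intake
#'
#' `s = sMx * rho / (1 + rho)` with `rho = A / (cm * w^em)` the ratio of the
#' year's prey-mass intake to metabolic demand. Saturates at `sMx` when prey
#' is abundant and vanishes without intake.
#'
#' @param A Prey mass consumed this year, g (vectorised).
#' @param w Body mass g.
#' @param dp A [demography_params()].
#' @return Survival probability in \[0, sMx\].
#' @export
survival_probability <- function(A, w, dp) {
  if (any(A < 0)) stop("intake must be nonnegative")
  if (any(w <= 0)) stop("mass must be positive")
  rho <- A / (dp$cm * w^dp$em)
  dp$sMx * rho / (1 + rho)
}

#' Genotype-dependent maturation age
#'
#' Growth-facilitating alleles delay maturation:
#' `age = age_mat_min + round(age_mat_span * p)` with round-half-up, so the
#' smallest genotype matures at 2 (landlocked) and the largest at 5
#' (anadromous).
#'
#' @param p Growth allele fraction (vectorised).
#' @param dp A [demography_params()].
#' @return Integer maturation ages.
#' @export
maturation_age <- function(p, dp) {
  dp$age_mat_min + as.integer(floor(dp$age_mat_span * p + 0.5))
}

#' Mean fecundity as a function of body mass
#'
#' Mean offspring per female scales linearly with body mass:
#' `fec_max * w / wMx`.
#'
#' @param w Female body mass g (vectorised).
#' @param wMx Body mass of the largest genotype at its asymptotic length.
#' @param dp A [demography_params()].
#' @return Mean offspring count.
#' @export
fecundity_mean <- function(w, wMx, dp) {
  if (any(w <= 0)) stop("mass must be positive")
  dp$fec_max * w / wMx
}

# ---- population container ---------------------------------------------------
# A fish population is a list of parallel vectors plus four genotype matrices
# (two haplotypes x two traits). Rows are individuals.

new_fish_population <- function(female, age, bO, gA1, gA2, gB1, gB2,
                                next_id = 1L) {
  n <- length(female)
  structure(list(id = seq.int(next_id, length.out = n),
                 female = female, age = as.integer(age), bO = bO,
                 gA1 = gA1, gA2 = gA2, gB1 = gB1, gB2 = gB2,
                 mature = rep(FALSE, n), next_id = next_id + n),
            class = "fish_population")
}

#' Number of fish in a population
#' @param pop A fish population.
#' @return Integer count.
#' @export
fish_count <- function(pop) length(pop$bO)

empty_fish_population <- function(nllA, nllB) {
  new_fish_population(logical(0), integer(0), numeric(0),
                      matrix(0L, 0, nllA), matrix(0L, 0, nllA),
                      matrix(0L, 0, nllB), matrix(0L, 0, nllB))
}

subset_population <- function(pop, keep) {
  pop$id <- pop$id[keep]
  pop$female <- pop$female[keep]
  pop$age <- pop$age[keep]
  pop$bO <- pop$bO[keep]
  pop$mature <- pop$mature[keep]
  pop$gA1 <- pop$gA1[keep, , drop = FALSE]
  pop$gA2 <- pop$gA2[keep, , drop = FALSE]
  pop$gB1 <- pop$gB1[keep, , drop = FALSE]
  pop$gB2 <- pop$gB2[keep, , drop = FALSE]
  pop
}

# growth allele fraction per fish
growth_fraction <- function(pop) {
  (rowSums(pop$gA1) + rowSums(pop$gA2)) / (NP * ncol(pop$gA1))
}

# raker allele count per fish
raker_allele_count <- function(pop) {
  rowSums(pop$gB1) + rowSums(pop$gB2)
}

#' Partition fish-removed prey mass into per-fish intake
#'
#' The prey update attributes to fish an abundance decline per size class
#' (the removal ledger of [step_community()]). The corresponding prey mass
#' `removed * k` is divided among fish in proportion to
#' `allocation * efficiency` on each class, so the ledger balances exactly:
#' the summed per-fish intake equals the total fish-attributable prey-mass
#' loss. If every fish has zero efficiency on a class that nonetheless lost
#' abundance, the mass is shared by allocation alone.
#'
#' @param alloc `n_fish` x `n_classes` allocation weights (rows sum to 1).
#' @param fe `n_fish` x `n_classes` foraging efficiencies.
#' @param removed_mass Vector of prey mass removed per class (g).
#' @return Per-fish intake `A` in g.
#' @export
partition_intake <- function(alloc, fe, removed_mass) {
  if (length(removed_mass) != ncol(alloc)) stop("class dimension mismatch")
  share <- alloc * fe
  col <- colSums(share)
  zero <- col <= 0
  if (any(zero & removed_mass > 0)) {
    share[, zero] <- alloc[, zero, drop = FALSE]
    col <- colSums(share)
  }
  col[col <= 0] <- 1 # classes with no removal and no weight: contribute 0
  as.numeric(share %*% (removed_mass / col))
}

#' Stochastic survival, aging and the maximum-age cull
#'
#' Each fish survives independently with its own probability, survivors age
#' one year, and fish beyond `max_age` are removed deterministically.
#'
#' @param pop A fish population.
#' @param s Per-fish survival probabilities.
#' @param dp A [demography_params()].
#' @return The surviving, aged population.
#' @export
annual_survival_and_aging <- function(pop, s, dp) {
  if (any(s < 0 | s > 1)) stop("survival probabilities must lie in [0, 1]")
  n <- fish_count(pop)
  keep <- runif(n) < s
  pop <- subset_population(pop, keep)
  pop$age <- pop$age + 1L
  subset_population(pop, pop$age <= dp$max_age)
}

#' Annual reproduction
#'
#' Each mature female draws one mature male uniformly with replacement
#' (promiscuous mating) and produces `Poisson(fecundity_mean(w))` offspring.
#' Every offspring receives one mutated gamete per trait from each parent
#' (unlinked loci, free recombination), is female with probability 0.5, and
#' enters the population at age 0 and length `bMn`.
#'
#' @param pop A fish population with up-to-date `mature` flags.
#' @param gp A [growth_params()].
#' @param dp A [demography_params()].
#' @param mu Per-allele mutation rate.
#' @param wMx Mass of the largest genotype at asymptote (fecundity scale).
#' @return List: `offspring` (a fish population, possibly empty) and
#'   `n_mothers`.
#' @export
reproduce <- function(pop, gp, dp, mu, wMx) {
  females <- which(pop$female & pop$mature)
  males <- which(!pop$female & pop$mature)
  nllA <- ncol(pop$gA1)
  nllB <- ncol(pop$gB1)
  if (length(females) == 0L) {
    return(list(offspring = empty_fish_population(nllA, nllB),
                n_mothers = 0L))
  }
  if (length(males) == 0L) {
    warning("mature females present but no mature males; no offspring")
    return(list(offspring = empty_fish_population(nllA, nllB),
                n_mothers = 0L))
  }
  w_f <- length_to_mass(pop$bO[females])
  n_off <- rpois(length(females), fecundity_mean(w_f, wMx, dp))
  mothers <- rep(females, n_off)
  total <- length(mothers)
  if (total == 0L) {
    return(list(offspring = empty_fish_population(nllA, nllB),
                n_mothers = length(females)))
  }
  fathers <- sample(males, total, replace = TRUE)
  off <- new_fish_population(
    female = runif(total) < 0.5,
    age = rep(0L, total),
    bO = rep(gp$bMn, total),
    gA1 = mutate_matrix(make_gametes_matrix(pop$gA1, pop$gA2, mothers), mu),
    gA2 = mutate_matrix(make_gametes_matrix(pop$gA1, pop$gA2, fathers), mu),
    gB1 = mutate_matrix(make_gametes_matrix(pop$gB1, pop$gB2, mothers), mu),
    gB2 = mutate_matrix(make_gametes_matrix(pop$gB1, pop$gB2, fathers), mu),
    next_id = pop$next_id)
  list(offspring = off, n_mothers = length(females))
}

# append offspring to a population
bind_populations <- function(pop, off) {
  if (fish_count(off) == 0L) return(pop)
  pop$id <- c(pop$id, off$id)
  pop$female <- c(pop$female, off$female)
  pop$age <- c(pop$age, off$age)
  pop$bO <- c(pop$bO, off$bO)
  pop$mature <- c(pop$mature, off$mature)
  pop$gA1 <- rbind(pop$gA1, off$gA1)
  pop$gA2 <- rbind(pop$gA2, off$gA2)
  pop$gB1 <- rbind(pop$gB1, off$gB1)
  pop$gB2 <- rbind(pop$gB2, off$gB2)
  pop$next_id <- max(pop$next_id, off$next_id)
  pop
}
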