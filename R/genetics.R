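#' @importFrom stats dnorm rbinom rpois runif rlnorm
#' @importFrom data.table data.table as.data.table rbindlist fwrite fread :=
NULL

# let data.table's non-standard evaluation work inside this package
.datatable.aware <- TRUE

# Number of alleles per locus (diploid). Fixed by design, not configurable.
NP <- 2L

#' Diploid biallelic genotype
#'
#' A genotype is a pair of haplotypes over `L` unlinked biallelic loci, each
#' allele coded 0 or 1. Traits map linearly onto the fraction of 1-alleles, so
#' a genotype carries no dominance or epistasis.
#'
#' @param h1,h2 Integer vectors of equal length with elements in \{0, 1\}: the
#'   maternal and paternal haplotypes.
#' @return An object of class `genotype` with fields `h1`, `h2` and `L`.
#' @examples
#' g <- genotype(c(1L, 0L, 1L), c(0L, 0L, 1L))
#' trait_fraction(g) # 3 of 6 alleles -> 0.5
#' @export
genotype <- function(h1, h2) {
  h1 <- as.integer(h1)
  h2 <- as.integer(h2)
  if (length(h1) != length(h2)) {
    stop("haplotypes must have equal length")
  }
  if (length(h1) < 1L) stop("a genotype needs at least one locus")
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L))) {
    stop("allele states must be 0 or 1")
  }
  structure(list(h1 = h1, h2 = h2, L = length(h1)), class = "genotype")
}

#' Fraction of trait-increasing alleles in a genotype
#'
#' The trait value of an individual is a linear function of this fraction:
#' number of 1-alleles over the total allele count `2 * L`.
#'
#' @param g A [genotype()].
#' @return A number in \[0, 1\].
#' @export
trait_fraction <- function(g) {
  stopifnot(inherits(g, "genotype"))
  (sum(g$h1) + sum(g$h2)) / (NP * g$L)
}

#' Draw a gamete from a genotype
#'
#' Loci are unlinked, so each gamete allele is drawn independently from the
#' two parental alleles at that locus with probability 1/2 (free
#' recombination). Uses the current R RNG stream.
#'
#' @param g A [genotype()].
#' @return An integer haplotype of length `g$L`.
#' @export
make_gamete <- function(g) {
  stopifnot(inherits(g, "genotype"))
  pick <- runif(g$L) < 0.5
  ifelse(pick, g$h1, g$h2)
}

#' Mutate a haplotype
#'
#' Each allele flips state (0 to 1 or 1 to 0) independently with probability
#' `mu`. Applied to gametes at reproduction, giving one mutation opportunity
#' per allele per generation.
#'
#' @param h Integer haplotype (0/1 vector).
#' @param mu Per-allele mutation probability in \[0, 1\].
#' @return The mutated haplotype.
#' @export
mutate_haplotype <- function(h, mu) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (mu == 0) return(h)
  flip <- runif(length(h)) < mu
  h[flip] <- 1L - h[flip]
  h
}

#' Sample a genotype at a given allele frequency
#'
#' Each of the `2 * L` alleles is 1 independently with probability `p0`. Used
#' to seed the founding fish population from a known population allele
#' frequency.
#'
#' @param p0 Allele-1 frequency in \[0, 1\].
#' @param L Number of loci.
#' @return A [genotype()].
#' @export
sample_initial_genotype <- function(p0, L) {
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  genotype(rbinom(L, 1L, p0), rbinom(L, 1L, p0))
}

# ---- vectorised population-level storage -----------------------------------
#
# The engine stores each trait's genotypes for the whole population as two
# N x L integer matrices (one per haplotype). These helpers are the vectorised
# counterparts of the single-genotype operations above and share their
# contracts; the scalar API stays the reference implementation in tests.

# N x L matrix pair sampled at allele frequency p0
sample_haplotype_matrix <- function(n, L, p0) {
  matrix(rbinom(n * L, 1L, p0), nrow = n, ncol = L)
}

# one gamete per row-index in `idx`, drawn from haplotype matrices m1/m2
make_gametes_matrix <- function(m1, m2, idx) {
  n <- length(idx)
  L <- ncol(m1)
  pick <- matrix(runif(n * L) < 0.5, nrow = n)
  out <- m1[idx, , drop = FALSE]
  alt <- m2[idx, , drop = FALSE]
  out[!pick] <- alt[!pick]
  out
}

mutate_matrix <- function(m, mu) {
  if (mu == 0) return(m)
  flip <- matrix(runif(length(m)) < mu, nrow = nrow(m))
  m[flip] <- 1L - m[flip]
  m
}

#' Population allele frequency for a trait
#'
#' Total count of trait-increasing alleles over the total allele count across
#' all individuals; identical to the mean of the per-individual
#' [trait_fraction()] values because all individuals carry the same number of
#' loci.
#'
#' @param pop A fish population (see [introduce_fish()]).
#' @param trait `"growth"` or `"raker"`.
#' @return Allele frequency in \[0, 1\]; `NA_real_` for an empty population
#'   (an undefined value, deliberately distinct from 0).
#' @export
population_allele_frequency <- function(pop, trait = c("growth", "raker")) {
  trait <- match.arg(trait)
  if (fish_count(pop) == 0L) return(NA_real_)
  m1 <- if (trait == "growth") pop$gA1 else pop$gB1
  m2 <- if (trait == "growth") pop$gA2 else pop$gB2
  (sum(m1) + sum(m2)) / (NP * length(m1))
}
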