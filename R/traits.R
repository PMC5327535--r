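# Foraging trade-off surface: gape, gill-raker spacing, clogging penalty,
# normalised efficiency, handling saturation and foraging-time allocation.

#' Trait parameters for the foraging trade-off
#'
#' @param lMx Maximum gill-raker spacing, in prey-mass units (g). Default 0.02,
#'   twice the body mass of large zooplankton (0.01 g).
#' @param lMn Minimum spacing (g). Default 0.001, 10 percent of the large
#'   zooplankton mass.
#' @param eb Body-size exponent on spacing. Low `eb` means small reductions in
#'   body size strongly improve small-prey foraging (see `eb_mode`).
#' @param lp Clog-penalty exponent on large-prey foraging (default 0.5).
#' @param fs Logistic steepness of the efficiency drop-off for very large or
#'   very small prey (default 10).
#' @param cg Gape multiplier converting body mass to the largest efficiently
#'   taken prey mass (default 0.01).
#' @param bMx,bMn Maximum (asymptotic, largest genotype) and minimum fish body
#'   lengths in mm; the corresponding masses `wMx`, `wMn` are derived through
#'   the length-mass allometry.
#' @param eb_mode `"direct"` (default) applies the exponent `eb` to the
#'   scaled body mass literally; `"reciprocal"` uses `1/eb` instead, making
#'   smaller `eb` strengthen the small-body effect on spacing. Direct mode
#'   reproduces the documented sensitivity pattern of gill-raker evolution
#'   across `eb`; see the methods vignette for the full rationale.
#' @param q Allocation-sharpness exponent on foraging scores (default 10,
#'   concentrating each fish's foraging time on its most profitable prey
#'   classes, approximating "targets the prey type with the highest
#'   harvestable mass"; `q = 1` gives fully graded time-sharing).
#' @return A list of class `trait_params`.
#' @export
trait_params <- function(lMx = 0.02, lMn = 0.001, eb = 0.125, lp = 0.5,
                         fs = 10, cg = 0.01, bMx = 273.684, bMn = 5,
                         eb_mode = c("direct", "reciprocal"), q = 10) {
  eb_mode <- match.arg(eb_mode)
  if (!(lMn > 0 && lMn < lMx)) stop("need 0 < lMn < lMx")
  if (fs <= 0) stop("fs must be positive")
  if (lp < 0) stop("lp must be nonnegative")
  if (eb < 0) stop("eb must be nonnegative")
  wMx <- length_to_mass(bMx)
  wMn <- length_to_mass(bMn)
  structure(list(lMx = lMx, lMn = lMn, eb = eb, lp = lp, fs = fs, cg = cg,
                 bMx = bMx, bMn = bMn, wMx = wMx, wMn = wMn,
                 eb_mode = eb_mode, q = q),
            class = "trait_params")
}

#' Handling-time parameters of the type II functional response
#'
#' @param cH Handling constant (default 0.1): foraging on a prey cluster is
#'   halved when its abundance is `cH` times the abundance predicted by the
#'   body-mass-abundance power law, i.e. at 10 percent of prediction under the
#'   default.
#' @param bf Abundance exponent (default 1 for a type II response).
#' @return A list of class `handling_params`.
#' @export
handling_params <- function(cH = 0.1, bf = 1) {
  if (cH < 0) stop("cH must be nonnegative")
  if (bf <= 0) stop("bf must be positive")
  structure(list(cH = cH, bf = bf), class = "handling_params")
}

#' Gape size: largest efficiently taken prey mass
#'
#' Gape scales allometrically with body mass: `u = cg * w(bO)` where `w(bO)`
#' is the length-mass conversion.
#'
#' @param bO Body length in mm (vectorised).
#' @param cg Gape multiplier.
#' @return Prey mass u in g.
#' @export
gape_size <- function(bO, cg = 0.01) {
  if (any(bO < 0)) stop("body length must be nonnegative")
  cg * length_to_mass(bO)
}

#' Gill-raker spacing
#'
#' Spacing decreases with the number of raker-increasing alleles and (for a
#' given raker count) increases with body mass:
#' `l = lMn + (lMx - lMn) * (1 - nml/(nll*np)) * g(x)` with
#' `x = (w - wMn)/(wMx - wMn)` the scaled body mass. In `reciprocal` mode
#' `g(x) = x^(1/eb)` (and the indicator of `x == 1` as `eb -> 0`); in
#' `direct` mode `g(x) = x^eb` with `0^0` defined as 0.
#'
#' @param nml Count of raker-increasing alleles (vectorised).
#' @param nll Number of raker loci.
#' @param w Body mass in g (vectorised; clamped into `[wMn, wMx]` with a
#'   warning).
#' @param p A [trait_params()].
#' @return Spacing l in g, always inside `[lMn, lMx]`.
#' @export
raker_spacing <- function(nml, nll, w, p) {
  if (any(nml < 0) || any(nml > nll * NP)) stop("nml out of [0, nll*np]")
  if (any(w < p$wMn - 1e-12) || any(w > p$wMx + 1e-12)) {
    warning("body mass outside [wMn, wMx]; clamping")
  }
  w <- pmin(pmax(w, p$wMn), p$wMx)
  x <- (w - p$wMn) / (p$wMx - p$wMn)
  g <- if (p$eb_mode == "reciprocal") {
    if (p$eb > 0) x^(1 / p$eb) else as.numeric(x == 1)
  } else {
    if (p$eb > 0) x^p$eb else as.numeric(x > 0) # 0^0 := 0 at minimum mass
  }
  p$lMn + (p$lMx - p$lMn) * (1 - nml / (nll * NP)) * g
}

#' Clogging penalty on large-prey foraging
#'
#' Closely spaced rakers clog when handling prey larger than the spacing:
#' the efficiency multiplier is `(l/k)^lp` for `k > l` and 1 otherwise.
#'
#' @param k Prey body mass g (vectorised).
#' @param l Gill-raker spacing g.
#' @param lp Penalty exponent.
#' @return Multiplier in (0, 1\].
#' @export
clog_penalty <- function(k, l, lp) {
  if (any(k <= 0) || any(l <= 0)) stop("k and l must be positive")
  if (lp < 0) stop("lp must be nonnegative")
  ifelse(k > l, (l / k)^lp, 1)
}

#' Normalising constant of the foraging-efficiency surface
#'
#' Scales the product of the two logistic shoulders so that, with the clog
#' penalty off, the maximum efficiency equals 1 at the log-midpoint prey mass
#' `tau = (log10 u + log10 l)/2`. Algebraically
#' `cF = (1 + exp(fs * d))^2` with `d = (log10 u - log10 l)/2`, which equals
#' the quotient form `[2 + e^(-fs(tau - log10 l)) + e^(-fs(tau - log10 u))] /
#' e^(-fs(tau - log10 l))`.
#'
#' @param u Gape (g), must exceed `l`.
#' @param l Spacing (g).
#' @param fs Steepness.
#' @return cF >= 4.
#' @export
efficiency_normalizer <- function(u, l, fs) {
  if (any(u <= l)) stop("efficiency_normalizer requires u > l")
  d <- (log10(u) - log10(l)) / 2
  (1 + exp(fs * d))^2
}

#' Foraging efficiency for a prey mass
#'
#' The product of the clog penalty, the normaliser `cF`, a rising logistic in
#' `log10(k/u)` (drop-off for very large prey relative to gape) and a falling
#' logistic in `log10(k/l)` (drop-off for very small prey relative to raker
#' spacing). Zero whenever `u <= l` (degenerate trait combination: the gape
#' admits nothing the rakers retain). With `lp = 0` the maximum over `k` is
#' exactly 1 at `k = sqrt(u * l)`.
#'
#' @param k Prey mass g (vectorised).
#' @param u Gape g.
#' @param l Spacing g.
#' @param fs Steepness.
#' @param lp Clog-penalty exponent.
#' @return Efficiency in \[0, 1\].
#' @export
foraging_efficiency <- function(k, u, l, fs, lp) {
  if (any(k <= 0)) stop("prey mass k must be positive")
  if (u <= l) return(rep(0, length(k)))
  cF <- efficiency_normalizer(u, l, fs)
  s_large <- 1 / (1 + exp(-fs * log10(k / u)))   # admits k up to ~u
  s_small <- 1 / (1 + exp(fs * log10(k / l)))    # retains k down to ~l
  clog_penalty(k, l, lp) * cF * s_large * s_small
}

#' Handling-time saturation multiplier
#'
#' Scarce prey take disproportionately long to find and handle: foraging on a
#' cluster with abundance `N` is scaled by `M = 1 / (1 + (cH * ra / N)^bf)`,
#' which is 0 at `N = 0`, increasing in `N`, and exactly 1/2 at
#' `N = cH * ra`. `ra` is the abundance predicted by the power law
#' [predicted_abundance()]. With `cH = 0` there is no handling cost (M = 1).
#'
#' @param N Prey abundance (vectorised, >= 0).
#' @param ra Predicted abundance (> 0).
#' @param h A [handling_params()].
#' @return Multiplier in \[0, 1\].
#' @export
handling_multiplier <- function(N, ra, h) {
  if (any(ra <= 0)) stop("predicted abundance ra must be positive")
  if (any(N < 0)) stop("abundance N must be nonnegative")
  if (h$cH == 0) return(ifelse(N > 0, 1, 0))
  ifelse(N > 0, 1 / (1 + (h$cH * ra / N)^h$bf), 0)
}

#' Foraging-time allocation over prey size classes
#'
#' An individual spends more foraging time on prey offering more efficiently
#' harvestable total mass: the score of class `(r, rc)` is
#' `fe(k) * M_r * k * N` (efficiency x cluster handling multiplier x class
#' standing mass), optionally sharpened by an exponent `q`, then normalised to
#' time fractions summing to 1. An all-zero score vector falls back to uniform
#' allocation.
#'
#' @param u,l Scalar gape and spacing of one fish.
#' @param k Vector of class masses across all clusters (g).
#' @param N Vector of class abundances (same layout as `k`).
#' @param M Vector of cluster handling multipliers expanded to classes.
#' @param fs,lp,q See [trait_params()].
#' @return Nonnegative weights summing to 1, same length as `k`.
#' @export
allocation_weights <- function(u, l, k, N, M, fs, lp, q = 1) {
  fe <- foraging_efficiency(k, u, l, fs, lp)
  score <- (fe * M * k * N)^q
  tot <- sum(score)
  if (!is.finite(tot) || tot <= 0) {
    return(rep(1 / length(k), length(k)))
  }
  score / tot
}

# Vectorised over fish: returns list(fe = N x C efficiency matrix,
# w = N x C allocation weights). k, N, M are class-level vectors (length C);
# u, l are per-fish vectors (length Nf).
allocation_matrix <- function(u, l, k, N, M, fs, lp, q = 1) {
  nf <- length(u)
  C <- length(k)
  lk <- log10(k)
  # fe[i, j]: logistic shoulders in log10 k, per-fish centres
  du <- outer(-log10(u), lk, `+`)           # log10(k/u)
  dl <- outer(-log10(l), lk, `+`)           # log10(k/l)
  s_large <- 1 / (1 + exp(-fs * du))
  s_small <- 1 / (1 + exp(fs * dl))
  d <- (log10(u) - log10(l)) / 2
  cF <- (1 + exp(fs * d))^2
  pf <- (10^pmin(outer(log10(l), lk, `-`), 0))^lp   # (l/k)^lp capped at 1
  fe <- pf * cF * s_large * s_small
  fe[u <= l, ] <- 0
  score <- (fe * rep(M * k * N, each = nf))^q
  tot <- rowSums(score)
  bad <- !is.finite(tot) | tot <= 0
  w <- score / tot
  if (any(bad)) w[bad, ] <- 1 / C
  list(fe = fe, w = w)
}
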