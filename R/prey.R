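# Size-structured prey clusters: allometric scaling, discrete Lotka-Volterra
# updates, class-structured body-size genetics and the fish-foraging coupling.

#' Community-level allometric parameters
#'
#' @param cA Abundance constant of the body-mass-abundance power law
#'   (default 5.0e6).
#' @param eA Abundance exponent (default 0.75; sensitivity grid 0.75, 1,
#'   1.25). Sets the carrying capacity `ra = cA * rMu^-eA` of each cluster and
#'   thereby the intensity of within-cluster competition.
#' @param ci Interaction scale of the predator-prey mass-ratio law
#'   (default 2.5e-6).
#' @param eI Interaction exponent (default 0.25; grid 0.25, 0.4, 0.55). Lower
#'   values mean stronger trophic interactions.
#' @param pc Feeding-benefit scale: conversion of consumed smaller-cluster
#'   prey into consumer growth (default 0.01).
#' @param wf Representative fish body mass used in the fish-foraging scaling
#'   (constant 30.27 g, the stable-stage mean mass of largest-genotype
#'   females).
#' @param nll_prey Loci controlling prey body mass (default 10), giving
#'   `cn = 2 * nll_prey + 1` size classes per cluster (21 by default).
#' @param mu_prey Prey mutation rate per allele per generation (default 1e-5).
#' @param sd_classes Standard deviation, in class units, of the initial
#'   normal abundance distribution over classes (default 2).
#' @param extinction_threshold Cluster total below which the cluster is zeroed
#'   and flagged extinct (default 1 individual).
#' @param handling A [handling_params()].
#' @return A list of class `community_params`.
#' @export
community_params <- function(cA = 5.0e6, eA = 0.75, ci = 2.5e-6, eI = 0.25,
                             pc = 0.01, wf = 30.27, nll_prey = 10L,
                             mu_prey = 1e-5, sd_classes = 2,
                             extinction_threshold = 1,
                             handling = handling_params()) {
  stopifnot(cA > 0, eA > 0, ci > 0, eI > 0, pc > 0, wf > 0, nll_prey >= 1,
            mu_prey >= 0, mu_prey <= 1, sd_classes > 0)
  structure(list(cA = cA, eA = eA, ci = ci, eI = eI, pc = pc, wf = wf,
                 nll_prey = as.integer(nll_prey),
                 cn = 2L * as.integer(nll_prey) + 1L,
                 mu_prey = mu_prey, sd_classes = sd_classes,
                 extinction_threshold = extinction_threshold,
                 handling = handling),
            class = "community_params")
}

#' Abundance predicted by the body-mass-abundance power law
#'
#' `ra = cA * rMu^-eA`: the equilibrium abundance a cluster of representative
#' body mass `rMu` can sustain.
#'
#' @param rMu Representative body mass g.
#' @param cA,eA Power-law constant and exponent.
#' @return Predicted abundance (individuals).
#' @export
predicted_abundance <- function(rMu, cA, eA) {
  if (any(rMu <= 0)) stop("rMu must be positive")
  cA * rMu^(-eA)
}

#' Within-cluster competition term
#'
#' `sI = (total cluster abundance at t-1) / ra`: competition is felt through
#' the ratio of standing abundance to the power-law carrying capacity.
#'
#' @param rsc_prev Abundance per size class at the previous step.
#' @param ra Predicted abundance of the cluster.
#' @return Nonnegative scalar.
#' @export
within_competition <- function(rsc_prev, ra) {
  if (ra <= 0) stop("ra must be positive")
  sum(rsc_prev) / ra
}

#' Predator-prey interaction coefficient between clusters
#'
#' Interaction strength scales with the prey/predator body-mass ratio:
#' `in = ci * (rMu_prey / rMu_pred)^eI` when the predator cluster is at least
#' as large-bodied as the prey cluster, else 0 (no upward predation).
#'
#' @param rMu_prey,rMu_pred Representative masses g.
#' @param ci,eI Scale and exponent.
#' @return Nonnegative coefficient.
#' @export
interaction_coefficient <- function(rMu_prey, rMu_pred, ci, eI) {
  if (any(rMu_prey <= 0) || any(rMu_pred <= 0)) stop("masses must be positive")
  ifelse(rMu_pred >= rMu_prey, ci * (rMu_prey / rMu_pred)^eI, 0)
}

#' Log-spaced class masses of a prey cluster
#'
#' Classes span a two-fold range either side of the representative mass:
#' `k_j = rMu * exp(ln 2 * (j - c)/c)` for `j = 0..cn-1`, `c = (cn-1)/2`, so
#' the centre class equals `rMu` and the end classes are `rMu/2` and
#' `2 * rMu`. Class `j` corresponds to `j` copies of the size-increasing
#' allele among the `2 * nll_prey` prey alleles.
#'
#' @param rMu Representative mass g.
#' @param cn Odd number of classes.
#' @return Strictly increasing masses, length `cn`.
#' @export
class_masses <- function(rMu, cn) {
  if (cn %% 2L != 1L) stop("cn must be odd")
  ctr <- (cn - 1) / 2
  rMu * exp(log(2) * ((seq_len(cn) - 1) - ctr) / ctr)
}

#' Initial abundance distribution over size classes
#'
#' Discretised normal density over class indices, centred on the middle class
#' with standard deviation `sd_classes`, scaled so the total equals `ra`.
#'
#' @param ra Cluster total abundance.
#' @param cn Number of classes.
#' @param sd_classes Spread in class units.
#' @return Abundance vector summing to `ra`.
#' @export
init_distribution <- function(ra, cn, sd_classes = 2) {
  if (ra <= 0) stop("ra must be positive")
  j <- seq_len(cn) - 1
  dens <- dnorm(j, mean = (cn - 1) / 2, sd = sd_classes)
  ra * dens / sum(dens)
}

#' Construct a prey cluster
#'
#' @param rMu Representative body mass g.
#' @param rI Intrinsic growth rate: 1 for the basal (smallest-mass) cluster,
#'   0 otherwise — only the basal cluster draws on resources outside the
#'   modelled web.
#' @param params A [community_params()].
#' @param rsc Optional initial class abundances; defaults to
#'   [init_distribution()] at the power-law total.
#' @return A list of class `prey_cluster` with fields `rMu`, `rI`, `ra`,
#'   `masses`, `rsc`, `extinct`.
#' @export
prey_cluster <- function(rMu, rI, params, rsc = NULL) {
  ra <- predicted_abundance(rMu, params$cA, params$eA)
  if (is.null(rsc)) rsc <- init_distribution(ra, params$cn, params$sd_classes)
  if (length(rsc) != params$cn) stop("rsc must have cn classes")
  if (any(rsc < 0)) stop("abundances must be nonnegative")
  structure(list(rMu = rMu, rI = rI, ra = ra,
                 masses = class_masses(rMu, params$cn),
                 rsc = rsc, extinct = FALSE),
            class = "prey_cluster")
}

#' Build the default prey community
#'
#' Two clusters (0.01 g large zooplankton, 0.224 g large fish egg) or three
#' (adding a 5 g small zooplanktivore), each initialised at its power-law
#' abundance.
#'
#' @param n_clusters 2 or 3 (or any subset via `rMu` override).
#' @param params A [community_params()].
#' @param rMu Optional vector of representative masses overriding the
#'   defaults.
#' @return A list of class `prey_community`: fields `clusters`, `params`.
#' @export
prey_community <- function(n_clusters = 3L, params = community_params(),
                           rMu = NULL) {
  if (is.null(rMu)) {
    rMu <- switch(as.character(n_clusters),
                  "2" = c(0.01, 0.224),
                  "3" = c(0.01, 0.224, 5),
                  stop("default communities have 2 or 3 clusters"))
  }
  rMu <- sort(rMu)
  rI <- c(1, rep(0, length(rMu) - 1L)) # basal cluster only
  clusters <- Map(function(m, g) prey_cluster(m, g, params), rMu, rI)
  structure(list(clusters = unname(clusters), params = params),
            class = "prey_community")
}

#' Predation pressure from larger-bodied clusters
#'
#' Sum over all larger-bodied clusters `rk` of
#' `in(r, rk) * N_rk * M(N_rk, ra_r)`: interaction coefficient times predator
#' abundance, saturated by the handling multiplier evaluated at the predator
#' abundance against the focal (prey) cluster's predicted abundance. The
#' pressure is identical across the size classes of the prey cluster.
#'
#' @param comm A [prey_community()].
#' @param r Index of the focal (prey) cluster.
#' @return Nonnegative scalar `nI`.
#' @export
predation_effect <- function(comm, r) {
  p <- comm$params
  focal <- comm$clusters[[r]]
  nI <- 0
  for (cl in comm$clusters) {
    if (cl$rMu > focal$rMu) {
      N_pred <- sum(cl$rsc)
      coef <- interaction_coefficient(focal$rMu, cl$rMu, p$ci, p$eI)
      nI <- nI + coef * N_pred * handling_multiplier(N_pred, focal$ra,
                                                     p$handling)
    }
  }
  nI
}

#' Feeding benefit from smaller-bodied clusters
#'
#' Consumers grow by eating smaller clusters: `pI = sum over smaller rk of
#' pc * in(rk, r) * N_rk * M(N_rk, ra_rk)`, where the handling multiplier is
#' evaluated at the resource's abundance against its own predicted abundance.
#' Zero for the basal cluster.
#'
#' @param comm A [prey_community()].
#' @param r Index of the focal (consumer) cluster.
#' @return Nonnegative scalar `pI`.
#' @export
feeding_benefit <- function(comm, r) {
  p <- comm$params
  focal <- comm$clusters[[r]]
  pI <- 0
  for (cl in comm$clusters) {
    if (cl$rMu < focal$rMu) {
      N_res <- sum(cl$rsc)
      coef <- interaction_coefficient(cl$rMu, focal$rMu, p$ci, p$eI)
      pI <- pI + p$pc * coef * N_res * handling_multiplier(N_res, cl$ra,
                                                           p$handling)
    }
  }
  pI
}

#' Per-capita fish-foraging scale of a cluster
#'
#' `fc_r = cn * ci * (rMu_r / wf)^eI`: the per-class effect of one fish
#' splitting its foraging time evenly over the cluster's `cn` classes equals
#' `fc_r` exactly.
#'
#' @param rMu Cluster representative mass g.
#' @param params A [community_params()].
#' @return Scalar `fc`.
#' @export
fish_foraging_scale <- function(rMu, params) {
  params$cn * params$ci * (rMu / params$wf)^params$eI
}

#' Fish-foraging pressure on the classes of a cluster
#'
#' `fI_{r,rc} = cn * fc_r * nc_{r,rc}` where `nc` is the (fractional) number
#' of fish foraging on class `rc`: the sum over fish of their foraging-time
#' allocation to that class.
#'
#' @param nc Vector of per-class fish counts (length `cn`).
#' @param rMu Cluster representative mass.
#' @param params A [community_params()].
#' @return Vector `fI` per class.
#' @export
fish_foraging_effect <- function(nc, rMu, params) {
  if (any(nc < 0)) stop("nc must be nonnegative")
  params$cn * fish_foraging_scale(rMu, params) * nc
}

#' Discrete Lotka-Volterra growth ratio
#'
#' `rt = (1 + rI + pI) / (1 + sI + nI + fI)`: gains (intrinsic growth,
#' feeding on smaller clusters) over losses (within-cluster competition,
#' predation by larger clusters, fish foraging). Applied multiplicatively per
#' size class.
#'
#' @param rI,sI,nI,pI Scalars >= 0.
#' @param fI Scalar or per-class vector >= 0.
#' @return Growth ratio(s) > 0.
#' @export
growth_ratio <- function(rI, sI, nI, pI, fI) {
  if (any(c(rI, sI, nI, pI, fI) < 0)) stop("all terms must be nonnegative")
  (1 + rI + pI) / (1 + sI + nI + fI)
}

#' Expected mutation flow between adjacent size classes
#'
#' Class `j` holds individuals with `j` copies of the size-increasing allele
#' among `2 * nll_prey` prey alleles. Asexual reproduction moves the expected
#' fraction `(2*nll - j) * mu` of class `j` up one class (a 0-allele flips)
#' and `j * mu` down one class (a 1-allele flips). Total abundance is
#' conserved exactly.
#'
#' @param rsc Class abundances (length `2*nll_prey + 1`).
#' @param nll_prey Number of prey loci.
#' @param mu Mutation rate.
#' @return Updated abundances with the same total.
#' @export
within_cluster_dynamics <- function(rsc, nll_prey, mu) {
  if (mu == 0) return(rsc)
  n_alleles <- 2L * nll_prey
  j <- seq_along(rsc) - 1
  up <- rsc * (n_alleles - j) * mu
  down <- rsc * j * mu
  out <- rsc - up - down
  out + c(0, up[-length(up)]) + c(down[-1], 0)
}

#' Advance the prey community one year
#'
#' For each cluster, the loss and gain terms `sI`, `nI`, `pI`, `fI` are
#' computed from the previous year's abundances (and this year's fish
#' allocations `nc`), the growth ratio is applied per class, and expected
#' mutation flow redistributes abundance between adjacent classes. The
#' abundance removed by fish from each class — the difference between the
#' no-fish and with-fish updates — is returned as a removal ledger so fish
#' intake can be made mass-consistent with prey loss.
#'
#' @param comm A [prey_community()].
#' @param nc Matrix of per-class fish counts, `n_clusters` x `cn`; `NULL`
#'   means no fish.
#' @return List: `community` (updated), `removed` (matrix of abundance
#'   removed by fish per class), `extinct` (logical per cluster).
#' @export
step_community <- function(comm, nc = NULL) {
  p <- comm$params
  ncl <- length(comm$clusters)
  if (is.null(nc)) nc <- matrix(0, nrow = ncl, ncol = p$cn)
  if (!all(dim(nc) == c(ncl, p$cn))) stop("nc must be n_clusters x cn")
  if (any(!is.finite(nc)) || any(nc < 0)) stop("invalid fish allocation nc")
  removed <- matrix(0, nrow = ncl, ncol = p$cn)
  new_rsc <- vector("list", ncl)
  for (r in seq_len(ncl)) {
    cl <- comm$clusters[[r]]
    if (any(!is.finite(cl$rsc)) || any(cl$rsc < 0)) {
      stop("invalid state in prey cluster ", r)
    }
    sI <- within_competition(cl$rsc, cl$ra)
    nI <- predation_effect(comm, r)
    pI <- feeding_benefit(comm, r)
    fI <- fish_foraging_effect(nc[r, ], cl$rMu, p)
    rt <- growth_ratio(cl$rI, sI, nI, pI, fI)
    rt_nofish <- growth_ratio(cl$rI, sI, nI, pI, 0)
    pre <- cl$rsc * rt
    removed[r, ] <- cl$rsc * (rt_nofish - rt)
    new_rsc[[r]] <- pmax(within_cluster_dynamics(pre, p$nll_prey, p$mu_prey),
                         0)
  }
  extinct <- logical(ncl)
  for (r in seq_len(ncl)) {
    if (sum(new_rsc[[r]]) < p$extinction_threshold) {
      new_rsc[[r]] <- rep(0, p$cn)
      extinct[r] <- TRUE
    }
    comm$clusters[[r]]$rsc <- new_rsc[[r]]
    comm$clusters[[r]]$extinct <- comm$clusters[[r]]$extinct || extinct[r]
  }
  list(community = comm, removed = removed, extinct = extinct)
}

#' Total abundance per cluster
#' @param comm A [prey_community()].
#' @return Numeric vector of cluster totals.
#' @export
cluster_totals <- function(comm) {
  vapply(comm$clusters, function(cl) sum(cl$rsc), numeric(1))
}
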