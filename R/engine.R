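# Annual loop, burn-in, fish introduction, replicate control and trajectory
# recording.

#' Resolve a configuration into parameter objects
#'
#' @param config A configuration list (see [default_config()]).
#' @return A list with `tp` (trait), `hp` (handling), `cp` (community),
#'   `gp` (growth), `dp` (demography) parameter objects plus the raw config.
#' @export
resolve_params <- function(config) {
  cfg <- validate_config(config)
  hp <- handling_params(cH = cfg$handling$cH, bf = cfg$handling$bf)
  tp <- trait_params(lMx = cfg$traits$lMx, lMn = cfg$traits$lMn,
                     eb = cfg$traits$eb, lp = cfg$traits$lp,
                     fs = cfg$traits$fs, cg = cfg$traits$cg,
                     bMx = cfg$growth$bMx, bMn = cfg$growth$bMn,
                     eb_mode = cfg$traits$eb_mode, q = cfg$traits$q)
  cp <- community_params(cA = cfg$community$cA, eA = cfg$community$eA,
                         ci = cfg$community$ci, eI = cfg$community$eI,
                         pc = cfg$community$pc, wf = cfg$community$wf,
                         nll_prey = cfg$community$nll_prey,
                         mu_prey = cfg$community$mu_prey,
                         sd_classes = cfg$community$sd_classes,
                         extinction_threshold =
                           cfg$community$extinction_threshold,
                         handling = hp)
  gp <- growth_params(bMx = cfg$growth$bMx, bMn = cfg$growth$bMn,
                      bLo = cfg$growth$bLo, K = cfg$growth$K,
                      bA = cfg$growth$bA, bcv = cfg$growth$bcv)
  dp <- demography_params(sMx = cfg$demography$sMx, cm = cfg$demography$cm,
                          em = cfg$demography$em,
                          age_mat_min = cfg$demography$age_mat_min,
                          age_mat_span = cfg$demography$age_mat_span,
                          fec_max = cfg$demography$fec_max,
                          max_age = cfg$demography$max_age,
                          pop_cap = if (is.null(cfg$demography$pop_cap)) Inf
                                    else cfg$demography$pop_cap)
  list(tp = tp, hp = hp, cp = cp, gp = gp, dp = dp, config = cfg)
}

#' Run the prey-only burn-in
#'
#' Steps the community `years` times with no fish, establishing the
#' size-structured prey equilibrium before fish introduction. Warns if any
#' non-extinct cluster total ends below its predicted abundance times 1e-3
#' (a stability warning), and errors on non-finite state.
#'
#' @param comm A [prey_community()].
#' @param years Number of burn-in years.
#' @return The community after the burn-in.
#' @export
run_burn_in <- function(comm, years) {
  for (t in seq_len(years)) {
    comm <- step_community(comm)$community
  }
  tot <- cluster_totals(comm)
  if (any(!is.finite(tot))) stop("non-finite prey state after burn-in")
  ra <- vapply(comm$clusters, `[[`, numeric(1), "ra")
  low <- tot < 1e-3 * ra & tot > 0
  if (any(low)) {
    warning("burn-in ended with cluster(s) far below predicted abundance: ",
            paste(which(low), collapse = ", "))
  }
  comm
}

# deterministic length at a given age for a genotype fraction p
deterministic_length_at_age <- function(p, age, gp) {
  Linf <- asymptotic_length(p, gp)
  Linf - (Linf - gp$bMn) * exp(-gp$K * age)
}

#' Create the founding fish population
#'
#' `n_intro_females` + `n_intro_males` adults with per-allele genotype
#' sampling at frequencies `p0A` (growth) and `p0B` (raker), ages uniform on
#' 3-6 years, lengths from deterministic growth to that age given each
#' individual's genotype, and maturity set by the genotype-dependent
#' maturation age.
#'
#' @param params Output of [resolve_params()].
#' @return A fish population.
#' @export
introduce_fish <- function(params) {
  cfg <- params$config
  nf <- cfg$schedule$n_intro_females
  nm <- cfg$schedule$n_intro_males
  n <- nf + nm
  nllA <- cfg$genetics$nll_growth
  nllB <- cfg$genetics$nll_raker
  pop <- new_fish_population(
    female = rep(c(TRUE, FALSE), c(nf, nm)),
    age = sample(3:6, n, replace = TRUE),
    bO = rep(0, n),
    gA1 = sample_haplotype_matrix(n, nllA, cfg$init$p0A),
    gA2 = sample_haplotype_matrix(n, nllA, cfg$init$p0A),
    gB1 = sample_haplotype_matrix(n, nllB, cfg$init$p0B),
    gB2 = sample_haplotype_matrix(n, nllB, cfg$init$p0B))
  p <- growth_fraction(pop)
  pop$bO <- deterministic_length_at_age(p, pop$age, params$gp)
  pop$mature <- pop$age >= maturation_age(p, params$dp)
  pop
}

# one simulated year with fish present; returns updated state plus intake
# diagnostics. Phases: growth -> traits/allocation -> prey update -> intake
# partition -> survival/aging -> maturity -> reproduction.
step_year <- function(comm, pop, params) {
  cfg <- params$config
  tp <- params$tp; cp <- params$cp; gp <- params$gp; dp <- params$dp
  n <- fish_count(pop)
  if (n == 0L) {
    res <- step_community(comm)
    return(list(community = res$community, pop = pop, extinct = res$extinct,
                total_removed_mass = 0, total_intake = 0))
  }
  # (1) growth: everyone, including last year's newborns, grows first
  pA <- growth_fraction(pop)
  pop$bO <- annual_growth(pop$bO, asymptotic_length(pA, gp), gp)
  if (any(!is.finite(pop$bO))) stop("non-finite length in growth phase")
  # (2) per-fish foraging traits and time allocation
  w <- length_to_mass(pop$bO)
  u <- gape_size(pop$bO, tp$cg)
  l <- raker_spacing(raker_allele_count(pop), ncol(pop$gB1), w, tp)
  k <- unlist(lapply(comm$clusters, `[[`, "masses"), use.names = FALSE)
  N <- unlist(lapply(comm$clusters, `[[`, "rsc"), use.names = FALSE)
  ra <- vapply(comm$clusters, `[[`, numeric(1), "ra")
  Mcl <- handling_multiplier(cluster_totals(comm), ra, params$hp)
  M <- rep(Mcl, each = cp$cn)
  am <- allocation_matrix(u, l, k, N, M, tp$fs, tp$lp, tp$q)
  if (isTRUE(cfg$traits$flat_fe)) { # neutral-control hook: no trait effect
    am$fe[] <- 1
    am$w[] <- 1 / length(k)
  }
  # (3) aggregate fractional fish counts per class and update the prey
  nc <- matrix(colSums(am$w), nrow = length(comm$clusters), ncol = cp$cn,
               byrow = TRUE)
  res <- step_community(comm, nc)
  comm <- res$community
  # (4) partition the fish-attributable prey-mass loss into intakes
  removed_mass <- as.numeric(t(res$removed)) * k
  A <- partition_intake(am$w, am$fe, removed_mass)
  # (5) Beverton-Holt survival, aging, max-age cull
  s <- survival_probability(A, w, dp)
  pop <- annual_survival_and_aging(pop, s, dp)
  # (6) maturity update
  pA <- growth_fraction(pop)
  pop$mature <- pop$age >= maturation_age(pA, dp)
  # (7) reproduction; the no-mature-males warning becomes a run flag
  no_males <- FALSE
  rep_out <- withCallingHandlers(
    reproduce(pop, gp, dp, cfg$genetics$mu, length_to_mass(gp$bMx)),
    warning = function(w) {
      if (grepl("no mature males", conditionMessage(w))) {
        no_males <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  pop <- bind_populations(pop, rep_out$offspring)
  if (is.finite(dp$pop_cap) && fish_count(pop) > dp$pop_cap) {
    pop <- subset_population(pop, sample.int(fish_count(pop), dp$pop_cap))
  }
  list(community = comm, pop = pop, extinct = res$extinct, no_males = no_males,
       total_removed_mass = sum(removed_mass), total_intake = sum(A))
}

#' Run one replicate of the full simulation
#'
#' Prey-only burn-in over years `1..burn_in_years`; the founding fish
#' population is created at the end of the burn-in year and recorded as
#' `years_post = 0` (its pristine, pre-selection state), so the fish live
#' their first year in year `burn_in_years + 1`. The state recorded for any
#' later year is the post-reproduction state of that year.
#'
#' @param config A configuration list.
#' @param seed RNG seed for this replicate.
#' @param replicate Replicate label stored in the output.
#' @return A [data.table::data.table] with columns `replicate`, `year`,
#'   `years_post` (years since introduction; `NA` during burn-in), `pA`,
#'   `pB`, `n_fish`, `cluster_<i>_total`, and `flags` (semicolon-separated
#'   event strings).
#' @export
run_simulation <- function(config, seed = 1L, replicate = 1L) {
  params <- resolve_params(config)
  cfg <- params$config
  set.seed(seed)
  comm <- prey_community(cfg$community$n_clusters, params$cp,
                         rMu = cfg$community$rMu)
  sched <- cfg$schedule
  intro_at <- sched$burn_in_years # founding population recorded here
  ncl <- length(comm$clusters)
  rows <- vector("list", sched$total_years + 1L)
  record <- function(year, pop, comm, flags) {
    tot <- cluster_totals(comm)
    row <- c(list(replicate = replicate, year = year,
                  years_post = if (year >= intro_at) year - intro_at
                               else NA_integer_,
                  pA = population_allele_frequency_or_na(pop, "growth"),
                  pB = population_allele_frequency_or_na(pop, "raker"),
                  n_fish = if (is.null(pop)) 0L else fish_count(pop)),
             stats::setNames(as.list(tot), paste0("cluster_", seq_len(ncl),
                                                  "_total")),
             list(flags = flags))
    data.table::as.data.table(row)
  }
  pop <- NULL
  fish_extinct_flagged <- FALSE
  for (year in seq_len(sched$total_years)) {
    flags <- character(0)
    if (year <= intro_at) {
      res <- step_community(comm)
      comm <- res$community
      if (any(res$extinct)) {
        flags <- c(flags, paste0("prey_extinct_", which(res$extinct)))
      }
      if (year == intro_at) {
        pop <- introduce_fish(params)
        flags <- c(flags, "introduction")
      }
    } else {
      st <- step_year(comm, pop, params)
      comm <- st$community
      pop <- st$pop
      if (any(st$extinct)) {
        flags <- c(flags, paste0("prey_extinct_", which(st$extinct)))
      }
      if (isTRUE(st$no_males)) flags <- c(flags, "no_mature_males")
      if (fish_count(pop) == 0L && !fish_extinct_flagged) {
        flags <- c(flags, "fish_extinct")
        fish_extinct_flagged <- TRUE
      }
    }
    if (year %% sched$record_every == 0L || year == intro_at ||
        year == sched$total_years) {
      rows[[year]] <- record(year, pop, comm,
                             paste(flags, collapse = ";"))
    }
  }
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

population_allele_frequency_or_na <- function(pop, trait) {
  if (is.null(pop) || fish_count(pop) == 0L) return(NA_real_)
  population_allele_frequency(pop, trait)
}

#' Run replicated simulations
#'
#' Replicate `i` uses seed `base_seed + i - 1`, so replicate streams are
#' independent and results do not depend on execution order.
#'
#' @param config A configuration list.
#' @param replicates Number of replicates (default from the config).
#' @param base_seed Base RNG seed (default from the config).
#' @return List with `records` (row-bound per-replicate tables) and `summary`
#'   (per recorded year: cross-replicate mean and standard deviation of `pA`
#'   and `pB`, and mean `n_fish`).
#' @export
run_replicates <- function(config, replicates = NULL, base_seed = NULL) {
  cfg <- validate_config(config)
  if (is.null(replicates)) replicates <- cfg$schedule$replicates
  if (is.null(base_seed)) base_seed <- cfg$schedule$base_seed
  out <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    out[[i]] <- tryCatch(
      run_simulation(cfg, seed = base_seed + i - 1L, replicate = i),
      error = function(e) {
        warning("replicate ", i, " failed: ", conditionMessage(e))
        NULL
      })
  }
  records <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  summary <- summarize_replicates(records)
  list(records = records, summary = summary)
}

#' Cross-replicate summary of allele-frequency trajectories
#'
#' @param records Row-bound output of [run_simulation()] calls.
#' @return A [data.table::data.table] keyed by `year` with `mean_pA`,
#'   `sd_pA`, `mean_pB`, `sd_pB`, `mean_n_fish`, `n_replicates`.
#' @export
summarize_replicates <- function(records) {
  year <- pA <- pB <- n_fish <- NULL # data.table NSE
  records[, list(mean_pA = mean(pA), sd_pA = stats::sd(pA),
                 mean_pB = mean(pB), sd_pB = stats::sd(pB),
                 mean_n_fish = mean(n_fish), n_replicates = .N),
          by = year]
}

#' Write a run's records and manifest
#'
#' The CSV is RFC 4180 with a header row; the manifest JSON captures the
#' fully resolved configuration, seeds and package version so a run can be
#' reproduced bit-for-bit.
#'
#' @param records Output records table.
#' @param config The configuration used.
#' @param dir Output directory (created if needed).
#' @param base_seed,replicates Seeding actually used.
#' @return Invisibly, the paths written.
#' @export
write_run_output <- function(records, config, dir, base_seed, replicates) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "records.csv")
  manifest <- file.path(dir, "manifest.json")
  data.table::fwrite(records, csv)
  jsonlite::write_json(
    list(package = "alewifesim",
         version = as.character(utils::packageVersion("alewifesim")),
         base_seed = base_seed, replicates = replicates,
         config = validate_config(config)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(csv = csv, manifest = manifest))
}
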