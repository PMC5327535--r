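# Configuration: defaults, schema validation, JSON round-trip, fixtures.
# The config is a two-level named list; JSON is the on-disk format.

#' Default simulation configuration
#'
#' All model parameters at their default values: 3 prey clusters, 8 loci per
#' fish trait, mutation rate 1e-5, allometric constants `cA = 5e6`,
#' `eA = 0.75`, `ci = 2.5e-6`, `eI = 0.25`, foraging parameters `eb = 0.125`
#' (reciprocal mode), `lp = 0.5`, `fs = 10`, handling `cH = 0.1`, growth
#' anchors `bMx = 273.684` mm / 260 mm at age 5, and a 1000-year prey burn-in
#' followed by the introduction of 500 + 500 adult alewives.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    genetics = list(nll_growth = 8L, nll_raker = 8L, mu = 1e-5),
    traits = list(lMx = 0.02, lMn = 0.001, eb = 0.125,
                  eb_mode = "direct", lp = 0.5, fs = 10, cg = 0.01,
                  q = 10, flat_fe = FALSE),
    handling = list(cH = 0.1, bf = 1),
    community = list(cA = 5.0e6, eA = 0.75, ci = 2.5e-6, eI = 0.25,
                     pc = 0.01, wf = 30.27, nll_prey = 10L, mu_prey = 1e-5,
                     sd_classes = 2, extinction_threshold = 1,
                     n_clusters = 3L, rMu = NULL),
    growth = list(bMx = 273.684, bMn = 5, bLo = 134.3, K = 0.5955,
                  bA = 0.25, bcv = 0.01),
    demography = list(sMx = 0.95, cm = 0.2, em = 0.75, age_mat_min = 2L,
                      age_mat_span = 3L, fec_max = 10, max_age = 10L,
                      pop_cap = NULL),
    init = list(p0A = 0.99, p0B = 0.01),
    schedule = list(burn_in_years = 1000L, total_years = 5000L,
                    n_intro_females = 500L, n_intro_males = 500L,
                    replicates = 10L, record_every = 1L, base_seed = 1L)
  )
}

# field ranges checked by validate_config: list(group$key = c(lo, hi))
.config_ranges <- list(
  "genetics.nll_growth" = c(1, Inf), "genetics.nll_raker" = c(1, Inf),
  "genetics.mu" = c(0, 1),
  "traits.lMx" = c(1e-12, Inf), "traits.lMn" = c(1e-12, Inf),
  "traits.eb" = c(0, Inf), "traits.lp" = c(0, Inf),
  "traits.fs" = c(1e-12, Inf), "traits.cg" = c(1e-12, Inf),
  "traits.q" = c(1e-12, Inf),
  "handling.cH" = c(0, Inf), "handling.bf" = c(1e-12, Inf),
  "community.cA" = c(1e-12, Inf), "community.eA" = c(1e-12, Inf),
  "community.ci" = c(1e-12, Inf), "community.eI" = c(1e-12, Inf),
  "community.pc" = c(1e-12, Inf), "community.wf" = c(1e-12, Inf),
  "community.nll_prey" = c(1, Inf), "community.mu_prey" = c(0, 1),
  "community.sd_classes" = c(1e-12, Inf),
  "community.extinction_threshold" = c(0, Inf),
  "community.n_clusters" = c(1, 6),
  "growth.bMx" = c(1e-12, Inf), "growth.bMn" = c(1e-12, Inf),
  "growth.bLo" = c(1e-12, Inf), "growth.K" = c(1e-12, Inf),
  "growth.bA" = c(1e-12, Inf), "growth.bcv" = c(0, Inf),
  "demography.sMx" = c(1e-12, 1), "demography.cm" = c(1e-12, Inf),
  "demography.em" = c(1e-12, Inf), "demography.age_mat_min" = c(0, Inf),
  "demography.age_mat_span" = c(0, Inf), "demography.fec_max" = c(1e-12, Inf),
  "demography.max_age" = c(1, Inf),
  "init.p0A" = c(0, 1), "init.p0B" = c(0, 1),
  "schedule.burn_in_years" = c(0, Inf), "schedule.total_years" = c(1, Inf),
  "schedule.n_intro_females" = c(1, Inf),
  "schedule.n_intro_males" = c(1, Inf),
  "schedule.replicates" = c(1, Inf), "schedule.record_every" = c(1, Inf),
  "schedule.base_seed" = c(-Inf, Inf)
)

#' Validate and complete a configuration
#'
#' Unknown groups or keys are rejected; missing keys are filled from
#' [default_config()]; every numeric field is range-checked and structural
#' invariants (`lMn < lMx`, `bMn < bLo < bMx`, `burn_in_years <
#' total_years`, ...) are enforced.
#'
#' @param config A (possibly partial) configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  def <- default_config()
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config group(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- def
  for (grp in names(config)) {
    sub <- config[[grp]]
    if (!is.list(sub)) stop("config group '", grp, "' must be a list")
    bad <- setdiff(names(sub), names(def[[grp]]))
    if (length(bad)) {
      stop("unknown key(s) in '", grp, "': ", paste(bad, collapse = ", "))
    }
    for (key in names(sub)) {
      if (!is.null(sub[[key]])) cfg[[grp]][[key]] <- sub[[key]]
    }
  }
  for (field in names(.config_ranges)) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- .config_ranges[[field]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < rng[1] || val > rng[2]) {
      stop("config field ", field, " out of range [", rng[1], ", ", rng[2],
           "]: ", format(val))
    }
  }
  if (!cfg$traits$eb_mode %in% c("reciprocal", "direct")) {
    stop("traits.eb_mode must be 'reciprocal' or 'direct'")
  }
  if (!(cfg$traits$lMn < cfg$traits$lMx)) stop("need lMn < lMx")
  if (!(cfg$growth$bMn < cfg$growth$bLo && cfg$growth$bLo < cfg$growth$bMx)) {
    stop("need bMn < bLo < bMx")
  }
  if (!(cfg$schedule$burn_in_years < cfg$schedule$total_years)) {
    stop("need burn_in_years < total_years")
  }
  if (!is.null(cfg$demography$pop_cap) &&
      (!is.numeric(cfg$demography$pop_cap) || cfg$demography$pop_cap < 1)) {
    stop("demography.pop_cap must be null or >= 1")
  }
  if (!is.null(cfg$community$rMu)) {
    if (any(cfg$community$rMu <= 0)) stop("community.rMu must be positive")
    cfg$community$n_clusters <- length(cfg$community$rMu)
  }
  # integer-valued fields
  for (field in c("genetics.nll_growth", "genetics.nll_raker",
                  "community.nll_prey", "community.n_clusters",
                  "demography.age_mat_min", "demography.age_mat_span",
                  "demography.max_age", "schedule.burn_in_years",
                  "schedule.total_years", "schedule.n_intro_females",
                  "schedule.n_intro_males", "schedule.replicates",
                  "schedule.record_every", "schedule.base_seed")) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (v != round(v)) stop("config field ", field, " must be an integer")
    cfg[[parts[1]]][[parts[2]]] <- as.integer(v)
  }
  cfg
}

#' Load a configuration from a JSON file
#'
#' Missing keys take their defaults; unknown keys are an error. An empty file
#' body (`{}`) yields the full default configuration.
#'
#' @param path Path to a JSON configuration.
#' @return The validated configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' Write a configuration to a JSON file
#'
#' `load_config(save_config(cfg, path))` is the identity on validated
#' configurations.
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  cfg <- validate_config(config)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Fast test configurations
#'
#' Reduced configurations preserving every structural feature of the model:
#' `tiny` has a 50-year burn-in, 50 + 50 introduced fish, 100 total years and
#' 5 prey size classes (`nll_prey = 2`); `small` has a 200-year burn-in,
#' 100 + 100 fish, 400 total years and the default 21 classes.
#'
#' @param profile `"tiny"` or `"small"`.
#' @return A validated configuration.
#' @export
make_fixture <- function(profile = c("tiny", "small")) {
  profile <- match.arg(profile)
  cfg <- default_config()
  if (profile == "tiny") {
    cfg$schedule$burn_in_years <- 50L
    cfg$schedule$total_years <- 100L
    cfg$schedule$n_intro_females <- 50L
    cfg$schedule$n_intro_males <- 50L
    cfg$schedule$replicates <- 2L
    cfg$community$nll_prey <- 2L
    cfg$community$n_clusters <- 2L
  } else {
    cfg$schedule$burn_in_years <- 200L
    cfg$schedule$total_years <- 400L
    cfg$schedule$n_intro_females <- 100L
    cfg$schedule$n_intro_males <- 100L
    cfg$schedule$replicates <- 3L
  }
  validate_config(cfg)
}
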