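# Scenario grids reproducing the sensitivity analyses: Cartesian products of
# parameter values, one output directory per grid point, and delta-frequency
# summaries.

#' The study's scenario grid values
#'
#' Named lists of the parameter values explored in the sensitivity analyses:
#' `eA` (within-trophic competition), `eI` (trophic interaction strength),
#' `eb` (body-size effect on raker spacing), `lp` (clog penalty), `fs`
#' (efficiency steepness), `cH` (handling), `bcv` (growth stochasticity),
#' `n_clusters`, and the initial allele-frequency pairs.
#'
#' @return A named list of value vectors; `init` is a two-column matrix of
#'   `(p0A, p0B)` pairs.
#' @export
scenario_grid_values <- function() {
  list(eA = c(0.75, 1, 1.25),
       eI = c(0.25, 0.4, 0.55),
       eb = c(0, 0.125, 0.25, 0.5),
       lp = c(0, 0.5),
       fs = c(10, 20),
       cH = c(0, 0.05, 0.1, 0.25),
       bcv = c(0.001, 0.01, 0.1, 0.2),
       n_clusters = c(2L, 3L),
       init = cbind(p0A = c(1, 0.9999, 0.999, 0.99, 0.01),
                    p0B = c(0, 0.0001, 0.001, 0.01, 0.99)))
}

# apply one grid point's scalar settings onto a base config
apply_grid_point <- function(cfg, point) {
  map <- list(eA = c("community", "eA"), eI = c("community", "eI"),
              eb = c("traits", "eb"), lp = c("traits", "lp"),
              fs = c("traits", "fs"), cH = c("handling", "cH"),
              bcv = c("growth", "bcv"),
              n_clusters = c("community", "n_clusters"),
              p0A = c("init", "p0A"), p0B = c("init", "p0B"))
  for (nm in names(point)) {
    if (is.null(map[[nm]])) stop("unknown grid parameter: ", nm)
    cfg[[map[[nm]][1]]][[map[[nm]][2]]] <- point[[nm]]
  }
  validate_config(cfg)
}

#' Run a scenario grid
#'
#' Executes the Cartesian product of the supplied parameter values (each a
#' vector named as in [scenario_grid_values()]), writing one records CSV and
#' manifest per grid point under `dir`, and returns a summary of allele
#' frequency changes since introduction at the reporting years. A failing
#' grid point is logged and skipped; the grid continues.
#'
#' @param grid Named list of parameter value vectors.
#' @param base_config Base configuration for all points.
#' @param dir Output directory.
#' @param replicates,base_seed Optional overrides of the config's schedule.
#' @param report_years Years since introduction at which deltas are reported
#'   (default 150, 250, 300, 1000; years beyond the simulated horizon are
#'   dropped).
#' @return A [data.table::data.table]: one row per grid point and report
#'   year, with the grid coordinates, `years_post`, `mean_pA`, `mean_pB`,
#'   `delta_pA`, `delta_pB` (mean frequency minus the introduction-year
#'   frequency) and the output directory.
#' @export
run_grid <- function(grid, base_config = default_config(), dir = tempfile(),
                     replicates = NULL, base_seed = NULL,
                     report_years = c(150L, 250L, 300L, 1000L)) {
  stopifnot(is.list(grid), length(grid) >= 1, !is.null(names(grid)))
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    point <- as.list(pts[i, , drop = FALSE])
    label <- paste(names(point), vapply(point, format, character(1)),
                   sep = "-", collapse = "_")
    sub <- file.path(dir, paste0("point_", i, "_", label))
    out[[i]] <- tryCatch({
      cfg <- apply_grid_point(base_config, point)
      run <- run_replicates(cfg, replicates = replicates,
                            base_seed = base_seed)
      write_run_output(run$records, cfg, sub,
                       base_seed = if (is.null(base_seed))
                         cfg$schedule$base_seed else base_seed,
                       replicates = if (is.null(replicates))
                         cfg$schedule$replicates else replicates)
      s <- summarize_deltas(run$records, report_years)
      cbind(data.table::as.data.table(point), s, dir = sub)
    }, error = function(e) {
      warning("grid point ", i, " (", label, ") failed: ",
              conditionMessage(e))
      NULL
    })
  }
  data.table::rbindlist(out[!vapply(out, is.null, logical(1))],
                        fill = TRUE)
}

#' Allele-frequency change since introduction
#'
#' For each requested number of years after introduction, the cross-replicate
#' mean of `pA` and `pB` at that year and its difference from the
#' introduction-year mean.
#'
#' @param records Row-bound [run_simulation()] records.
#' @param report_years Years since introduction to report.
#' @return A [data.table::data.table] with one row per available report year.
#' @export
summarize_deltas <- function(records, report_years = c(150L, 250L, 300L,
                                                       1000L)) {
  years_post <- pA <- pB <- NULL # data.table NSE
  fish_rows <- records[!is.na(years_post)]
  if (nrow(fish_rows) == 0L) stop("records contain no post-introduction rows")
  by_year <- fish_rows[, list(mean_pA = mean(pA), mean_pB = mean(pB)),
                       by = years_post]
  p0 <- by_year[years_post == 0L]
  if (nrow(p0) != 1L) stop("introduction year missing from records")
  keep <- by_year[years_post %in% report_years]
  keep[, `:=`(delta_pA = keep$mean_pA - p0$mean_pA,
              delta_pB = keep$mean_pB - p0$mean_pB)]
  keep[]
}
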