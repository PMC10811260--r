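#' Duration of a treatment window
#'
#' Days from the installation of the rain-out shelters to their removal,
#' `end_doy - start_doy` (the start day is excluded from the count, the end
#' day included — the convention under which a window opened on DOY 134 and
#' closed on DOY 184 lasts 50 days).
#'
#' @param start_doy,end_doy day-of-year bounds of the window.
#' @return integer number of days.
#' @examples
#' drought_window_duration(134, 184)  # 50
#' drought_window_duration(134, 203)  # 69
#' @export
drought_window_duration <- function(start_doy, end_doy) {
  if (any(end_doy <= start_doy)) stop("end_doy must exceed start_doy")
  as.integer(end_doy - start_doy)
}

#' Demo season timeline
#'
#' Management timeline of the bundled demo trial, one of two seasons of a
#' red clover rain-out-shelter experiment: four cuts per season, a drought
#' window opened at the first cut, and the irrigation events applied to each
#' field.
#'
#' @param year season 1 or 2.
#' @return list: year, cut_doys, drought_window (`c(start, end)`),
#'   irrigation (list of data.frames per field with doy, amount in mm).
#' @export
demo_timeline <- function(year = 1) {
  if (year == 1) {
    list(year = 1, cut_doys = c(134, 185, 232, 277),
         drought_window = c(134, 184),
         irrigation = list(
           control = data.frame(doy = c(144, 152, 167),
                                amount = c(23, 23, 23)),
           drought = data.frame(doy = c(185, 191), amount = c(10, 10))))
  } else if (year == 2) {
    list(year = 2, cut_doys = c(134, 198, 246, 290),
         drought_window = c(134, 203),
         irrigation = list(
           control = data.frame(doy = c(143, 152), amount = c(23, 23)),
           drought = data.frame(doy = c(204, 219, 224),
                                amount = c(23, 29, 32))))
  } else stop("year must be 1 or 2")
}

#' Default pipeline configuration
#'
#' A complete configuration for a synthetic end-to-end run, sized for quick
#' demonstration (small panel, small grid). Every entry can be overridden;
#' see [validate_config()] for the invariants.
#'
#' @param panel_size accessions including the control.
#' @param geometry list blocks/columns/rows per field.
#' @param reps,control_reps replication (grid must fill exactly:
#'   `(panel_size - 1) * reps + control_reps = blocks * columns * rows`).
#' @param year season (selects the demo timeline).
#' @param seed master seed.
#' @param ... overrides for `sim` ([sim_params()] arguments), `qc`
#'   ([qc_rules()] arguments), `target_size`, `pca_keep`,
#'   `select_structure`.
#' @return list of class `pipeline_config`.
#' @export
default_config <- function(panel_size = 60,
                           geometry = list(blocks = 3, columns = 2,
                                           rows = 21),
                           reps = 2, control_reps = 8, year = 1, seed = 1,
                           ...) {
  tl <- demo_timeline(year)
  cfg <- list(panel_size = panel_size, geometry = geometry, reps = reps,
              control_id = "CTRL", control_reps = control_reps,
              season_doys = 1:300, timeline = tl, seed = seed,
              sim = list(year = year),
              qc = list(),
              target_size = 15, pca_keep = NULL, select_structure = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks design arithmetic (exact grid fill), the season timeline (drought
#' window inside the season, strictly increasing cut DOYs) and irrigation
#' amounts. Returns all violations rather than stopping at the first.
#'
#' @param cfg a [default_config()]-style list.
#' @return data.frame with columns `field` and `problem`; zero rows iff
#'   valid.
#' @export
validate_config <- function(cfg) {
  bad <- list()
  note <- function(field, problem) {
    bad[[length(bad) + 1L]] <<- data.frame(field = field, problem = problem,
                                           stringsAsFactors = FALSE)
  }
  g <- cfg$geometry
  cap <- g$blocks * g$columns * g$rows
  need <- (cfg$panel_size - 1L) * cfg$reps + cfg$control_reps
  if (cap != need) {
    note("geometry", sprintf("grid holds %d plots but design needs %d",
                             cap, need))
  }
  tl <- cfg$timeline
  season <- range(cfg$season_doys)
  if (tl$drought_window[1] < season[1] || tl$drought_window[2] > season[2]) {
    note("timeline", "drought window outside the season DOY range")
  }
  if (tl$drought_window[2] <= tl$drought_window[1]) {
    note("timeline", "drought window must end after it starts")
  }
  if (any(diff(tl$cut_doys) <= 0)) {
    note("timeline", "cut DOYs must be strictly increasing")
  }
  for (f in names(tl$irrigation)) {
    ir <- tl$irrigation[[f]]
    if (nrow(ir) > 0 && any(ir$amount < 0)) {
      note("irrigation", paste0("negative irrigation amount (", f, ")"))
    }
    if (nrow(ir) > 0 && any(ir$doy < season[1] | ir$doy > season[2])) {
      note("irrigation", paste0("irrigation outside season (", f, ")"))
    }
  }
  if (length(bad) == 0L) {
    data.frame(field = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, bad)
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Orchestrates, from one configuration: design construction, trial
#' simulation, water-balance computation for both fields, QC filtering,
#' field-wise variance-component fits with BLUPs and heritability, the Yr
#' drought-response table with its Z-test trajectory, PCA, and the
#' top-quartile overlap ranking. Deterministic for a fixed config.
#'
#' @param cfg a [default_config()] list.
#' @param out_dir optional directory: stage outputs are written as CSV/JSON
#'   together with a manifest (seed, stage checksums).
#' @return list: design, truth, observations, weather, cwd (per field), qc
#'   report, fits (per field: blups + summary), yr, trajectory, pca,
#'   ranking, config.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL) {
  viol <- validate_config(cfg)
  if (nrow(viol) > 0L) {
    stop("invalid config: ",
         paste(viol$field, viol$problem, sep = ": ", collapse = "; "))
  }

  panel <- make_panel(cfg$panel_size, control_id = cfg$control_id,
                      seed = cfg$seed)
  design <- build_design(panel, cfg$geometry, reps = cfg$reps,
                         control_id = cfg$control_id,
                         control_reps = cfg$control_reps, seed = cfg$seed)

  params <- do.call(sim_params, cfg$sim)
  sim <- simulate_trial(design, params, seed = cfg$seed)

  tl <- cfg$timeline
  cwd <- list(
    control = compute_cwd(sim$weather, irrigation = tl$irrigation$control),
    drought = compute_cwd(sim$weather, irrigation = tl$irrigation$drought,
                          shelter_windows = list(tl$drought_window)))

  qc <- filter_observations(sim$observations, do.call(qc_rules, cfg$qc))

  fits <- list(
    control = fit_field(qc$table, "control",
                        select_structure = cfg$select_structure),
    drought = fit_field(qc$table, "drought",
                        select_structure = cfg$select_structure))

  yr <- yr_table(fits$control$blups, fits$drought$blups)
  traj <- yr_trajectory(yr, year = tl$year,
                        drought_windows = list(tl$drought_window))

  pca_mat <- if (is.null(cfg$pca_keep)) fits$control$blups else
    reduce_variables(fits$control$blups, keep = cfg$pca_keep)
  pca <- run_pca(pca_mat)

  growth_vars <- grep("^(CC|CH)_", colnames(fits$control$blups),
                      value = TRUE)
  ranking <- rank_overlap(fits$control$blups[, growth_vars, drop = FALSE],
                          fits$drought$blups[, growth_vars, drop = FALSE],
                          target_size = cfg$target_size)

  out <- list(design = design, truth = sim$truth,
              observations = sim$observations, weather = sim$weather,
              cwd = cwd, qc_report = qc$report, fits = fits, yr = yr,
              trajectory = traj, pca = pca, ranking = ranking, config = cfg)
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  write_design_csv(res$design, file.path(out_dir, "design.csv"))
  w(res$observations, "observations.csv")
  w(res$weather, "weather.csv")
  w(res$cwd$control, "cwd_control.csv")
  w(res$cwd$drought, "cwd_drought.csv")
  w(res$qc_report, "qc_report.csv")
  for (f in names(res$fits)) {
    w(res$fits[[f]]$summary, paste0("fit_summary_", f, ".csv"))
    w(data.frame(accession_id = rownames(res$fits[[f]]$blups),
                 res$fits[[f]]$blups, check.names = FALSE),
      paste0("blups_", f, ".csv"))
  }
  w(data.frame(accession_id = rownames(res$yr), res$yr,
               check.names = FALSE), "yr.csv")
  w(res$trajectory, "yr_trajectory.csv")
  w(data.frame(variable = rownames(res$pca$loadings), res$pca$loadings,
               check.names = FALSE), "pca_loadings.csv")
  ov <- res$ranking$overlap
  w(data.frame(n_control = ov$n_control, n_drought = ov$n_drought,
               n_both = ov$n_both,
               fraction_of_control = ov$fraction_of_control),
    "ranking_overlap.csv")
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(seed = res$config$seed,
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config` list (validated with [validate_config()]).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}
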