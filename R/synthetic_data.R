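#' Simulation parameters for a synthetic trial
#'
#' Bundles the generating parameters of a synthetic two-field trial. The
#' defaults emulate the structure of a rain-out-shelter drought experiment on
#' a red clover accession panel: accession (genetic) random effects,
#' block/column/row spatial effects, a time-varying proportional drought
#' effect with optional genotype-by-treatment interaction, maturity-driven
#' height boosts during flowering windows, bounded canopy cover, and a
#' crop water stress index that rises under drought.
#'
#' Variance components are on the trait scale for CH and CWSI (identity
#' link) and on the logit scale for CC (which is generated through a scaled
#' logit link so values stay in [0, 100] and treatment effects act
#' multiplicatively near the bounds).
#'
#' @param variance_components named list per variable, each a list with
#'   `V_G`, `V_block`, `V_column`, `V_row`, `V_R` (squared trait/link units).
#' @param trait_baselines named list per variable of functions `f(doy)`
#'   giving the mean trajectory (natural scale: CC %, CH cm, CWSI unitless).
#' @param doys named list per variable of observation days of year.
#' @param drought_effect function `delta(doy)` in [0, 1]: proportional
#'   reduction imposed on CC and CH in the drought field at that DOY.
#' @param cwsi_drought_shift additive increase of CWSI in the drought field
#'   while `delta(doy) > 0` (stress raises canopy temperature).
#' @param gxe_sd standard deviation of the per-accession treatment
#'   sensitivity s_i (multiplier `1 + s_i` on the log-scale drought term).
#' @param early_fraction proportion of early-maturity (flowering) accessions.
#' @param flowering_ch_boost cm added to CH of early accessions inside
#'   `flowering_windows`.
#' @param flowering_windows list of `c(start, end)` DOY intervals.
#' @param fld_mean,fld_sd distribution of flowering DOY for early accessions.
#' @param fld_flower_prob probability that a plot of an early accession
#'   actually flowers (others carry the non-flowering code).
#' @param nonflowering_code FLD code for plots that never flowered.
#' @param fault_rate proportion of plot-by-variable cells made faulty.
#' @param outlier_offset value shift applied to `outlier` faults.
#' @param year trial year label attached to observations.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(
    variance_components = list(
      CC   = list(V_G = 0.16, V_block = 0.01, V_column = 0.01,
                  V_row = 0.005, V_R = 0.04),
      CH   = list(V_G = 9, V_block = 1, V_column = 0.5, V_row = 0.25,
                  V_R = 4),
      CWSI = list(V_G = 0.004, V_block = 0.0005, V_column = 0.0005,
                  V_row = 0.0002, V_R = 0.002)),
    trait_baselines = list(
      CC   = function(doy) {
        t <- doy - .last_cut(doy)                    # regrowth since cut
        20 + 70 / (1 + exp(-(t - 18) / 8))
      },
      CH   = function(doy) {
        t <- doy - .last_cut(doy)
        7 + 28 * (1 - exp(-t / 25))
      },
      CWSI = function(doy) 0.25),
    doys = list(CC = c(165, 178, 205, 225, 256, 273),
                CH = c(165, 178, 205, 225, 256, 273),
                CWSI = 206),
    drought_effect = function(doy) {
      ifelse(doy >= 134 & doy <= 205, 0.35 * pmin((doy - 134) / 30, 1), 0)
    },
    cwsi_drought_shift = 0.28,
    gxe_sd = 0.1,
    early_fraction = 0.5,
    flowering_ch_boost = 10,
    flowering_windows = list(c(150, 185)),
    fld_mean = 160, fld_sd = 10, fld_flower_prob = 0.8,
    nonflowering_code = 222,
    fault_rate = 0,
    outlier_offset = 1e3,
    year = 1) {
  p <- list(variance_components = variance_components,
            trait_baselines = trait_baselines, doys = doys,
            drought_effect = drought_effect,
            cwsi_drought_shift = cwsi_drought_shift,
            gxe_sd = gxe_sd, early_fraction = early_fraction,
            flowering_ch_boost = flowering_ch_boost,
            flowering_windows = flowering_windows,
            fld_mean = fld_mean, fld_sd = fld_sd,
            fld_flower_prob = fld_flower_prob,
            nonflowering_code = nonflowering_code,
            fault_rate = fault_rate, outlier_offset = outlier_offset,
            year = year)
  for (v in names(p$variance_components)) {
    if (any(unlist(p$variance_components[[v]]) < 0))
      stop("negative variance component for ", v)
  }
  if (p$early_fraction < 0 || p$early_fraction > 1)
    stop("early_fraction must be in [0, 1]")
  if (p$fault_rate < 0 || p$fault_rate >= 1)
    stop("fault_rate must be in [0, 1)")
  class(p) <- "sim_params"
  p
}

#' Simulate a daily weather series
#'
#' Generates one record per day of year: mean temperature, precipitation,
#' reference evapotranspiration (ET0) and shortwave radiation. ET0 follows a
#' seasonal gamma model whose daily mean over the simulated range equals
#' `et0_mean`; precipitation is a Bernoulli-gamma mixture.
#'
#' @param doy_range integer vector of days of year to simulate.
#' @param et0_mean mean daily ET0 (mm) over `doy_range`.
#' @param et0_shape gamma shape of daily ET0 (larger = less day-to-day
#'   noise).
#' @param rain_prob probability that a given day has rain.
#' @param rain_mean mean rainfall amount (mm) on rain days.
#' @param year year label.
#' @param seed integer seed.
#' @return data.frame of class `weather_series`: year, doy, tmean,
#'   precipitation, et0, radiation.
#' @export
simulate_weather <- function(doy_range = 1:300, et0_mean = 2.5,
                             et0_shape = 8, rain_prob = 0.35,
                             rain_mean = 5, year = 1, seed = 1) {
  stopifnot(all(doy_range >= 1 & doy_range <= 366))
  set.seed(as.integer(seed))
  n <- length(doy_range)
  season <- 1 + 0.8 * sin((doy_range - 80) * 2 * pi / 366)
  season <- pmax(season, 0.05)
  et0_profile <- et0_mean * season / mean(season)   # mean exactly et0_mean
  et0 <- stats::rgamma(n, shape = et0_shape,
                       scale = et0_profile / et0_shape)
  rain <- stats::rbinom(n, 1L, rain_prob) *
    stats::rgamma(n, shape = 1.2, scale = rain_mean / 1.2)
  tmean <- 10.5 + 8 * sin((doy_range - 105) * 2 * pi / 366) +
    stats::rnorm(n, 0, 2)
  rad <- pmax(2 + 16 * pmax(sin((doy_range - 80) * 2 * pi / 366), 0) +
                stats::rnorm(n, 0, 2), 0.5)
  structure(data.frame(year = year, doy = doy_range, tmean = tmean,
                       precipitation = rain, et0 = et0, radiation = rad),
            class = c("weather_series", "data.frame"))
}

#' Simulate a complete two-field trial with known ground truth
#'
#' Generates a long-format phenotype table for every plot of a trial design.
#' For a variable v observed at day t on plot p (field f, block b, column c,
#' row r) of accession i, the signal is
#' `mu_v(t) + g_i + u_b + u_c + u_r` on the link scale (identity for CH and
#' CWSI, scaled logit for CC). In the drought field, CC and CH are reduced by
#' the factor `(1 - delta(t))^(1 + s_i)` (applied on the logit scale for CC
#' as an additive `log(1 - delta) (1 + s_i)` shift), and CWSI is raised by
#' `cwsi_drought_shift` while `delta(t) > 0`. Early-maturity accessions get
#' `flowering_ch_boost` added to CH inside the flowering windows, producing
#' the bimodal height distribution typical of mixed-maturity panels.
#' Residual noise is added on the link scale for CC (values then mapped back
#' to [0, 100]) and on the trait scale otherwise.
#'
#' @param design a `trial_design` from [build_design()].
#' @param params a `sim_params` list.
#' @param seed integer seed; substreams for effects, flowering, noise and
#'   faults are derived from it so runs are reproducible.
#' @return list with `observations` (long-format data.frame: plot_id, field,
#'   block, column, row, accession_id, variable, year, doy, value, flag),
#'   `weather` (a `weather_series`), and `truth` (generating effects:
#'   genetic effects per variable, treatment sensitivities, spatial effects,
#'   early-maturity flags, fault records, the parameter set).
#' @export
simulate_trial <- function(design, params = sim_params(), seed = 1) {
  viol <- validate_design(design)
  if (nrow(viol) > 0L) {
    stop("invalid design: ", paste(viol$type, collapse = ", "))
  }
  set.seed(as.integer(seed))
  sub <- stats::setNames(sample.int(.Machine$integer.max, 5L),
                         c("effects", "flowering", "noise", "faults",
                           "weather"))

  plots <- design$plots[!design$plots$is_border, , drop = FALSE]
  acc <- sort(unique(plots$accession_id))
  vars <- names(params$variance_components)

  set.seed(sub[["effects"]])
  g <- sapply(vars, function(v)
    stats::rnorm(length(acc), 0, sqrt(params$variance_components[[v]]$V_G)))
  rownames(g) <- acc
  s_i <- stats::setNames(stats::rnorm(length(acc), 0, params$gxe_sd), acc)
  spatial <- list()
  for (f in c("control", "drought")) {
    for (v in vars) {
      vc <- params$variance_components[[v]]
      spatial[[f]][[v]] <- list(
        block = stats::rnorm(design$geometry$blocks, 0, sqrt(vc$V_block)),
        column = stats::rnorm(design$geometry$blocks * design$geometry$columns,
                              0, sqrt(vc$V_column)),
        row = stats::rnorm(design$geometry$rows, 0, sqrt(vc$V_row)))
    }
  }

  set.seed(sub[["flowering"]])
  n_early <- round(params$early_fraction * length(acc))
  early <- stats::setNames(rep(FALSE, length(acc)), acc)
  early[sample(acc, n_early)] <- TRUE

  set.seed(sub[["noise"]])
  obs <- list()
  for (v in vars) {
    vc <- params$variance_components[[v]]
    for (t in params$doys[[v]]) {
      base <- params$trait_baselines[[v]](t)
      delta <- params$drought_effect(t)
      col_idx <- (plots$block - 1L) * design$geometry$columns + plots$column
      eta <- g[plots$accession_id, v] +
        vapply(seq_len(nrow(plots)), function(k) {
          sp <- spatial[[plots$field[k]]][[v]]
          sp$block[plots$block[k]] + sp$column[col_idx[k]] +
            sp$row[plots$row[k]]
        }, 0)
      drought <- plots$field == "drought"
      sens <- 1 + s_i[plots$accession_id]
      eps <- stats::rnorm(nrow(plots), 0, sqrt(vc$V_R))
      if (v == "CC") {
        z <- .logit(base / 100) + eta +
          ifelse(drought & delta > 0, log(1 - delta) * sens, 0) + eps
        value <- 100 * stats::plogis(z)
      } else if (v == "CWSI") {
        value <- base + eta +
          ifelse(drought & delta > 0, params$cwsi_drought_shift, 0) + eps
      } else { # CH and other identity-link traits: proportional reduction
        mu <- base + eta
        if (v == "CH") {
          inwin <- any(vapply(params$flowering_windows,
                              function(w) t >= w[1] && t <= w[2], TRUE))
          if (inwin) {
            mu <- mu + params$flowering_ch_boost *
              early[plots$accession_id]
          }
        }
        value <- mu * ifelse(drought & delta > 0,
                             (1 - delta)^sens, 1) + eps
      }
      obs[[length(obs) + 1L]] <- data.frame(
        plots[, c("plot_id", "field", "block", "column", "row",
                  "accession_id")],
        variable = v, year = params$year, doy = t, value = value,
        flag = "ok", stringsAsFactors = FALSE)
    }
  }

  # flowering observations (FLD), control field, first growth period
  fld_plots <- plots[plots$field == "control", , drop = FALSE]
  is_early <- early[fld_plots$accession_id]
  flowers <- is_early &
    stats::runif(nrow(fld_plots)) < params$fld_flower_prob
  fld_val <- ifelse(flowers,
                    pmin(round(stats::rnorm(nrow(fld_plots), params$fld_mean,
                                            params$fld_sd)),
                         params$nonflowering_code - 1),
                    params$nonflowering_code)
  obs[[length(obs) + 1L]] <- data.frame(
    fld_plots[, c("plot_id", "field", "block", "column", "row",
                  "accession_id")],
    variable = "FLD", year = params$year, doy = 130, value = fld_val,
    flag = "ok", stringsAsFactors = FALSE)

  table <- do.call(rbind, obs)
  rownames(table) <- NULL

  truth <- list(genetic_effects = g, sensitivities = s_i,
                spatial_effects = spatial, early = early,
                faults = NULL, params = params, seed = as.integer(seed))

  if (params$fault_rate > 0) {
    table <- inject_faults(table, params$fault_rate, seed = sub[["faults"]],
                           outlier_offset = params$outlier_offset)
    truth$faults <- attr(table, "fault_truth")
  }

  weather <- simulate_weather(seed = sub[["weather"]], year = params$year)
  list(observations = table, weather = weather, truth = truth)
}

.logit <- function(p) log(p / (1 - p))

# most recent mowing DOY before `doy` (demo season: four cuts); growth
# starts from the season start before the first cut
.last_cut <- function(doy, cuts = c(110, 134, 185, 232, 277)) {
  vapply(doy, function(d) {
    prev <- cuts[cuts < d]
    if (length(prev) == 0L) cuts[1] else max(prev)
  }, 0)
}

#' Inject plot faults into a phenotype table
#'
#' Emulates the faulty plots a field trial accumulates: plots where the crop
#' never established, plots damaged (e.g. by herbivores), and measurement
#' outliers. A proportion `fault_rate` of plot-by-variable cells is sampled;
#' each receives one of the three fault types with equal probability.
#' `not_established` and `damaged` set the observation flag (as field notes
#' would); `outlier` faults shift the value by `outlier_offset` but leave the
#' flag at `"ok"` so that statistical QC has something to detect. All faults
#' are recorded in the `fault_truth` attribute.
#'
#' @param table long-format observation data.frame (plot_id, variable, ...).
#' @param fault_rate proportion of (plot, variable) cells to perturb.
#' @param seed integer seed.
#' @param outlier_offset value added to outlier cells.
#' @return the table with flags/values modified and a `fault_truth`
#'   attribute (data.frame: plot_id, variable, fault).
#' @export
inject_faults <- function(table, fault_rate, seed = 1,
                          outlier_offset = 1e3) {
  stopifnot(fault_rate >= 0, fault_rate < 1)
  if (fault_rate == 0) {
    attr(table, "fault_truth") <- data.frame(plot_id = character(),
                                             variable = character(),
                                             fault = character())
    return(table)
  }
  set.seed(as.integer(seed))
  cells <- unique(table[, c("plot_id", "variable")])
  n_fault <- stats::rbinom(1L, nrow(cells), fault_rate)
  idx <- sample(nrow(cells), n_fault)
  faults <- cells[idx, , drop = FALSE]
  faults$fault <- sample(c("not_established", "damaged", "outlier"),
                         n_fault, replace = TRUE)
  for (k in seq_len(nrow(faults))) {
    rows <- table$plot_id == faults$plot_id[k] &
      table$variable == faults$variable[k]
    if (faults$fault[k] == "outlier") {
      table$value[rows] <- table$value[rows] + outlier_offset
    } else {
      table$flag[rows] <- faults$fault[k]
    }
  }
  rownames(faults) <- NULL
  attr(table, "fault_truth") <- faults
  table
}
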