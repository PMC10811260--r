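#' Compose and parse time-stamped variable names
#'
#' Observed variables are named by their abbreviation followed by the day of
#' year, e.g. `CC_178` for canopy cover measured on DOY 178. `parse_variable`
#' inverts the naming.
#'
#' @param variable variable abbreviation (e.g. `"CC"`, `"CH"`, `"CWSI"`).
#' @param doy integer day of year in 1..366.
#' @return `name_variable`: the `"VAR_DOY"` string. `parse_variable`: a list
#'   with `variable` and `doy`.
#' @examples
#' name_variable("CC", 178)     # "CC_178"
#' parse_variable("CH_165")     # list(variable = "CH", doy = 165)
#' @export
name_variable <- function(variable, doy) {
  if (any(doy < 1 | doy > 366 | doy != round(doy))) {
    stop("invalid DOY: ", paste(doy[doy < 1 | doy > 366 | doy != round(doy)],
                                collapse = ", "))
  }
  paste0(variable, "_", as.integer(doy))
}

#' @rdname name_variable
#' @param name a `"VAR_DOY"` string.
#' @export
parse_variable <- function(name) {
  m <- regmatches(name, regexec("^(.+)_([0-9]+)$", name))[[1]]
  if (length(m) != 3L) stop("cannot parse variable name '", name, "'")
  doy <- as.integer(m[3])
  if (doy < 1 || doy > 366) stop("invalid DOY in '", name, "'")
  list(variable = m[2], doy = doy)
}

#' QC rules for observation filtering
#'
#' @param iqr_multiplier values outside `median +/- k * IQR` within a
#'   variable x field x year x DOY stratum are excluded as outliers
#'   (default k = 3; conservative, to avoid trimming genuine genetic tails).
#' @param drop_flags observation flags that exclude a (plot, variable) cell.
#' @param plot_level_flags flags that exclude the whole plot for all
#'   variables (a plot where the crop never established has no valid
#'   observation of any kind).
#' @return list of class `qc_rules`.
#' @export
qc_rules <- function(iqr_multiplier = 3,
                     drop_flags = c("not_established", "damaged", "missing"),
                     plot_level_flags = "not_established") {
  structure(list(iqr_multiplier = iqr_multiplier, drop_flags = drop_flags,
                 plot_level_flags = plot_level_flags), class = "qc_rules")
}

#' Filter faulty plots and statistical outliers
#'
#' Applies the trial's QC policy to a long-format observation table:
#' \enumerate{
#'   \item plots carrying a plot-level flag (crop not established) are
#'     excluded for \emph{all} variables;
#'   \item observations carrying any other drop flag (damage, missing) are
#'     excluded for that variable;
#'   \item remaining values are screened per variable x field x year x DOY
#'     stratum: values outside `median +/- k * IQR` are excluded as
#'     outliers. The rule is iterated to a fixed point, which makes the
#'     filter idempotent.
#' }
#'
#' @param table long-format data.frame with at least plot_id, variable,
#'   year, doy, value, flag (field column used for stratification when
#'   present).
#' @param rules a [qc_rules()] list.
#' @return list with `table` (retained rows, flags untouched) and `report`
#'   (data.frame per variable: n_input, n_retained, and exclusion counts by
#'   reason).
#' @export
filter_observations <- function(table, rules = qc_rules()) {
  stopifnot(all(c("plot_id", "variable", "value", "flag") %in% names(table)))
  tab <- table
  reason <- rep(NA_character_, nrow(tab))

  bad_plots <- unique(tab$plot_id[tab$flag %in% rules$plot_level_flags])
  reason[tab$plot_id %in% bad_plots] <- "not_established_plot"
  cell_drop <- is.na(reason) & tab$flag %in% rules$drop_flags
  reason[cell_drop] <- tab$flag[cell_drop]

  strat_cols <- intersect(c("variable", "field", "year", "doy"), names(tab))
  strat <- interaction(tab[strat_cols], drop = TRUE)
  repeat {
    changed <- FALSE
    for (s in levels(strat)) {
      in_s <- strat == s & is.na(reason)
      v <- tab$value[in_s]
      if (sum(!is.na(v)) < 4L) next
      med <- stats::median(v, na.rm = TRUE)
      iqr <- stats::IQR(v, na.rm = TRUE, type = 7)
      lim <- rules$iqr_multiplier * iqr
      out <- !is.na(v) & (v < med - lim | v > med + lim)
      if (any(out)) {
        reason[which(in_s)[out]] <- "outlier"
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  keep <- is.na(reason)
  report <- do.call(rbind, lapply(unique(tab$variable), function(v) {
    in_v <- tab$variable == v
    data.frame(
      variable = v,
      n_input = sum(in_v),
      n_retained = sum(in_v & keep),
      n_not_established = sum(in_v & !keep &
                                reason == "not_established_plot",
                              na.rm = TRUE),
      n_damaged = sum(in_v & !keep & reason == "damaged", na.rm = TRUE),
      n_missing = sum(in_v & !keep & reason == "missing", na.rm = TRUE),
      n_outlier = sum(in_v & !keep & reason == "outlier", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  out_tab <- tab[keep, , drop = FALSE]
  rownames(out_tab) <- NULL
  list(table = out_tab, report = report)
}

#' Correlate ground and UAV canopy height
#'
#' Pairs each ground (rising plate meter, `CH_rpm`) measurement date with the
#' nearest UAV (`CH`) date within `max_gap_days` per field and year, and
#' reports the per-pair Pearson correlation over common plots. Ties in date
#' distance are broken toward the earlier UAV date. Pairs without a UAV date
#' inside the window, or with fewer than 3 common plots, are listed with
#' `r = NA`.
#'
#' @param table long-format observation data.frame containing both `CH` and
#'   `CH_rpm` variables.
#' @param max_gap_days maximum allowed date distance (default 7).
#' @param ground,uav variable codes of the two height sources.
#' @return data.frame: field, year, doy_ground, doy_uav, gap, n, r; with the
#'   mean of defined r values in attribute `mean_r`.
#' @export
correlate_ground_uav <- function(table, max_gap_days = 7,
                                 ground = "CH_rpm", uav = "CH") {
  stopifnot(all(c(ground, uav) %in% table$variable))
  res <- list()
  groups <- unique(table[, intersect(c("field", "year"), names(table)),
                         drop = FALSE])
  for (gi in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(table))
    for (cn in names(groups)) sel <- sel & table[[cn]] == groups[[cn]][gi]
    sub <- table[sel, , drop = FALSE]
    gdates <- sort(unique(sub$doy[sub$variable == ground]))
    udates <- sort(unique(sub$doy[sub$variable == uav]))
    for (gd in gdates) {
      gap <- abs(udates - gd)
      ud <- NA_integer_; n <- 0L; r <- NA_real_
      if (length(udates) > 0L && min(gap) <= max_gap_days) {
        cand <- udates[gap == min(gap)]
        ud <- min(cand)   # tie toward the earlier UAV date
        a <- sub[sub$variable == ground & sub$doy == gd,
                 c("plot_id", "value")]
        b <- sub[sub$variable == uav & sub$doy == ud,
                 c("plot_id", "value")]
        common <- intersect(a$plot_id, b$plot_id)
        n <- length(common)
        if (n >= 3L) {
          r <- stats::cor(a$value[match(common, a$plot_id)],
                          b$value[match(common, b$plot_id)])
        }
      }
      row <- groups[gi, , drop = FALSE]
      row$doy_ground <- gd
      row$doy_uav <- ud
      row$gap <- if (is.na(ud)) NA_integer_ else abs(ud - gd)
      row$n <- n
      row$r <- r
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  out
}
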