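#' Relative drought performance index Yr
#'
#' For each accession, `Yr = (Control - Drought) / Control` on the
#' per-accession trait values of the two fields (BLUPs from the field-wise
#' model fits by default). A positive Yr means the accession's value was
#' lower under drought; negative means it exceeded the control, and the
#' index is not clamped. Accessions whose control value falls below the
#' denominator guard (|C| < `guard_frac` times the median |C|) get `NA`
#' instead of an explosive ratio.
#'
#' @param control,drought named numeric vectors of per-accession values for
#'   one variable; matched by name.
#' @param guard_frac denominator guard as a fraction of the median absolute
#'   control value (default 0.01).
#' @return named numeric vector of Yr with attribute `n_guarded`.
#' @examples
#' compute_yr(c(a = 100, b = 50), c(a = 60, b = 60))  # 0.4, -0.2
#' @export
compute_yr <- function(control, drought, guard_frac = 0.01) {
  acc <- intersect(names(control), names(drought))
  C <- control[acc]; D <- drought[acc]
  guard <- guard_frac * stats::median(abs(C), na.rm = TRUE)
  bad <- !is.na(C) & abs(C) < guard
  yr <- (C - D) / C
  yr[bad] <- NA_real_
  attr(yr, "n_guarded") <- sum(bad)
  yr
}

#' Two-sided Z-test of a mean against zero
#'
#' Tests whether the average index over accessions differs from zero:
#' `z = mean / (sd / sqrt(n))` with the sample standard deviation (large-n
#' normal approximation), two-sided p from the standard normal, and
#' significance stars at p < 0.05 / 0.01 / 0.001.
#'
#' @param values numeric vector (NAs dropped).
#' @return list: n, mean, sd, z, p, stars (`""`, `"*"`, `"**"`, `"***"`);
#'   z/p are `NA` with a `degenerate` note when n < 3 or sd = 0.
#' @export
ztest_mean_vs_zero <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  m <- mean(v); s <- stats::sd(v)
  if (n < 3L || !isTRUE(s > 0)) {
    return(list(n = n, mean = if (n > 0) m else NA_real_, sd = s,
                z = NA_real_, p = NA_real_, stars = "",
                degenerate = if (n < 3L) "n < 3" else "sd = 0"))
  }
  z <- m / (s / sqrt(n))
  p <- 2 * stats::pnorm(-abs(z))
  list(n = n, mean = m, sd = s, z = z, p = p, stars = .p_stars(p),
       degenerate = NULL)
}

.p_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Yr matrix for all shared variables of two BLUP matrices
#'
#' Columns are named `Yr_VAR_DOY` (e.g. `Yr_CC_178`).
#'
#' @param blups_control,blups_drought matrices (accessions x VAR_DOY
#'   variables) as returned by [fit_field()].
#' @param guard_frac see [compute_yr()].
#' @return matrix accessions x Yr variables.
#' @export
yr_table <- function(blups_control, blups_drought, guard_frac = 0.01) {
  vars <- intersect(colnames(blups_control), colnames(blups_drought))
  if (length(vars) == 0L) stop("no shared variables between the two fields")
  acc <- intersect(rownames(blups_control), rownames(blups_drought))
  out <- sapply(vars, function(v) {
    compute_yr(stats::setNames(blups_control[acc, v], acc),
               stats::setNames(blups_drought[acc, v], acc),
               guard_frac = guard_frac)
  })
  colnames(out) <- paste0("Yr_", vars)
  rownames(out) <- acc
  out
}

#' Mean-Yr trajectory over the season with Z-test annotations
#'
#' Summarizes a Yr matrix into one row per (year, variable, DOY), ordered by
#' DOY within variable: the accession count, mean and SD of Yr, the Z
#' statistic, p-value and significance stars. Optionally annotates which
#' observations fall inside the drought window(s).
#'
#' @param yr matrix from [yr_table()] (columns `Yr_VAR_DOY`).
#' @param year year label for the output.
#' @param drought_windows optional list of `c(start, end)` DOY intervals.
#' @return data.frame: year, variable, doy, n, mean_yr, sd, z, p, stars,
#'   in_drought.
#' @export
yr_trajectory <- function(yr, year = 1, drought_windows = NULL) {
  stopifnot(ncol(yr) >= 1L)
  rows <- lapply(colnames(yr), function(cn) {
    pv <- parse_variable(sub("^Yr_", "", cn))
    zt <- ztest_mean_vs_zero(yr[, cn])
    in_win <- if (is.null(drought_windows)) NA else
      any(vapply(drought_windows,
                 function(w) pv$doy >= w[1] && pv$doy <= w[2], TRUE))
    data.frame(year = year, variable = pv$variable, doy = pv$doy,
               n = zt$n, mean_yr = zt$mean, sd = zt$sd, z = zt$z, p = zt$p,
               stars = zt$stars, in_drought = in_win,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$variable, out$doy), , drop = FALSE]
  rownames(out) <- NULL
  out
}
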