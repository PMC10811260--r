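#' Canopy cover of a plot
#'
#' Percentage of the plot polygon covered by vegetation: `100 *`
#' (vegetation pixels) / (total pixels). The vegetation mask is an input;
#' see [mask_excess_green()] for a simple RGB-based helper.
#'
#' @param vegetation_mask logical matrix, `TRUE` where a pixel is vegetation.
#' @return canopy cover in percent, in [0, 100].
#' @examples
#' m <- matrix(c(rep(TRUE, 37), rep(FALSE, 63)), 10, 10)
#' compute_canopy_cover(m)  # 37
#' @export
compute_canopy_cover <- function(vegetation_mask) {
  stopifnot(is.logical(vegetation_mask))
  n <- length(vegetation_mask)
  if (n == 0L) stop("plot polygon contains zero pixels")
  100 * sum(vegetation_mask, na.rm = TRUE) / n
}

#' Canopy height of a plot (quantile summary)
#'
#' Summarizes per-pixel canopy height above soil over the vegetation pixels
#' of a plot as the `q`-th quantile (default Q90). Quantiles use the
#' linear-interpolation definition between order statistics
#' (`stats::quantile` type 7); the convention is fixed because quantile
#' definitions differ across tools.
#'
#' @param height_grid numeric matrix of height above soil (cm) per pixel.
#' @param vegetation_mask logical matrix of the same shape.
#' @param q quantile in (0, 1]; default 0.90.
#' @return height in cm, or `NA` if the mask has no vegetation pixel.
#' @export
compute_canopy_height <- function(height_grid, vegetation_mask, q = 0.90) {
  stopifnot(identical(dim(height_grid), dim(vegetation_mask)),
            q > 0, q <= 1)
  h <- height_grid[vegetation_mask]
  h <- h[is.finite(h)]
  if (length(h) == 0L) return(NA_real_)
  unname(stats::quantile(h, probs = q, type = 7))
}

#' Crop water stress index from canopy temperature
#'
#' The empirical CWSI normalizes canopy temperature between a fully
#' transpiring wet reference and a non-transpiring dry reference:
#' `CWSI = (Tc - Twet) / (Tdry - Twet)`. 0 means unstressed (canopy as cool
#' as the wet reference), 1 means no transpiration. Values falling outside
#' [0, 1] — possible with noisy references — are clamped, with a warning
#' reporting how many.
#'
#' @param tc numeric vector of plot canopy temperatures (deg C).
#' @param twet wet (fully transpiring) reference temperature.
#' @param tdry dry (non-transpiring) reference temperature; must exceed
#'   `twet`.
#' @return CWSI per plot, in [0, 1].
#' @export
compute_cwsi <- function(tc, twet, tdry) {
  if (!(tdry > twet)) {
    stop("dry reference (", tdry, ") must exceed wet reference (", twet, ")")
  }
  x <- (tc - twet) / (tdry - twet)
  n_out <- sum(x < 0 | x > 1, na.rm = TRUE)
  if (n_out > 0L) {
    warning(n_out, " CWSI value(s) outside [0, 1] clamped")
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Reference temperatures from a thermal scene
#'
#' When no measured wet/dry panels are available, picks the references as
#' percentiles of the scene's temperature distribution (default 1st and
#' 99th).
#'
#' @param scene_temperatures numeric vector of scene pixel/plot temperatures.
#' @param probs length-2 vector of percentiles for (wet, dry).
#' @return list with `twet` and `tdry`.
#' @export
scene_references <- function(scene_temperatures, probs = c(0.01, 0.99)) {
  qs <- stats::quantile(scene_temperatures, probs = probs, na.rm = TRUE,
                        type = 7)
  list(twet = unname(qs[1]), tdry = unname(qs[2]))
}

#' Cumulative water deficit from weather, irrigation and shelter windows
#'
#' Computes the daily water balance of a field and accumulates the deficit
#' from the season start: `CWD(t) = sum_{u <= t} (ET0(u) - P_eff(u) - I(u))`,
#' where effective precipitation `P_eff` is zero on days covered by a
#' rain-out shelter and station precipitation otherwise, and `I` is applied
#' irrigation. Deficit is signed positive (larger = drier).
#'
#' @param weather data.frame with columns `doy`, `precipitation`, `et0`
#'   (e.g. a [simulate_weather()] series).
#' @param irrigation data.frame with columns `doy`, `amount` (mm); may be
#'   empty or `NULL`.
#' @param shelter_windows list of `c(start, end)` DOY intervals during which
#'   precipitation is excluded; `NULL` for the un-sheltered control field.
#' @param start_doy DOY at which accumulation starts (default: first day of
#'   the weather series).
#' @return data.frame: doy, et0, precipitation_effective, irrigation, cwd.
#' @export
compute_cwd <- function(weather, irrigation = NULL, shelter_windows = NULL,
                        start_doy = min(weather$doy)) {
  stopifnot(all(c("doy", "precipitation", "et0") %in% names(weather)))
  w <- weather[order(weather$doy), , drop = FALSE]
  w <- w[w$doy >= start_doy, , drop = FALSE]

  irr <- rep(0, nrow(w))
  if (!is.null(irrigation) && nrow(irrigation) > 0L) {
    miss <- !(irrigation$doy %in% w$doy)
    if (any(miss)) {
      stop("irrigation event(s) outside the weather DOY range: ",
           paste(irrigation$doy[miss], collapse = ", "))
    }
    if (any(irrigation$amount < 0)) stop("negative irrigation amount")
    irr[match(irrigation$doy, w$doy)] <- irrigation$amount
  }

  p_eff <- w$precipitation
  if (!is.null(shelter_windows)) {
    for (win in shelter_windows) {
      p_eff[w$doy >= win[1] & w$doy <= win[2]] <- 0
    }
  }

  data.frame(doy = w$doy, et0 = w$et0, precipitation_effective = p_eff,
             irrigation = irr, cwd = cumsum(w$et0 - p_eff - irr))
}

#' Vegetation mask from an RGB raster by excess-green thresholding
#'
#' Convenience helper for RGB plot rasters: classifies a pixel as vegetation
#' when the excess-green index `2G - R - B` (on channels scaled to [0, 1])
#' exceeds a threshold. Supplied for exploration; the validated trait
#' extraction takes the mask as input.
#'
#' @param r,g,b numeric matrices of the red, green, blue channels in [0, 1].
#' @param threshold excess-green threshold (default 0.1).
#' @return logical matrix.
#' @export
mask_excess_green <- function(r, g, b, threshold = 0.1) {
  stopifnot(identical(dim(r), dim(g)), identical(dim(g), dim(b)))
  (2 * g - r - b) > threshold
}

#' Extract CC and CH for a set of plot rasters
#'
#' Applies [compute_canopy_cover()] and [compute_canopy_height()] to a list
#' of plot rasters and returns rows in the long observation format.
#'
#' @param rasters named list (by plot_id) of lists with `height_grid` and
#'   `vegetation_mask`.
#' @param doy,year observation time attached to the rows.
#' @param q quantile used for canopy height.
#' @return long-format data.frame: plot_id, variable, year, doy, value, flag.
#' @export
extract_plot_traits <- function(rasters, doy, year = 1, q = 0.90) {
  rows <- lapply(names(rasters), function(id) {
    pr <- rasters[[id]]
    cc <- compute_canopy_cover(pr$vegetation_mask)
    ch <- compute_canopy_height(pr$height_grid, pr$vegetation_mask, q = q)
    data.frame(plot_id = id, variable = c("CC", "CH"), year = year,
               doy = doy, value = c(cc, ch),
               flag = c("ok", if (is.na(ch)) "missing" else "ok"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
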