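#' The six candidate variance-component model structures
#'
#' Every candidate contains a random accession (genetic) effect; the spatial
#' terms Block, Column and Row enter in the combinations that avoid carrying
#' Block and Column simultaneously (columns are nested in blocks, so the full
#' base model would be overparameterized):
#' \enumerate{
#'   \item Accession
#'   \item Accession + Block
#'   \item Accession + Column
#'   \item Accession + Row
#'   \item Accession + Block + Row
#'   \item Accession + Column + Row
#' }
#'
#' @return list of six specs, each a list with `structure_id` and
#'   `random_terms`.
#' @export
vc_candidates <- function() {
  terms <- list(character(0), "block", "column", "row",
                c("block", "row"), c("column", "row"))
  lapply(seq_along(terms), function(i) {
    list(structure_id = i, random_terms = c("accession", terms[[i]]))
  })
}

#' Fit an intercept-plus-random-effects variance component model
#'
#' Fits `value ~ 1 + (1 | accession) [+ (1 | block) ...]` by restricted
#' maximum likelihood (REML, via \pkg{lme4}), with variance components
#' constrained non-negative. The spatial Column factor is coded as the
#' (block, column) pair — columns are nested in blocks — and Row by its
#' index shared across blocks (a positional effect). Boundary estimates
#' (a component shrunk to exactly 0) are reported as 0 and flagged.
#'
#' The AIC convention counts intercept + all variance components (including
#' the residual) as parameters, `AIC = -2 logLik_REML + 2 k`; all candidates
#' share the same intercept-only fixed part, so REML AICs are comparable
#' across them.
#'
#' @param data data.frame with columns accession, block, column, row, value
#'   (column is the within-block index 1..C).
#' @param spec one element of [vc_candidates()], or a character vector of
#'   random terms.
#' @param variable optional variable name carried into the result.
#' @return object of class `vc_fit`: list with variable, structure_id,
#'   random_terms, intercept, vc (named numeric: V_G, V_block, V_column,
#'   V_row — NA when absent — and V_R), accession_effects (named numeric
#'   u_i), logLik, AIC, n, boundary (logical), model (the merMod fit).
#' @export
fit_vc_model <- function(data, spec, variable = NA_character_) {
  if (is.character(spec)) spec <- list(structure_id = NA, random_terms = spec)
  stopifnot(all(c("accession", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  data$accession <- factor(data$accession)
  if (nlevels(data$accession) < 2L) {
    stop("need at least 2 accessions with observations")
  }
  terms <- spec$random_terms
  for (tm in setdiff(terms, "accession")) {
    if (!tm %in% names(data)) stop("factor '", tm, "' missing from data")
  }
  if ("column" %in% terms) {
    data$column_f <- factor(paste0("b", data$block, "_c", data$column))
  }
  if ("block" %in% terms) data$block_f <- factor(data$block)
  if ("row" %in% terms) data$row_f <- factor(data$row)

  fterms <- c("(1 | accession)",
              if ("block" %in% terms) "(1 | block_f)",
              if ("column" %in% terms) "(1 | column_f)",
              if ("row" %in% terms) "(1 | row_f)")
  for (fac in intersect(c("block_f", "column_f", "row_f"), names(data))) {
    if (nlevels(data[[fac]]) < 2L) {
      stop("factor '", fac, "' has a single level; cannot estimate its ",
           "variance")
    }
  }
  fml <- stats::as.formula(paste("value ~ 1 +",
                                 paste(fterms, collapse = " + ")))
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, data = data, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore",
                   optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10))),
      error = function(e) stop("model fit failed: ", conditionMessage(e))),
    message = function(m) invokeRestart("muffleMessage"))

  vcdf <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vcdf$vcov, vcdf$grp)
  vc <- c(V_G = unname(comp["accession"]),
          V_block = unname(comp["block_f"]),
          V_column = unname(comp["column_f"]),
          V_row = unname(comp["row_f"]),
          V_R = unname(comp["Residual"]))
  u <- lme4::ranef(fit)$accession
  k <- 1L + sum(!is.na(vc))   # intercept + variance components (incl. V_R)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(
    variable = variable,
    structure_id = spec$structure_id,
    random_terms = terms,
    intercept = unname(lme4::fixef(fit)[1]),
    vc = vc,
    accession_effects = stats::setNames(u[, 1], rownames(u)),
    logLik = ll,
    AIC = -2 * ll + 2 * k,
    n = nrow(data),
    boundary = !is.na(vc) & vc == 0,
    model = fit), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance-component fit",
      if (!is.na(x$variable)) paste0("(", x$variable, ")"), "\n")
  cat("  random terms:", paste(x$random_terms, collapse = " + "), "\n")
  cat("  intercept:", format(x$intercept, digits = 5), " n:", x$n, "\n")
  vc <- x$vc[!is.na(x$vc)]
  cat("  ", paste(names(vc), format(vc, digits = 4), sep = " = ",
                  collapse = ", "), "\n")
  cat("  AIC:", format(x$AIC, digits = 6), "\n")
  invisible(x)
}

#' Fit all six candidate structures for one variable
#'
#' Non-converging candidates are dropped (with a warning); at least one must
#' succeed.
#'
#' @inheritParams fit_vc_model
#' @return list of `vc_fit` objects.
#' @export
fit_vc_candidates <- function(data, variable = NA_character_) {
  fits <- lapply(vc_candidates(), function(sp) {
    tryCatch(fit_vc_model(data, sp, variable = variable),
             error = function(e) {
               warning("structure ", sp$structure_id, " failed: ",
                       conditionMessage(e))
               NULL
             })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all candidate fits failed")
  fits
}

#' Select the best fit by AIC
#'
#' Returns the fit with minimal AIC; exact ties are broken toward the
#' structure with fewer variance components.
#'
#' @param fits list of `vc_fit` objects.
#' @param tie_tol AICs within this distance of the minimum count as tied
#'   (default 1e-8, i.e. numerically exact ties only).
#' @return the selected `vc_fit`.
#' @export
select_vc_model <- function(fits, tie_tol = 1e-8) {
  if (length(fits) == 0L) stop("no converged fits to select from")
  aic <- vapply(fits, function(f) f$AIC, 0)
  tied <- which(aic <= min(aic) + tie_tol)
  nterms <- vapply(fits[tied], function(f) length(f$random_terms), 0L)
  fits[[tied[which.min(nterms)]]]
}

#' Accession BLUPs from a fit
#'
#' The reported accession value is the sum of the intercept and the
#' predicted random accession effect, `BLUP_i = intercept + u_i`.
#'
#' @param fit a `vc_fit`.
#' @return named numeric vector of BLUPs per accession (trait units).
#' @export
compute_blups <- function(fit) {
  fit$intercept + fit$accession_effects
}

#' Broad-sense heritability from a fit
#'
#' `H2 = V_G / (V_G + V_R)`: the fraction of phenotypic variance due to the
#' accession variance component. Undefined (NA) when `V_G + V_R = 0`.
#'
#' @param fit a `vc_fit`.
#' @return list with `variable`, `H2`, `structure_id`.
#' @export
compute_heritability <- function(fit) {
  vg <- fit$vc[["V_G"]]; vr <- fit$vc[["V_R"]]
  h2 <- if (isTRUE(vg + vr > 0)) vg / (vg + vr) else NA_real_
  list(variable = fit$variable, H2 = h2, structure_id = fit$structure_id)
}

#' Fit, select and summarize all variables of one field
#'
#' Splits a filtered long-format observation table by `VAR_DOY` variable
#' within one field, fits the candidate structures (or a fixed one), selects
#' by AIC, and returns the BLUP matrix plus a per-variable summary — the
#' substrate for the drought-response and multivariate stages.
#'
#' @param table long-format data.frame (plot_id, field, block, column, row,
#'   accession_id, variable, doy, value).
#' @param field which field to fit (`"control"` or `"drought"`); models are
#'   fit separately per field.
#' @param variables optional character vector of variable codes to include
#'   (default: all except FLD and ground heights are eligible; pass codes
#'   explicitly to restrict).
#' @param select_structure `TRUE` to compare the six candidates by AIC;
#'   `FALSE` fits the accession-only structure (fast path for simulations).
#' @return list with `blups` (matrix accessions x VAR_DOY variables) and
#'   `summary` (data.frame: variable, structure_id, V_G, V_R, AIC, H2, n).
#' @export
fit_field <- function(table, field, variables = NULL,
                      select_structure = TRUE) {
  tab <- table[table$field == field, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no observations for field '", field, "'")
  if (is.null(variables)) variables <- setdiff(unique(tab$variable), "FLD")
  tab <- tab[tab$variable %in% variables, , drop = FALSE]

  keys <- unique(tab[, c("variable", "doy")])
  keys <- keys[order(keys$variable, keys$doy), , drop = FALSE]
  acc <- sort(unique(tab$accession_id))
  blups <- matrix(NA_real_, length(acc), nrow(keys),
                  dimnames = list(acc, name_variable(keys$variable,
                                                     keys$doy)))
  summ <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- tab[tab$variable == keys$variable[k] & tab$doy == keys$doy[k], ]
    d <- data.frame(accession = sub$accession_id, block = sub$block,
                    column = sub$column, row = sub$row, value = sub$value)
    best <- if (select_structure) {
      select_vc_model(fit_vc_candidates(d, variable = colnames(blups)[k]))
    } else {
      fit_vc_model(d, vc_candidates()[[1]], variable = colnames(blups)[k])
    }
    b <- compute_blups(best)
    blups[names(b), k] <- b
    h2 <- compute_heritability(best)
    summ[[k]] <- data.frame(variable = colnames(blups)[k],
                            structure_id = best$structure_id,
                            V_G = best$vc[["V_G"]], V_R = best$vc[["V_R"]],
                            AIC = best$AIC, H2 = h2$H2, n = best$n,
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(blups = blups, summary = summary)
}
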