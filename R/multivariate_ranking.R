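#' Reduce a BLUP/Yr matrix to an informative variable subset
#'
#' Two modes. List mode keeps exactly the named `VAR_DOY` columns — the
#' usual reduction to one mid-period and one end-of-period observation per
#' growing period, since observations within a growing period are strongly
#' correlated. Threshold mode greedily scans column pairs in matrix order
#' and drops the later column of any pair whose absolute correlation exceeds
#' the threshold.
#'
#' @param mat matrix accessions x variables.
#' @param keep character vector of column names to retain (list mode).
#' @param cor_threshold absolute-correlation threshold (threshold mode);
#'   exactly one of `keep`/`cor_threshold` must be given.
#' @return the reduced matrix (columns in the order requested / retained).
#' @export
reduce_variables <- function(mat, keep = NULL, cor_threshold = NULL) {
  if (is.null(keep) == is.null(cor_threshold)) {
    stop("supply exactly one of 'keep' or 'cor_threshold'")
  }
  if (!is.null(keep)) {
    missing <- setdiff(keep, colnames(mat))
    if (length(missing) > 0L) {
      stop("requested variable(s) absent: ", paste(missing, collapse = ", "))
    }
    return(mat[, keep, drop = FALSE])
  }
  kept <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    ok <- TRUE
    for (i in which(kept)) {
      r <- stats::cor(mat[, i], mat[, j], use = "complete.obs")
      if (is.finite(r) && abs(r) > cor_threshold) { ok <- FALSE; break }
    }
    kept[j] <- ok
  }
  mat[, kept, drop = FALSE]
}

#' Principal component analysis of accession trait values
#'
#' PCA of a (by default standardized) accession x variable matrix. Rows with
#' any missing value are dropped and counted. When `groups` is supplied
#' (a factor/character vector named by accession, e.g. maturity class,
#' geographic region or variety type), per-group mean scores on the first
#' two components are summarized for overlay plots.
#'
#' @param mat matrix accessions x variables (>= 2 columns).
#' @param standardize scale columns to unit variance (default TRUE; the
#'   variables mix %, cm and unitless indices).
#' @param groups optional named vector of group labels.
#' @return list of class `trial_pca`: loadings (variables x PCs, orthonormal
#'   columns), scores (accessions x PCs), explained (fraction of variance
#'   per PC, summing to 1), n_dropped, group_means (or NULL).
#' @export
run_pca <- function(mat, standardize = TRUE, groups = NULL) {
  stopifnot(ncol(mat) >= 2L)
  complete <- stats::complete.cases(mat)
  x <- mat[complete, , drop = FALSE]
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be standardized: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  explained <- p$sdev^2 / sum(p$sdev^2)
  group_means <- NULL
  if (!is.null(groups)) {
    g <- groups[rownames(x)]
    group_means <- stats::aggregate(p$x[, 1:min(2L, ncol(p$x)), drop = FALSE],
                                    by = list(group = g), FUN = mean)
  }
  structure(list(loadings = p$rotation, scores = p$x, explained = explained,
                 n_dropped = sum(!complete), group_means = group_means),
            class = "trial_pca")
}

#' @export
print.trial_pca <- function(x, ...) {
  k <- min(3L, length(x$explained))
  cat("PCA:", nrow(x$scores), "accessions,", nrow(x$loadings),
      "variables\n")
  cat("  explained:",
      paste0("PC", seq_len(k), " = ",
             sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
             collapse = ", "), "\n")
  if (x$n_dropped > 0) cat("  rows dropped (missing values):",
                           x$n_dropped, "\n")
  invisible(x)
}

#' Count top-quartile appearances per accession
#'
#' For each variable, accessions whose value is at or above the 75th
#' percentile (linear-interpolation quantile; boundary ties included) score
#' one hit; hits are summed over variables. Missing cells are skipped
#' without penalty.
#'
#' @param mat matrix accessions x variables (higher = better).
#' @param prob quantile defining the top fraction (default 0.75).
#' @return named integer vector of hit counts per accession.
#' @export
top_quartile_counts <- function(mat, prob = 0.75) {
  stopifnot(nrow(mat) >= 4L)
  hits <- sapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    thr <- stats::quantile(v, probs = prob, na.rm = TRUE, type = 7)
    as.integer(!is.na(v) & v >= thr)
  })
  stats::setNames(as.integer(rowSums(hits)), rownames(mat))
}

#' Select the top-performing accession set
#'
#' Returns every accession whose hit count reaches the `target_size`-th
#' largest count; ties at that threshold may enlarge the set beyond
#' `target_size`.
#'
#' @param counts named numeric vector (e.g. from [top_quartile_counts()]).
#' @param target_size nominal set size (default 50).
#' @return character vector of accession ids, decreasing by count.
#' @export
select_top_set <- function(counts, target_size = 50) {
  stopifnot(length(counts) >= target_size)
  ord <- order(counts, decreasing = TRUE)
  thr <- counts[ord][target_size]
  ids <- names(counts)[counts >= thr]
  ids[order(counts[ids], decreasing = TRUE)]
}

#' Overlap between the control-field and drought-field top sets
#'
#' @param set_control,set_drought character vectors of accession ids.
#' @return list: n_control, n_drought, n_both, fraction_of_control.
#' @export
overlap_sets <- function(set_control, set_drought) {
  both <- intersect(set_control, set_drought)
  list(n_control = length(set_control), n_drought = length(set_drought),
       n_both = length(both),
       fraction_of_control = if (length(set_control) > 0)
         length(both) / length(set_control) else NA_real_)
}

#' Top-quartile overlap analysis between fields
#'
#' Runs the full ranking on two BLUP matrices: top-quartile hit counting per
#' field, tie-inclusive top-set selection, and the overlap summary.
#'
#' @param blups_control,blups_drought matrices accessions x variables.
#' @param target_size nominal top-set size.
#' @return list: counts_control, counts_drought, set_control, set_drought,
#'   overlap.
#' @export
rank_overlap <- function(blups_control, blups_drought, target_size = 50) {
  cc <- top_quartile_counts(blups_control)
  cd <- top_quartile_counts(blups_drought)
  sc <- select_top_set(cc, target_size)
  sd_ <- select_top_set(cd, target_size)
  list(counts_control = cc, counts_drought = cd,
       set_control = sc, set_drought = sd_,
       overlap = overlap_sets(sc, sd_))
}
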