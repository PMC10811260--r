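#' Construct a two-field incomplete block trial design
#'
#' Lays out a panel of accessions over two fields (an irrigated control field
#' and a rain-out-shelter drought field) following an identical incomplete
#' block scheme with independent randomizations. Each field is a grid of
#' `blocks x columns x rows` plots; every non-control accession is replicated
#' `reps` times per field and the control cultivar `control_reps` times, so
#' the grid must be filled exactly.
#'
#' When `distinct_blocks = TRUE` (default) and `reps <= blocks`, the
#' replicates of an accession are placed in distinct blocks. Placement uses a
#' capacity-balancing rule (each accession takes the blocks with the most
#' remaining space, ties broken at random), which always succeeds when the
#' grid capacity is exact.
#'
#' @param panel data.frame with at least `accession_id`; see [make_panel()].
#' @param geometry list with integers `blocks`, `columns`, `rows`.
#' @param reps replicates per non-control accession per field.
#' @param control_id accession id of the repeated control cultivar.
#' @param control_reps replicates of the control per field.
#' @param seed integer seed; the layout is reproducible given the seed.
#' @param distinct_blocks place an accession's replicates in distinct blocks
#'   whenever `reps <= blocks`; set `FALSE` for unconstrained randomization.
#' @return An object of class `trial_design`: a list with `plots`
#'   (data.frame: plot_id, field, block, column, row, accession_id,
#'   is_border), `panel`, `geometry`, `reps`, `control_id`, `control_reps`,
#'   `seed`.
#' @examples
#' pan <- make_panel(20, control_id = "CTRL")
#' des <- build_design(pan, list(blocks = 3, columns = 1, rows = 15),
#'                     reps = 2, control_id = "CTRL", control_reps = 7,
#'                     seed = 1)
#' nrow(des$plots)  # 2 fields x 45 plots
#' @export
build_design <- function(panel, geometry, reps = 2, control_id,
                         control_reps = 7, seed = 1,
                         distinct_blocks = TRUE) {
  stopifnot(is.data.frame(panel), "accession_id" %in% names(panel))
  ids <- as.character(panel$accession_id)
  if (length(ids) == 0L) stop("panel is empty")
  if (anyDuplicated(ids)) {
    stop("duplicate accession ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!control_id %in% ids) stop("control_id '", control_id, "' not in panel")
  geometry <- lapply(geometry[c("blocks", "columns", "rows")], as.integer)
  capacity <- geometry$blocks * geometry$columns * geometry$rows
  needed <- (length(ids) - 1L) * reps + control_reps
  if (capacity != needed) {
    stop("grid capacity mismatch: design requires ", needed,
         " plots per field but geometry provides ", capacity)
  }

  set.seed(as.integer(seed))
  fields <- c("control", "drought")
  plots <- do.call(rbind, lapply(fields, function(f) {
    lay <- .randomize_field(ids, control_id, reps, control_reps, geometry,
                            distinct_blocks)
    lay$field <- f
    lay
  }))
  plots$plot_id <- sprintf("%s_b%d_c%d_r%d", plots$field, plots$block,
                           plots$column, plots$row)
  plots$is_border <- FALSE
  plots <- plots[, c("plot_id", "field", "block", "column", "row",
                     "accession_id", "is_border")]
  rownames(plots) <- NULL
  structure(list(plots = plots, panel = panel, geometry = geometry,
                 reps = reps, control_id = control_id,
                 control_reps = control_reps, seed = as.integer(seed)),
            class = "trial_design")
}

# one field: assign accessions to blocks (capacity-balanced), then shuffle
# positions within each block
.randomize_field <- function(ids, control_id, reps, control_reps, geometry,
                             distinct_blocks) {
  nb <- geometry$blocks
  block_cap <- rep(geometry$columns * geometry$rows, nb)
  assign_block <- vector("list", nb)
  others <- setdiff(ids, control_id)

  take <- function(block, id, n = 1L) {
    assign_block[[block]] <<- c(assign_block[[block]], rep(id, n))
    block_cap[block] <<- block_cap[block] - n
  }

  # control replicates: spread round-robin over blocks by remaining capacity
  for (k in seq_len(control_reps)) {
    b <- .max_cap_block(block_cap, 1L)
    take(b, control_id)
  }

  if (distinct_blocks && reps <= nb) {
    for (id in sample(others)) {
      bs <- .max_cap_block(block_cap, reps)
      for (b in bs) take(b, id)
    }
  } else {
    pool <- rep(sample(others), times = reps)
    for (id in sample(pool)) take(.max_cap_block(block_cap, 1L), id)
  }

  cells <- expand.grid(column = seq_len(geometry$columns),
                       row = seq_len(geometry$rows))
  do.call(rbind, lapply(seq_len(nb), function(b) {
    entries <- sample(assign_block[[b]])
    data.frame(block = b, column = cells$column, row = cells$row,
               accession_id = entries, stringsAsFactors = FALSE)
  }))
}

# indices of the k blocks with the largest remaining capacity; random ties
.max_cap_block <- function(cap, k) {
  ord <- order(cap + stats::runif(length(cap)) * 0.5, decreasing = TRUE)
  ord[seq_len(k)]
}

#' Validate a trial design against its declared invariants
#'
#' Checks index ranges, uniqueness of (field, block, column, row) cells,
#' exact grid fill, and replicate counts per accession per field. Border
#' plots are ignored.
#'
#' @param design a `trial_design` object (or a compatible list with `plots`,
#'   `geometry`, `reps`, `control_id`, `control_reps`).
#' @return data.frame with columns `type` and `detail`, one row per
#'   violation; zero rows iff the design is valid.
#' @export
validate_design <- function(design) {
  p <- design$plots[!design$plots$is_border, , drop = FALSE]
  g <- design$geometry
  bad <- list()
  note <- function(type, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(type = type, detail = detail,
                                           stringsAsFactors = FALSE)
  }

  rng <- list(block = g$blocks, column = g$columns, row = g$rows)
  for (v in names(rng)) {
    out <- p[[v]] < 1L | p[[v]] > rng[[v]]
    if (any(out)) {
      note("range", sprintf("%s out of 1..%d at plots: %s", v, rng[[v]],
                            paste(p$plot_id[out], collapse = ", ")))
    }
  }

  key <- interaction(p$field, p$block, p$column, p$row, drop = TRUE)
  if (anyDuplicated(key)) {
    note("duplicate_cell",
         sprintf("%d duplicated (field, block, column, row) cells",
                 sum(duplicated(key))))
  }

  cap <- g$blocks * g$columns * g$rows
  for (f in unique(p$field)) {
    n <- sum(p$field == f)
    if (n != cap) {
      note("capacity", sprintf("field %s has %d plots, expected %d", f, n, cap))
    }
    counts <- table(p$accession_id[p$field == f])
    expected <- ifelse(names(counts) == design$control_id,
                       design$control_reps, design$reps)
    off <- counts != expected
    if (any(off)) {
      note("replication",
           sprintf("field %s: %s", f,
                   paste(sprintf("%s has %d reps (expected %d)",
                                 names(counts)[off], as.integer(counts[off]),
                                 expected[off]), collapse = "; ")))
    }
  }
  if (length(bad) == 0L) {
    data.frame(type = character(), detail = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Classify accession maturity from flowering observations
#'
#' An accession is `early` if it flowered in at least one plot, i.e. if any
#' flowering-date (FLD) value is below the non-flowering code; `late` if all
#' plots carry the non-flowering code; `unknown` if no FLD data exist. The
#' number of plots supporting each call is reported.
#'
#' @param flowering data.frame with columns `accession_id` and `value`
#'   (FLD in day-of-year, non-flowering plots encoded as
#'   `nonflowering_code`).
#' @param accessions optional character vector of accession ids to classify;
#'   ids absent from `flowering` are returned as `unknown`.
#' @param nonflowering_code the documented ceiling code (default 222).
#' @return data.frame: accession_id, maturity (`early`/`late`/`unknown`),
#'   n_obs.
#' @export
classify_maturity <- function(flowering, accessions = NULL,
                              nonflowering_code = 222) {
  stopifnot(all(c("accession_id", "value") %in% names(flowering)))
  if (any(flowering$value > nonflowering_code)) {
    stop("FLD values above the non-flowering code ", nonflowering_code,
         " are invalid")
  }
  ids <- unique(as.character(flowering$accession_id))
  if (is.null(accessions)) accessions <- ids
  res <- data.frame(accession_id = as.character(accessions),
                    maturity = "unknown", n_obs = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    v <- flowering$value[flowering$accession_id == res$accession_id[i]]
    if (length(v) == 0L) next
    res$n_obs[i] <- length(v)
    res$maturity[i] <- if (any(v < nonflowering_code)) "early" else "late"
  }
  res
}

#' Generate an accession panel
#'
#' Creates a synthetic panel of accessions with passport descriptors
#' (country, geographic region group, variety type) for use with
#' [build_design()] and [simulate_trial()]. Maturity is `unknown` until
#' classified from flowering data.
#'
#' @param n panel size, including the control.
#' @param control_id id given to the control cultivar (first entry).
#' @param seed integer seed for descriptor sampling.
#' @return data.frame: accession_id, country, region_group, variety_type,
#'   maturity.
#' @export
make_panel <- function(n, control_id = "CTRL", seed = 1) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  regions <- c("N_Europe", "W_Europe", "Central_Europe", "SE_Europe",
               "Non_European")
  countries <- list(N_Europe = c("SE", "NO", "FI"),
                    W_Europe = c("BE", "FR", "GB", "NL"),
                    Central_Europe = c("DE", "CH", "CZ", "PL"),
                    SE_Europe = c("RO", "BG", "RS"),
                    Non_European = c("US", "NZ", "CA"))
  region <- sample(regions, n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.25, 0.15, 0.1))
  country <- vapply(region, function(r) sample(countries[[r]], 1L), "")
  data.frame(
    accession_id = c(control_id,
                     sprintf("ACC%03d", seq_len(max(n - 1L, 0L)))),
    country = country,
    region_group = region,
    variety_type = sample(c("ecotype", "landrace", "cultivar", "breeding"),
                          n, replace = TRUE,
                          prob = c(0.35, 0.25, 0.2, 0.2)),
    maturity = "unknown",
    stringsAsFactors = FALSE
  )
}

#' Write / read a trial design layout as CSV
#'
#' @param design a `trial_design`.
#' @param file path to a CSV file.
#' @return `read_design_csv` returns the plots data.frame.
#' @export
write_design_csv <- function(design, file) {
  utils::write.csv(design$plots, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
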