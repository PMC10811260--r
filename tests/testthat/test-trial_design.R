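test_that("the full-scale two-field design fills 795 plots per field with the stated replication", {
  pan <- make_panel(395, control_id = "CTRL", seed = 7)
  des <- build_design(pan, list(blocks = 3, columns = 5, rows = 53),
                      reps = 2, control_id = "CTRL", control_reps = 7,
                      seed = 7)
  for (f in c("control", "drought")) {
    p <- des$plots[des$plots$field == f, ]
    expect_equal(nrow(p), 795)
    counts <- table(p$accession_id)
    expect_equal(unname(counts[["CTRL"]]), 7)
    expect_true(all(counts[names(counts) != "CTRL"] == 2))
    expect_equal(sum(names(counts) != "CTRL"), 394)
  }
  expect_equal(nrow(validate_design(des)), 0)
})

test_that("a minimal exact-fill design places one plot per accession", {
  pan <- data.frame(accession_id = c("A", "B"))
  des <- build_design(pan, list(blocks = 1, columns = 1, rows = 2),
                      reps = 1, control_id = "A", control_reps = 1, seed = 3)
  p <- des$plots[des$plots$field == "control", ]
  expect_equal(sort(p$accession_id), c("A", "B"))
  expect_equal(nrow(des$plots), 4)
})

test_that("an exhaustive scan finds no duplicated cells and no replication errors", {
  des <- small_design(panel_size = 39, seed = 11,
                      geometry = list(blocks = 3, columns = 2, rows = 13))
  p <- des$plots
  expect_equal(anyDuplicated(p[, c("field", "block", "column", "row")]), 0)
  for (f in c("control", "drought")) {
    counts <- table(p$accession_id[p$field == f])
    expected <- ifelse(names(counts) == "CTRL", 2, 2)
    expect_true(all(counts == expected))
  }
})

test_that("replicates land in distinct blocks when the flag is on", {
  des <- small_design(panel_size = 50, seed = 5,
                      geometry = list(blocks = 3, columns = 2, rows = 17),
                      control_reps = 4)
  p <- des$plots[des$plots$accession_id != "CTRL", ]
  nb <- tapply(p$block, interaction(p$field, p$accession_id),
               function(b) length(unique(b)))
  expect_true(all(nb == 2))
})

test_that("layouts are reproducible by seed and differ across seeds", {
  g <- list(blocks = 2, columns = 2, rows = 8)
  pan <- make_panel(16, control_id = "CTRL", seed = 1)
  d1 <- build_design(pan, g, 2, "CTRL", 2, seed = 21)
  d2 <- build_design(pan, g, 2, "CTRL", 2, seed = 21)
  d3 <- build_design(pan, g, 2, "CTRL", 2, seed = 22)
  expect_identical(d1$plots, d2$plots)
  expect_false(identical(d1$plots$accession_id, d3$plots$accession_id))
})

test_that("capacity mismatches and duplicate ids are rejected with informative errors", {
  pan <- make_panel(10, control_id = "CTRL", seed = 1)
  expect_error(build_design(pan, list(blocks = 1, columns = 1, rows = 10),
                            2, "CTRL", 2, seed = 1),
               "capacity mismatch.*20.*10")
  pan2 <- rbind(pan, pan[2, ])
  expect_error(build_design(pan2, list(blocks = 1, columns = 1, rows = 22),
                            2, "CTRL", 2, seed = 1), "duplicate")
  expect_error(build_design(pan, list(blocks = 1, columns = 1, rows = 20),
                            2, "NOPE", 2, seed = 1), "not in panel")
})

test_that("validate_design reports constructed violations by name", {
  des <- small_design(panel_size = 15, seed = 2,
                      geometry = list(blocks = 1, columns = 2, rows = 15))
  expect_equal(nrow(validate_design(des)), 0)

  bad <- des
  idx <- which(bad$plots$field == "control" &
                 bad$plots$accession_id == "ACC001")[1]
  other <- which(bad$plots$field == "control" &
                   bad$plots$accession_id == "ACC002")[1]
  bad$plots$accession_id[other] <- "ACC001"   # ACC001 x3, ACC002 x1
  rep_viol <- validate_design(bad)
  expect_true(any(rep_viol$type == "replication" &
                    grepl("ACC001", rep_viol$detail)))

  bad2 <- des
  bad2$plots$row[1] <- 54L
  expect_true(any(validate_design(bad2)$type == "range"))
})

test_that("maturity classification follows the any-flowering rule", {
  fl <- data.frame(
    accession_id = rep(c("a", "b", "c"), each = 4),
    value = c(160, 222, 222, 222,   222, 222, 222, 222,   150, 151, 149, 152))
  m <- classify_maturity(fl)
  expect_equal(m$maturity[match(c("a", "b", "c"), m$accession_id)],
               c("early", "late", "early"))
  expect_equal(m$n_obs, rep(4L, 3))

  # unknown when no data; order-invariant; ceiling enforced
  m2 <- classify_maturity(fl, accessions = c("a", "zzz"))
  expect_equal(m2$maturity[m2$accession_id == "zzz"], "unknown")
  m3 <- classify_maturity(fl[sample(nrow(fl)), ])
  expect_equal(m3[order(m3$accession_id), ], m[order(m$accession_id), ],
               ignore_attr = TRUE)
  expect_error(classify_maturity(data.frame(accession_id = "a", value = 300)),
               "invalid")
})

test_that("design CSV round-trips", {
  des <- small_design(panel_size = 10, seed = 3,
                      geometry = list(blocks = 1, columns = 1, rows = 20))
  f <- tempfile(fileext = ".csv")
  write_design_csv(des, f)
  back <- read_design_csv(f)
  expect_equal(back$accession_id, des$plots$accession_id)
  unlink(f)
})
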