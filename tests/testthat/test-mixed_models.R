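sim_oneway <- function(a, n, vg, vr, seed) {
  set.seed(seed)
  g <- rnorm(a, 0, sqrt(vg))
  data.frame(accession = rep(sprintf("A%03d", seq_len(a)), each = n),
             block = 1, column = 1, row = 1,
             value = 50 + rep(g, each = n) + rnorm(a * n, 0, sqrt(vr)))
}

test_that("the six candidate structures are exactly as specified", {
  cand <- vc_candidates()
  expect_length(cand, 6)
  expect_equal(cand[[1]]$random_terms, "accession")
  terms <- lapply(cand, `[[`, "random_terms")
  expect_true(all(vapply(terms, function(t) "accession" %in% t, TRUE)))
  # nesting: no candidate carries block and column together
  expect_false(any(vapply(terms,
                          function(t) all(c("block", "column") %in% t),
                          TRUE)))
  expect_equal(vapply(terms, length, 0L), c(1, 2, 2, 2, 3, 3))
  expect_setequal(terms[[5]], c("accession", "block", "row"))
  expect_setequal(terms[[6]], c("accession", "column", "row"))
})

test_that("REML estimates match the balanced one-way ANOVA closed form", {
  d <- sim_oneway(25, 4, vg = 3, vr = 1, seed = 10)
  fit <- fit_vc_model(d, vc_candidates()[[1]])
  oracle <- anova_oneway_vc(d$value, d$accession)
  expect_equal(fit$vc[["V_G"]], oracle$V_G, tolerance = 1e-6)
  expect_equal(fit$vc[["V_R"]], oracle$V_R, tolerance = 1e-6)
  expect_equal(fit$intercept, mean(d$value), tolerance = 1e-6)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * 3)
})

test_that("identical replicates drive V_R to 0 and H2 to 1", {
  d <- sim_oneway(15, 3, vg = 2, vr = 0, seed = 3)
  fit <- fit_vc_model(d, vc_candidates()[[1]])
  expect_lt(fit$vc[["V_R"]], 1e-8)
  expect_gt(compute_heritability(fit)$H2, 1 - 1e-6)
})

test_that("REML estimates agree with a dense grid search of the restricted likelihood", {
  d <- sim_oneway(100, 2, vg = 4, vr = 1, seed = 77)
  fit <- fit_vc_model(d, vc_candidates()[[1]])
  grid <- reml_grid_oneway(d$value, d$accession,
                           vg_range = c(0.5, 10), vr_range = c(0.1, 4))
  expect_equal(fit$vc[["V_G"]], unname(grid["vg"]), tolerance = 5e-4)
  expect_equal(fit$vc[["V_R"]], unname(grid["vr"]), tolerance = 5e-4)
})

test_that("REML is shift-invariant: components unchanged, intercept shifts", {
  d <- sim_oneway(20, 3, vg = 2, vr = 1, seed = 5)
  d2 <- d; d2$value <- d$value + 1000
  f1 <- fit_vc_model(d, vc_candidates()[[1]])
  f2 <- fit_vc_model(d2, vc_candidates()[[1]])
  expect_equal(f2$vc[["V_G"]], f1$vc[["V_G"]], tolerance = 1e-5)
  expect_equal(f2$vc[["V_R"]], f1$vc[["V_R"]], tolerance = 1e-5)
  expect_equal(f2$intercept, f1$intercept + 1000, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- sim_oneway(10, 2, 1, 1, seed = 1)
  expect_error(fit_vc_model(d[d$accession == "A001", ],
                            vc_candidates()[[1]]), "at least 2 accessions")
  d$block <- 1
  expect_error(fit_vc_model(d, vc_candidates()[[2]]), "single level")
})

test_that("model selection takes the lowest AIC with ties broken to fewer components", {
  fake_fit <- function(aic, terms) {
    structure(list(AIC = aic, random_terms = terms), class = "vc_fit")
  }
  fits <- list(fake_fit(100.2, c("accession", "block")),
               fake_fit(98.7, c("accession", "row")),
               fake_fit(99.5, "accession"))
  expect_equal(select_vc_model(fits)$AIC, 98.7)
  expect_equal(select_vc_model(fits[3])$AIC, 99.5)

  tied <- list(fake_fit(100, c("accession", "block")),
               fake_fit(100, "accession"))
  expect_equal(select_vc_model(tied)$random_terms, "accession")
  # enumeration of the rule: any permutation picks the same winner
  expect_equal(select_vc_model(rev(tied))$random_terms, "accession")
  expect_error(select_vc_model(list()), "no converged fits")
})

test_that("AIC selection recovers the generating spatial structure when it is strong", {
  # rows with variance comparable to V_R should make {A, Row} win over {A}
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    a <- 60; n <- 2
    d <- data.frame(accession = rep(sprintf("A%02d", 1:a), each = n),
                    block = rep(1:2, a), column = 1,
                    row = rep(rep(1:10, length.out = a), each = n))
    d$value <- 50 + rep(rnorm(a, 0, 2), each = n) +
      rnorm(10, 0, 1.5)[d$row] + rnorm(a * n, 0, 1)
    best <- select_vc_model(list(
      fit_vc_model(d, vc_candidates()[[1]]),
      fit_vc_model(d, vc_candidates()[[4]])))
    if (identical(sort(best$random_terms), c("accession", "row"))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 7)
})

test_that("BLUPs are intercept plus predicted effect, with the balanced shrinkage form", {
  fake <- structure(list(intercept = 50,
                         accession_effects = c(a = 2, b = -2)),
                    class = "vc_fit")
  expect_equal(compute_blups(fake), c(a = 52, b = 48))

  d <- sim_oneway(30, 4, vg = 2, vr = 1, seed = 8)
  fit <- fit_vc_model(d, vc_candidates()[[1]])
  b <- compute_blups(fit)
  vg <- fit$vc[["V_G"]]; vr <- fit$vc[["V_R"]]; n <- 4
  shrink <- n * vg / (n * vg + vr)
  means <- tapply(d$value, d$accession, mean)
  oracle <- fit$intercept + shrink * (means - mean(d$value))
  expect_equal(unname(b[names(means)]), as.numeric(oracle),
               tolerance = 1e-5)
  expect_lt(abs(sum(fit$accession_effects)), 1e-6)

  # complete shrinkage at V_G = 0: all BLUPs equal the intercept
  d0 <- sim_oneway(20, 3, vg = 0, vr = 1, seed = 9)
  d0$value <- rnorm(nrow(d0), 50, 1)   # no genetic signal at all
  f0 <- fit_vc_model(d0, vc_candidates()[[1]])
  if (f0$vc[["V_G"]] < 1e-10) {
    expect_true(all(abs(compute_blups(f0) - f0$intercept) < 1e-6))
  }
})

test_that("heritability follows V_G / (V_G + V_R)", {
  mk <- function(vg, vr) {
    structure(list(variable = "x", structure_id = 1,
                   vc = c(V_G = vg, V_block = NA, V_column = NA,
                          V_row = NA, V_R = vr)), class = "vc_fit")
  }
  expect_equal(compute_heritability(mk(2, 2))$H2, 0.5)
  expect_equal(compute_heritability(mk(0, 3))$H2, 0)
  expect_equal(compute_heritability(mk(3, 1))$H2, 0.75)
  expect_true(is.na(compute_heritability(mk(0, 0))$H2))
})

test_that("fit_field produces a BLUP matrix and per-variable summaries", {
  des <- small_design(panel_size = 25, seed = 12,
                      geometry = list(blocks = 2, columns = 2, rows = 13),
                      control_reps = 4)
  sim <- simulate_trial(des, ch_only_params(doys = c(150, 170)), seed = 12)
  res <- fit_field(sim$observations, "control", select_structure = FALSE)
  expect_equal(colnames(res$blups), c("CH_150", "CH_170"))
  expect_equal(nrow(res$blups), 25)
  expect_true(all(res$summary$H2 > 0 & res$summary$H2 < 1))
  expect_equal(res$summary$n, c(52, 52))
})
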