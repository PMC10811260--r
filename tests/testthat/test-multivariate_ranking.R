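make_blup_matrix <- function(n = 40, vars, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(vars)), n, length(vars),
              dimnames = list(sprintf("a%03d", seq_len(n)), vars))
  m
}

test_that("list-mode variable reduction keeps exactly the configured columns", {
  doys <- c(165, 178, 205, 225, 256, 273)
  vars <- c(paste0("CC_", doys), paste0("CH_", doys), "CWSI_206")
  m <- make_blup_matrix(30, vars)
  keep <- c(paste0("CC_", doys), paste0("CH_", doys))
  red <- reduce_variables(m, keep = keep)
  expect_equal(ncol(red), 12)
  expect_equal(colnames(red), keep)

  expect_identical(reduce_variables(m, keep = colnames(m)), m)
  expect_error(reduce_variables(m, keep = "CC_999"), "CC_999")
  expect_error(reduce_variables(m, keep = "CC_165", cor_threshold = 0.9),
               "exactly one")
})

test_that("threshold-mode reduction drops the later of highly correlated pairs", {
  set.seed(2)
  x <- rnorm(50)
  m <- cbind(v1 = x, v2 = x + rnorm(50, 0, 0.05), v3 = rnorm(50))
  rownames(m) <- sprintf("a%02d", 1:50)
  stopifnot(abs(cor(m[, 1], m[, 2])) > 0.95)
  red <- reduce_variables(m, cor_threshold = 0.95)
  expect_equal(colnames(red), c("v1", "v3"))
  # brute-force check: no retained pair exceeds the threshold
  cors <- cor(red)
  expect_true(all(abs(cors[upper.tri(cors)]) <= 0.95))
})

test_that("PC1 of two standardized variables explains (1 + |r|)/2", {
  set.seed(3)
  x <- rnorm(200)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(200)
  m <- cbind(v1 = x, v2 = y); rownames(m) <- sprintf("a%03d", 1:200)
  r <- cor(x, y)
  p <- run_pca(m, standardize = TRUE)
  expect_equal(p$explained[1], (1 + abs(r)) / 2, tolerance = 1e-10)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
})

test_that("a duplicated column makes PC1 explain everything; loadings stay orthonormal", {
  set.seed(4)
  x <- rnorm(60)
  m <- cbind(v1 = x, v2 = x); rownames(m) <- sprintf("a%02d", 1:60)
  p <- run_pca(m)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)

  m2 <- make_blup_matrix(50, paste0("v", 1:6), seed = 5)
  p2 <- run_pca(m2)
  expect_lt(max(abs(crossprod(p2$loadings) - diag(6))), 1e-10)
  expect_true(all(diff(p2$explained) <= 1e-12))
})

test_that("PCA handles missing rows, constant columns, and row permutations", {
  m <- make_blup_matrix(40, paste0("v", 1:4), seed = 6)
  m[3, 2] <- NA
  p <- run_pca(m)
  expect_equal(p$n_dropped, 1)
  expect_equal(nrow(p$scores), 39)

  mc <- m; mc[, 1] <- 5
  expect_error(run_pca(mc), "v1")

  perm <- sample(nrow(m))
  expect_equal(run_pca(m[perm, ])$explained, p$explained)
})

test_that("PCA group overlays summarize scores by label", {
  m <- make_blup_matrix(30, c("v1", "v2"), seed = 7)
  groups <- setNames(rep(c("early", "late"), 15), rownames(m))
  p <- run_pca(m, groups = groups)
  expect_equal(sort(p$group_means$group), c("early", "late"))
})

test_that("top-quartile hits use the interpolated 75th percentile, ties included", {
  m <- matrix(1:8, 8, 1, dimnames = list(letters[1:8], "v1"))
  counts <- top_quartile_counts(m)
  # threshold by enumeration: quantile(1..8, .75) = 6.25 -> values 7, 8
  expect_equal(counts[c("g", "h")], c(g = 1L, h = 1L))
  expect_equal(sum(counts), 2)

  tied <- matrix(5, 8, 1, dimnames = list(letters[1:8], "v1"))
  expect_equal(unname(top_quartile_counts(tied)), rep(1L, 8))

  # two perfectly rank-correlated variables: counts are 0 or 2
  m2 <- cbind(v1 = 1:8, v2 = (1:8) * 10)
  rownames(m2) <- letters[1:8]
  expect_true(all(top_quartile_counts(m2) %in% c(0L, 2L)))

  # missing cells are skipped without penalty
  m3 <- m; m3[8, 1] <- NA
  expect_equal(unname(top_quartile_counts(m3)["h"]), 0L)
})

test_that("top-set selection honors the target size and enlarges on ties", {
  counts <- setNames(c(5, 4, 4, 4, 2, 1), paste0("a", 1:6))
  expect_setequal(select_top_set(counts, 3), c("a1", "a2", "a3", "a4"))

  distinct <- setNames(100:41, sprintf("a%03d", 1:60))
  expect_length(select_top_set(distinct, 50), 50)

  with_ties <- setNames(c(rep(10, 47), rep(5, 5), rep(1, 8)),
                        sprintf("a%03d", 1:60))
  s <- select_top_set(with_ties, 50)
  expect_length(s, 52)   # 3 tied at the 50th count pull in 2 extra
})

test_that("overlap bookkeeping matches set arithmetic", {
  s <- sprintf("a%02d", 1:50)
  same <- overlap_sets(s, s)
  expect_equal(same$n_both, 50)
  expect_equal(same$fraction_of_control, 1)

  disj <- overlap_sets(s[1:25], sprintf("b%02d", 1:25))
  expect_equal(disj$n_both, 0)

  part <- overlap_sets(s[1:30], s[21:50])
  expect_equal(part[c("n_control", "n_drought", "n_both")],
               list(n_control = 30, n_drought = 30, n_both = 10))
  expect_true(part$n_both <= min(part$n_control, part$n_drought))
})

test_that("independent rankings overlap at the s^2/A null rate", {
  set.seed(8)
  A <- 395; s <- 50
  draws <- replicate(2000, {
    length(intersect(sample(A, s), sample(A, s)))
  })
  expect_lt(abs(mean(draws) - s^2 / A), 0.15)
})

test_that("overlap fraction rises with the between-field genetic correlation", {
  frac_at <- function(rho, reps = 20) {
    mean(replicate(reps, {
      g <- matrix(rnorm(120 * 2), 120, 2) %*% chol(matrix(c(1, rho, rho, 1),
                                                          2, 2))
      mats <- lapply(1:2, function(f) {
        m <- sapply(1:6, function(j) g[, f] + rnorm(120, 0, 0.5))
        rownames(m) <- sprintf("a%03d", 1:120)
        colnames(m) <- paste0("v", 1:6)
        m
      })
      rank_overlap(mats[[1]], mats[[2]], target_size = 30)$overlap$
        fraction_of_control
    }))
  }
  set.seed(9)
  fr <- c(frac_at(0), frac_at(0.5), frac_at(0.95))
  expect_true(all(diff(fr) > 0))
})
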