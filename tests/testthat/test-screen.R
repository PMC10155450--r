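expand_table <- function(n11, n10, n01, n00) {
  list(x = rep(c(1L, 1L, 0L, 0L), c(n11, n10, n01, n00)),
       y = rep(c(1L, 0L, 1L, 0L), c(n11, n10, n01, n00)))
}

test_that("phi matches the contingency-table closed form", {
  v <- expand_table(20, 10, 10, 60)
  expect_equal(phi_correlation(v$x, v$y), (1200 - 100) / 2100,
               tolerance = 1e-12)
  # self-correlation and balanced independence
  x <- c(1L, 1L, 0L, 0L)
  expect_equal(phi_correlation(x, x), 1)
  v <- expand_table(25, 25, 25, 25)
  expect_equal(phi_correlation(v$x, v$y), 0)
})

test_that("phi equals brute-force Pearson on random tables", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:1000, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    v <- expand_table(cells[1], cells[2], cells[3], cells[4])
    if (length(unique(v$x)) < 2 || length(unique(v$y)) < 2) next
    expect_equal(phi_correlation(v$x, v$y), stats::cor(v$x, v$y),
                 tolerance = 1e-12)
  }
})

test_that("phi rejects constant vectors, naming the offender", {
  expect_error(phi_correlation(c(1L, 1L, 1L), c(0L, 1L, 0L)), "first vector")
  expect_error(phi_correlation(c(0L, 1L, 0L), c(0L, 0L, 0L)), "second vector")
})

test_that("fisher_ci reproduces its closed form and frozen values", {
  # frozen from the stated closed form: tanh(atanh(r) -+ 1.959964 / sqrt(n-3))
  ci <- fisher_ci(0.5238, 100)
  expect_equal(unname(ci), c(0.3649, 0.6530), tolerance = 5e-4)
  # symmetry about 0 at r = 0
  ci0 <- fisher_ci(0, 500)
  expect_equal(ci0[["low"]], -ci0[["high"]], tolerance = 1e-12)
  expect_error(fisher_ci(1, 100), "degenerate")
})

test_that("fisher_ci contains r and narrows with n", {
  set.seed(7)
  for (i in 1:50) {
    r <- runif(1, -0.95, 0.95)
    n <- sample(5:5000, 1)
    ci <- fisher_ci(r, n)
    expect_lt(ci[["low"]], ci[["high"]])
    expect_true(ci[["low"]] <= r && r <= ci[["high"]])
  }
  widths <- vapply(c(10, 50, 200, 1000, 10000),
                   function(n) diff(fisher_ci(0.3, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("p-values use the t reference and behave monotonically", {
  expect_equal(correlation_p_value(0, 100), 1)
  expect_lt(correlation_p_value(0.5238, 100), 1e-6)
  # strictly decreasing in |r| for fixed n
  ps <- vapply(seq(0.05, 0.9, by = 0.05),
               function(r) correlation_p_value(r, 200), numeric(1))
  expect_true(all(diff(ps) < 0))
  # cross-check against cor.test on expanded vectors
  v <- expand_table(20, 10, 10, 60)
  ct <- stats::cor.test(v$x, v$y)
  expect_equal(correlation_p_value(phi_correlation(v$x, v$y), 100),
               ct$p.value, tolerance = 1e-10)
})

test_that("post-hoc power equals alpha at the null and is monotone", {
  for (a in c(0.01, 0.05, 0.2)) {
    expect_identical(post_hoc_power(0, 1000, a), a)
  }
  pw_n <- vapply(c(10, 50, 100, 1000, 10000),
                 function(n) post_hoc_power(0.15, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  # strictly increasing in |r| until the power saturates numerically
  pw_r <- vapply(seq(0.05, 0.45, 0.05),
                 function(r) post_hoc_power(r, 100), numeric(1))
  expect_true(all(diff(pw_r) > 0))
  expect_true(all(pw_n >= 0 & pw_n <= 1))
})

test_that("cohen_band applies the conventional edges, lower edge inclusive", {
  cfg <- screen_config()
  expect_identical(cohen_band(0.26, cfg), "small")
  expect_identical(cohen_band(0.05, cfg), "negligible")
  expect_identical(cohen_band(-0.30, cfg), "medium")
  expect_identical(cohen_band(0.10, cfg), "small")
  expect_identical(cohen_band(0.50, cfg), "large")
  expect_identical(cohen_band(-0.75, cfg), "large")
})

test_that("screen orders by |r|, skips constants, and is complete", {
  set.seed(13)
  n <- 400
  index <- rbinom(n, 1, 0.3)
  m <- cbind(index = index,
             copy = index,                      # r = 1, must rank first
             noise = rbinom(n, 1, 0.5),
             dead = rep(0L, n))                 # constant, skipped
  storage.mode(m) <- "integer"
  rownames(m) <- sprintf("p%03d", seq_len(n))
  cfg <- screen_config(index_symptom = "index")
  expect_warning(res <- screen_correlations(m, cfg), "constant column")
  expect_identical(res$symptom[1], "copy")
  expect_equal(res$r[1], 1)
  # output is a permutation of the non-constant, non-index columns
  expect_setequal(res$symptom, c("copy", "noise"))
  expect_identical(res$df, res$n - 2L)
  expect_true(all(res$ci_low <= res$r & res$r <= res$ci_high))
})

test_that("screen recovers planted effects and planted independence", {
  cfg_gen <- small_config(n = 10000, seed = 2)
  m <- sample_binary_matrix(cfg_gen)
  res <- screen_correlations(m, screen_config(index_symptom = "index"))
  expect_equal(res$r[res$symptom == "voices"], 0.26, tolerance = 0.03 / 0.26)
  expect_lt(abs(res$r[res$symptom == "numbness"]), 0.03)
  expect_identical(nrow(res), 5L)
})

test_that("screen errors on a missing or constant index symptom", {
  m <- matrix(c(1L, 0L, 1L, 1L), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(screen_correlations(m, screen_config(index_symptom = "zzz")),
               "not a column")
  expect_error(screen_correlations(m, screen_config(index_symptom = "y")),
               "constant")
})

test_that("BH adjustment is available by flag and never smaller than raw p", {
  set.seed(5)
  m <- sample_binary_matrix(small_config(n = 2000, seed = 5))
  cfg <- screen_config(index_symptom = "index", adjust = "benjamini-hochberg")
  res <- screen_correlations(m, cfg)
  expect_true("p_adjusted" %in% names(res))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_equal(res$p_adjusted,
               stats::p.adjust(res$p_value, method = "BH"))
})

test_that("independent_set applies the zero tolerance at two decimals", {
  res <- data.frame(symptom = c("b", "a", "c"),
                    r = c(0.004, -0.0049, 0.006))
  cfg <- screen_config()
  expect_identical(independent_set(res, cfg), c("a", "b"))
})

test_that("display formatting rounds half away from zero", {
  expect_identical(round_half_away(c(0.125, -0.125, 2.5), c(2, 2, 0)),
                   c(0.13, -0.13, 3))
  res <- data.frame(symptom = "x", r = 0.255, ci_low = 0.2349,
                    ci_high = 0.275, p_value = 2e-5, power = 0.999,
                    n = 100L, df = 98L, band = "small")
  disp <- format_screen_display(res)
  expect_identical(disp$r, "0.26")
  expect_identical(disp$ci_95, "[0.23, 0.28]")
  expect_identical(disp$p_value, "< 0.0001")
})
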