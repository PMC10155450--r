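test_that("feasible phi bounds follow the Frechet limits", {
  b <- feasible_phi_bounds(0.5, 0.5)
  expect_equal(unname(b), c(-1, 1))
  # oracle: extreme 2x2 table at margins (0.9, 0.1): P11max = 0.1
  b <- feasible_phi_bounds(0.9, 0.1)
  expect_equal(unname(b["max"]), (0.1 - 0.09) / sqrt(0.9 * 0.1 * 0.1 * 0.9),
               tolerance = 1e-12)
  # equal margins attain phi = 1
  expect_equal(unname(feasible_phi_bounds(0.057, 0.057)["max"]), 1,
               tolerance = 1e-12)
})

test_that("phi-to-latent inversion matches the half-margin closed form", {
  # independence maps to independence, exactly
  expect_identical(phi_to_latent_correlation(0.3, 0.7, 0), 0)
  # at p1 = p2 = 0.5, phi = (2/pi) asin(rho), so rho = sin(pi phi / 2)
  expect_equal(phi_to_latent_correlation(0.5, 0.5, 0.5), sin(pi * 0.5 / 2),
               tolerance = 1e-6)
  expect_equal(phi_to_latent_correlation(0.5, 0.5, -0.3), sin(-0.3 * pi / 2),
               tolerance = 1e-6)
  # boundary excluded
  expect_error(phi_to_latent_correlation(0.5, 0.5, 1), "infeasible")
})

test_that("inversion round-trips through the forward map at 1e-6", {
  cases <- expand.grid(p1 = c(0.057, 0.2, 0.5), p2 = c(0.035, 0.3),
                       phi = c(-0.03, 0.1, 0.26))
  tested <- 0
  for (i in seq_len(nrow(cases))) {
    p1 <- cases$p1[i]; p2 <- cases$p2[i]; phi <- cases$phi[i]
    b <- feasible_phi_bounds(p1, p2)
    if (phi <= b["min"] + 0.01 || phi >= b["max"] - 0.01) next
    rho <- phi_to_latent_correlation(p1, p2, phi)
    expect_equal(phi_from_latent(p1, p2, rho), phi, tolerance = 1e-6)
    tested <- tested + 1
  }
  expect_gte(tested, 12)
})

test_that("the forward map is monotone increasing in rho", {
  rhos <- seq(-0.9, 0.9, by = 0.2)
  phis <- vapply(rhos, function(r) phi_from_latent(0.057, 0.3, r), numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("sampling is deterministic given the seed", {
  cfg <- small_config(n = 500, seed = 99)
  expect_identical(sample_binary_matrix(cfg), sample_binary_matrix(cfg))
  cfg2 <- small_config(n = 500, seed = 100)
  expect_false(identical(sample_binary_matrix(cfg), sample_binary_matrix(cfg2)))
})

test_that("empirical phi and prevalence converge to their targets", {
  cfg <- small_config(n = 10000, seed = 1)
  m <- sample_binary_matrix(cfg)
  # tolerance 3 * sqrt((1 - phi^2) / n) for the strongest target
  expect_equal(phi_correlation(m[, "index"], m[, "voices"]), 0.26,
               tolerance = 3 * sqrt((1 - 0.26^2) / 10000) / 0.26)
  expect_equal(mean(m[, "index"]), 0.057, tolerance = 3 * sqrt(0.057 * 0.943 / 10000) / 0.057)
  # untargeted pair stays near zero
  expect_lt(abs(phi_correlation(m[, "voices"], m[, "aches"])), 0.03)
})

test_that("a config without targets yields independent symptoms", {
  cfg <- generator_config(n_patients = 10000,
                          prevalences = c(a = 0.3, b = 0.2, c = 0.4),
                          seed = 5)
  m <- sample_binary_matrix(cfg)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_lt(abs(phi_correlation(m[, pair[1]], m[, pair[2]])), 0.03)
  }
})

test_that("jointly infeasible targets fail loudly, or repair on request", {
  cfg <- generator_config(
    n_patients = 100,
    prevalences = c(a = 0.5, b = 0.5, c = 0.5),
    phi_targets = data.frame(symptom_a = c("a", "a", "b"),
                             symptom_b = c("b", "c", "c"),
                             phi = c(-0.6, -0.6, -0.6)),
    seed = 1)
  expect_error(sample_binary_matrix(cfg), "not positive semidefinite")
  expect_warning(m <- sample_binary_matrix(cfg, nearest_psd = TRUE),
                 "nearest PSD")
  expect_identical(dim(m), c(100L, 3L))
})

test_that("zero patients is a valid degenerate config", {
  cfg <- generator_config(n_patients = 0, prevalences = c(a = 0.3), seed = 1)
  m <- sample_binary_matrix(cfg)
  expect_identical(nrow(m), 0L)
})

test_that("infeasible pairwise targets are rejected at config time", {
  expect_error(generator_config(
    n_patients = 10, prevalences = c(a = 0.9, b = 0.1),
    phi_targets = data.frame(symptom_a = "a", symptom_b = "b", phi = 0.5)),
    "outside feasible range")
  expect_error(generator_config(
    n_patients = 10, prevalences = c(a = 0.9),
    phi_targets = data.frame(symptom_a = "a", symptom_b = "b", phi = 0.1)),
    "missing from prevalences")
})

test_that("rendered narratives contain present symptoms and no absent ones", {
  lex <- small_lexicon()
  cfg <- small_config(n = 60, seed = 21)
  cfg$filler_vocabulary <- small_filler()
  m <- sample_binary_matrix(cfg)
  corpus <- render_narratives(m, lex, cfg)
  idx <- symptomics:::build_match_index(lex)
  for (i in seq_len(nrow(m))) {
    got <- symptomics:::match_tokens(normalize_text(corpus$text[i]), idx, 0)
    expect_setequal(got, colnames(m)[m[i, ] == 1L])
  }
  # all-zero rows render as filler-only text
  zero <- which(rowSums(m) == 0)
  if (length(zero) > 0) {
    toks <- normalize_text(corpus$text[zero[1]])
    expect_true(all(toks %in% cfg$filler_vocabulary))
  }
})

test_that("high repeat-mention rates still encode as 1", {
  lex <- small_lexicon()
  cfg <- small_config(n = 20, seed = 4)
  cfg$filler_vocabulary <- small_filler()
  cfg$repeat_mention_rate <- 10
  m <- sample_binary_matrix(cfg)
  corpus <- render_narratives(m, lex, cfg)
  sets <- extract_corpus(corpus, lex, quiet = TRUE)
  back <- build_matrix(sets, lex, all_canonicals = TRUE)
  expect_identical(back[, colnames(m)], m)
})

test_that("filler words colliding with surface-form tokens are refused", {
  lex <- small_lexicon()
  cfg <- small_config(n = 5, seed = 1)
  cfg$filler_vocabulary <- c("today", "dread")
  m <- sample_binary_matrix(cfg)
  expect_error(render_narratives(m, lex, cfg), "collide")
})

test_that("rendering is deterministic given the seed", {
  lex <- small_lexicon()
  cfg <- small_config(n = 40, seed = 8)
  cfg$filler_vocabulary <- small_filler()
  m <- sample_binary_matrix(cfg)
  expect_identical(render_narratives(m, lex, cfg), render_narratives(m, lex, cfg))
})

test_that("the study-scale default profile is internally consistent", {
  cfg <- default_profile(n_patients = 2000, seed = 3)
  expect_s3_class(cfg, "generator_config")
  expect_true(all(c(names(cfg$prevalences)) %in%
                  lexicon_canonicals(demo_lexicon())))
  # the factor completion must yield a PSD latent matrix
  R <- symptomics:::latent_correlation_matrix(cfg)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_identical(cfg$n_duplicate_records, 1L)
})
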