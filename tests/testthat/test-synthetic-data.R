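test_that("the default cohort has the study's shape", {
  coh <- generate_cohort(seed = 5)
  expect_identical(nrow(coh$subjects), 160L)
  expect_identical(sum(coh$subjects$group == "NW"), 80L)
  expect_identical(sum(coh$subjects$group == "OB"), 80L)
  expect_length(measurement_columns(coh$matrix), 600L)
  expect_true(all(coh$subjects$bmi == round(coh$subjects$bmi)))
  expect_true(all(coh$subjects$bmi[coh$subjects$group == "NW"] %in% 19:24))
  expect_true(all(coh$subjects$bmi[coh$subjects$group == "OB"] %in% 25:47))
  # OB band weighting mirrors the cohort's decreasing tail
  ob <- coh$subjects$bmi[coh$subjects$group == "OB"]
  expect_identical(c(sum(ob < 30), sum(ob >= 30 & ob < 35), sum(ob >= 35)),
                   c(49L, 19L, 12L))
  expect_true(all(coh$truth$column %in% measurement_columns(coh$matrix)))
})

test_that("cohorts are byte-identical for a fixed seed", {
  a <- generate_cohort(n_nw = 15, n_ob = 15, n_tracts = 4,
                       panel = c("arithmetic_mean", "median"),
                       planted = default_planted_columns(n_planted = 2),
                       seed = 9)
  b <- generate_cohort(n_nw = 15, n_ob = 15, n_tracts = 4,
                       panel = c("arithmetic_mean", "median"),
                       planted = default_planted_columns(n_planted = 2),
                       seed = 9)
  expect_identical(a$matrix, b$matrix)
  d <- generate_cohort(n_nw = 15, n_ob = 15, n_tracts = 4,
                       panel = c("arithmetic_mean", "median"),
                       planted = default_planted_columns(n_planted = 2),
                       seed = 10)
  expect_false(identical(a$matrix, d$matrix))
})

test_that("a noiseless planted column correlates perfectly with BMI", {
  planted <- default_planted_columns(n_planted = 1, beta = 0.01)
  coh <- generate_cohort(n_nw = 30, n_ob = 30, noise_sd = 0,
                         planted = planted, seed = 3)
  expect_equal(cor(coh$matrix[[planted$column]], coh$matrix$bmi), 1,
               tolerance = 1e-12)
})

test_that("planted-column correlation follows the closed form", {
  planted <- default_planted_columns(n_planted = 1, beta = 0.003)
  rs <- vapply(1:200, function(s) {
    coh <- generate_cohort(n_nw = 40, n_ob = 40, n_tracts = 2,
                           panel = c("arithmetic_mean", "median"),
                           planted = planted, noise_sd = 0.02, seed = s)
    cor(coh$matrix[[planted$column]], coh$matrix$bmi)
  }, numeric(1))
  # beta sd(BMI) / sqrt(beta^2 var(BMI) + sigma^2), at the cohort's BMI spread
  coh <- generate_cohort(n_nw = 40, n_ob = 40, n_tracts = 2,
                         panel = c("arithmetic_mean", "median"),
                         planted = planted, noise_sd = 0.02, seed = 1)
  v <- var(coh$matrix$bmi)
  expected <- 0.003 * sqrt(v) / sqrt(0.003^2 * v + 0.02^2)
  expect_lt(abs(mean(rs) - expected), 0.05)
})

test_that("image-mode planted tracts reach screening through the statistics stage", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    coh <- generate_cohort(n_nw = 40, n_ob = 40, mode = "image",
                           planted = default_planted_columns(n_planted = 5),
                           seed = 200 + s)
    mat <- compute_measurement_matrix(coh$subjects, coh$volumes, coh$atlas)
    scr <- choose_measurements(mat)
    for (tr in unique(coh$truth$tract)) {
      total <- total + 1L
      col <- paste0(tr, "|arithmetic_mean")
      if (scr$chosen[scr$column == col]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("image-mode volumes are valid FA over a disjoint block atlas", {
  coh <- generate_cohort(n_nw = 3, n_ob = 3, n_tracts = 8, mode = "image",
                         planted = default_planted_columns(n_planted = 2),
                         seed = 7)
  expect_length(coh$volumes, 6)
  counts <- table(coh$atlas$labels)
  expect_equal(unname(counts[as.character(1:8)]), rep(64L, 8),
               ignore_attr = TRUE)
  v <- coh$volumes[[1]]$voxels
  expect_true(all(v >= 0 & v <= 1))
  expect_error(generate_cohort(n_nw = 2, n_ob = 2, n_tracts = 300,
                               mode = "image", shape = c(8L, 8L, 8L),
                               planted = default_planted_columns(n_planted = 1),
                               seed = 1),
               class = "fatract_input_error")
})

test_that("truth recovery counts and enrichment match brute-force tails", {
  universe <- paste0("c", 1:50)
  truth <- universe[1:5]
  # perfect selection
  rep1 <- truth_recovery_report(truth, truth, universe)
  expect_identical(rep1$false_positives, 0L)
  expect_identical(rep1$true_positives, 5L)

  set.seed(55)
  for (r in 1:50) {
    k <- sample(1:20, 1)
    sel <- sample(universe, k)
    got <- truth_recovery_report(sel, truth, universe)
    expect_equal(got$enrichment_p,
                 oracle_hyper_tail(got$true_positives, 5, 50, k),
                 tolerance = 1e-12)
  }
  expect_error(truth_recovery_report("x1", truth, universe),
               class = "fatract_input_error")
})
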