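test_that("constant input collapses location statistics and zeroes spread", {
  x <- rep(0.37, 20)
  for (s in c("arithmetic_mean", "median", "geometric_mean", "harmonic_mean",
              "root_mean_square", "maximum", "minimum")) {
    expect_equal(compute_statistic(x, s), 0.37, tolerance = 1e-12, label = s)
  }
  for (s in c("standard_deviation", "variance", "range",
              "interquartile_range", "mean_absolute_deviation",
              "median_absolute_deviation")) {
    expect_equal(compute_statistic(x, s), 0, tolerance = 1e-12, label = s)
  }
})

test_that("hand-computed examples are reproduced", {
  x <- c(0.2, 0.4, 0.8)
  expect_equal(compute_statistic(x, "geometric_mean"), 0.4, tolerance = 1e-12)
  expect_equal(compute_statistic(x, "harmonic_mean"), 3 / 8.75,
               tolerance = 1e-12)
})

test_that("all 13 statistics agree with brute-force formulas", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    x <- runif(n)
    for (s in tract_statistic_names()) {
      expect_equal(compute_statistic(x, s), oracle_statistic(x, s),
                   tolerance = 1e-12, label = sprintf("%s rep %d", s, rep))
    }
  }
})

test_that("mean-ordering and spread identities hold on random input", {
  set.seed(3)
  for (rep in 1:50) {
    x <- runif(sample(3:50, 1), min = 0.01)
    hm <- compute_statistic(x, "harmonic_mean")
    gm <- compute_statistic(x, "geometric_mean")
    am <- compute_statistic(x, "arithmetic_mean")
    rms <- compute_statistic(x, "root_mean_square")
    expect_true(hm <= gm + 1e-12 && gm <= am + 1e-12 && am <= rms + 1e-12)
    expect_true(compute_statistic(x, "minimum") <= compute_statistic(x, "median"))
    expect_true(compute_statistic(x, "median") <= compute_statistic(x, "maximum"))
    expect_equal(compute_statistic(x, "range"),
                 compute_statistic(x, "maximum") - compute_statistic(x, "minimum"))
    expect_equal(compute_statistic(x, "variance"),
                 compute_statistic(x, "standard_deviation")^2, tolerance = 1e-12)
    # permutation invariance
    xp <- sample(x)
    for (s in tract_statistic_names()) {
      expect_equal(compute_statistic(xp, s), compute_statistic(x, s),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate inputs yield NA sentinels with a warning", {
  expect_warning(v <- compute_statistic(numeric(), "arithmetic_mean"),
                 class = "fatract_empty_tract")
  expect_true(is.na(v))
  expect_warning(v2 <- compute_statistic(c(0, 0), "geometric_mean"),
                 class = "fatract_degenerate_stat")
  expect_true(is.na(v2))
  # zeros are dropped only for the two multiplicative means
  expect_equal(compute_statistic(c(0, 0.4), "arithmetic_mean"), 0.2)
  expect_equal(compute_statistic(c(0, 0.2, 0.8), "geometric_mean"), 0.4,
               tolerance = 1e-12)
})

test_that("the default panel has 12 of the 13 statistics", {
  expect_length(tract_statistic_names(), 13L)
  expect_length(default_statistic_panel(), 12L)
  expect_false("mean_absolute_deviation" %in% default_statistic_panel())
})

test_that("measurement matrix has subject rows and tract-major panel columns", {
  atlas <- toy_atlas(c(6L, 6L, 6L), labels = 1:2)
  subjects <- tibble::tibble(subject_id = sprintf("s%d", 1:5),
                             bmi = c(20, 22, 26, 30, 35),
                             group = c("NW", "NW", "OB", "OB", "OB"))
  volumes <- lapply(1:5, function(i) random_fa(c(6L, 6L, 6L), seed = i))
  panel <- c("arithmetic_mean", "median", "maximum")
  mat <- compute_measurement_matrix(subjects, volumes, atlas, panel)

  expect_identical(dim(mat), c(5L, 3L + 6L))
  expect_identical(measurement_columns(mat)[1:3],
                   paste0("tract_1|", panel))

  # cell-by-cell oracle: recompute each entry from scratch
  for (i in 1:5) for (lb in 1:2) for (s in panel) {
    vox <- extract_tract_voxels(volumes[[i]], atlas, lb)
    expect_equal(mat[[paste0("tract_", lb, "|", s)]][i],
                 oracle_statistic(vox, s), tolerance = 1e-12)
  }
})

test_that("an empty tract produces missing values, not an error", {
  atlas <- toy_atlas(c(4L, 4L, 4L), labels = 1:2)
  atlas$labels[atlas$labels == 2L] <- 0L  # tract 2 has no voxels
  subjects <- tibble::tibble(subject_id = "s1", bmi = 21, group = "NW")
  suppressMessages(
    mat <- compute_measurement_matrix(subjects, list(random_fa(c(4L, 4L, 4L))),
                                      atlas, c("arithmetic_mean", "median"))
  )
  expect_true(all(is.na(mat[["tract_2|arithmetic_mean"]])))
  expect_false(anyNA(mat[["tract_1|arithmetic_mean"]]))
})

test_that("measurement matrices round-trip through CSV", {
  dir <- withr::local_tempdir()
  mat <- small_problem(n = 12, p = 4, seed = 5)
  path <- file.path(dir, "matrix.csv")
  write_measurement_matrix(mat, path)
  back <- read_measurement_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(mat), tolerance = 1e-12)
  expect_error(read_measurement_matrix({
    p2 <- file.path(dir, "bad.csv")
    readr::write_csv(tibble::tibble(a = 1), p2); p2
  }), class = "fatract_schema_error")
})
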