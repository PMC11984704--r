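test_that("least-squares fits recover exact and collinear structure", {
  mat <- small_problem(n = 20, p = 3, n_signal = 0, seed = 2)
  mat$bmi <- mat[["t1|arithmetic_mean"]]  # response equals the feature
  m <- fit_linear(mat, "t1|arithmetic_mean", mat$bmi)
  expect_equal(unname(m$coefficients), 1, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)

  # duplicated column: minimum-norm solution, identical predictions
  mat2 <- mat
  mat2[["t9|arithmetic_mean"]] <- mat2[["t1|arithmetic_mean"]]
  m2 <- fit_linear(mat2, c("t1|arithmetic_mean", "t9|arithmetic_mean"),
                   mat2$bmi)
  expect_equal(predict(m2, mat2), predict(m, mat), tolerance = 1e-8)
})

test_that("fits and predictions agree with lm() on random systems", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(10:40, 1); p <- sample(1:5, 1)
    mat <- small_problem(n = n, p = p, n_signal = min(p, 2), seed = rep)
    feats <- colnames(mat)[-(1:3)]
    m <- fit_linear(mat, feats, mat$bmi)
    ref <- stats::lm(mat$bmi ~ as.matrix(mat[, feats]))
    expect_equal(unname(predict(m, mat)), unname(stats::fitted(ref)),
                 tolerance = 1e-8)
  }
})

test_that("prediction is the coefficient/measurement product plus intercept", {
  mat <- small_problem(n = 10, p = 4, seed = 3)
  m <- fit_linear(mat, colnames(mat)[4:6], mat$bmi)
  manual <- m$intercept + as.matrix(mat[, m$features]) %*% m$coefficients
  expect_equal(predict(m, mat), drop(manual), tolerance = 1e-12)

  m0 <- m; m0$coefficients[] <- 0
  expect_equal(predict(m0, mat), rep(m0$intercept, nrow(mat)))
  expect_error(predict(m, mat[, 1:3]), class = "fatract_schema_error")
})

test_that("regression scoring averages train and validation correlations", {
  mat <- small_problem(n = 30, p = 2, n_signal = 2, seed = 4, noise = 0)
  tr <- mat[1:20, ]; va <- mat[21:30, ]
  m <- fit_linear(tr, colnames(mat)[4:5], tr$bmi)
  sc <- score_regression(m, tr, tr$bmi, va, va$bmi)
  expect_equal(sc$mean_score, (sc$train_score + sc$val_score) / 2)
  expect_equal(sc$mean_score, 1, tolerance = 1e-6)

  # r_train equals sqrt(R^2) of the same OLS fit on training data
  mat2 <- small_problem(n = 40, p = 3, n_signal = 2, seed = 5)
  m2 <- fit_linear(mat2, colnames(mat2)[4:6], mat2$bmi)
  sc2 <- score_regression(m2, mat2, mat2$bmi, mat2, mat2$bmi)
  r2 <- summary(stats::lm(mat2$bmi ~ as.matrix(mat2[, m2$features])))$r.squared
  expect_equal(sc2$train_score, sqrt(r2), tolerance = 1e-8)

  # degenerate predictions can never improve
  m0 <- m2; m0$coefficients[] <- 0
  expect_identical(score_regression(m0, mat2, mat2$bmi, mat2, mat2$bmi)$mean_score,
                   -Inf)
})

test_that("classification scoring counts correct sides of the threshold", {
  grid <- tibble::tibble(subject_id = letters[1:12], bmi = 0, group = "NW",
                         `s|x` = c(-1, -2, -3, 1, 2, 3, -0.5, 4,
                                   -1, -1, 2, 0))
  m <- structure(list(task = "classification", features = "s|x",
                      coefficients = c(`s|x` = 1), intercept = 0),
                 class = "tract_model")
  tr <- grid[1:8, ]; va <- grid[9:12, ]
  lab_tr <- c(-1, -1, -1, 1, 1, 1, 1, 1)   # 7 of 8 correct
  lab_va <- c(-1, 1, 1, -1)                # 3 of 4 correct (0 scores as NW)
  sc <- score_classification(m, tr, lab_tr, va, lab_va)
  expect_equal(sc$train_score, 0.875)
  expect_equal(sc$val_score, 0.75)
  expect_equal(sc$mean_score, 0.8125)
})

test_that("a single candidate forces a one-step, one-feature model", {
  mat <- small_problem(n = 30, p = 3, n_signal = 1, seed = 6)
  sp <- stratified_split(mat, sizes = c(16, 7, 7), seed = 1)
  out <- run_search(mat, sp, "t1|arithmetic_mean", "regression",
                    search_config(restarts = 3, seed = 2))
  expect_identical(out$model$features, "t1|arithmetic_mean")
  expect_identical(nrow(out$trace), 1L)
})

test_that("a noiseless perfect predictor is found with score one", {
  mat <- small_problem(n = 40, p = 3, n_signal = 0, seed = 7)
  mat[["t1|arithmetic_mean"]] <- 0.5 + 0.01 * mat$bmi   # exact line
  sp <- stratified_split(mat, sizes = c(20, 10, 10), seed = 1)
  out <- run_search(mat, sp, colnames(mat)[4:6], "regression",
                    search_config(restarts = 10, seed = 3))
  expect_true("t1|arithmetic_mean" %in% out$model$features)
  expect_equal(out$best_score$mean_score, 1, tolerance = 1e-9)
})

test_that("traces are strictly monotone, reproducible and closed over candidates", {
  mat <- small_problem(n = 60, p = 8, n_signal = 3, seed = 8)
  sp <- stratified_split(mat, sizes = c(30, 15, 15), seed = 2)
  cands <- colnames(mat)[4:11]
  cfg <- search_config(restarts = 15, seed = 9)
  a <- run_search(mat, sp, cands, "regression", cfg)
  b <- run_search(mat, sp, cands, "regression", cfg)
  expect_identical(a$model, b$model)
  expect_identical(a$trace, b$trace)

  expect_true(all(diff(a$trace$mean_score) > 0))
  expect_true(all(a$model$features %in% cands))
  # never worse than the winning restart's seed model
  expect_gte(a$best_score$mean_score, a$trace$mean_score[1])
  # recorded model sizes change by the recorded k with the action sign
  if (nrow(a$trace) > 1) {
    dm <- diff(a$trace$m)
    sign_k <- ifelse(a$trace$action[-1] == "add", 1, -1) * a$trace$k[-1]
    expect_equal(dm, sign_k)
  }
})

test_that("the search attains the exhaustive best subset on small problems", {
  hits <- 0L
  for (run in 1:20) {
    mat <- small_problem(n = 40, p = 6, n_signal = 2, seed = 100 + run,
                         noise = 3)
    sp <- stratified_split(mat, sizes = c(20, 10, 10), seed = run)
    cands <- colnames(mat)[4:9]
    tr <- mat[match(sp$train_ids, mat$subject_id), ]
    va <- mat[match(sp$val_ids, mat$subject_id), ]

    # exhaustive oracle over all 63 non-empty subsets
    best_oracle <- -Inf
    for (k in 1:6) {
      combos <- utils::combn(cands, k, simplify = FALSE)
      for (s in combos) {
        m <- fit_linear(tr, s, tr$bmi)
        sc <- score_regression(m, tr, tr$bmi, va, va$bmi)
        best_oracle <- max(best_oracle, sc$mean_score)
      }
    }
    out <- run_search(mat, sp, cands, "regression",
                      search_config(restarts = 200, seed = 1000 + run))
    expect_lte(out$best_score$mean_score, best_oracle + 1e-10)
    if (out$best_score$mean_score >= best_oracle - 1e-10) hits <- hits + 1L
    expect_true(all(diff(out$trace$mean_score) > 0))
  }
  expect_gte(hits, 19L)
})

test_that("search results serialize and read back as equivalent models", {
  dir <- withr::local_tempdir()
  mat <- small_problem(n = 30, p = 4, n_signal = 2, seed = 10)
  sp <- stratified_split(mat, sizes = c(16, 7, 7), seed = 3)
  out <- run_search(mat, sp, colnames(mat)[4:7], "regression",
                    search_config(restarts = 5, seed = 4))
  write_search(out, file.path(dir, "model.json"), file.path(dir, "trace.csv"))
  back <- read_model(file.path(dir, "model.json"))
  expect_equal(predict(back, mat), predict(out$model, mat), tolerance = 1e-12)
  expect_identical(nrow(readr::read_csv(file.path(dir, "trace.csv"),
                                        show_col_types = FALSE)),
                   nrow(out$trace))
})
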