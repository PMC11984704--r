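#' Pearson correlation with Fisher-z confidence interval
#'
#' The 95% (or `level`) confidence interval uses the Fisher z transform,
#' `tanh(atanh(r) +/- z_(1-a/2)/sqrt(n-3))`, and the p-value the two-sided
#' t statistic with n - 2 degrees of freedom. `pearson_ci_from_r()` exposes
#' the closed form for a given r and n.
#'
#' @param actual,predicted Numeric vectors (n >= 4, non-constant).
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble: `r`, `ci_lower`, `ci_upper`, `p`, `n`.
#' @examples
#' pearson_ci_from_r(0.8124, 80)  # (0.7215, 0.8758) at 4 decimals
#' @export
pearson_with_ci <- function(actual, predicted, level = 0.95) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  n <- length(actual)
  if (n < 4L || length(predicted) != n) {
    abort("Need equal-length vectors with n >= 4.", class = "fatract_input_error")
  }
  if (sd(actual) == 0 || sd(predicted) == 0) {
    abort("Constant vector: correlation undefined.",
          class = "fatract_input_error")
  }
  pearson_ci_from_r(cor(actual, predicted), n, level)
}

#' @rdname pearson_with_ci
#' @param r Pearson correlation coefficient.
#' @param n Sample size (> 3).
#' @export
pearson_ci_from_r <- function(r, n, level = 0.95) {
  stopifnot(n > 3, abs(r) <= 1)
  q <- qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * q / sqrt(n - 3))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, ci_lower = ci[1], ci_upper = ci[2], p = p,
                 n = as.integer(n))
}

#' Error metrics
#'
#' `rmse()` is the root mean squared error; `mape()` the mean absolute
#' percentage error, `mean(|a - p| / |a|) * 100`, requiring nonzero actual
#' values.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return A single number (`mape()` in percent).
#' @export
rmse <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rmse
#' @export
mape <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  if (any(actual == 0)) {
    abort("MAPE undefined for zero actual values.",
          class = "fatract_input_error")
  }
  mean(abs(actual - predicted) / abs(actual)) * 100
}

#' Bland-Altman agreement analysis
#'
#' Differences are predicted minus actual. The reproducibility coefficient
#' (RPC) is 1.96 times the sample SD of the differences; the coefficient of
#' variation (CV) is 100 times that SD over the mean of the paired means.
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 2).
#' @return One-row tibble: `mean_diff`, `sd_diff`, `rpc`, `cv`.
#' @export
bland_altman <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2L)
  d <- predicted - actual
  sd_d <- sd(d)
  tibble::tibble(mean_diff = mean(d), sd_diff = sd_d, rpc = 1.96 * sd_d,
                 cv = 100 * sd_d / mean((actual + predicted) / 2))
}

#' Bland-Altman plot
#'
#' @param actual,predicted Numeric vectors.
#' @return A ggplot object with the mean difference and the
#'   `mean +/- 1.96 SD` limits of agreement.
#' @export
plot_bland_altman <- function(actual, predicted) {
  ba <- bland_altman(actual, predicted)
  df <- tibble::tibble(m = (actual + predicted) / 2, d = predicted - actual)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = 2) +
    ggplot2::geom_hline(yintercept = ba$mean_diff + c(-1.96, 1.96) * ba$sd_diff,
                        linetype = 3) +
    ggplot2::labs(x = "Mean of actual and predicted",
                  y = "Predicted - actual",
                  title = sprintf("Bland-Altman (RPC %.2f)", ba$rpc)) +
    ggplot2::theme_minimal()
}

#' Classification metrics under the -1/+1 label convention
#'
#' Raw scores are hardened at `threshold` (`s > 0` is OB/+1, otherwise
#' NW/-1; OB is the positive class). Sensitivity is computed over the
#' actual-positive rows, specificity over the actual-negative rows, and
#' accuracy over all rows. For each metric, RMSE and MAPE are computed
#' between the -1/+1 actual labels and the hardened predicted labels over
#' that metric's row subset — a misclassified subject contributes an error
#' of magnitude 2, so RMSE = 2 sqrt(1 - rate) and MAPE = 200 (1 - rate) %.
#' When a class is absent its metrics are `NA`.
#'
#' @param actual Numeric -1/+1 labels.
#' @param scores Raw model outputs.
#' @param threshold Decision threshold, default 0.
#' @return Tibble with rows sensitivity / specificity / accuracy and columns
#'   `metric`, `value`, `rmse`, `mape`, `n`.
#' @export
classification_metrics <- function(actual, scores, threshold = 0) {
  stopifnot(length(actual) == length(scores), all(actual %in% c(-1, 1)))
  predicted <- ifelse(scores > threshold, 1, -1)
  subset_metrics <- function(idx) {
    if (!length(idx)) {
      return(list(value = NA_real_, rmse = NA_real_, mape = NA_real_, n = 0L))
    }
    a <- actual[idx]; p <- predicted[idx]
    list(value = mean(a == p), rmse = rmse(a, p), mape = mape(a, p),
         n = length(idx))
  }
  rows <- list(
    sensitivity = subset_metrics(which(actual == 1)),
    specificity = subset_metrics(which(actual == -1)),
    accuracy = subset_metrics(seq_along(actual))
  )
  tibble::tibble(
    metric = names(rows),
    value = unname(purrr::map_dbl(rows, "value")),
    rmse = unname(purrr::map_dbl(rows, "rmse")),
    mape = unname(purrr::map_dbl(rows, "mape")),
    n = unname(purrr::map_int(rows, "n"))
  )
}

#' Evaluate a fitted model on every split subset
#'
#' `evaluate_regression()` reports, per subset, the Pearson correlation of
#' actual and predicted BMI with its confidence interval and p-value, RMSE
#' and MAPE, and the Bland-Altman agreement quantities.
#' `evaluate_classification()` reports sensitivity, specificity and
#' accuracy per subset with the -1/+1 RMSE/MAPE convention.
#'
#' @param model A `tract_model`.
#' @param matrix Measurement-matrix tibble.
#' @param split A [stratified_split()] result.
#' @return A tibble, one row per subset (x metric for classification).
#' @export
evaluate_regression <- function(model, matrix, split) {
  purrr::map_dfr(c("train", "val", "test"), function(ss) {
    rows <- split_rows(matrix, split, ss)
    pred <- predict(model, rows)
    pc <- pearson_with_ci(rows$bmi, pred)
    ba <- bland_altman(rows$bmi, pred)
    dplyr::bind_cols(tibble::tibble(subset = ss), pc,
                     tibble::tibble(rmse = rmse(rows$bmi, pred),
                                    mape = mape(rows$bmi, pred)),
                     ba)
  })
}

#' @rdname evaluate_regression
#' @export
evaluate_classification <- function(model, matrix, split) {
  purrr::map_dfr(c("train", "val", "test"), function(ss) {
    rows <- split_rows(matrix, split, ss)
    labels <- ifelse(rows$group == "OB", 1, -1)
    dplyr::bind_cols(tibble::tibble(subset = ss),
                     classification_metrics(labels, predict(model, rows)))
  })
}

#' Scatter of classification scores by subset
#'
#' @param model A `tract_model` (classification task).
#' @param matrix Measurement-matrix tibble.
#' @param split A [stratified_split()] result.
#' @return A ggplot of raw scores against the 0 threshold, coloured by the
#'   actual group.
#' @export
plot_classification_scores <- function(model, matrix, split) {
  df <- purrr::map_dfr(c("train", "val", "test"), function(ss) {
    rows <- split_rows(matrix, split, ss)
    tibble::tibble(subset = ss, subject_id = rows$subject_id,
                   group = rows$group, score = predict(model, rows))
  })
  df$subset <- factor(df$subset, levels = c("train", "val", "test"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~subset, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Model output s") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
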