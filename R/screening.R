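#' Wilcoxon rank-sum p-value with midranks
#'
#' Two-sided rank-sum test comparing two groups of tract measurements. Ties
#' are handled by midranks throughout. When both groups have at most
#' `exact_max` observations the null distribution is enumerated exactly over
#' all group assignments of the pooled midranks, and the p-value is
#' `P(|W - mu| >= |w - mu|)`; otherwise the tie-corrected normal
#' approximation with a 0.5 continuity correction is used.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # 1/3 by exact enumeration
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    abort("Each group needs at least two values.", class = "fatract_input_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))          # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- combn(r, n1, sum)
    mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)  # all values tied
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    2 * pnorm(-max(z, 0))
  }
}

#' Spearman correlation of a measurement with BMI
#'
#' The coefficient is the Pearson correlation of midranks; its significance
#' comes from the two-sided t approximation with n - 2 degrees of freedom.
#' A constant input vector has no defined rank correlation and returns
#' `NA` for both fields so the column can be flagged and excluded.
#'
#' @param x Numeric measurement vector.
#' @param bmi Numeric BMI vector of the same length (>= 3).
#' @return A list with elements `rho` and `p`.
#' @export
spearman_with_bmi <- function(x, bmi) {
  x <- as.numeric(x); bmi <- as.numeric(bmi)
  n <- length(x)
  if (length(bmi) != n || n < 3L) {
    abort("`x` and `bmi` must have equal length >= 3.",
          class = "fatract_input_error")
  }
  if (sd(x) == 0 || sd(bmi) == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(bmi))
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input. `NA` entries
#' (flagged columns) stay `NA` and do not count toward the family size.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "fatract_input_error")
  }
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Two-condition screening of tract measurements
#'
#' Applies the candidate-selection rule to every measurement column of the
#' matrix. Condition one: the NW and OB groups differ by the Wilcoxon
#' rank-sum test (`p_w < alpha`, uncorrected). Condition two: the
#' measurement is Spearman-correlated with BMI over the whole cohort
#' (`p_c < alpha` after Benjamini-Hochberg correction across the full
#' column family). A column is chosen when it meets both; the number of
#' chosen columns is `N`. Columns with missing values or zero variance are
#' flagged and excluded from the family.
#'
#' @param matrix Measurement-matrix tibble (see
#'   [compute_measurement_matrix()]); must contain both groups.
#' @param alpha Significance level for both conditions (default 0.05,
#'   strict inequality).
#' @param exact_max Passed to [wilcoxon_rank_sum()].
#' @return A tibble of class `screening_result` with one row per column:
#'   `column`, `tract`, `statistic`, `p_w`, `rho`, `p_c_raw`, `p_c_adj`,
#'   `passes_c1`, `passes_c2`, `chosen`; attributes `N`, `alpha` and
#'   `family_size`.
#' @export
choose_measurements <- function(matrix, alpha = 0.05, exact_max = 8L) {
  cols <- measurement_columns(matrix)
  if (!all(c("NW", "OB") %in% matrix$group)) {
    abort("Both groups (NW, OB) must be present.", class = "fatract_input_error")
  }
  nw <- matrix$group == "NW"
  bmi <- matrix$bmi

  per_col <- purrr::map(cols, function(cn) {
    v <- matrix[[cn]]
    if (anyNA(v) || sd(v) == 0) {
      return(list(p_w = NA_real_, rho = NA_real_, p_c_raw = NA_real_))
    }
    sp <- spearman_with_bmi(v, bmi)
    list(p_w = wilcoxon_rank_sum(v[nw], v[!nw], exact_max = exact_max),
         rho = sp$rho, p_c_raw = sp$p)
  })
  res <- dplyr::bind_cols(
    split_column_name(cols),
    tibble::tibble(
      p_w = purrr::map_dbl(per_col, "p_w"),
      rho = purrr::map_dbl(per_col, "rho"),
      p_c_raw = purrr::map_dbl(per_col, "p_c_raw")
    )
  )
  n_flagged <- sum(is.na(res$p_c_raw))
  if (n_flagged > 0) {
    message(sprintf("%d column(s) flagged (missing or constant) and excluded from screening.",
                    n_flagged))
  }
  res$p_c_adj <- fdr_adjust(res$p_c_raw)
  res$passes_c1 <- !is.na(res$p_w) & res$p_w < alpha
  res$passes_c2 <- !is.na(res$p_c_adj) & res$p_c_adj < alpha
  res$chosen <- res$passes_c1 & res$passes_c2

  structure(res,
            N = sum(res$chosen), alpha = alpha,
            family_size = sum(!is.na(res$p_c_raw)),
            class = c("screening_result", class(res)))
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> N = %d of %d columns chosen (family %d, alpha %.3g)\n",
              attr(x, "N"), nrow(x), attr(x, "family_size"), attr(x, "alpha")))
  NextMethod()
}

#' @rdname choose_measurements
#' @param x A `screening_result`.
#' @param ... Unused.
#' @method glance screening_result
#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(N = attr(x, "N"), alpha = attr(x, "alpha"),
                 family_size = attr(x, "family_size"), n_columns = nrow(x))
}

#' @rdname choose_measurements
#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "screening_result")
  attr(out, "N") <- attr(out, "alpha") <- attr(out, "family_size") <- NULL
  out
}

#' Serialize a screening result
#'
#' Writes the per-column table as CSV and the `{N, alpha, family_size}`
#' summary as JSON.
#'
#' @param result A `screening_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_screening_result <- function(result, csv_path, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(tidy(result), csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(result)), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(result)
}

#' Plot screening outcomes
#'
#' Tract-by-statistic tile map of the chosen measurements, coloured by the
#' Spearman coefficient, in the spirit of the screening figures produced by
#' the analysis.
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  chosen <- dplyr::filter(tibble::as_tibble(object), .data$chosen)
  ggplot2::ggplot(chosen, ggplot2::aes(x = .data$statistic, y = .data$tract,
                                       fill = .data$rho)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = sprintf("Chosen tract measurements (N = %d)",
                                  attr(object, "N"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
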