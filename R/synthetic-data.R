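#' Default planted effects for the synthetic cohort
#'
#' Ten measurement columns (or ten tracts in image mode) carry a linear BMI
#' effect of +/- 0.003 FA units per kg/m^2 with alternating sign, spread
#' over the first ten atlas tracts and cycling through the central-tendency
#' statistics. At the default noise level this corresponds to a per-column
#' Spearman correlation with BMI of roughly 0.6 — a clearly detectable but
#' not noiseless effect.
#'
#' @param tracts Tract name universe.
#' @param n_planted Number of planted columns/tracts.
#' @param beta Absolute effect size per kg/m^2.
#' @return Tibble `column`, `tract`, `statistic`, `beta`.
#' @export
default_planted_columns <- function(tracts = icbm_dti_81_labels()$tract_name,
                                    n_planted = 10L, beta = 0.003) {
  stats_cycle <- rep(c("arithmetic_mean", "median", "geometric_mean",
                       "harmonic_mean", "root_mean_square"),
                     length.out = n_planted)
  tr <- rep(tracts, length.out = n_planted)
  tibble::tibble(
    column = measurement_column_name(tr, stats_cycle),
    tract = tr, statistic = stats_cycle,
    beta = beta * rep_len(c(1, -1), n_planted)
  )
}

#' Generate a synthetic two-group cohort
#'
#' Emulates the study cohort the pipeline expects: `n_nw` normal-weight
#' subjects with integer BMI uniform on 19-24 and `n_ob` overweight/obese
#' subjects with integer BMI on 25-47, the latter split 49:19:12 across the
#' 25-29 / 30-34 / 35-47 bands (uniform within band) to mimic the real
#' cohort's decreasing tail. Group labels follow the BMI-25 boundary.
#'
#' In `matrix` mode each measurement column j is
#' `x_ij = mu_j + beta_j (BMI_i - mean BMI) + eps`, `eps ~ N(0, noise_sd^2)`,
#' with `beta_j = 0` except on the planted columns — exact control of the
#' planted structure, and the fast path for testing screening and search.
#' In `image` mode small FA volumes are generated over a block-label atlas:
#' each tract is a disjoint cube of `block^3` voxels whose FA values are
#' drawn from a Beta distribution with concentration `kappa`; in planted
#' tracts the Beta mean shifts linearly with BMI, so the planted effects
#' reach the pipeline through the imaging and statistics stages.
#'
#' @param n_nw,n_ob Group sizes (defaults 80/80).
#' @param n_tracts Number of tracts (default 50, named after the shipped
#'   ICBM-DTI-81 table).
#' @param panel Statistic panel for the measurement matrix.
#' @param planted Tibble of planted effects (`column` and `beta` in matrix
#'   mode; `tract` and `beta` in image mode); default
#'   [default_planted_columns()].
#' @param noise_sd Measurement noise SD in FA units (matrix mode).
#' @param mode `"matrix"` or `"image"`.
#' @param shape,block Image-mode grid shape and tract cube edge.
#' @param kappa Image-mode Beta concentration.
#' @param seed Integer seed; the cohort is byte-identical given it.
#' @return An object of class `synthetic_cohort`: list with `subjects`,
#'   `truth`, `mode`, and either `matrix` (matrix mode) or `volumes` +
#'   `atlas` (image mode).
#' @examples
#' coh <- generate_cohort(n_nw = 10, n_ob = 10, n_tracts = 5,
#'                        panel = c("arithmetic_mean", "median"),
#'                        planted = default_planted_columns(n_planted = 2),
#'                        seed = 1)
#' dim(coh$matrix)
#' @export
generate_cohort <- function(n_nw = 80L, n_ob = 80L, n_tracts = 50L,
                            panel = default_statistic_panel(),
                            planted = default_planted_columns(),
                            noise_sd = 0.02,
                            mode = c("matrix", "image"),
                            shape = c(24L, 24L, 24L), block = 4L,
                            kappa = 50, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(noise_sd >= 0, n_nw >= 1L, n_ob >= 1L)
  tracts <- synthetic_tract_names(n_tracts)
  planted <- tibble::as_tibble(planted)

  local_seed(seed, {
    subjects <- synthetic_subjects(n_nw, n_ob)
    if (mode == "matrix") {
      cols <- as.vector(t(outer(tracts, panel, measurement_column_name)))
      if (!all(planted$column %in% cols)) {
        abort("Planted columns must exist in the tract x panel design.",
              class = "fatract_input_error")
      }
      beta <- setNames(rep(0, length(cols)), cols)
      beta[planted$column] <- planted$beta
      mu <- runif(length(cols), 0.3, 0.6)
      bmi_c <- subjects$bmi - mean(subjects$bmi)
      grid <- outer(rep(1, nrow(subjects)), mu) + outer(bmi_c, beta) +
        matrix(rnorm(nrow(subjects) * length(cols), sd = noise_sd),
               nrow(subjects))
      colnames(grid) <- cols
      mat <- dplyr::bind_cols(subjects, tibble::as_tibble(grid))
      class(mat) <- c("tract_matrix", class(mat))
      structure(list(subjects = subjects, matrix = mat,
                     truth = planted, mode = mode, seed = as.integer(seed)),
                class = "synthetic_cohort")
    } else {
      if (!"tract" %in% names(planted)) {
        abort("Image-mode `planted` needs a `tract` column.",
              class = "fatract_input_error")
      }
      atlas <- block_atlas(shape, block, tracts)
      beta_t <- setNames(rep(0, length(tracts)), tracts)
      beta_t[planted$tract] <- planted$beta
      mu_t <- runif(length(tracts), 0.35, 0.55)
      bmi_c <- subjects$bmi - mean(subjects$bmi)
      idx_by_tract <- purrr::map(seq_along(tracts),
                                 function(t) which(atlas$labels == t))
      volumes <- purrr::map(seq_len(nrow(subjects)), function(i) {
        vox <- array(0, dim = shape)
        for (t in seq_along(tracts)) {
          m <- min(max(mu_t[t] + beta_t[t] * bmi_c[i], 0.05), 0.95)
          vox[idx_by_tract[[t]]] <- rbeta(length(idx_by_tract[[t]]),
                                          m * kappa, (1 - m) * kappa)
        }
        fa_volume(vox, subject_id = subjects$subject_id[i])
      })
      structure(list(subjects = subjects, volumes = volumes, atlas = atlas,
                     truth = planted, mode = mode, seed = as.integer(seed)),
                class = "synthetic_cohort")
    }
  })
}

synthetic_tract_names <- function(n_tracts) {
  icbm <- icbm_dti_81_labels()$tract_name
  if (n_tracts <= length(icbm)) head(icbm, n_tracts)
  else sprintf("tract_%03d", seq_len(n_tracts))
}

synthetic_subjects <- function(n_nw, n_ob) {
  bmi_nw <- sample(19:24, n_nw, replace = TRUE)
  # OB bands 25-29 / 30-34 / 35-47 in the cohort's 49:19:12 proportion
  n1 <- round(n_ob * 49 / 80); n2 <- round(n_ob * 19 / 80)
  n3 <- n_ob - n1 - n2
  bmi_ob <- c(sample(25:29, n1, replace = TRUE),
              sample(30:34, n2, replace = TRUE),
              sample(35:47, n3, replace = TRUE))
  tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n_nw + n_ob)),
    bmi = as.numeric(c(bmi_nw, bmi_ob)),
    group = rep(c("NW", "OB"), c(n_nw, n_ob))
  )
}

# disjoint cube blocks in deterministic raster order
block_atlas <- function(shape, block, tracts) {
  nb <- shape %/% block
  if (prod(nb) < length(tracts)) {
    abort(sprintf("Geometry infeasible: %d blocks available for %d tracts.",
                  prod(nb), length(tracts)),
          class = "fatract_input_error")
  }
  labels <- array(0L, dim = shape)
  t <- 0L
  for (k in seq_len(nb[3])) for (j in seq_len(nb[2])) for (i in seq_len(nb[1])) {
    if (t >= length(tracts)) break
    t <- t + 1L
    labels[((i - 1L) * block + 1L):(i * block),
           ((j - 1L) * block + 1L):(j * block),
           ((k - 1L) * block + 1L):(k * block)] <- t
  }
  atlas_volume(labels, tibble::tibble(label = seq_along(tracts),
                                      tract_name = tracts))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d NW / %d OB), %s mode, %d planted effect(s), seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == "NW"),
              sum(x$subjects$group == "OB"), x$mode, nrow(x$truth), x$seed))
  invisible(x)
}

#' Planted-effect recovery report
#'
#' Compares a selection of measurement columns (a screening result's chosen
#' columns, a model's features, or a plain character vector) against the
#' planted truth, and computes the hypergeometric enrichment p-value
#' `P(overlap >= observed)` for drawing `|selected|` columns from the
#' universe.
#'
#' @param result A `screening_result`, `tract_model`, or character vector
#'   of selected column names.
#' @param truth Character vector of planted column names (or a tibble with
#'   a `column` column).
#' @param universe Character vector (or count) of the column universe from
#'   which the selection was made. Defaults to the screening family when
#'   `result` is a `screening_result`.
#' @return One-row tibble: `true_positives`, `false_positives`,
#'   `n_selected`, `n_planted`, `n_universe`, `enrichment_p`.
#' @export
truth_recovery_report <- function(result, truth, universe = NULL) {
  if (is.data.frame(truth)) truth <- truth$column
  selected <- if (inherits(result, "screening_result")) {
    if (is.null(universe)) universe <- result$column[!is.na(result$p_c_raw)]
    result$column[result$chosen]
  } else if (inherits(result, "tract_model")) {
    result$features
  } else {
    as.character(result)
  }
  if (is.null(universe)) {
    abort("`universe` is required unless `result` is a screening_result.",
          class = "fatract_input_error")
  }
  m <- if (is.numeric(universe)) as.integer(universe) else length(universe)
  if (!is.numeric(universe) &&
      (!all(selected %in% universe) || !all(truth %in% universe))) {
    abort("Selected and planted columns must lie in the universe.",
          class = "fatract_input_error")
  }
  tp <- length(intersect(selected, truth))
  k <- length(selected); K <- length(truth)
  tibble::tibble(
    true_positives = tp, false_positives = k - tp,
    n_selected = k, n_planted = K, n_universe = m,
    enrichment_p = phyper(tp - 1, K, m - K, k, lower.tail = FALSE)
  )
}
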