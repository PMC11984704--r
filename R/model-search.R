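#' Search configuration
#'
#' Parameters of the randomized add/exclude stepwise search. Defaults mirror
#' the published procedure: up to five measurements added or excluded at a
#' time and 1,000 independent restarts. `max_model_size` defaults to
#' `n_train - 2` at run time, keeping the least-squares fit over-determined;
#' candidate subsets exceeding it are treated as non-improvements.
#' `full_sweep = TRUE` enumerates every k-subset of the pool instead of the
#' default disjoint-partition sweep; it is only practical for small
#' candidate sets and is used by the exhaustive-oracle tests.
#'
#' @param k_max Largest number of measurements added/excluded at once.
#' @param restarts Number of independent restarts.
#' @param seed Integer seed; restart r uses the substream `seed + r`.
#' @param max_model_size Cap on model size, or `NULL` for `n_train - 2`.
#' @param full_sweep Enumerate all k-subsets instead of a disjoint partition.
#' @return A list of class `search_config`.
#' @export
search_config <- function(k_max = 5L, restarts = 1000L, seed = 1L,
                          max_model_size = NULL, full_sweep = FALSE) {
  stopifnot(k_max >= 1L, restarts >= 1L)
  structure(list(k_max = as.integer(k_max), restarts = as.integer(restarts),
                 seed = as.integer(seed), max_model_size = max_model_size,
                 full_sweep = isTRUE(full_sweep)),
            class = "search_config")
}

#' Ordinary least-squares fit on selected measurement columns
#'
#' Fits `targets ~ intercept + selected columns` by least squares on the
#' training rows. Rank-deficient designs (duplicated or collinear columns)
#' are solved by the minimum-norm solution through the singular value
#' decomposition, so the fit is deterministic and predictions agree with any
#' other least-squares solution.
#'
#' @param train_rows Measurement-matrix tibble (training rows).
#' @param features Character vector of measurement column names (may be
#'   empty, giving an intercept-only model).
#' @param targets Numeric response (BMI for regression, -1/+1 labels for
#'   classification).
#' @param task `"regression"` or `"classification"`.
#' @return An object of class `tract_model`: list with `task`, `features`,
#'   `coefficients` (named) and `intercept`.
#' @export
fit_linear <- function(train_rows, features, targets,
                       task = c("regression", "classification")) {
  task <- match.arg(task)
  y <- as.numeric(targets)
  stopifnot(length(y) == nrow(train_rows), nrow(train_rows) >= 2L)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(train_rows[, features, drop = FALSE]))
  beta <- minimum_norm_ls(X, y)
  structure(
    list(task = task, features = as.character(features),
         coefficients = setNames(beta[-1L], features), intercept = beta[[1L]]),
    class = "tract_model"
  )
}

# Minimum-norm least-squares solution via SVD; tolerance relative to the
# largest singular value.
minimum_norm_ls <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * max(dim(X)) * .Machine$double.eps * 100
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}

#' @export
print.tract_model <- function(x, ...) {
  cat(sprintf("<tract_model> %s, %d feature(s), intercept %.4g\n",
              x$task, length(x$features), x$intercept))
  invisible(x)
}

#' Predict from a fitted tract model
#'
#' The linear combination of the model's measurement columns plus the
#' intercept. For classification this is the raw score `s`; hardening at
#' the 0 threshold is the caller's (or [classification_metrics()]'s) job.
#'
#' @param object A `tract_model`.
#' @param newdata Measurement-matrix tibble containing all model features.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.tract_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("Missing model feature column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "fatract_schema_error")
  }
  if (length(object$features) == 0L) {
    return(rep(object$intercept, nrow(newdata)))
  }
  drop(as.matrix(newdata[, object$features, drop = FALSE]) %*%
         object$coefficients) + object$intercept
}

#' @rdname fit_linear
#' @param x,object A `tract_model`.
#' @param ... Unused.
#' @method tidy tract_model
#' @export
tidy.tract_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname fit_linear
#' @method glance tract_model
#' @export
glance.tract_model <- function(x, ...) {
  tibble::tibble(task = x$task, n_features = length(x$features),
                 intercept = x$intercept)
}

#' Score a model on the training and validation subsets
#'
#' `score_regression()` computes the Pearson correlation between actual and
#' predicted BMI on each subset and averages the two (`r_mean`); a
#' prediction vector with zero variance makes the whole pair `-Inf`, so a
#' degenerate model can never be an improvement. `score_classification()`
#' hardens the raw score at 0 (`s < 0` is NW, `s > 0` is OB, the
#' measure-zero `s == 0` counts as NW for determinism), computes the
#' fraction correctly classified on each subset and averages.
#'
#' @param model A `tract_model`.
#' @param train_rows,val_rows Measurement-matrix tibbles.
#' @param train_targets,val_targets Numeric BMI (regression) or -1/+1 labels
#'   (classification).
#' @return A list with `train_score`, `val_score`, `mean_score`.
#' @export
score_regression <- function(model, train_rows, train_targets,
                             val_rows, val_targets) {
  r_tr <- safe_pearson(train_targets, predict(model, train_rows))
  r_va <- safe_pearson(val_targets, predict(model, val_rows))
  pair(r_tr, r_va)
}

safe_pearson <- function(a, b) {
  if (length(a) < 3L || sd(a) == 0 || sd(b) == 0 || anyNA(b)) return(-Inf)
  cor(a, b)
}

#' @rdname score_regression
#' @export
score_classification <- function(model, train_rows, train_targets,
                                 val_rows, val_targets) {
  acc <- function(rows, lab) {
    stopifnot(all(lab %in% c(-1, 1)))
    mean(harden_labels(predict(model, rows)) == lab)
  }
  pair(acc(train_rows, train_targets), acc(val_rows, val_targets))
}

# s < 0 -> NW (-1), s > 0 -> OB (+1); s == 0 counts as NW.
harden_labels <- function(scores) ifelse(scores > 0, 1, -1)

pair <- function(train_score, val_score) {
  m <- if (is.finite(train_score) && is.finite(val_score)) {
    (train_score + val_score) / 2
  } else -Inf
  list(train_score = train_score, val_score = val_score, mean_score = m)
}

#' Randomized add/exclude stepwise model search
#'
#' Builds a linear model over the screened candidate measurements by the
#' randomized forward-backward procedure. Each restart seeds the incumbent
#' with one uniformly drawn candidate, then alternates an ADD phase (k = 1
#' to `k_max` measurements at a time) and an EXCLUDE phase (k-subsets of the
#' incumbent's features). At each k level the pool is shuffled once and
#' swept in disjoint consecutive k-subsets; a candidate model is accepted
#' only when its mean train/validation score strictly exceeds the
#' incumbent's (`r_mean > r_mean*`), upon which the sweep restarts at ADD
#' k = 1 with a fresh pool. A restart ends when both phases exhaust all
#' levels without an acceptance. The best incumbent across `restarts`
#' independent restarts is returned.
#'
#' Scores are mean Pearson correlation (regression against BMI) or mean
#' accuracy (classification of -1/+1 group labels at threshold 0).
#'
#' @param matrix Measurement-matrix tibble.
#' @param split A [stratified_split()] result.
#' @param candidates Character vector of screened column names.
#' @param task `"regression"` or `"classification"`.
#' @param config A [search_config()].
#' @return A list of class `tract_search` with elements `model`
#'   (`tract_model`), `trace` (tibble of accepted steps across the winning
#'   restart), `best_restart`, `best_score`, `restarts_done`, and `config`.
#' @export
run_search <- function(matrix, split, candidates,
                       task = c("regression", "classification"),
                       config = search_config()) {
  task <- match.arg(task)
  if (length(candidates) == 0L) {
    abort("Need at least one candidate measurement.",
          class = "fatract_input_error")
  }
  stopifnot(all(candidates %in% names(matrix)))
  tr <- split_rows(matrix, split, "train")
  va <- split_rows(matrix, split, "val")
  y_tr <- search_targets(tr, task)
  y_va <- search_targets(va, task)
  max_size <- config$max_model_size %||% (nrow(tr) - 2L)

  fit_score <- function(features) {
    model <- fit_linear(tr, features, y_tr, task = task)
    sc <- if (task == "regression") {
      score_regression(model, tr, y_tr, va, y_va)
    } else {
      score_classification(model, tr, y_tr, va, y_va)
    }
    list(model = model, score = sc)
  }

  best <- NULL
  best_trace <- NULL
  best_restart <- NA_integer_
  for (r in seq_len(config$restarts)) {
    res <- local_seed(config$seed + r, {
      one_restart(candidates, fit_score, config, max_size)
    })
    if (is.null(best) || res$score$mean_score > best$score$mean_score) {
      best <- res[c("model", "score")]
      best_trace <- res$trace
      best_restart <- r
    }
  }
  best_trace$restart <- best_restart
  structure(
    list(model = best$model, trace = best_trace, best_restart = best_restart,
         best_score = best$score, restarts_done = config$restarts,
         config = config, task = task),
    class = "tract_search"
  )
}

search_targets <- function(rows, task) {
  if (task == "regression") as.numeric(rows$bmi)
  else ifelse(rows$group == "OB", 1, -1)
}

# One restart of the add/exclude search; RNG state is already seeded.
one_restart <- function(candidates, fit_score, config, max_size) {
  seed_feat <- sample(candidates, 1L)
  inc <- fit_score(seed_feat)
  steps <- list(step_row(1L, "add", 1L, seed_feat, inc))

  # sweep one phase at level k; returns an accepted fit or NULL
  sweep_level <- function(pool, k, base_features, action) {
    if (length(pool) < k) return(NULL)
    subsets <- if (config$full_sweep) {
      cols <- combn(pool, k, simplify = FALSE)
      sample(cols)
    } else {
      shuffled <- sample(pool)
      n_sub <- length(shuffled) %/% k
      purrr::map(seq_len(n_sub),
                 function(i) shuffled[((i - 1L) * k + 1L):(i * k)])
    }
    for (s in subsets) {
      feats <- if (action == "add") c(base_features, s)
      else setdiff(base_features, s)
      if (length(feats) > max_size || length(feats) == 0L) next
      cand <- fit_score(feats)
      if (cand$score$mean_score > inc$score$mean_score) {
        return(list(fit = cand, subset = s))
      }
    }
    NULL
  }

  repeat {
    accepted <- FALSE
    for (k in seq_len(config$k_max)) {
      hit <- sweep_level(setdiff(candidates, inc$model$features), k,
                         inc$model$features, "add")
      if (!is.null(hit)) {
        inc <- hit$fit
        steps[[length(steps) + 1L]] <-
          step_row(length(steps) + 1L, "add", k, hit$subset, inc)
        accepted <- TRUE
        break
      }
    }
    if (accepted) next
    for (k in seq_len(config$k_max)) {
      hit <- sweep_level(inc$model$features, k, inc$model$features, "exclude")
      if (!is.null(hit)) {
        inc <- hit$fit
        steps[[length(steps) + 1L]] <-
          step_row(length(steps) + 1L, "exclude", k, hit$subset, inc)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  list(model = inc$model, score = inc$score, trace = dplyr::bind_rows(steps))
}

step_row <- function(step, action, k, features, fit) {
  tibble::tibble(
    step = step, action = action, k = as.integer(k),
    features = paste(features, collapse = ";"),
    m = length(fit$model$features),
    train_score = fit$score$train_score,
    val_score = fit$score$val_score,
    mean_score = fit$score$mean_score
  )
}

#' @export
print.tract_search <- function(x, ...) {
  cat(sprintf("<tract_search> %s: best mean score %.4f (restart %d of %d), %d feature(s)\n",
              x$task, x$best_score$mean_score, x$best_restart,
              x$restarts_done, length(x$model$features)))
  invisible(x)
}

#' @rdname run_search
#' @param x,object A `tract_search`.
#' @param ... Unused.
#' @method tidy tract_search
#' @export
tidy.tract_search <- function(x, ...) x$trace

#' @rdname run_search
#' @method glance tract_search
#' @export
glance.tract_search <- function(x, ...) {
  tibble::tibble(task = x$task, n_features = length(x$model$features),
                 n_steps = nrow(x$trace), best_restart = x$best_restart,
                 restarts = x$restarts_done,
                 train_score = x$best_score$train_score,
                 val_score = x$best_score$val_score,
                 mean_score = x$best_score$mean_score)
}

#' Plot the search trace
#'
#' Step-wise model size and train/validation/mean score of the winning
#' restart — the familiar monotone staircase of the stepwise search.
#'
#' @param object A `tract_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tract_search
#' @export
autoplot.tract_search <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("train_score", "val_score", "mean_score"),
                              names_to = "series", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$score,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Step", y = "Score",
                  title = sprintf("Search trace (%s), final model size %d",
                                  object$task, length(object$model$features))) +
    ggplot2::theme_minimal()
}

#' Serialize a search result
#'
#' The model goes to JSON (features, coefficients, intercept, task, search
#' provenance); the trace goes to CSV for plotting step curves.
#'
#' @param search A `tract_search`.
#' @param model_path JSON path (or `NULL`).
#' @param trace_path CSV path (or `NULL`).
#' @export
write_search <- function(search, model_path, trace_path = NULL) {
  if (!is.null(model_path)) {
    jsonlite::write_json(
      list(task = search$task, features = search$model$features,
           coefficients = unname(search$model$coefficients),
           intercept = search$model$intercept,
           best_restart = search$best_restart,
           restarts = search$restarts_done,
           seed = search$config$seed, k_max = search$config$k_max,
           train_score = search$best_score$train_score,
           val_score = search$best_score$val_score,
           mean_score = search$best_score$mean_score),
      model_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(trace_path)) {
    readr::write_csv(search$trace, trace_path, progress = FALSE)
  }
  invisible(search)
}

#' @rdname write_search
#' @param path JSON path written by `write_search()`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  features <- as.character(x$features %||% character())
  structure(
    list(task = x$task, features = features,
         coefficients = setNames(as.numeric(x$coefficients %||% numeric()),
                                 features),
         intercept = as.numeric(x$intercept)),
    class = "tract_model"
  )
}
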