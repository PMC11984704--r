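#' Stratified training/validation/testing split
#'
#' Partitions the cohort into training, validation and testing subsets with
#' an approximately homogeneous BMI distribution: within each integer-BMI
#' stratum of size c, floor(c/2) subjects go to training and the remainder
#' is split as evenly as possible between validation and testing (the 2:1
#' rule). Odd-stratum remainders are then assigned by a seeded random draw,
#' constrained so the global sizes are hit exactly; for size triples that
#' cannot satisfy both the stratum rule and the global sizes, a randomized
#' repair pass relaxes the stratum rule. Real-valued BMI is rounded to the
#' nearest integer for stratification only.
#'
#' @param subjects Tibble with `subject_id` and `bmi`.
#' @param sizes Integer triple `(train, val, test)`, summing to the cohort
#'   size; default `c(80, 40, 40)`.
#' @param seed Integer seed; the split is deterministic given it.
#' @return An object of class `cohort_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `sizes`, `seed`.
#' @examples
#' subj <- tibble::tibble(subject_id = sprintf("s%02d", 1:8),
#'                        bmi = c(20, 20, 20, 20, 30, 30, 30, 30))
#' stratified_split(subj, sizes = c(4, 2, 2), seed = 1)
#' @export
stratified_split <- function(subjects, sizes = c(80L, 40L, 40L), seed = 1L) {
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("subject_id", "bmi") %in% names(subjects)))
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || sum(sizes) != nrow(subjects) || any(sizes < 0)) {
    abort("`sizes` must be a triple of non-negative counts summing to the cohort size.",
          class = "fatract_input_error")
  }
  ids <- as.character(subjects$subject_id)
  stratum <- as.integer(round(subjects$bmi))

  assign <- local_seed(seed, {
    strata <- sort(unique(stratum))
    counts <- vapply(strata, function(b) sum(stratum == b), integer(1))

    # phase 1: every stratum gives floor(c/2) to train; the train shortfall
    # is covered by bumping randomly chosen odd strata to ceil(c/2)
    n_tr <- counts %/% 2L
    t_extra <- sizes[1] - sum(n_tr)
    odd <- which(counts %% 2L == 1L)
    feasible <- t_extra >= 0L && t_extra <= length(odd)
    if (feasible) {
      bump <- odd[sample.int(length(odd))][seq_len(t_extra)]
      n_tr[bump] <- n_tr[bump] + 1L
      # phase 2: split each remainder near-evenly; strata with an odd
      # remainder are randomly chosen to give the extra subject to val
      rest <- counts - n_tr
      n_val <- rest %/% 2L
      v_extra <- sizes[2] - sum(n_val)
      odd_rest <- which(rest %% 2L == 1L)
      feasible <- v_extra >= 0L && v_extra <= length(odd_rest)
      if (feasible) {
        vbump <- odd_rest[sample.int(length(odd_rest))][seq_len(v_extra)]
        n_val[vbump] <- n_val[vbump] + 1L
      }
    }

    lab <- setNames(rep(NA_character_, length(ids)), ids)
    if (feasible) {
      for (i in seq_along(strata)) {
        members <- sample(ids[stratum == strata[i]])
        lab[members] <- rep(c("train", "val", "test"),
                            c(n_tr[i], n_val[i],
                              counts[i] - n_tr[i] - n_val[i]))
      }
    } else {
      # size triples incompatible with the stratum rule: start from the
      # plain 2:1:1 allocation and repair by random moves
      for (i in seq_along(strata)) {
        members <- sample(ids[stratum == strata[i]])
        r <- counts[i] - counts[i] %/% 2L
        lab[members] <- rep(c("train", "val", "test"),
                            c(counts[i] %/% 2L, ceiling(r / 2), floor(r / 2)))
      }
      target <- c(train = sizes[1], val = sizes[2], test = sizes[3])
      repeat {
        excess <- c(train = sum(lab == "train"), val = sum(lab == "val"),
                    test = sum(lab == "test")) - target
        if (all(excess == 0L)) break
        from <- names(excess)[which.max(excess)]
        to <- names(excess)[which.min(excess)]
        mv <- sample(names(lab)[lab == from], 1L)
        lab[mv] <- to
      }
    }
    lab
  })

  structure(
    list(train_ids = ids[assign[ids] == "train"],
         val_ids = ids[assign[ids] == "val"],
         test_ids = ids[assign[ids] == "test"],
         sizes = sizes, seed = as.integer(seed)),
    class = "cohort_split"
  )
}

# Evaluate `expr` under a temporary RNG state so package functions do not
# perturb the caller's random stream.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' @rdname stratified_split
#' @param x A `cohort_split`.
#' @param ... Unused.
#' @method tidy cohort_split
#' @export
tidy.cohort_split <- function(x, ...) {
  tibble::tibble(
    subject_id = c(x$train_ids, x$val_ids, x$test_ids),
    subset = rep(c("train", "val", "test"),
                 c(length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  )
}

#' Serialize a cohort split as JSON
#'
#' @param split A `cohort_split`.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, sizes = split$sizes, train_ids = split$train_ids,
         val_ids = split$val_ids, test_ids = split$test_ids),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 val_ids = as.character(x$val_ids),
                 test_ids = as.character(x$test_ids),
                 sizes = as.integer(x$sizes), seed = as.integer(x$seed)),
            class = "cohort_split")
}

# rows of `matrix` belonging to one subset, in split order
split_rows <- function(matrix, split, subset = c("train", "val", "test")) {
  subset <- match.arg(subset)
  ids <- switch(subset, train = split$train_ids, val = split$val_ids,
                test = split$test_ids)
  matrix[match(ids, matrix$subject_id), , drop = FALSE]
}
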