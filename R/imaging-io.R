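#' FA volumes and label atlases
#'
#' `fa_volume()` wraps a 3D grid of fractional-anisotropy values;
#' `atlas_volume()` wraps a 3D integer label grid together with its label
#' table (a tibble with columns `label` and `tract_name`). Both are plain
#' lists carrying the voxel array, so they compose with base array tools.
#' FA is dimensionless and every finite voxel must lie in \[0, 1\] (a small
#' tolerance absorbs floating-point storage error; offending volumes are
#' rejected). Non-finite voxels are legal — registration padding produces
#' NaNs — and are treated as background downstream.
#'
#' @param voxels 3D numeric array of FA values.
#' @param subject_id Subject identifier carried along with the volume.
#' @param labels 3D array of non-negative integer labels; 0 is background.
#' @param label_table Tibble or data frame with columns `label` (positive
#'   integer) and `tract_name` (character). Every nonzero label present in
#'   `labels` must appear in the table.
#' @return An object of class `fa_volume` or `atlas_volume`.
#' @examples
#' vol <- fa_volume(array(0.5, c(4, 4, 4)), subject_id = "sub-001")
#' atl <- atlas_volume(array(c(0L, 1L), c(4, 4, 4)),
#'                     tibble::tibble(label = 1L, tract_name = "toy tract"))
#' length(extract_tract_voxels(vol, atl, 1L))
#' @export
fa_volume <- function(voxels, subject_id = NA_character_) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.", class = "fatract_format_error")
  }
  storage.mode(voxels) <- "double"
  check_fa_range(voxels)
  structure(
    list(voxels = voxels, shape = dim(voxels),
         subject_id = as.character(subject_id)),
    class = "fa_volume"
  )
}

# FA must lie in [0,1]; tolerance 1e-5 absorbs storage rounding only.
check_fa_range <- function(voxels, tol = 1e-5) {
  finite <- voxels[is.finite(voxels)]
  if (length(finite) && (min(finite) < -tol || max(finite) > 1 + tol)) {
    abort(
      sprintf("FA values outside [0, 1] beyond tolerance (range %.4g..%.4g).",
              min(finite), max(finite)),
      class = "fatract_format_error"
    )
  }
  invisible(voxels)
}

#' @rdname fa_volume
#' @export
atlas_volume <- function(labels, label_table) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D array.", class = "fatract_format_error")
  }
  if (any(!is.finite(labels)) || any(labels != round(labels)) || any(labels < 0)) {
    abort("Atlas voxels must be non-negative integers.",
          class = "fatract_format_error")
  }
  storage.mode(labels) <- "integer"
  label_table <- tibble::as_tibble(label_table)
  if (!all(c("label", "tract_name") %in% names(label_table)) ||
      nrow(label_table) < 1L) {
    abort("`label_table` needs >= 1 row with columns `label`, `tract_name`.",
          class = "fatract_format_error")
  }
  label_table$label <- as.integer(label_table$label)
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, label_table$label)
  if (length(missing)) {
    abort(sprintf("Atlas labels missing from label table: %s.",
                  paste(missing, collapse = ", ")),
          class = "fatract_format_error")
  }
  structure(
    list(labels = labels, label_table = label_table, shape = dim(labels)),
    class = "atlas_volume"
  )
}

#' @export
print.fa_volume <- function(x, ...) {
  cat(sprintf("<fa_volume> subject %s, %s voxels\n", x$subject_id,
              paste(x$shape, collapse = " x ")))
  invisible(x)
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("<atlas_volume> %s voxels, %d tracts\n",
              paste(x$shape, collapse = " x "), nrow(x$label_table)))
  invisible(x)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()].
#' `read_fa_volume()` enforces 3D data and the \[0, 1\] FA range;
#' `read_atlas()` additionally requires integer voxels and a label table
#' covering every nonzero label. Affine metadata is carried opaquely by
#' RNifti; the package compares volumes by shape only and never resamples —
#' an FA/atlas grid mismatch is an error, not an implicit interpolation.
#'
#' @param path Path to a 3D NIfTI file (`.nii` or `.nii.gz`).
#' @param subject_id Optional subject id; defaults to the file stem.
#' @param label_table_path Path to a two-column TSV `label<TAB>tract_name`
#'   (header optional).
#' @return `read_fa_volume()` an [fa_volume()]; `read_atlas()` an
#'   [atlas_volume()].
#' @export
read_fa_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "fatract_format_error")
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort(sprintf("Expected a 3D volume, got %d dimensions.",
                  length(dim(img))),
          class = "fatract_format_error")
  }
  arr <- array(as.numeric(img), dim = dim(img))  # drop NIfTI attributes
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  fa_volume(arr, subject_id = subject_id)
}

#' @rdname read_fa_volume
#' @param volume An [fa_volume()] (or [atlas_volume()] for `write_atlas()`).
#' @export
write_fa_volume <- function(volume, path) {
  stopifnot(inherits(volume, "fa_volume"))
  RNifti::writeNifti(RNifti::asNifti(volume$voxels), path, datatype = "double")
  invisible(path)
}

#' @rdname read_fa_volume
#' @export
read_atlas <- function(path, label_table_path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "fatract_format_error")
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort("Atlas volume must be 3D.", class = "fatract_format_error")
  }
  arr <- array(as.numeric(img), dim = dim(img))
  atlas_volume(arr, read_label_table(label_table_path))
}

#' @rdname read_fa_volume
#' @export
write_atlas <- function(volume, path) {
  stopifnot(inherits(volume, "atlas_volume"))
  RNifti::writeNifti(RNifti::asNifti(volume$labels), path, datatype = "int")
  invisible(path)
}

#' @rdname read_fa_volume
#' @export
read_label_table <- function(label_table_path) {
  raw <- readr::read_tsv(label_table_path, col_names = FALSE,
                         col_types = "cc", progress = FALSE)
  if (ncol(raw) != 2L) {
    abort("Label table must have exactly two columns.",
          class = "fatract_format_error")
  }
  # header row optional: drop it when the first field is not numeric
  if (suppressWarnings(is.na(as.integer(raw[[1]][1])))) raw <- raw[-1, ]
  tibble::tibble(label = as.integer(raw[[1]]), tract_name = raw[[2]])
}

#' The shipped ICBM-DTI-81 white-matter label table
#'
#' The 50-tract ICBM-DTI-81 parcellation of deep white matter in MNI152
#' space, as a `label` / `tract_name` tibble. These names define the default
#' tract universe for the synthetic generator and the biomarker matrices.
#'
#' @return A 50-row tibble.
#' @examples
#' nrow(icbm_dti_81_labels())
#' @export
icbm_dti_81_labels <- function() {
  read_label_table(system.file("extdata", "icbm_dti_81_labels.tsv",
                               package = "fatract", mustWork = TRUE))
}

#' Extract the FA values of one tract
#'
#' Returns the FA values at exactly the voxels carrying `label` in the
#' atlas, dropping non-finite values (registration padding). Order follows
#' the array's column-major storage, so it is deterministic for fixed input.
#'
#' @param fa An [fa_volume()].
#' @param atlas An [atlas_volume()] on the same grid.
#' @param label Integer tract label present in the atlas label table.
#' @return Numeric vector (possibly empty when the label does not occur).
#' @export
extract_tract_voxels <- function(fa, atlas, label) {
  stopifnot(inherits(fa, "fa_volume"), inherits(atlas, "atlas_volume"))
  if (!identical(fa$shape, atlas$shape)) {
    abort(sprintf("FA grid %s does not match atlas grid %s.",
                  paste(fa$shape, collapse = "x"),
                  paste(atlas$shape, collapse = "x")),
          class = "fatract_shape_error")
  }
  label <- as.integer(label)
  if (!label %in% atlas$label_table$label) {
    abort(sprintf("Label %d is not in the atlas label table.", label),
          class = "fatract_label_error")
  }
  vals <- fa$voxels[atlas$labels == label]
  vals[is.finite(vals)]
}
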